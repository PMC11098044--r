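# End-to-end orchestration: simulate -> qc -> connectivity -> graph ->
# metrics -> hdi -> stats as one reproducible run with a manifest, plus the
# small worked-example fixture bundle used in tests and documentation.

#' Default pipeline configuration
#'
#' Every constant of the analysis is visible and overridable here: the 5%
#' cost, the d4 filter with 4 levels and the 0.032-0.065 Hz analysis band,
#' the 5 mm / 3 SD / 10% quality-control thresholds, the cohort structure
#' (20 HS, 9 MCS-like at disruption strength 0.5, 15 C-like at 0.2) and
#' all seeds. The configuration round-trips losslessly through YAML.
#'
#' @param ... overrides of the defaults, by name.
#' @return a named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    n_regions = 107,
    n_hubs = 10,
    cost = 0.05,
    wavelet_filter = "d4",
    n_levels = 4,
    target_band = c(0.032, 0.065),
    sampling_interval = 2,
    n_volumes = 400,
    clustering_variant = "coefficient",
    edge_corr = 0.3,
    cohort_sizes = c(HS = 20, MCS = 9, C = 15),
    disruption_strengths = c(HS = 0, MCS = 0.5, C = 0.2),
    motion_mm_threshold = 5,
    signal_sd_threshold = 3,
    max_outlier_fraction = 0.10,
    seed = 1L,
    outdir = "hdinet_run"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown configuration fields: %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param cfg configuration list from [pipelineConfig()].
#' @param path file path.
#' @return the path (write) or the configuration list (read).
#' @export
writeConfigYAML <- function(cfg, path) {
  # named vectors must become maps, or YAML drops the group names
  cfg$cohort_sizes <- as.list(cfg$cohort_sizes)
  cfg$disruption_strengths <- as.list(cfg$disruption_strengths)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cohort_sizes <- unlist(cfg$cohort_sizes)
  cfg$disruption_strengths <- unlist(cfg$disruption_strengths)
  cfg$target_band <- as.numeric(unlist(cfg$target_band))
  do.call(pipelineConfig, cfg)
}

#' Run the full synthetic-cohort analysis
#'
#' Generates a hub-structured template and one graph per subject (healthy
#' subjects keep the template topology; patient groups are hub-disrupted at
#' their group strength), simulates band-limited BOLD series per subject,
#' runs quality control and nuisance regression, estimates the wavelet
#' correlation matrix at the configured band, thresholds to the configured
#' cost, computes nodal metrics and HDI against the healthy reference
#' (leave-one-out for its members), and runs the group statistics. Every
#' artifact is written under `cfg$outdir` together with a manifest of
#' inputs, seeds, checksums and per-stage counts. Identical configurations
#' produce identical checksums.
#'
#' @param cfg configuration list from [pipelineConfig()].
#' @return the manifest, invisibly (a named list).
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  t0 <- Sys.time()

  # --- simulate ---------------------------------------------------------
  tpl <- makeTemplateGraph(
    cfg$n_regions, cfg$n_hubs,
    costToEdgeCount(cfg$n_regions, cfg$cost),
    seed = cfg$seed
  )
  cohort <- simulateGraphCohort(
    tpl,
    sizes = cfg$cohort_sizes,
    strengths = cfg$disruption_strengths, seed = cfg$seed + 1L
  )
  writeGraphTSV(tpl, file.path(cfg$outdir, "template.tsv"))
  level <- selectScale(cfg$sampling_interval, cfg$target_band)
  state_of <- function(sid) sub("[0-9]+$", "", sid)

  subjects <- list()
  flagged <- integer(0)
  kept <- character(0)
  for (sid in names(cohort)) {
    sseed <- cfg$seed + 1000L + length(subjects)
    covm <- graphToCovariance(cohort[[sid]], edgeCorr = cfg$edge_corr)
    ts <- simulateBold(covm,
      nVolumes = cfg$n_volumes,
      samplingInterval = cfg$sampling_interval,
      targetScale = level, seed = sseed
    )
    art <- simulateMotionArtifacts(cfg$n_volumes, seed = sseed + 1L)

    # --- qc -------------------------------------------------------------
    gs <- rowMeans(tsMatrix(ts))
    mask <- flagOutlierVolumes(art$motion, gs,
      motionMmThreshold = cfg$motion_mm_threshold,
      signalSdThreshold = cfg$signal_sd_threshold
    )
    flagged[sid] <- sum(mask)
    if (!rejectDataset(mask, cfg$max_outlier_fraction)) next
    kept <- c(kept, sid)
    clean <- regressNuisance(ts, art$motion, mask)

    # --- connectivity / graph / metrics --------------------------------
    cm <- waveletCorrelationMatrix(clean,
      level = level,
      filter = cfg$wavelet_filter
    )
    bg <- thresholdToCost(cm, cost = cfg$cost, provenance = sid)
    subjects[[sid]] <- nodalMetrics(bg, cfg$clustering_variant)
    writeGraphTSV(bg, file.path(cfg$outdir, sprintf("graph_%s.tsv", sid)))
  }

  # --- hdi --------------------------------------------------------------
  hs <- kept[state_of(kept) == "HS"]
  if (length(hs) < 2) stopf("fewer than 2 healthy subjects survived QC")
  hdi_tab <- hdiCohort(subjects, hs, looForReferenceMembers = TRUE)
  hdi_tab$state <- state_of(hdi_tab$subject)
  hdi_tab$timepoint <- 1L
  writeCohortCSV(
    data.frame(
      subject = hdi_tab$subject, timepoint = hdi_tab$timepoint,
      state = hdi_tab$state, hdi_metric = hdi_tab$metric,
      hdi_value = hdi_tab$hdi
    ),
    file.path(cfg$outdir, "hdi.csv")
  )

  # --- stats ------------------------------------------------------------
  tests <- list()
  for (met in unique(hdi_tab$metric)) {
    sub <- hdi_tab[hdi_tab$metric == met, ]
    groups <- split(sub$hdi, sub$state)
    if (all(c("MCS", "C") %in% names(groups))) {
      tests[[paste0("mann_whitney_", met)]] <-
        mannWhitney(groups$MCS, groups$C)
    }
    if (length(groups) >= 2) {
      tests[[paste0("kruskal_wallis_", met)]] <- kruskalWallis(groups)
    }
  }
  jsonlite::write_json(tests, file.path(cfg$outdir, "tests.json"),
    auto_unbox = TRUE, digits = NA
  )

  files <- list.files(cfg$outdir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest$stages <- list(
    simulate = list(
      n_subjects = length(cohort),
      template_nodes = nNodes(tpl), template_edges = edgeCount(tpl)
    ),
    qc = list(
      volumes_flagged = as.list(flagged),
      datasets_kept = length(kept),
      datasets_rejected = length(cohort) - length(kept)
    ),
    graph = list(
      wavelet_level = level,
      edges_per_graph = costToEdgeCount(cfg$n_regions, cfg$cost)
    ),
    hdi = list(n_estimates = nrow(hdi_tab)),
    stats = list(tests = names(tests))
  )
  manifest$checksums <- as.list(tools::md5sum(sort(files)))
  names(manifest$checksums) <- basename(sort(files))
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Write the small worked-example fixture bundle
#'
#' Emits, under `outdir`: the 3-region correlation matrix whose spanning
#' tree is resolvable by hand (|r| = 0.9 / 0.5 / 0.1), the 4-node reference
#' / reversed-profile HDI example (slope -2), a toy template graph, a tiny
#' 4 x 4 x 2 x 10 NIfTI phantom with a 2-parcel atlas and grey-matter
#' probability map, and a seeded motion trace. Regenerates identically for
#' the same seed.
#'
#' @param seed integer seed.
#' @param outdir writable output directory.
#' @return invisibly, the vector of files written.
#' @export
makeFixtures <- function(seed = 1L, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  m3 <- diag(3)
  m3[1, 2] <- m3[2, 1] <- 0.9
  m3[1, 3] <- m3[3, 1] <- 0.5
  m3[2, 3] <- m3[3, 2] <- 0.1
  dimnames(m3) <- list(paste0("r", 1:3), paste0("r", 1:3))
  paths <- c(paths, writeCorrelationTSV(m3, file.path(outdir, "mst3.tsv")))

  hdi_ex <- data.frame(reference = c(1, 2, 3, 4), individual = c(4, 3, 2, 1))
  p <- file.path(outdir, "hdi_example.csv")
  utils::write.table(hdi_ex, p, sep = ",", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  tpl <- makeTemplateGraph(20, 3, 40, seed = seed)
  paths <- c(paths, writeGraphTSV(tpl, file.path(outdir, "template20.tsv")))

  art <- simulateMotionArtifacts(100, spikeTimes = c(50L), seed = seed)
  paths <- c(paths, writeMotionTSV(art$motion, file.path(outdir, "motion.tsv")))

  # NIfTI phantom: 4 x 4 x 2 grid, 2 parcels, 10 volumes
  atlas <- array(0L, c(4, 4, 2))
  atlas[1:2, , ] <- 1L
  atlas[3:4, , ] <- 2L
  gm <- array(0.8, c(4, 4, 2))
  bold <- with_seed(seed, array(rnorm(4 * 4 * 2 * 10), c(4, 4, 2, 10)))
  f_atlas <- file.path(outdir, "phantom_atlas.nii.gz")
  f_gm <- file.path(outdir, "phantom_gm.nii.gz")
  f_bold <- file.path(outdir, "phantom_bold.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas), f_atlas)
  RNifti::writeNifti(RNifti::asNifti(gm), f_gm)
  RNifti::writeNifti(RNifti::asNifti(bold), f_bold)
  paths <- c(paths, f_atlas, f_gm, f_bold)

  invisible(paths)
}
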