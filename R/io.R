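# Plain-text serialisation of the pipeline artifacts: regional series and
# motion traces as TSV, correlation matrices as labelled square TSV, graphs
# as commented edge lists, cohort/HDI tables as CSV.

#' Write regional time series as TSV
#'
#' Header row of region labels, one row per volume. The sampling interval
#' travels in a `# sampling_interval=` comment line.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param path output file.
#' @export
writeTimeSeriesTSV <- function(ts, path) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_interval=%.10g", ts@samplingInterval), con)
  writeLines(paste(ts@regionLabels, collapse = "\t"), con)
  utils::write.table(ts@data, con,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read regional time series from TSV
#' @param path file written by [writeTimeSeriesTSV()].
#' @param samplingInterval override; default is taken from the comment
#'   header (or 2 if absent).
#' @return a [RegionalTimeSeries-class].
#' @export
readTimeSeriesTSV <- function(path, samplingInterval = NULL) {
  lines <- readLines(path)
  meta <- grep("^# sampling_interval=", lines, value = TRUE)
  if (is.null(samplingInterval)) {
    samplingInterval <- if (length(meta)) {
      as.numeric(sub("^# sampling_interval=", "", meta[1]))
    } else {
      2
    }
  }
  body <- lines[!startsWith(lines, "#")]
  labels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  dat <- utils::read.table(
    text = paste(body[-1], collapse = "\n"),
    sep = "\t", header = FALSE
  )
  new("RegionalTimeSeries",
    data = as.matrix(dat), regionLabels = labels,
    samplingInterval = samplingInterval
  )
}

#' Write a motion trace as 6-column TSV
#' @param motion volumes x 6 matrix.
#' @param path output file.
#' @export
writeMotionTSV <- function(motion, path) {
  motion <- as.matrix(motion)
  stopifnot(ncol(motion) == 6)
  utils::write.table(motion, path,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a motion trace (6-column whitespace/TSV, SPM rp_*.txt dialect)
#' @param path input file.
#' @return volumes x 6 numeric matrix.
#' @export
readMotionTSV <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stopf("motion trace must have 6 columns, found %d", ncol(m))
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Write a correlation matrix as labelled square TSV
#' @param m a [CorrelationMatrix-class] or plain matrix.
#' @param path output file.
#' @export
writeCorrelationTSV <- function(m, path) {
  if (is(m, "CorrelationMatrix")) m <- m@matrix
  utils::write.table(m, path,
    sep = "\t", quote = FALSE,
    row.names = TRUE, col.names = NA
  )
  invisible(path)
}

#' Read a correlation matrix from labelled square TSV
#' @param path input file.
#' @return numeric matrix with dimnames.
#' @export
readCorrelationTSV <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1))
}

#' Write a graph as an edge-list TSV
#'
#' `# n_nodes=` (and optionally `# cost=`) header lines, then one
#' `u<TAB>v` pair per line with `u < v`, 0-based node indices.
#'
#' @param g a [BrainGraph-class], [TemplateNetwork-class] or igraph object.
#' @param path output file.
#' @export
writeGraphTSV <- function(g, path) {
  ig <- .as_igraph(g)
  el <- igraph::as_edgelist(ig, names = FALSE)
  el <- t(apply(el, 1, sort)) - 1
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d", igraph::vcount(ig)), con)
  if (is(g, "BrainGraph")) {
    writeLines(sprintf("# cost=%.10g", g@cost), con)
  }
  utils::write.table(el, con,
    sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read an edge-list TSV graph
#' @param path file written by [writeGraphTSV()].
#' @return an igraph object.
#' @export
readGraphTSV <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# n_nodes=", lines, value = TRUE)
  if (!length(meta)) stopf("missing '# n_nodes=' header in %s", path)
  n <- as.integer(sub("^# n_nodes=", "", meta[1]))
  body <- lines[!startsWith(lines, "#")]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(body)) {
    el <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t")
    g <- igraph::add_edges(g, t(as.matrix(el) + 1))
  }
  g
}

#' Write a cohort/HDI table as CSV
#' @param records data.frame with columns subject, timepoint, state,
#'   hdi_metric, hdi_value.
#' @param path output file.
#' @export
writeCohortCSV <- function(records, path) {
  utils::write.table(records, path,
    sep = ",", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' Read a cohort/HDI table from CSV
#' @param path input file.
#' @return data.frame.
#' @export
readCohortCSV <- function(path) {
  utils::read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
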