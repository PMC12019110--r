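# All TSV writers use 17 significant digits so doubles round-trip losslessly
# through text.
.fmt <- function(x) sprintf("%.17g", x)

#' Read multi-trial time series from delimited text
#'
#' Accepts either one file per trial (frames as rows, nodes as columns,
#' header row of node labels) or a single file with a trial-ID column. The
#' delimiter is auto-detected from the extension (.csv = comma, otherwise
#' tab).
#'
#' @param paths character vector of file paths (one per trial), or a single
#'   path when \code{trialColumn} is given.
#' @param samplingInterval seconds per frame.
#' @param trialColumn name of the trial-ID column for single-file input, or
#'   NULL.
#' @return A [RoiTimeSeriesSet-class].
#' @export
readTimeSeriesTSV <- function(paths, samplingInterval = 0.72,
                              trialColumn = NULL) {
  readOne <- function(p) {
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE)
  }
  if (!is.null(trialColumn)) {
    if (length(paths) != 1L)
      stop("trialColumn implies a single input file")
    df <- readOne(paths)
    if (!trialColumn %in% names(df))
      stop(sprintf("trial column '%s' not found", trialColumn))
    ids <- df[[trialColumn]]
    mats <- lapply(split(df[setdiff(names(df), trialColumn)], ids),
                   as.matrix)
  } else {
    mats <- lapply(paths, function(p) as.matrix(readOne(p)))
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all trials must have identical frame and node counts")
  arr <- array(unlist(mats), c(dim(mats[[1L]]), length(mats)))
  RoiTimeSeriesSet(arr, nodeLabels = colnames(mats[[1L]]),
                   samplingInterval = samplingInterval)
}

#' Write multi-trial time series as one TSV per trial
#'
#' @param ts a [RoiTimeSeriesSet-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix; files are named
#'   \code{<prefix>_trial<k>.tsv}.
#' @return invisibly, the written paths.
#' @export
writeTimeSeriesTSV <- function(ts, dir, prefix = "timeseries") {
  stopifnot(is(ts, "RoiTimeSeriesSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nTrials(ts))
  for (tr in seq_len(nTrials(ts))) {
    m <- ts@values[, , tr]
    if (!is.matrix(m)) m <- matrix(m, ncol = nNodes(ts))
    df <- as.data.frame(apply(m, 2L, .fmt))
    names(df) <- ts@nodeLabels
    paths[tr] <- file.path(dir, sprintf("%s_trial%03d.tsv", prefix, tr))
    utils::write.table(df, paths[tr], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a weighted directed network from delimited text
#'
#' Auto-detects the layout: a square labeled adjacency matrix (absent edge
#' = 0), or an edge list with columns source, target, weight (and optional
#' p_value). Override with \code{format}.
#'
#' @param path input file (TSV; .csv uses commas).
#' @param format "auto", "adjacency" or "edgelist".
#' @return A [DirectedNetwork-class].
#' @export
readNetworkTSV <- function(path, format = c("auto", "adjacency",
                                            "edgelist")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "auto") {
    format <- if (all(c("source", "target", "weight") %in% names(df)))
      "edgelist" else "adjacency"
  }
  if (format == "edgelist") {
    nodes <- sort(unique(c(df$source, df$target)))
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    P <- matrix(NA_real_, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(df))) {
      W[df$source[i], df$target[i]] <- df$weight[i]
      if ("p_value" %in% names(df)) P[df$source[i], df$target[i]] <-
          df$p_value[i]
    }
    return(directedNetwork(W, nodes = nodes, pvalues = P))
  }
  lab <- as.character(df[[1L]])
  W <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(W) != ncol(W) || !identical(lab, colnames(W)))
    stop("adjacency input must be square with matching row/column labels")
  rownames(W) <- lab
  storage.mode(W) <- "double"
  directedNetwork(W, nodes = lab)
}

#' Write a network as a labeled adjacency matrix TSV
#'
#' @param net a [DirectedNetwork-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNetworkTSV <- function(net, path) {
  stopifnot(is(net, "DirectedNetwork"))
  W <- net@weights
  df <- data.frame(node = net@nodes, apply(W, 2L, .fmt),
                   check.names = FALSE)
  names(df) <- c("node", net@nodes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge-list TSV (source, target, weight, p_value)
#'
#' @param net a [DirectedNetwork-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeEdgeListTSV <- function(net, path) {
  el <- edgeList(net)
  el$weight <- .fmt(el$weight)
  el$p_value <- ifelse(is.na(el$p_value), "NA", .fmt(el$p_value))
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complex decomposition as TSV
#'
#' Columns: complex_id, mc_weight, parent_id, members (comma-joined),
#' n_members.
#'
#' @param decomp a [ComplexDecomposition-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeComplexesTSV <- function(decomp, path) {
  tab <- complexTable(decomp)
  tab$mc_weight <- .fmt(tab$mc_weight)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-node metrics as TSV
#'
#' @param metrics named list of [CorenessMap-class] / [NodeMetricMap-class] /
#'   named numeric vectors sharing one node set; names become columns.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeNodeMetricsTSV <- function(metrics, path) {
  vals <- lapply(metrics, function(m)
    if (is.numeric(m)) m else m@values)
  nodes <- names(vals[[1L]])
  df <- data.frame(node = nodes, check.names = FALSE)
  for (nm in names(vals)) df[[nm]] <- .fmt(vals[[nm]][nodes])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
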