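#' Read a pattern set from a delimited text file
#'
#' One pattern per row; entries are 0/1 integers separated by whitespace or
#' commas.  CRLF and LF line endings are both accepted.  The reader validates
#' binarity and equal row lengths and reports the offending line and field.
#'
#' @param path file path.
#' @param kind pattern kind to record on the result.
#' @return a [pattern_set()].
#' @export
read_patterns <- function(path, kind = "forward") {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no patterns in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("parse error in %s, line %d, field %d: '%s' is not a number",
                   path, i, which(is.na(vals))[1], fields[which(is.na(vals))[1]]))
    bad <- which(!vals %in% c(0, 1))
    if (length(bad))
      stop(sprintf("parse error in %s, line %d, field %d: entry %s is not 0/1",
                   path, i, bad[1], vals[bad[1]]))
    vals
  })
  len <- unique(lengths(rows))
  if (length(len) != 1)
    stop("patterns in ", path, " differ in length: ", paste(len, collapse = ", "))
  pattern_set(do.call(rbind, rows), kind)
}

#' Write a pattern set as delimited text
#'
#' @param ps a `pattern_set` or binary matrix.
#' @param path file path.
#' @export
write_patterns <- function(ps, path) {
  utils::write.table(unclass(ps), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as delimited text with an index header
#'
#' Values are printed with full double precision so that a write/read
#' round-trip is lossless.
#'
#' @param m numeric matrix (e.g. a correlation matrix).
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(seq_len(ncol(m)) - 1L, collapse = "\t"), con)
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("no matrix rows in ", path)
  rows <- lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]]))
  if (anyNA(unlist(rows))) stop("non-numeric entry in ", path)
  do.call(rbind, rows)
}

#' Persist trained synaptic weights as delimited text
#'
#' The matrix is written with one neuron per column and `2 * nSyn + N` rows:
#' the backprojection block on top, then the recurrent block, then the
#' forward block — the orientation in which the synaptic matrix of the model
#' is usually displayed, with each column one dendrite.  Header comment lines
#' record the parameters and seed so a run can be reproduced.
#'
#' @param syn a `synaptic_state`.
#' @param params the `network_params` used.
#' @param path file path.
#' @param seed the seed used for the run (recorded in the header).
#' @export
write_weights <- function(syn, params, path, seed = params$seed) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- unclass(params)
  for (nm in names(p))
    writeLines(sprintf("# %s: %s", nm, p[[nm]]), con)
  writeLines(sprintf("# runSeed: %d", seed), con)
  writeLines(sprintf("# blocks: bp %d, rec %d, comp %d (rows, top to bottom)",
                     ncol(syn$Wbp), ncol(syn$Wrec), ncol(syn$Wcomp)), con)
  m <- t(cbind(syn$Wbp, syn$Wrec, syn$Wcomp))  # rows = synapses, cols = neurons
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read synaptic weights written by [write_weights()]
#'
#' @param path file path.
#' @return list with `syn` (a `synaptic_state`), `header` (named character
#'   vector of the recorded parameters).
#' @export
read_weights <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  header <- stats::setNames(vapply(kv, `[`, character(1), 3),
                            vapply(kv, `[`, character(1), 2))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])))
  W <- t(m)  # back to neurons x synapses
  nSyn <- as.integer(header[["nSyn"]]); N <- as.integer(header[["N"]])
  if (ncol(W) != 2L * nSyn + N)
    stop("weight file has ", ncol(W), " synapse rows; expected ", 2L * nSyn + N)
  syn <- list(Wbp   = W[, seq_len(nSyn), drop = FALSE],
              Wrec  = W[, nSyn + seq_len(N), drop = FALSE],
              Wcomp = W[, nSyn + N + seq_len(nSyn), drop = FALSE])
  class(syn) <- "synaptic_state"
  list(syn = syn, header = header)
}

#' Write a run report as structured text
#'
#' Scalar fields are written as `key: value` lines; the category labels as a
#' comma-separated list.  Correlation matrices and output patterns are large
#' and are written to side files when `matrices = TRUE`.
#'
#' @param report a `run_report`.
#' @param path file path of the summary.
#' @param matrices also write `<path>.inputCorr.tsv` etc.
#' @export
write_run_report <- function(report, path, matrices = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  scalars <- c("seed", "nCategories", "contiguous", "attractorStable",
               "attractorStableLong", "recallCorrect", "meanAbsInputCorr",
               "meanAbsDistinctOutputCorr", "meanAbsDistinctRecallCorr")
  for (nm in scalars)
    writeLines(sprintf("%s: %s", nm,
                       format(report[[nm]], digits = 17, scientific = FALSE)),
               con)
  writeLines(sprintf("categoryLabels: %s",
                     paste(report$categoryLabels, collapse = ",")), con)
  if (matrices) {
    for (nm in c("inputCorr", "outputCorrForward", "outputCorrRecall"))
      if (is.matrix(report[[nm]]))
        write_matrix(report[[nm]], paste0(path, ".", nm, ".tsv"))
  }
  invisible(path)
}

#' Read the scalar fields of a run report written by [write_run_report()]
#'
#' @param path file path.
#' @return named list of scalar values and the category label vector.
#' @export
read_run_report <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+): (.*)$", lines))
  out <- list()
  for (m in kv) {
    key <- m[2]; val <- m[3]
    out[[key]] <- switch(key,
      categoryLabels = as.integer(strsplit(val, ",")[[1]]),
      seed = , nCategories = , recallCorrect = as.integer(val),
      contiguous = , attractorStable = , attractorStableLong = as.logical(val),
      as.numeric(val))
  }
  out
}
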