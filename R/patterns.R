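#' Construct a pattern set
#'
#' A pattern set is a binary matrix with one pattern per row and one input
#' line per column, carrying a `kind` attribute that records what the
#' patterns are used for (`"forward"`, `"backprojection"` or `"output"`).
#'
#' @param x binary matrix (rows = patterns, columns = input lines).
#' @param kind one of `"forward"`, `"backprojection"`, `"output"`.
#' @return an object of class `pattern_set` (a binary matrix).
#' @export
pattern_set <- function(x, kind = c("forward", "backprojection", "output")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (!all(x == 0 | x == 1))
    stop("pattern set entries must all be 0 or 1")
  storage.mode(x) <- "double"
  structure(x, kind = kind, class = c("pattern_set", class(x)))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set: %d %s patterns x %d lines, %s active per pattern>\n",
              nrow(x), attr(x, "kind"), ncol(x),
              paste(unique(rowSums(x)), collapse = "/")))
  invisible(x)
}

#' Shifted overlapping binary patterns
#'
#' Generates `nPatterns` binary patterns of length `nLines`, each with exactly
#' `nActive` active lines.  Pattern `i` (0-based) is active at positions
#' `(i * step + p) mod nLines` for `p = 0 .. nActive - 1`, so consecutive
#' patterns overlap in `nActive - step` lines when `step < nActive`.  Positions
#' wrap circularly, which preserves both the active count and the consecutive
#' overlap for the final patterns.  The default arguments produce the standard
#' training set for the forward inputs: 28 patterns, 20 active of 100 lines,
#' step 3, hence a 17-line overlap between neighbours and a mean absolute
#' pairwise correlation of 0.31.
#'
#' @param nPatterns number of patterns.
#' @param nLines pattern length (number of input lines).
#' @param nActive number of active (rate 1) lines per pattern.
#' @param step shift between consecutive patterns, in lines.
#' @return a `pattern_set` of kind `"forward"`.
#' @seealso [make_orthogonal_patterns()], [make_random_patterns()]
#' @export
make_shifted_patterns <- function(nPatterns = 28L, nLines = 100L,
                                  nActive = 20L, step = 3L) {
  if (nPatterns < 1 || nLines < 1 || nActive < 1 || step < 1)
    stop("nPatterns, nLines, nActive and step must all be positive")
  if (nActive > nLines)
    stop("nActive must not exceed nLines")
  m <- matrix(0, nPatterns, nLines)
  for (i in seq_len(nPatterns) - 1L)
    m[i + 1L, (i * step + 0:(nActive - 1L)) %% nLines + 1L] <- 1
  pattern_set(m, "forward")
}

#' Orthogonal (pairwise disjoint) binary patterns
#'
#' Pattern `i` (0-based) is active at the `nActive` consecutive positions
#' starting at `i * nActive`, so distinct patterns share no active line.  The
#' defaults produce the standard backprojection cue set: 28 patterns, 3 active
#' of 100 lines.
#'
#' @inheritParams make_shifted_patterns
#' @return a `pattern_set` of kind `"backprojection"`.
#' @export
make_orthogonal_patterns <- function(nPatterns = 28L, nLines = 100L,
                                     nActive = 3L) {
  if (nPatterns < 1 || nLines < 1 || nActive < 1)
    stop("nPatterns, nLines and nActive must all be positive")
  if (nPatterns * nActive > nLines)
    stop("cannot place ", nPatterns, " disjoint patterns of ", nActive,
         " lines in ", nLines, " lines")
  m <- matrix(0, nPatterns, nLines)
  for (i in seq_len(nPatterns) - 1L)
    m[i + 1L, i * nActive + 1:nActive] <- 1
  pattern_set(m, "backprojection")
}

#' Random binary patterns of fixed sparseness
#'
#' Each pattern has exactly `round(sparseness * nLines)` active lines drawn
#' uniformly without replacement.  Reproducible for a given `seed`.
#'
#' @inheritParams make_shifted_patterns
#' @param sparseness fraction of active lines, in (0, 1].
#' @param seed integer seed for the pattern draw.
#' @return a `pattern_set` of kind `"forward"`.
#' @export
make_random_patterns <- function(nPatterns, nLines, sparseness, seed) {
  if (sparseness <= 0 || sparseness > 1)
    stop("sparseness must lie in (0, 1]")
  nActive <- round(sparseness * nLines)
  if (nActive < 1)
    stop("sparseness * nLines rounds to zero active lines")
  m <- with_seed(seed, {
    t(vapply(seq_len(nPatterns), function(i) {
      v <- numeric(nLines)
      v[sample.int(nLines, nActive)] <- 1
      v
    }, numeric(nLines)))
  })
  pattern_set(m, "forward")
}

#' Pearson correlation matrix of a pattern set
#'
#' Entry (i, j) is the Pearson correlation between patterns i and j across
#' lines.  Degenerate (constant) patterns have no defined correlation and are
#' rejected.
#'
#' @param ps a `pattern_set` or binary matrix with one pattern per row.
#' @return square symmetric matrix with unit diagonal.
#' @export
correlation_matrix <- function(ps) {
  m <- unclass(ps)
  if (nrow(m) < 2) stop("need at least two patterns")
  v <- apply(m, 1, stats::var)
  if (any(v == 0))
    stop("degenerate (constant) pattern(s) at row(s): ",
         paste(which(v == 0), collapse = ", "))
  cm <- stats::cor(t(m))
  dimnames(cm) <- NULL
  cm
}

#' Mean absolute off-diagonal correlation
#'
#' The summary statistic used to describe how correlated a pattern set is:
#' the arithmetic mean of the absolute values of all off-diagonal entries.
#' For the default shifted forward set this equals 13/42 = 0.3095, printed
#' as 0.31.  The signed counterpart is [mean_offdiag()].
#'
#' @param cm square correlation matrix.
#' @return scalar mean of `|cm[i, j]|` over all `i != j`.
#' @export
mean_abs_offdiag <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("cm must be a square matrix of size >= 2")
  off <- row(cm) != col(cm)
  mean(abs(cm[off]))
}

#' Mean signed off-diagonal correlation
#'
#' @inheritParams mean_abs_offdiag
#' @return scalar mean of `cm[i, j]` over all `i != j`.
#' @export
mean_offdiag <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2)
    stop("cm must be a square matrix of size >= 2")
  off <- row(cm) != col(cm)
  mean(cm[off])
}

#' Number of shared active lines between two binary patterns
#'
#' @param p1,p2 binary vectors of equal length.
#' @return count of positions active in both.
#' @export
overlap <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != length(p2))
    stop("patterns differ in length (", length(p1), " vs ", length(p2), ")")
  sum(p1 * p2)
}

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
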