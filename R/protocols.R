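#' Train a network and measure categorisation, attractor and recall behaviour
#'
#' Runs the full experiment: initialises random weights, trains on the paired
#' pattern sets, then (with frozen weights) tests every forward input alone,
#' runs the free attractor from each forward output, and presents every
#' backprojection cue alone.
#'
#' Category identity of an output is the exact set of active neurons (binary
#' vector equality); category ids are assigned in order of first occurrence.
#' `contiguous` records whether each category's members occupy one contiguous
#' run of the pattern order (allowing a single wrap-around join), the expected
#' outcome when consecutive patterns are the most similar.
#'
#' @param params a [network_params()].
#' @param forward forward `pattern_set`; defaults to the standard 28-pattern
#'   shifted set.
#' @param backproj backprojection `pattern_set`; defaults to the standard
#'   28-pattern orthogonal cue set.
#' @param seed integer seed for weights and permutations; defaults to
#'   `params$seed`.
#' @param attractorIters iterations of the free-running attractor test.
#' @param attractorItersLong extended attractor check.
#' @return an object of class `run_report`: list with fields `inputCorr`,
#'   `outputCorrForward`, `outputCorrRecall`, `categoryLabels`, `nCategories`,
#'   `contiguous`, `attractorStable`, `attractorStableLong`, `recallCorrect`,
#'   `meanAbsInputCorr`, `meanAbsDistinctOutputCorr`,
#'   `meanAbsDistinctRecallCorr`, `outputsForward`, `outputsRecall`, `params`,
#'   `seed`.
#' @export
run_experiment <- function(params = network_params(),
                           forward = make_shifted_patterns(),
                           backproj = make_orthogonal_patterns(),
                           seed = params$seed,
                           attractorIters = 10L, attractorItersLong = 100L) {
  syn <- init_weights(params, seed)
  syn <- train(syn, params, forward, backproj, seed = seed + 1L)
  nP <- nrow(forward)

  outF <- t(vapply(seq_len(nP), function(p) test_forward(syn, params, forward[p, ]),
                   numeric(params$N)))
  outR <- t(vapply(seq_len(nP), function(p) recall(syn, params, backproj[p, ]),
                   numeric(params$N)))

  keys <- apply(outF, 1, paste, collapse = "")
  labels <- match(keys, unique(keys))
  nCat <- length(unique(keys))

  stable_over <- function(nIter) {
    all(vapply(seq_len(nP), function(p) {
      traj <- run_attractor(syn, params, outF[p, ], nIter)
      all(traj == rep(outF[p, ], each = nIter))
    }, logical(1)))
  }

  # outputs can contain all-zero rows in degenerate regimes (e.g. gBp = 0);
  # report NA correlations rather than fail
  safe_corr <- function(m) tryCatch(correlation_matrix(m),
                                    error = function(e) NA)
  distinct_corr <- function(out) {
    d <- unique(out)
    if (nrow(d) < 2) return(NA_real_)
    cm <- safe_corr(d)
    if (!is.matrix(cm)) return(NA_real_)
    mean_abs_offdiag(cm)
  }

  structure(list(
    inputCorr = correlation_matrix(forward),
    outputCorrForward = safe_corr(outF),
    outputCorrRecall = safe_corr(outR),
    categoryLabels = labels,
    nCategories = nCat,
    contiguous = all_categories_contiguous(labels),
    attractorStable = stable_over(attractorIters),
    attractorStableLong = stable_over(attractorItersLong),
    recallCorrect = sum(vapply(seq_len(nP),
                               function(p) all(outF[p, ] == outR[p, ]),
                               logical(1))),
    meanAbsInputCorr = mean_abs_offdiag(correlation_matrix(forward)),
    meanAbsDistinctOutputCorr = distinct_corr(outF),
    meanAbsDistinctRecallCorr = distinct_corr(outR),
    outputsForward = outF,
    outputsRecall = outR,
    synapses = syn,
    params = params,
    seed = seed
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed %d: %d patterns -> %d categories (%scontiguous)\n",
              x$seed, length(x$categoryLabels), x$nCategories,
              if (x$contiguous) "" else "non-"))
  cat(sprintf("  mean |input corr| %.4f; mean |distinct output corr| %.4f (forward), %.4f (recall)\n",
              x$meanAbsInputCorr, x$meanAbsDistinctOutputCorr,
              x$meanAbsDistinctRecallCorr))
  cat(sprintf("  recall correct %d/%d; attractor stable: %s (extended: %s)\n",
              x$recallCorrect, length(x$categoryLabels),
              x$attractorStable, x$attractorStableLong))
  invisible(x)
}

# Wrap-aware contiguity of category membership along the pattern order:
# each label must occupy one circular run.
all_categories_contiguous <- function(labels) {
  n <- length(labels)
  all(vapply(unique(labels), function(u) {
    idx <- which(labels == u)
    if (length(idx) == 1) return(TRUE)
    gaps <- sum(diff(idx) != 1)
    # one interior gap is allowed iff the run wraps around the ends
    gaps == 0 || (gaps == 1 && idx[1] == 1 && idx[length(idx)] == n)
  }, logical(1)))
}

#' Category statistics over multiple seeded runs
#'
#' Repeats [run_experiment()] with seeds `baseSeed + 0 .. nSeeds - 1` and
#' summarises the run-to-run variation that the random weight initialisation
#' produces.
#'
#' @inheritParams run_experiment
#' @param nSeeds number of independently seeded runs.
#' @param baseSeed first seed.
#' @return list with `nCategories` (per run), `distribution` (table),
#'   `modal` (modal category count), `contiguousRate`, `recallCorrect`
#'   (per run), `recallPerfectRate`, `attractorStableRate`, and `reports`
#'   (the individual `run_report`s).
#' @export
category_statistics <- function(params = network_params(),
                                forward = make_shifted_patterns(),
                                backproj = make_orthogonal_patterns(),
                                nSeeds = 20L, baseSeed = 0L) {
  if (nSeeds < 1) stop("nSeeds must be >= 1")
  reports <- lapply(baseSeed + seq_len(nSeeds) - 1L, function(s)
    run_experiment(params, forward, backproj, seed = s))
  nc <- vapply(reports, `[[`, integer(1), "nCategories")
  rc <- vapply(reports, `[[`, numeric(1), "recallCorrect")
  tab <- table(nc)
  list(nCategories = nc,
       distribution = tab,
       modal = as.integer(names(tab)[which.max(tab)]),
       contiguousRate = mean(vapply(reports, `[[`, logical(1), "contiguous")),
       recallCorrect = rc,
       recallPerfectRate = mean(rc == nrow(forward)),
       attractorStableRate = mean(vapply(reports, `[[`, logical(1),
                                         "attractorStable")),
       reports = reports)
}

#' Parameter-robustness sweep
#'
#' Evaluates [category_statistics()] at every row of a parameter grid and
#' summarises how far from the default operating point the network keeps
#' working.  A single run is classed as *operational* when recall is perfect,
#' the attractor is stable over the test iterations, and the number of
#' categories lies in `catRange`.
#'
#' @inheritParams category_statistics
#' @param base the base [network_params()]; each grid row overrides fields.
#' @param grid data.frame whose columns are `network_params` field names
#'   (e.g. `gRec`, `gBp`, `alphaComp`, `alphaRec`, `alphaBp`, `sparseness`)
#'   and whose rows are the points to evaluate.
#' @param catRange acceptable category-count range for the operational flag.
#' @return data.frame of class `sweep_result`: the grid plus `modalCategories`,
#'   `contiguousRate`, `attractorStableRate`, `recallPerfectRate`,
#'   `meanRecallCorrect`, `operationalRate` and `operational` (TRUE when all
#'   runs at the point were operational).
#' @export
robustness_sweep <- function(base = network_params(), grid, nSeeds = 5L,
                             forward = make_shifted_patterns(),
                             backproj = make_orthogonal_patterns(),
                             baseSeed = 0L, catRange = c(3L, 6L)) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) stop("empty parameter grid")
  bad <- setdiff(names(grid), names(unclass(base)))
  if (length(bad)) stop("unknown parameter(s) in grid: ", paste(bad, collapse = ", "))
  nP <- nrow(forward)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- unclass(base)
    for (nm in names(grid)) p[[nm]] <- grid[r, nm]
    p <- do.call(network_params, p[setdiff(names(p), character(0))])
    cs <- category_statistics(p, forward, backproj, nSeeds, baseSeed)
    op <- vapply(cs$reports, function(rep)
      rep$recallCorrect == nP && rep$attractorStable &&
        rep$nCategories >= catRange[1] && rep$nCategories <= catRange[2],
      logical(1))
    data.frame(grid[r, , drop = FALSE],
               modalCategories = cs$modal,
               contiguousRate = cs$contiguousRate,
               attractorStableRate = cs$attractorStableRate,
               recallPerfectRate = cs$recallPerfectRate,
               meanRecallCorrect = mean(cs$recallCorrect),
               operationalRate = mean(op),
               operational = all(op))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("sweep_result", class(res))
  res
}

#' Top-down attention probe with ambiguous forward inputs
#'
#' For every ordered pair of distinct learned categories, builds an ambiguous
#' forward stimulus as the element-wise maximum of one exemplar from each
#' category, presents it attenuated by `fGain` together with the cue of the
#' second category's exemplar attenuated by `bGain`, and records which
#' category wins with and without the cue.  The returned fraction measures
#' how often the weak top-down signal pulls the competition toward the cued
#' category.
#'
#' @param syn a trained `synaptic_state`.
#' @param params the `network_params` used in training.
#' @param forward,backproj the training pattern sets.
#' @param fGain,bGain attenuation of the ambiguous forward input and of the
#'   cue.
#' @return list with `trials` (data.frame: category pair, unbiased winner,
#'   biased winner, whether the cued category won in each condition) and
#'   `biasedWinFraction` (fraction of pairs where the cued category wins when
#'   the cue is on).
#' @export
attention_experiment <- function(syn, params, forward, backproj,
                                 fGain = 0.5, bGain = 0.5) {
  nP <- nrow(forward)
  outF <- t(vapply(seq_len(nP), function(p) test_forward(syn, params, forward[p, ]),
                   numeric(params$N)))
  keys <- apply(outF, 1, paste, collapse = "")
  labels <- match(keys, unique(keys))
  cats <- unique(labels)
  if (length(cats) < 2) stop("need at least two learned categories")
  # exemplar: the middle member of each category
  exemplar <- vapply(cats, function(u) {
    idx <- which(labels == u); idx[ceiling(length(idx) / 2)]
  }, integer(1))

  category_of <- function(y) {
    k <- paste(y, collapse = "")
    i <- match(k, keys)
    if (is.na(i)) NA_integer_ else labels[i]
  }

  pairs <- expand.grid(a = cats, b = cats)
  pairs <- pairs[pairs$a != pairs$b, ]
  trials <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    ea <- exemplar[pairs$a[r]]; eb <- exemplar[pairs$b[r]]
    mix <- pmax(forward[ea, ], forward[eb, ])
    cue <- backproj[eb, ]
    unb <- category_of(attention_bias(syn, params, mix, cue, fGain, 0))
    bia <- category_of(attention_bias(syn, params, mix, cue, fGain, bGain))
    data.frame(catA = pairs$a[r], catB = pairs$b[r],
               unbiasedWinner = unb, biasedWinner = bia,
               cueWinsUnbiased = identical(unb, pairs$b[r]),
               cueWinsBiased = identical(bia, pairs$b[r]))
  }))
  list(trials = trials, biasedWinFraction = mean(trials$cueWinsBiased))
}
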