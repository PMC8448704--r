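#' Network parameters
#'
#' All fixed scalars of the combined competitive / attractor / backprojection
#' network.  A single population of `N` binary-rate neurons receives three
#' classes of synaptic input on each dendrite: forward (competitive) inputs,
#' recurrent collaterals from the same population, and backprojections from a
#' higher area.  Each class contributes `nSyn` synapses per neuron, so every
#' dendrite carries `2 * nSyn + N` weights (with the default `nSyn = N`,
#' 300 weights).
#'
#' The scale factors `gComp`, `gRec` and `gBp` multiply each class's
#' contribution to the activation; the recurrent and backprojection factors
#' default to 0.1 so that forward inputs dominate during learning while the
#' weaker inputs still suffice to sustain short-term memory and drive recall
#' once the forward input is absent.  `alphaComp`, `alphaRec` and `alphaBp`
#' are the Hebbian learning rates of the three synapse classes.
#'
#' @param N number of output neurons.
#' @param nSyn synapses per input class per neuron (defaults to `N`).
#' @param gComp,gRec,gBp fixed scale factors of the forward, recurrent and
#'   backprojection inputs in the activation (dimensionless).
#' @param alphaComp,alphaRec,alphaBp Hebbian learning rates of the three
#'   synapse classes.
#' @param sparseness fraction of output neurons left firing by the binary
#'   threshold activation function; the default 0.01 leaves a single winner
#'   for `N = 100`.
#' @param epochs training epochs; each epoch presents every pattern pair once
#'   in a fresh random permutation.
#' @param settleIters activation-settling passes per presentation.  The rates
#'   start at zero, so with the default single pass the recurrent collaterals
#'   contribute nothing to the presented pattern's rates; additional passes
#'   feed the rates back through the recurrent weights.
#' @param normalize when the dendritic weight normalization is applied:
#'   after every pattern presentation (default) or once per epoch.
#' @param seed default integer seed used by [init_weights()] and [train()]
#'   when no explicit seed is given.
#' @return an object of class `network_params` (a validated list).
#' @export
network_params <- function(N = 100L, nSyn = N, gComp = 1.0, gRec = 0.1,
                           gBp = 0.1, alphaComp = 0.1, alphaRec = 0.03,
                           alphaBp = 0.1, sparseness = 0.01, epochs = 5L,
                           settleIters = 1L,
                           normalize = c("presentation", "epoch"),
                           seed = 1L) {
  p <- list(N = as.integer(N), nSyn = as.integer(nSyn), gComp = gComp,
            gRec = gRec, gBp = gBp, alphaComp = alphaComp,
            alphaRec = alphaRec, alphaBp = alphaBp, sparseness = sparseness,
            epochs = as.integer(epochs), settleIters = as.integer(settleIters),
            normalize = match.arg(normalize), seed = as.integer(seed))
  if (p$N < 1 || p$nSyn < 1) stop("N and nSyn must be positive")
  if (any(c(p$gComp, p$gRec, p$gBp, p$alphaComp, p$alphaRec, p$alphaBp) < 0))
    stop("scale factors and learning rates must be >= 0")
  if (p$sparseness <= 0 || p$sparseness > 1)
    stop("sparseness must lie in (0, 1]")
  if (n_winners(p) < 1) stop("sparseness * N rounds to zero winners")
  if (p$epochs < 0) stop("epochs must be >= 0")
  if (p$settleIters < 1) stop("settleIters must be >= 1")
  class(p) <- "network_params"
  p
}

n_winners <- function(params) max(1L, as.integer(round(params$sparseness * params$N)))

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params: N=%d nSyn=%d g=(%g, %g, %g) alpha=(%g, %g, %g)\n",
    x$N, x$nSyn, x$gComp, x$gRec, x$gBp, x$alphaComp, x$alphaRec, x$alphaBp))
  cat(sprintf("  sparseness=%g (%d winner%s) epochs=%d settleIters=%d normalize=%s seed=%d>\n",
              x$sparseness, n_winners(x), if (n_winners(x) > 1) "s" else "",
              x$epochs, x$settleIters, x$normalize, x$seed))
  invisible(x)
}

#' Scale a presynaptic rate vector to unit total rate
#'
#' Presynaptic input vectors enter the activation scaled so that their
#' entries sum to one, the convention of Rumelhart-Zipser competitive
#' learning: a pattern's total drive is then independent of how many of its
#' lines are active, so forward patterns (many active lines), recurrent rates
#' and sparse backprojection cues deliver comparable input per unit scale
#' factor.  An all-zero vector is returned unchanged.
#'
#' @param x numeric rate vector.
#' @return `x / sum(x)`, or `x` when `sum(x) == 0`.
#' @export
unit_rate <- function(x) {
  s <- sum(x)
  if (s > 0) x / s else x
}

#' Initialise the synaptic state
#'
#' All weights are drawn uniform on \[0, 1\] and each neuron's concatenated
#' dendritic weight vector (its row across the forward, recurrent and
#' backprojection blocks) is then normalized to unit total strength, so every
#' neuron starts with the same synaptic resource and competition is fair.
#'
#' @param params a [network_params()] object.
#' @param seed integer seed for the weight draw; defaults to `params$seed`.
#' @return an object of class `synaptic_state`: list with matrices `Wcomp`
#'   (`N x nSyn`), `Wrec` (`N x N`) and `Wbp` (`N x nSyn`), all non-negative,
#'   each row of the concatenation summing to one.
#' @export
init_weights <- function(params, seed = params$seed) {
  N <- params$N; nSyn <- params$nSyn
  W <- with_seed(seed, matrix(stats::runif(N * (2L * nSyn + N)), N))
  W <- W / rowSums(W)
  syn <- list(Wcomp = W[, seq_len(nSyn), drop = FALSE],
              Wrec  = W[, nSyn + seq_len(N), drop = FALSE],
              Wbp   = W[, nSyn + N + seq_len(nSyn), drop = FALSE])
  class(syn) <- "synaptic_state"
  syn
}

#' @export
print.synaptic_state <- function(x, ...) {
  cat(sprintf("<synaptic_state: %d neurons, blocks comp %dx%d rec %dx%d bp %dx%d>\n",
              nrow(x$Wcomp), nrow(x$Wcomp), ncol(x$Wcomp),
              nrow(x$Wrec), ncol(x$Wrec), nrow(x$Wbp), ncol(x$Wbp)))
  invisible(x)
}

#' Total dendritic weight of each neuron
#'
#' @param syn a `synaptic_state`.
#' @return numeric vector: the sum of each neuron's concatenated weight row.
#' @export
dendrite_norms <- function(syn) {
  rowSums(syn$Wcomp) + rowSums(syn$Wrec) + rowSums(syn$Wbp)
}

# Renormalize the listed neurons' dendrites to unit total weight.
normalize_dendrites <- function(syn, neurons = seq_len(nrow(syn$Wcomp))) {
  s <- rowSums(syn$Wcomp[neurons, , drop = FALSE]) +
       rowSums(syn$Wrec[neurons, , drop = FALSE]) +
       rowSums(syn$Wbp[neurons, , drop = FALSE])
  syn$Wcomp[neurons, ] <- syn$Wcomp[neurons, , drop = FALSE] / s
  syn$Wrec[neurons, ]  <- syn$Wrec[neurons, , drop = FALSE] / s
  syn$Wbp[neurons, ]   <- syn$Wbp[neurons, , drop = FALSE] / s
  syn
}

#' Neuronal activations: scaled weighted sum of the three input classes
#'
#' Computes, for every neuron i,
#' `h_i = gComp * sum_k xComp_k Wcomp_ik + gRec * sum_l xRec_l Wrec_il +
#'  gBp * sum_m xBp_m Wbp_im`.
#' The vectors are used exactly as given; callers such as [settle()] apply
#' the unit-total-rate scaling ([unit_rate()]) before invoking this.
#'
#' @param syn a `synaptic_state`.
#' @param params a `network_params`.
#' @param xComp forward input rate vector, length `nSyn`.
#' @param xRec recurrent presynaptic rate vector, length `N`.
#' @param xBp backprojection input rate vector, length `nSyn`.
#' @return numeric activation vector of length `N`.
#' @export
compute_activation <- function(syn, params, xComp, xRec, xBp) {
  if (length(xComp) != ncol(syn$Wcomp) || length(xBp) != ncol(syn$Wbp) ||
      length(xRec) != ncol(syn$Wrec))
    stop("input vector length does not match the synaptic block")
  as.numeric(params$gComp * (syn$Wcomp %*% xComp) +
             params$gRec  * (syn$Wrec  %*% xRec) +
             params$gBp   * (syn$Wbp   %*% xBp))
}

#' Binary threshold activation enforcing fixed sparseness
#'
#' Stands in for the population's inhibitory interneurons: the
#' `round(sparseness * N)` neurons with the highest activations fire at rate
#' 1 and the rest at 0.  Ties are broken toward the lowest neuron index.  If
#' no activation is positive, no neuron fires.
#'
#' @param h activation vector of length `N`.
#' @param params a `network_params`.
#' @return binary rate vector of length `N`.
#' @export
apply_sparseness <- function(h, params) {
  if (length(h) != params$N) stop("h must have length N")
  y <- numeric(params$N)
  if (all(h <= 0)) return(y)
  y[order(-h, seq_along(h))[seq_len(n_winners(params))]] <- 1
  y
}

#' Settle the network on a pair of external inputs
#'
#' Rates start at zero; each settling pass recomputes the activations from
#' the (unit-rate scaled, optionally gain-attenuated) external inputs plus
#' the recurrent feedback of the current rates, then re-applies the
#' sparseness threshold.  With the default single pass the recurrent
#' collaterals do not influence the returned rates.
#'
#' @param syn a `synaptic_state`.
#' @param params a `network_params`.
#' @param xComp forward input pattern (raw binary, length `nSyn`).
#' @param xBp backprojection input pattern (raw binary, length `nSyn`).
#' @param fGain,bGain multiplicative attenuation in \[0, 1\] applied to the
#'   scaled forward and backprojection inputs (used for attention probes).
#' @return list with elements `activations` (numeric, length `N`) and
#'   `rates` (binary, length `N`), of class `network_state`.
#' @export
settle <- function(syn, params, xComp, xBp, fGain = 1, bGain = 1) {
  xc <- fGain * unit_rate(xComp)
  xb <- bGain * unit_rate(xBp)
  y <- numeric(params$N)
  h <- numeric(params$N)
  for (i in seq_len(params$settleIters)) {
    h <- compute_activation(syn, params, xc, unit_rate(y), xb)
    y <- apply_sparseness(h, params)
  }
  structure(list(activations = h, rates = y), class = "network_state")
}

#' One Hebbian update with whole-dendrite weight normalization
#'
#' Applies the associative increments `alphaComp * y_i * xComp_k` to the
#' forward weights, `alphaRec * y_i * xRec_l` to the recurrent weights and
#' `alphaBp * y_i * xBp_m` to the backprojection weights, then renormalizes
#' every modified neuron's whole dendritic weight vector back to unit total
#' strength.  The renormalization silently weakens the synapses of an active
#' neuron that did not receive input — heterosynaptic depression — which is
#' what frees a competitive neuron from its initial random preferences.
#' Neurons with `y_i = 0` are untouched (their dendrite already sums to one).
#'
#' The presynaptic vectors are used exactly as given; [train()] passes the
#' unit-rate scaled patterns so that each class's total increment per
#' presentation is its learning rate.
#'
#' @inheritParams compute_activation
#' @param y binary postsynaptic rate vector, length `N`.
#' @param renormalize apply the dendrite normalization (default); [train()]
#'   defers it to the end of the epoch when `params$normalize == "epoch"`.
#' @return the updated `synaptic_state`.
#' @export
hebbian_update <- function(syn, params, xComp, xRec, xBp, y,
                           renormalize = TRUE) {
  act <- which(y > 0)
  if (length(act) == 0L) return(syn)
  syn$Wcomp[act, ] <- syn$Wcomp[act, , drop = FALSE] +
    params$alphaComp * tcrossprod(y[act], xComp)
  syn$Wrec[act, ] <- syn$Wrec[act, , drop = FALSE] +
    params$alphaRec * tcrossprod(y[act], xRec)
  syn$Wbp[act, ] <- syn$Wbp[act, , drop = FALSE] +
    params$alphaBp * tcrossprod(y[act], xBp)
  if (renormalize) syn <- normalize_dendrites(syn, act)
  syn
}

#' Train the network on paired forward and backprojection pattern sets
#'
#' For each epoch, visits every (forward, backprojection) pattern pair once
#' in a fresh seeded random permutation.  Each presentation settles the rates
#' from the two external inputs ([settle()]), then applies the Hebbian update
#' with the settled rates serving both as the postsynaptic rates and as the
#' recurrent presynaptic rates (so recurrent learning is autoassociative, the
#' substrate of the attractor), followed by the dendrite normalization.
#'
#' @param syn a `synaptic_state` (typically from [init_weights()]).
#' @param params a `network_params`.
#' @param forward forward `pattern_set` (rows of length `nSyn`).
#' @param backproj backprojection `pattern_set`, same number of patterns.
#' @param seed integer seed for the presentation permutations; defaults to
#'   `params$seed`.
#' @return the trained `synaptic_state`.
#' @export
train <- function(syn, params, forward, backproj, seed = params$seed) {
  if (nrow(forward) != nrow(backproj))
    stop("forward and backprojection sets must have the same pattern count")
  if (ncol(forward) != ncol(syn$Wcomp) || ncol(backproj) != ncol(syn$Wbp))
    stop("pattern length does not match nSyn")
  nP <- nrow(forward)
  with_seed(seed, {
    for (e in seq_len(params$epochs)) {
      for (p in sample.int(nP)) {
        st <- settle(syn, params, forward[p, ], backproj[p, ])
        syn <- hebbian_update(syn, params,
                              xComp = unit_rate(forward[p, ]),
                              xRec  = unit_rate(st$rates),
                              xBp   = unit_rate(backproj[p, ]),
                              y     = st$rates,
                              renormalize = params$normalize == "presentation")
      }
      if (params$normalize == "epoch") syn <- normalize_dendrites(syn)
    }
  })
  syn
}

#' Test categorisation with a forward input alone
#'
#' Presents a forward pattern with no backprojection input and frozen
#' weights; returns the binary output rates.
#'
#' @inheritParams train
#' @param f forward input pattern, length `nSyn`.
#' @return binary rate vector of length `N`.
#' @export
test_forward <- function(syn, params, f) {
  settle(syn, params, f, numeric(ncol(syn$Wbp)))$rates
}

#' Free-running attractor iterations after input removal
#'
#' Starting from the rates `y0`, iterates the recurrent collaterals alone
#' (no forward or backprojection input, no learning): each step computes the
#' activations from the current rates and re-applies the sparseness
#' threshold.  A trained network should hold the initiating pattern as a
#' stable fixed point — the short-term memory.
#'
#' @inheritParams train
#' @param y0 initial binary rate vector, length `N`.
#' @param nIter number of free-running iterations.
#' @return `nIter x N` binary matrix, one row per iteration.
#' @export
run_attractor <- function(syn, params, y0, nIter = 10L) {
  zc <- numeric(ncol(syn$Wcomp)); zb <- numeric(ncol(syn$Wbp))
  out <- matrix(0, nIter, params$N)
  y <- y0
  for (i in seq_len(nIter)) {
    h <- compute_activation(syn, params, zc, unit_rate(y), zb)
    y <- apply_sparseness(h, params)
    out[i, ] <- y
  }
  out
}

#' Recall from a backprojection cue alone
#'
#' Presents a backprojection pattern with no forward input and frozen
#' weights; after learning, the cue should recall exactly the output rates
#' that the corresponding forward input produces.
#'
#' @inheritParams train
#' @param b backprojection cue pattern, length `nSyn`.
#' @return binary rate vector of length `N`.
#' @export
recall <- function(syn, params, b) {
  settle(syn, params, numeric(ncol(syn$Wcomp)), b)$rates
}

#' Biased competition: weak forward input plus weak top-down cue
#'
#' Presents a forward pattern attenuated by `fGain` together with a
#' backprojection cue attenuated by `bGain`; the returned rates show which
#' interpretation of the (possibly ambiguous) forward input wins the
#' competition.  `fGain = 1, bGain = 0` reduces to [test_forward()];
#' `fGain = 0, bGain = 1` reduces to [recall()].
#'
#' @inheritParams settle
#' @param f forward input pattern, length `nSyn`.
#' @param b backprojection cue pattern, length `nSyn`.
#' @return binary rate vector of length `N`.
#' @export
attention_bias <- function(syn, params, f, b, fGain, bGain) {
  if (fGain < 0 || fGain > 1 || bGain < 0 || bGain > 1)
    stop("fGain and bGain must lie in [0, 1]")
  settle(syn, params, f, b, fGain = fGain, bGain = bGain)$rates
}
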