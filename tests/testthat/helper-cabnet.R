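# Shared fixtures and independent oracles.

# Naive Eq.-style activation: explicit triple loop over neurons and synapses,
# written independently of the matrix implementation.
naive_activation <- function(syn, params, xComp, xRec, xBp) {
  N <- nrow(syn$Wcomp)
  h <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (k in seq_along(xComp)) s <- s + params$gComp * xComp[k] * syn$Wcomp[i, k]
    for (l in seq_along(xRec))  s <- s + params$gRec  * xRec[l]  * syn$Wrec[i, l]
    for (m in seq_along(xBp))   s <- s + params$gBp   * xBp[m]   * syn$Wbp[i, m]
    h[i] <- s
  }
  h
}

# Two-pass Pearson correlation, independent of stats::cor.
naive_pearson <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Small network for cheap structural tests.
small_params <- function(...) {
  args <- utils::modifyList(
    list(N = 20L, nSyn = 20L, sparseness = 0.05, epochs = 2L), list(...))
  do.call(network_params, args)
}

small_sets <- function() {
  list(fwd = make_shifted_patterns(6L, 20L, 5L, 2L),
       bp = make_orthogonal_patterns(6L, 20L, 2L))
}

expect_unit_dendrites <- function(syn, tol = 1e-10) {
  expect_true(all(abs(dendrite_norms(syn) - 1) < tol))
}
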