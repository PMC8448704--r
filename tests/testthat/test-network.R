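test_that("parameter validation catches out-of-range values", {
  expect_error(network_params(N = 0), "positive")
  expect_error(network_params(sparseness = 0), "sparseness")
  expect_error(network_params(sparseness = 1.2), "sparseness")
  expect_error(network_params(gRec = -0.1), ">= 0")
  expect_error(network_params(epochs = -1), "epochs")
  p <- network_params()
  expect_s3_class(p, "network_params")
  expect_equal(cabnet:::n_winners(p), 1L)
  expect_equal(cabnet:::n_winners(network_params(sparseness = 0.1)), 10L)
})

test_that("initial weights are uniform, non-negative, and dendrite-normalized", {
  p <- network_params()
  syn <- init_weights(p, seed = 3)
  expect_equal(dim(syn$Wcomp), c(100L, 100L))
  expect_equal(dim(syn$Wrec), c(100L, 100L))
  expect_equal(dim(syn$Wbp), c(100L, 100L))
  expect_true(all(syn$Wcomp >= 0) && all(syn$Wrec >= 0) && all(syn$Wbp >= 0))
  expect_unit_dendrites(syn)
  # same seed -> bit-identical; different seed -> different
  expect_identical(syn, init_weights(p, seed = 3))
  expect_false(identical(syn, init_weights(p, seed = 4)))
})

test_that("activation matches a naive per-synapse oracle", {
  p <- small_params()
  syn <- init_weights(p, seed = 5)
  for (case in 1:5) {
    set.seed(100 + case)
    xc <- rbinom(20, 1, 0.3); xr <- rbinom(20, 1, 0.2); xb <- rbinom(20, 1, 0.1)
    expect_equal(compute_activation(syn, p, xc, xr, xb),
                 naive_activation(syn, p, xc, xr, xb), tolerance = 1e-12)
  }
  # zero input -> zero activation; one-hot forward input -> a weight column
  z <- numeric(20)
  expect_equal(compute_activation(syn, p, z, z, z), numeric(20))
  oh <- z; oh[7] <- 1
  expect_equal(compute_activation(syn, p, oh, z, z), p$gComp * syn$Wcomp[, 7])
  expect_error(compute_activation(syn, p, numeric(5), z, z), "length")
})

test_that("sparseness threshold picks top-m with lowest-index tie-break", {
  p3 <- network_params(N = 3, nSyn = 3, sparseness = 1 / 3)
  expect_equal(apply_sparseness(c(0.5, 0.9, 0.1), p3), c(0, 1, 0))
  expect_equal(apply_sparseness(c(0.4, 0.4, 0.4), p3), c(1, 0, 0))
  expect_equal(apply_sparseness(c(0, 0, 0), p3), c(0, 0, 0))
  expect_equal(apply_sparseness(c(-1, -2, -3), p3), c(0, 0, 0))
  p10 <- network_params(N = 10, nSyn = 10, sparseness = 0.3)
  y <- apply_sparseness(runif(10), p10)
  expect_equal(sum(y), 3)
  expect_error(apply_sparseness(numeric(5), p10), "length N")
})

test_that("single settling pass is blind to the recurrent weights", {
  s <- small_sets()
  p1 <- small_params(settleIters = 1L)
  p0 <- small_params(settleIters = 1L, gRec = 0)
  syn <- init_weights(p1, seed = 9)
  st1 <- settle(syn, p1, s$fwd[1, ], s$bp[1, ])
  st0 <- settle(syn, p0, s$fwd[1, ], s$bp[1, ])
  expect_identical(st1$rates, st0$rates)
  # with gRec = 0 extra settling passes change nothing
  p0b <- small_params(settleIters = 4L, gRec = 0)
  expect_identical(settle(syn, p0b, s$fwd[1, ], s$bp[1, ])$rates, st0$rates)
})

test_that("settling reaches a fixed point that further passes preserve", {
  s <- small_sets()
  p <- small_params(settleIters = 6L)
  syn <- train(init_weights(p, seed = 2), p, s$fwd, s$bp, seed = 3)
  st6 <- settle(syn, p, s$fwd[2, ], s$bp[2, ])
  p12 <- small_params(settleIters = 12L)
  expect_identical(settle(syn, p12, s$fwd[2, ], s$bp[2, ])$rates, st6$rates)
})

test_that("Hebbian update applies alpha*y*x increments then renormalizes", {
  p <- small_params()
  syn <- init_weights(p, seed = 1)
  y <- numeric(20); y[4] <- 1
  xc <- numeric(20); xc[c(2, 6)] <- 1
  xr <- numeric(20); xb <- numeric(20); xb[9] <- 1
  raw <- hebbian_update(syn, p, xc, xr, xb, y, renormalize = FALSE)
  # pre-normalization increment is exactly alpha at the active synapses
  expect_equal(raw$Wcomp[4, 2] - syn$Wcomp[4, 2], p$alphaComp)
  expect_equal(raw$Wcomp[4, 6] - syn$Wcomp[4, 6], p$alphaComp)
  expect_equal(raw$Wbp[4, 9] - syn$Wbp[4, 9], p$alphaBp)
  expect_equal(raw$Wcomp[4, 3], syn$Wcomp[4, 3])   # inactive synapse untouched
  # silent neurons are untouched entirely
  upd <- hebbian_update(syn, p, xc, xr, xb, y)
  expect_identical(upd$Wcomp[-4, ], syn$Wcomp[-4, ])
  expect_identical(upd$Wrec[-4, ], syn$Wrec[-4, ])
  # and the all-silent update is the identity
  expect_identical(hebbian_update(syn, p, xc, xr, xb, numeric(20)), syn)
  # renormalization restores unit total dendritic weight
  expect_unit_dendrites(upd)
  # heterosynaptic depression: the active neuron's inactive synapses weaken
  expect_true(upd$Wcomp[4, 3] < syn$Wcomp[4, 3])
})

test_that("training conserves dendrite norms and non-negativity throughout", {
  s <- small_sets()
  p <- small_params()
  syn <- init_weights(p, seed = 21)
  # step the training loop manually to observe every intermediate state
  for (e in 1:2) for (q in sample(6)) {
    st <- settle(syn, p, s$fwd[q, ], s$bp[q, ])
    syn <- hebbian_update(syn, p, unit_rate(s$fwd[q, ]), unit_rate(st$rates),
                          unit_rate(s$bp[q, ]), st$rates)
    expect_unit_dendrites(syn)
    expect_true(all(syn$Wcomp >= 0) && all(syn$Wrec >= 0) && all(syn$Wbp >= 0))
  }
})

test_that("train is seed-reproducible and epochs = 0 is the identity", {
  s <- small_sets()
  p <- small_params()
  syn0 <- init_weights(p, seed = 11)
  p0 <- small_params(epochs = 0L)
  expect_identical(train(syn0, p0, s$fwd, s$bp, seed = 1), syn0)
  t1 <- train(syn0, p, s$fwd, s$bp, seed = 5)
  t2 <- train(syn0, p, s$fwd, s$bp, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, train(syn0, p, s$fwd, s$bp, seed = 6)))
  expect_error(train(syn0, p, s$fwd, s$bp[1:3, ], seed = 1), "pattern count")
})

test_that("every emitted rate vector has exact sparseness", {
  p <- network_params(sparseness = 0.03)  # 3 winners
  fwd <- make_shifted_patterns(); bp <- make_orthogonal_patterns()
  syn <- train(init_weights(p, seed = 2), p, fwd, bp, seed = 3)
  for (q in c(1, 10, 28)) {
    expect_equal(sum(test_forward(syn, p, fwd[q, ])), 3)
    expect_equal(sum(recall(syn, p, bp[q, ])), 3)
  }
  traj <- run_attractor(syn, p, test_forward(syn, p, fwd[1, ]), 10)
  expect_true(all(rowSums(traj) == 3))
})

test_that("attractor from a zero state stays silent", {
  p <- small_params()
  syn <- init_weights(p, seed = 2)
  traj <- run_attractor(syn, p, numeric(20), 5)
  expect_true(all(traj == 0))
})

test_that("attention gains reduce to the pure forward and recall tests", {
  s <- small_sets()
  p <- small_params()
  syn <- train(init_weights(p, seed = 4), p, s$fwd, s$bp, seed = 5)
  expect_identical(attention_bias(syn, p, s$fwd[3, ], s$bp[3, ], 1, 0),
                   test_forward(syn, p, s$fwd[3, ]))
  expect_identical(attention_bias(syn, p, s$fwd[3, ], s$bp[3, ], 0, 1),
                   recall(syn, p, s$bp[3, ]))
  expect_error(attention_bias(syn, p, s$fwd[1, ], s$bp[1, ], 2, 0), "fGain")
})
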