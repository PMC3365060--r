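test_that("random orthonormal bases are orthonormal and reproducible", {
  Q <- random_orthonormal(3, 3, seed = 40)
  expect_lte(max(abs(crossprod(Q) - diag(3))), 1e-12)
  expect_identical(Q, random_orthonormal(3, 3, seed = 40))
  expect_error(random_orthonormal(2, 3), "orthonormal columns")

  set.seed(41)
  norms <- replicate(200, sqrt(colSums(random_orthonormal(15, 4)^2)))
  expect_lte(max(abs(norms - 1)), 1e-12)
})

test_that("spec validation rejects infeasible designs", {
  expect_error(simulation_spec(imposed_vaf = cbind(c(-0.1, 0.5), c(0.5, 0.5))),
               "nonnegative")
  expect_error(simulation_spec(imposed_vaf = cbind(c(0, 0), c(0.5, 0.5))),
               "positive signal")
  expect_error(simulation_spec(imposed_vaf = cbind(c(0.5, 0), c(0.5, 0))),
               "at least one block")
  expect_error(simulation_spec(imposed_vaf = make_profile(1, 1, 0),
                               noise_fraction = 1), "noise_fraction")
  expect_error(simulation_spec(dims = c(5, 4, 3),
                               imposed_vaf = make_profile(2, 2, 0)),
               "smallest dimension")
})

test_that("the generated signal carries exactly the imposed structure", {
  # distinct concatenated weights (0.55, 0.65, 0.45) keep the SVD of the
  # concatenation free of ties, so SCA recovers V up to sign only
  spec <- simulation_spec(dims = c(12, 9, 7),
                          imposed_vaf = cbind(c(0.55, 0, 0.20),
                                              c(0, 0.65, 0.25)),
                          noise_fraction = 0, seed = 42)
  sim <- simulate_blocks(spec)
  tr <- sim$truth
  expect_lte(max(abs(crossprod(tr$U1) - diag(3))), 1e-10)
  expect_lte(max(abs(crossprod(tr$V) - diag(3))), 1e-10)
  # noise-free: blocks equal the signal; per-component SS matches imposed
  X1 <- sim$blocks$blocks$X1
  expect_equal(X1, tr$U1 %*% (tr$singvals[, 1] * t(tr$V)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums((X1 %*% tr$V)^2), spec$imposed_vaf[, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  # a distinctive component leaves no trace in the absent block
  X2 <- sim$blocks$blocks$X2
  expect_lte(max(abs(X2 %*% tr$V[, 1])), 1e-12)   # component 1 is X1-only

  # same seed, same data; SCA at the true rank recovers V exactly
  expect_identical(simulate_blocks(spec)$blocks$blocks$X1, X1)
  model <- sca(sim$blocks, 3)
  expect_gte(match_components(tr$V, model$shared_factor)$mean_phi, 1 - 1e-6)
})

test_that("realized noise fraction concentrates at the nominal level", {
  spec <- simulation_spec(imposed_vaf = study_conditions("mixed")[[1]]$imposed_vaf)
  fr <- vapply(1:30, function(i)
    simulate_blocks(spec, seed = 100 + i)$realized_noise_fraction, numeric(2))
  expect_lte(max(abs(fr - 0.2)), 0.02)        # per paper-size block and rep
  expect_lte(max(abs(rowMeans(fr) - 0.2)), 3 * 0.02 / sqrt(30))
})

test_that("the study driver reports the expected ordering of methods", {
  conds <- study_conditions(c("distinctive", "common"),
                            dims = c(40L, 24L, 16L))
  st <- run_simulation_study(conds, n_reps = 3,
                             methods = c("gsvd", "disco"),
                             base_seed = 43, n_restarts = 2)
  expect_s3_class(st, "simulation_study")
  # DISCO approximates at least as well as the naive GSVD in total VAF
  for (cond in names(conds)) {
    g <- st$vaf_tables[[cond]]$gsvd$overall_total
    d <- st$vaf_tables[[cond]]$disco$overall_total
    expect_gte(d, g - 1e-9)
  }
  # with common components the gap in recovery is large
  cong <- st$congruence
  phi_g <- cong$phi_V[cong$condition == "common" & cong$method == "gsvd"]
  phi_d <- cong$phi_V[cong$condition == "common" & cong$method == "disco"]
  expect_gt(phi_d, phi_g + 0.1)

  # noise-free single replication: DISCO congruences are exactly 1
  noisefree <- simulation_spec(dims = c(12, 10, 8),
                               imposed_vaf = make_profile(1, 1, 1),
                               noise_fraction = 0)
  st0 <- run_simulation_study(list(nf = noisefree), n_reps = 1,
                              methods = "disco", base_seed = 44,
                              n_restarts = 2)
  expect_equal(unlist(st0$congruence[, c("phi_V", "phi_U1", "phi_U2")]),
               c(phi_V = 1, phi_U1 = 1, phi_U2 = 1), tolerance = 1e-6)
})
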