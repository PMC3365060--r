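test_that("perfectly distinctive blocks decompose exactly", {
  X1 <- matrix(c(1, 0, 0, 0), 2, 2,
               dimnames = list(c("a1", "a2"), c("s1", "s2")))
  X2 <- matrix(c(0, 0, 0, 1), 2, 2,
               dimnames = list(c("b1", "b2"), c("s1", "s2")))
  lb <- linked_blocks(X1 = X1, X2 = X2)
  fit <- gsvd(lb)
  expect_equal(sort(fit$c^2), c(0, 1), tolerance = 1e-12)
  expect_equal(fit$c^2 + fit$s^2, rep(1, 2), tolerance = 1e-12)
  expect_equal(fit$U1 %*% (fit$c * t(fit$V)), X1,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$U2 %*% (fit$s * t(fit$V)), X2,
               tolerance = 1e-10, ignore_attr = TRUE)
  # the block-1-distinctive component accounts for all of block 1, none of 2
  q1 <- which(fit$c^2 > 0.5)
  expect_equal(unname(fit$vaf$per_block[q1, ]), c(1, 0), tolerance = 1e-12)
})

test_that("gsvd invariants hold on random instances", {
  set.seed(10)
  for (i in 1:100) {
    I1 <- sample(3:9, 1); I2 <- sample(3:9, 1)
    J <- sample(2:min(I1, I2), 1)
    lb <- rand_blocks(I1, I2, J)
    fit <- gsvd(lb)
    expect_lte(max(abs(fit$c^2 + fit$s^2 - 1)), 1e-10)
    expect_lte(max(abs(crossprod(fit$U1) - diag(fit$Q))), 1e-10)
    expect_lte(max(abs(crossprod(fit$U2) - diag(fit$Q))), 1e-10)
    X1 <- lb$blocks$X1; X2 <- lb$blocks$X2
    expect_lte(norm(X1 - fit$U1 %*% (fit$c * t(fit$V)), "F") / norm(X1, "F"),
               1e-8)
    expect_lte(norm(X2 - fit$U2 %*% (fit$s * t(fit$V)), "F") / norm(X2, "F"),
               1e-8)
    # components are ordered by descending concatenated VAF
    expect_false(is.unsorted(rev(fit$vaf$concatenated)))
  }
})

test_that("identical blocks give c^2 = 1/2 on every component", {
  lb <- rand_blocks(5, 5, 4, seed = 11)
  lb$blocks$X2 <- lb$blocks$X1
  rownames(lb$blocks$X2) <- paste0("b", 1:5)
  lb <- linked_blocks(lb$blocks)
  fit <- gsvd(lb)
  expect_equal(fit$c^2, rep(0.5, fit$Q), tolerance = 1e-10)
})

test_that("full-decomposition per-block VAF totals reach one", {
  lb <- rand_blocks(7, 6, 5, seed = 12)
  fit <- gsvd(lb)
  expect_equal(unname(fit$vaf$block_totals), c(1, 1), tolerance = 1e-9)
  expect_equal(fit$vaf$overall_total, 1, tolerance = 1e-9)
})

test_that("adapted gsvd equals the full gsvd at full rank and is exact on noise-free data", {
  lb <- rand_blocks(6, 5, 4, seed = 13)
  full <- gsvd(lb)
  adapted <- adapted_gsvd(lb, full$Q)
  expect_equal(adapted$vaf$block_totals, full$vaf$block_totals,
               tolerance = 1e-9)
  expect_error(adapted_gsvd(lb, full$Q + 1L), "rank")

  sim <- simulate_blocks(simulation_spec(dims = c(10, 8, 6),
    imposed_vaf = make_profile(1, 1, 1), noise_fraction = 0, seed = 14))
  fit <- adapted_gsvd(sim$blocks, 3)
  X1 <- sim$blocks$blocks$X1
  expect_lte(norm(X1 - fit$U1 %*% (fit$c * t(fit$V)), "F") / norm(X1, "F"),
             1e-8)
})

test_that("adapted gsvd total VAF equals the rank-R SCA total VAF", {
  set.seed(15)
  for (i in 1:10) {
    lb <- rand_blocks(sample(6:10, 1), sample(5:9, 1), 5)
    for (R in c(2L, 4L)) {
      adapted <- adapted_gsvd(lb, R)
      model <- sca(lb, R)
      expect_equal(adapted$vaf$block_totals, model$vaf$block_totals,
                   tolerance = 1e-9)
    }
  }
})

test_that("noise-free distinctive structure is recovered with congruence 1", {
  sim <- simulate_blocks(simulation_spec(dims = c(12, 10, 8),
    imposed_vaf = make_profile(2, 2, 0), noise_fraction = 0, seed = 16))
  for (fit in list(gsvd(sim$blocks), adapted_gsvd(sim$blocks, 4))) {
    keep <- seq_len(4)
    rep <- recovery_report(sim, list(V = fit$V[, keep], U1 = fit$U1[, keep],
                                     U2 = fit$U2[, keep]))
    expect_gte(rep$V, 1 - 1e-6)
    expect_gte(rep$U1, 1 - 1e-6)
    expect_gte(rep$U2, 1 - 1e-6)
  }
})

test_that("component classification follows the c^2 bands", {
  fake <- structure(list(c = sqrt(c(0.5, 1, 0.7, 0.02)),
                         s = sqrt(1 - c(0.5, 1, 0.7, 0.02))),
                    class = "gsvd")
  expect_equal(classify_components(fake),
               c("common", "distinctive_1", "undetermined", "distinctive_2"))
  expect_error(classify_components(fake, common_band = c(0.01, 0.6)),
               "overlap")
})
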