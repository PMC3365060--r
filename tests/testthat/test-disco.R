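test_that("target masks are built per the status assignment", {
  lb <- rand_blocks(3, 2, 4, seed = 30)
  tgt <- build_target(list(1L, 2L, 1:2), lb)
  expect_equal(tgt$mask,
               cbind(c(0, 0, 0, 1, 1),    # distinctive for block 1
                     c(1, 1, 1, 0, 0),    # distinctive for block 2
                     c(0, 0, 0, 0, 0)))   # common: nothing targeted
  expect_equal(tgt$label, "d1=1,d2=1,common=1")

  all_common <- build_target(rep(list(1:2), 3), lb)
  expect_true(all(all_common$mask == 0))
  expect_error(build_target(list(1L, integer(0)), lb), "empty status")
})

test_that("target enumeration counts follow (R+1)(R+2)/2", {
  expect_length(enumerate_targets(5), 21L)
  expect_length(enumerate_targets(1), 3L)
  expect_length(enumerate_targets(6), 28L)
  for (R in 1:10) {
    # brute force: count distinct (d1, d2) with d1 + d2 <= R
    brute <- sum(outer(0:R, 0:R, "+") <= R)
    expect_length(enumerate_targets(R), brute)
    expect_equal(brute, (R + 1) * (R + 2) / 2)
  }
})

test_that("a model already matching the target rotates trivially", {
  sim <- simulate_blocks(simulation_spec(dims = c(10, 8, 6),
    imposed_vaf = make_profile(1, 1, 1), noise_fraction = 0, seed = 31))
  model <- sca(sim$blocks, 3)
  tgt <- build_target(composition_statuses(1, 1, 1), model)
  rot <- disco_rotate(model, tgt, n_restarts = 2, seed = 1)
  expect_lte(rot$objective, 1e-12)
  expect_lte(rot$max_deviation, 1e-8)
})

test_that("rotation results satisfy their structural invariants", {
  set.seed(32)
  for (i in 1:5) {
    lb <- rand_blocks(9, 7, 6)
    model <- sca(lb, 4)
    tgt <- build_target(composition_statuses(2, 1, 1), model)
    rot <- disco_rotate(model, tgt, n_restarts = 3, seed = i)
    expect_lte(max(abs(crossprod(rot$B) - diag(4))), 1e-10)
    # rotation leaves total per-block VAF unchanged
    expect_equal(rot$vaf$block_totals, model$vaf$block_totals,
                 tolerance = 1e-10)
    # majorization trajectory is nonincreasing
    expect_lte(max(diff(rot$objective_trajectory)), 1e-10)
  }
})

test_that("the R=2 optimum agrees with a Givens-angle grid search", {
  set.seed(33)
  for (i in 1:5) {
    lb <- rand_blocks(6, 5, 4)
    model <- sca(lb, 2)
    tgt <- build_target(list(1L, 2L), model)
    rot <- disco_rotate(model, tgt, n_restarts = 5, seed = i)

    # brute-force oracle over rotation angles (reflections only flip column
    # signs, which the masked criterion ignores)
    Tm <- model$block_factor
    W <- tgt$mask
    theta <- seq(0, pi, length.out = 1e5)
    col1 <- outer(Tm[, 1], cos(theta)) + outer(Tm[, 2], sin(theta))
    col2 <- outer(Tm[, 1], -sin(theta)) + outer(Tm[, 2], cos(theta))
    obj <- colSums((W[, 1] * col1)^2) + colSums((W[, 2] * col2)^2)
    expect_lte(rot$objective, min(obj) + 1e-6)
  }
})

test_that("componentwise deviations match a direct VAF computation", {
  # crafted two-component solution: a block-1-distinctive component leaking
  # VAF 0.07 into block 2, and a common component with block VAFs 0.30/0.20
  P <- diag(4)[, 1:2]
  T1 <- rbind(c(sqrt(0.63), 0), c(0, sqrt(0.30)))
  T2 <- rbind(c(sqrt(0.07), 0), c(0, sqrt(0.20)))
  X1 <- T1 %*% t(P); X1[1, 3] <- sqrt(0.07)   # SS(X1) = 1
  X2 <- T2 %*% t(P); X2[1, 4] <- sqrt(0.73)   # SS(X2) = 1
  dimnames(X1) <- list(c("a1", "a2"), paste0("s", 1:4))
  dimnames(X2) <- list(c("b1", "b2"), paste0("s", 1:4))
  lb <- linked_blocks(X1 = X1, X2 = X2)

  fake <- structure(list(
    rotated = list(block_factor = rbind(T1, T2), shared_factor = P),
    target = build_target(list(1L, 1:2), lb),
    vaf = NULL), class = "disco_rotation")
  dev <- target_deviation(fake, lb)
  expect_equal(dev$per_component, c(0.07, 0.10), tolerance = 1e-12)
  expect_equal(dev$max_deviation, 0.10, tolerance = 1e-12)
})

test_that("select_target recovers a noise-free (2,2,1) structure", {
  sim <- simulate_blocks(simulation_spec(dims = c(14, 12, 9),
    imposed_vaf = make_profile(2, 2, 1), noise_fraction = 0, seed = 34))
  sel <- select_target(sim$blocks, 5, n_restarts = 3, seed = 1)
  expect_equal(sel$best$target$label, "d1=2,d2=2,common=1")
  expect_lte(sel$best$max_deviation, 1e-8)
  expect_equal(nrow(sel$deviation_table), 21L)
})

test_that("target strings parse and validate", {
  st <- parse_target("d1=2,d2=1,common=2", 5)
  expect_equal(st, composition_statuses(2, 1, 2))
  expect_error(parse_target("d1=2,common=1", 5), "sum to 3 but R = 5")
  expect_error(parse_target("nonsense", 2), "cannot parse")
})

test_that("disco_sca front door ties the pieces together", {
  sim <- simulate_blocks(simulation_spec(dims = c(12, 10, 8),
    imposed_vaf = make_profile(1, 1, 1), noise_fraction = 0.1, seed = 35))
  fit <- disco_sca(sim$blocks, R = 3, target = "d1=1,d2=1,common=1",
                   n_restarts = 3, seed = 1)
  expect_s3_class(fit, "disco_sca")
  expect_equal(fit$target$label, "d1=1,d2=1,common=1")
  expect_equal(dim(coef(fit)), c(8L, 3L))
  res <- residuals(fit, sim$blocks)
  rec <- fitted(fit)
  expect_equal(rec$X1 + res$X1, sim$blocks$blocks$X1, tolerance = 1e-10)
  # summary carries the per-component deviation report
  s <- summary(fit)
  expect_length(s$deviations, 3L)
})
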