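## Seed handling: run code under a temporary seed without disturbing the
## caller's RNG state.  A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## square Haar-ish random orthogonal matrix from the current RNG stream
random_orthogonal <- function(n) {
  qr_dec <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_dec)
  sweep(q, 2L, sign(diag(qr.R(qr_dec))), "*")
}

#' Random matrix with orthonormal columns
#'
#' Orthogonalized standard-normal draws: the QR factor of an \eqn{n \times
#' r} Gaussian matrix with the sign of the R diagonal absorbed, which makes
#' the distribution uniform (Haar) over the Stiefel manifold and the result
#' reproducible per seed.
#'
#' @param n number of rows.
#' @param r number of columns, at most \code{n}.
#' @param seed optional seed; the caller's RNG state is left untouched.
#' @return an \eqn{n \times r} matrix \eqn{Q} with \eqn{Q^T Q = I}.
#' @export
random_orthonormal <- function(n, r, seed = NULL) {
  if (r > n) stop("cannot draw ", r, " orthonormal columns in dimension ", n)
  with_seed(seed, {
    qr_dec <- qr(matrix(stats::rnorm(n * r), n, r))
    q <- qr.Q(qr_dec)
    sweep(q, 2L, sign(diag(qr.R(qr_dec))[seq_len(r)]), "*")
  })
}

#' Specification of a simulated linked-block pair
#'
#' Describes the generating model \eqn{X_k = U_k S_k V^T + E_k} with
#' orthonormal \eqn{U_1, U_2, V}: block and column dimensions, the
#' per-component signal weights per block, and the noise level.
#'
#' \code{imposed_vaf[r, k]} sets the signal sum of squares of component
#' \eqn{r} in block \eqn{k} (the squared generating singular value
#' \eqn{s_{kr}^2}), proportionally: a component is common when both block
#' entries are positive and distinctive for one block when only that entry
#' is.  Noise is scaled relative to the signal so that it accounts for
#' \code{noise_fraction} of each block's variation in expectation.
#'
#' @param dims integer triple \eqn{(I_1, I_2, J)}; default the
#'   \eqn{144 \times 28} and \eqn{44 \times 28} pair used throughout the
#'   package's simulation study.
#' @param imposed_vaf \eqn{R \times 2} matrix of nonnegative per-component
#'   signal weights (columns = blocks); see also
#'   \code{\link{study_conditions}} for ready-made profiles.
#' @param noise_fraction expected proportion of each block's SS due to
#'   noise, in \eqn{[0, 1)}; default 0.20.
#' @param seed optional generation seed.
#' @return an object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(dims = c(144L, 44L, 28L), imposed_vaf,
                            noise_fraction = 0.2, seed = NULL) {
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  imposed_vaf <- as.matrix(imposed_vaf)
  if (ncol(imposed_vaf) != 2L)
    stop("imposed_vaf must have one column per block (K = 2)")
  if (any(imposed_vaf < 0)) stop("imposed_vaf entries must be nonnegative")
  if (any(colSums(imposed_vaf) == 0))
    stop("each block needs at least one component with positive signal")
  if (any(rowSums(imposed_vaf) == 0))
    stop("every component must have positive signal in at least one block")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop("noise_fraction must lie in [0, 1)")
  R <- nrow(imposed_vaf)
  if (R > min(dims))
    stop("R = ", R, " components exceed the smallest dimension")
  statuses <- lapply(seq_len(R), function(r) which(imposed_vaf[r, ] > 0))
  structure(list(dims = as.integer(dims), R = R, imposed_vaf = imposed_vaf,
                 noise_fraction = noise_fraction, seed = seed,
                 statuses = statuses),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Simulation spec: X1 ", x$dims[1L], "x", x$dims[3L], ", X2 ",
      x$dims[2L], "x", x$dims[3L], ", R = ", x$R,
      ", noise fraction ", x$noise_fraction, "\n", sep = "")
  lab <- vapply(x$statuses, function(s)
    if (length(s) == 2L) "common" else paste0("distinctive_", s), character(1))
  cat("  components:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a linked-block pair with known ground truth
#'
#' Draws uniformly random orthonormal bases \eqn{U_1, U_2, V}, builds the
#' signal \eqn{U_k S_k V^T} with squared singular values proportional to the
#' imposed per-component weights, and adds isotropic Gaussian noise
#' \eqn{E_k} scaled so that \eqn{SS(E_k) = f/(1-f) \cdot SS(\mathrm{signal}_k)}
#' with \eqn{f} the noise fraction — i.e. noise accounts for \eqn{f} of the
#' block's variation in expectation (signal-noise cross terms make the
#' realized fraction stochastic).
#'
#' @param spec a \code{\link{simulation_spec}} (its \code{seed} is used when
#'   \code{seed} is \code{NULL}).
#' @param seed overriding generation seed.
#' @return An object of class \code{"simulated_pair"}: \code{blocks} (a
#'   \code{\link{linked_blocks}}), \code{truth} (list with \code{U1},
#'   \code{U2}, \code{V}, the singular-value matrix \code{singvals}
#'   (\eqn{R \times 2}), \code{statuses} and the generating target
#'   statuses), \code{realized_noise_fraction} per block, and \code{spec}.
#' @export
simulate_blocks <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(seed)) seed <- spec$seed
  I1 <- spec$dims[1L]; I2 <- spec$dims[2L]; J <- spec$dims[3L]
  R <- spec$R
  with_seed(seed, {
    U1 <- random_orthonormal(I1, R)
    U2 <- random_orthonormal(I2, R)
    V <- random_orthonormal(J, R)
    S <- sqrt(spec$imposed_vaf)          # R x 2, s_kr = sqrt of weight
    signal1 <- U1 %*% (S[, 1L] * t(V))
    signal2 <- U2 %*% (S[, 2L] * t(V))
    f <- spec$noise_fraction
    make_noise <- function(signal) {
      if (f == 0) return(array(0, dim(signal)))
      target_ss <- f / (1 - f) * sum(signal^2)
      E <- matrix(stats::rnorm(length(signal)), nrow(signal))
      E * sqrt(target_ss / (nrow(E) * ncol(E)))
    }
    E1 <- make_noise(signal1)
    E2 <- make_noise(signal2)
    X1 <- signal1 + E1
    X2 <- signal2 + E2
    dimnames(X1) <- list(paste0("b1_v", seq_len(I1)), paste0("s", seq_len(J)))
    dimnames(X2) <- list(paste0("b2_v", seq_len(I2)), paste0("s", seq_len(J)))
    blocks <- linked_blocks(X1 = X1, X2 = X2)
    structure(list(blocks = blocks,
                   truth = list(U1 = U1, U2 = U2, V = V, singvals = S,
                                statuses = spec$statuses),
                   realized_noise_fraction =
                     c(X1 = sum(E1^2) / sum(X1^2),
                       X2 = sum(E2^2) / sum(X2^2)),
                   spec = spec),
              class = "simulated_pair")
  })
}

#' @export
print.simulated_pair <- function(x, ...) {
  print(x$spec)
  cat("  realized noise fraction:",
      paste(names(x$realized_noise_fraction),
            format(round(x$realized_noise_fraction, 3)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ready-made simulation conditions
#'
#' The three per-component VAF profiles of the package's simulation study —
#' all components distinctive (three per block), a mix of two distinctive
#' per block plus two common, and all components common — at the standard
#' dimensions \eqn{X_1: 144 \times 28}, \eqn{X_2: 44 \times 28}, \eqn{R = 6}
#' and 20\% noise.
#'
#' @param which subset of \code{c("distinctive", "mixed", "common")}.
#' @param dims,noise_fraction overrides passed to
#'   \code{\link{simulation_spec}}.
#' @return named list of \code{simulation_spec} objects.
#' @export
study_conditions <- function(which = c("distinctive", "mixed", "common"),
                             dims = c(144L, 44L, 28L),
                             noise_fraction = 0.2) {
  which <- match.arg(which, several.ok = TRUE)
  profiles <- list(
    distinctive = cbind(X1 = c(0.00, 0.44, 0.23, 0.00, 0.13, 0.00),
                        X2 = c(0.48, 0.00, 0.00, 0.21, 0.00, 0.10)),
    mixed = cbind(X1 = c(0.31, 0.20, 0.20, 0.00, 0.11, 0.00),
                  X2 = c(0.30, 0.19, 0.00, 0.20, 0.00, 0.10)),
    common = cbind(X1 = c(0.27, 0.18, 0.12, 0.10, 0.07, 0.06),
                   X2 = c(0.27, 0.19, 0.12, 0.10, 0.07, 0.06)))
  lapply(profiles[which], function(p)
    simulation_spec(dims = dims, imposed_vaf = p,
                    noise_fraction = noise_fraction))
}

#' Run the recovery simulation study
#'
#' For each condition, generates a representative pair and tabulates the
#' per-component per-block VAF recovered by each method (with estimated
#' components matched to the generated ones), then repeats generation
#' \code{n_reps} times and averages the matched Tucker congruences for the
#' shared structure \eqn{V} and the block bases \eqn{U_1, U_2}.  Replication
#' \eqn{i} uses seed \code{base_seed + i}, so the study is reproducible from
#' a single integer.
#'
#' @param conditions named list of \code{\link{simulation_spec}} objects,
#'   e.g. \code{\link{study_conditions}()}.
#' @param n_reps replications per condition for the congruence summary.
#' @param methods subset of \code{c("gsvd", "adapted_gsvd", "disco")}.
#' @param base_seed integer; all randomness derives from it.
#' @param n_restarts rotation restarts passed to \code{\link{disco_rotate}}.
#' @return An object of class \code{"simulation_study"}: \code{vaf_tables}
#'   (per condition, per method: a \code{vaf_table} whose rows follow the
#'   generated component order), \code{congruence} (data frame with mean
#'   \eqn{\phi} for \code{V}, \code{U1}, \code{U2} per condition and
#'   method) and the settings.
#' @export
run_simulation_study <- function(conditions, n_reps = 100L,
                                 methods = c("gsvd", "adapted_gsvd", "disco"),
                                 base_seed = 1L, n_restarts = 5L) {
  stopifnot(n_reps >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(conditions)))
    names(conditions) <- paste0("condition", seq_along(conditions))

  vaf_tables <- list()
  cong_rows <- list()
  for (cond in names(conditions)) {
    spec <- conditions[[cond]]
    rep_pair <- simulate_blocks(spec, seed = base_seed)
    vaf_tables[[cond]] <- lapply(
      stats::setNames(methods, methods), function(m)
        method_vaf_matched(m, rep_pair, n_restarts, base_seed))

    phi <- array(NA_real_, dim = c(n_reps, length(methods), 3L),
                 dimnames = list(NULL, methods, c("V", "U1", "U2")))
    for (i in seq_len(n_reps)) {
      pair <- simulate_blocks(spec, seed = base_seed + i)
      for (m in methods) {
        est <- method_estimates(m, pair, n_restarts, base_seed + i)
        rep_phi <- recovery_report(pair, est)
        phi[i, m, ] <- c(rep_phi$V, rep_phi$U1, rep_phi$U2)
      }
    }
    for (m in methods)
      cong_rows[[paste(cond, m)]] <- data.frame(
        condition = cond, method = m,
        phi_V = mean(phi[, m, "V"]),
        phi_U1 = mean(phi[, m, "U1"]),
        phi_U2 = mean(phi[, m, "U2"]))
  }
  structure(list(vaf_tables = vaf_tables,
                 congruence = do.call(rbind, c(cong_rows,
                                               make.row.names = FALSE)),
                 n_reps = n_reps, methods = methods, base_seed = base_seed),
            class = "simulation_study")
}

## estimates of (V, U1, U2) by one method on one simulated pair; for the
## GSVD variants the R components with highest concatenated VAF are taken
method_estimates <- function(method, pair, n_restarts, seed) {
  R <- pair$spec$R
  switch(method,
    gsvd = {
      fit <- gsvd(pair$blocks)
      keep <- seq_len(min(R, fit$Q))
      list(V = fit$V[, keep, drop = FALSE],
           U1 = fit$U1[, keep, drop = FALSE],
           U2 = fit$U2[, keep, drop = FALSE],
           block_factor = gsvd_block_factor(fit, keep))
    },
    adapted_gsvd = {
      fit <- adapted_gsvd(pair$blocks, R)
      list(V = fit$V, U1 = fit$U1, U2 = fit$U2,
           block_factor = gsvd_block_factor(fit, seq_len(fit$Q)))
    },
    disco = {
      model <- sca(pair$blocks, R)
      tgt <- build_target(pair$truth$statuses, model)
      rot <- disco_rotate(model, tgt, n_restarts = n_restarts, seed = seed)
      I1 <- nrow(pair$truth$U1)
      Trot <- rot$rotated$block_factor
      list(V = rot$rotated$shared_factor,
           U1 = Trot[seq_len(I1), , drop = FALSE],
           U2 = Trot[-seq_len(I1), , drop = FALSE],
           block_factor = Trot)
    })
}

## concatenated block factor of selected GSVD components, carrying the full
## rank-1 scale: the SS of component q inside block k is s_kq^2 ||v_q||^2,
## so the factor columns are U_k (c_q ||v_q||) and U_k (s_q ||v_q||)
gsvd_block_factor <- function(fit, keep) {
  vnorm <- sqrt(colSums(fit$V^2))[keep]
  rbind(fit$U1[, keep, drop = FALSE] *
          rep(fit$c[keep] * vnorm, each = nrow(fit$U1)),
        fit$U2[, keep, drop = FALSE] *
          rep(fit$s[keep] * vnorm, each = nrow(fit$U2)))
}

## per-block VAF table of a method's components, rows matched (by |phi| on
## the concatenated block factor) to the generated component order
method_vaf_matched <- function(method, pair, n_restarts, seed) {
  est <- method_estimates(method, pair, n_restarts, seed)
  truth_T <- rbind(pair$truth$U1 * rep(pair$truth$singvals[, 1L],
                                       each = nrow(pair$truth$U1)),
                   pair$truth$U2 * rep(pair$truth$singvals[, 2L],
                                       each = nrow(pair$truth$U2)))
  m <- match_components(truth_T, est$block_factor)
  block_ss <- total_ss(pair$blocks, by_block = TRUE)
  I1 <- nrow(pair$truth$U1)
  vaf_of <- function(cols) {
    Tm <- est$block_factor[, cols, drop = FALSE]
    cbind(colSums(Tm[seq_len(I1), , drop = FALSE]^2) / block_ss[1L],
          colSums(Tm[-seq_len(I1), , drop = FALSE]^2) / block_ss[2L])
  }
  per_block <- vaf_of(m$permutation)
  colnames(per_block) <- names(block_ss)
  concat <- rowSums(sweep(per_block, 2L, block_ss, "*")) / sum(block_ss)
  new_vaf_table(per_block, concat,
                note = "rows follow the generated component order")
}

#' @export
print.simulation_study <- function(x, digits = 3, ...) {
  cat("Simulation study:", x$n_reps, "replications, methods:",
      paste(x$methods, collapse = ", "), "\n\n")
  cat("Mean matched Tucker congruence:\n")
  tab <- x$congruence
  tab[, 3:5] <- round(tab[, 3:5], digits)
  print(tab, row.names = FALSE)
  cat("\nPer-block total VAF (representative pair):\n")
  for (cond in names(x$vaf_tables)) {
    totals <- vapply(x$vaf_tables[[cond]], function(v)
      v$block_totals, numeric(2))
    cat(" ", cond, ":\n")
    print(round(t(totals), digits))
  }
  invisible(x)
}
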