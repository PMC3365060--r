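#' Build a rotation target from component statuses
#'
#' A target assigns each of the \code{R} components a status: common
#' (present in every block) or distinctive for a subset of blocks.  The
#' associated binary mask \eqn{W} has a 1 exactly at the block-factor
#' positions that the rotation should drive to zero — the rows of every
#' block in which a component should be absent.  Common components
#' contribute no mask entries.
#'
#' @param statuses list of length \code{R}; element \code{r} is the integer
#'   vector of block indices in which component \code{r} is present
#'   (\code{1:K} for a common component, a single index for a distinctive
#'   one).
#' @param blocks a \code{\link{linked_blocks}} object (only block row counts
#'   are used), or an \code{\link{sca}} fit.
#' @return An object of class \code{"disco_target"}: \code{statuses},
#'   \code{mask} (\eqn{\sum_k I_k \times R}), \code{R}, \code{K},
#'   \code{n_distinctive} (per block) and a readable \code{label} such as
#'   \code{"d1=2,d2=2,common=1"}.
#' @export
build_target <- function(statuses, blocks) {
  if (inherits(blocks, "sca")) {
    row_index <- blocks$row_index
  } else {
    stopifnot(inherits(blocks, "linked_blocks"))
    row_index <- block_row_index(blocks)
  }
  K <- length(row_index)
  R <- length(statuses)
  if (R < 1L) stop("empty status list")
  statuses <- lapply(statuses, function(s) sort(unique(as.integer(s))))
  for (r in seq_len(R)) {
    s <- statuses[[r]]
    if (length(s) == 0L) stop("component ", r, " has an empty status set")
    if (any(s < 1L | s > K))
      stop("component ", r, " refers to a block outside 1..", K)
  }
  n_rows <- sum(lengths(row_index))
  mask <- matrix(0, n_rows, R)
  for (r in seq_len(R))
    for (k in setdiff(seq_len(K), statuses[[r]]))
      mask[row_index[[k]], r] <- 1
  n_dist <- vapply(seq_len(K), function(k)
    sum(vapply(statuses, function(s) identical(s, k), logical(1))), integer(1))
  n_common <- sum(vapply(statuses, function(s) length(s) == K, logical(1)))
  label <- paste0(paste0("d", seq_len(K), "=", n_dist, collapse = ","),
                  ",common=", n_common)
  structure(list(statuses = statuses, mask = mask, R = R, K = K,
                 n_distinctive = n_dist, n_common = n_common, label = label),
            class = "disco_target")
}

#' @export
print.disco_target <- function(x, ...) {
  cat("DISCO rotation target:", x$label, "\n")
  invisible(x)
}

#' Enumerate all candidate common/distinctive targets
#'
#' For two blocks, every unordered composition of \code{R} components into
#' \eqn{d_1} distinctive for block 1, \eqn{d_2} distinctive for block 2 and
#' \eqn{R - d_1 - d_2} common ones, giving \eqn{(R+1)(R+2)/2} candidates
#' (21 for \eqn{R = 5}).
#'
#' @param R number of components.
#' @param K number of blocks; only \code{K = 2} is enumerated.
#' @return list of status lists, each usable with \code{\link{build_target}}.
#' @export
enumerate_targets <- function(R, K = 2L) {
  stopifnot(R >= 1L)
  if (K != 2L)
    stop("target enumeration is implemented for K = 2 blocks")
  out <- list()
  for (d1 in 0:R) for (d2 in 0:(R - d1)) {
    statuses <- c(rep(list(1L), d1), rep(list(2L), d2),
                  rep(list(1:2), R - d1 - d2))
    out[[length(out) + 1L]] <- statuses
  }
  out
}

## Eq-style masked rotation objective
masked_objective <- function(Tmat, B, mask) sum((mask * (Tmat %*% B))^2)

#' Orthogonally rotate an SCA solution to a partially specified target
#'
#' Finds the orthogonal \eqn{R \times R} matrix \eqn{B} minimizing
#' \deqn{\| W \circ ([T_1^T \dots T_K^T]^T B) \|_F^2,}
#' i.e. the sum of squares of the rotated block factor on the positions the
#' target specifies as zero; the unspecified positions do not influence the
#' objective.  The rotated model \eqn{(T B, P B)} fits the data exactly as
#' well as the unrotated one.
#'
#' Minimization is by iterative majorization: at the current \eqn{B_0} set
#' \eqn{Z = (1 - W) \circ (T B_0)} and update \eqn{B} to the orthogonal
#' Procrustes solution of \eqn{\min_B \|T B - Z\|_F^2} (the polar factor of
#' \eqn{T^T Z}); the objective is nonincreasing along the iterations.  The
#' criterion is rotation-invariant for components sharing an identical
#' status, so after convergence each same-status group is re-rotated so that
#' its first component explains maximal variation in the block factor and
#' each subsequent one the maximum of the residual (as in an SVD), which
#' resolves the indeterminacy.  Because the criterion is non-convex, the
#' identity start is supplemented with random orthogonal restarts and the
#' best local optimum is kept.
#'
#' @param model an \code{\link{sca}} fit.
#' @param target a \code{\link{disco_target}} (or a status list, passed to
#'   \code{\link{build_target}}).
#' @param tol relative objective decrease declaring convergence.
#' @param max_iter iteration cap per start; exceeding it yields a warning
#'   and the best iterate.
#' @param n_restarts random orthogonal starts in addition to the identity.
#' @param seed optional seed for the restart stream.
#' @return An object of class \code{"disco_rotation"}: the orthogonal
#'   \code{B}, \code{rotated} (list with \code{block_factor} and
#'   \code{shared_factor}), \code{objective},
#'   \code{objective_trajectory} (of the winning start), \code{vaf} (per
#'   rotated component per block), \code{deviations} and
#'   \code{max_deviation} (see \code{\link{target_deviation}}),
#'   \code{target}, \code{n_restarts_used}, \code{converged}.
#' @export
disco_rotate <- function(model, target, tol = 1e-10, max_iter = 1000L,
                         n_restarts = 10L, seed = NULL) {
  stopifnot(inherits(model, "sca"))
  if (!inherits(target, "disco_target")) target <- build_target(target, model)
  if (target$R != model$R)
    stop("target has ", target$R, " components but the model has ", model$R)
  if (nrow(target$mask) != nrow(model$block_factor))
    stop("target mask rows do not match the concatenated block factor")
  Tmat <- model$block_factor
  W <- target$mask
  R <- model$R

  starts <- c(list(diag(R)),
              with_seed(seed, lapply(seq_len(n_restarts), function(i)
                random_orthogonal(R))))

  best <- NULL
  for (B0 in starts) {
    run <- majorize_rotation(Tmat, W, B0, tol, max_iter)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  if (!best$converged)
    warning("rotation did not converge within ", max_iter,
            " iterations; best iterate returned")

  B <- rerotate_groups(Tmat, best$B, target$statuses)
  ## sign convention on the rotated shared factor
  P_rot <- model$shared_factor %*% B
  for (r in seq_len(R)) {
    piv <- which.max(abs(P_rot[, r]))
    if (P_rot[piv, r] < 0) {
      P_rot[, r] <- -P_rot[, r]; B[, r] <- -B[, r]
    }
  }
  T_rot <- Tmat %*% B
  colnames(T_rot) <- colnames(P_rot) <- paste0("C", seq_len(R))

  vaf <- new_vaf_table(factor_block_vaf(T_rot, model$row_index,
                                        model$block_ss),
                       colSums(T_rot^2) / model$concatenated_ss)
  dev <- deviation_from_vaf(vaf$per_block, target$statuses)

  structure(list(B = B, target = target,
                 rotated = list(block_factor = T_rot, shared_factor = P_rot),
                 objective = best$objective,
                 objective_trajectory = best$trajectory,
                 vaf = vaf, deviations = dev$per_component,
                 max_deviation = dev$max,
                 n_restarts_used = length(starts),
                 converged = best$converged),
            class = "disco_rotation")
}

## single majorization run from start B0
majorize_rotation <- function(Tmat, W, B0, tol, max_iter) {
  B <- B0
  keep <- 1 - W
  obj <- masked_objective(Tmat, B, W)
  trajectory <- obj
  converged <- FALSE
  scale_ref <- sum(Tmat^2)
  for (it in seq_len(max_iter)) {
    Z <- keep * (Tmat %*% B)
    M <- crossprod(Tmat, Z)
    sv <- svd(M)
    B <- sv$u %*% t(sv$v)
    obj_new <- masked_objective(Tmat, B, W)
    trajectory <- c(trajectory, obj_new)
    if (obj - obj_new < tol * max(obj, scale_ref * 1e-12)) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(B = B, objective = obj, trajectory = trajectory, converged = converged)
}

## within identical-status groups, rotate so successive components explain
## maximal VAF in the block factor (SVD of the group's columns); preserves
## the masked objective because equal-status columns have equal mask columns
rerotate_groups <- function(Tmat, B, statuses) {
  keys <- vapply(statuses, function(s) paste(s, collapse = ","), character(1))
  for (key in unique(keys)) {
    g <- which(keys == key)
    if (length(g) < 2L) next
    sub <- Tmat %*% B[, g, drop = FALSE]
    sv <- svd(sub)
    B[, g] <- B[, g, drop = FALSE] %*% sv$v
  }
  B
}

## deviation of each rotated component from its target status, from a
## per-component x per-block VAF matrix
deviation_from_vaf <- function(vaf_pb, statuses) {
  K <- ncol(vaf_pb)
  per_component <- vapply(seq_along(statuses), function(r) {
    s <- statuses[[r]]
    if (length(s) == K) {
      ## common: largest pairwise absolute VAF difference among the blocks
      ## (for K = 2 simply |VAF_1 - VAF_2|)
      max(stats::dist(vaf_pb[r, ]))
    } else {
      ## distinctive: VAF in the block(s) where the component should be
      ## absent, each normalized by that block's own SS
      max(vaf_pb[r, setdiff(seq_len(K), s)])
    }
  }, numeric(1))
  list(per_component = per_component, max = max(per_component))
}

#' Deviation of a rotated solution from its target
#'
#' Quantifies how well each rotated component attains its intended status:
#' for a distinctive component, the proportion of variation it accounts for
#' in the block where it should be absent; for a common component, the
#' absolute difference in proportion of VAF between the blocks (largest
#' pairwise difference when \eqn{K > 2}).  The maximum over components
#' summarizes the solution and is the quantity compared across candidate
#' targets.
#'
#' @param result a \code{\link{disco_rotate}} result (or a fitted
#'   \code{\link{disco_sca}} model).
#' @param blocks optionally, \code{linked_blocks} to measure VAF against;
#'   defaults to the blocks the model was fitted to (their stored SS).
#' @return list with \code{per_component}, \code{max_deviation} and the
#'   underlying per-block VAF matrix.
#' @export
target_deviation <- function(result, blocks = NULL) {
  if (inherits(result, "disco_sca")) result <- result$rotation
  stopifnot(inherits(result, "disco_rotation"))
  vaf_pb <- result$vaf$per_block
  if (!is.null(blocks)) {
    stopifnot(inherits(blocks, "linked_blocks"))
    vaf_pb <- factor_block_vaf(result$rotated$block_factor,
                               block_row_index(blocks),
                               total_ss(blocks, by_block = TRUE))
  }
  dev <- deviation_from_vaf(vaf_pb, result$target$statuses)
  list(per_component = dev$per_component, max_deviation = dev$max,
       vaf_per_block = vaf_pb)
}

#' @export
print.disco_rotation <- function(x, ...) {
  cat("DISCO rotation to target", x$target$label, "\n")
  cat("  objective:", format(x$objective, digits = 6),
      " (", length(x$objective_trajectory) - 1L, "iterations,",
      x$n_restarts_used, "starts )\n")
  cat("  max componentwise deviation:",
      format(x$max_deviation, digits = 4), "\n")
  invisible(x)
}

#' Select the best common/distinctive target
#'
#' Rotates the \code{R}-component SCA solution to every candidate target
#' from \code{\link{enumerate_targets}} and retains the solution whose
#' maximal componentwise deviation is lowest.  Ties (within \code{1e-9}) are
#' broken in favour of fewer distinctive components, then lexicographically
#' smaller \eqn{(d_1, d_2)}.
#'
#' @param blocks a \code{\link{linked_blocks}} object.
#' @param R number of components.
#' @param model optionally a precomputed \code{\link{sca}} fit of rank
#'   \code{R} (avoids refitting).
#' @param ... options passed to \code{\link{disco_rotate}} (\code{tol},
#'   \code{max_iter}, \code{n_restarts}, \code{seed}).
#' @return list with \code{best} (the winning \code{disco_rotation}),
#'   \code{deviation_table} (one row per candidate: label, number of
#'   distinctive components, max deviation) and \code{rotations} (all
#'   candidate results, named by target label).
#' @export
select_target <- function(blocks, R, model = NULL, ...) {
  stopifnot(inherits(blocks, "linked_blocks"))
  if (is.null(model)) model <- sca(blocks, R)
  stopifnot(model$R == R)
  candidates <- enumerate_targets(R, n_blocks(blocks))
  rotations <- vector("list", length(candidates))
  info <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    tgt <- build_target(candidates[[i]], model)
    rot <- disco_rotate(model, tgt, ...)
    rotations[[i]] <- rot
    info[[i]] <- data.frame(target = tgt$label,
                            d1 = tgt$n_distinctive[1L],
                            d2 = tgt$n_distinctive[2L],
                            n_distinctive = sum(tgt$n_distinctive),
                            n_common = tgt$n_common,
                            max_deviation = rot$max_deviation)
  }
  tab <- do.call(rbind, info)
  names(rotations) <- tab$target
  ## minimum max-deviation; ties at 1e-9 resolved toward fewer distinctive
  ## components, then lexicographically smaller (d1, d2)
  tied <- which(tab$max_deviation <= min(tab$max_deviation) + 1e-9)
  tied <- tied[order(tab$n_distinctive[tied], tab$d1[tied], tab$d2[tied])]
  best_i <- tied[1L]
  list(best = rotations[[best_i]],
       deviation_table = tab[order(tab$n_distinctive, tab$d1, tab$d2), ],
       rotations = rotations)
}

#' Fit a DISCO-SCA model
#'
#' The front door of the package: fits the rank-\code{R} simultaneous
#' component model to the linked blocks and rotates it to common/distinctive
#' structure.  When \code{target} is supplied, the components are rotated to
#' that single target; otherwise every candidate target is tried and the one
#' with the smallest maximal componentwise deviation is retained (see
#' \code{\link{select_target}}).
#'
#' @param blocks a \code{\link{linked_blocks}} object.
#' @param R number of components; choose it from \code{\link{sca_scree}}.
#' @param target \code{NULL} (select automatically), a status list, a
#'   \code{\link{disco_target}}, or a string such as
#'   \code{"d1=2,d2=2,common=1"}.
#' @param tol,max_iter,n_restarts,seed rotation options, see
#'   \code{\link{disco_rotate}}.
#' @return An object of class \code{"disco_sca"}: \code{sca} (the unrotated
#'   fit), \code{rotation} (a \code{disco_rotation}), \code{target},
#'   \code{vaf} (rotated per-component per-block VAF), \code{deviations},
#'   \code{max_deviation}, \code{deviation_table} (when selection ran) and
#'   the matched \code{call}.  Methods: \code{print}, \code{summary},
#'   \code{coef} (rotated shared factor), \code{fitted}, \code{residuals},
#'   \code{plot}.
#' @examples
#' sim <- simulate_blocks(simulation_spec(dims = c(24, 16, 12),
#'   imposed_vaf = cbind(c(0.45, 0, 0.2), c(0, 0.5, 0.2)),
#'   noise_fraction = 0, seed = 3))
#' fit <- disco_sca(sim$blocks, R = 3, n_restarts = 3, seed = 1)
#' fit$target$label   # recovers "d1=1,d2=1,common=1"
#' @export
disco_sca <- function(blocks, R, target = NULL, tol = 1e-10,
                      max_iter = 1000L, n_restarts = 10L, seed = NULL) {
  stopifnot(inherits(blocks, "linked_blocks"))
  model <- sca(blocks, R)
  deviation_table <- NULL
  if (is.null(target)) {
    sel <- select_target(blocks, R, model = model, tol = tol,
                         max_iter = max_iter, n_restarts = n_restarts,
                         seed = seed)
    rotation <- sel$best
    deviation_table <- sel$deviation_table
  } else {
    if (is.character(target)) target <- parse_target(target, R)
    if (!inherits(target, "disco_target"))
      target <- build_target(target, model)
    rotation <- disco_rotate(model, target, tol = tol, max_iter = max_iter,
                             n_restarts = n_restarts, seed = seed)
  }
  structure(list(sca = model, rotation = rotation,
                 target = rotation$target, vaf = rotation$vaf,
                 deviations = rotation$deviations,
                 max_deviation = rotation$max_deviation,
                 deviation_table = deviation_table,
                 block_ids = blocks$block_ids,
                 call = match.call()),
            class = "disco_sca")
}

#' Parse a target description string
#'
#' Turns \code{"d1=2,d2=2,common=1"} into a status list for
#' \code{\link{build_target}}.
#'
#' @param text the description; keys \code{d1}, \code{d2} and \code{common}.
#' @param R expected number of components; counts must sum to \code{R}.
#' @return a status list of length \code{R}.
#' @export
parse_target <- function(text, R) {
  parts <- strsplit(gsub("\\s", "", text), ",")[[1L]]
  kv <- strsplit(parts, "=")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- suppressWarnings(as.integer(vapply(kv, `[`, character(1), 2L)))
  if (anyNA(vals) || !all(keys %in% c("d1", "d2", "common")))
    stop("cannot parse target '", text,
         "'; expected e.g. \"d1=2,d2=2,common=1\"")
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else 0L
  d1 <- get("d1"); d2 <- get("d2"); nc <- get("common")
  if (d1 + d2 + nc != R)
    stop("target counts sum to ", d1 + d2 + nc, " but R = ", R)
  c(rep(list(1L), d1), rep(list(2L), d2), rep(list(1:2), nc))
}

#' @export
print.disco_sca <- function(x, ...) {
  cat("DISCO-SCA model with R =", x$sca$R, "components\n")
  cat("  target:", x$target$label,
      if (!is.null(x$deviation_table)) "(selected over all candidates)"
      else "(user-specified)", "\n")
  cat("  max componentwise deviation:",
      format(x$max_deviation, digits = 4), "\n")
  cat("  total VAF per block:",
      paste(names(x$sca$block_ss), format(round(x$vaf$block_totals, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.disco_sca <- function(object, ...) {
  status <- vapply(object$target$statuses, function(s)
    if (length(s) == object$target$K) "common"
    else paste0("distinctive_", paste(s, collapse = "+")), character(1))
  structure(list(R = object$sca$R, target = object$target$label,
                 status = status, vaf = object$vaf,
                 deviations = object$deviations,
                 max_deviation = object$max_deviation,
                 deviation_table = object$deviation_table),
            class = "summary.disco_sca")
}

#' @export
print.summary.disco_sca <- function(x, ...) {
  cat("DISCO-SCA, R =", x$R, ", target", x$target, "\n\n")
  tab <- data.frame(status = x$status,
                    round(x$vaf$per_block, 3),
                    deviation = round(x$deviations, 4),
                    check.names = FALSE)
  rownames(tab) <- rownames(x$vaf$per_block)
  print(tab)
  cat("\nTotal VAF per block:",
      paste(format(round(x$vaf$block_totals, 3)), collapse = " "), "\n")
  cat("Max deviation:", format(x$max_deviation, digits = 4), "\n")
  if (!is.null(x$deviation_table)) {
    cat("\nDeviation by candidate target:\n")
    print(x$deviation_table, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.disco_sca <- function(object, ...) object$rotation$rotated$shared_factor

#' @export
fitted.disco_sca <- function(object, ...) {
  rec <- object$rotation$rotated$block_factor %*%
    t(object$rotation$rotated$shared_factor)
  lapply(stats::setNames(seq_along(object$sca$row_index), object$block_ids),
         function(k) rec[object$sca$row_index[[k]], , drop = FALSE])
}

#' @export
residuals.disco_sca <- function(object, blocks, ...) {
  stopifnot(inherits(blocks, "linked_blocks"))
  fit <- fitted(object)
  lapply(stats::setNames(seq_along(fit), object$block_ids),
         function(k) blocks$blocks[[k]] - fit[[k]])
}

#' @export
plot.disco_sca <- function(x, ...) {
  if (is.null(x$deviation_table)) {
    plot_vaf_scree(x$vaf, main = "DISCO-SCA variation accounted for", ...)
    return(invisible(x))
  }
  tab <- x$deviation_table
  plot(tab$n_distinctive, tab$max_deviation,
       xlab = "number of distinctive components",
       ylab = "deviation from target",
       main = "Target selection", pch = 19, ...)
  env <- vapply(split(tab$max_deviation, tab$n_distinctive), min, numeric(1))
  graphics::lines(as.integer(names(env)), env)
  graphics::points(sum(x$target$n_distinctive), x$max_deviation,
                   col = 2, cex = 1.6)
  invisible(x)
}
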