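#' Generalized singular value decomposition of two linked blocks
#'
#' Jointly decomposes two matrices \eqn{X_1} (\eqn{I_1 \times J}) and
#' \eqn{X_2} (\eqn{I_2 \times J}) sharing their column mode as
#' \deqn{X_1 = U_1 S_1 V^T, \qquad X_2 = U_2 S_2 V^T,}
#' with \eqn{U_1, U_2} having orthonormal columns, \eqn{S_1 =
#' \mathrm{diag}(c)}, \eqn{S_2 = \mathrm{diag}(s)} satisfying
#' \eqn{c_q^2 + s_q^2 = 1}, and \eqn{V} (\eqn{J \times Q}) a shared
#' full-column-rank structure.  This is a FULL decomposition of rank
#' \eqn{Q = \mathrm{rank}(X_c)} of the concatenation
#' \eqn{X_c = [X_1^T\,X_2^T]^T}; unlike the SVD it is not a least-squares
#' optimal rank-R approximation when truncated (see
#' \code{\link{adapted_gsvd}} for the least-squares variant).
#'
#' The value \eqn{c_q^2} (equivalently \eqn{s_q^2 = 1 - c_q^2}) gauges the
#' status of component \eqn{q}: values near 0.5 indicate a process common to
#' both blocks, values near 1 (0) a process distinctive for block 1
#' (block 2).
#'
#' @section Algorithm:
#' Thin SVD \eqn{X_c = P \Sigma W^T} at rank \eqn{Q}, split of \eqn{P} into
#' its top \eqn{I_1} rows \eqn{P_1} and bottom rows \eqn{P_2}, CS
#' decomposition of the pair via the SVD \eqn{P_1 = U_1 C Z^T}; then
#' \eqn{U_2} and \eqn{S_2} follow from column-wise orthonormalization of
#' \eqn{P_2 Z}, and \eqn{V = W \Sigma Z}.  Components whose sine is
#' numerically zero get their \eqn{U_2} column from an orthonormal
#' completion (the column is arbitrary; see the \code{stable} flag).
#'
#' @param blocks a \code{\link{linked_blocks}} object with exactly two
#'   blocks.
#' @param rank_tol threshold below which singular values of \eqn{X_c} are
#'   treated as zero, relative to the largest one.  Default
#'   \code{max(I1+I2, J) * .Machine$double.eps}.
#' @return An object of class \code{"gsvd"} with elements \code{U1},
#'   \code{U2}, \code{c}, \code{s} (cosine/sine vectors, so \code{c^2} and
#'   \code{s^2} are the per-block VAF weights), \code{V}, \code{Q},
#'   \code{vaf} (a VAF table against the supplied blocks), \code{stable}
#'   (logical; \code{FALSE} where near-equal \code{c^2} values make the
#'   component pair non-unique, or where a block's basis vector is
#'   arbitrary), \code{adapted = FALSE} and \code{block_ss}.  Components are
#'   ordered by descending VAF in the concatenated data.
#' @seealso \code{\link{adapted_gsvd}}, \code{\link{gsvd_vaf}},
#'   \code{\link{classify_components}}
#' @examples
#' sim <- simulate_blocks(simulation_spec(dims = c(12, 9, 8),
#'   imposed_vaf = cbind(c(0.5, 0), c(0, 0.6)), noise_fraction = 0, seed = 1))
#' fit <- gsvd(sim$blocks)
#' round(fit$c^2, 3)  # 1 for the X1-distinctive, 0 for the X2-distinctive part
#' @export
gsvd <- function(blocks, rank_tol = NULL) {
  stopifnot(inherits(blocks, "linked_blocks"))
  if (n_blocks(blocks) != 2L)
    stop("the GSVD is defined for exactly two blocks (K = 2)")
  X1 <- blocks$blocks[[1L]]
  X2 <- blocks$blocks[[2L]]
  if (anyNA(X1) || anyNA(X2)) stop("missing values; preprocess first")
  Xc <- rbind(X1, X2)
  I1 <- nrow(X1)

  sv <- svd(Xc)
  if (sv$d[1L] == 0) stop("concatenated data matrix is zero")
  if (is.null(rank_tol))
    rank_tol <- max(dim(Xc)) * .Machine$double.eps
  Q <- sum(sv$d > rank_tol * sv$d[1L])
  core_gsvd(sv, Q, I1, blocks)
}

## shared core: GSVD of the rank-Q part of a precomputed SVD of Xc,
## with VAF denominators taken from `blocks`
core_gsvd <- function(sv, Q, I1, blocks, adapted = FALSE) {
  if (Q > min(I1, nrow(sv$u) - I1))
    stop("rank of the concatenated data (", Q, ") exceeds a block's row ",
         "count; the GSVD orthonormal block bases do not exist")
  P <- sv$u[, seq_len(Q), drop = FALSE]
  Sig <- sv$d[seq_len(Q)]
  W <- sv$v[, seq_len(Q), drop = FALSE]
  P1 <- P[seq_len(I1), , drop = FALSE]
  P2 <- P[-seq_len(I1), , drop = FALSE]

  cs <- svd(P1, nu = Q, nv = Q)
  U1 <- cs$u
  Z <- cs$v
  cvec <- pmin(cs$d, 1)

  ## components with (numerically) equal cosines are determined only up to a
  ## joint rotation; canonicalize each such group so that its V columns are
  ## orthogonal with descending norm, which restores the generating
  ## structure whenever the group's scales differ
  if (Q > 1L) {
    grp_end <- c(which(abs(diff(cvec)) > 1e-8), Q)
    grp_start <- c(1L, utils::head(grp_end, -1L) + 1L)
    for (i in seq_along(grp_end)) {
      g <- grp_start[i]:grp_end[i]
      if (length(g) < 2L) next
      Vg <- W %*% (Sig * Z[, g, drop = FALSE])
      M <- svd(Vg)$v
      Z[, g] <- Z[, g, drop = FALSE] %*% M
      U1[, g] <- U1[, g, drop = FALSE] %*% M
    }
  }

  M2 <- P2 %*% Z
  svec <- sqrt(colSums(M2^2))
  zero_s <- svec < 1e-12
  U2 <- M2
  U2[, !zero_s] <- sweep(M2[, !zero_s, drop = FALSE], 2L,
                         svec[!zero_s], "/")
  if (any(zero_s))
    U2[, zero_s] <- orthonormal_completion(U2[, !zero_s, drop = FALSE],
                                           nrow(U2), sum(zero_s))
  V <- W %*% (Sig * Z)

  ## order by descending concatenated VAF = ||v_q||^2 / ||Xc||^2
  vnorm2 <- colSums(V^2)
  ord <- order(vnorm2, decreasing = TRUE)
  U1 <- U1[, ord, drop = FALSE]; U2 <- U2[, ord, drop = FALSE]
  cvec <- cvec[ord]; svec <- svec[ord]; V <- V[, ord, drop = FALSE]
  vnorm2 <- vnorm2[ord]

  ## sign convention: largest-magnitude element of each v_q positive
  for (q in seq_len(Q)) {
    piv <- which.max(abs(V[, q]))
    if (V[piv, q] < 0) {
      V[, q] <- -V[, q]; U1[, q] <- -U1[, q]; U2[, q] <- -U2[, q]
    }
  }

  ## non-uniqueness flag: near-equal c^2 pairs, or arbitrary basis vectors
  c2 <- cvec^2
  stable <- rep(TRUE, Q)
  if (Q > 1L)
    for (q in seq_len(Q))
      if (any(abs(c2[q] - c2[-q]) < 1e-6)) stable[q] <- FALSE
  stable[zero_s[ord]] <- FALSE
  stable[cvec < 1e-12] <- FALSE

  block_ss <- total_ss(blocks, by_block = TRUE)
  dimnames(U1) <- list(rownames(blocks$blocks[[1L]]), paste0("C", seq_len(Q)))
  dimnames(U2) <- list(rownames(blocks$blocks[[2L]]), paste0("C", seq_len(Q)))
  dimnames(V) <- list(blocks$col_ids, paste0("C", seq_len(Q)))

  res <- structure(list(U1 = U1, U2 = U2, c = cvec, s = svec, V = V, Q = Q,
                        stable = stable, adapted = adapted,
                        block_ss = block_ss,
                        concatenated_ss = sum(block_ss)),
                   class = "gsvd")
  res$vaf <- gsvd_vaf(res, blocks)
  res
}

## append k extra orthonormal columns orthogonal to the columns of A (n x m)
orthonormal_completion <- function(A, n, k) {
  m <- if (length(A)) ncol(A) else 0L
  Qfull <- qr.Q(qr(cbind(A, diag(n))))
  Qfull[, m + seq_len(k), drop = FALSE]
}

#' Adapted (least-squares) GSVD
#'
#' Replaces the data by their rank-\code{R} least-squares approximation (the
#' truncated SVD of the concatenation) and applies the GSVD to the result.
#' The outcome is a rank-\code{R} decomposition whose total VAF per block
#' equals that of the rank-\code{R} simultaneous component analysis exactly
#' — the adapted GSVD is an optimal-approximation method, unlike the full
#' GSVD.  Reported VAF values are computed against the ORIGINAL (untruncated)
#' blocks.
#'
#' @param blocks a \code{\link{linked_blocks}} object with two blocks.
#' @param R number of components, between 1 and the rank of the
#'   concatenation.
#' @return An object of class \code{"gsvd"} with \code{Q = R} components and
#'   \code{adapted = TRUE}; see \code{\link{gsvd}} for the fields.
#' @export
adapted_gsvd <- function(blocks, R) {
  stopifnot(inherits(blocks, "linked_blocks"))
  if (n_blocks(blocks) != 2L)
    stop("the adapted GSVD is defined for exactly two blocks (K = 2)")
  Xc <- concat_blocks(blocks)
  if (anyNA(Xc)) stop("missing values; preprocess first")
  sv <- svd(Xc)
  rank_c <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  if (R < 1L || R > rank_c)
    stop("R must lie between 1 and the rank of the concatenated data (",
         rank_c, ")")
  core_gsvd(sv, R, nrow(blocks$blocks[[1L]]), blocks, adapted = TRUE)
}

#' VAF accounting for a GSVD
#'
#' Computes, per component, the proportion of variation accounted for in
#' each block and in the concatenated data.  The concatenated VAF of
#' component \eqn{q} is \eqn{\|v_q\|^2 / \|X_c\|_F^2} (the sum of squares of
#' its rank-1 term, using \eqn{c_q^2 + s_q^2 = 1}); the block-\eqn{k} VAF is
#' \eqn{s_{kq}^2 \|v_q\|^2 / \|X_k\|_F^2}.  Because the columns of \eqn{V}
#' are not orthogonal, per-component values of a full GSVD need not sum to
#' the VAF of the corresponding joint approximation.
#'
#' @param result a \code{\link{gsvd}} fit.
#' @param blocks the \code{linked_blocks} the fit was computed from (or any
#'   blocks of identical shape to measure against).
#' @return a \code{vaf_table}.
#' @export
gsvd_vaf <- function(result, blocks) {
  stopifnot(inherits(result, "gsvd"), inherits(blocks, "linked_blocks"))
  if (nrow(result$U1) != nrow(blocks$blocks[[1L]]) ||
      nrow(result$U2) != nrow(blocks$blocks[[2L]]) ||
      nrow(result$V) != length(blocks$col_ids))
    stop("blocks do not match the dimensions of the GSVD result")
  block_ss <- total_ss(blocks, by_block = TRUE)
  vnorm2 <- colSums(result$V^2)
  per_block <- cbind(result$c^2 * vnorm2 / block_ss[1L],
                     result$s^2 * vnorm2 / block_ss[2L])
  colnames(per_block) <- blocks$block_ids
  new_vaf_table(per_block, vnorm2 / sum(block_ss),
                note = paste("per-component values need not sum to the joint",
                             "VAF: the columns of V are not orthogonal"))
}

#' Classify GSVD components as common or distinctive
#'
#' Uses the cosine weights: \eqn{c_q^2} close to 0.5 marks a common
#' component, close to 1 a component distinctive for block 1, close to 0 one
#' distinctive for block 2.  "Close to" is operationalised by configurable
#' bands; components falling in neither band are labelled
#' \code{"undetermined"}.
#'
#' @param result a \code{\link{gsvd}} fit.
#' @param common_band interval of \eqn{c_q^2} values labelled common.
#' @param distinct_margin components with \eqn{c_q^2 \ge 1 -}
#'   \code{distinct_margin} (\eqn{\le} \code{distinct_margin}) are labelled
#'   distinctive for block 1 (block 2).
#' @return character vector of per-component labels.
#' @export
classify_components <- function(result, common_band = c(0.4, 0.6),
                                distinct_margin = 0.05) {
  stopifnot(inherits(result, "gsvd"),
            length(common_band) == 2L, common_band[1L] < common_band[2L],
            distinct_margin > 0)
  if (common_band[1L] < distinct_margin ||
      common_band[2L] > 1 - distinct_margin)
    stop("common band overlaps the distinctive bands")
  c2 <- result$c^2
  labels <- rep("undetermined", length(c2))
  labels[c2 >= common_band[1L] & c2 <= common_band[2L]] <- "common"
  labels[c2 >= 1 - distinct_margin] <- "distinctive_1"
  labels[c2 <= distinct_margin] <- "distinctive_2"
  labels
}

#' @export
print.gsvd <- function(x, ...) {
  cat(if (x$adapted) "Adapted (least-squares) GSVD" else
      "Generalized singular value decomposition", "\n", sep = "")
  cat("  components Q =", x$Q, "\n")
  cat("  c^2 (block-1 weight): ", paste(format(round(x$c^2, 3)), collapse = " "),
      "\n", sep = "")
  cat("  total VAF per block: ",
      paste(names(x$block_ss), format(round(x$vaf$block_totals, 3)),
            collapse = ", "), "\n", sep = " ")
  if (!all(x$stable))
    cat("  note: components", toString(which(!x$stable)),
        "are not uniquely determined\n")
  invisible(x)
}

#' @export
summary.gsvd <- function(object, ...) {
  out <- list(Q = object$Q, adapted = object$adapted,
              c2 = object$c^2,
              status = classify_components(object),
              vaf = object$vaf)
  class(out) <- "summary.gsvd"
  out
}

#' @export
print.summary.gsvd <- function(x, ...) {
  cat(if (x$adapted) "Adapted GSVD" else "GSVD", "with", x$Q, "components\n")
  tab <- data.frame(c2 = round(x$c2, 3), status = x$status)
  rownames(tab) <- paste0("C", seq_len(x$Q))
  print(tab)
  cat("\nVariation accounted for:\n")
  print(x$vaf)
  invisible(x)
}
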