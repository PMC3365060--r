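#' Simultaneous component analysis of linked blocks
#'
#' Fits the rank-\code{R} simultaneous component model
#' \deqn{X_k \approx T_k P^T, \qquad k = 1, \dots, K,}
#' in which all blocks share one factor \eqn{P} on their common (column)
#' mode.  The least-squares solution is the truncated SVD of the row-wise
#' concatenation \eqn{X_c = U_c S_c V_c^T}: the block factor is
#' \eqn{[T_1^T \dots T_K^T]^T = U_{cR} S_{cR}} and the shared factor
#' \eqn{P = V_{cR}}.
#'
#' The canonical orientation used internally puts the orthonormal factor on
#' the shared mode and the scale on the block factor; with \eqn{P^T P = I}
#' the sum of squares of component \eqn{r} inside block \eqn{k} is simply
#' the squared norm of column \eqn{r} of that block's factor rows (cross
#' terms vanish), which makes per-block per-component VAF additive — the
#' property the DISCO deviation measure relies on.
#'
#' @param blocks a \code{\link{linked_blocks}} object.
#' @param R number of components, between 1 and the rank of \eqn{X_c}.
#' @return An object of class \code{"sca"}: \code{block_factor}
#'   (\eqn{\sum_k I_k \times R}, rows grouped by block), \code{shared_factor}
#'   (\eqn{J \times R}, orthonormal columns), \code{singvals},
#'   \code{R}, \code{row_index} (list of concatenated-row ranges per block),
#'   \code{block_ss}, \code{vaf} (a \code{vaf_table}),
#'   \code{boundary_tie} (\code{TRUE} when the \code{R}-th and
#'   \code{R+1}-th singular values coincide, so the retained subspace is not
#'   unique), plus ids and the call.
#' @seealso \code{\link{disco_sca}} for the rotation to common/distinctive
#'   structure; \code{\link{sca_scree}} for choosing \code{R}.
#' @examples
#' sim <- simulate_blocks(simulation_spec(dims = c(20, 12, 10),
#'   imposed_vaf = cbind(c(0.4, 0.2), c(0.4, 0.2)), noise_fraction = 0.1,
#'   seed = 7))
#' fit <- sca(sim$blocks, R = 2)
#' fit$vaf
#' @export
sca <- function(blocks, R) {
  stopifnot(inherits(blocks, "linked_blocks"))
  Xc <- concat_blocks(blocks)
  if (anyNA(Xc)) stop("missing values; preprocess first")
  sv <- svd(Xc)
  rank_c <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  if (R < 1L || R > rank_c)
    stop("R must lie between 1 and the rank of the concatenated data (",
         rank_c, ")")

  Tmat <- sv$u[, seq_len(R), drop = FALSE] %*% diag(sv$d[seq_len(R)], R)
  P <- sv$v[, seq_len(R), drop = FALSE]

  ## sign convention: largest-magnitude element of each shared-factor
  ## column positive
  for (r in seq_len(R)) {
    piv <- which.max(abs(P[, r]))
    if (P[piv, r] < 0) {
      P[, r] <- -P[, r]; Tmat[, r] <- -Tmat[, r]
    }
  }

  row_index <- block_row_index(blocks)
  block_ss <- total_ss(blocks, by_block = TRUE)
  vaf <- new_vaf_table(factor_block_vaf(Tmat, row_index, block_ss),
                       sv$d[seq_len(R)]^2 / sum(block_ss))

  rownames(Tmat) <- unlist(lapply(blocks$blocks, rownames), use.names = FALSE)
  colnames(Tmat) <- paste0("C", seq_len(R))
  dimnames(P) <- list(blocks$col_ids, paste0("C", seq_len(R)))

  boundary_tie <- R < rank_c &&
    (sv$d[R] - sv$d[R + 1L]) < 1e-10 * sv$d[1L]

  structure(list(block_factor = Tmat, shared_factor = P,
                 singvals = sv$d[seq_len(R)], R = R,
                 row_index = row_index, block_ss = block_ss,
                 concatenated_ss = sum(block_ss),
                 block_ids = blocks$block_ids, col_ids = blocks$col_ids,
                 boundary_tie = boundary_tie, vaf = vaf,
                 call = match.call()),
            class = "sca")
}

#' Scree-style VAF table for component-number selection
#'
#' Computes the per-component, per-block VAF of the first \code{R_max}
#' simultaneous components, ordered by their VAF in the concatenated data.
#' Plotted per block, this generalizes the scree graph of principal
#' component analysis to linked blocks: a pronounced drop after component
#' \eqn{r} in all blocks suggests retaining \eqn{r} components.
#'
#' @param blocks a \code{\link{linked_blocks}} object.
#' @param R_max largest number of components to chart; values beyond the
#'   rank of the concatenation appear as exact-zero rows.
#' @return a \code{vaf_table} with \code{R_max} rows.
#' @export
sca_scree <- function(blocks, R_max) {
  stopifnot(R_max >= 1L)
  Xc <- concat_blocks(blocks)
  if (anyNA(Xc)) stop("missing values; preprocess first")
  sv <- svd(Xc)
  rank_c <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * sv$d[1L])
  vaf <- sca(blocks, min(R_max, rank_c))$vaf
  if (R_max <= rank_c) return(vaf)
  pad <- R_max - rank_c
  new_vaf_table(rbind(vaf$per_block, matrix(0, pad, ncol(vaf$per_block))),
                c(vaf$concatenated, rep(0, pad)), note = vaf$note)
}

#' @export
print.sca <- function(x, ...) {
  cat("Simultaneous component analysis, R =", x$R, "components\n")
  cat("  blocks:", paste(x$block_ids, collapse = ", "), "\n")
  cat("  total VAF per block:",
      paste(names(x$block_ss), format(round(x$vaf$block_totals, 3)),
            collapse = ", "), "\n")
  if (x$boundary_tie)
    cat("  note: singular-value tie at the rank boundary; the retained",
        "subspace is not unique\n")
  invisible(x)
}

#' @export
summary.sca <- function(object, ...) {
  structure(list(R = object$R, vaf = object$vaf,
                 singvals = object$singvals,
                 block_ids = object$block_ids), class = "summary.sca")
}

#' @export
print.summary.sca <- function(x, ...) {
  cat("Simultaneous component analysis, R =", x$R, "\n\n")
  cat("Variation accounted for:\n")
  print(x$vaf)
  invisible(x)
}

#' @export
coef.sca <- function(object, ...) object$shared_factor

#' @export
fitted.sca <- function(object, ...) {
  rec <- object$block_factor %*% t(object$shared_factor)
  lapply(stats::setNames(seq_along(object$row_index), object$block_ids),
         function(k) rec[object$row_index[[k]], , drop = FALSE])
}

#' @export
plot.sca <- function(x, ...) {
  plot_vaf_scree(x$vaf, main = "SCA variation accounted for", ...)
}

#' Scree-style barplot of a VAF table
#'
#' One panel per block, components on the horizontal axis in concatenated-
#' VAF order.
#'
#' @param vaf a \code{vaf_table}.
#' @param main overall title.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @return invisibly, \code{vaf}.
#' @export
plot_vaf_scree <- function(vaf, main = "Variation accounted for", ...) {
  pb <- vaf$per_block
  K <- ncol(pb)
  old <- graphics::par(mfrow = c(K, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(K))
    graphics::barplot(pb[, k], ylab = "proportion of VAF",
                      main = if (k == 1L) main else "",
                      sub = colnames(pb)[k], ...)
  invisible(vaf)
}
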