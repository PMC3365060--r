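## Variation-accounted-for tables ------------------------------------------

#' Construct a VAF table
#'
#' Internal constructor shared by the SCA, GSVD and DISCO code paths.  A VAF
#' table holds, for a set of components, the proportion of each block's sum
#' of squares that the component accounts for, together with the proportion
#' of the concatenated SS.
#'
#' @param per_block components x blocks matrix of proportions.
#' @param concatenated per-component proportions of the concatenated SS.
#' @param note optional character remark carried along (e.g. that per-
#'   component values of a full GSVD need not sum to the joint VAF because
#'   the shared structure V is not column-orthogonal).
#' @return an object of class \code{"vaf_table"}.
#' @keywords internal
new_vaf_table <- function(per_block, concatenated, note = NULL) {
  stopifnot(is.matrix(per_block), nrow(per_block) == length(concatenated))
  rownames(per_block) <- paste0("C", seq_len(nrow(per_block)))
  structure(list(per_block = per_block,
                 concatenated = stats::setNames(concatenated,
                                                rownames(per_block)),
                 block_totals = colSums(per_block),
                 overall_total = sum(concatenated),
                 note = note),
            class = "vaf_table")
}

#' @export
print.vaf_table <- function(x, digits = 3, ...) {
  tab <- cbind(x$per_block, concatenated = x$concatenated)
  tab <- rbind(tab, Total = c(x$block_totals, x$overall_total))
  print(round(tab, digits))
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' @export
as.matrix.vaf_table <- function(x, ...) x$per_block

## per-component, per-block VAF of a (block_factor, orthonormal shared
## factor) pair: with the shared factor column-orthonormal the SS of
## component r inside block k is just the squared norm of the block's factor
## column, cross terms vanish.
factor_block_vaf <- function(block_factor, row_index, block_ss) {
  K <- length(row_index)
  R <- ncol(block_factor)
  out <- matrix(0, R, K)
  for (k in seq_len(K))
    out[, k] <- colSums(block_factor[row_index[[k]], , drop = FALSE]^2) / block_ss[k]
  colnames(out) <- names(block_ss)
  out
}
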