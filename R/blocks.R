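#' Linked data blocks sharing one mode
#'
#' Bundles two or more numeric matrices that share their column mode (the
#' same samples, time points, ...) into a single object that every method in
#' the package consumes.  Rows are block-specific variables (genes,
#' metabolites); columns are the shared entities and must carry identical
#' identifiers across blocks.  Blocks whose columns are a permutation of the
#' first block's are silently re-ordered to match it.
#'
#' @param ... numeric matrices with unique rownames and colnames, or a single
#'   list of such matrices.  Names of the arguments (or list) become block
#'   identifiers; unnamed blocks are called \code{"X1"}, \code{"X2"}, ...
#' @return An object of class \code{"linked_blocks"}: a list with elements
#'   \code{blocks} (named list of matrices), \code{block_ids},
#'   \code{col_ids}, \code{block_rows} (row counts) and
#'   \code{concatenated_ss}, the total sum of squares of the row-wise
#'   concatenation (\code{NA} while missing values are still present).
#' @examples
#' X1 <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' X2 <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("m", 1:3), paste0("s", 1:4)))
#' lb <- linked_blocks(X1 = X1, X2 = X2)
#' lb
#' @export
linked_blocks <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1L]]) && !is.matrix(dots[[1L]]))
    dots <- dots[[1L]]
  if (length(dots) < 2L)
    stop("at least two linked blocks are required (K >= 2)")
  ids <- names(dots)
  if (is.null(ids)) ids <- rep("", length(dots))
  empty <- !nzchar(ids)
  ids[empty] <- paste0("X", seq_along(dots))[empty]
  if (anyDuplicated(ids)) stop("block ids must be unique")

  blocks <- lapply(seq_along(dots), function(k) {
    x <- dots[[k]]
    if (!is.matrix(x) || !is.numeric(x))
      stop("block '", ids[k], "' is not a numeric matrix")
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("block '", ids[k], "' must have row and column identifiers")
    if (anyDuplicated(rownames(x)))
      stop("duplicated row ids in block '", ids[k], "'")
    if (anyDuplicated(colnames(x)))
      stop("duplicated column ids in block '", ids[k], "'")
    x
  })
  names(blocks) <- ids

  ref <- colnames(blocks[[1L]])
  for (k in seq_along(blocks)[-1L]) {
    have <- colnames(blocks[[k]])
    if (!setequal(ref, have)) {
      miss <- setdiff(ref, have)
      extra <- setdiff(have, ref)
      stop("column ids of block '", ids[k], "' do not match block '", ids[1L],
           "'", if (length(miss)) paste0("; missing: ", toString(miss)),
           if (length(extra)) paste0("; extra: ", toString(extra)))
    }
    blocks[[k]] <- blocks[[k]][, ref, drop = FALSE]
  }

  ss <- vapply(blocks, function(x) sum(x^2), numeric(1))
  structure(list(blocks = blocks,
                 block_ids = ids,
                 col_ids = ref,
                 block_rows = vapply(blocks, nrow, integer(1)),
                 concatenated_ss = sum(ss)),
            class = "linked_blocks")
}

#' @export
print.linked_blocks <- function(x, ...) {
  cat("Linked data blocks (K = ", length(x$blocks), ", shared columns J = ",
      length(x$col_ids), ")\n", sep = "")
  for (k in seq_along(x$blocks)) {
    b <- x$blocks[[k]]
    cat(sprintf("  %-10s %5d x %d  SS = %s\n", x$block_ids[k],
                nrow(b), ncol(b),
                format(sum(b^2), digits = 6)))
  }
  invisible(x)
}

#' Number of blocks
#' @param blocks a \code{linked_blocks} object.
#' @return integer K.
#' @export
n_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "linked_blocks"))
  length(blocks$blocks)
}

#' Row-wise concatenation of linked blocks
#'
#' @param blocks a \code{linked_blocks} object.
#' @return The matrix \eqn{X_c = [X_1^T ... X_K^T]^T}.
#' @export
concat_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "linked_blocks"))
  do.call(rbind, unname(blocks$blocks))
}

#' Sums of squares of linked blocks
#'
#' @param blocks a \code{linked_blocks} object.
#' @param by_block return per-block values instead of the total?
#' @return total (default) or named per-block sum of squares.
#' @export
total_ss <- function(blocks, by_block = FALSE) {
  stopifnot(inherits(blocks, "linked_blocks"))
  ss <- vapply(blocks$blocks, function(x) sum(x^2), numeric(1))
  if (by_block) ss else sum(ss)
}

## Row ranges of each block inside the concatenated matrix.
block_row_index <- function(blocks) {
  ends <- cumsum(blocks$block_rows)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(k) starts[k]:ends[k])
}

## Apply a per-matrix transformation to every block, revalidating at the end.
map_blocks <- function(blocks, f, ...) {
  out <- lapply(seq_along(blocks$blocks), function(k)
    f(blocks$blocks[[k]], blocks$block_ids[k], ...))
  names(out) <- blocks$block_ids
  linked_blocks(out)
}

read_one_block <- function(path, delimiter, block_id) {
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  m <- as.matrix(raw)
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m), dimnames = dimnames(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric value in block '", block_id, "' at row '",
         rownames(m)[bad[1L, 1L]], "', column '", colnames(m)[bad[1L, 2L]],
         "': \"", m[bad[1L, , drop = FALSE]], "\"")
  num
}

#' Read linked blocks from delimited text files
#'
#' Each file holds one block: a header row of column ids, a leading column of
#' row ids, and numeric cells.  Empty fields and \code{NA} are read as
#' missing (only meaningful for data that will pass through
#' \code{\link{impute_below_detection}}).  Columns of later files are aligned
#' to the order of the first file's columns.
#'
#' @param paths character vector of file paths (length >= 2).
#' @param delimiter field separator; tab by default.
#' @param block_ids optional block identifiers; defaults to the file base
#'   names without extension.
#' @return a \code{\link{linked_blocks}} object.
#' @export
read_linked_blocks <- function(paths, delimiter = "\t", block_ids = NULL) {
  if (length(paths) < 2L) stop("need at least two block files")
  if (is.null(block_ids)) {
    block_ids <- sub("\\.[^.]*$", "", basename(paths))
    if (anyDuplicated(block_ids)) block_ids <- paste0("X", seq_along(paths))
  }
  mats <- lapply(seq_along(paths), function(k)
    read_one_block(paths[k], delimiter, block_ids[k]))
  names(mats) <- block_ids
  linked_blocks(mats)
}

#' Write linked blocks to delimited text files
#'
#' Inverse of \code{\link{read_linked_blocks}}; numbers are written with 10
#' significant digits so that finite decimals round-trip exactly.
#'
#' @param blocks a \code{linked_blocks} object.
#' @param paths one output path per block.
#' @param delimiter field separator; tab by default.
#' @return \code{paths}, invisibly.
#' @export
write_linked_blocks <- function(blocks, paths, delimiter = "\t") {
  stopifnot(inherits(blocks, "linked_blocks"),
            length(paths) == length(blocks$blocks))
  for (k in seq_along(paths)) {
    x <- blocks$blocks[[k]]
    cells <- formatC(x, digits = 10L, format = "g")
    cells[is.na(x)] <- "NA"
    lines <- c(paste(c("id", colnames(x)), collapse = delimiter),
               paste(rownames(x), apply(cells, 1L, paste, collapse = delimiter),
                     sep = delimiter))
    writeLines(lines, paths[k])
  }
  invisible(paths)
}

## dispatch helper: run a single-matrix operation on a matrix or on every
## block of a linked_blocks object
apply_block_op <- function(x, f, ...) {
  if (inherits(x, "linked_blocks")) {
    map_blocks(x, function(m, id) f(m, id, ...))
  } else if (is.matrix(x)) {
    f(x, "block", ...)
  } else stop("expected a matrix or a linked_blocks object")
}

#' Center and scale each row
#'
#' Subtracts the row mean and scales each row to sum of squares one — the
#' standard per-gene (per-metabolite) preprocessing that stops absolute
#' abundance differences from dominating the component solutions.
#'
#' @param x a numeric matrix or a \code{linked_blocks} object.
#' @return the same type as \code{x}, rows centered and with unit SS.
#' @export
center_scale_rows <- function(x) {
  apply_block_op(x, function(m, id) {
    if (anyNA(m)) stop("missing values in block '", id, "'; impute first")
    centered <- m - rowMeans(m)
    ss <- rowSums(centered^2)
    bad <- ss == 0
    if (any(bad))
      stop("constant rows in block '", id, "': ",
           toString(rownames(m)[bad]))
    centered / sqrt(ss)
  })
}

#' Square-root transform
#'
#' Elementwise square root, used to reduce the skewness of peak-area data.
#' All values must be nonnegative.
#'
#' @inheritParams center_scale_rows
#' @return the transformed matrix or blocks.
#' @export
sqrt_transform <- function(x) {
  apply_block_op(x, function(m, id) {
    if (any(m < 0, na.rm = TRUE))
      stop("negative values in block '", id, "'; sqrt transform undefined")
    sqrt(m)
  })
}

#' Impute values below the detection threshold
#'
#' Replaces every missing cell by one half of the smallest detected value of
#' its block, modelling a single detection limit per measurement platform.
#' Detected means non-missing and strictly positive.
#'
#' @inheritParams center_scale_rows
#' @return the imputed matrix or blocks; no missing values remain.
#' @export
impute_below_detection <- function(x) {
  apply_block_op(x, function(m, id) {
    detected <- m[!is.na(m) & m > 0]
    if (!anyNA(m)) return(m)
    if (length(detected) == 0L)
      stop("block '", id, "' has no detected (positive) values to impute from")
    m[is.na(m)] <- min(detected) / 2
    m
  })
}

#' Block weighting
#'
#' Rescales whole blocks so that no single block dominates the joint
#' analysis: \code{"sqrt_rows"} divides a block by the square root of its
#' number of rows (appropriate when rows were already scaled to unit SS);
#' \code{"unit_ss"} scales each block to total sum of squares one;
#' \code{"none"} leaves the data untouched.
#'
#' @inheritParams center_scale_rows
#' @param mode one of \code{"sqrt_rows"}, \code{"unit_ss"}, \code{"none"}.
#' @return the weighted matrix or blocks.
#' @export
weight_block <- function(x, mode = c("sqrt_rows", "unit_ss", "none")) {
  mode <- match.arg(mode)
  apply_block_op(x, function(m, id) {
    switch(mode,
      sqrt_rows = m / sqrt(nrow(m)),
      unit_ss = {
        ss <- sum(m^2)
        if (ss == 0) stop("block '", id, "' has zero sum of squares")
        m / sqrt(ss)
      },
      none = m)
  })
}
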