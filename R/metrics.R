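#' Tucker's coefficient of congruence
#'
#' The cosine between two component vectors,
#' \eqn{\phi = a^T b / (\|a\| \|b\|)}: a scale-invariant similarity in
#' \eqn{[-1, 1]} that is sensitive to rotation but not to (positive)
#' rescaling, which makes it the standard recovery measure for component
#' solutions defined only up to scaling.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return \eqn{\phi} in \eqn{[-1, 1]}.
#' @examples
#' tucker_congruence(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
tucker_congruence <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("congruence is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

## all injective assignments of `r` items into `n` slots (list of integer
## vectors); r <= n, sizes meant for small component counts
injections <- function(n, r) {
  if (r == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(chosen, remaining) {
    if (length(chosen) == r) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (x in remaining) recurse(c(chosen, x), setdiff(remaining, x))
  }
  recurse(integer(0), seq_len(n))
  out
}

#' Match estimated components to true components
#'
#' Components of a factorization are identified only up to permutation and
#' reflection (sign flip).  This finds, for each column of \code{truth}, a
#' distinct column of \code{estimate} so that the mean absolute Tucker
#' congruence over the matched pairs is maximal, and the sign making each
#' matched congruence nonnegative.  The search is exhaustive (hence exactly
#' optimal) for up to 8 estimate columns and greedy beyond that.
#'
#' \code{estimate} may have more columns than \code{truth} (e.g. when only
#' the components with nonzero generated signal are scored); the surplus
#' columns are left unmatched.
#'
#' @param truth matrix of true component vectors (columns).
#' @param estimate matrix of estimated component vectors; at least as many
#'   columns as \code{truth}.
#' @return An object of class \code{"match_result"}: \code{permutation}
#'   (estimate column matched to each truth column), \code{signs},
#'   \code{per_column_phi} (matched congruences, all \eqn{\ge 0}) and
#'   \code{mean_phi}.
#' @export
match_components <- function(truth, estimate) {
  truth <- as.matrix(truth); estimate <- as.matrix(estimate)
  if (nrow(truth) != nrow(estimate))
    stop("component matrices differ in row count")
  r <- ncol(truth); n <- ncol(estimate)
  if (n < r) stop("estimate has fewer columns than truth")

  phi <- matrix(0, r, n)
  for (i in seq_len(r)) for (j in seq_len(n))
    phi[i, j] <- tucker_congruence(truth[, i], estimate[, j])
  aphi <- abs(phi)

  if (n <= 8L) {
    best <- NULL; best_val <- -Inf
    for (perm in injections(n, r)) {
      val <- sum(aphi[cbind(seq_len(r), perm)])
      if (val > best_val) { best_val <- val; best <- perm }
    }
  } else {
    ## greedy: repeatedly take the best remaining pair
    best <- integer(r)
    work <- aphi
    repeat {
      idx <- which(work == max(work), arr.ind = TRUE)[1L, ]
      best[idx[1L]] <- idx[2L]
      work[idx[1L], ] <- -Inf
      work[, idx[2L]] <- -Inf
      if (all(best > 0L)) break
    }
  }
  signs <- ifelse(phi[cbind(seq_len(r), best)] < 0, -1, 1)
  per_phi <- aphi[cbind(seq_len(r), best)]
  structure(list(permutation = best, signs = signs,
                 per_column_phi = per_phi, mean_phi = mean(per_phi)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Component matching: mean |phi| =", format(x$mean_phi, digits = 4),
      "\n  permutation:", paste(x$permutation, collapse = " "),
      "\n  signs:      ", paste(ifelse(x$signs > 0, "+", "-"),
                                collapse = " "), "\n")
  invisible(x)
}

#' Recovery of the generating structures
#'
#' Mean matched Tucker congruence between the generated bases of a
#' \code{\link{simulate_blocks}} pair and their estimates: for the shared
#' structure \eqn{V} over all \eqn{R} components, and for each block basis
#' \eqn{U_k} only over the components with nonzero generated signal in
#' block \eqn{k} — where the generated singular value is zero the basis
#' vector is arbitrary, so it is excluded from the score.  Because
#' \eqn{\phi} is scale-invariant, estimates may be supplied with or without
#' singular-value scaling (\eqn{U_k} or \eqn{U_k S_k}) with identical
#' results.
#'
#' @param sim a \code{\link{simulate_blocks}} result.
#' @param estimates list with matrices \code{V}, \code{U1}, \code{U2}
#'   (each with \eqn{R} columns, e.g. from
#'   \code{\link{gsvd}} / \code{\link{disco_sca}} fits).
#' @return list with elements \code{V}, \code{U1}, \code{U2}: mean matched
#'   \eqn{\phi} per structure (matched separately per structure).
#' @export
recovery_report <- function(sim, estimates) {
  stopifnot(inherits(sim, "simulated_pair"),
            all(c("V", "U1", "U2") %in% names(estimates)))
  S <- sim$truth$singvals
  score <- function(truth, est, keep) {
    truth <- truth[, keep, drop = FALSE]
    if (ncol(truth) == 0L) return(NA_real_)
    match_components(truth, est)$mean_phi
  }
  list(V = score(sim$truth$V, estimates$V, rep(TRUE, ncol(sim$truth$V))),
       U1 = score(sim$truth$U1, estimates$U1, S[, 1L] > 0),
       U2 = score(sim$truth$U2, estimates$U2, S[, 2L] > 0))
}

#' Separation of labelled rows in component space
#'
#' Measures whether rows (e.g. genes) sharing a class label lie close
#' together in the component space: the Pearson correlation, over all pairs
#' of labelled rows, between (i) the cross product of their loading vectors
#' (closeness) and (ii) the binary indicator same (0) / different (1)
#' label.  With that coding, well-separated tight clusters give a strongly
#' \emph{negative} correlation (close pairs share labels); the absolute
#' value is reported alongside the literal signed value since either
#' orientation is found in practice.
#'
#' @param loadings rows-by-components numeric matrix.
#' @param labels class labels, one per row of \code{loadings}; \code{NA}
#'   marks unlabelled rows, which are ignored.
#' @return list with \code{correlation} (signed, coding same = 0 /
#'   different = 1), \code{abs_correlation} and \code{n_pairs}.
#' @export
label_separation <- function(loadings, labels) {
  loadings <- as.matrix(loadings)
  if (length(labels) != nrow(loadings))
    stop("one label (possibly NA) is required per row")
  keep <- !is.na(labels)
  if (sum(keep) < 3L) stop("need at least 3 labelled rows")
  labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("need at least two distinct labels")
  L <- loadings[keep, , drop = FALSE]
  G <- tcrossprod(L)
  pair <- which(upper.tri(G), arr.ind = TRUE)
  closeness <- G[pair]
  different <- as.numeric(labels[pair[, 1L]] != labels[pair[, 2L]])
  r <- stats::cor(closeness, different)
  list(correlation = r, abs_correlation = abs(r), n_pairs = nrow(pair))
}
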