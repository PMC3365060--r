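# Fixtures shared across the test files.  Everything is generated in code.

# random linked blocks with dimnames
rand_blocks <- function(I1, I2, J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X1 <- matrix(rnorm(I1 * J), I1, J,
               dimnames = list(paste0("a", seq_len(I1)), paste0("s", seq_len(J))))
  X2 <- matrix(rnorm(I2 * J), I2, J,
               dimnames = list(paste0("b", seq_len(I2)), paste0("s", seq_len(J))))
  linked_blocks(X1 = X1, X2 = X2)
}

# decreasing distinct weights summing to `total`
distinct_weights <- function(n, total) {
  if (n == 0L) return(numeric(0))
  w <- rev(seq_len(n))
  w / sum(w) * total
}

# imposed-VAF profile for a (d1, d2, common) composition that a noise-free
# pair can realize exactly: every block carries signal, common components
# have equal VAF proportions in both blocks, and weights within a
# same-status group are distinct (so the re-rotation is identifiable)
make_profile <- function(d1, d2, nc) {
  dtot <- if (nc > 0L) 0.6 else 1.0
  p1 <- c(distinct_weights(d1, dtot), rep(0, d2), distinct_weights(nc, 0.4))
  p2 <- c(rep(0, d1), distinct_weights(d2, dtot), distinct_weights(nc, 0.4))
  cbind(X1 = p1, X2 = p2)
}

# compositions (d1, d2, common) whose exact noise-free realization exists:
# each block must carry signal, and common components can have equal VAF
# proportions in both blocks only when the blocks' distinctive shares match
# (both zero or both positive)
realizable_compositions <- function(R) {
  out <- list()
  for (d1 in 0:R) for (d2 in 0:(R - d1)) {
    nc <- R - d1 - d2
    if (d1 + nc == 0L || d2 + nc == 0L) next
    if (nc > 0L && xor(d1 > 0L, d2 > 0L)) next
    out[[length(out) + 1L]] <- c(d1 = d1, d2 = d2, common = nc)
  }
  out
}

# status list for a (d1, d2, common) composition, in enumeration order
composition_statuses <- function(d1, d2, nc) {
  c(rep(list(1L), d1), rep(list(2L), d2), rep(list(1:2), nc))
}

# (V, U1, U2) estimates of a fitted disco rotation
disco_estimates <- function(rot, I1) {
  Tr <- rot$rotated$block_factor
  list(V = rot$rotated$shared_factor,
       U1 = Tr[seq_len(I1), , drop = FALSE],
       U2 = Tr[-seq_len(I1), , drop = FALSE])
}
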