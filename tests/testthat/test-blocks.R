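test_that("construction validates and aligns shared columns", {
  lb <- rand_blocks(5, 3, 4, seed = 1)
  expect_s3_class(lb, "linked_blocks")
  expect_equal(n_blocks(lb), 2L)
  expect_equal(lb$concatenated_ss, sum(concat_blocks(lb)^2))

  # permuted columns are re-aligned to the first block's order
  X1 <- lb$blocks$X1
  X2p <- lb$blocks$X2[, c(3, 1, 4, 2)]
  lb2 <- linked_blocks(X1 = X1, X2 = X2p)
  expect_identical(lb2$blocks$X2, lb$blocks$X2)

  # missing column is an alignment error naming the block
  expect_error(linked_blocks(X1 = X1, X2 = lb$blocks$X2[, 1:3]),
               "column ids of block 'X2'")
  expect_error(linked_blocks(X1 = X1), "at least two")
  Xdup <- X1; rownames(Xdup) <- rep("r", nrow(Xdup))
  expect_error(linked_blocks(X1 = X1, X2 = Xdup), "duplicated row ids")
})

test_that("delimited round trip preserves values and alignment", {
  lb <- rand_blocks(6, 4, 5, seed = 2)
  # finite decimals at the written precision
  lb <- linked_blocks(lapply(lb$blocks, function(m) round(m, 4)))
  paths <- file.path(tempdir(), c("x1.tsv", "x2.tsv"))
  write_linked_blocks(lb, paths)
  back <- read_linked_blocks(paths)
  expect_identical(back$blocks[[1]], lb$blocks[[1]])
  expect_identical(back$blocks[[2]], lb$blocks[[2]])

  # column permutation in the file is healed on read
  tab <- read.table(paths[2], sep = "\t", header = TRUE, row.names = 1,
                    check.names = FALSE)
  perm <- tab[, c(4, 2, 5, 1, 3)]
  write.table(data.frame(id = rownames(perm), perm, check.names = FALSE),
              paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- read_linked_blocks(paths)
  expect_equal(back2$blocks[[2]], lb$blocks[[2]])

  # non-numeric cell is a parse error with its location
  lines <- readLines(paths[1])
  lines[3] <- sub("\t[^\t]*$", "\toops", lines[3])
  writeLines(lines, paths[1])
  expect_error(read_linked_blocks(paths), "row 'a2'.*column 's5'")
})

test_that("row centering and scaling matches the hand example and is idempotent", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  out <- center_scale_rows(m)
  expect_equal(unname(out[1, ]), c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(3)
  m2 <- matrix(rnorm(40), 5, 8)
  once <- center_scale_rows(m2)
  expect_equal(rowMeans(once), rep(0, 5), tolerance = 1e-12)
  expect_equal(rowSums(once^2), rep(1, 5), tolerance = 1e-12)
  expect_equal(center_scale_rows(once), once, tolerance = 1e-12)

  mc <- rbind(bad1 = c(5, 5, 5), ok = c(1, 2, 4), bad2 = c(0, 0, 0))
  expect_error(center_scale_rows(mc), "bad1, bad2")
})

test_that("sqrt transform and below-detection imputation follow the rules", {
  expect_equal(sqrt_transform(matrix(c(4, 0, 1, 9, 16, 25), 2)),
               matrix(c(2, 0, 1, 3, 4, 5), 2))
  expect_error(sqrt_transform(matrix(c(1, -1), 1)), "negative")

  m <- matrix(c(2, 4, NA, 8), 2)
  expect_equal(impute_below_detection(m), matrix(c(2, 4, 1, 8), 2))
  full <- matrix(1:4, 2)
  expect_identical(impute_below_detection(full), full)
  expect_error(impute_below_detection(matrix(NA_real_, 2, 2)),
               "no detected")
})

test_that("block weighting modes scale as documented", {
  set.seed(4)
  m <- matrix(rnorm(16), 4, 4)
  expect_equal(weight_block(m, "sqrt_rows"), m / 2)
  expect_equal(sum(weight_block(m, "unit_ss")^2), 1, tolerance = 1e-12)
  expect_identical(weight_block(m, "none"), m)
  expect_error(weight_block(matrix(0, 2, 2), "unit_ss"), "zero sum of squares")

  # applied to linked blocks, every block is treated separately
  lb <- rand_blocks(4, 9, 3, seed = 5)
  w <- weight_block(lb, "unit_ss")
  expect_equal(unname(total_ss(w, by_block = TRUE)), c(1, 1),
               tolerance = 1e-12)
})
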