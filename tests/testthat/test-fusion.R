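# a block where column "sep" separates the classes and the rest is noise
planted_block <- function(n = 200, noise_cols = 9, seed = 41) {
  set.seed(seed)
  labels <- rep(c("positive", "negative"), each = n / 2)
  x <- matrix(rnorm(n * noise_cols), n, noise_cols)
  x <- cbind(x, sep = as.numeric(labels == "positive") + rnorm(n, sd = 0.05))
  colnames(x) <- c(paste0("noise", seq_len(noise_cols)), "sep")
  list(block = feature_block("toy", x), labels = labels)
}

test_that("importance ranking finds planted signal and ignores constants", {
  pb <- planted_block()
  imp <- rank_feature_importance(pb$block, pb$labels, seed = 1)
  expect_length(imp, 10)
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "sep")
  expect_gt(imp["sep"], max(imp[names(imp) != "sep"]))

  # a constant column is never split on
  x2 <- cbind(pb$block$x, flat = rep(1, nrow(pb$block$x)))
  imp2 <- rank_feature_importance(feature_block("toy", x2), pb$labels)
  expect_equal(unname(imp2["flat"]), 0)

  # determinism under a fixed seed
  expect_identical(imp, rank_feature_importance(pb$block, pb$labels, seed = 1))

  expect_error(rank_feature_importance(pb$block, rep("positive", 200)),
               "both classes")
})

test_that("mean-importance selection keeps columns at or above the mean", {
  pb <- planted_block()
  mask <- select_features(pb$block, pb$labels, seed = 1)
  expect_s3_class(mask, "selection_mask")
  expect_equal(mask$keep, unname(mask$importances >= mean(mask$importances)))
  expect_true(mask$keep[which(colnames(pb$block$x) == "sep")])
  expect_true(any(mask$keep))

  # the separating column survives selection across seeds
  for (s in 1:20) {
    m <- select_features(pb$block, pb$labels, seed = s)
    expect_true(m$keep[10])
  }

  # all-equal importances (all-constant block: every importance 0) keep
  # every column, the boundary of the >= rule
  const <- feature_block("flat", matrix(1, 100, 4,
                                        dimnames = list(NULL, letters[1:4])))
  m0 <- select_features(const, rep(c("positive", "negative"), 50))
  expect_equal(m0$keep, rep(TRUE, 4))

  mt <- select_features(pb$block, pb$labels, rule = "top_n", n = 3, seed = 1)
  expect_equal(sum(mt$keep), 3)
  expect_true(mt$keep[10])
})

test_that("fusion concatenates kept columns and preserves values", {
  set.seed(42)
  a <- feature_block("A", matrix(rnorm(20), 5, 4,
                                 dimnames = list(NULL, paste0("a", 1:4))))
  b <- feature_block("B", matrix(rnorm(15), 5, 3,
                                 dimnames = list(NULL, paste0("b", 1:3))))

  all_mask <- structure(list(block_name = "A", keep = rep(TRUE, 4)),
                        class = "selection_mask")
  ident <- fuse(list(a), list(all_mask))
  expect_equal(unname(ident$x), unname(a$x))
  expect_equal(colnames(ident$x), paste0("A:", colnames(a$x)))

  ma <- structure(list(block_name = "A", keep = c(TRUE, FALSE, TRUE, FALSE)),
                  class = "selection_mask")
  mb <- structure(list(block_name = "B", keep = c(FALSE, TRUE, FALSE)),
                  class = "selection_mask")
  fused <- fuse(list(a, b), list(ma, mb))
  expect_equal(ncol(fused$x), 3)
  expect_equal(colnames(fused$x), c("A:a1", "A:a3", "B:b2"))
  # every fused cell traces to its source-block cell
  expect_equal(fused$x[, "A:a3"], a$x[, "a3"])
  expect_equal(fused$x[, "B:b2"], b$x[, "b2"])

  short <- feature_block("B", b$x[1:4, ])
  expect_error(fuse(list(a, short)), "rows")
})

test_that("fused k-mer columns equal the original k-mer block columns", {
  set.seed(43)
  set <- balanced_window_set(10, 21)
  kb <- encode_dataset(set, encoder_spec("kmer", k = 3))
  bb <- encode_dataset(set, "binary")
  fused <- fuse(list(bb, kb))
  expect_equal(fused$x[, "kmer:AAT"], kb$x[, "AAT"])
})

test_that("min-max normalization rescales, zeroes constants, and clips", {
  x <- cbind(v = c(0, 5, 10), w = c(2, 2, 2))
  blk <- feature_block("t", x)
  params <- fit_minmax(blk)
  norm <- apply_minmax(params, blk)
  expect_equal(unname(norm$x[, "v"]), c(0, 0.5, 1))
  expect_equal(unname(norm$x[, "w"]), c(0, 0, 0))

  # already [0,1] training data is untouched
  u <- feature_block("u", cbind(a = c(0, 0.3, 1)))
  expect_equal(apply_minmax(fit_minmax(u), u)$x, u$x)

  # out-of-range new data is clipped
  test <- feature_block("t", cbind(v = c(-5, 20), w = c(0, 9)))
  clipped <- apply_minmax(params, test)
  expect_equal(unname(clipped$x[, "v"]), c(0, 1))
  expect_true(all(clipped$x >= 0 & clipped$x <= 1))

  wrong <- feature_block("t", cbind(z = 1:3))
  expect_error(apply_minmax(params, wrong), "columns")

  # non-constant training columns span exactly [0, 1]
  set.seed(44)
  big <- feature_block("r", matrix(rnorm(600), 60, 10,
                                   dimnames = list(NULL, paste0("c", 1:10))))
  nb <- apply_minmax(fit_minmax(big), big)
  expect_equal(unname(apply(nb$x, 2, min)), rep(0, 10))
  expect_equal(unname(apply(nb$x, 2, max)), rep(1, 10))
})

test_that("selection modes compose: before/after/both all run, dims shrink", {
  gen <- generate_dataset(generator_config(40, 40, window_length = 21,
                                           effect_size = 0.8, seed = 45))
  dims <- sapply(c("none", "before", "after", "both"), function(mode) {
    fit <- train_pipeline(gen$set, pipeline_config(selection = mode, seed = 1))
    length(fit$norm$min)
  })
  expect_lte(dims[["before"]], dims[["none"]])
  expect_lte(dims[["both"]], dims[["before"]])
  expect_lte(dims[["both"]], dims[["after"]])
})
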