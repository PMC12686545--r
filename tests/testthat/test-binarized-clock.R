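test_that("binarization applies the strict nonzero-median rule", {
  m <- matrix(c(0, 0, 5, 10, 20), ncol = 1,
              dimnames = list(paste0("g", 1:5), "s1"))
  expect_equal(unname(binarize(m)[, 1]), c(0L, 0L, 0L, 0L, 1L))
  # all genes at the same positive value: nothing strictly above the median
  eq <- matrix(7, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_true(all(binarize(eq) == 0L))
  # an all-zero sample has no nonzero median
  z <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(binarize(z), "empty")
})

test_that("binarization commutes with gene permutation and caps the 1-fraction", {
  set.seed(1)
  m <- matrix(rpois(300, 40), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  perm <- sample(nrow(m))
  expect_identical(binarize(m[perm, ]), binarize(m)[perm, ])
  # with an odd number of distinct positive values, strictly-above-median
  # leaves under half of the genes at 1 (even counts sit exactly at half)
  mc <- matrix(runif(310, 1, 100), 31, 10,
               dimnames = list(sprintf("g%02d", 1:31), colnames(m)))
  b <- binarize(mc)
  expect_true(all(colMeans(b) < 0.5))
  # binarizing a 0/1 matrix whose nonzero median is 1 yields all zeros
  expect_true(all(colSums(b) > 0))
  expect_true(all(binarize(b + 0) == 0L))
})

test_that("biological age rescaling is the lifespan ratio and inverts", {
  expect_equal(rescale_biological_age(100, 500, 500), 100)
  expect_equal(rescale_biological_age(100, 800, 400), 50)
  expect_equal(rescale_biological_age(0, 123, 456), 0)
  # applying the inverse ratio recovers the chronological age
  b <- rescale_biological_age(72, 800, 640)
  expect_equal(rescale_biological_age(b, 640, 800), 72)
  expect_error(rescale_biological_age(10, 0, 100), "lifespans")
})

test_that("age prediction is the coefficient sum plus intercept", {
  model <- structure(list(coefficients = c(g1 = 2, g2 = -1), intercept = 100,
                          n_genes = 2L, meta = list()), class = "clock_model")
  bin <- matrix(c(1, 0,  0, 0,  1, 1), 2, 3,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  p <- predict_age(bin, model)
  expect_equal(p$predicted_biological_age_h, c(102, 100, 101))
  # activating a positive-coefficient gene never decreases the prediction
  bin2 <- bin
  bin2["g1", "b"] <- 1
  p2 <- predict_age(bin2, model)
  expect_true(all(p2$predicted_biological_age_h >=
                    p$predicted_biological_age_h))
  # clock genes missing from the query count as state 0, with a warning
  expect_warning(pm <- predict_age(bin[1, , drop = FALSE], model), "absent")
  expect_equal(pm$predicted_biological_age_h, c(102, 100, 102))
})

test_that("aging rate reproduces the dauer worked examples", {
  expect_equal(round(aging_rate(123, 180, 24, 96), 2), 0.79)
  expect_equal(round(aging_rate(180, 256, 96, 720), 2), 0.12)
  expect_equal(aging_rate(50, 50, 0, 10), 0)
  expect_error(aging_rate(1, 2, 100, 100), "span")
})

test_that("clock training recovers a noiseless age-informative gene", {
  # young/old design where one gene's state tracks age exactly; a single
  # binary feature then predicts the two age levels perfectly
  set.seed(9)
  n <- 40
  ages <- rep(c(100, 400), each = n / 2)
  bin <- matrix(rbinom(200 * n, 1, 0.5), 200, n,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n)))
  bin["g001", ] <- as.integer(ages > median(ages))
  train <- c(1:15, 21:35)
  m <- train_clock(bin[, train], ages[train], seed = 4)
  expect_true("g001" %in% names(m$coefficients))
  expect_gt(m$coefficients[["g001"]], 0)
  p <- predict_age(bin[, -train], m)
  expect_gte(cor(p$predicted_biological_age_h, ages[-train]), 0.9)
})

test_that("clock training is deterministic and validates its inputs", {
  set.seed(2)
  bin <- matrix(rbinom(600, 1, 0.4), 30, 20,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  ages <- runif(20, 100, 500)
  m1 <- train_clock(bin, ages, seed = 7)
  m2 <- train_clock(bin, ages, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$intercept, m2$intercept)
  expect_equal(m1$n_genes, length(m1$coefficients))
  expect_error(train_clock(bin, rep(100, 20)), "distinct")
  expect_error(train_clock(bin, ages, cv_folds = 21), "exceeds")
})

test_that("clock models round-trip through JSON", {
  set.seed(3)
  ages <- runif(20, 100, 500)
  bin <- matrix(rbinom(600, 1, 0.4), 30, 20,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  # plant signal so the fitted model keeps several genes
  bin["g01", ] <- as.integer(ages > 250)
  bin["g02", ] <- as.integer(ages > 350)
  m <- train_clock(bin, ages, seed = 1)
  expect_gt(m$n_genes, 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_model(m, path)
  back <- read_clock_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(predict_age(bin, back), predict_age(bin, m))
})
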