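test_that("equal-frequency discretization matches quantile cuts", {
  tab <- tibble::tibble(class_label = rep(c("a", "b"), 4),
                        f1 = as.numeric(1:8))
  d <- discretize(tab, bins = 4L)
  expect_equal(unname(d$codes[, "f1"]), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # constant feature collapses to a single bin
  tab$f2 <- 5
  d2 <- discretize(tab, bins = 4L)
  expect_true(all(d2$codes[, "f2"] == 0L))
  expect_equal(mutual_information(d2$codes[, "f2"], d2$target), 0)
})

test_that("bin occupancies agree with brute-force quantile computation", {
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(40))
    tab <- tibble::tibble(class_label = rep(c("a", "b"), 20), f = x)
    codes <- discretize(tab, bins = 4L)$codes[, "f"]
    qs <- unique(quantile(x, probs = seq(0, 1, 0.25), names = FALSE))
    want <- as.integer(cut(x, qs, include.lowest = TRUE)) - 1L
    expect_identical(unname(codes), want)
    occ <- table(codes)
    expect_true(all(abs(occ - 10) <= 1))
  }
})

test_that("mutual information matches hand computations", {
  x <- rep(0:3, each = 5)
  expect_equal(mutual_information(x, x), 2)  # I(x; x) = H(x) = 2 bits
  # exact product design: independent
  grid <- expand.grid(a = 0:3, b = 0:3)
  expect_equal(mutual_information(grid$a, grid$b), 0)
  # printed 2x2 joint count table {{4,1},{1,4}}
  x2 <- c(rep(0, 5), rep(1, 5))
  y2 <- c(rep(0, 4), 1, 0, rep(1, 4))
  expect_equal(mutual_information(x2, y2), 0.2780719, tolerance = 1e-6)
  expect_error(mutual_information(1:3, 1:4),
               class = "fibrotype_parameter_error")
})

test_that("mutual information is symmetric and nonnegative", {
  for (s in 1:20) {
    xy <- withr::with_seed(s, list(x = sample(0:3, 30, TRUE),
                                   y = sample(0:2, 30, TRUE)))
    expect_identical(mutual_information(xy$x, xy$y),
                     mutual_information(xy$y, xy$x))
    expect_gte(mutual_information(xy$x, xy$y), 0)
  }
})

test_that("a redundant copy of the top feature is deferred", {
  # f1 is strongly (not perfectly) informative, f2 duplicates it exactly,
  # f3 is weak independent noise; after selecting f1 the copy is maximally
  # redundant, so the noise feature must precede it.
  c_ <- rep(0:1, each = 10)
  f1 <- c_; f1[1] <- 1L
  f2 <- f1
  f3 <- c(rep(0:1, 9), 0, 1)[1:20]
  codes <- cbind(f1 = f1, f2 = f2, f3 = f3)
  dt <- structure(list(codes = codes, edges = NULL, target = c_),
                  class = "discretized_table")
  rk <- mrmr_rank(dt)
  expect_equal(rk$ranked_features[1], "f1")
  expect_lt(match("f3", rk$ranked_features), match("f2", rk$ranked_features))
  # cross-check against the brute-force oracle
  expect_identical(rk$ranked_features, bf_mrmr_rank(codes, c_))
})

test_that("greedy ranking equals the brute-force oracle on random tables", {
  for (s in 1:30) {
    tab <- random_feature_table(n = 20, p = 6, seed = s)
    d <- discretize(tab, bins = 3L)
    rk <- mrmr_rank(d)
    expect_identical(rk$ranked_features, bf_mrmr_rank(d$codes, d$target))
    # permutation with max-relevance first
    expect_setequal(rk$ranked_features, colnames(d$codes))
    expect_equal(rk$criterion_values[1], max(unlist(lapply(
      colnames(d$codes), function(f) bf_mi(d$codes[, f], d$target)))))
  }
})

test_that("a planted signal feature is ranked first", {
  hits <- sapply(1:50, function(s) {
    tab <- withr::with_seed(s, {
      cls <- rep(c("normal", "scar", "adjacent"), each = 10)
      t0 <- tibble::as_tibble(stats::setNames(
        as.data.frame(matrix(rnorm(30 * 8), 30, 8)),
        sprintf("f%02d", 1:8)))
      t0$f05 <- as.integer(factor(cls)) + rnorm(30, 0, 0.3)
      t0$class_label <- cls
      t0
    })
    rk <- mrmr_rank(discretize(tab, bins = 4L))
    rk$ranked_features[1] == "f05"
  })
  expect_gte(mean(hits), 0.95)
})

test_that("incremental subsets are nested prefixes of the ranking", {
  ft <- small_feature_table()
  rk <- mrmr_rank(discretize(ft))
  expect_setequal(rk$ranked_features, feature_names())
  subsets <- incremental_subsets(rk)
  expect_length(subsets, 28)
  expect_equal(lengths(subsets), 1:28)
  expect_equal(subsets[[1]], rk$ranked_features[1])
  expect_setequal(subsets[[28]], feature_names())
  for (n in 2:28) {
    expect_identical(subsets[[n]][1:(n - 1)], subsets[[n - 1]])
  }
})

test_that("rankings survive a CSV round trip and reject bad input", {
  ft <- small_feature_table()
  rk <- mrmr_rank(discretize(ft))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking(rk, path)
  back <- read_ranking(path)
  expect_identical(back$ranked_features, rk$ranked_features)
  expect_equal(back$criterion_values, rk$criterion_values, tolerance = 1e-12)
  one_class <- ft; one_class$class_label <- "scar"
  expect_error(mrmr_rank(discretize(one_class)),
               class = "fibrotype_parameter_error")
})
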