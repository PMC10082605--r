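make_blobs <- function(n_per = 20, gap = 8, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
               matrix(rnorm(n_per * 2) + gap, ncol = 2),
               cbind(rnorm(n_per) + gap, rnorm(n_per) - gap))
    colnames(X) <- c("x1", "x2")
    list(X = X, y = rep(c("a", "b", "c"), each = n_per))
  })
}

test_that("well-separated classes are fit perfectly and deterministically", {
  d <- make_blobs()
  m <- train_sgd(d$X, d$y, sgd_config(seed = 4L))
  expect_equal(mean(predict(m, d$X) == d$y), 1)
  m2 <- train_sgd(d$X, d$y, sgd_config(seed = 4L))
  expect_identical(m$weights, m2$weights)
  expect_identical(m$intercept, m2$intercept)
  m3 <- train_sgd(d$X, d$y, sgd_config(seed = 5L))
  expect_false(identical(m$weights, m3$weights))
  expect_error(train_sgd(d$X, rep("a", nrow(d$X))),
               class = "fibrotype_parameter_error")
})

test_that("probabilities are valid and follow the modified-huber mapping", {
  d <- make_blobs()
  m <- train_sgd(d$X, d$y, sgd_config(seed = 2L))
  p <- predict(m, d$X, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
  expect_true(all(p >= 0 & p <= 1))
  s <- predict(m, d$X, type = "score")
  clipped <- (pmin(pmax(s, -1), 1) + 1) / 2
  expect_equal(unname(p), unname(clipped / rowSums(clipped)))
})

test_that("leave-one-out uses one fold per sample without leakage", {
  d <- make_blobs(n_per = 5)
  tab <- tibble::as_tibble(as.data.frame(d$X))
  tab$class_label <- d$y
  res <- loo_evaluate(tab, c("x1", "x2"), sgd_config(seed = 3L))
  expect_equal(nrow(res$probabilities), 15)
  expect_false(anyNA(res$probabilities))
  expect_equal(sum(res$confusion), 15)
  expect_equal(unname(rowSums(res$confusion)), as.vector(table(d$y)))
  # the fold model ignores the held-out sample entirely
  X2 <- d$X; X2[7, ] <- X2[7, ] + 1000
  m_a <- fibrotype:::loo_fold_model(d$X, d$y, sgd_config(seed = 3L), 7L)
  m_b <- fibrotype:::loo_fold_model(X2, d$y, sgd_config(seed = 3L), 7L)
  expect_identical(m_a$weights, m_b$weights)
  expect_identical(m_a$center, m_b$center)
  expect_error(loo_evaluate(tab, "nope", sgd_config()),
               class = "fibrotype_parameter_error")
})

test_that("twinned samples are classified perfectly by leave-one-out", {
  base <- make_blobs(n_per = 4, gap = 10, seed = 6)
  X <- rbind(base$X, base$X + 1e-9)
  tab <- tibble::as_tibble(as.data.frame(X))
  tab$class_label <- c(base$y, base$y)
  res <- loo_evaluate(tab, c("x1", "x2"), sgd_config(seed = 8L))
  expect_equal(res$accuracy, 1)
})

test_that("label-shuffled data scores near chance", {
  accs <- sapply(1:10, function(s) {
    d <- withr::with_seed(s, {
      X <- matrix(rnorm(60 * 5), 60, 5,
                  dimnames = list(NULL, paste0("f", 1:5)))
      list(X = X, y = sample(rep(c("a", "b", "c"), 20)))
    })
    tab <- tibble::as_tibble(as.data.frame(d$X))
    tab$class_label <- d$y
    loo_evaluate(tab, paste0("f", 1:5),
                 sgd_config(seed = s, max_epochs = 60L))$accuracy
  })
  expect_true(all(accs >= 0.1 & accs <= 0.6))
  expect_true(abs(mean(accs) - 1 / 3) < 0.15)
})

test_that("subset sweep averages repeats and prefers smaller ties", {
  d <- make_blobs(n_per = 5)
  tab <- tibble::as_tibble(as.data.frame(d$X))
  tab$class_label <- d$y
  sw <- subset_sweep(tab, list("x1", c("x1", "x2")),
                     sgd_config(seed = 2L), repeats = 3L)
  expect_equal(nrow(sw$evaluations), 6)
  expect_equal(sort(unique(sw$evaluations$n)), c(1, 2))
  agg <- tapply(sw$evaluations$accuracy, sw$evaluations$n, mean)
  expect_equal(as.numeric(agg), sw$mean_accuracy$mean_accuracy)
  expect_equal(sw$best_n,
               min(as.integer(names(agg)[agg == max(agg)])))
  # single subset: best_n is that size
  sw1 <- subset_sweep(tab, list(c("x1", "x2")), sgd_config(seed = 2L),
                      repeats = 1L)
  expect_equal(sw1$best_n, 2)
  # determinism
  sw2 <- subset_sweep(tab, list("x1", c("x1", "x2")),
                      sgd_config(seed = 2L), repeats = 3L)
  expect_identical(sw$evaluations, sw2$evaluations)
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  for (s in 1:50) {
    sc <- withr::with_seed(s, {
      list(scores = round(runif(40), 1),  # coarse grid forces ties
           labels = sample(c("pos", "neg"), 40, TRUE, prob = c(0.4, 0.6)))
    })
    if (length(unique(sc$labels)) < 2) next
    m <- cbind(pos = sc$scores, neg = 1 - sc$scores)
    r <- roc_auc(m, sc$labels)
    expect_equal(unname(r$auc["pos"]),
                 bf_auc_u(sc$scores, sc$labels == "pos"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  for (s in 1:10) {
    sc <- withr::with_seed(40 + s, round(runif(30), 1))
    lab <- withr::with_seed(80 + s, sample(0:1, 30, TRUE))
    if (length(unique(lab)) < 2) next
    got <- unname(roc_auc(cbind(pos = sc, neg = -sc),
                          ifelse(lab == 1, "pos", "neg"))$auc["pos"])
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("AUC is 1 for perfect separation and ~0.5 for random scores", {
  m <- cbind(a = c(rep(0.9, 5), rep(0.1, 5)),
             b = c(rep(0.1, 5), rep(0.9, 5)))
  labels <- rep(c("a", "b"), each = 5)
  r <- roc_auc(m, labels)
  expect_equal(unname(r$auc), c(1, 1))
  null_auc <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      sc <- runif(30)
      lab <- sample(c("a", "b"), 30, TRUE)
      if (length(unique(lab)) < 2) return(NA)
      unname(roc_auc(cbind(a = sc, b = 1 - sc), lab)$auc["a"])
    })
  })
  expect_true(abs(mean(null_auc, na.rm = TRUE) - 0.5) < 0.1)
  expect_error(roc_auc(m, rep("a", 10)), class = "fibrotype_parameter_error")
})

test_that("ROC curves are monotone staircases from (0,0) to (1,1)", {
  sc <- withr::with_seed(9, runif(25))
  lab <- withr::with_seed(10, sample(c("a", "b"), 25, TRUE))
  r <- roc_auc(cbind(a = sc, b = 1 - sc), lab)
  for (k in c("a", "b")) {
    cur <- r$curves[r$curves$class == k, ]
    expect_equal(cur$fpr[1], 0)
    expect_equal(cur$tpr[1], 0)
    expect_equal(cur$fpr[nrow(cur)], 1)
    expect_equal(cur$tpr[nrow(cur)], 1)
    expect_true(all(diff(cur$fpr) >= 0))
    expect_true(all(diff(cur$tpr) >= 0))
  }
})

test_that("tidiers and plots expose the expected shapes", {
  d <- make_blobs(n_per = 5)
  tab <- tibble::as_tibble(as.data.frame(d$X))
  tab$class_label <- d$y
  sw <- subset_sweep(tab, list("x1", c("x1", "x2")), sgd_config(seed = 1L),
                     repeats = 2L)
  expect_identical(tidy(sw), sw$evaluations)
  expect_equal(glance(sw)$best_n, sw$best_n)
  expect_s3_class(autoplot(sw), "ggplot")
  res <- loo_evaluate(tab, c("x1", "x2"), sgd_config(seed = 1L))
  r <- roc_auc(res$probabilities, res$truth)
  expect_s3_class(tidy(r), "tbl_df")
  expect_s3_class(autoplot(r), "ggplot")
})
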