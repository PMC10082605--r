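#' Stochastic-gradient-descent classifier configuration
#'
#' Hyperparameters of the linear one-vs-rest SGD classifier used as the final
#' model: modified-huber loss, elastic-net penalty with strength `alpha`,
#' constant learning rate `eta0`, fitted intercept. `power_t` only affects
#' inverse-scaling learning-rate schedules and is inert under the constant
#' schedule; it is stored for configuration fidelity. `l1_ratio` is the
#' elastic-net mixing weight (0 = ridge, 1 = lasso).
#'
#' @param alpha Penalty strength (> 0), default 0.001.
#' @param eta0 Constant learning rate (> 0), default 0.01.
#' @param l1_ratio Elastic-net mixing in `[0, 1]`, default 0.15.
#' @param loss Loss name; only `"modified_huber"` is implemented.
#' @param penalty Penalty name; only `"elasticnet"` is implemented.
#' @param learning_rate Schedule name; only `"constant"` is implemented.
#' @param fit_intercept Whether to fit intercepts (kept `TRUE`).
#' @param power_t Stored but unused under the constant schedule.
#' @param max_epochs Number of passes over the training data.
#' @param seed Seed controlling the per-epoch visit order.
#' @return An `sgd_config` list.
#' @export
sgd_config <- function(alpha = 0.001, eta0 = 0.01, l1_ratio = 0.15,
                       loss = "modified_huber", penalty = "elasticnet",
                       learning_rate = "constant", fit_intercept = TRUE,
                       power_t = 0.5, max_epochs = 300L, seed = 1L) {
  check_number(alpha, "alpha", lower = 1e-12)
  check_number(eta0, "eta0", lower = 1e-12)
  check_number(l1_ratio, "l1_ratio", lower = 0, upper = 1)
  max_epochs <- check_count(max_epochs, "max_epochs", lower = 1L)
  if (loss != "modified_huber" || penalty != "elasticnet" ||
      learning_rate != "constant" || !isTRUE(fit_intercept)) {
    abort(paste("only the modified-huber / elastic-net / constant-rate /",
                "intercept configuration is implemented."),
          class = "fibrotype_parameter_error")
  }
  structure(list(alpha = alpha, eta0 = eta0, l1_ratio = l1_ratio,
                 loss = loss, penalty = penalty,
                 learning_rate = learning_rate, fit_intercept = fit_intercept,
                 power_t = power_t, max_epochs = max_epochs,
                 seed = as.integer(seed)),
            class = "sgd_config")
}

#' Train the one-vs-rest SGD linear classifier
#'
#' One binary modified-huber / elastic-net SGD learner per class, trained
#' with a constant learning rate; deterministic given `config$seed` (which
#' drives the per-epoch sample visit order). Features are z-score
#' standardized by default (statistics stored in the model and re-applied at
#' prediction time); constant features get unit scale.
#'
#' @param features Numeric matrix (samples x features) or data frame of the
#'   feature columns.
#' @param labels Class labels (character or factor), >= 2 classes.
#' @param config An [sgd_config()].
#' @param standardize Standardize features before fitting (default `TRUE`).
#' @return An `sgd_model` with weights (classes x features), intercepts,
#'   class order, and standardization statistics.
#' @export
train_sgd <- function(features, labels, config = sgd_config(),
                      standardize = TRUE) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  cls <- sort(unique(as.character(labels)))
  if (length(cls) < 2) {
    abort("training requires at least 2 classes.",
          class = "fibrotype_parameter_error")
  }
  y <- match(as.character(labels), cls) - 1L
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  n <- nrow(Xs)
  order_mat <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_len(config$max_epochs),
                          function(e) sample.int(n)))
  })
  fit <- cpp_sgd_fit(Xs, y, length(cls), config$alpha, config$l1_ratio,
                     config$eta0, order_mat)
  structure(list(weights = fit$weights, intercept = as.numeric(fit$intercept),
                 classes = cls, center = center, scale = scale_,
                 config = config,
                 feature_names = colnames(X)),
            class = "sgd_model")
}

#' Decision scores and class probabilities of an SGD model
#'
#' Decision scores are the per-class linear responses. Probabilities use the
#' modified-huber mapping: scores clipped to `[-1, 1]`, shifted to `[0, 1]`,
#' and renormalized across classes (uniform when all classes map to zero).
#'
#' @param object An `sgd_model`.
#' @param newdata Feature matrix or data frame.
#' @param type `"class"`, `"prob"`, or `"score"`.
#' @param ... Unused.
#' @return Predicted labels, a probability matrix, or a score matrix.
#' @export
predict.sgd_model <- function(object, newdata, type = c("class", "prob",
                                                        "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  scores <- Xs %*% t(object$weights) +
    matrix(object$intercept, nrow(Xs), length(object$classes), byrow = TRUE)
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  if (type == "class") {
    return(object$classes[max.col(scores, ties.method = "first")])
  }
  p <- (pmin(pmax(scores, -1), 1) + 1) / 2
  tot <- rowSums(p)
  uniform <- tot <= 0
  p[uniform, ] <- 1 / ncol(p)
  tot[uniform] <- 1
  p / tot
}

# The model of fold i depends only on the training rows X[-i, ]; the held-out
# sample influences neither standardization nor training.
loo_fold_model <- function(X, y, config, i) {
  fold_config <- config
  fold_config$seed <- derive_seed(config$seed, i)
  train_sgd(X[-i, , drop = FALSE], y[-i], fold_config)
}

#' Leave-one-out evaluation of a feature subset
#'
#' Exactly `n` folds, each holding out one sample. Standardization statistics
#' and the classifier are recomputed on each training fold only, so the
#' held-out sample never leaks into its own fold. Held-out class
#' probabilities are retained for ROC analysis.
#'
#' @param table Feature table as from [cohort_feature_table()].
#' @param feature_subset Character vector of feature columns to use.
#' @param config An [sgd_config()]; fold-level seeds derive from
#'   `config$seed`.
#' @return A `loo_result`: `accuracy`, `predicted`, `probabilities`
#'   (samples x classes), `confusion` matrix, `classes`.
#' @export
loo_evaluate <- function(table, feature_subset, config = sgd_config()) {
  unknown <- setdiff(feature_subset, names(table))
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
          class = "fibrotype_parameter_error")
  }
  X <- as.matrix(table[, feature_subset, drop = FALSE])
  y <- as.character(table$class_label)
  cls <- sort(unique(y))
  n <- nrow(X)
  if (n < length(cls) + 1) {
    abort("need at least n_classes + 1 samples for leave-one-out.",
          class = "fibrotype_parameter_error")
  }
  probs <- matrix(NA_real_, n, length(cls), dimnames = list(NULL, cls))
  predicted <- character(n)
  for (i in seq_len(n)) {
    model <- loo_fold_model(X, y, config, i)
    probs[i, model$classes] <- predict(model, X[i, , drop = FALSE],
                                       type = "prob")[1, ]
    probs[i, is.na(probs[i, ])] <- 0  # class absent from training fold
    predicted[i] <- cls[which.max(probs[i, ])]
  }
  confusion <- table(factor(y, levels = cls), factor(predicted, levels = cls))
  structure(list(accuracy = mean(predicted == y), predicted = predicted,
                 probabilities = probs, truth = y,
                 confusion = confusion, classes = cls),
            class = "loo_result")
}

#' Accuracy sweep over incremental feature subsets
#'
#' Evaluates every subset with `repeats` leave-one-out runs under distinct
#' derived seeds and averages the accuracies. The best subset size is the
#' smallest one attaining the maximum mean accuracy (parsimony tie-break).
#'
#' @param table Feature table.
#' @param subsets List of feature-name vectors (see [incremental_subsets()]).
#' @param config An [sgd_config()].
#' @param repeats Leave-one-out repetitions per subset (default 5).
#' @return A `subset_sweep` object: `evaluations` tibble
#'   (`n`, `repeat_id`, `accuracy`), `mean_accuracy` tibble, `best_n`.
#' @export
subset_sweep <- function(table, subsets, config = sgd_config(),
                         repeats = 5L) {
  if (length(subsets) == 0) {
    abort("`subsets` must be nonempty.", class = "fibrotype_parameter_error")
  }
  repeats <- check_count(repeats, "repeats", lower = 1L)
  rows <- list()
  for (s in seq_along(subsets)) {
    nfeat <- length(subsets[[s]])
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 10000L * s + r)
      res <- loo_evaluate(table, subsets[[s]], cfg)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n = nfeat, repeat_id = r, accuracy = res$accuracy)
    }
  }
  evaluations <- dplyr::bind_rows(rows)
  mean_acc <- evaluations |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop")
  best <- mean_acc$n[mean_acc$mean_accuracy == max(mean_acc$mean_accuracy)]
  structure(list(evaluations = evaluations, mean_accuracy = mean_acc,
                 best_n = min(best)),
            class = "subset_sweep")
}

#' @export
print.subset_sweep <- function(x, ...) {
  cat(sprintf("<subset_sweep> %d subset sizes, best n = %d (mean acc %.3f)\n",
              nrow(x$mean_accuracy), x$best_n,
              max(x$mean_accuracy$mean_accuracy)))
  invisible(x)
}

#' @method tidy subset_sweep
#' @export
tidy.subset_sweep <- function(x, ...) x$evaluations

#' @method glance subset_sweep
#' @export
glance.subset_sweep <- function(x, ...) {
  tibble::tibble(best_n = x$best_n,
                 best_mean_accuracy = max(x$mean_accuracy$mean_accuracy))
}

#' Accuracy-versus-subset-size plot
#'
#' @param object A `subset_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subset_sweep
#' @export
autoplot.subset_sweep <- function(object, ...) {
  ggplot2::ggplot(object$mean_accuracy,
                  ggplot2::aes(x = .data$n, y = .data$mean_accuracy)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_n, linetype = "dashed") +
    ggplot2::labs(x = "number of top-ranked features",
                  y = "mean leave-one-out accuracy") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curve and AUC
#'
#' For each class, sweeps thresholds over the observed held-out scores of
#' that class (class versus pooled rest), accumulating true/false positive
#' rates at every distinct score; AUC by trapezoidal integration, which under
#' this construction equals the rank-based Mann-Whitney statistic
#' `U / (n_pos * n_neg)` with the standard tie convention.
#'
#' @param scores Numeric matrix (samples x classes) of class scores or
#'   probabilities with class names as column names.
#' @param labels True class labels.
#' @return A `roc_result`: tibble `curves` (`class`, `threshold`, `fpr`,
#'   `tpr`) and named numeric `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  cls <- colnames(scores)
  if (is.null(cls)) {
    abort("`scores` must have class names as column names.",
          class = "fibrotype_parameter_error")
  }
  missing_cls <- setdiff(cls, unique(labels))
  if (length(missing_cls) > 0) {
    abort(sprintf("class '%s' absent from labels.", missing_cls[1]),
          class = "fibrotype_parameter_error")
  }
  curves <- list()
  aucs <- stats::setNames(numeric(length(cls)), cls)
  for (k in cls) {
    s <- scores[, k]
    pos <- labels == k
    ord <- order(s, decreasing = TRUE)
    s_ord <- s[ord]
    pos_ord <- pos[ord]
    distinct <- !duplicated(s_ord)
    # cumulative counts at the *last* index of each distinct score value
    last_of_value <- c(which(distinct)[-1] - 1L, length(s_ord))
    tp <- cumsum(pos_ord)[last_of_value]
    fp <- cumsum(!pos_ord)[last_of_value]
    tpr <- c(0, tp / sum(pos))
    fpr <- c(0, fp / sum(!pos))
    thresholds <- c(Inf, s_ord[distinct])
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    aucs[k] <- auc
    curves[[k]] <- tibble::tibble(class = k, threshold = thresholds,
                                  fpr = fpr, tpr = tpr)
  }
  structure(list(curves = dplyr::bind_rows(curves), auc = aucs),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC:",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curves

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::as_tibble(as.list(stats::setNames(x$auc,
                                            paste0("auc_", names(x$auc)))))
}

#' One-vs-rest ROC plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
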