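#' Equal-frequency discretization of a feature table
#'
#' Cuts every continuous feature at its empirical quantiles into at most
#' `bins` equal-frequency bins (duplicate edges merged, so heavily tied or
#' constant features get fewer bins — a constant feature occupies a single
#' bin and carries zero mutual information with anything). The class label is
#' left categorical. With the ~34-sample cohorts this pipeline targets,
#' density estimation of the continuous mutual-information integral is not
#' viable; plug-in estimation on a handful of equal-frequency bins is the
#' standard route.
#'
#' @param table Feature table as from [cohort_feature_table()].
#' @param bins Maximum number of bins per feature (>= 2, default 4).
#' @param features Which columns to discretize; defaults to every numeric
#'   column except `sample_id` / `class_label`.
#' @return A `discretized_table`: list with `codes` (integer matrix, samples
#'   by features, values in `[0, bins)`), `edges` (per-feature bin edges), and
#'   `target` (integer class codes with a `levels` attribute).
#' @export
discretize <- function(table, bins = 4L, features = NULL) {
  bins <- check_count(bins, "bins", lower = 2L)
  features <- features %||%
    setdiff(names(table)[vapply(table, is.numeric, logical(1))],
            c("sample_id", "class_label"))
  codes <- matrix(0L, nrow(table), length(features),
                  dimnames = list(NULL, features))
  edges <- vector("list", length(features))
  names(edges) <- features
  for (f in features) {
    x <- table[[f]]
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                          names = FALSE))
    if (length(qs) <= 2) {
      codes[, f] <- 0L
      edges[[f]] <- qs
      next
    }
    codes[, f] <- as.integer(cut(x, breaks = qs, include.lowest = TRUE)) - 1L
    edges[[f]] <- qs
  }
  cls <- factor(table$class_label)
  target <- as.integer(cls) - 1L
  attr(target, "levels") <- levels(cls)
  structure(list(codes = codes, edges = edges, target = target),
            class = "discretized_table")
}

#' Plug-in mutual information between two code vectors
#'
#' `I = sum p(a, b) log2 [p(a, b) / (p(a) p(b))]` over the occupied cells of
#' the joint empirical table, in bits; tiny negative rounding is clamped to 0.
#'
#' @param x_codes,y_codes Equal-length integer (or factor) vectors.
#' @return Nonnegative mutual information in bits.
#' @export
mutual_information <- function(x_codes, y_codes) {
  if (length(x_codes) != length(y_codes) || length(x_codes) < 1) {
    abort("`x_codes` and `y_codes` must have equal positive length.",
          class = "fibrotype_parameter_error")
  }
  joint <- table(x_codes, y_codes) / length(x_codes)
  px <- rowSums(joint)
  py <- colSums(joint)
  occupied <- joint > 0
  outer_p <- outer(px, py)
  mi <- sum(joint[occupied] * log2(joint[occupied] / outer_p[occupied]))
  max(mi, 0)
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy incremental ranking: the first feature maximizes the relevance
#' `I(x_j; c)` to the class label; thereafter the m-th feature maximizes the
#' relevance-minus-mean-redundancy objective
#' `I(x_j; c) - (1 / (m - 1)) * sum_{x_i in S} I(x_j; x_i)` over the
#' not-yet-selected features (the "MID" difference form). Ties break toward
#' the canonical column order so rankings are reproducible.
#'
#' @param dtable A [discretize()]d table.
#' @return An `mrmr_ranking` object: `ranked_features` (permutation of the
#'   feature names), `criterion_values` (objective value at each step),
#'   `relevance` (per-feature `I(x_j; c)`, in ranking order).
#' @export
mrmr_rank <- function(dtable) {
  stopifnot(inherits(dtable, "discretized_table"))
  if (length(unique(dtable$target)) < 2) {
    abort("the class label must have at least 2 classes.",
          class = "fibrotype_parameter_error")
  }
  feats <- colnames(dtable$codes)
  p <- length(feats)
  relevance <- vapply(feats, function(f) {
    mutual_information(dtable$codes[, f], dtable$target)
  }, numeric(1))
  # pairwise feature MI, filled lazily
  pair_mi <- matrix(NA_real_, p, p, dimnames = list(feats, feats))
  get_mi <- function(a, b) {
    if (is.na(pair_mi[a, b])) {
      v <- mutual_information(dtable$codes[, a], dtable$codes[, b])
      pair_mi[a, b] <<- v
      pair_mi[b, a] <<- v
    }
    pair_mi[a, b]
  }
  selected <- character(0)
  criterion <- numeric(0)
  remaining <- feats
  while (length(remaining) > 0) {
    m <- length(selected) + 1L
    obj <- vapply(remaining, function(f) {
      if (m == 1L) return(relevance[[f]])
      red <- mean(vapply(selected, function(s) get_mi(f, s), numeric(1)))
      relevance[[f]] - red
    }, numeric(1))
    # ties are common in discrete plug-in MI; round away float summation
    # noise so the canonical-order tie-break is well defined
    obj_r <- round(obj, 10)
    best <- remaining[which.max(obj_r)]
    selected <- c(selected, best)
    criterion <- c(criterion, max(obj))
    remaining <- setdiff(remaining, best)
  }
  structure(list(ranked_features = selected,
                 criterion_values = criterion,
                 relevance = relevance[selected]),
            class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat("<mrmr_ranking> top features:",
      paste(head(x$ranked_features, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Tidy an MRMR ranking
#'
#' @param x An `mrmr_ranking`.
#' @param ... Unused.
#' @return Tibble with columns `rank`, `feature`, `criterion_value`,
#'   `relevance_bits`.
#' @method tidy mrmr_ranking
#' @export
tidy.mrmr_ranking <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$ranked_features),
                 feature = x$ranked_features,
                 criterion_value = x$criterion_values,
                 relevance_bits = unname(x$relevance))
}

#' Nested incremental feature subsets
#'
#' Subset `n` holds the first `n` names of the ranking, for
#' `n = 1, ..., p` — the incremental-feature-selection construction whose
#' accuracy sweep locates the best subset size.
#'
#' @param ranking An [mrmr_rank()] result.
#' @return List of character vectors of sizes `1..p`.
#' @export
incremental_subsets <- function(ranking) {
  stopifnot(inherits(ranking, "mrmr_ranking"))
  lapply(seq_along(ranking$ranked_features),
         function(n) ranking$ranked_features[seq_len(n)])
}

#' Write / read a ranking as CSV
#'
#' @param ranking An `mrmr_ranking`.
#' @param path CSV path.
#' @return `path` (write); an `mrmr_ranking` (read).
#' @export
write_ranking <- function(ranking, path) {
  readr::write_csv(tidy(ranking), path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  structure(list(ranked_features = tab$feature,
                 criterion_values = tab$criterion_value,
                 relevance = stats::setNames(tab$relevance_bits, tab$feature)),
            class = "mrmr_ranking")
}
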