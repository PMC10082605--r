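#' Canonical names of the 28 features
#'
#' 14 features per channel, prefixed `C_` (collagen / SHG) and `E_`
#' (elastin / TPEF), ordered morphology (density, length, width, alignment),
#' then histogram statistics, then co-occurrence statistics. The order is
#' fixed so that rank indices and serialized tables are stable.
#'
#' @return Character vector of length 28.
#' @export
feature_names <- function() {
  base <- c("density", "length", "width", "alignment",
            "mean_int", "std", "smoothness", "skewness", "uniformity",
            "entropy",
            "contrast", "correlation", "energy", "homogeneity")
  c(paste0("C_", base), paste0("E_", base))
}

#' Feature family membership
#'
#' @return Tibble with columns `feature`, `channel`, `family`
#'   (`morphology`, `histogram`, `glcm`).
#' @export
feature_families <- function() {
  base <- c(rep("morphology", 4), rep("histogram", 6), rep("glcm", 4))
  tibble::tibble(
    feature = feature_names(),
    channel = rep(c("collagen", "elastin"), each = 14),
    family = rep(base, 2)
  )
}

channel_features <- function(img, glcm_levels = 8L, min_length_px = 10,
                             denoise_window = 3L) {
  den <- denoise(img, window = denoise_window)
  morph <- morphology_features(den, min_length_px = min_length_px)
  hist <- histogram_features(den)
  gl <- glcm_features(glcm(den, levels = glcm_levels))
  c(density = morph$density, length = morph$mean_length_px,
    width = morph$mean_width_px, alignment = morph$alignment_k,
    mean_int = hist$mean_int, std = hist$std, smoothness = hist$smoothness,
    skewness = hist$skewness, uniformity = hist$uniformity,
    entropy = hist$entropy,
    contrast = gl$contrast, correlation = gl$correlation,
    energy = gl$energy, homogeneity = gl$homogeneity)
}

#' Extract the 28 features of one imaged region
#'
#' Runs denoising, morphology, histogram, and co-occurrence analysis on both
#' channels of a region and returns the canonical 28-entry named vector.
#'
#' @param region A [region_record()].
#' @param glcm_levels Quantization levels for the co-occurrence matrix.
#' @param min_length_px Minimum traced fiber length in pixels.
#' @param denoise_window Median filter window (see [denoise()]).
#' @return Named numeric vector of length 28 in [feature_names()] order.
#' @export
extract_region_features <- function(region, glcm_levels = 8L,
                                    min_length_px = 10,
                                    denoise_window = 3L) {
  stopifnot(inherits(region, "region_record"))
  cf <- channel_features(region$collagen, glcm_levels, min_length_px,
                         denoise_window)
  ef <- channel_features(region$elastin, glcm_levels, min_length_px,
                         denoise_window)
  out <- c(stats::setNames(cf, paste0("C_", names(cf))),
           stats::setNames(ef, paste0("E_", names(ef))))
  out[feature_names()]
}

#' Average region features into one sample vector
#'
#' Per-sample features are the arithmetic mean of the region feature vectors
#' (multiple neighbouring regions are imaged per tissue section and averaged).
#'
#' @param region_features List of named numeric vectors (one per region), or
#'   a matrix with regions in rows.
#' @return Named numeric vector of length 28.
#' @export
aggregate_sample <- function(region_features) {
  if (is.matrix(region_features)) {
    region_features <- lapply(seq_len(nrow(region_features)),
                              function(i) region_features[i, ])
  }
  if (length(region_features) == 0) {
    abort("at least one region is required.",
          class = "fibrotype_parameter_error")
  }
  mat <- do.call(rbind, region_features)
  colMeans(mat)
}

#' Build the cohort feature table
#'
#' Extracts the 28 features for every region of every sample and averages
#' them per sample. Any non-finite feature aborts with the offending sample
#' named (silent imputation would corrupt the downstream mutual-information
#' ranking).
#'
#' @param cohort Cohort tibble as from [generate_cohort()] or
#'   [load_cohort()].
#' @inheritParams extract_region_features
#' @return Tibble: `sample_id`, `class_label`, then the 28 feature columns.
#' @export
cohort_feature_table <- function(cohort, glcm_levels = 8L, min_length_px = 10,
                                 denoise_window = 3L) {
  rows <- purrr::map2(cohort$sample_id, cohort$regions, function(sid, regs) {
    feats <- lapply(regs, extract_region_features, glcm_levels = glcm_levels,
                    min_length_px = min_length_px,
                    denoise_window = denoise_window)
    vec <- aggregate_sample(feats)
    if (any(!is.finite(vec))) {
      abort(sprintf("non-finite feature value(s) for sample '%s': %s", sid,
                    paste(names(vec)[!is.finite(vec)], collapse = ", ")),
            class = "fibrotype_feature_error")
    }
    tibble::as_tibble(as.list(vec))
  })
  dplyr::bind_cols(
    tibble::tibble(sample_id = cohort$sample_id,
                   class_label = cohort$class_label),
    dplyr::bind_rows(rows)
  )
}

#' Mann-Whitney group difference for one feature
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between two classes for a
#' named feature. The exact distribution is used for combined n <= 20
#' (falling back to the tie-corrected normal approximation when ties make the
#' exact computation impossible); the normal approximation is used otherwise.
#'
#' @param table Feature table as from [cohort_feature_table()].
#' @param feature_name One of [feature_names()].
#' @param group_a,group_b Class labels to compare.
#' @return Two-sided p-value.
#' @export
group_difference_test <- function(table, feature_name, group_a, group_b) {
  if (!feature_name %in% names(table)) {
    abort(sprintf("unknown feature '%s'.", feature_name),
          class = "fibrotype_parameter_error")
  }
  x <- table[[feature_name]][table$class_label == group_a]
  y <- table[[feature_name]][table$class_label == group_b]
  if (length(x) < 1 || length(y) < 1) {
    abort("both groups must contain at least one sample.",
          class = "fibrotype_parameter_error")
  }
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)$p.value
  )
}

#' Write / read a feature table as CSV
#'
#' @param table Feature table tibble.
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("sample_id", "class_label", feature_names()),
                          names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("feature table is missing column(s): %s",
                  paste(head(missing_cols, 4), collapse = ", ")),
          class = "fibrotype_format_error")
  }
  tab
}
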