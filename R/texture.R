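#' Histogram texture statistics
#'
#' The six first-order texture statistics of the gray-level histogram
#' `p(z_i)` over the image's `L = 2^bit_depth` levels: mean intensity,
#' standard deviation, smoothness `R = 1 - 1/(1 + (sigma/(L-1))^2)` (the
#' normalization by `L - 1` keeps smoothness in `[0, 1)` regardless of bit
#' depth), standardized skewness (0 for constant images), uniformity
#' `sum p^2`, and Shannon entropy in bits.
#'
#' @param img A [channel_image()], normally after [denoise()].
#' @return Named list: `mean_int`, `std`, `smoothness`, `skewness`,
#'   `uniformity`, `entropy`.
#' @export
histogram_features <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  L <- 2L^img$bit_depth
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = L)
  p <- h / sum(h)
  z <- 0:(L - 1)
  m <- sum(z * p)
  v <- sum((z - m)^2 * p)
  s <- sqrt(v)
  skew <- if (s > 0) sum(((z - m) / s)^3 * p) else 0
  pos <- p > 0
  list(
    mean_int = m,
    std = s,
    smoothness = 1 - 1 / (1 + (s / (L - 1))^2),
    skewness = skew,
    uniformity = sum(p^2),
    entropy = -sum(p[pos] * log2(p[pos]))
  )
}

#' Gray-level co-occurrence matrix
#'
#' Pixel values are linearly quantized to `levels` gray levels; symmetric
#' co-occurrence counts (each offset together with its opposite) are
#' accumulated over the given offsets and normalized to sum 1. The default
#' offsets are the four standard directions (0, 45, 90, 135 degrees) at
#' distance 1; matrices are summed over directions before normalization.
#'
#' @param img A [channel_image()], normally after [denoise()].
#' @param levels Number of quantized gray levels (>= 2, `<= 2^bit_depth`).
#' @param offsets Integer matrix with one `(row_offset, col_offset)` pair per
#'   row. Row offsets are positive downwards.
#' @return A `levels x levels` matrix summing to 1, symmetric.
#' @export
glcm <- function(img, levels = 8L,
                 offsets = rbind(c(0L, 1L),    # 0 deg
                                 c(-1L, 1L),   # 45 deg
                                 c(-1L, 0L),   # 90 deg
                                 c(-1L, -1L))) {  # 135 deg
  stopifnot(inherits(img, "channel_image"))
  levels <- check_count(levels, "levels", lower = 2L)
  if (levels > 2^img$bit_depth) {
    abort("`levels` cannot exceed the number of gray levels in the image.",
          class = "fibrotype_parameter_error")
  }
  if (!is.matrix(offsets) || nrow(offsets) == 0 || ncol(offsets) != 2) {
    abort("`offsets` must be a nonempty 2-column matrix.",
          class = "fibrotype_parameter_error")
  }
  L <- 2^img$bit_depth
  codes <- matrix(pmin(as.integer(floor(img$pixels / L * levels)),
                       levels - 1L),
                  nrow(img$pixels), ncol(img$pixels))
  storage.mode(offsets) <- "integer"
  counts <- cpp_glcm_counts(codes, levels, offsets)
  total <- sum(counts)
  if (total == 0) {
    abort("image too small for the requested offsets.",
          class = "fibrotype_parameter_error")
  }
  counts / total
}

#' Haralick statistics of a co-occurrence table
#'
#' With `p(i, j)` the normalized co-occurrence table: contrast
#' `sum (i - j)^2 p`, correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` (defined as 1 when either
#' marginal is degenerate), energy `sum p^2`, and homogeneity
#' `sum p / (1 + |i - j|)`.
#'
#' @param table Normalized symmetric co-occurrence matrix (as from [glcm()]).
#' @return Named list: `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(table) {
  if (!is.matrix(table) || nrow(table) != ncol(table)) {
    abort("`table` must be a square matrix.",
          class = "fibrotype_parameter_error")
  }
  if (abs(sum(table) - 1) > 1e-8) {
    abort("`table` must be normalized to sum 1.",
          class = "fibrotype_parameter_error")
  }
  n <- nrow(table)
  i <- matrix(seq_len(n) - 1, n, n)
  j <- t(i)
  pi_ <- rowSums(table)
  mu_i <- sum((seq_len(n) - 1) * pi_)
  sd_i <- sqrt(sum(((seq_len(n) - 1) - mu_i)^2 * pi_))
  pj_ <- colSums(table)
  mu_j <- sum((seq_len(n) - 1) * pj_)
  sd_j <- sqrt(sum(((seq_len(n) - 1) - mu_j)^2 * pj_))
  corr <- if (sd_i * sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * table) / (sd_i * sd_j)
  } else 1
  list(
    contrast = sum((i - j)^2 * table),
    correlation = corr,
    energy = sum(table^2),
    homogeneity = sum(table / (1 + abs(i - j)))
  )
}
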