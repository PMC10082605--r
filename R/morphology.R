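#' Otsu threshold of an integer image
#'
#' Maximizes the between-class variance of the gray-level histogram over all
#' integer cut points. Returns the threshold `t` such that foreground is
#' `pixels > t`. Zero-variance images return `NA` (no foreground).
#'
#' @param img A [channel_image()].
#' @return Integer threshold, or `NA_integer_` for constant images.
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "channel_image"))
  L <- 2L^img$bit_depth
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = L)
  p <- h / sum(h)
  if (sum(p > 0) < 2L) return(NA_integer_)
  z <- 0:(L - 1)
  omega <- cumsum(p)                     # P(class0) for threshold t = z
  mu <- cumsum(p * z)
  mu_total <- mu[L]
  # between-class variance at each candidate threshold t (foreground > t)
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, L)
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  as.integer(z[which.max(sigma_b)])
}

#' Fiber density
#'
#' Fraction of "effective" (foreground) pixels over the total pixel count,
#' with foreground defined by Otsu's threshold on the gray-level histogram.
#' Constant (zero-variance) images have no foreground and return 0.
#'
#' @param img A [channel_image()], normally after [denoise()].
#' @return A number in `[0, 1]`.
#' @export
fiber_density <- function(img) {
  t <- otsu_threshold(img)
  if (is.na(t)) return(0)
  mean(img$pixels > t)
}

#' Fiber orientation distribution from the FFT power spectrum
#'
#' Computes the 2-D FFT power spectrum (zero-frequency centred), removes the
#' DC/low-frequency disk of radius `r_min` and frequencies beyond `r_max`,
#' sums the remaining power radially into 180 one-degree angular bins, rotates
#' by 90 degrees so that spectral angle maps to real-space fiber angle, and
#' normalizes to unit mass. Bin centres are at 0.5, 1.5, ..., 179.5 degrees.
#'
#' @param img A square [channel_image()], side >= 64.
#' @param r_min Inner band-pass radius in cycles/image (default 4).
#' @param r_max Outer radius; default 0.8 of the Nyquist radius.
#' @return An `orientation_distribution` list with `angles_deg` (bin centres)
#'   and `mass` (nonnegative, sums to 1).
#' @export
orientation_distribution <- function(img, r_min = 4, r_max = NULL) {
  stopifnot(inherits(img, "channel_image"))
  n <- nrow(img$pixels)
  if (n != ncol(img$pixels)) {
    abort("orientation analysis requires a square image; pad or crop first.",
          class = "fibrotype_parameter_error")
  }
  if (n < 64) {
    abort("image side must be >= 64 for orientation analysis.",
          class = "fibrotype_parameter_error")
  }
  r_max <- r_max %||% (0.8 * n / 2)
  x <- img$pixels - mean(img$pixels)
  P <- Mod(stats::fft(x))^2
  # centre the zero frequency, map indices to signed frequencies
  freq <- function(k) ifelse(k <= n / 2, k - 1, k - 1 - n)
  u <- freq(seq_len(n))  # along rows
  v <- freq(seq_len(n))  # along columns
  U <- matrix(u, n, n)          # row frequency (vertical spatial frequency)
  V <- matrix(v, n, n, byrow = TRUE)  # column frequency (horizontal)
  r <- sqrt(U^2 + V^2)
  keep <- r >= r_min & r <= r_max
  # spectral angle measured like the image-space angle convention:
  # 0 = horizontal axis, increasing counter-clockwise in display (row down)
  ang <- atan2(-U, V) * 180 / pi
  fiber_ang <- (ang + 90) %% 180
  bins <- pmin(floor(fiber_ang) + 1L, 180L)
  mass <- rep(0, 180)
  tab <- tapply(P[keep], bins[keep], sum)
  mass[as.integer(names(tab))] <- tab
  if (sum(mass) <= 0) {
    mass <- rep(1 / 180, 180)  # zero-variance image: uniform by convention
  } else {
    mass <- mass / sum(mass)
  }
  structure(list(angles_deg = seq(0.5, 179.5, by = 1), mass = mass),
            class = "orientation_distribution")
}

# Semicircular von Mises density on [0, pi):
# f(theta; mu, k) = exp(k cos 2(theta - mu)) / (pi I0(k)), theta in radians.
semicircular_vm_density <- function(theta_rad, mu_rad, k) {
  exp(k * cos(2 * (theta_rad - mu_rad))) / (pi * besselI(k, 0))
}

# Invert the mean resultant length R = A(k) = I1(k)/I0(k) (Fisher's
# approximation), used to initialize the concentration estimate.
a_inv <- function(R) {
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Fit a semicircular von Mises distribution to an orientation distribution
#'
#' Least-squares fit of the semicircular von Mises density
#' `f(theta; mu, k) = exp(k cos 2(theta - mu)) / (pi I0(k))` to the binned
#' orientation mass (bin mass approximated as density times the 1-degree bin
#' width). Initialized from the circular moments of the doubled angles
#' (mean resultant direction for `mu`, Fisher's `A(k)` inversion for `k`)
#' and refined with bounded L-BFGS-B; `k` is constrained to `[0, 500]`.
#' If refinement fails the moment estimate is returned with the residual of
#' that estimate.
#'
#' @param dist An [orientation_distribution()].
#' @return An `alignment_fit` list: `k` (concentration, >= 0), `mu_deg`
#'   (preferred orientation in `[0, 180)`), `fit_residual` (residual sum of
#'   squares).
#' @export
fit_von_mises <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  theta <- dist$angles_deg * pi / 180
  mass <- dist$mass
  width <- pi / 180
  # moment initialization on doubled angles
  C <- sum(mass * cos(2 * theta))
  S <- sum(mass * sin(2 * theta))
  Rbar <- sqrt(C^2 + S^2)
  mu0 <- (atan2(S, C) / 2) %% pi
  k0 <- min(max(a_inv(min(Rbar, 0.999)), 0), 500)
  rss <- function(par) {
    f <- semicircular_vm_density(theta, par[1], par[2]) * width
    sum((f - mass)^2)
  }
  fit <- tryCatch(
    optim(c(mu0, k0), rss, method = "L-BFGS-B",
          lower = c(-pi, 0), upper = c(2 * pi, 500),
          control = list(maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    par <- c(mu0, k0)
    value <- rss(par)
  } else {
    par <- fit$par
    value <- fit$value
    if (value > rss(c(mu0, k0))) {  # guard: never worse than the init
      par <- c(mu0, k0)
      value <- rss(par)
    }
  }
  structure(list(k = max(par[2], 0), mu_deg = (par[1] * 180 / pi) %% 180,
                 fit_residual = value),
            class = "alignment_fit")
}

#' Trace individual fibers from a channel image
#'
#' A transparent stand-in for curvelet-based fiber extraction: the Otsu
#' foreground mask is skeletonized (Zhang-Suen thinning), branch points are
#' removed, the remaining 8-connected segments are traced, and segments
#' shorter than `min_length_px` are discarded. Length is the geodesic path
#' length (1 per axial step, sqrt(2) per diagonal step, plus 1 for the pixel
#' itself). Width is derived from the Euclidean distance transform of the
#' foreground mask sampled along the path: for a slab of width `w` the
#' centreline distance is `(w + 1) / 2`, so width is reported as twice the
#' mean sampled distance minus 1.
#'
#' @param img A [channel_image()], normally after [denoise()].
#' @param min_length_px Minimum traced length to keep (default 10).
#' @return A tibble with one row per fiber: `fiber_id`, `length_px`,
#'   `width_px`, and `path` (list column of n x 2 coordinate matrices).
#'   Zero rows when the image has no foreground.
#' @export
trace_fibers <- function(img, min_length_px = 10) {
  stopifnot(inherits(img, "channel_image"))
  t <- otsu_threshold(img)
  empty <- tibble::tibble(fiber_id = integer(0), length_px = numeric(0),
                          width_px = numeric(0), path = list())
  if (is.na(t)) return(empty)
  mask <- img$pixels > t
  if (!any(mask)) return(empty)
  skel <- cpp_thin(mask)
  segs <- cpp_trace_segments(skel)
  if (length(segs) == 0) return(empty)
  dmap <- EBImage::distmap(EBImage::Image(mask * 1), metric = "euclidean")
  dmap <- EBImage::imageData(dmap)
  rows <- lapply(segs, function(p) {
    if (nrow(p) < 2) {
      len <- 1
    } else {
      steps <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
      len <- 1 + sum(steps)
    }
    wid <- 2 * mean(dmap[p]) - 1
    c(len, wid)
  })
  lens <- vapply(rows, `[`, numeric(1), 1)
  wids <- pmax(vapply(rows, `[`, numeric(1), 2), 1)
  keep <- lens >= min_length_px
  tibble::tibble(fiber_id = seq_len(sum(keep)),
                 length_px = lens[keep], width_px = wids[keep],
                 path = segs[keep])
}

#' The four morphological features of one channel image
#'
#' Bundles fiber density, the fitted orientation concentration `k`, and the
#' mean traced fiber width and length. Images with no traced fibers report
#' width and length 0; zero-variance images short-circuit to all zeros.
#'
#' @param img A [channel_image()], normally after [denoise()].
#' @param min_length_px Minimum traced fiber length (see [trace_fibers()]).
#' @return Named list: `density`, `alignment_k`, `mean_width_px`,
#'   `mean_length_px`.
#' @export
morphology_features <- function(img, min_length_px = 10) {
  stopifnot(inherits(img, "channel_image"))
  if (is.na(otsu_threshold(img))) {
    return(list(density = 0, alignment_k = 0,
                mean_width_px = 0, mean_length_px = 0))
  }
  fit <- fit_von_mises(orientation_distribution(img))
  fibers <- trace_fibers(img, min_length_px = min_length_px)
  list(
    density = fiber_density(img),
    alignment_k = fit$k,
    mean_width_px = if (nrow(fibers) > 0) mean(fibers$width_px) else 0,
    mean_length_px = if (nrow(fibers) > 0) mean(fibers$length_px) else 0
  )
}
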