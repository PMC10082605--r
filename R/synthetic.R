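#' Parameters of one synthetic fiber class
#'
#' Describes how fibers of one tissue class are drawn: how many, how long and
#' wide, how strongly aligned (semicircular von Mises concentration `k` under
#' the doubled-angle convention), and the intensity/noise model. The three
#' built-in presets (see [fiber_class_presets()]) encode the qualitative
#' histology of the three tissue types: normal skin has long continuous
#' fibers, keloid scar has short, discrete, disordered fibers, and
#' scar-adjacent tissue has highly ordered fibers.
#'
#' @param class_label One of `"normal"`, `"scar"`, `"adjacent"`.
#' @param n_fibers Number of fibers to draw (nonnegative integer).
#' @param length_mean,length_sd Fiber length distribution, pixels.
#' @param width_mean Fiber stroke width, pixels (>= 1).
#' @param dispersion_k Von Mises concentration of fiber orientations (>= 0;
#'   0 = isotropic).
#' @param mean_orientation Preferred orientation, degrees in `[0, 180)`.
#' @param fill_fraction_target Approximate intended foreground coverage in
#'   `[0, 1]`; informational, derived from the geometry when `NULL`.
#' @param intensity_mean,intensity_sd Per-fiber peak intensity distribution,
#'   gray levels.
#' @param background_level Constant background offset, gray levels.
#' @param noise_sd Additive Gaussian background noise, gray levels.
#' @param seed RNG seed making the rendering deterministic.
#'
#' @return A `fiber_class_params` list.
#' @export
fiber_class_params <- function(class_label = c("normal", "scar", "adjacent"),
                               n_fibers = 60L,
                               length_mean = 200, length_sd = 40,
                               width_mean = 4,
                               dispersion_k = 2,
                               mean_orientation = 90,
                               fill_fraction_target = NULL,
                               intensity_mean = 170, intensity_sd = 25,
                               background_level = 8,
                               noise_sd = 8,
                               seed = 1L) {
  class_label <- match.arg(class_label)
  n_fibers <- check_count(n_fibers, "n_fibers", lower = 0L)
  check_number(length_mean, "length_mean", lower = 1e-9)
  check_number(length_sd, "length_sd", lower = 0)
  check_number(width_mean, "width_mean", lower = 1)
  check_number(dispersion_k, "dispersion_k", lower = 0)
  check_number(mean_orientation, "mean_orientation", lower = 0, upper = 180)
  check_number(intensity_mean, "intensity_mean", lower = 0)
  check_number(intensity_sd, "intensity_sd", lower = 0)
  check_number(background_level, "background_level", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(fill_fraction_target)) {
    fill_fraction_target <- min(1, n_fibers * length_mean * width_mean / 512^2)
  }
  check_number(fill_fraction_target, "fill_fraction_target",
               lower = 0, upper = 1)
  structure(
    list(class_label = class_label, n_fibers = n_fibers,
         length_mean = length_mean, length_sd = length_sd,
         width_mean = width_mean, dispersion_k = dispersion_k,
         mean_orientation = mean_orientation %% 180,
         fill_fraction_target = fill_fraction_target,
         intensity_mean = intensity_mean, intensity_sd = intensity_sd,
         background_level = background_level, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "fiber_class_params"
  )
}

#' Default per-class rendering presets
#'
#' Returns, for each tissue class, a pair of [fiber_class_params()] (collagen
#' and elastin channels). The presets encode the qualitative class contrasts
#' the classifier is expected to exploit: fiber length
#' (normal > adjacent > scar), orientation concentration
#' (adjacent > normal > scar), and the weaker, more fragmented elastin signal
#' in scar tissue. No quantitative per-class fiber geometry is published for
#' this system; values are chosen as a realistic desk-scale phantom and held
#' fixed.
#'
#' @return Named list (`normal`, `scar`, `adjacent`), each with elements
#'   `collagen` and `elastin`.
#' @export
fiber_class_presets <- function() {
  list(
    normal = list(
      collagen = fiber_class_params("normal", n_fibers = 55,
                                    length_mean = 260, length_sd = 50,
                                    width_mean = 4.5, dispersion_k = 2,
                                    intensity_mean = 170, intensity_sd = 25),
      elastin = fiber_class_params("normal", n_fibers = 45,
                                   length_mean = 220, length_sd = 45,
                                   width_mean = 3, dispersion_k = 2,
                                   intensity_mean = 150, intensity_sd = 25)
    ),
    scar = list(
      collagen = fiber_class_params("scar", n_fibers = 160,
                                    length_mean = 60, length_sd = 15,
                                    width_mean = 3, dispersion_k = 0.6,
                                    intensity_mean = 185, intensity_sd = 30),
      elastin = fiber_class_params("scar", n_fibers = 110,
                                   length_mean = 45, length_sd = 12,
                                   width_mean = 2.2, dispersion_k = 0.5,
                                   intensity_mean = 115, intensity_sd = 25)
    ),
    adjacent = list(
      collagen = fiber_class_params("adjacent", n_fibers = 60,
                                    length_mean = 230, length_sd = 45,
                                    width_mean = 4, dispersion_k = 9,
                                    intensity_mean = 175, intensity_sd = 25),
      elastin = fiber_class_params("adjacent", n_fibers = 50,
                                   length_mean = 200, length_sd = 40,
                                   width_mean = 3, dispersion_k = 8,
                                   intensity_mean = 145, intensity_sd = 25)
    )
  )
}

#' Sample semicircular von Mises orientations
#'
#' Draws fiber orientations on `[0, 180)` degrees using the doubled-angle
#' construction: a standard von Mises variate with mean `2 * mu` and
#' concentration `kappa` is drawn on `[0, 2*pi)` (Best-Fisher rejection
#' sampling) and halved. `kappa = 0` gives the uniform semicircular law.
#'
#' @param n Number of draws.
#' @param mu_deg Mean orientation, degrees in `[0, 180)`.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in degrees, `[0, 180)`.
#' @export
rvonmises_semicircular <- function(n, mu_deg, kappa) {
  n <- check_count(n, "n", lower = 0L)
  check_number(kappa, "kappa", lower = 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-12) return(runif(n, 0, 180))
  mu2 <- 2 * mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        theta2 <- (mu2 + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        out[i] <- theta2 / 2 * 180 / pi
        break
      }
    }
  }
  out %% 180
}

# Control points of one fiber: a 3-point polyline through `center` with
# direction `angle_deg` (0 deg = horizontal, increasing counter-clockwise in
# conventional image display), total length `len`, and a small perpendicular
# bow at the midpoint.
fiber_polyline <- function(center, angle_deg, len, bow) {
  th <- angle_deg * pi / 180
  dc <- cos(th)
  dr <- -sin(th)  # row axis points down
  p0 <- center - len / 2 * c(dr, dc)
  p2 <- center + len / 2 * c(dr, dc)
  mid <- center + bow * c(dc, -dr)  # unit normal
  rbind(p0, mid, p2)
}

#' Render one synthetic fiber image
#'
#' Draws `n_fibers` anti-aliased thick polylines (3 control points, small
#' random curvature) with orientations from the semicircular von Mises law,
#' then adds the constant background and Gaussian noise and quantizes to the
#' integer gray range. Deterministic given `params$seed`.
#'
#' @param params A [fiber_class_params()].
#' @param size Image side in pixels (>= 64; images are square).
#' @param channel Channel tag for the resulting image.
#' @param bit_depth Output bit depth (8 or 16).
#' @return A [channel_image()]. The drawn fiber orientations are attached as
#'   attribute `"orientations_deg"` for validation work.
#' @export
render_fiber_image <- function(params, size = 512L,
                               channel = c("collagen", "elastin"),
                               bit_depth = 8L) {
  stopifnot(inherits(params, "fiber_class_params"))
  channel <- match.arg(channel)
  size <- check_count(size, "size", lower = 64L)
  L <- 2^bit_depth - 1
  with_seed(params$seed, {
    canvas <- matrix(0, size, size)
    angles <- numeric(0)
    if (params$n_fibers > 0L) {
      angles <- rvonmises_semicircular(params$n_fibers,
                                       params$mean_orientation,
                                       params$dispersion_k)
      centers_r <- runif(params$n_fibers, 1, size)
      centers_c <- runif(params$n_fibers, 1, size)
      lens <- pmax(8, rnorm(params$n_fibers, params$length_mean,
                            params$length_sd))
      bows <- rnorm(params$n_fibers, 0, 0.03 * lens)
      ints <- pmin(pmax(rnorm(params$n_fibers, params$intensity_mean,
                              params$intensity_sd), 0), L)
      for (i in seq_len(params$n_fibers)) {
        pts <- fiber_polyline(c(centers_r[i], centers_c[i]),
                              angles[i], lens[i], bows[i])
        cpp_draw_polyline(canvas, pts, params$width_mean / 2, ints[i])
      }
    }
    canvas <- canvas + params$background_level
    if (params$noise_sd > 0) {
      canvas <- canvas + matrix(rnorm(size^2, 0, params$noise_sd), size, size)
    }
    img <- channel_image(matrix(as.integer(pmin(pmax(round(canvas), 0), L)),
                                size, size),
                         channel = channel, bit_depth = bit_depth)
    attr(img, "orientations_deg") <- angles
    img
  })
}

#' Render a paired collagen/elastin region
#'
#' The two channels are rendered with independent seeds derived from a shared
#' region seed, and share the region's preferred orientation.
#'
#' @param collagen_params,elastin_params [fiber_class_params()] for the two
#'   channels.
#' @param size Image side in pixels.
#' @param region_id Identifier for the region.
#' @param region_seed Shared seed; defaults to `collagen_params$seed`.
#' @return A [region_record()].
#' @export
render_region <- function(collagen_params, elastin_params, size = 512L,
                          region_id = "region", region_seed = NULL) {
  region_seed <- region_seed %||% collagen_params$seed
  collagen_params$seed <- derive_seed(region_seed, 1L)
  elastin_params$seed <- derive_seed(region_seed, 2L)
  region_record(
    render_fiber_image(collagen_params, size, channel = "collagen"),
    render_fiber_image(elastin_params, size, channel = "elastin"),
    region_id = region_id
  )
}

#' Cohort study design
#'
#' The default design mirrors the study this pipeline targets: 26 tissue
#' sections (16 keloid scar, 10 normal) plus scar-adjacent regions from 8
#' scar specimens, with 2-3 imaged regions per section whose features are
#' later averaged per sample.
#'
#' @param n_scar_sections,n_normal_sections,n_adjacent_specimens Sample
#'   counts per class.
#' @param regions_min,regions_max Range of imaged regions per sample
#'   (uniform choice, seeded).
#' @param image_size Image side in pixels.
#' @param presets Per-class channel parameters as from
#'   [fiber_class_presets()].
#' @param master_seed Seed from which all sample/region/channel seeds derive.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_scar_sections = 16L, n_normal_sections = 10L,
                          n_adjacent_specimens = 8L,
                          regions_min = 2L, regions_max = 3L,
                          image_size = 512L,
                          presets = fiber_class_presets(),
                          master_seed = 1L) {
  n_scar_sections <- check_count(n_scar_sections, "n_scar_sections")
  n_normal_sections <- check_count(n_normal_sections, "n_normal_sections")
  n_adjacent_specimens <- check_count(n_adjacent_specimens,
                                      "n_adjacent_specimens")
  if (n_scar_sections + n_normal_sections + n_adjacent_specimens == 0L) {
    abort("at least one sample must be requested.",
          class = "fibrotype_parameter_error")
  }
  regions_min <- check_count(regions_min, "regions_min", lower = 1L)
  regions_max <- check_count(regions_max, "regions_max", lower = regions_min)
  image_size <- check_count(image_size, "image_size", lower = 64L)
  stopifnot(all(c("normal", "scar", "adjacent") %in% names(presets)))
  structure(
    list(n_scar_sections = n_scar_sections,
         n_normal_sections = n_normal_sections,
         n_adjacent_specimens = n_adjacent_specimens,
         regions_min = regions_min, regions_max = regions_max,
         image_size = image_size, presets = presets,
         master_seed = as.integer(master_seed)),
    class = "cohort_design"
  )
}

#' Generate a labelled synthetic cohort
#'
#' One row per sample. Each sample carries 2-3 rendered regions (uniform
#' seeded choice within the design's range); every region draws its own
#' preferred fiber orientation uniformly on `[0, 180)`, shared by its two
#' channels, so classes differ in orientation concentration rather than in
#' absolute direction. Fully reproducible from `design$master_seed`.
#'
#' @param design A [cohort_design()].
#' @return A tibble with columns `sample_id`, `class_label`, and `regions`
#'   (list column of [region_record()] lists).
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  plan <- tibble::tibble(
    class_label = c(rep("scar", design$n_scar_sections),
                    rep("normal", design$n_normal_sections),
                    rep("adjacent", design$n_adjacent_specimens))
  )
  idx <- stats::ave(seq_along(plan$class_label), plan$class_label,
                    FUN = seq_along)
  plan$sample_id <- sprintf("%s_%02d", plan$class_label, idx)

  regions <- vector("list", nrow(plan))
  for (s in seq_len(nrow(plan))) {
    cls <- plan$class_label[s]
    sample_seed <- derive_seed(design$master_seed, s)
    choices <- design$regions_min:design$regions_max
    n_regions <- if (length(choices) == 1L) {
      choices
    } else {
      with_seed(sample_seed, sample(choices, 1L))
    }
    recs <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      region_seed <- derive_seed(sample_seed, 100L + r)
      mu <- with_seed(derive_seed(region_seed, 3L), runif(1, 0, 180))
      cp <- design$presets[[cls]]$collagen
      ep <- design$presets[[cls]]$elastin
      cp$mean_orientation <- mu
      ep$mean_orientation <- mu
      recs[[r]] <- render_region(cp, ep, size = design$image_size,
                                 region_id = sprintf("%s_r%d",
                                                     plan$sample_id[s], r),
                                 region_seed = region_seed)
    }
    regions[[s]] <- recs
  }
  tibble::tibble(sample_id = plan$sample_id,
                 class_label = plan$class_label,
                 regions = regions)
}
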