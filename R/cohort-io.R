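#' Write a cohort to disk
#'
#' Lays out a cohort as `dir/<sample_id>/<region_id>_{collagen,elastin}.tif`
#' plus a `manifest.csv` with columns `sample_id`, `class_label`,
#' `region_id`, `collagen_path`, `elastin_path` (paths relative to `dir`).
#'
#' @param cohort Cohort tibble as from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$sample_id[s]
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    for (rec in cohort$regions[[s]]) {
      cpath <- file.path(sid, paste0(rec$region_id, "_collagen.tif"))
      epath <- file.path(sid, paste0(rec$region_id, "_elastin.tif"))
      write_channel_image(rec$collagen, file.path(dir, cpath))
      write_channel_image(rec$elastin, file.path(dir, epath))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, class_label = cohort$class_label[s],
        region_id = rec$region_id,
        collagen_path = cpath, elastin_path = epath)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Reads a `manifest.csv` written by [write_cohort()] (or assembled by hand
#' for real data), validates it, and returns the grouped cohort tibble.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return Cohort tibble with columns `sample_id`, `class_label`, `regions`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path),
          class = "fibrotype_io_error")
  }
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  required <- c("sample_id", "class_label", "region_id",
                "collagen_path", "elastin_path")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "fibrotype_format_error")
  }
  if (nrow(manifest) == 0) {
    abort("manifest is empty.", class = "fibrotype_format_error")
  }
  bad <- !manifest$class_label %in% c("normal", "scar", "adjacent")
  if (any(bad)) {
    abort(sprintf("unknown class label '%s' in manifest row %d.",
                  manifest$class_label[which(bad)[1]], which(bad)[1]),
          class = "fibrotype_format_error")
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  cpaths <- resolve(manifest$collagen_path)
  epaths <- resolve(manifest$elastin_path)
  missing_files <- c(cpaths[!file.exists(cpaths)], epaths[!file.exists(epaths)])
  if (length(missing_files) > 0) {
    abort(sprintf("missing image file(s): %s",
                  paste(head(missing_files, 3), collapse = ", ")),
          class = "fibrotype_io_error")
  }
  labels <- tapply(manifest$class_label, manifest$sample_id,
                   function(x) unique(x))
  multi <- names(labels)[lengths(labels) > 1]
  if (length(multi) > 0) {
    abort(sprintf("sample '%s' has conflicting class labels.", multi[1]),
          class = "fibrotype_format_error")
  }
  sample_ids <- unique(manifest$sample_id)
  regions <- lapply(sample_ids, function(sid) {
    sub <- manifest[manifest$sample_id == sid, , drop = FALSE]
    lapply(seq_len(nrow(sub)), function(r) {
      region_record(
        read_channel_image(resolve(sub$collagen_path[r]), "collagen"),
        read_channel_image(resolve(sub$elastin_path[r]), "elastin"),
        region_id = sub$region_id[r])
    })
  })
  tibble::tibble(
    sample_id = sample_ids,
    class_label = unname(vapply(labels[sample_ids], identity, character(1))),
    regions = regions
  )
}
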