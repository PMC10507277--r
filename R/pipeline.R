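# End-to-end composition: align -> measure -> architecture (-> symmetry,
# contact summary), with deterministic file products.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with documented defaults.
#' The resolved configuration is echoed verbatim into every JSON product so
#' results are self-describing.
#'
#' @param spacing Voxel spacing `(sz, sy, sx)` in micrometres of the input
#'   volume (ignored when a generated volume is passed directly).
#' @param resample_target Isotropic spacing to resample to before any
#'   morphometry; `NA` keeps already-isotropic input unchanged.
#' @param cytoplasm_label Label id of the cytoplasm, or `NA` for none.
#' @param tol_deg Alignment convergence tolerance, degrees.
#' @param full_threshold Full-coverage contact ratio threshold.
#' @param max_m Highest angular harmonic examined.
#' @param outlier_k Volume-profile outlier threshold (robust SDs).
#' @param seed Integer seed for any randomized step.
#' @param flip_z Aperture orientation: `"auto"`, `"never"`, `"always"`.
#' @param max_pair_index Cap on homologous pair indices in the symmetry
#'   analysis (`Inf` = all pairs).
#' @param exclude_aperture Scales trimmed from each label-order end before
#'   the architecture analysis.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = c(0.02, 0.0073, 0.0073),
                            resample_target = NA_real_,
                            cytoplasm_label = NA_integer_,
                            tol_deg = 0.5,
                            full_threshold = 0.99,
                            max_m = 12L,
                            outlier_k = 3,
                            seed = 0L,
                            flip_z = "auto",
                            max_pair_index = Inf,
                            exclude_aperture = 0L) {
  structure(list(
    spacing = spacing, resample_target = resample_target,
    cytoplasm_label = cytoplasm_label, tol_deg = tol_deg,
    full_threshold = full_threshold, max_m = as.integer(max_m),
    outlier_k = outlier_k, seed = as.integer(seed), flip_z = flip_z,
    max_pair_index = max_pair_index,
    exclude_aperture = as.integer(exclude_aperture)
  ), class = "pipeline_config")
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$max_pair_index <- if (is.infinite(cfg$max_pair_index)) "all"
                        else cfg$max_pair_index
  cfg
}

write_json_product <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full shell-analysis pipeline
#'
#' Aligns the volume (long axis onto +Z, aperture up), measures per-scale
#' morphometrics, quantifies the helical architecture and, when the volume
#' holds both an `M*` and a `D*` shell, the mother/daughter symmetry.
#' Writes `morphometry.csv`, `alignment.json`, `architecture.json`,
#' `contact_summary.json` (when a cytoplasm label is configured),
#' `symmetry.json` (two shells) and a plain-text `report.txt` into
#' `out_dir`.  All products are deterministic given the volume, the
#' configuration and the seed; log lines go to standard error.
#'
#' @param volume A [new_label_volume()], or a path to a multi-page TIFF
#'   (read with `config$spacing`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @return A list of class `pipeline_result`: `alignment`, `morphometry`,
#'   `architecture`, `contact` (or `NULL`), `symmetry` (or `NULL`),
#'   `config`.
#' @export
run_pipeline <- function(volume, config = pipeline_config(), out_dir = NULL) {
  if (is.character(volume))
    volume <- read_label_volume(volume, config$spacing)
  cyt <- if (is.na(config$cytoplasm_label)) NULL else config$cytoplasm_label

  if (!is_isotropic(volume)) {
    target <- config$resample_target
    if (is.na(target)) target <- min(volume$spacing)
    message(sprintf("resampling to isotropic %g um", target))
    volume <- resample_isotropic(volume, target)
  } else if (!is.na(config$resample_target) &&
             abs(volume$spacing[1] - config$resample_target) >
               1e-12 * config$resample_target) {
    volume <- resample_isotropic(volume, config$resample_target)
  }

  message("aligning long axis")
  al <- align_long_axis(volume, tol_deg = config$tol_deg,
                        cytoplasm_label = cyt, flip_z = config$flip_z)
  message("measuring scales")
  rec <- measure_scales(al$volume, cytoplasm_label = cyt,
                        full_threshold = config$full_threshold)
  message("quantifying architecture")
  arch <- shell_architecture(rec, max_m = config$max_m,
                             outlier_k = config$outlier_k,
                             exclude_aperture = config$exclude_aperture)
  contact <- if (!is.null(cyt))
    contact_summary(rec, config$full_threshold) else NULL

  sym <- NULL
  is_m <- grepl("^M\\d+$", rec$name)
  is_d <- grepl("^D\\d+$", rec$name)
  if (sum(is_m) >= 2 && sum(is_d) >= 2) {
    message("analysing mother/daughter symmetry")
    sym <- symmetry_analysis(rec[is_m, ], rec[is_d, ],
                             max_pair_index = config$max_pair_index)
  }

  res <- structure(list(alignment = al$result, morphometry = rec,
                        architecture = arch, contact = contact,
                        symmetry = sym, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_products(res, out_dir)
  res
}

write_pipeline_products <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config_echo(res$config)
  write_morphometry_csv(res$morphometry, file.path(out_dir, "morphometry.csv"))
  al <- res$alignment
  write_json_product(list(
    rotation = al$rotation, center_um = al$center,
    residual_angle_deg = al$residual_angle, iterations = al$iterations,
    converged = al$converged, flipped = al$flipped, config = cfg
  ), file.path(out_dir, "alignment.json"))
  a <- res$architecture
  write_json_product(list(
    petal_count = a$petal_count, twist_rev = a$twist,
    twist_ci_rev = a$twist_ci, handedness = a$handedness,
    spectrum = as.list(a$spectrum),
    spectrum_helical = as.list(unclass(a$spectrum_helical)),
    volume_profile = list(fit = as.list(a$volume_profile$fit),
                          method = a$volume_profile$method),
    outliers = a$outliers, config = cfg
  ), file.path(out_dir, "architecture.json"))
  if (!is.null(res$contact))
    write_json_product(c(unclass(res$contact), list(config = cfg)),
                       file.path(out_dir, "contact_summary.json"))
  if (!is.null(res$symmetry)) {
    s <- res$symmetry
    write_json_product(list(
      axis_point_um = s$axis$point, axis_direction = s$axis$direction,
      collinearity_rmsd_um = s$collinearity_rmsd,
      overlap_rmsd_um = s$overlap_rmsd, n_pairs = s$n_pairs, config = cfg
    ), file.path(out_dir, "symmetry.json"))
  }
  writeLines(pipeline_report(res), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

pipeline_report <- function(res) {
  a <- res$architecture
  lines <- c(
    "shell-architecture report",
    "=========================",
    sprintf("scales analysed: %d", nrow(res$morphometry)),
    sprintf("alignment: residual %.3f deg after %d iteration(s)%s",
            res$alignment$residual_angle, res$alignment$iterations,
            if (res$alignment$flipped) " (Z flipped)" else ""),
    sprintf("petal count (helical columns): %d  [rate-compensated angular spectrum]",
            a$petal_count),
    sprintf("twist: %.3f +/- %s revolutions, handedness %s  [per-column angular fits]",
            a$twist, ifelse(is.na(a$twist_ci), "NA",
                            sprintf("%.3f", a$twist_ci)), a$handedness),
    sprintf("volume-profile outliers (%s fit): %s", a$volume_profile$method,
            if (length(a$outliers)) paste(a$outliers, collapse = ", ")
            else "none")
  )
  if (!is.null(res$contact)) {
    ct <- res$contact
    lines <- c(lines, sprintf(
      "cytoplasm contact: %d of %d scales (%d partial, %d full; largest partial %.3f um^2 on %s)",
      ct$n_in_contact, ct$n_scales, ct$n_partial, ct$n_full,
      ct$max_partial_contact,
      ifelse(is.na(ct$max_partial_label), "-", ct$max_partial_label)))
  }
  if (!is.null(res$symmetry)) {
    s <- res$symmetry
    lines <- c(lines, sprintf(
      "two-fold symmetry: %d pairs, midpoint collinearity RMSD %.4f um, 180-deg overlap RMSD %.4f um",
      s$n_pairs, s$collinearity_rmsd, s$overlap_rmsd))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}

#' Contact summary of a surface/contact-area table
#'
#' Convenience wrapper: classify each row of a per-scale area table (such
#' as [table1_scales()] or a morphometry CSV) and summarise the contact
#' states.
#'
#' @param table A data.frame with `surface_area_um2` and
#'   `contact_area_um2`, or a path to a CSV with those columns.
#' @param full_threshold Full-coverage ratio threshold.
#' @return A `contact_summary` (see [contact_summary()]).
#' @export
summarize_contacts <- function(table, full_threshold = 0.99) {
  if (is.character(table)) table <- utils::read.csv(table)
  table$contact_class <- classify_contact(table$surface_area_um2,
                                          table$contact_area_um2,
                                          full_threshold)
  contact_summary(table, full_threshold)
}
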