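#' Strictly standardized mean difference (SSMD)
#'
#' Computes `(mean(a) - mean(b)) / sqrt(var(a) + var(b))` with unbiased
#' (n - 1) sample variances, preserving the sign of the difference. SSMD is
#' the plate-quality beta score: the separation between a positive-control
#' group and the negative-control group in units of their combined spread.
#'
#' @param group_a,group_b Numeric vectors of well intensities, each of length
#'   `>= 2`.
#' @return A single SSMD value.
#' @examples
#' compute_ssmd(c(10, 12, 14, 16, 18), c(4, 5, 6, 7, 8))
#' @export
compute_ssmd <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("SSMD requires at least 2 values per group",
          class = "appscreen_input_error")
  }
  va <- var(group_a)
  vb <- var(group_b)
  if (va + vb == 0) {
    abort("SSMD undefined: both groups have zero variance",
          class = "appscreen_ssmd_undefined")
  }
  (mean(group_a) - mean(group_b)) / sqrt(va + vb)
}

#' Per-plate SSMD quality control against positive controls
#'
#' For every plate x replicate, computes the SSMD between each positive
#' control group (siAPP, siPSEN1) and the non-targeting group on both
#' channels, using raw (pre-normalization) well means. A plate passes when
#' `|beta| >= threshold` for **both** positive controls on every required
#' channel (default mCherry only, the main read-out). Magnitude is compared
#' because the two controls shift the reporter in opposite directions.
#'
#' @param wells Well-record tibble with columns `plate_id`, `replicate`,
#'   `role`, `mcherry_mean`, `yfp_mean`.
#' @param threshold SSMD magnitude required to pass (default 3).
#' @param channels_required Channels on which both controls must reach the
#'   threshold (subset of `c("mcherry", "yfp")`).
#' @return A tibble of class `plate_qc`: one row per plate x replicate with
#'   the four beta scores (`beta_siAPP_mcherry`, `beta_siAPP_yfp`,
#'   `beta_siPSEN1_mcherry`, `beta_siPSEN1_yfp`) and `passed`.
#' @examples
#' sim <- simulate_screen(screen_sim_config(seed = 3),
#'                        simulate_gene_effects(30, seed = 3))
#' qc_plates(sim$wells)
#' @export
qc_plates <- function(wells, threshold = 3, channels_required = "mcherry") {
  wells <- as_tibble(wells)
  assert_scalar_number(threshold, "threshold", lower = 0)
  stopifnot(all(channels_required %in% c("mcherry", "yfp")))
  qc <- wells |>
    group_by(.data$plate_id, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      nt <- filter(df, .data$role == "non_targeting")
      betas <- list()
      for (ctl in c("siAPP", "siPSEN1")) {
        grp <- filter(df, .data$role == ctl)
        if (nrow(grp) == 0 || nrow(nt) == 0) {
          abort(sprintf("plate %s replicate %s is missing its %s wells",
                        key$plate_id, key$replicate,
                        if (nrow(nt) == 0) "non_targeting" else ctl),
                class = "appscreen_qc_error")
        }
        betas[[paste0("beta_", ctl, "_mcherry")]] <-
          compute_ssmd(grp$mcherry_mean, nt$mcherry_mean)
        betas[[paste0("beta_", ctl, "_yfp")]] <-
          compute_ssmd(grp$yfp_mean, nt$yfp_mean)
      }
      as_tibble(betas)
    }) |>
    ungroup()
  req_cols <- as.vector(outer(c("beta_siAPP_", "beta_siPSEN1_"),
                              channels_required, paste0))
  qc$passed <- apply(abs(as.matrix(qc[req_cols])) >= threshold, 1, all)
  class(qc) <- c("plate_qc", class(qc))
  attr(qc, "threshold") <- threshold
  qc
}

#' Flag wells for inclusion by cell count and plate QC
#'
#' A well is included when its analyzable cell count reaches `min_cells`
#' (default 300) **and** its plate x replicate passed SSMD quality control.
#' When `qc` is `NULL`, only the cell-count rule applies.
#'
#' @param wells Well-record tibble with `cell_count` (and `plate_id`,
#'   `replicate` when `qc` is given).
#' @param qc Optional `plate_qc` tibble from [qc_plates()].
#' @param min_cells Minimum analyzable cells per well (default 300); a well
#'   with 299 cells is excluded, one with exactly 300 is included.
#' @return `wells` with a logical `included` column.
#' @export
filter_wells <- function(wells, qc = NULL, min_cells = 300) {
  wells <- as_tibble(wells)
  assert_scalar_number(min_cells, "min_cells", lower = 0)
  included <- wells$cell_count >= min_cells
  if (!is.null(qc)) {
    pass <- left_join(
      select(wells, "plate_id", "replicate"),
      select(as_tibble(qc), "plate_id", "replicate", "passed"),
      by = c("plate_id", "replicate")
    )$passed
    pass[is.na(pass)] <- FALSE
    included <- included & pass
  }
  mutate(wells, included = included)
}

#' Within-plate fold-change normalization to non-targeting controls
#'
#' For every plate x replicate, divides each well's channel mean by the
#' arithmetic mean of the included non-targeting wells on the same plate,
#' filling `mcherry_fc` and `yfp_fc`. Non-targeting wells receive fold-changes
#' too, so their per-plate mean fold-change is exactly 1. Being a
#' within-plate ratio, the fold-change is invariant to any common plate
#' factor.
#'
#' @param wells Well-record tibble; an `included` column is honoured when
#'   present (excluded NT wells do not enter the reference mean), otherwise
#'   all wells are treated as included.
#' @return `wells` with `mcherry_fc` and `yfp_fc` columns added.
#' @export
normalize_wells <- function(wells) {
  wells <- as_tibble(wells)
  if (!"included" %in% names(wells)) {
    wells$included <- TRUE
  }
  out <- wells |>
    group_by(.data$plate_id, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      nt <- filter(df, .data$role == "non_targeting", .data$included)
      if (nrow(nt) == 0) {
        abort(sprintf(
          "plate %s replicate %s has no included non-targeting wells to normalize against",
          key$plate_id, key$replicate),
          class = "appscreen_normalization_error")
      }
      mutate(df,
             mcherry_fc = .data$mcherry_mean / mean(nt$mcherry_mean),
             yfp_fc = .data$yfp_mean / mean(nt$yfp_mean))
    }) |>
    ungroup()
  out
}

#' @export
autoplot.plate_qc <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 3
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = dplyr::starts_with("beta_"),
    names_to = "control_channel", names_prefix = "beta_",
    values_to = "ssmd"
  )
  ggplot(long, aes(x = .data$plate_id, y = abs(.data$ssmd),
                   colour = .data$control_channel,
                   shape = factor(.data$replicate))) +
    geom_point() +
    geom_hline(yintercept = thr, linetype = "dashed") +
    labs(x = "plate", y = "|SSMD|", colour = "control / channel",
         shape = "replicate",
         title = "Plate quality control (SSMD vs non-targeting)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}
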