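#' Configuration for the intensity-level screen simulator
#'
#' Describes a triplicate, 384-well-plate siRNA screen at the level of
#' per-well mean intensities, bypassing images so that plate QC,
#' normalization and hit calling can be exercised at genome scale in seconds.
#' Each plate carries non-targeting (NT) negative-control wells plus two
#' positive-control groups: siAPP (knocks the tagged APP reporter down on both
#' channels) and siPSEN1 (gamma-secretase knock-down, accumulating
#' intracellular APP fragments and raising both channels).
#'
#' @param plate_size Wells per plate (default 384).
#' @param n_replicates Independent screen replicates (default 3).
#' @param n_nt_wells_per_plate Non-targeting wells per plate (default 14,
#'   mirroring the positive-control group size).
#' @param n_siapp_wells_per_plate,n_sipsen1_wells_per_plate Positive-control
#'   wells per plate (default 14 each).
#' @param baseline_mcherry,baseline_yfp Baseline well-mean intensities for an
#'   inert perturbation, arbitrary fluorescence units.
#' @param well_noise_cv Multiplicative log-normal well-to-well noise CV.
#' @param plate_effect_cv Multiplicative log-normal plate-level factor CV
#'   (shared by every well on a plate; cancelled by within-plate
#'   normalization).
#' @param cellcount_mean,cellcount_sd Analyzable-cell-count calibration in
#'   cells (defaults 795 and 345; see [sample_cell_counts()]).
#' @param control_effects Named list of per-control multiplicative channel
#'   factors, each a named numeric `c(mcherry = , yfp = )`. Defaults reduce
#'   both channels to 0.4x for siAPP and raise them (2.2x mCherry, 1.8x YFP)
#'   for siPSEN1, giving plate SSMD magnitudes well above 3 at default noise.
#' @param seed Integer seed used by [simulate_screen()].
#'
#' @return An object of class `screen_sim_config`.
#' @examples
#' cfg <- screen_sim_config(seed = 1)
#' cfg$n_replicates
#' @export
screen_sim_config <- function(plate_size = 384,
                              n_replicates = 3,
                              n_nt_wells_per_plate = 14,
                              n_siapp_wells_per_plate = 14,
                              n_sipsen1_wells_per_plate = 14,
                              baseline_mcherry = 400,
                              baseline_yfp = 200,
                              well_noise_cv = 0.1,
                              plate_effect_cv = 0.1,
                              cellcount_mean = 795,
                              cellcount_sd = 345,
                              control_effects = list(
                                siAPP = c(mcherry = 0.4, yfp = 0.4),
                                siPSEN1 = c(mcherry = 2.2, yfp = 1.8)
                              ),
                              seed = 1L) {
  n_control <- n_nt_wells_per_plate + n_siapp_wells_per_plate +
    n_sipsen1_wells_per_plate
  if (n_control >= plate_size) {
    abort("control wells per plate must leave room for sample wells",
          class = "appscreen_param_error")
  }
  assert_scalar_number(well_noise_cv, "well_noise_cv", lower = 0)
  assert_scalar_number(plate_effect_cv, "plate_effect_cv", lower = 0)
  assert_scalar_number(n_replicates, "n_replicates", lower = 1)
  for (ctl in c("siAPP", "siPSEN1")) {
    eff <- control_effects[[ctl]]
    if (is.null(eff) || anyNA(eff[c("mcherry", "yfp")])) {
      abort(sprintf("`control_effects` must define mcherry and yfp factors for %s", ctl),
            class = "appscreen_param_error")
    }
  }
  structure(
    list(plate_size = as.integer(plate_size),
         n_replicates = as.integer(n_replicates),
         n_nt_wells_per_plate = as.integer(n_nt_wells_per_plate),
         n_siapp_wells_per_plate = as.integer(n_siapp_wells_per_plate),
         n_sipsen1_wells_per_plate = as.integer(n_sipsen1_wells_per_plate),
         baseline_mcherry = baseline_mcherry,
         baseline_yfp = baseline_yfp,
         well_noise_cv = well_noise_cv,
         plate_effect_cv = plate_effect_cv,
         cellcount_mean = cellcount_mean,
         cellcount_sd = cellcount_sd,
         control_effects = control_effects,
         seed = as.integer(seed)),
    class = "screen_sim_config"
  )
}

#' Simulate per-gene reporter effects
#'
#' Draws a gene-effect table in which a fraction of genes perturb the
#' mCherry/YFP read-out. Active genes receive a signed log2 effect whose
#' magnitude is uniform on `effect_range`; the YFP effect is the mCherry
#' effect shrunk by `yfp_attenuation` (the membrane YFP signal responds more
#' weakly than mCherry). Inactive genes have zero effect.
#'
#' @param n_genes Number of genes.
#' @param prop_active Fraction of genes with a true effect (default 0.05).
#' @param effect_range Range of absolute log2 effects for active genes.
#' @param yfp_attenuation Multiplier applied to the mCherry effect to obtain
#'   the YFP effect.
#' @param seed Optional integer seed.
#' @return Tibble: `gene_id`, `mcherry_log2_effect`, `yfp_log2_effect`.
#' @examples
#' eff <- simulate_gene_effects(100, seed = 1)
#' mean(eff$mcherry_log2_effect != 0)
#' @export
simulate_gene_effects <- function(n_genes, prop_active = 0.05,
                                  effect_range = c(0.5, 2),
                                  yfp_attenuation = 0.6,
                                  seed = NULL) {
  stopifnot(n_genes >= 1, prop_active >= 0, prop_active <= 1)
  with_seed_maybe(seed, {
    n_active <- round(prop_active * n_genes)
    active <- sample.int(n_genes, n_active)
    eff <- numeric(n_genes)
    eff[active] <- sample(c(-1, 1), n_active, replace = TRUE) *
      runif(n_active, effect_range[1], effect_range[2])
    tibble(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      mcherry_log2_effect = eff,
      yfp_log2_effect = eff * yfp_attenuation
    )
  })
}

# Build the plate layout implied by a config: controls occupy the first wells
# of the plate (edge-adjacent in row-major order), samples fill the rest
# column-ordered.
build_layouts <- function(config, n_genes) {
  n_sample <- config$plate_size - config$n_nt_wells_per_plate -
    config$n_siapp_wells_per_plate - config$n_sipsen1_wells_per_plate
  n_plates <- ceiling(n_genes / n_sample)
  wells <- well_names_384(config$plate_size)
  roles <- c(rep("non_targeting", config$n_nt_wells_per_plate),
             rep("siAPP", config$n_siapp_wells_per_plate),
             rep("siPSEN1", config$n_sipsen1_wells_per_plate),
             rep("sample", n_sample))
  purrr::map_dfr(seq_len(n_plates), function(p) {
    first_gene <- (p - 1L) * n_sample + 1L
    gene_idx <- first_gene:min(first_gene + n_sample - 1L, n_genes)
    sirna <- c(rep("NT", config$n_nt_wells_per_plate),
               rep("siAPP", config$n_siapp_wells_per_plate),
               rep("siPSEN1", config$n_sipsen1_wells_per_plate),
               sprintf("gene%05d", gene_idx),
               rep(NA_character_, n_sample - length(gene_idx)))
    keep <- !is.na(sirna)
    tibble(plate_id = sprintf("P%03d", p),
           well_id = wells[keep],
           sirna_id = sirna[keep],
           role = roles[keep])
  })
}

#' Simulate a complete multi-replicate screen at the intensity level
#'
#' Lays genes out across 384-well plates (fixed gene-to-well assignment in
#' every replicate), spikes control wells with their configured effects, and
#' generates per-well mean intensities as
#' `baseline * 2^effect * plate_factor * well_noise` with log-normal plate
#' and well noise. Analyzable cell counts are drawn from the zero-truncated
#' normal calibration.
#'
#' @param config A [screen_sim_config()].
#' @param effects Gene-effect tibble ([simulate_gene_effects()]); its
#'   `gene_id` values become the sample-well siRNA identifiers.
#' @param max_plates Optional cap on plates per replicate; requesting more
#'   genes than the capped plates can hold is a capacity error.
#' @return List of class `screen_sim` with elements `wells` (one row per well
#'   per replicate: `plate_id`, `well_id`, `replicate`, `sirna_id`, `role`,
#'   `cell_count`, `mcherry_mean`, `yfp_mean`) and `layout` (plate map).
#' @examples
#' cfg <- screen_sim_config(seed = 7)
#' sim <- simulate_screen(cfg, simulate_gene_effects(50, seed = 7))
#' dplyr::count(sim$wells, role)
#' @export
simulate_screen <- function(config, effects, max_plates = Inf) {
  stopifnot(inherits(config, "screen_sim_config"))
  effects <- as_tibble(effects)
  n_genes <- nrow(effects)
  n_sample <- config$plate_size - config$n_nt_wells_per_plate -
    config$n_siapp_wells_per_plate - config$n_sipsen1_wells_per_plate
  if (n_sample < 1) {
    abort("no sample wells available per plate", class = "appscreen_capacity_error")
  }
  if (ceiling(n_genes / n_sample) > max_plates) {
    abort(sprintf(
      "%d genes exceed the %d sample wells available on %s plates",
      n_genes, n_sample * max_plates, format(max_plates)),
      class = "appscreen_capacity_error")
  }

  layout <- build_layouts(config, n_genes)
  # gene ids in the layout are positional; rename to the caller's ids
  gene_map <- setNames(effects$gene_id, sprintf("gene%05d", seq_len(n_genes)))
  layout$sirna_id <- ifelse(layout$role == "sample",
                            unname(gene_map[layout$sirna_id]),
                            layout$sirna_id)

  ctl <- config$control_effects
  eff_tbl <- bind_rows(
    tibble(sirna_id = effects$gene_id,
           mch_factor = 2^effects$mcherry_log2_effect,
           yfp_factor = 2^effects$yfp_log2_effect),
    tibble(sirna_id = "NT", mch_factor = 1, yfp_factor = 1),
    tibble(sirna_id = "siAPP",
           mch_factor = ctl$siAPP[["mcherry"]], yfp_factor = ctl$siAPP[["yfp"]]),
    tibble(sirna_id = "siPSEN1",
           mch_factor = ctl$siPSEN1[["mcherry"]], yfp_factor = ctl$siPSEN1[["yfp"]])
  )

  with_seed_maybe(config$seed, {
    wells <- purrr::map_dfr(seq_len(config$n_replicates), function(rep_i) {
      tbl <- layout
      tbl$replicate <- rep_i
      plates <- unique(tbl$plate_id)
      plate_factor <- setNames(rlnorm_cv1(length(plates), config$plate_effect_cv),
                               plates)
      tbl <- left_join(tbl, eff_tbl, by = "sirna_id")
      nw <- nrow(tbl)
      tbl$mcherry_mean <- config$baseline_mcherry * tbl$mch_factor *
        unname(plate_factor[tbl$plate_id]) * rlnorm_cv1(nw, config$well_noise_cv)
      tbl$yfp_mean <- config$baseline_yfp * tbl$yfp_factor *
        unname(plate_factor[tbl$plate_id]) * rlnorm_cv1(nw, config$well_noise_cv)
      tbl$cell_count <- sample_cell_counts(nw, config$cellcount_mean,
                                           config$cellcount_sd)
      select(tbl, "plate_id", "well_id", "replicate", "sirna_id", "role",
             "cell_count", "mcherry_mean", "yfp_mean")
    })
    structure(list(wells = wells, layout = layout), class = "screen_sim")
  })
}

#' Write a simulated screen as delimited tables
#'
#' Emits the plate-map CSV (`plate_id`, `well`, `sirna_id`, `role`) and the
#' per-well results table consumed by the QC/normalization stage, making
#' simulated and image-derived data interchangeable.
#'
#' @param sim A `screen_sim` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_screen_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "screen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map_path <- file.path(dir, "plate_map.csv")
  wells_path <- file.path(dir, "well_records.csv")
  readr::write_csv(rename(sim$layout, well = "well_id"), map_path)
  readr::write_csv(sim$wells, wells_path)
  invisible(c(plate_map = map_path, well_records = wells_path))
}
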