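#' Analyze a screen's well records end to end
#'
#' Runs the gatekeeping and scoring stages in order: SSMD plate quality
#' control, well filtering by analyzable cell count, within-plate fold-change
#' normalization to non-targeting controls, replicate aggregation, two-tailed
#' percentile hit calling, and the replicate-robustness summary. Optionally
#' cross-references hits against a GWAS-locus gene list and applies the
#' gene-wide Bonferroni filter to an association table.
#'
#' @param wells Well-record tibble (`plate_id`, `well_id`, `replicate`,
#'   `sirna_id`, `role`, `cell_count`, `mcherry_mean`, `yfp_mean`).
#' @param min_cells Minimum analyzable cells per well (default 300).
#' @param ssmd_threshold Plate SSMD magnitude required (default 3).
#' @param channels_required Channels on which plate QC must pass.
#' @param tail_fraction Hit fraction per tail (default 0.025).
#' @param hit_channel Channel ranking the hits (default `"mcherry"`).
#' @param min_replicates Minimum included replicates per gene (default 2).
#' @param locus_genes Optional GWAS-locus gene list for [crossref_hits()].
#' @param associations Optional association table for [bonferroni_filter()].
#' @param family_alpha Family-wise alpha for the Bonferroni filter.
#'
#' @return An object of class `screen_analysis`: a list with `wells`
#'   (filtered + normalized records), `qc`, `scores` (hit table),
#'   `robustness`, and when the inputs were given `overlap` and `survivors`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_screen(screen_sim_config(seed = 5),
#'                        simulate_gene_effects(200, seed = 5))
#' res <- analyze_screen(sim$wells)
#' glance(res)
#' @export
analyze_screen <- function(wells,
                           min_cells = 300,
                           ssmd_threshold = 3,
                           channels_required = "mcherry",
                           tail_fraction = 0.025,
                           hit_channel = "mcherry",
                           min_replicates = 2,
                           locus_genes = NULL,
                           associations = NULL,
                           family_alpha = 0.05) {
  qc <- qc_plates(wells, threshold = ssmd_threshold,
                  channels_required = channels_required)
  wells <- filter_wells(wells, qc, min_cells = min_cells)
  wells <- normalize_wells(wells)
  scores <- aggregate_replicates(wells, min_replicates = min_replicates)
  scores <- call_hits(scores, tail_fraction = tail_fraction,
                      channel = hit_channel)
  robustness <- robustness_report(scores)
  out <- list(wells = wells, qc = qc, scores = scores,
              robustness = robustness)
  if (!is.null(locus_genes)) {
    out$overlap <- crossref_hits(scores, locus_genes)
  }
  if (!is.null(associations)) {
    out$survivors <- bonferroni_filter(associations,
                                       family_alpha = family_alpha)
  }
  structure(out, class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  g <- glance(x)
  cat("High-content screen analysis\n")
  cat(sprintf("  wells: %d (%d included), plates passing QC: %d/%d\n",
              nrow(x$wells), sum(x$wells$included),
              sum(x$qc$passed), nrow(x$qc)))
  cat(sprintf("  genes scored: %d, hits: %d (%d up, %d down)\n",
              g$n_genes, g$n_hits, g$n_up, g$n_down))
  if (!is.null(x$overlap)) {
    cat(sprintf("  hits in GWAS loci: %d\n", nrow(x$overlap)))
  }
  if (!is.null(x$survivors)) {
    cat(sprintf("  Bonferroni survivors (p < %s): %s\n",
                format(attr(x$survivors, "threshold_display")),
                paste(x$survivors$gene, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname analyze_screen
#' @param x A `screen_analysis` object.
#' @param ... Unused.
#' @export
tidy.screen_analysis <- function(x, ...) {
  as_tibble(x$scores)
}

#' @rdname analyze_screen
#' @export
glance.screen_analysis <- function(x, ...) {
  tibble(
    n_wells = nrow(x$wells),
    n_wells_included = sum(x$wells$included),
    n_plates = nrow(x$qc),
    plate_pass_rate = mean(x$qc$passed),
    n_genes = nrow(x$scores),
    n_hits = sum(x$scores$hit),
    n_up = sum(x$scores$direction == "up"),
    n_down = sum(x$scores$direction == "down"),
    mean_fc_sd_pct = x$robustness$mean_fc_sd_pct
  )
}

#' @rdname analyze_screen
#' @param object A `screen_analysis` object.
#' @export
autoplot.screen_analysis <- function(object, ...) {
  autoplot(object$scores, ...)
}

pipeline_default_config <- function() {
  list(
    seed = 1L,
    min_cells = 300,
    ssmd_threshold = 3,
    tail_fraction = 0.025,
    hit_channel = "mcherry",
    min_replicates = 2,
    family_alpha = 0.05,
    n_genes = 2000L,
    use_packaged_genetics = TRUE,
    screen_sim = list(),
    image_sim = list()
  )
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "appscreen_config_error")
  }
  config <- modifyList(defaults, config)
  assert_scalar_number(config$min_cells, "min_cells", lower = 0)
  assert_scalar_number(config$ssmd_threshold, "ssmd_threshold", lower = 0)
  if (!(config$tail_fraction > 0 && config$tail_fraction < 0.5)) {
    abort("`tail_fraction` must lie in (0, 0.5)", class = "appscreen_config_error")
  }
  config
}

#' Run the full screen pipeline and write its result bundle
#'
#' Simulates an intensity-level screen from the configuration (or consumes a
#' pre-quantified well-record table), analyzes it with [analyze_screen()],
#' and writes every stage output as a delimited table together with a
#' manifest of MD5 checksums. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognised keys: `seed`, `min_cells`, `ssmd_threshold`,
#'   `tail_fraction`, `hit_channel`, `min_replicates`, `family_alpha`,
#'   `n_genes`, `use_packaged_genetics`, `screen_sim` (arguments to
#'   [screen_sim_config()]), `image_sim` (unused in the intensity path).
#'   Unknown keys are rejected.
#' @param out_dir Output directory.
#' @param wells Optional pre-quantified well-record tibble; when supplied the
#'   simulator is skipped.
#' @return Invisibly, the `screen_analysis` result.
#' @export
run_screen_pipeline <- function(config = list(), out_dir, wells = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(wells)) {
    sim_cfg <- do.call(screen_sim_config,
                       modifyList(list(seed = config$seed), config$screen_sim))
    effects <- simulate_gene_effects(config$n_genes, seed = config$seed)
    sim <- simulate_screen(sim_cfg, effects)
    wells <- sim$wells
    readr::write_csv(sim$layout, file.path(out_dir, "plate_map.csv"))
    readr::write_csv(effects, file.path(out_dir, "true_gene_effects.csv"))
  }

  locus_genes <- if (isTRUE(config$use_packaged_genetics)) load_igap_locus_genes()
  associations <- if (isTRUE(config$use_packaged_genetics)) load_igap_associations()

  res <- analyze_screen(
    wells,
    min_cells = config$min_cells,
    ssmd_threshold = config$ssmd_threshold,
    tail_fraction = config$tail_fraction,
    hit_channel = config$hit_channel,
    min_replicates = config$min_replicates,
    locus_genes = locus_genes,
    associations = associations,
    family_alpha = config$family_alpha
  )

  readr::write_csv(res$wells, file.path(out_dir, "well_records.csv"))
  readr::write_csv(as_tibble(res$qc), file.path(out_dir, "plate_qc.csv"))
  readr::write_csv(as_tibble(res$scores), file.path(out_dir, "hit_table.csv"))
  readr::write_csv(res$robustness, file.path(out_dir, "robustness_summary.csv"))
  if (!is.null(res$overlap)) {
    readr::write_csv(res$overlap, file.path(out_dir, "gwas_overlap.csv"))
  }
  if (!is.null(res$survivors)) {
    surv <- mutate(as_tibble(res$survivors),
                   bonferroni_threshold = attr(res$survivors, "threshold"),
                   bonferroni_threshold_display = attr(res$survivors, "threshold_display"))
    readr::write_csv(surv, file.path(out_dir, "bonferroni_survivors.csv"))
  }

  files <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                        file.path(out_dir, "manifest.csv")))
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  invisible(res)
}
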