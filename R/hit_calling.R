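#' Aggregate replicate fold-changes into per-gene scores
#'
#' Takes normalized, filtered well records, keeps included sample wells, and
#' summarises each gene across replicates: per-replicate log2 fold-changes
#' are averaged (the geometric-mean convention: log2 first, then mean) and
#' their unbiased SD reported per channel. The replicate-robustness metric
#' `fc_sd_pct` is the unbiased SD of the *linear* mCherry fold-changes,
#' expressed in percent. Genes with fewer than `min_replicates` included
#' replicates are dropped from the scores and reported in the `dropped`
#' attribute.
#'
#' @param wells Normalized well records (columns `sirna_id`, `role`,
#'   `included`, `mcherry_fc`, `yfp_fc`).
#' @param min_replicates Minimum included replicates per gene (default 2).
#' @return A tibble of gene scores: `gene_id`, `n_replicates_used`,
#'   `mcherry_log2fc_mean`, `mcherry_log2fc_sd`, `yfp_log2fc_mean`,
#'   `yfp_log2fc_sd`, `fc_sd_pct`; attribute `dropped` lists genes removed
#'   for insufficient replicates.
#' @examples
#' sim <- simulate_screen(screen_sim_config(seed = 4),
#'                        simulate_gene_effects(40, seed = 4))
#' wells <- normalize_wells(filter_wells(sim$wells, qc_plates(sim$wells)))
#' aggregate_replicates(wells)
#' @export
aggregate_replicates <- function(wells, min_replicates = 2) {
  wells <- as_tibble(wells)
  assert_scalar_number(min_replicates, "min_replicates", lower = 1)
  usable <- filter(wells, .data$role == "sample", .data$included)
  scores <- usable |>
    group_by(gene_id = .data$sirna_id) |>
    summarise(
      n_replicates_used = dplyr::n(),
      mcherry_log2fc_mean = mean(log2(.data$mcherry_fc)),
      mcherry_log2fc_sd = sd(log2(.data$mcherry_fc)),
      yfp_log2fc_mean = mean(log2(.data$yfp_fc)),
      yfp_log2fc_sd = sd(log2(.data$yfp_fc)),
      fc_sd_pct = sd(.data$mcherry_fc) * 100,
      .groups = "drop"
    )
  dropped <- filter(scores, .data$n_replicates_used < min_replicates)
  scores <- filter(scores, .data$n_replicates_used >= min_replicates)
  attr(scores, "dropped") <- dropped
  scores
}

#' Call two-tailed percentile hits on the main read-out
#'
#' Ranks genes by mean log2 fold-change on the selected channel and flags the
#' `floor(tail_fraction * N)` most down-regulated and the same number of most
#' up-regulated genes as hits (default 2.5% per tail, i.e. the strongest 5%
#' of variations). Ties are broken by lexicographic `gene_id`, so the call is
#' deterministic and invariant to input order.
#'
#' @param scores Gene-score tibble from [aggregate_replicates()].
#' @param tail_fraction Fraction flagged per tail, in (0, 0.5); default 0.025.
#' @param channel Channel whose mean log2 fold-change ranks the genes
#'   (default `"mcherry"`).
#' @return `scores` with logical `hit` and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns, ordered by the ranking channel;
#'   class `hit_table`.
#' @examples
#' scores <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
#'                          mcherry_log2fc_mean = seq(-2, 2, length.out = 40))
#' sum(call_hits(scores)$hit)
#' @export
call_hits <- function(scores, tail_fraction = 0.025, channel = "mcherry") {
  scores <- as_tibble(scores)
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    abort("`tail_fraction` must lie in (0, 0.5)", class = "appscreen_param_error")
  }
  value_col <- paste0(channel, "_log2fc_mean")
  stopifnot(value_col %in% names(scores))
  n <- nrow(scores)
  k <- floor(tail_fraction * n)
  if (k < 1) {
    abort(sprintf(
      "too few genes (%d) for tail fraction %.4f: no full tail can be formed",
      n, tail_fraction),
      class = "appscreen_sizing_error")
  }
  v <- scores[[value_col]]
  ord <- order(v, scores$gene_id)
  # 2k <= n because tail_fraction < 0.5, so the two tails never overlap
  down_idx <- ord[seq_len(k)]
  up_idx <- ord[(n - k + 1):n]
  direction <- rep("none", n)
  direction[down_idx] <- "down"
  direction[up_idx] <- "up"
  out <- mutate(scores,
                hit = direction != "none",
                direction = direction)
  out <- arrange(out, .data[[value_col]], .data$gene_id)
  attr(out, "tail_fraction") <- tail_fraction
  attr(out, "channel") <- channel
  class(out) <- c("hit_table", class(out))
  out
}

#' Replicate-robustness summary of gene scores
#'
#' Descriptive summary of the linear fold-change SD (in percent) across
#' replicates: mean and SD over all genes and over hits, plus the number of
#' genes whose SD exceeds `sd_threshold_pct` overall and among hits.
#'
#' @param scores A gene-score tibble; a `hit` column (e.g. from
#'   [call_hits()]) enables the hit-restricted columns.
#' @param sd_threshold_pct Exceedance threshold in percent (default 25).
#' @return One-row tibble: `n_genes`, `mean_fc_sd_pct`, `sd_fc_sd_pct`,
#'   `n_above_threshold`, and when hits are flagged `n_hits`,
#'   `mean_fc_sd_pct_hits`, `sd_fc_sd_pct_hits`, `n_above_threshold_hits`.
#' @export
robustness_report <- function(scores, sd_threshold_pct = 25) {
  scores <- as_tibble(scores)
  out <- tibble(
    n_genes = nrow(scores),
    mean_fc_sd_pct = mean(scores$fc_sd_pct, na.rm = TRUE),
    sd_fc_sd_pct = sd(scores$fc_sd_pct, na.rm = TRUE),
    n_above_threshold = sum(scores$fc_sd_pct > sd_threshold_pct, na.rm = TRUE)
  )
  if ("hit" %in% names(scores)) {
    hits <- filter(scores, .data$hit)
    out$n_hits <- nrow(hits)
    out$mean_fc_sd_pct_hits <- mean(hits$fc_sd_pct, na.rm = TRUE)
    out$sd_fc_sd_pct_hits <- sd(hits$fc_sd_pct, na.rm = TRUE)
    out$n_above_threshold_hits <- sum(hits$fc_sd_pct > sd_threshold_pct,
                                      na.rm = TRUE)
  }
  out
}

#' @export
autoplot.hit_table <- function(object, bins = 80, ...) {
  channel <- attr(object, "channel") %||% "mcherry"
  value_col <- paste0(channel, "_log2fc_mean")
  ggplot(object, aes(x = .data[[value_col]], fill = .data$direction)) +
    geom_histogram(bins = bins) +
    scale_fill_manual(values = c(down = "#4575b4", none = "grey70",
                                 up = "#d73027")) +
    labs(x = sprintf("mean %s log2 fold-change", channel), y = "genes",
         title = sprintf("Hit calling: extreme %.1f%% per tail",
                         100 * (attr(object, "tail_fraction") %||% 0.025))) +
    theme_minimal()
}
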