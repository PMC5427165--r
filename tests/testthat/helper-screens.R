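# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

noiseless_params <- function(image_size = 256, ...) {
  image_sim_params(image_size = image_size,
                   noise_sd = c(hoechst = 0, yfp = 0, mcherry = 0),
                   ...)
}

# Match quantified cells to ground-truth rows by nearest centroid.
match_cells_to_truth <- function(cells, truth) {
  idx <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((truth$center_row - cells$center_row[i])^2 +
                (truth$center_col - cells$center_col[i])^2)
  }, integer(1))
  truth[idx, ]
}

# A minimal one-plate, one-replicate well table with explicit intensities.
manual_plate <- function(nt_mcherry, sample_mcherry,
                         plate_id = "P001", replicate = 1L,
                         cell_count = 500L) {
  n_nt <- length(nt_mcherry)
  n_s <- length(sample_mcherry)
  tibble::tibble(
    plate_id = plate_id,
    well_id = sprintf("W%02d", seq_len(n_nt + n_s)),
    replicate = replicate,
    sirna_id = c(rep("NT", n_nt), sprintf("g%02d", seq_len(n_s))),
    role = c(rep("non_targeting", n_nt), rep("sample", n_s)),
    cell_count = cell_count,
    mcherry_mean = c(nt_mcherry, sample_mcherry),
    yfp_mean = c(nt_mcherry, sample_mcherry) / 2
  )
}

# Gene-score tibble with prescribed mCherry scores.
manual_scores <- function(values, ids = sprintf("g%03d", seq_along(values))) {
  tibble::tibble(
    gene_id = ids,
    n_replicates_used = 3L,
    mcherry_log2fc_mean = values,
    mcherry_log2fc_sd = 0,
    yfp_log2fc_mean = values / 2,
    yfp_log2fc_sd = 0,
    fc_sd_pct = 0
  )
}
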