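zero_noise_config <- function(...) {
  screen_sim_config(well_noise_cv = 0, plate_effect_cv = 0, seed = 1, ...)
}

test_that("noise-free simulation reproduces baselines and injected effects exactly", {
  cfg <- zero_noise_config()
  effects <- tibble::tibble(gene_id = c("gA", "gB"),
                            mcherry_log2_effect = c(0, 1),
                            yfp_log2_effect = c(0, 0))
  sim <- simulate_screen(cfg, effects)
  samples <- dplyr::filter(sim$wells, role == "sample")
  expect_identical(
    samples$mcherry_mean[samples$sirna_id == "gA"],
    rep(cfg$baseline_mcherry, cfg$n_replicates)
  )
  expect_identical(
    samples$mcherry_mean[samples$sirna_id == "gB"],
    rep(2 * cfg$baseline_mcherry, cfg$n_replicates)
  )
})

test_that("control wells carry their configured multiplicative effects", {
  cfg <- zero_noise_config()
  sim <- simulate_screen(cfg, tibble::tibble(gene_id = "g1",
                                             mcherry_log2_effect = 0,
                                             yfp_log2_effect = 0))
  w <- dplyr::filter(sim$wells, replicate == 1)
  nt <- mean(w$mcherry_mean[w$role == "non_targeting"])
  expect_equal(mean(w$mcherry_mean[w$role == "siAPP"]), 0.4 * nt)
  expect_equal(mean(w$mcherry_mean[w$role == "siPSEN1"]), 2.2 * nt)
  expect_equal(mean(w$yfp_mean[w$role == "siAPP"]),
               0.4 * mean(w$yfp_mean[w$role == "non_targeting"]))
})

test_that("identity control effects give SSMD about zero and a failed plate", {
  cfg <- screen_sim_config(
    seed = 8,
    control_effects = list(siAPP = c(mcherry = 1, yfp = 1),
                           siPSEN1 = c(mcherry = 1, yfp = 1))
  )
  sim <- simulate_screen(cfg, simulate_gene_effects(10, seed = 8))
  qc <- qc_plates(sim$wells)
  expect_true(all(!qc$passed))
  expect_true(all(abs(qc$beta_siAPP_mcherry) < 3))
})

test_that("default control effects pass plate QC at default noise", {
  sim <- simulate_screen(screen_sim_config(seed = 21),
                         simulate_gene_effects(300, seed = 21))
  qc <- qc_plates(sim$wells)
  expect_true(all(qc$passed))
})

test_that("simulation is deterministic under the config seed", {
  cfg <- screen_sim_config(seed = 33)
  eff <- simulate_gene_effects(40, seed = 33)
  s1 <- simulate_screen(cfg, eff)
  s2 <- simulate_screen(cfg, eff)
  expect_identical(s1$wells, s2$wells)
})

test_that("with noise off, the analysis recovers injected effects exactly", {
  # positive-control wells need nonzero variance for SSMD, so bypass QC
  cfg <- zero_noise_config()
  effects <- simulate_gene_effects(25, prop_active = 0.4, seed = 10)
  sim <- simulate_screen(cfg, effects)
  wells <- normalize_wells(filter_wells(sim$wells, min_cells = 0))
  scores <- aggregate_replicates(wells)
  merged <- dplyr::inner_join(scores, effects, by = "gene_id")
  expect_equal(merged$mcherry_log2fc_mean, merged$mcherry_log2_effect)
  expect_equal(merged$yfp_log2fc_mean, merged$yfp_log2_effect)
  expect_true(all(merged$mcherry_log2fc_sd == 0))
})

test_that("a common plate factor cancels in the fold-changes", {
  cfg <- screen_sim_config(seed = 12)
  sim <- simulate_screen(cfg, simulate_gene_effects(400, seed = 12))
  wells <- filter_wells(sim$wells, min_cells = 0)
  scaled <- wells
  on_plate <- scaled$plate_id == "P001"
  scaled$mcherry_mean[on_plate] <- scaled$mcherry_mean[on_plate] * 7
  scaled$yfp_mean[on_plate] <- scaled$yfp_mean[on_plate] * 7
  expect_equal(normalize_wells(scaled)$mcherry_fc,
               normalize_wells(wells)$mcherry_fc)
})

test_that("layout fills plates and respects per-plate control counts", {
  cfg <- screen_sim_config(seed = 2)
  sim <- simulate_screen(cfg, simulate_gene_effects(700, seed = 2))
  per_plate <- dplyr::count(dplyr::filter(sim$wells, replicate == 1),
                            plate_id, role)
  controls <- dplyr::filter(per_plate, role != "sample")
  expect_true(all(controls$n == 14))
  n_sample_first <- per_plate$n[per_plate$plate_id == "P001" &
                                  per_plate$role == "sample"]
  expect_equal(n_sample_first, 384 - 3 * 14)
})

test_that("capped plate capacity raises a capacity error", {
  cfg <- screen_sim_config(seed = 2)
  expect_error(simulate_screen(cfg, simulate_gene_effects(700, seed = 2),
                               max_plates = 2),
               class = "appscreen_capacity_error")
})

test_that("screen tables round-trip through the delimited interface", {
  dir <- withr::local_tempdir()
  sim <- simulate_screen(screen_sim_config(seed = 3),
                         simulate_gene_effects(30, seed = 3))
  paths <- write_screen_tables(sim, dir)
  wells <- readr::read_csv(paths[["well_records"]], show_col_types = FALSE)
  expect_equal(nrow(wells), nrow(sim$wells))
  pm <- readr::read_csv(paths[["plate_map"]], show_col_types = FALSE)
  expect_named(pm, c("plate_id", "well", "sirna_id", "role"))
})
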