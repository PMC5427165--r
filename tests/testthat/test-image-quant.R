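test_that("a blank image yields zero nuclei without error", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  expect_equal(max(segment_nuclei(matrix(7, 64, 64))), 0)
})

test_that("noiseless nuclei are found exactly, with sub-pixel centroids", {
  p <- noiseless_params(image_size = 512)
  gt <- sample_well_layout(50, p, seed = 7)
  stack <- render_well(p, gt, seed = 7)
  labs <- segment_nuclei(stack$hoechst)
  expect_equal(max(labs), 50)
  rows <- row(labs)[labs > 0]
  cols <- col(labs)[labs > 0]
  cent_r <- tapply(rows, labs[labs > 0], mean)
  cent_c <- tapply(cols, labs[labs > 0], mean)
  for (i in seq_len(50)) {
    d <- sqrt((gt$center_row - cent_r[i])^2 + (gt$center_col - cent_c[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("two tangent nuclei are split into two labels by the watershed", {
  cells <- tibble::tibble(
    cell_id = 1:2, center_row = c(64, 64), center_col = c(52, 64),
    nucleus_radius = 6, cytoplasm_radius = 14,
    true_hoechst_mean = 300, true_yfp_mean = 200, true_mcherry_mean = 400
  )
  p <- noiseless_params(image_size = 128, overlap_allowed = TRUE)
  stack <- render_well(p, cells)
  expect_equal(max(segment_nuclei(stack$hoechst)), 2)
})

test_that("an isolated cell grows a full ring of the configured width", {
  cells <- tibble::tibble(
    cell_id = 1L, center_row = 64, center_col = 64,
    nucleus_radius = 6, cytoplasm_radius = 20,
    true_hoechst_mean = 300, true_yfp_mean = 200, true_mcherry_mean = 400
  )
  p <- noiseless_params(image_size = 128)
  stack <- render_well(p, cells)
  nuc <- segment_nuclei(stack$hoechst)
  seg <- segment_cells(nuc, stack$hoechst, ring_width = 6)
  # cytoplasm = cell minus nucleus, disjoint from the nucleus
  expect_true(all(seg$cytoplasm_labels[seg$nucleus_labels > 0] == 0))
  expect_identical(seg$cytoplasm_labels > 0,
                   seg$cell_labels > 0 & seg$nucleus_labels == 0)
  # ring extends ~ring_width beyond the nucleus in the cardinal directions
  nuc_width <- sum(nuc[64, ] > 0)
  cell_width <- sum(seg$cell_labels[64, ] > 0)
  expect_gte(cell_width, nuc_width + 2 * 5)
  expect_lte(cell_width, nuc_width + 2 * 8)
})

test_that("adjacent cells split territory equidistantly between seeds", {
  cells <- tibble::tibble(
    cell_id = 1:2, center_row = c(64, 64), center_col = c(56, 72),
    nucleus_radius = 6, cytoplasm_radius = 8,
    true_hoechst_mean = 300, true_yfp_mean = 200, true_mcherry_mean = 400
  )
  p <- noiseless_params(image_size = 128, overlap_allowed = TRUE)
  stack <- render_well(p, cells)
  nuc <- segment_nuclei(stack$hoechst)
  seg <- segment_cells(nuc, stack$hoechst, ring_width = 6)
  lab_left <- seg$cell_labels[64, 56]
  lab_right <- seg$cell_labels[64, 72]
  expect_true(lab_left != lab_right)
  # every contested pixel belongs to the nearer seed (within 1.5 px slack)
  idx <- which(seg$cell_labels > 0, arr.ind = TRUE)
  d1 <- sqrt((idx[, 1] - 64)^2 + (idx[, 2] - 56)^2)
  d2 <- sqrt((idx[, 1] - 64)^2 + (idx[, 2] - 72)^2)
  assigned <- seg$cell_labels[idx]
  nearer <- ifelse(d1 < d2, lab_left, lab_right)
  mismatch <- assigned != nearer & abs(d1 - d2) > 1.5
  expect_false(any(mismatch))
})

test_that("zero ring width warns and yields empty cytoplasm", {
  p <- noiseless_params(image_size = 128)
  gt <- sample_well_layout(2, p, seed = 9)
  stack <- render_well(p, gt, seed = 9)
  nuc <- segment_nuclei(stack$hoechst)
  expect_warning(seg <- segment_cells(nuc, stack$hoechst, ring_width = 0),
                 regexp = "empty cytoplasm")
  expect_true(all(seg$cytoplasm_labels == 0))
})

test_that("noiseless quantification equals ground truth exactly", {
  p <- noiseless_params(image_size = 512)
  gt <- sample_well_layout(40, p, seed = 13)
  stack <- render_well(p, gt, seed = 13)
  q <- quantify_well(stack)
  expect_equal(q$well$cell_count, 40)
  truth <- match_cells_to_truth(q$cells, gt)
  expect_equal(q$cells$mcherry_mean, truth$true_mcherry_mean)
  expect_equal(q$cells$yfp_mean, truth$true_yfp_mean)
  expect_equal(q$well$mcherry_mean, mean(q$cells$mcherry_mean))
})

test_that("quantification is invariant to a uniform background shift", {
  p <- noiseless_params(image_size = 256)
  gt <- sample_well_layout(10, p, seed = 4)
  stack <- render_well(p, gt, seed = 4)
  shifted <- stack
  shifted$mcherry <- stack$mcherry + 37
  shifted$yfp <- stack$yfp + 37
  q0 <- quantify_well(stack)
  q1 <- quantify_well(shifted)
  expect_equal(q1$cells$mcherry_mean, q0$cells$mcherry_mean)
  expect_equal(q1$well$yfp_mean, q0$well$yfp_mean)
})

test_that("scaling a channel scales its reported means equivariantly", {
  p <- noiseless_params(image_size = 256,
                        background = c(hoechst = 0, yfp = 0, mcherry = 0))
  gt <- sample_well_layout(10, p, seed = 4)
  stack <- render_well(p, gt, seed = 4)
  scaled <- stack
  scaled$mcherry <- stack$mcherry * 3
  q0 <- quantify_well(stack)
  q1 <- quantify_well(scaled)
  expect_equal(q1$cells$mcherry_mean, 3 * q0$cells$mcherry_mean)
})

test_that("a well with no cells is flagged, not an error", {
  p <- noiseless_params(image_size = 64)
  stack <- render_well(p, sample_well_layout(0, p, seed = 1), seed = 1)
  q <- quantify_well(stack)
  expect_equal(q$well$cell_count, 0)
  expect_true(q$well$flagged)
  expect_true(is.na(q$well$mcherry_mean))
})

test_that("count and intensity recovery hold at default noise over wells", {
  n_wells <- 20
  count_err <- numeric(n_wells)
  mae_pct <- numeric(n_wells)
  for (w in seq_len(n_wells)) {
    p <- image_sim_params(image_size = 512)
    gt <- sample_well_layout(60, p, seed = 100 + w)
    stack <- render_well(p, gt, seed = 100 + w)
    q <- quantify_well(stack)
    count_err[w] <- abs(q$well$cell_count - nrow(gt)) / nrow(gt)
    truth <- match_cells_to_truth(q$cells, gt)
    mae_pct[w] <- mean(abs(q$cells$mcherry_mean - truth$true_mcherry_mean) /
                         truth$true_mcherry_mean) * 100
  }
  expect_lte(mean(count_err), 0.05)
  expect_lte(mean(mae_pct), 2)
})

test_that("a full-scale noiseless well reports its exact calibrated count", {
  p <- noiseless_params(image_size = 1536)
  gt <- sample_well_layout(795, p, seed = 17)
  stack <- render_well(p, gt, seed = 17)
  q <- quantify_well(stack)
  expect_equal(q$well$cell_count, 795)
})
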