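#' Parameters for synthetic well-image simulation
#'
#' Bundles the geometry, intensity and noise settings used by
#' [sample_well_layout()] and [render_well()]. A simulated well is a single
#' square field containing non-overlapping cells, each drawn as a circular
#' nucleus (visible in the Hoechst channel) surrounded by a concentric annular
#' cytoplasm carrying the mCherry and YFP reporter signal.
#'
#' @param image_size Side length of the square field, in pixels.
#' @param nucleus_radius Nucleus radius, pixels.
#' @param cytoplasm_radius Outer cytoplasm radius, pixels; must exceed
#'   `nucleus_radius`.
#' @param hoechst_mean,mcherry_mean,yfp_mean Mean per-cell fluorescence of each
#'   channel, arbitrary units. Per-cell values are drawn log-normally around
#'   these with coefficient of variation `intensity_cv`, so well-level
#'   averaging is non-trivial.
#' @param intensity_cv Per-cell intensity heterogeneity (CV of the log-normal
#'   draw), dimensionless.
#' @param background Named numeric vector of per-channel additive background
#'   (`hoechst`, `yfp`, `mcherry`), fluorescence units.
#' @param noise_sd Named numeric vector of per-channel additive Gaussian pixel
#'   noise SD (truncated at zero after addition), fluorescence units.
#' @param overlap_allowed If `FALSE` (default) cell footprints (discs of
#'   radius `cytoplasm_radius`) may not overlap.
#' @param max_attempts Rejection-sampling attempt budget per cell when placing
#'   non-overlapping cells.
#'
#' @return An object of class `image_sim_params` (a validated list).
#' @examples
#' p <- image_sim_params(image_size = 256)
#' p$cytoplasm_radius
#' @export
image_sim_params <- function(image_size = 1536,
                             nucleus_radius = 6,
                             cytoplasm_radius = 14,
                             hoechst_mean = 300,
                             mcherry_mean = 400,
                             yfp_mean = 200,
                             intensity_cv = 0.3,
                             background = c(hoechst = 50, yfp = 50, mcherry = 50),
                             noise_sd = c(hoechst = 10, yfp = 10, mcherry = 10),
                             overlap_allowed = FALSE,
                             max_attempts = 200000L) {
  assert_scalar_number(image_size, "image_size", lower = 16)
  assert_scalar_number(nucleus_radius, "nucleus_radius", lower = 1)
  assert_scalar_number(cytoplasm_radius, "cytoplasm_radius",
                       lower = nucleus_radius + 1)
  assert_scalar_number(intensity_cv, "intensity_cv", lower = 0)
  channels <- c("hoechst", "yfp", "mcherry")
  background <- background[channels]
  noise_sd <- noise_sd[channels]
  if (anyNA(background) || any(background < 0)) {
    abort("`background` must name hoechst, yfp and mcherry with values >= 0",
          class = "appscreen_param_error")
  }
  if (anyNA(noise_sd) || any(noise_sd < 0)) {
    abort("`noise_sd` must name hoechst, yfp and mcherry with values >= 0",
          class = "appscreen_param_error")
  }
  structure(
    list(image_size = as.integer(image_size),
         nucleus_radius = nucleus_radius,
         cytoplasm_radius = cytoplasm_radius,
         hoechst_mean = hoechst_mean,
         mcherry_mean = mcherry_mean,
         yfp_mean = yfp_mean,
         intensity_cv = intensity_cv,
         background = background,
         noise_sd = noise_sd,
         overlap_allowed = isTRUE(overlap_allowed),
         max_attempts = as.integer(max_attempts)),
    class = "image_sim_params"
  )
}

#' Sample a ground-truth cell layout for one well
#'
#' Places `n_cells` cells uniformly at random inside the field, rejecting
#' placements whose footprints would overlap an existing cell (unless
#' `params$overlap_allowed`) or extend beyond the image bounds. Per-cell true
#' channel means are drawn log-normally around the configured channel means.
#'
#' @param n_cells Number of cells to place (`>= 0`). Use
#'   [sample_cell_counts()] to draw realistic per-well counts.
#' @param params An [image_sim_params()] object.
#' @param seed Optional integer seed; identical seed and parameters give an
#'   identical layout.
#'
#' @return A tibble of ground truth with one row per cell: `cell_id`,
#'   `center_row`, `center_col`, `nucleus_radius`, `cytoplasm_radius`,
#'   `true_hoechst_mean`, `true_yfp_mean`, `true_mcherry_mean`.
#' @examples
#' gt <- sample_well_layout(5, image_sim_params(image_size = 256), seed = 1)
#' nrow(gt)
#' @export
sample_well_layout <- function(n_cells, params = image_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "image_sim_params"))
  assert_scalar_number(n_cells, "n_cells", lower = 0)
  n_cells <- as.integer(n_cells)
  with_seed_maybe(seed, {
    r <- params$cytoplasm_radius
    lo <- r + 1
    hi <- params$image_size - r
    if (hi < lo && n_cells > 0) {
      abort("image too small to contain a single cell footprint",
            class = "appscreen_placement_error")
    }
    rows <- numeric(n_cells)
    cols <- numeric(n_cells)
    placed <- 0L
    attempts <- 0L
    while (placed < n_cells) {
      if (attempts >= params$max_attempts) {
        abort(sprintf(
          "could not place %d non-overlapping cells within %d attempts (placed %d)",
          n_cells, params$max_attempts, placed),
          class = "appscreen_placement_error")
      }
      attempts <- attempts + 1L
      cand_r <- runif(1, lo, hi)
      cand_c <- runif(1, lo, hi)
      if (!params$overlap_allowed && placed > 0L) {
        d2 <- (rows[seq_len(placed)] - cand_r)^2 + (cols[seq_len(placed)] - cand_c)^2
        if (any(d2 < (2 * r)^2)) next
      }
      placed <- placed + 1L
      rows[placed] <- cand_r
      cols[placed] <- cand_c
    }
    tibble(
      cell_id = seq_len(n_cells),
      center_row = round(rows),
      center_col = round(cols),
      nucleus_radius = rep(params$nucleus_radius, n_cells),
      cytoplasm_radius = rep(params$cytoplasm_radius, n_cells),
      true_hoechst_mean = params$hoechst_mean * rlnorm_cv1(n_cells, params$intensity_cv),
      true_yfp_mean = params$yfp_mean * rlnorm_cv1(n_cells, params$intensity_cv),
      true_mcherry_mean = params$mcherry_mean * rlnorm_cv1(n_cells, params$intensity_cv)
    )
  })
}

#' Render a synthetic three-channel well image
#'
#' Draws each ground-truth cell into a three-channel field: a filled nuclear
#' disc in the Hoechst channel and a uniform annular cytoplasm (between
#' `nucleus_radius` and `cytoplasm_radius`) in the YFP and mCherry channels at
#' the cell's true mean, then adds per-channel background and additive
#' Gaussian noise floored at zero.
#'
#' @param params An [image_sim_params()] object.
#' @param cells Ground-truth tibble as produced by [sample_well_layout()].
#' @param well_id Identifier stored on the stack.
#' @param seed Optional integer seed controlling the pixel noise.
#'
#' @return A `well_image_stack`: list with numeric matrices `hoechst`, `yfp`,
#'   `mcherry`, the `well_id`, and the `ground_truth` tibble.
#' @examples
#' p <- image_sim_params(image_size = 128, noise_sd = c(hoechst = 0, yfp = 0, mcherry = 0))
#' gt <- sample_well_layout(3, p, seed = 2)
#' stack <- render_well(p, gt, seed = 2)
#' dim(stack$mcherry)
#' @export
render_well <- function(params, cells, well_id = "well", seed = NULL) {
  stopifnot(inherits(params, "image_sim_params"))
  cells <- as_tibble(cells)
  n <- params$image_size
  if (nrow(cells) > 0) {
    r <- cells$cytoplasm_radius
    out_of_bounds <- cells$center_row - r < 1 | cells$center_row + r > n |
      cells$center_col - r < 1 | cells$center_col + r > n
    if (any(out_of_bounds)) {
      abort(sprintf("cell(s) %s fall outside image bounds",
                    paste(cells$cell_id[out_of_bounds], collapse = ", ")),
            class = "appscreen_placement_error")
    }
  }

  channels <- c("hoechst", "yfp", "mcherry")
  imgs <- lapply(channels, function(ch) matrix(0, n, n))
  names(imgs) <- channels

  for (i in seq_len(nrow(cells))) {
    cr <- cells$center_row[i]
    cc <- cells$center_col[i]
    rn <- cells$nucleus_radius[i]
    rc <- cells$cytoplasm_radius[i]
    box <- disc_box(cr, cc, rc, n)
    nuc <- box$d2 <= rn^2
    cyto <- box$d2 <= rc^2 & !nuc
    imgs$hoechst[box$rows, box$cols][nuc] <-
      imgs$hoechst[box$rows, box$cols][nuc] + cells$true_hoechst_mean[i]
    imgs$yfp[box$rows, box$cols][cyto] <-
      imgs$yfp[box$rows, box$cols][cyto] + cells$true_yfp_mean[i]
    imgs$mcherry[box$rows, box$cols][cyto] <-
      imgs$mcherry[box$rows, box$cols][cyto] + cells$true_mcherry_mean[i]
  }

  with_seed_maybe(seed, {
    for (ch in channels) {
      img <- imgs[[ch]] + params$background[[ch]]
      if (params$noise_sd[[ch]] > 0) {
        img <- img + matrix(rnorm(n * n, 0, params$noise_sd[[ch]]), n, n)
      }
      imgs[[ch]] <- pmax(img, 0)
    }
  })

  structure(
    list(hoechst = imgs$hoechst, yfp = imgs$yfp, mcherry = imgs$mcherry,
         well_id = well_id, ground_truth = cells),
    class = "well_image_stack"
  )
}

# Bounding-box pixel grid and squared distances to a disc centre.
disc_box <- function(center_row, center_col, radius, n) {
  rows <- max(1, floor(center_row - radius)):min(n, ceiling(center_row + radius))
  cols <- max(1, floor(center_col - radius)):min(n, ceiling(center_col + radius))
  d2 <- outer((rows - center_row)^2, (cols - center_col)^2, `+`)
  list(rows = rows, cols = cols, d2 = d2)
}

#' Ground-truth pixel masks for a rendered well
#'
#' Reconstructs exact nucleus and cytoplasm masks from a ground-truth table,
#' mainly for validating segmentation and quantification against the
#' generative model.
#'
#' @param cells Ground-truth tibble ([sample_well_layout()]).
#' @param image_size Field side length in pixels.
#' @return List of integer label matrices `nucleus` and `cytoplasm`
#'   (label = `cell_id`, 0 = background).
#' @export
ground_truth_masks <- function(cells, image_size) {
  nuc <- matrix(0L, image_size, image_size)
  cyto <- matrix(0L, image_size, image_size)
  for (i in seq_len(nrow(cells))) {
    box <- disc_box(cells$center_row[i], cells$center_col[i],
                    cells$cytoplasm_radius[i], image_size)
    in_nuc <- box$d2 <= cells$nucleus_radius[i]^2
    in_cyto <- box$d2 <= cells$cytoplasm_radius[i]^2 & !in_nuc
    nuc[box$rows, box$cols][in_nuc] <- cells$cell_id[i]
    cyto[box$rows, box$cols][in_cyto] <- cells$cell_id[i]
  }
  list(nucleus = nuc, cytoplasm = cyto)
}

#' Write a well image stack as TIFF files plus sidecar tables
#'
#' Writes one single-channel 32-bit float TIFF per channel
#' (`<well_id>_<channel>.tif`), a sidecar metadata table mapping files to
#' channel roles, and the ground truth as a TSV.
#'
#' @param stack A `well_image_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble of the files written (`well_id`, `channel`,
#'   `file`).
#' @export
write_well_images <- function(stack, dir) {
  stopifnot(inherits(stack, "well_image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- c("hoechst", "yfp", "mcherry")
  files <- file.path(dir, paste0(stack$well_id, "_", channels, ".tif"))
  # tiff stores float samples as-is; intensities keep their arbitrary units
  for (i in seq_along(channels)) {
    tiff::writeTIFF(stack[[channels[i]]] / 65535, files[i],
                    bits.per.sample = 32L)
  }
  meta <- tibble(well_id = stack$well_id, channel = channels,
                 file = basename(files))
  readr::write_tsv(meta, file.path(dir, paste0(stack$well_id, "_channels.tsv")))
  readr::write_tsv(stack$ground_truth,
                   file.path(dir, paste0(stack$well_id, "_truth.tsv")))
  invisible(meta)
}

#' Read a well image stack written by [write_well_images()]
#'
#' @param dir Directory containing the TIFFs and sidecar metadata.
#' @param well_id Well identifier used when writing.
#' @return A `well_image_stack` (with `ground_truth` attached when the truth
#'   sidecar is present).
#' @export
read_well_images <- function(dir, well_id) {
  meta <- readr::read_tsv(file.path(dir, paste0(well_id, "_channels.tsv")),
                          show_col_types = FALSE)
  imgs <- lapply(seq_len(nrow(meta)), function(i) {
    tiff::readTIFF(file.path(dir, meta$file[i])) * 65535
  })
  names(imgs) <- meta$channel
  truth_file <- file.path(dir, paste0(well_id, "_truth.tsv"))
  truth <- if (file.exists(truth_file)) {
    readr::read_tsv(truth_file, show_col_types = FALSE)
  } else {
    NULL
  }
  structure(
    list(hoechst = imgs$hoechst, yfp = imgs$yfp, mcherry = imgs$mcherry,
         well_id = well_id, ground_truth = truth),
    class = "well_image_stack"
  )
}
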