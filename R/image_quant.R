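#' Segment nuclei from a Hoechst image
#'
#' Gaussian-smooths the Hoechst channel, thresholds it with Otsu's method,
#' splits touching nuclei by a distance-transform watershed, then refines
#' each nucleus boundary at half of its own smoothed peak intensity (above
#' background). The refinement makes the segmented nuclear edge invariant to
#' per-cell staining brightness: a global threshold alone makes bright nuclei
#' too large and dim ones too small after smoothing. Objects below a minimum
#' area are removed.
#'
#' @param hoechst Numeric matrix of Hoechst intensities.
#' @param sigma Gaussian smoothing SD in pixels before thresholding.
#' @param min_area Minimum object area in pixels; smaller objects are dropped.
#'
#' @return Integer label matrix (0 = background). An all-background image
#'   yields an all-zero label matrix, not an error.
#' @examples
#' p <- image_sim_params(image_size = 128,
#'                       noise_sd = c(hoechst = 0, yfp = 0, mcherry = 0))
#' gt <- sample_well_layout(3, p, seed = 1)
#' labs <- segment_nuclei(render_well(p, gt, seed = 1)$hoechst)
#' max(labs)
#' @export
segment_nuclei <- function(hoechst, sigma = 2, min_area = 30) {
  stopifnot(is.matrix(hoechst), length(hoechst) > 0)
  assert_scalar_number(sigma, "sigma", lower = 0)
  rng <- range(hoechst)
  if (rng[2] <= rng[1]) {
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  # EBImage expects intensities in [0, 1]
  img <- EBImage::Image((hoechst - rng[1]) / (rng[2] - rng[1]))
  if (sigma > 0) {
    img <- EBImage::gblur(img, sigma = sigma)
  }
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- img > thr
  if (sum(mask) == 0) {
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  dm <- EBImage::distmap(mask)
  labs <- EBImage::watershed(dm, tolerance = 1)

  # Half-peak refinement: give every nucleus some room to grow or shrink
  # (nearest-seed territories a few px beyond the Otsu mask), then keep the
  # pixels above the midpoint between local background and that nucleus's
  # smoothed peak.
  territory <- EBImage::propagate(img, seeds = labs,
                                  mask = EBImage::dilate(mask, EBImage::makeBrush(7, "disc")) > 0,
                                  lambda = 1e6)
  terr <- EBImage::imageData(territory)
  smoothed <- EBImage::imageData(img)
  bg_level <- median(smoothed[terr == 0])
  lab_vals <- EBImage::imageData(labs)
  peaks <- tapply(smoothed[lab_vals > 0], lab_vals[lab_vals > 0], max)
  level <- rep(Inf, max(terr))
  level[as.integer(names(peaks))] <- (peaks + bg_level) / 2
  refined <- terr > 0
  refined[refined] <- smoothed[refined] >= level[terr[refined]]
  labs <- terr
  labs[!refined] <- 0L

  # drop sub-threshold fragments and relabel compactly
  counts <- tabulate(labs[labs > 0])
  keep <- which(counts >= min_area)
  relabel <- integer(length(counts))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labs), ncol(labs))
  nz <- labs > 0
  out[nz] <- relabel[labs[nz]]
  out
}

#' Grow cell and cytoplasm regions from nucleus seeds
#'
#' Each cell is grown from its nucleus by a bounded dilation of `ring_width`
#' pixels; where neighbouring cells meet, territory is assigned to the nearest
#' seed (Voronoi-style propagation). The nuclear mask is padded by one pixel
#' before subtraction so that perinuclear boundary pixels are not counted as
#' cytoplasm; the cytoplasm of each cell is its cell region minus this
#' (returned) nuclear region.
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param hoechst The Hoechst matrix (used only as the propagation substrate).
#' @param ring_width Cytoplasm ring width in pixels (default 6). A width of 0
#'   produces empty cytoplasm masks with a warning.
#'
#' @return List with integer label matrices `nucleus_labels` (the padded
#'   nuclei actually subtracted), `cell_labels` and `cytoplasm_labels`.
#' @export
segment_cells <- function(nucleus_labels, hoechst, ring_width = 6) {
  stopifnot(is.matrix(nucleus_labels))
  assert_scalar_number(ring_width, "ring_width", lower = 0)
  nuc <- EBImage::Image(nucleus_labels)
  # 1-px guard: Otsu can under-estimate the nuclear edge slightly
  nuc_pad <- EBImage::dilate(nuc, EBImage::makeBrush(3, shape = "box"))
  if (ring_width == 0) {
    warn("ring_width = 0 produces empty cytoplasm masks")
    zero <- matrix(0L, nrow(nucleus_labels), ncol(nucleus_labels))
    return(list(nucleus_labels = as_label_matrix(nuc_pad),
                cell_labels = as_label_matrix(nuc_pad),
                cytoplasm_labels = zero))
  }
  brush_size <- 2 * floor(ring_width) + 1
  territory <- EBImage::dilate(nuc_pad, EBImage::makeBrush(brush_size, shape = "disc"))
  rng <- range(hoechst)
  sub <- if (rng[2] > rng[1]) (hoechst - rng[1]) / (rng[2] - rng[1]) else hoechst * 0
  # large lambda makes propagation distance effectively Euclidean -> nearest seed
  cells <- EBImage::propagate(EBImage::Image(sub), seeds = nuc_pad,
                              mask = territory > 0, lambda = 1e6)
  cell_m <- as_label_matrix(cells)
  nuc_m <- as_label_matrix(nuc_pad)
  cyto <- cell_m
  cyto[nuc_m > 0] <- 0L
  list(nucleus_labels = nuc_m, cell_labels = cell_m, cytoplasm_labels = cyto)
}

as_label_matrix <- function(img) {
  m <- EBImage::imageData(img)
  storage.mode(m) <- "integer"
  m
}

#' Quantify per-cell cytoplasmic intensities and the per-well summary
#'
#' Estimates each channel's background as the median intensity over pixels
#' outside every cell mask, subtracts it (flooring per-cell means at zero),
#' and reports per-cell cytoplasmic mean mCherry/YFP plus the well-level
#' record: analyzable cell count and unweighted mean over cells of the
#' per-cell means.
#'
#' @param stack A `well_image_stack` (channels `hoechst`, `yfp`, `mcherry`).
#' @param seg Segmentation as returned by [segment_cells()]; computed from the
#'   stack when `NULL`.
#' @param exclude_border Drop cells whose cell mask touches the image border
#'   (default `TRUE`); border cells are partially out of field and bias both
#'   the count and the mean.
#' @param ... Passed to [segment_nuclei()] / [segment_cells()] when `seg` is
#'   `NULL`.
#'
#' @return List with `well` (one-row tibble: `well_id`, `cell_count`,
#'   `mcherry_mean`, `yfp_mean`, `flagged` — `TRUE` when no cells were found
#'   and the means are undefined) and `cells` (tibble of `cell_id`,
#'   `mcherry_mean`, `yfp_mean`, `cytoplasm_area`, `center_row`, `center_col`).
#' @export
quantify_well <- function(stack, seg = NULL, exclude_border = TRUE, ...) {
  stopifnot(inherits(stack, "well_image_stack"))
  if (is.null(seg)) {
    dots <- list(...)
    nuc_args <- dots[names(dots) %in% c("sigma", "min_area")]
    cell_args <- dots[names(dots) %in% "ring_width"]
    nuc <- do.call(segment_nuclei, c(list(stack$hoechst), nuc_args))
    seg <- do.call(segment_cells, c(list(nuc, stack$hoechst), cell_args))
  }
  if (!identical(dim(seg$cell_labels), dim(stack$mcherry))) {
    abort("segmentation dimensions do not match the image stack",
          class = "appscreen_param_error")
  }
  cell_labs <- seg$cell_labels
  cyto_labs <- seg$cytoplasm_labels

  ids <- sort(unique(cell_labs[cell_labs > 0]))
  if (exclude_border && length(ids) > 0) {
    nr <- nrow(cell_labs); nc <- ncol(cell_labs)
    border <- unique(c(cell_labs[1, ], cell_labs[nr, ],
                       cell_labs[, 1], cell_labs[, nc]))
    ids <- setdiff(ids, border)
  }

  bg_mask <- cell_labs == 0
  bg <- c(mcherry = median(stack$mcherry[bg_mask]),
          yfp = median(stack$yfp[bg_mask]))

  if (length(ids) == 0) {
    well <- tibble(well_id = stack$well_id, cell_count = 0L,
                   mcherry_mean = NA_real_, yfp_mean = NA_real_, flagged = TRUE)
    return(list(well = well, cells = tibble(
      cell_id = integer(), mcherry_mean = numeric(), yfp_mean = numeric(),
      cytoplasm_area = integer(), center_row = numeric(), center_col = numeric())))
  }

  in_cyto <- cyto_labs > 0 & cyto_labs %in% ids
  lab_vec <- cyto_labs[in_cyto]
  f <- factor(lab_vec, levels = ids)
  area <- as.integer(table(f))
  mch <- as.numeric(tapply(stack$mcherry[in_cyto], f, mean, default = NA_real_))
  yfp <- as.numeric(tapply(stack$yfp[in_cyto], f, mean, default = NA_real_))

  rows_idx <- row(cell_labs)[cell_labs %in% ids]
  cols_idx <- col(cell_labs)[cell_labs %in% ids]
  fc <- factor(cell_labs[cell_labs %in% ids], levels = ids)
  cells <- tibble(
    cell_id = ids,
    mcherry_mean = pmax(mch - bg[["mcherry"]], 0),
    yfp_mean = pmax(yfp - bg[["yfp"]], 0),
    cytoplasm_area = area,
    center_row = as.numeric(tapply(rows_idx, fc, mean)),
    center_col = as.numeric(tapply(cols_idx, fc, mean))
  )
  # cells whose cytoplasm is empty (e.g. ring_width 0) carry no intensity
  cells <- filter(cells, .data$cytoplasm_area > 0)

  well <- tibble(
    well_id = stack$well_id,
    cell_count = length(ids),
    mcherry_mean = mean(cells$mcherry_mean),
    yfp_mean = mean(cells$yfp_mean),
    flagged = FALSE
  )
  list(well = well, cells = cells)
}

#' Quantify a set of rendered wells into a well-record table
#'
#' Convenience wrapper mapping [quantify_well()] over a list of stacks and
#' binding the per-well rows, attaching plate-map metadata when supplied.
#'
#' @param stacks List of `well_image_stack` objects.
#' @param plate_map Optional tibble (`well_id`, `sirna_id`, `role`, and
#'   optionally `plate_id`, `replicate`) joined onto the result.
#' @param ... Passed to [quantify_well()].
#' @return Tibble of per-well records.
#' @export
quantify_wells <- function(stacks, plate_map = NULL, ...) {
  wells <- purrr::map_dfr(stacks, function(s) quantify_well(s, ...)$well)
  if (!is.null(plate_map)) {
    wells <- left_join(wells, as_tibble(plate_map), by = "well_id")
  }
  wells
}
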