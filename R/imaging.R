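# Segmentation and per-cell morphometry. Nuclei detected on the nuclear
# channel seed a region growing over the cell-body channel; each segmented
# cell is summarized by elongation E = major/minor axis of the
# moment-matched ellipse and cell shape index CSI = 4*pi*area/perimeter^2.

#' Segmentation parameters
#'
#' @param min_cell_area,max_cell_area Area bounds in px^2; objects outside
#'   are removed.
#' @param border_exclusion Remove objects touching the image border.
#' @param smoothing_sigma Gaussian smoothing applied to the nuclear channel
#'   before thresholding, in pixels.
#' @param opening_size Diameter of the disc used to clean the nucleus mask.
#' @param min_seed_area Minimum nucleus area (px^2) for a valid seed.
#' @param min_contrast Minimum nuclear-channel dynamic range (on the unit
#'   intensity scale) required to attempt thresholding; images below it
#'   (blank or noise-only wells) return an empty mask with a warning.
#' @return A validated parameter list.
#' @export
segmentation_params <- function(min_cell_area = 25, max_cell_area = 5e4,
                                border_exclusion = TRUE, smoothing_sigma = 1,
                                opening_size = 3L, min_seed_area = 9,
                                min_contrast = 0.1) {
  if (!(min_cell_area > 0 && min_cell_area < max_cell_area)) {
    stopf("need 0 < min_cell_area < max_cell_area")
  }
  list(min_cell_area = min_cell_area, max_cell_area = max_cell_area,
       border_exclusion = border_exclusion, smoothing_sigma = smoothing_sigma,
       opening_size = as.integer(opening_size), min_seed_area = min_seed_area,
       min_contrast = min_contrast)
}

as_two_channel <- function(image) {
  if (is.list(image) && all(c("image") %in% names(image))) image <- image$image
  if (is.list(image) && length(image) == 2L) {
    if (!identical(dim(image[[1]]), dim(image[[2]]))) {
      stopf("channel shapes differ")
    }
    image <- array(c(image[[1]], image[[2]]),
                   dim = c(dim(image[[1]]), 2L))
  }
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 2L)) {
    stopf("expected a two-channel image (H x W x 2 array)")
  }
  image
}

#' Segment cells from a two-channel well image
#'
#' Nuclei are detected on channel 1 by Otsu thresholding, morphological
#' opening and connected-component labeling; each nucleus seeds a
#' watershed-style region growing ([EBImage::propagate()]) over channel 2
#' restricted to the Otsu foreground of the cell-body stain. Objects touching
#' the border (when `border_exclusion`) or outside the area bounds are
#' removed and the remaining labels renumbered 1..n.
#'
#' @param image `H x W x 2` array (channels nucleus, body), or the list
#'   returned by [render_well()], or a list of two equally sized matrices.
#' @param params A [segmentation_params()] list.
#' @return An integer label matrix (0 = background). If no nucleus is found
#'   an all-zero mask is returned with a warning.
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  image <- as_two_channel(image)
  nuc <- image[, , 1L]
  body <- image[, , 2L]
  if (max(nuc) == min(nuc) || max(body) == min(body)) {
    warnf("constant channel: no cells segmented")
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  nuc_s <- if (params$smoothing_sigma > 0) {
    as.matrix(EBImage::gblur(nuc, sigma = params$smoothing_sigma))
  } else nuc
  if (diff(range(nuc_s)) < params$min_contrast) {
    warnf("nuclear channel contrast below %.2g: no nuclei detected",
          params$min_contrast)
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  nuc_mask <- nuc_s > EBImage::otsu(EBImage::Image(nuc_s), range = c(0, 1))
  if (params$opening_size > 1L) {
    brush <- EBImage::makeBrush(params$opening_size, shape = "disc")
    nuc_mask <- EBImage::opening(nuc_mask, brush) > 0
  }
  seeds <- EBImage::bwlabel(nuc_mask)
  seed_area <- tabulate(seeds[seeds > 0])
  tiny <- which(seed_area < params$min_seed_area)
  if (length(tiny)) seeds[seeds %in% tiny] <- 0L
  if (max(seeds) == 0 || !any(seeds > 0)) {
    warnf("no nuclei detected; returning empty mask")
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  body_s <- if (params$smoothing_sigma > 0) {
    as.matrix(EBImage::gblur(body, sigma = params$smoothing_sigma))
  } else body
  body_mask <- body_s > EBImage::otsu(EBImage::Image(body_s), range = c(0, 1))
  body_mask <- body_mask | seeds > 0  # seeds always belong to the foreground
  labels <- EBImage::propagate(EBImage::Image(body_s), seeds,
                               mask = body_mask)
  labels <- matrix(as.integer(labels), nrow(nuc), ncol(nuc))

  if (params$border_exclusion) {
    edge <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
    edge <- edge[edge > 0]
    if (length(edge)) labels[labels %in% edge] <- 0L
  }
  areas <- tabulate(labels[labels > 0])
  bad <- which(areas < params$min_cell_area | areas > params$max_cell_area)
  if (length(bad)) labels[labels %in% bad] <- 0L
  keep <- sort(unique(labels[labels > 0]))
  if (!length(keep)) {
    warnf("no cells passed the size/border filters")
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  relab <- integer(max(keep))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  labels
}

#' Crofton perimeter estimator
#'
#' Cauchy-Crofton estimate from foreground/background transition counts
#' along four line directions (horizontal, vertical, both diagonals):
#' `P = pi/8 * (n_h + n_v + (n_d1 + n_d2)/sqrt(2))`. Exact in expectation
#' for smooth convex shapes (a digitized disk of radius r gives ~2*pi*r);
#' naive boundary-pixel counting overestimates and would push CSI of
#' digitized circles above 1.
#'
#' @param mask Logical or 0/1 matrix of one object.
#' @return Estimated perimeter in pixels.
#' @export
crofton_perimeter <- function(mask) {
  b <- (mask > 0) + 0
  n <- nrow(b); m <- ncol(b)
  pad_at <- function(di, dj) {
    p <- matrix(0, n + 1L, m + 1L)
    p[di + seq_len(n), dj + seq_len(m)] <- b
    p
  }
  n_h <- sum(cbind(b, 0) != cbind(0, b))
  n_v <- sum(rbind(b, 0) != rbind(0, b))
  # diagonal: b[i, j] vs b[i + 1, j + 1]; anti-diagonal: vs b[i + 1, j - 1]
  n_d1 <- sum(pad_at(0L, 0L) != pad_at(1L, 1L))
  n_d2 <- sum(pad_at(0L, 1L) != pad_at(1L, 0L))
  pi / 8 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Measure per-cell morphometrics from a labeled mask
#'
#' For each label: area = pixel count; perimeter via [crofton_perimeter()];
#' major/minor axis lengths from the ellipse with matching normalized second
#' central moments (4 * sqrt of the covariance eigenvalues); E = major/minor;
#' CSI = 4*pi*area/perimeter^2 clamped to <= 1. When the cell-body intensity
#' channel is supplied the moments are intensity-weighted over each label,
#' which recovers sub-pixel boundary information from partially covered edge
#' pixels and makes E nearly rotation-invariant; otherwise every mask pixel
#' weighs equally. Degenerate objects (under one pixel across) are flagged,
#' not dropped.
#'
#' @param mask Integer label matrix from [segment_cells()].
#' @param intensity Optional cell-body channel matrix matching `mask`.
#' @param well_id Well identifier recorded on every row.
#' @return A data.frame of cell records: `well_id`, `label`, `area`,
#'   `perimeter`, `major_axis`, `minor_axis`, `elongation_e`, `csi`,
#'   `degenerate`.
#' @export
measure_shape <- function(mask, intensity = NULL, well_id = "well") {
  if (!is.null(intensity) && !identical(dim(intensity)[1:2], dim(mask))) {
    stopf("intensity channel shape must match the mask")
  }
  pix <- which(mask > 0)
  if (!length(pix)) {
    return(data.frame(well_id = character(), label = integer(),
                      area = numeric(), perimeter = numeric(),
                      major_axis = numeric(), minor_axis = numeric(),
                      elongation_e = numeric(), csi = numeric(),
                      degenerate = logical()))
  }
  coords <- arrayInd(pix, dim(mask))
  labs <- mask[pix]
  out <- lapply(split(seq_along(labs), labs), function(ii) {
    x <- coords[ii, 1]; y <- coords[ii, 2]
    n <- length(ii)
    w <- if (is.null(intensity)) rep(1 / n, n) else {
      wi <- pmax(intensity[pix[ii]], 0)
      if (sum(wi) <= 0) rep(1 / n, n) else wi / sum(wi)
    }
    mx <- sum(w * x); my <- sum(w * y)
    # 1/12 terms: pixels are unit squares, not points; without them thin
    # axis-aligned objects read systematically too narrow
    mu20 <- sum(w * (x - mx)^2) + 1 / 12
    mu02 <- sum(w * (y - my)^2) + 1 / 12
    mu11 <- sum(w * (x - mx) * (y - my))
    ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2L), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
    sub <- matrix(FALSE, diff(range(x)) + 1L, diff(range(y)) + 1L)
    sub[cbind(x - min(x) + 1L, y - min(y) + 1L)] <- TRUE
    per <- crofton_perimeter(sub)
    # degeneracy judged on raw point moments: a one-pixel-wide object has
    # zero spread before the 1/12 pixel-extent term is added
    minor_pt <- 4 * sqrt(max(min(eigen(matrix(c(mu20 - 1 / 12, mu11, mu11,
                                                mu02 - 1 / 12), 2L),
                                       symmetric = TRUE,
                                       only.values = TRUE)$values), 0))
    degen <- minor_pt < 1 || n < 4L
    data.frame(area = n, perimeter = per, major_axis = major,
               minor_axis = minor,
               elongation_e = if (degen) NA_real_ else major / minor,
               csi = if (degen) NA_real_ else shape_index(n, per),
               degenerate = degen)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(well_id = well_id,
                          label = as.integer(names(out))), res)
  rownames(res) <- NULL
  res
}

#' Phenotype classification thresholds
#'
#' Defaults follow the published decision rules: contractile cells have
#' E > 3 and 0 < CSI < 0.4; synthetic cells have 1 < E < 3 and
#' 0.6 < CSI <= 1; cells with 0.4 < CSI < 0.6 are undecided. The CSI upper
#' bound is inclusive because measured CSI is clamped to 1.
#'
#' @param e_contractile_min,csi_contractile_max Contractile class bounds.
#' @param e_synthetic_min,e_synthetic_max,csi_synthetic_min Synthetic class
#'   bounds.
#' @param csi_undecided Two-element CSI interval of the undecided band.
#' @return A validated threshold list.
#' @export
class_thresholds <- function(e_contractile_min = 3, csi_contractile_max = 0.4,
                             e_synthetic_min = 1, e_synthetic_max = 3,
                             csi_synthetic_min = 0.6,
                             csi_undecided = c(0.4, 0.6)) {
  if (!(csi_contractile_max <= csi_undecided[1] &&
        csi_undecided[1] < csi_undecided[2] &&
        csi_undecided[2] <= csi_synthetic_min)) {
    stopf("CSI intervals must be ordered and non-overlapping")
  }
  if (!(e_synthetic_min < e_synthetic_max)) {
    stopf("synthetic E interval must be non-degenerate")
  }
  list(e_contractile_min = e_contractile_min,
       csi_contractile_max = csi_contractile_max,
       e_synthetic_min = e_synthetic_min, e_synthetic_max = e_synthetic_max,
       csi_synthetic_min = csi_synthetic_min, csi_undecided = csi_undecided)
}

#' Classify cells as contractile, synthetic, undecided or unclassified
#'
#' Strict inequalities throughout (boundary values fall through to
#' unclassified), and combinations the published classes do not cover --
#' e.g. high E together with high CSI -- are labeled unclassified rather
#' than forced into a class. Records with missing metrics (degenerate
#' objects) are unclassified with a warning. Exactly one label per record.
#'
#' @param records Cell-record data.frame with `elongation_e` and `csi`
#'   columns ([measure_shape()] or [truth_records()] output).
#' @param thresholds A [class_thresholds()] list.
#' @return `records` with a `phenotype` factor column added (levels
#'   contractile, synthetic, undecided, unclassified).
#' @export
classify_phenotype <- function(records, thresholds = class_thresholds()) {
  stopifnot(all(c("elongation_e", "csi") %in% names(records)))
  e <- records$elongation_e
  csi <- records$csi
  bad <- !is.finite(e) | !is.finite(csi)
  if (any(bad)) {
    warnf("%d record(s) with missing/non-finite metrics -> unclassified",
          sum(bad))
  }
  th <- thresholds
  phen <- rep("unclassified", length(e))
  con <- !bad & e > th$e_contractile_min & csi > 0 &
    csi < th$csi_contractile_max
  syn <- !bad & e > th$e_synthetic_min & e < th$e_synthetic_max &
    csi > th$csi_synthetic_min & csi <= 1
  und <- !bad & csi > th$csi_undecided[1] & csi < th$csi_undecided[2]
  phen[und] <- "undecided"
  phen[syn] <- "synthetic"
  phen[con] <- "contractile"
  records$phenotype <- factor(phen, levels = c("contractile", "synthetic",
                                               "undecided", "unclassified"))
  records
}
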