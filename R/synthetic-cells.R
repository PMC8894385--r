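# Synthetic well images: elliptical cells with known geometry, rendered into
# a two-channel (nucleus + cell body) image so the segmentation and
# morphometry stages can be validated against planted ground truth.

#' Construct a table of cell specifications
#'
#' @param center_x,center_y Cell centers in pixel coordinates.
#' @param semi_major,semi_minor Ellipse semi-axes in pixels
#'   (`semi_major >= semi_minor > 0`).
#' @param orientation Major-axis orientation in radians (default 0).
#' @param body_intensity Peak cell-body stain intensity on a 0-1 scale.
#' @param nucleus_scale Nucleus semi-axes as a fraction of the cell's.
#' @param phenotype_true Optional planted phenotype label carried through to
#'   the ground-truth table.
#' @return A data.frame, one row per cell.
#' @export
cell_specs <- function(center_x, center_y, semi_major, semi_minor,
                       orientation = 0, body_intensity = 0.8,
                       nucleus_scale = 0.45, phenotype_true = NA_character_) {
  d <- data.frame(center_x = center_x, center_y = center_y,
                  semi_major = semi_major, semi_minor = semi_minor,
                  orientation = orientation, body_intensity = body_intensity,
                  nucleus_scale = nucleus_scale,
                  phenotype_true = phenotype_true,
                  stringsAsFactors = FALSE)
  validate_cell_specs(d)
  d
}

validate_cell_specs <- function(specs) {
  needed <- c("center_x", "center_y", "semi_major", "semi_minor")
  if (!all(needed %in% names(specs))) {
    stopf("cell specs must have columns %s", paste(needed, collapse = ", "))
  }
  if (any(specs$semi_minor <= 0) || any(specs$semi_major < specs$semi_minor)) {
    stopf("cell specs require semi_major >= semi_minor > 0")
  }
  invisible(specs)
}

# Disjointness of bounding circles; stricter than true ellipse disjointness,
# which keeps the check cheap and the guarantee conservative.
specs_overlap <- function(specs) {
  n <- nrow(specs)
  if (n < 2L) return(FALSE)
  r <- specs$semi_major
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d2 <- (specs$center_x[i] - specs$center_x[j])^2 +
      (specs$center_y[i] - specs$center_y[j])^2
    if (any(d2 < (r[i] + r[j])^2)) return(TRUE)
  }
  FALSE
}

# Pixel-center membership rendering (used for exact digitized masks).
draw_ellipse <- function(img, cx, cy, a, b, theta, value) {
  n1 <- nrow(img); n2 <- ncol(img)
  x0 <- max(1L, floor(cx - a)); x1 <- min(n1, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(n2, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  ct <- cos(theta); st <- sin(theta)
  dx <- xs - cx; dy <- ys - cy
  u <- outer(dx * ct, dy * st, `+`)
  v <- outer(-dx * st, dy * ct, `+`)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[xs, ys, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  img[xs, ys] <- sub
  img
}

# Anti-aliased rendering: per-pixel coverage fraction from an ss x ss
# subpixel grid, so boundary pixels carry partial intensity. Binary
# rendering would bake grid-aligned aliasing into every downstream
# measurement.
draw_ellipse_aa <- function(img, cx, cy, a, b, theta, value, ss = 4L) {
  n1 <- nrow(img); n2 <- ncol(img)
  x0 <- max(1L, floor(cx - a)); x1 <- min(n1, ceiling(cx + a))
  y0 <- max(1L, floor(cy - a)); y1 <- min(n2, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  ct <- cos(theta); st <- sin(theta)
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  cover <- matrix(0, length(xs), length(ys))
  for (ox in offs) {
    for (oy in offs) {
      dx <- xs + ox - cx; dy <- ys + oy - cy
      u <- outer(dx * ct, dy * st, `+`)
      v <- outer(-dx * st, dy * ct, `+`)
      cover <- cover + ((u / a)^2 + (v / b)^2 <= 1)
    }
  }
  img[xs, ys] <- pmax(img[xs, ys, drop = FALSE], cover / ss^2 * value)
  img
}

#' Render one well as a two-channel image with ground truth
#'
#' Channel 1 carries the nuclear stain (inner ellipse scaled by
#' `nucleus_scale`), channel 2 the whole-cell body stain, emulating a
#' Hoechst + lipophilic membrane dye pair. Both channels receive a Gaussian
#' blur and additive Gaussian read noise, then are clamped to the unit
#' intensity range.
#'
#' @param specs Cell specification table (see [cell_specs()]); cells must be
#'   mutually non-overlapping and fully inside the image.
#' @param image_size Side length of the square image in pixels.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables blur).
#' @param seed Integer seed for the noise; the caller's RNG state is restored.
#' @return A list with `image` (array `image_size x image_size x 2`, channels
#'   named nucleus/body) and `truth` (data.frame with each cell's true
#'   semi-axes, elongation `e_true`, shape index `csi_true` and, when
#'   supplied, `phenotype_true`).
#' @export
render_well <- function(specs, image_size = 512L, noise_sd = 0.02,
                        blur_sigma = 1, seed = NULL) {
  validate_cell_specs(specs)
  if (nrow(specs) == 0L) stopf("no cells to render")
  lo <- specs$center_x - specs$semi_major
  hi <- specs$center_x + specs$semi_major
  lo2 <- specs$center_y - specs$semi_major
  hi2 <- specs$center_y + specs$semi_major
  if (any(lo < 1 | lo2 < 1 | hi > image_size | hi2 > image_size)) {
    stopf("cell ellipse out of image bounds (image_size = %d)", image_size)
  }
  if (specs_overlap(specs)) {
    stopf("cell specs overlap; wells must contain non-overlapping cells")
  }
  body_int <- specs$body_intensity %||% 0.8
  if (is.null(specs$body_intensity)) specs$body_intensity <- body_int
  if (is.null(specs$nucleus_scale)) specs$nucleus_scale <- 0.45
  nuc <- body <- matrix(0, image_size, image_size)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    body <- draw_ellipse_aa(body, s$center_x, s$center_y, s$semi_major,
                            s$semi_minor, s$orientation, s$body_intensity)
    nuc <- draw_ellipse_aa(nuc, s$center_x, s$center_y,
                           s$semi_major * s$nucleus_scale,
                           s$semi_minor * s$nucleus_scale, s$orientation, 1)
  }
  img <- with_seed(seed, {
    if (blur_sigma > 0) {
      nuc <- as.matrix(EBImage::gblur(nuc, sigma = blur_sigma))
      body <- as.matrix(EBImage::gblur(body, sigma = blur_sigma))
    }
    if (noise_sd > 0) {
      nuc <- nuc + stats::rnorm(length(nuc), 0, noise_sd)
      body <- body + stats::rnorm(length(body), 0, noise_sd)
    }
    arr <- array(0, dim = c(image_size, image_size, 2L),
                 dimnames = list(NULL, NULL, c("nucleus", "body")))
    arr[, , 1L] <- pmin(pmax(nuc, 0), 1)
    arr[, , 2L] <- pmin(pmax(body, 0), 1)
    arr
  })
  truth <- cbind(
    data.frame(cell_id = seq_len(nrow(specs))),
    specs[, intersect(c("center_x", "center_y", "semi_major", "semi_minor",
                        "orientation", "phenotype_true"), names(specs))],
    ellipse_shape_truth(specs$semi_major, specs$semi_minor)
  )
  rownames(truth) <- NULL
  list(image = img, truth = truth)
}

#' Shape-sampling parameters for the two phenotypes
#'
#' Contractile cells are drawn as strongly elongated ellipses and synthetic
#' cells as near-round ones, with both families kept well away from the
#' published decision boundaries (E = 3, CSI = 0.4/0.6) so planted truth
#' labels are unambiguous. For an ideal ellipse CSI falls below 0.4 only for
#' aspect ratios above roughly 5.8, hence the contractile range starts at 7.
#'
#' @param contractile_e_range Axis-ratio range for contractile cells.
#' @param synthetic_e_range Axis-ratio range for synthetic cells.
#' @param semi_minor_range Minor semi-axis range in pixels.
#' @param body_intensity,nucleus_scale Rendering intensities (see
#'   [cell_specs()]).
#' @return A named list of parameters.
#' @export
phenotype_params <- function(contractile_e_range = c(7, 10),
                             synthetic_e_range = c(1.2, 2.0),
                             semi_minor_range = c(5, 8),
                             body_intensity = 0.8, nucleus_scale = 0.45) {
  stopifnot(contractile_e_range[1] < contractile_e_range[2],
            synthetic_e_range[1] < synthetic_e_range[2],
            semi_minor_range[1] < semi_minor_range[2],
            semi_minor_range[1] > 0)
  list(contractile_e_range = contractile_e_range,
       synthetic_e_range = synthetic_e_range,
       semi_minor_range = semi_minor_range,
       body_intensity = body_intensity, nucleus_scale = nucleus_scale)
}

sample_shapes <- function(n_contractile, n_synthetic, params) {
  n <- n_contractile + n_synthetic
  phen <- c(rep("contractile", n_contractile), rep("synthetic", n_synthetic))
  e <- c(stats::runif(n_contractile, params$contractile_e_range[1],
                      params$contractile_e_range[2]),
         stats::runif(n_synthetic, params$synthetic_e_range[1],
                      params$synthetic_e_range[2]))
  b <- stats::runif(n, params$semi_minor_range[1], params$semi_minor_range[2])
  ord <- sample.int(n)
  data.frame(phenotype_true = phen[ord], semi_major = (e * b)[ord],
             semi_minor = b[ord],
             orientation = stats::runif(n, 0, pi),
             stringsAsFactors = FALSE)
}

# Sequential rejection sampling of non-overlapping bounding circles. The
# padding keeps neighboring cells separated by more than the blur tails, so
# rendered bodies never fuse across the background gap.
place_cells <- function(radii, image_size, max_attempts = 10000L,
                        padding = 4) {
  radii <- radii + padding / 2
  n <- length(radii)
  ord <- order(radii, decreasing = TRUE)  # large cells first packs better
  cx <- cy <- numeric(n)
  for (k in seq_len(n)) {
    i <- ord[k]
    r <- radii[i]
    lo <- r + 1; hi <- image_size - r
    if (hi <= lo) stopf("image_size %d too small for cell radius %.1f",
                        image_size, r)
    placed <- FALSE
    prev <- ord[seq_len(k - 1L)]
    for (att in seq_len(max_attempts)) {
      x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
      if (k == 1L ||
          all((x - cx[prev])^2 + (y - cy[prev])^2 > (r + radii[prev])^2)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stopf("cell placement failed after %d attempts; reduce cell density",
            max_attempts)
    }
    cx[i] <- x; cy[i] <- y
  }
  data.frame(center_x = cx, center_y = cy)
}

#' Build a replicate plate design
#'
#' One negative-control well plus one well per condition in each replicate.
#'
#' @param conditions Character vector of condition (miRNA) labels.
#' @param fractions Contractile fraction per condition (recycled).
#' @param replicates Replicate identifiers (default screens A, B, C).
#' @param n_cells Cells seeded per well.
#' @param control_fraction Contractile fraction of the negative control.
#' @param control_label Label of the negative-control condition.
#' @return A design data.frame with columns `well_id`, `condition_label`,
#'   `replicate_id`, `is_negative_control`, `n_cells`,
#'   `contractile_fraction`.
#' @export
plate_design <- function(conditions, fractions,
                         replicates = c("A", "B", "C"), n_cells = 400L,
                         control_fraction = 0.2,
                         control_label = "neg_control") {
  stopifnot(length(conditions) >= 1L)
  fractions <- rep_len(fractions, length(conditions))
  rows <- lapply(replicates, function(r) {
    data.frame(
      well_id = paste0(r, "_", c(control_label, conditions)),
      condition_label = c(control_label, conditions),
      replicate_id = r,
      is_negative_control = c(TRUE, rep(FALSE, length(conditions))),
      n_cells = n_cells,
      contractile_fraction = c(control_fraction, fractions),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

validate_plate_design <- function(design) {
  needed <- c("well_id", "condition_label", "replicate_id",
              "is_negative_control", "n_cells", "contractile_fraction")
  if (!all(needed %in% names(design))) {
    stopf("plate design must have columns %s", paste(needed, collapse = ", "))
  }
  if (any(design$n_cells <= 0)) stopf("plate design requires n_cells > 0")
  if (any(design$contractile_fraction < 0 | design$contractile_fraction > 1)) {
    stopf("contractile_fraction must lie in [0, 1]")
  }
  ctrl <- tapply(design$is_negative_control, design$replicate_id, any)
  if (!all(ctrl)) {
    stopf("every replicate needs at least one negative-control well")
  }
  invisible(design)
}

#' Generate a plate of wells with planted phenotype labels
#'
#' Each well draws its per-cell phenotype labels Binomial(n_cells,
#' contractile_fraction) and samples cell shapes from [phenotype_params()].
#' With `render = TRUE` cells are additionally placed without overlap
#' (rejection sampling) and rendered via [render_well()]; with the default
#' `render = FALSE` only the ground-truth geometry is produced, which is what
#' large screen simulations consume.
#'
#' @param design Plate design (see [plate_design()]).
#' @param params Shape-sampling parameters from [phenotype_params()].
#' @param seed Root seed; each well uses a derived child seed.
#' @param render Render pixel images for each well.
#' @param image_size,noise_sd,blur_sigma Passed to [render_well()].
#' @param max_attempts Placement attempts per cell before giving up.
#' @return A list with `design` and `wells`, a named list holding per well
#'   `truth` (and `image` when rendered).
#' @export
generate_plate <- function(design, params = phenotype_params(), seed = 1L,
                           render = FALSE, image_size = 512L,
                           noise_sd = 0.02, blur_sigma = 1,
                           max_attempts = 10000L) {
  validate_plate_design(design)
  wells <- vector("list", nrow(design))
  names(wells) <- design$well_id
  for (i in seq_len(nrow(design))) {
    w <- design[i, ]
    wells[[i]] <- with_seed(child_seed(seed, i), {
      n_con <- stats::rbinom(1L, w$n_cells, w$contractile_fraction)
      shapes <- sample_shapes(n_con, w$n_cells - n_con, params)
      if (render) {
        pos <- place_cells(shapes$semi_major, image_size, max_attempts)
        specs <- cbind(pos, shapes,
                       body_intensity = params$body_intensity,
                       nucleus_scale = params$nucleus_scale)
        out <- render_well(specs, image_size = image_size,
                           noise_sd = noise_sd, blur_sigma = blur_sigma)
        out$truth$well_id <- w$well_id
        out
      } else {
        truth <- cbind(data.frame(cell_id = seq_len(nrow(shapes))), shapes,
                       ellipse_shape_truth(shapes$semi_major,
                                           shapes$semi_minor))
        truth$well_id <- w$well_id
        list(truth = truth)
      }
    })
  }
  list(design = design, wells = wells)
}

#' Combined ground-truth table of a generated plate
#'
#' @param plate Result of [generate_plate()].
#' @return One data.frame with a `well_id` column.
#' @export
plate_truth <- function(plate) {
  do.call(rbind, c(lapply(plate$wells, `[[`, "truth"),
                   list(make.row.names = FALSE)))
}

#' Convert generator ground truth to cell records
#'
#' Maps a truth table (true E/CSI per cell) onto the record layout produced
#' by [measure_shape()], so classification and screen aggregation can run
#' directly on planted geometry without rendering pixels.
#'
#' @param truth Ground-truth table from [generate_plate()]/[render_well()].
#' @return A cell-record data.frame with `elongation_e` and `csi` columns.
#' @export
truth_records <- function(truth) {
  data.frame(
    well_id = truth$well_id %||% "well",
    label = truth$cell_id,
    area = pi * truth$semi_major * truth$semi_minor,
    perimeter = ellipse_perimeter(truth$semi_major, truth$semi_minor),
    major_axis = 2 * truth$semi_major,
    minor_axis = 2 * truth$semi_minor,
    elongation_e = truth$e_true,
    csi = truth$csi_true,
    degenerate = FALSE,
    stringsAsFactors = FALSE
  )
}
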