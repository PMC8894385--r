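# Independent oracles used to validate package computations.

# Ellipse circumference by numerical quadrature (arc-length integral).
ellipse_perimeter_quadrature <- function(a, b) {
  f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
  stats::integrate(f, 0, 2 * pi, rel.tol = 1e-10)$value
}

# Ordinary pooled two-sample t statistic, coded directly.
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Benjamini-Hochberg step-up, coded directly from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Brute-force MCC: enumerate every vertex subset of a small graph, keep the
# maximal cliques, and sum (|C| - 1)! per member. adj is a named list.
mcc_bruteforce_oracle <- function(adj) {
  vs <- names(adj)
  n <- length(vs)
  stopifnot(n <= 12)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(FALSE)
    for (i in idx) {
      if (!all(vs[setdiff(idx, i)] %in% adj[[vs[i]]])) return(FALSE)
    }
    TRUE
  }
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (is_clique(idx)) cliques[[length(cliques) + 1]] <- idx
  }
  maximal <- Filter(function(cl) {
    !any(vapply(cliques, function(other) {
      length(other) > length(cl) && all(cl %in% other)
    }, logical(1)))
  }, cliques)
  mcc <- stats::setNames(numeric(n), vs)
  for (cl in maximal) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

# Random simple graph as an edge-list data.frame plus its adjacency list.
random_graph <- function(n, p_edge = 0.35) {
  vs <- paste0("v", seq_len(n))
  pairs <- utils::combn(vs, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                      stringsAsFactors = FALSE)
  adj <- stats::setNames(lapply(vs, function(v) {
    c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])
  }), vs)
  list(edges = edges, adj = adj, nodes = vs)
}

# Draw one ellipse directly into a binary mask (bypasses render_well).
ellipse_mask <- function(a, b, theta = 0, n = 2 * ceiling(a) + 16,
                         off_x = 0, off_y = 0) {
  img <- matrix(0, n, n)
  img <- vsmcscreen:::draw_ellipse(img, n / 2 + off_x, n / 2 + off_y,
                                   a, b, theta, 1)
  (img > 0) * 1L
}

# Render a single cell and measure it through the full segmentation path.
render_one_and_measure <- function(a, b, theta, off_x = 0, off_y = 0,
                                   seed = 1) {
  n <- 2 * ceiling(a) + 30
  sp <- cell_specs(n / 2 + off_x, n / 2 + off_y, a, b, orientation = theta)
  w <- render_well(sp, image_size = n, seed = seed)
  mask <- segment_cells(w$image)
  measure_shape(mask, w$image[, , 2])
}

# Render a well of sampled shapes, segment it, and pair each planted cell
# with the measured record under its centroid.
render_and_measure <- function(shapes, image_size, seed,
                               params = segmentation_params()) {
  pos <- vsmcscreen:::place_cells(shapes$semi_major, image_size)
  specs <- cbind(pos, shapes, body_intensity = 0.8, nucleus_scale = 0.45)
  well <- render_well(specs, image_size = image_size, seed = seed)
  mask <- segment_cells(well$image, params)
  rec <- measure_shape(mask, well$image[, , 2])
  idx <- mask[cbind(round(specs$center_x), round(specs$center_y))]
  matched <- idx > 0
  cbind(well$truth[matched, c("e_true", "csi_true")],
        rec[match(idx[matched], rec$label),
            c("elongation_e", "csi", "area", "perimeter")],
        row.names = NULL)
}
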