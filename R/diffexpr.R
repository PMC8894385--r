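# logCPM transform and two-group moderated-t differential expression with
# empirical-Bayes variance shrinkage and BH-FDR control.

#' log2 counts per million
#'
#' `log2((count + 0.5) / (lib_size + 1) * 1e6)` -- the voom-style transform
#' of library-size-normalized counts.
#'
#' @param counts Non-negative count matrix (miRNA x sample).
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Matrix of logCPM values, same dimnames as `counts`.
#' @export
logcpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(lib_sizes) != ncol(counts)) {
    stopf("lib_sizes must have one entry per sample")
  }
  if (any(lib_sizes <= 0)) stopf("lib_sizes must be positive")
  log2(sweep(counts + 0.5, 2L, lib_sizes + 1, `/`) * 1e6)
}

#' Inverse of the trigamma function
#'
#' Newton iteration on `trigamma(y) = x`, used by the empirical-Bayes prior
#' fit. Monotone and convex, so the iteration converges from `y = 0.5 + 1/x`.
#'
#' @param x Positive values.
#' @return `y` with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Fit a scaled-F prior (d0, s0^2) to gene-wise sample variances by moment
# matching on the log scale: log s^2 ~ log s0^2 + log F(dg, d0) and the
# digamma/trigamma moments of log chi^2 give closed-form estimates.
fit_variance_prior <- function(s2, dg) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    warnf("too few positive gene variances; using infinite prior df")
    return(list(d0 = Inf, s02 = mean(s2[ok]) %||% NA_real_))
  }
  z <- log(s2[ok])
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    warnf("variance of log variances at or below sampling floor; prior df set to Inf (full shrinkage)")
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Two-group moderated-t differential expression
#'
#' Per miRNA: log2FC is the group-mean difference of logCPM values (second
#' factor level minus first); the pooled residual variance `s^2_g` with
#' `d_g = n1 + n2 - 2` df is shrunk towards an empirical-Bayes prior
#' `(d0, s0^2)` estimated by log-scale moment matching of a scaled-F
#' distribution; the moderated t uses the posterior variance
#' `(d0 s0^2 + d_g s^2_g) / (d0 + d_g)` and `d0 + d_g` df; p-values are
#' BH-adjusted across all miRNAs.
#'
#' @param x logCPM matrix (miRNA x sample), see [logcpm()].
#' @param groups Factor (or coercible) of length `ncol(x)` with two levels;
#'   if the levels are normal_serum/low_serum the contrast is low vs normal.
#' @param prior_df Optional override of the estimated prior df `d0`
#'   (0 = ordinary t, Inf = full shrinkage).
#' @return A list of class `de_fit`: `table` (data.frame with `mirna`,
#'   `mean_logcpm`, `log2fc`, `t_moderated`, `p_value`, `fdr`), `d0`, `s02`,
#'   `df_residual`, `df_total`, `groups`.
#' @export
fit_moderated <- function(x, groups, prior_df = NULL) {
  x <- as.matrix(x)
  if (!is.factor(groups)) {
    lev <- unique(as.character(groups))
    if (all(c("normal_serum", "low_serum") %in% lev)) {
      lev <- c("normal_serum", "low_serum")
    }
    groups <- factor(groups, levels = lev)
  }
  if (nlevels(groups) != 2L || length(groups) != ncol(x)) {
    stopf("groups must be a two-level factor matching the columns of x")
  }
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stopf("need at least two samples per group")
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  lfc <- m2 - m1
  ss <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
    rowSums((x[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- ss / dg

  if (all(s2 == 0)) {
    warnf("zero within-group variance for every miRNA; falling back to the ordinary t statistic")
    prior <- list(d0 = 0, s02 = NA_real_)
  } else if (!is.null(prior_df)) {
    prior <- list(d0 = prior_df,
                  s02 = if (prior_df > 0) fit_variance_prior(s2, dg)$s02
                        else NA_real_)
  } else {
    prior <- fit_variance_prior(s2, dg)
  }
  d0 <- prior$d0
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(prior$s02, length(s2))
  } else {
    (d0 * prior$s02 + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tmod <- ifelse(lfc == 0, 0, lfc / se)
  df_total <- min(d0 + dg, .Machine$double.xmax)
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  ids <- rownames(x) %||% sprintf("mir_%04d", seq_len(nrow(x)))
  tab <- data.frame(mirna = ids, mean_logcpm = rowMeans(x), log2fc = lfc,
                    t_moderated = tmod, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, d0 = d0, s02 = prior$s02, df_residual = dg,
                 df_total = df_total, groups = groups),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("Moderated-t fit: %d miRNAs, %s vs %s\n", nrow(x$table),
              levels(x$groups)[2], levels(x$groups)[1]))
  cat(sprintf("  prior df d0 = %.3g, prior variance s0^2 = %.3g\n",
              x$d0, x$s02))
  invisible(x)
}

#' Call differentially expressed miRNAs at volcano thresholds
#'
#' `up` when log2FC exceeds `lfc_threshold` and the significance criterion
#' holds; `down` for log2FC below `-lfc_threshold`; otherwise `ns`. The
#' significance criterion is the raw p-value by default (as volcano legends
#' print) or the BH-FDR when `use_fdr = TRUE` (pipeline-level control).
#'
#' @param fit A `de_fit` from [fit_moderated()] (or its `table`).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 0.6).
#' @param alpha Significance level (default 0.05).
#' @param use_fdr Test the BH-adjusted p instead of the raw p.
#' @return The result table with a `call` factor column (up/down/ns),
#'   ready for volcano-plot export.
#' @export
call_de <- function(fit, lfc_threshold = 0.6, alpha = 0.05, use_fdr = FALSE) {
  tab <- if (inherits(fit, "de_fit")) fit$table else fit
  stopifnot(all(c("log2fc", "p_value", "fdr") %in% names(tab)))
  sig <- if (use_fdr) tab$fdr < alpha else tab$p_value < alpha
  call <- rep("ns", nrow(tab))
  call[sig & tab$log2fc > lfc_threshold] <- "up"
  call[sig & tab$log2fc < -lfc_threshold] <- "down"
  tab$call <- factor(call, levels = c("up", "down", "ns"))
  tab
}
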