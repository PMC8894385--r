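# Well-level aggregation of classified cells, per-replicate fold changes
# against negative controls, and hit calling for replicated miRNA
# overexpression screens.

#' Summarize one well's classified cell records
#'
#' The readout statistic is the contractile/synthetic ratio with a
#' Haldane-Anscombe pseudocount of 0.5 in numerator and denominator, which
#' keeps the ratio finite for wells without synthetic cells. Wells with no
#' contractile and no synthetic cells are flagged `low_information` (their
#' ratio degenerates to 1).
#'
#' @param records Classified cell records (see [classify_phenotype()]).
#' @param well_id Optional well identifier; defaults to the records' one.
#' @param pseudocount Pseudocount added to both class counts (default 0.5).
#' @return One-row data.frame: class counts, `ratio_con_syn`,
#'   `low_information`.
#' @export
summarize_well <- function(records, well_id = NULL, pseudocount = 0.5) {
  if (is.null(records) || nrow(records) == 0L) {
    stopf("well failed: no cell records to summarize")
  }
  stopifnot("phenotype" %in% names(records))
  if (is.null(well_id)) {
    well_id <- as.character(records$well_id[1] %||% "well")
  }
  n <- table(factor(records$phenotype,
                    levels = c("contractile", "synthetic", "undecided",
                               "unclassified")))
  ratio <- (n[["contractile"]] + pseudocount) /
    (n[["synthetic"]] + pseudocount)
  data.frame(well_id = well_id,
             n_contractile = n[["contractile"]],
             n_synthetic = n[["synthetic"]],
             n_undecided = n[["undecided"]],
             n_unclassified = n[["unclassified"]],
             ratio_con_syn = ratio,
             low_information = n[["contractile"]] + n[["synthetic"]] == 0L,
             stringsAsFactors = FALSE)
}

#' Fold change of a well's con/syn ratio against its replicate control
#'
#' @param ratio Treatment well `ratio_con_syn` (or a [summarize_well()] row).
#' @param control_ratio Negative-control ratio of the same replicate.
#' @return `ratio / control_ratio`.
#' @export
fold_change <- function(ratio, control_ratio) {
  if (is.data.frame(ratio)) ratio <- ratio$ratio_con_syn
  if (!is.finite(control_ratio) || control_ratio <= 0) {
    stopf("control ratio must be a positive number (missing control well?)")
  }
  ratio / control_ratio
}

#' Call a screen hit from per-replicate fold changes
#'
#' Rules: `strong_contractile` when the averaged fold change exceeds
#' `strong_fc` (default 1.5) and every replicate moved in the contractile
#' direction (FC > 1); `weak_contractile` when not strong but the average
#' exceeds `weak_fc` (default 1.2); `strong_synthetic` when every replicate
#' decreased (FC < 1) and the average is below `1/weak_fc`; otherwise
#' `none`. Non-finite fold changes exclude the condition with a warning
#' (category `NA`).
#'
#' @param per_replicate_fc Numeric vector of fold changes, length >= 2.
#' @param strong_fc,weak_fc Averaged-FC thresholds.
#' @return A list: `per_replicate_fc`, `avg_fc`, `category`.
#' @export
call_hits <- function(per_replicate_fc, strong_fc = 1.5, weak_fc = 1.2) {
  if (length(per_replicate_fc) < 2L) {
    stopf("need fold changes from at least two replicates")
  }
  if (any(!is.finite(per_replicate_fc))) {
    warnf("non-finite fold change: condition excluded from hit calling")
    return(list(per_replicate_fc = per_replicate_fc,
                avg_fc = NA_real_, category = NA_character_))
  }
  avg <- mean(per_replicate_fc)
  category <- if (avg > strong_fc && all(per_replicate_fc > 1)) {
    "strong_contractile"
  } else if (avg > weak_fc) {
    "weak_contractile"
  } else if (all(per_replicate_fc < 1) && avg < 1 / weak_fc) {
    "strong_synthetic"
  } else {
    "none"
  }
  list(per_replicate_fc = per_replicate_fc, avg_fc = avg, category = category)
}

#' Build the screen table from well summaries
#'
#' Joins well summaries with the plate design, normalizes each treatment
#' well by the mean negative-control ratio of its own replicate (per-plate
#' normalization), and calls one hit category per condition.
#'
#' @param summaries Row-bound [summarize_well()] output for every well.
#' @param design Plate design table (see [plate_design()]).
#' @param strong_fc,weak_fc Passed to [call_hits()].
#' @return A list with `conditions` (one row per condition: per-replicate
#'   FCs as comma string, `avg_fc`, `category`), `wells` (well-level table
#'   with fold changes) and `fc_matrix` (condition x replicate).
#' @export
screen_table <- function(summaries, design, strong_fc = 1.5, weak_fc = 1.2) {
  validate_plate_design(design)
  tab <- merge(design, summaries, by = "well_id", sort = FALSE)
  if (nrow(tab) < nrow(design)) {
    stopf("missing well summaries for %d design wells",
          nrow(design) - nrow(tab))
  }
  reps <- sort(unique(tab$replicate_id))
  ctrl <- tab[tab$is_negative_control, ]
  ctrl_ratio <- tapply(ctrl$ratio_con_syn, ctrl$replicate_id, mean)
  if (any(!reps %in% names(ctrl_ratio))) {
    stopf("missing negative control for replicate(s) %s",
          paste(setdiff(reps, names(ctrl_ratio)), collapse = ", "))
  }
  tab$fold_change <- mapply(function(r, rep) {
    fold_change(r, ctrl_ratio[[rep]])
  }, tab$ratio_con_syn, tab$replicate_id)

  conds <- unique(tab$condition_label[!tab$is_negative_control])
  fc_mat <- matrix(NA_real_, length(conds), length(reps),
                   dimnames = list(conds, reps))
  for (cond in conds) {
    sub <- tab[tab$condition_label == cond & !tab$is_negative_control, ]
    fc_mat[cond, ] <- tapply(sub$fold_change, factor(sub$replicate_id,
                                                     levels = reps), mean)
  }
  calls <- lapply(seq_along(conds), function(i) {
    fc <- fc_mat[i, ]
    hc <- call_hits(fc[!is.na(fc)], strong_fc = strong_fc, weak_fc = weak_fc)
    data.frame(condition_label = conds[i],
               per_replicate_fc = paste(signif(fc, 6), collapse = ","),
               avg_fc = hc$avg_fc, category = hc$category,
               stringsAsFactors = FALSE)
  })
  conditions <- do.call(rbind, calls)
  conditions <- conditions[order(-conditions$avg_fc), ]
  rownames(conditions) <- NULL
  list(conditions = conditions, wells = tab, fc_matrix = fc_mat)
}

#' Run the screen aggregation on a generated plate
#'
#' Classifies every well's records (planted truth geometry by default),
#' summarizes wells, and builds the screen table.
#'
#' @param plate Result of [generate_plate()].
#' @param thresholds Classification thresholds ([class_thresholds()]).
#' @param records_fun Function mapping a well's truth table to cell records;
#'   defaults to [truth_records()]. Supply a segmentation-based records
#'   table per well instead to run from pixels.
#' @param ... Passed to [screen_table()].
#' @return See [screen_table()].
#' @export
run_screen <- function(plate, thresholds = class_thresholds(),
                       records_fun = truth_records, ...) {
  summaries <- do.call(rbind, lapply(plate$wells, function(w) {
    rec <- classify_phenotype(records_fun(w$truth), thresholds)
    summarize_well(rec)
  }))
  rownames(summaries) <- NULL
  screen_table(summaries, plate$design, ...)
}
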