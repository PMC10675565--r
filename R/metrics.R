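# Precision / recall / F1 per flight and treatment, treatment-level
# aggregation, and IoU-distribution diagnostics. All metrics are percentages
# computed directly from the integer counts:
#   precision = 100 TP / (TP + FP)
#   recall    = 100 TP / (TP + FN)
#   F1        = 100 TP / (TP + 0.5 (FP + FN))
# F1 comes from the counts, never from rounded precision/recall (the two
# disagree in the last decimal for some rows; counts are the primary data).
# A zero denominator yields NA (undefined), never an error, and NAs are
# excluded from treatment means.

#' Per-flight metric row from match counts
#'
#' @param counts a [match_counts][match_sequence] or any list with integer
#'   `tp`, `fp`, `fn`.
#' @param flight_id flight label.
#' @param treatment treatment code or display label.
#' @return one-row data.frame (class `metric_row`) with unrounded `precision`,
#'   `recall`, `f1` in percent (NA when undefined).
#' @export
compute_metrics <- function(counts, flight_id = "flight", treatment = "RGB") {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (anyNA(c(tp, fp, fn)) || any(c(tp, fp, fn) < 0)) {
    stop_validation("tp, fp, fn must be non-negative")
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  row <- data.frame(flight_id = as.character(flight_id),
                    treatment = match_treatment(treatment),
                    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                    precision = pct(tp, tp + fp),
                    recall = pct(tp, tp + fn),
                    f1 = pct(tp, tp + 0.5 * (fp + fn)),
                    stringsAsFactors = FALSE)
  class(row) <- c("metric_row", class(row))
  row
}

#' Aggregate metric rows per treatment
#'
#' Unweighted arithmetic mean and sd (n-1 denominator) of the per-flight
#' unrounded metrics, per treatment. Undefined (NA) per-flight values are
#' excluded from the aggregates; a treatment with no rows is omitted with a
#' warning.
#'
#' @param rows data.frame of stacked [compute_metrics()] rows.
#' @return data.frame with one row per treatment: `treatment`, `n_flights`,
#'   `mean_f1`, `sd_f1`, `mean_precision`, `mean_recall`.
#' @export
summarize_treatments <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop_validation("need at least one metric row")
  present <- TREATMENTS[TREATMENTS %in% rows$treatment]
  absent <- setdiff(unique(rows$treatment), TREATMENTS)
  if (length(absent)) warning("unknown treatments ignored: ", paste(absent, collapse = ", "))
  out <- do.call(rbind, lapply(present, function(tr) {
    d <- rows[rows$treatment == tr, , drop = FALSE]
    m <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    s <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)
    data.frame(treatment = tr, n_flights = nrow(d),
               mean_f1 = m(d$f1), sd_f1 = s(d$f1),
               mean_precision = m(d$precision), mean_recall = m(d$recall),
               stringsAsFactors = FALSE)
  }))
  missing_tr <- setdiff(TREATMENTS, present)
  if (length(missing_tr)) {
    warning("no rows for treatment(s): ",
            paste(TREATMENT_LABELS[missing_tr], collapse = ", "))
  }
  out
}

#' Histogram of matched-pair IoUs with peak detection
#'
#' Fixed bins of width `bin_width` spanning `[0, 1]`. Peaks are interior bins
#' strictly greater than both neighbours whose count reaches
#' `prominence_floor * max(counts)`; a well-localised detector shows one peak
#' near 0.74, and overlapping animals add a secondary peak near 0.35.
#'
#' @param ious numeric vector of IoUs in `[0, 1]`.
#' @param bin_width bin width, default 0.02.
#' @param prominence_floor fraction of the tallest bin a local maximum must
#'   reach to count as a peak, default 0.25.
#' @return an object of class `iou_histogram`: `bin_edges`, `mids`, `counts`,
#'   `peaks` (bin centres of detected peaks, increasing).
#' @export
iou_histogram <- function(ious, bin_width = 0.02, prominence_floor = 0.25) {
  if (any(ious < 0 | ious > 1)) stop_validation("IoU values must lie in [0, 1]")
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  k <- length(edges) - 1
  if (length(ious) == 0) {
    return(structure(list(bin_edges = edges, mids = (edges[-1] + edges[-(k + 1)]) / 2,
                          counts = integer(k), peaks = numeric(0)),
                     class = "iou_histogram"))
  }
  # right-closed last bin so iou = 1 is counted
  bin <- pmin(findInterval(ious, edges, rightmost.closed = TRUE), k)
  counts <- tabulate(bin, nbins = k)
  mids <- (edges[-1] + edges[-(k + 1)]) / 2
  floor_count <- prominence_floor * max(counts)
  is_peak <- vapply(seq_len(k), function(i) {
    i > 1 && i < k &&
      counts[i] > counts[i - 1] && counts[i] > counts[i + 1] &&
      counts[i] >= floor_count
  }, TRUE)
  structure(list(bin_edges = edges, mids = mids, counts = counts,
                 peaks = mids[is_peak]),
            class = "iou_histogram")
}

#' @export
print.iou_histogram <- function(x, ...) {
  cat(sprintf("<iou_histogram> %d values in %d bins; peaks at {%s}\n",
              sum(x$counts), length(x$counts),
              paste(format(x$peaks), collapse = ", ")))
  invisible(x)
}

format_pct <- function(v) ifelse(is.na(v), "NA", format(round_half_away(v, 1), nsmall = 1))

#' Render the evaluation report
#'
#' Emits, under `dir`: `metrics.csv` (columns
#' `Flight,Sensor,TP,FP,FN,Precision,Recall,F1`, one row per
#' flight-by-treatment, percentages rounded to one decimal, half away from
#' zero, bit-stable across runs), `summary.md` (treatment means with a
#' machine-readable JSON block), and one `iou_hist_<flight>_<treatment>.csv`
#' per supplied histogram.
#'
#' @param rows stacked [compute_metrics()] rows (non-empty).
#' @param summaries output of [summarize_treatments()], or `NULL` to omit the
#'   summary section.
#' @param histograms optional named list of [iou_histogram()] objects; names
#'   become file suffixes.
#' @param dir output directory (created if needed).
#' @return character vector of paths written, invisibly.
#' @export
render_report <- function(rows, summaries = NULL, histograms = NULL, dir = ".") {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop_validation("need at least one metric row")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io("cannot create output directory ", dir)
  # Table layout: rows grouped by flight, treatments in fixed sensor order
  ord <- order(rows$flight_id, match(rows$treatment, TREATMENTS))
  rows <- rows[ord, , drop = FALSE]
  tab <- data.frame(Flight = rows$flight_id,
                    Sensor = unname(TREATMENT_LABELS[rows$treatment]),
                    TP = rows$tp, FP = rows$fp, FN = rows$fn,
                    Precision = format_pct(rows$precision),
                    Recall = format_pct(rows$recall),
                    F1 = format_pct(rows$f1),
                    stringsAsFactors = FALSE)
  metrics_path <- file.path(dir, "metrics.csv")
  utils::write.csv(tab, metrics_path, row.names = FALSE, quote = FALSE)
  paths <- metrics_path

  md <- c("# Detection-reliability report", "",
          sprintf("%d flight x treatment rows.", nrow(rows)), "")
  if (!is.null(summaries) && nrow(as.data.frame(summaries)) > 0) {
    summaries <- as.data.frame(summaries)
    md <- c(md, "## Treatment means", "",
            "| Sensor | n flights | mean F1 | sd F1 | mean precision | mean recall |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %d | %s | %s | %s | %s |",
                    TREATMENT_LABELS[summaries$treatment], summaries$n_flights,
                    format_pct(summaries$mean_f1), format_pct(summaries$sd_f1),
                    format_pct(summaries$mean_precision),
                    format_pct(summaries$mean_recall)),
            "", "```json",
            jsonlite::toJSON(summaries, dataframe = "rows", auto_unbox = TRUE,
                             digits = NA, na = "null"),
            "```")
  } else {
    md <- c(md, "## Treatment means", "", "_absent_ (no summaries supplied)")
  }
  summary_path <- file.path(dir, "summary.md")
  writeLines(md, summary_path)
  paths <- c(paths, summary_path)

  for (nm in names(histograms)) {
    h <- histograms[[nm]]
    hp <- file.path(dir, paste0("iou_hist_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv"))
    utils::write.csv(data.frame(bin_lo = h$bin_edges[-length(h$bin_edges)],
                                bin_hi = h$bin_edges[-1],
                                count = h$counts),
                     hp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, hp)
  }
  invisible(paths)
}
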