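# Published per-flight detection counts from the original three-camera field
# study (nine dolphin flights, three sensor treatments), shipped as a
# fixture together with the precision/recall/F1 values printed alongside
# them. The counts are the primary data: every metric is recomputable from
# them, which is what check_reference_counts() does.

#' Reference per-flight detection counts
#'
#' The published TP/FP/FN tallies for nine flights times three sensor
#' treatments, with the printed one-decimal precision, recall and F1 values.
#'
#' @param path optional CSV with columns `flight`, `sensor`, `tp`, `fp`,
#'   `fn` (and optionally `precision_printed`, `recall_printed`,
#'   `f1_printed`); defaults to the packaged fixture.
#' @return data.frame of 27 rows (for the packaged fixture).
#' @export
reference_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_counts.csv", package = "droneval")
  }
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("flight", "sensor", "tp", "fp", "fn")
  if (!all(need %in% names(df))) {
    stop_validation(path, ": expected at least columns ",
                    paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) stop_validation(path, ": no rows")
  if (anyNA(df[c("tp", "fp", "fn")]) || any(df$tp < 0 | df$fp < 0 | df$fn < 0)) {
    stop_validation(path, ": tp, fp, fn must be non-negative integers")
  }
  df
}

#' Recompute metrics from reference counts and flag agreement
#'
#' Recomputes precision, recall and F1 from the TP/FP/FN counts of every row
#' of a reference-counts table, plus unweighted per-treatment means, and —
#' when the table carries printed values — flags each row by whether the
#' recomputed one-decimal value agrees with the printed one (to ±0.05, i.e.
#' to the printed precision). A handful of published rows disagree in the
#' last decimal of F1; the recomputation from counts is taken as primary.
#'
#' @param path optional counts CSV; defaults to the packaged fixture.
#' @return list of class `reference_check`: `rows` (recomputed metrics and
#'   agreement flags), `summaries` (per-treatment means of the recomputed,
#'   unrounded per-flight metrics).
#' @export
check_reference_counts <- function(path = NULL) {
  df <- reference_counts(path)
  rows <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    compute_metrics(df[i, ], flight_id = as.character(df$flight[i]),
                    treatment = df$sensor[i])
  }))
  out <- data.frame(flight = df$flight, sensor = df$sensor,
                    tp = df$tp, fp = df$fp, fn = df$fn,
                    precision = rows$precision, recall = rows$recall,
                    f1 = rows$f1, stringsAsFactors = FALSE)
  for (m in c("precision", "recall", "f1")) {
    printed_col <- paste0(m, "_printed")
    if (printed_col %in% names(df)) {
      out[[printed_col]] <- df[[printed_col]]
      out[[paste0(m, "_agrees")]] <-
        abs(round_half_away(out[[m]], 1) - df[[printed_col]]) <= 0.05
    }
  }
  structure(list(rows = out, summaries = summarize_treatments(rows)),
            class = "reference_check")
}

#' @export
print.reference_check <- function(x, ...) {
  agree_cols <- grep("_agrees$", names(x$rows), value = TRUE)
  cat(sprintf("<reference_check> %d rows recomputed\n", nrow(x$rows)))
  for (col in agree_cols) {
    cat(sprintf("  %s: %d/%d rows agree with the printed value\n",
                sub("_agrees$", "", col), sum(x$rows[[col]]), nrow(x$rows)))
  }
  s <- x$summaries
  cat("  treatment mean F1: ",
      paste(sprintf("%s %.1f", TREATMENT_LABELS[s$treatment], s$mean_f1),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
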