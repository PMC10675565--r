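#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Display rounding used throughout the report tables: exact halves move away
#' from zero (so 48.95 -> 49.0, -0.5 -> -1), unlike base [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("droneval_validation_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("droneval_parse_error",
                                             "droneval_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("droneval_io_error", "error")))
}

TREATMENTS <- c("RGB", "GREEN", "GREEN_POL")
TREATMENT_LABELS <- c(RGB = "RGB", GREEN = "Green", GREEN_POL = "Green/Pol")

match_treatment <- function(x) {
  if (x %in% TREATMENTS) return(x)
  hit <- names(TREATMENT_LABELS)[match(x, TREATMENT_LABELS)]
  if (is.na(hit)) {
    stop_validation("unknown treatment '", x, "'; expected one of ",
                    paste(TREATMENTS, collapse = ", "))
  }
  hit
}
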