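# Shared small helpers: label coercion, input checks, condition constructors.

#' Coerce case/control labels to a logical case flag
#'
#' Accepts logical, 0/1 numeric, or factor/character with levels
#' "case"/"control". TRUE means case (future ACS event).
#' @param labels label vector
#' @return logical vector, TRUE = case
#' @keywords internal
as_case_flag <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA))) {
      stop("numeric labels must be 0 (control) or 1 (case)")
    }
    return(labels == 1)
  }
  x <- tolower(as.character(labels))
  if (all(x %in% c("case", "control", NA))) return(x == "case")
  stop("labels must be logical, 0/1, or 'case'/'control'")
}

config_error <- function(field, message) {
  stop(errorCondition(sprintf("invalid configuration: field '%s' %s", field, message),
                      field = field, class = "acs_config_error"))
}

stage_error <- function(stage, message) {
  stop(errorCondition(sprintf("[%s] %s", stage, message),
                      stage = stage, class = "acs_stage_error"))
}

check_prob <- function(p, what = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(p)
}

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
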