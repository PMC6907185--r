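#' Score a K6 psychological-distress questionnaire response
#'
#' The Kessler K6 has six items, each rated on a 0--4 frequency scale; the
#' total is the plain item sum and lies between 0 and 24. Higher totals
#' indicate greater psychological distress.
#'
#' @param items Integer vector of exactly six item ratings, each in 0..4.
#' @return Integer total score in 0..24.
#' @examples
#' score_k6(c(1, 2, 0, 3, 4, 2))
#' @seealso [score_phq9()], [k6_distress_flag()]
#' @export
score_k6 <- function(items) {
  validate_items(items, n = 6L, max_code = 4L, scale = "K6")
  as.integer(sum(items))
}

#' Score a PHQ-9 depression questionnaire response
#'
#' The PHQ-9 has nine items, each rated on a 0--3 frequency scale; the total
#' is the item sum and lies between 0 and 27 (20--27 is the severe band).
#'
#' @param items Integer vector of exactly nine item ratings, each in 0..3.
#' @return Integer total score in 0..27.
#' @examples
#' score_phq9(c(1, 1, 2, 0, 3, 0, 1, 2, 0))
#' @export
score_phq9 <- function(items) {
  validate_items(items, n = 9L, max_code = 3L, scale = "PHQ-9")
  as.integer(sum(items))
}

#' Flag moderate psychological distress from a K6 total
#'
#' A K6 total of 5 or more is the established cut-off for moderate mental
#' distress.
#'
#' @param total Integer K6 total(s) in 0..24. Vectorised; `NA` passes through.
#' @return Integer 0/1 flag(s); 1 iff `total >= 5`.
#' @export
k6_distress_flag <- function(total) {
  ok <- is.na(total) | (total >= 0 & total <= 24)
  if (!all(ok)) {
    stop("K6 total out of range [0, 24]: ", paste(total[!ok], collapse = ", "))
  }
  as.integer(total >= 5)
}

# Shared item validation: length and per-item code range.
validate_items <- function(items, n, max_code, scale) {
  if (length(items) != n) {
    stop(scale, " response must have exactly ", n, " items, got ",
         length(items))
  }
  if (anyNA(items)) stop(scale, " items must not contain NA")
  if (any(items != as.integer(items)) ||
      any(items < 0L) || any(items > max_code)) {
    stop(scale, " items must be integers in {0..", max_code, "}")
  }
  invisible(TRUE)
}

# Reconcile item-level and pre-summed questionnaire columns: totals take
# precedence, but when both are present their consistency is enforced.
reconcile_total <- function(total, items, scorer, scale) {
  has_items <- !anyNA(items)
  if (!is.na(total)) {
    if (has_items) {
      s <- scorer(items)
      if (s != total) {
        stop(scale, " item sum (", s, ") disagrees with supplied total (",
             total, ")")
      }
    }
    return(as.integer(total))
  }
  if (has_items) return(scorer(items))
  NA_integer_
}
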