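## Life Event Questionnaire (LEQ) scoring and stress-group assignment.
##
## The LEQ has 39 items; each experienced event is rated for desirability on
## the integer scale -2 (very negative) .. +2 (very positive). Events never
## experienced carry no rating (NA here). The negative-life-event (NLE) count
## is the number of items rated below zero and the negative total is the sum
## of those ratings; positive, zero, and unexperienced items contribute
## nothing to either.

LEQ_N_ITEMS <- 39L

#' Score a 39-item life-event questionnaire response
#'
#' @param items numeric vector of exactly 39 ratings, each in
#'   `{-2, -1, 0, 1, 2}` or `NA` for an event never experienced.
#' @return a list of class `stress_score` with `n_nle` (count of events rated
#'   negative), `negative_total` (sum of negative ratings, always <= 0) and
#'   `group` (unset, `NA`; see [assign_group()]).
#' @examples
#' score_leq(c(-2, -1, -2, rep(0, 36)))
#' @export
score_leq <- function(items) {
  mn_assert(length(items) == LEQ_N_ITEMS,
            sprintf("LEQ response must have exactly %d items, got %d",
                    LEQ_N_ITEMS, length(items)))
  ok <- is.na(items) | (items %in% c(-2, -1, 0, 1, 2))
  mn_assert(all(ok), paste0("invalid LEQ ratings (allowed: -2..2 or NA): ",
                            paste(unique(items[!ok]), collapse = ", ")))
  neg <- !is.na(items) & items < 0
  structure(list(n_nle = sum(neg),
                 negative_total = sum(items[neg]),
                 group = NA_character_),
            class = "stress_score")
}

#' Assign Low/High stress group from NLE count and negative total
#'
#' Cut-offs: Low = at most 5 NLEs with a negative total in `[-5, 0]`;
#' High = 6 or more NLEs with a negative total in `[-20, -11]`. Scores
#' outside both windows are `"Unclassified"` and excluded from group
#' analyses. The two windows are disjoint so every score maps to exactly one
#' label. Vectorized.
#'
#' @param n_nle NLE count(s), or a `stress_score` from [score_leq()].
#' @param negative_total sum(s) of negative ratings (ignored when `n_nle` is
#'   a `stress_score`).
#' @return character vector in `{"Low", "High", "Unclassified"}`.
#' @examples
#' assign_group(3, -3)   # "Low"
#' assign_group(9, -14)  # "High"
#' assign_group(5, -7)   # "Unclassified"
#' @export
assign_group <- function(n_nle, negative_total) {
  if (inherits(n_nle, "stress_score")) {
    negative_total <- n_nle$negative_total
    n_nle <- n_nle$n_nle
  }
  mn_assert(length(n_nle) == length(negative_total),
            "n_nle and negative_total must have equal length")
  mn_assert(all(negative_total <= 0), "negative_total must be <= 0")
  out <- rep("Unclassified", length(n_nle))
  out[n_nle <= 5 & negative_total >= -5] <- "Low"
  out[n_nle >= 6 & negative_total >= -20 & negative_total <= -11] <- "High"
  out
}

#' Score every subject of a cohort table
#'
#' Looks for columns `leq_item_1 .. leq_item_39` and appends `n_nle`,
#' `leq_negative_total` and `stress_group`.
#'
#' @param cohort data frame with 39 `leq_item_*` columns (`NA` = event never
#'   experienced).
#' @return `cohort` with the three scoring columns appended/overwritten.
#' @export
score_cohort <- function(cohort) {
  cols <- paste0("leq_item_", seq_len(LEQ_N_ITEMS))
  mn_assert(all(cols %in% names(cohort)),
            "cohort is missing leq_item_1..leq_item_39 columns")
  items <- as.matrix(cohort[, cols])
  scores <- apply(items, 1, score_leq)
  cohort$n_nle <- vapply(scores, `[[`, integer(1), "n_nle")
  cohort$leq_negative_total <- vapply(scores, function(s)
    as.double(s$negative_total), double(1))
  cohort$stress_group <- assign_group(cohort$n_nle, cohort$leq_negative_total)
  cohort
}

#' @export
print.stress_score <- function(x, ...) {
  cat(sprintf("<stress_score> n_nle=%d negative_total=%d group=%s\n",
              x$n_nle, as.integer(x$negative_total),
              ifelse(is.na(x$group), "(unset)", x$group)))
  invisible(x)
}
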