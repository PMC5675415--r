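#' Per-symptom ratings of the vestibular syndrome scale
#'
#' The five posturo-locomotor symptoms and their ratings: tumbling 5,
#' retropulsion 4, circling 3, bobbing 2, head tilt 1. The composite score of
#' an observation is the sum of the ratings of the symptoms present, giving
#' the canonical states 15 (all five), 10 (tumbling gone), 6 (tumbling and
#' retropulsion gone), 3 (bobbing + head tilt) and 1 (head tilt alone), and 0
#' when no abnormal behaviour is observed. The additive convention is used
#' throughout: the bobbing + head-tilt state scores 2 + 1 = 3.
#'
#' @return Named integer vector of ratings.
#' @export
symptom_ratings <- function() {
  c(tumbling = 5L, retropulsion = 4L, circling = 3L, bobbing = 2L,
    head_tilt = 1L)
}

#' Score a set of vestibular symptoms
#'
#' @param symptoms Character vector (possibly empty) of observed symptoms;
#'   see [symptom_ratings()] for the valid names.
#' @return Integer score in 0..15.
#' @examples
#' score_symptoms(c("circling", "bobbing", "head_tilt")) # 6
#' score_symptoms(character(0)) # 0
#' @export
score_symptoms <- function(symptoms) {
  ratings <- symptom_ratings()
  symptoms <- unique(as.character(symptoms))
  bad <- setdiff(symptoms, names(ratings))
  if (length(bad)) {
    stop("unknown symptom(s): ", paste(bad, collapse = ", "),
         "; valid symptoms are: ", paste(names(ratings), collapse = ", "))
  }
  sum(ratings[symptoms])
}

#' Animal exclusion rule
#'
#' An animal is excluded from the study when it still exhibits the maximal
#' syndrome (score 15) 48 hours after the lesion, i.e. at the D2 observation,
#' or when its acquisition files are unusable. A missing D2 observation makes
#' the check indeterminate rather than an exclusion.
#'
#' @param timeline A data.frame of syndrome observations sorted by time, with
#'   columns `time` (labels such as `"awakening"`, `"4h"`, `"D1"` ... `"D21"`)
#'   and `score` (0-15).
#' @param unusable_files Data-quality flag: `TRUE` when the animal's
#'   acquisition files cannot be analysed.
#' @param at Time label at which the maximal-syndrome rule applies
#'   (default `"D2"`, the 48 h observation).
#' @return A list with `excluded` (`TRUE`, `FALSE` or `NA` for
#'   indeterminate) and `reason` (`"max_syndrome_48h"`, `"unusable_files"`,
#'   `"missing_48h_observation"` or `"none"`).
#' @examples
#' tl <- data.frame(time = c("awakening", "D1", "D2"), score = c(15, 10, 6))
#' exclusion_check(tl)
#' @export
exclusion_check <- function(timeline, unusable_files = FALSE, at = "D2") {
  if (isTRUE(unusable_files)) {
    return(list(excluded = TRUE, reason = "unusable_files"))
  }
  if (is.null(timeline) || nrow(timeline) == 0L ||
      !all(c("time", "score") %in% names(timeline))) {
    return(list(excluded = NA, reason = "missing_48h_observation"))
  }
  stopifnot(all(timeline$score >= 0 & timeline$score <= 15))
  d2 <- timeline$score[timeline$time == at]
  if (length(d2) == 0L) {
    return(list(excluded = NA, reason = "missing_48h_observation"))
  }
  if (any(d2 == 15)) {
    list(excluded = TRUE, reason = "max_syndrome_48h")
  } else {
    list(excluded = FALSE, reason = "none")
  }
}

#' Score a table of syndrome observations
#'
#' Adds a `score` column to an observation table with one logical column per
#' symptom (see [symptom_ratings()]).
#'
#' @param observations Data.frame with logical (or 0/1) columns named after
#'   the five symptoms; other columns are carried through.
#' @return The table with a `score` column.
#' @export
score_observations <- function(observations) {
  ratings <- symptom_ratings()
  missing <- setdiff(names(ratings), names(observations))
  if (length(missing)) {
    stop("observation table lacks symptom column(s): ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(observations[, names(ratings)])
  storage.mode(m) <- "integer"
  observations$score <- as.integer(m %*% ratings)
  observations
}
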