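#' Standard sex-age partition of the consumption survey
#'
#' Eight subgroups: children 3-6 y and 7-12 y (sexes pooled), then
#' sex-specific 13-17 y, 18-59 y and >= 60 y. Age bins are half-open
#' [min, max) except the last, which is right-unbounded.
#'
#' @return data.frame with columns `label`, `sex` (`"both"`, `"male"`,
#'   `"female"`), `age_min`, `age_max`.
#' @export
default_subgroups <- function() {
  data.frame(
    label = c("3-6", "7-12", "13-17 male", "13-17 female",
              "18-59 male", "18-59 female", ">=60 male", ">=60 female"),
    sex = c("both", "both", "male", "female", "male", "female",
            "male", "female"),
    age_min = c(3, 7, 13, 13, 18, 18, 60, 60),
    age_max = c(7, 13, 18, 18, 60, 60, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign survey individuals to sex-age subgroups
#'
#' Each individual maps to exactly one sex-age subgroup of the partition (NA,
#' with a warning, if younger than the partition minimum), always belongs to
#' the implicit "All" population, and belongs to "Consumer only" according to
#' `consumer_rule`: `"every_day"` requires positive consumption on every
#' present recall day, `"any_day"` on at least one.
#'
#' @param survey `cp_survey` data.frame.
#' @param partition subgroup table, see [default_subgroups()].
#' @param consumer_rule `"every_day"` (default) or `"any_day"`.
#' @return the survey with added columns `subgroup` and `consumer_only`.
#' @export
assign_subgroups <- function(survey, partition = default_subgroups(),
                             consumer_rule = c("every_day", "any_day")) {
  consumer_rule <- match.arg(consumer_rule)
  stopifnot(!anyDuplicated(partition$label))
  lab <- rep(NA_character_, nrow(survey))
  for (i in seq_len(nrow(partition))) {
    ok <- survey$age >= partition$age_min[i] &
      survey$age < partition$age_max[i] &
      (partition$sex[i] == "both" | survey$sex == partition$sex[i])
    if (any(ok & !is.na(lab))) {
      stop("partition is not disjoint: individual matched twice",
           call. = FALSE)
    }
    lab[ok] <- partition$label[i]
  }
  if (anyNA(lab) && nrow(survey) > 0L) {
    warning(sum(is.na(lab)),
            " individual(s) below the partition minimum age; ",
            "assigned only to 'All'", call. = FALSE)
  }
  days <- as.matrix(survey[, c("day1", "day2", "day3"), drop = FALSE])
  pos <- days > 0
  consumer <- if (consumer_rule == "every_day") {
    apply(pos, 1L, function(r) all(r[!is.na(r)]) && any(!is.na(r)))
  } else {
    apply(pos, 1L, function(r) any(r[!is.na(r)]))
  }
  survey$subgroup <- lab
  survey$consumer_only <- as.logical(consumer)
  survey
}

#' Members of a named population group
#'
#' Resolves the pseudo-groups `"All"` and `"Consumer only"` as well as any
#' partition label produced by [assign_subgroups()].
#'
#' @param survey survey with `subgroup`/`consumer_only` columns.
#' @param label group label.
#' @return logical membership vector.
#' @export
subgroup_members <- function(survey, label) {
  if (label == "All") rep(TRUE, nrow(survey))
  else if (label == "Consumer only") survey$consumer_only
  else !is.na(survey$subgroup) & survey$subgroup == label
}
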