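#' Interval-of-need dependency levels
#'
#' The interval-of-need scale classifies a person by the frequency with which
#' they need care: `independent` (free from care), `low` (help less than
#' daily), `medium` (help at regular times daily) and `high` (24-hour care).
#' The levels form a total order `independent < low < medium < high`.
#'
#' @return Character vector of the four levels in increasing severity.
#' @export
ion_levels <- function() c("independent", "low", "medium", "high")

#' Cognition categories from MMSE cut-points
#'
#' @return Character vector of categories in decreasing severity.
#' @export
cognition_levels <- function() c("severe", "moderate", "mild", "normal")

# inclusive MMSE ranges; the four rows partition 0-30 exactly
.mmse_cuts <- data.frame(
  label = c("severe", "moderate", "mild", "normal"),
  lo = c(0L, 10L, 21L, 27L),
  hi = c(9L, 20L, 26L, 30L),
  stringsAsFactors = FALSE
)

#' Categorise an MMSE score
#'
#' Maps a Mini-Mental State Examination score (integer 0-30) to a cognition
#' category: 0-9 severe impairment, 10-20 moderate, 21-26 mild, 27-30 normal
#' cognition. Vectorised.
#'
#' @param score Integer vector of MMSE scores in 0-30. `NA` is allowed and
#'   propagates.
#' @return Character vector of categories (`"severe"`, `"moderate"`,
#'   `"mild"`, `"normal"`), one per score.
#' @examples
#' categorise_mmse(c(9, 21, 27))
#' @export
categorise_mmse <- function(score) {
  if (length(score) == 0L) return(character(0))
  bad <- !is.na(score) & (score != round(score) | score < 0 | score > 30)
  if (any(bad)) {
    stop("MMSE score must be an integer in 0-30; got ",
         paste(utils::head(score[bad], 3), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(score))
  ok <- !is.na(score)
  idx <- findInterval(score[ok], c(0, 10, 21, 27))
  out[ok] <- .mmse_cuts$label[idx]
  out
}

#' Care-need item sets
#'
#' The two item dialects used to classify the interval of need. Dialect
#' `study_a` is the richer set: it includes proxy-interview items, an MMSE
#' rule in the high-dependency row, and instrumental items (toenails, heavy
#' housework, shopping). Dialect `study_b` is the leaner set with
#' pushing/pulling and house/garden-work difficulty items.
#'
#' @param dialect `"study_a"` or `"study_b"`.
#' @return Character vector of the indicator names interpretable in that
#'   dialect.
#' @export
care_need_items <- function(dialect = c("study_a", "study_b")) {
  dialect <- match.arg(dialect)
  common <- c("help_toilet", "chairfast_or_bedfast", "incontinent",
              "help_shoes_socks", "help_hot_meal", "help_bathe")
  if (dialect == "study_a") {
    c(common, "help_feed_proxy", "help_dress_proxy", "help_cut_toenails",
      "help_heavy_housework", "help_shopping_or_light_housework",
      "household_tasks_proxy")
  } else {
    c(common, "difficulty_push_pull", "difficulty_house_garden_work")
  }
}

# Rule tables. Each level is a list of clauses; a clause is a character
# vector of items that must all be TRUE (disjunctive normal form).
.ion_rules <- list(
  study_a = list(
    high = list("help_toilet", "chairfast_or_bedfast",
                c("incontinent", "help_shoes_socks"),
                "help_feed_proxy",
                c("incontinent", "help_dress_proxy")),
    medium = list("help_shoes_socks", "help_hot_meal", "help_dress_proxy"),
    low = list("help_bathe", "help_cut_toenails", "help_heavy_housework",
               "help_shopping_or_light_housework", "household_tasks_proxy")
  ),
  study_b = list(
    high = list("help_toilet", "chairfast_or_bedfast",
                c("incontinent", "help_shoes_socks")),
    medium = list("help_shoes_socks", "help_hot_meal"),
    low = list("help_bathe", "difficulty_push_pull",
               "difficulty_house_garden_work")
  )
)

# evaluate one DNF rule set over a named logical vector; returns TRUE if any
# clause has all items TRUE, FALSE if every clause has a FALSE item, NA when
# undetermined because of missing items
.eval_rules <- function(clauses, items) {
  fired <- FALSE
  undetermined <- FALSE
  for (cl in clauses) {
    v <- items[cl]
    if (all(!is.na(v)) && all(v)) return(TRUE)
    if (!any(!is.na(v) & !v)) undetermined <- TRUE  # no definite FALSE item
  }
  if (undetermined) NA else fired
}

#' Classify the interval of need from care-need items
#'
#' Applies the dependency categorisation rules top-down (high, then medium,
#' then low); the first level whose rule fires is returned. In dialect
#' `study_a` an MMSE score of 0-9 (severe cognitive impairment) forces
#' `high`. `independent` is returned only when no rule fires and no item of
#' any rule is missing. Incontinence never classifies alone: it enters only
#' in conjunction with needing help putting on shoes and socks (or, in
#' `study_a`, with proxy-reported help to dress).
#'
#' Missing items are tolerated as long as some rule fires: a person is
#' classifiable at a level when the items triggering that level are present
#' and true, whatever else is missing. If no rule fires and any rule item is
#' missing, the person is unclassifiable and an error is raised.
#'
#' @param items Named list or named logical vector of care-need indicators
#'   (see [care_need_items()]); `NA` marks a missing item. Indicators not
#'   interpretable in the chosen dialect are ignored.
#' @param mmse MMSE score (integer 0-30) or `NULL`/`NA` when not measured.
#'   Used only by the `study_a` high-dependency rule.
#' @param dialect `"study_a"` or `"study_b"`.
#' @return One of `"independent"`, `"low"`, `"medium"`, `"high"`.
#' @examples
#' classify_interval_of_need(list(help_toilet = TRUE), dialect = "study_b")
#' classify_interval_of_need(list(help_shoes_socks = TRUE, incontinent = FALSE,
#'                                help_toilet = FALSE, chairfast_or_bedfast = FALSE,
#'                                help_hot_meal = FALSE, help_bathe = FALSE,
#'                                difficulty_push_pull = FALSE,
#'                                difficulty_house_garden_work = FALSE),
#'                           dialect = "study_b")
#' @export
classify_interval_of_need <- function(items, mmse = NULL,
                                      dialect = c("study_a", "study_b")) {
  dialect <- match.arg(dialect)
  valid <- care_need_items(dialect)
  iv <- rep(NA, length(valid))
  names(iv) <- valid
  if (length(items)) {
    items <- unlist(items)
    known <- intersect(names(items), valid)
    iv[known] <- as.logical(items[known])
  }
  mmse_missing <- is.null(mmse) || is.na(mmse)
  if (!mmse_missing) {
    mmse_severe <- categorise_mmse(mmse) == "severe"
  }
  if (all(is.na(iv)) && (dialect == "study_b" || mmse_missing)) {
    stop("all care-need items missing: interval of need unclassifiable",
         call. = FALSE)
  }

  rules <- .ion_rules[[dialect]]
  any_na <- FALSE
  # high row: in study_a, MMSE 0-9 is one more disjunct
  if (dialect == "study_a" && !mmse_missing && mmse_severe) return("high")
  for (level in c("high", "medium", "low")) {
    r <- .eval_rules(rules[[level]], iv)
    if (isTRUE(r)) return(level)
    if (is.na(r)) any_na <- TRUE
  }
  # study_a: a missing MMSE leaves the high row undetermined
  if (dialect == "study_a" && mmse_missing) any_na <- TRUE
  if (any_na) {
    stop("no rule fires but some items are missing: ",
         "interval of need unclassifiable", call. = FALSE)
  }
  "independent"
}

#' Combine physical dependency with cognition
#'
#' Physical dependency is modelled free of cognitive impairment; the final
#' interval of need is the more severe of the physical level and the floor
#' implied by cognition. Only severe cognitive impairment (MMSE 0-9) imposes
#' a floor, namely `high`; moderate, mild and normal cognition impose none.
#' Vectorised over both arguments.
#'
#' @param physical Character vector of physical dependency levels
#'   (see [ion_levels()]).
#' @param cognition Character vector of cognition categories
#'   (see [cognition_levels()]).
#' @return Character vector of combined interval-of-need levels.
#' @examples
#' combine_physical_and_cognition("low", "severe")   # "high"
#' combine_physical_and_cognition("medium", "normal") # "medium"
#' @export
combine_physical_and_cognition <- function(physical, cognition) {
  lv <- ion_levels()
  p <- match(physical, lv)
  if (any(is.na(p) & !is.na(physical)) || any(is.na(physical))) {
    stop("invalid physical dependency level", call. = FALSE)
  }
  if (any(!cognition %in% cognition_levels())) {
    stop("invalid cognition category", call. = FALSE)
  }
  floor_idx <- ifelse(cognition == "severe", 4L, 1L)
  lv[pmax(p, floor_idx)]
}
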