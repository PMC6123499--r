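# round half away from zero, the convention of the report tables
.report_round <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reporting age bands for the older population
#' @param age_years Numeric ages.
#' @return `"65-74"`, `"75-84"` or `"85+"` (`NA` under 65).
#' @export
report_age_band <- function(age_years) {
  age_band(age_years, breaks = c(65, 75, 85))
}

#' Disease-count stratum
#'
#' Multimorbidity strata used in the cross-tabulations: `"0-1"`, `"2"`,
#' `"3+"` chronic diseases (of the eight tracked).
#'
#' @param n_diseases Integer vector of disease counts.
#' @return Character stratum labels.
#' @export
disease_stratum <- function(n_diseases) {
  ifelse(n_diseases <= 1, "0-1", ifelse(n_diseases == 2, "2", "3+"))
}

#' Tabulate run snapshots into an output cube
#'
#' Exact integer counts of alive individuals aged 65+ indexed by run,
#' output year, sex, age band (65-74, 75-84, 85+), interval of need,
#' disease-count stratum and dementia flag. The factor converting counts
#' to population units (the inverse sampling fraction of the base
#' population) is carried in the `scaling_factor` attribute.
#'
#' @param results A `simulation_results` object from [run_simulation()].
#' @return Object of class `output_cube`: data.frame of non-empty cells
#'   with a `count` column.
#' @export
tabulate_runs <- function(results) {
  rows <- list()
  for (rr in results$runs) {
    for (yr in names(rr$snapshots)) {
      s <- rr$snapshots[[yr]]
      s <- s[s$alive & s$age_months >= 65 * 12, , drop = FALSE]
      if (!nrow(s)) next
      ndis <- rowSums(as.matrix(as.data.frame(s[disease_names()])))
      cell <- data.frame(
        run = rr$run, year = as.integer(yr), sex = s$sex,
        age_band = report_age_band(s$age_months / 12),
        interval_of_need = s$interval_of_need,
        disease_stratum = disease_stratum(ndis),
        dementia = s$dementia, stringsAsFactors = FALSE)
      agg <- stats::aggregate(
        list(count = rep(1L, nrow(cell))),
        cell, sum)
      rows[[length(rows) + 1]] <- agg
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = integer(0), year = integer(0), sex = character(0),
               age_band = character(0), interval_of_need = character(0),
               disease_stratum = character(0), dementia = logical(0),
               count = integer(0))
  attr(out, "scaling_factor") <- results$scaling_factor %||% 1
  structure(out, class = c("output_cube", "data.frame"))
}

#' Aggregate an output cube over chosen indices
#'
#' @param cube An `output_cube`.
#' @param by Character vector of index columns to keep.
#' @return Data.frame of counts summed over the dropped indices.
#' @export
cube_margin <- function(cube, by = c("run", "year", "interval_of_need")) {
  stats::aggregate(cube["count"], cube[by], sum)
}

#' Relative change between two counts, in percent
#'
#' `100 * (n_end - n_start) / n_start`, rounded half away from zero to one
#' decimal, the style of the projection tables.
#'
#' @param n_start Baseline count (> 0).
#' @param n_end Final count.
#' @return Percent change to one decimal.
#' @examples
#' relative_change(3655, 5602) # 53.3
#' @export
relative_change <- function(n_start, n_end) {
  if (any(n_start <= 0)) .stopf("relative change undefined for n_start <= 0")
  .report_round(100 * (n_end - n_start) / n_start, 1)
}

#' Proportion of total life expectancy, in percent
#'
#' @param years_state Years lived in the state.
#' @param total_le Total remaining life expectancy (> 0).
#' @return `100 * years_state / total_le` to one decimal.
#' @examples
#' proportion_of_le(1.2, 18.7) # 6.4
#' @export
proportion_of_le <- function(years_state, total_le) {
  if (any(total_le <= 0)) .stopf("total life expectancy must be > 0")
  .report_round(100 * years_state / total_le, 1)
}

#' Age-sex dependency prevalence from a snapshot
#'
#' Single-year-of-age proportions in each interval-of-need level among the
#' alive population, by sex. Ages whose cell size falls below `min_cell`
#' are smoothed by a 5-year centred moving window on the counts before
#' proportions are formed; ages beyond the observed range carry the
#' nearest observed age's proportions (needed to close the lifetable).
#'
#' @param snapshot A snapshot data.frame with `interval_of_need`.
#' @param ages Integer ages the prevalence schedule must cover.
#' @param min_cell Minimum persons at an age before smoothing kicks in.
#' @return Data.frame `sex`, `age`, `level`, `prop`; proportions sum to 1
#'   within each sex-age.
#' @export
dependency_prevalence <- function(snapshot, ages = 65:105, min_cell = 30L) {
  s <- snapshot[snapshot$alive & !is.na(snapshot$interval_of_need), ,
                drop = FALSE]
  s$age <- s$age_months %/% 12L
  levels <- ion_levels()
  out <- list()
  for (sx in unique(s$sex)) {
    ss <- s[s$sex == sx, ]
    obs_ages <- sort(unique(ss$age))
    cnt <- matrix(0L, nrow = length(obs_ages), ncol = length(levels),
                  dimnames = list(obs_ages, levels))
    tab <- table(factor(ss$age, levels = obs_ages),
                 factor(ss$interval_of_need, levels = levels))
    cnt[] <- as.integer(tab)
    tot <- rowSums(cnt)
    for (a in ages) {
      nearest <- obs_ages[which.min(abs(obs_ages - a))]
      i <- match(nearest, obs_ages)
      use <- cnt[i, ]
      if (tot[i] < min_cell) {
        win <- which(abs(obs_ages - nearest) <= 2)
        use <- colSums(cnt[win, , drop = FALSE])
      }
      if (sum(use) == 0) use <- c(1, 0, 0, 0)  # empty: treat as independent
      out[[length(out) + 1]] <- data.frame(
        sex = sx, age = a, level = levels, prop = as.numeric(use / sum(use)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sullivan-method health expectancies
#'
#' Partitions period life expectancy at `from_age` into state-specific
#' expectancies by weighting lifetable person-years by cross-sectional
#' state prevalence:
#' \deqn{e_{state} = \sum_{x \ge a} \pi_{state}(x) L_x / l_a.}
#' The state expectancies sum to total life expectancy by construction.
#'
#' @param prevalence Data.frame `sex`, `age`, `level`, `prop`; the
#'   proportions must sum to 1 within each sex-age (tolerance 1e-6) and
#'   cover every lifetable age from `from_age` to the terminal age.
#' @param lifetable A [generate_lifetable()] table.
#' @param from_age Age at which expectancies are evaluated.
#' @param year Optional calendar-year tag copied to the output.
#' @return Object of class `health_expectancy`: data.frame with one row
#'   per sex and level: `sex`, `year`, `level`, `years`, `proportion_pct`,
#'   `total_le`.
#' @export
sullivan <- function(prevalence, lifetable, from_age = 65, year = NA) {
  out <- list()
  for (sx in unique(prevalence$sex)) {
    lt <- lifetable[lifetable$sex == sx & lifetable$age >= from_age, ]
    if (!nrow(lt)) .stopf("lifetable does not cover sex '%s'", sx)
    pv <- prevalence[prevalence$sex == sx, ]
    missing_ages <- setdiff(lt$age, pv$age)
    if (length(missing_ages)) {
      .stopf("prevalence missing age(s) %s for %s",
             paste(utils::head(missing_ages, 4), collapse = ", "), sx)
    }
    sums <- tapply(pv$prop, pv$age, sum)
    if (any(abs(sums - 1) > 1e-6)) {
      .stopf("prevalence proportions do not sum to 1 for %s (max dev %.2e)",
             sx, max(abs(sums - 1)))
    }
    l_a <- lt$l_x[lt$age == from_age]
    total <- sum(lt$L_x) / l_a
    for (lev in ion_levels()) {
      pr <- pv$prop[pv$level == lev][match(lt$age, pv$age[pv$level == lev])]
      yrs <- sum(pr * lt$L_x) / l_a
      out[[length(out) + 1]] <- data.frame(
        sex = sx, year = year, level = lev, years = yrs,
        proportion_pct = 100 * yrs / total, total_le = total,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, out), class = c("health_expectancy", "data.frame"))
}

#' Birth-cohort independence traces
#'
#' For each 5-year birth cohort and sex, the proportion of alive members
#' who are independent at each output year, from the first run's
#' snapshots. Cohorts younger than 65 at a given year are suppressed;
#' empty cohort-year cells are emitted as `NA`, not zero.
#'
#' @param results A `simulation_results`.
#' @param cohort_width Cohort width in years.
#' @param run Which run's snapshots to trace.
#' @return Data.frame `sex`, `cohort` (birth-year band label), `year`,
#'   `n`, `prop_independent`.
#' @export
cohort_trace <- function(results, cohort_width = 5L, run = 1L) {
  rr <- results$runs[[run]]
  out <- list()
  for (yr in names(rr$snapshots)) {
    y <- as.integer(yr)
    s <- rr$snapshots[[yr]]
    s <- s[s$alive & s$age_months >= 65 * 12, , drop = FALSE]
    if (!nrow(s)) next
    birth <- y - s$age_months %/% 12L
    lo <- (birth %/% cohort_width) * cohort_width
    # suppress cohorts whose youngest birth year is not yet 65 this year
    keep <- y - (lo + cohort_width - 1L) >= 65L
    s <- s[keep, , drop = FALSE]
    if (!nrow(s)) next
    lo <- lo[keep]
    s$cohort <- paste0(lo, "-", lo + cohort_width - 1L)
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(s)),
           ind = as.numeric(s$interval_of_need == "independent")),
      list(sex = s$sex, cohort = s$cohort), sum)
    agg$year <- y
    agg$prop_independent <- ifelse(agg$n > 0, agg$ind / agg$n, NA_real_)
    agg$ind <- NULL
    out[[length(out) + 1]] <- agg
  }
  if (!length(out)) {
    return(data.frame(sex = character(0), cohort = character(0),
                      year = integer(0), n = integer(0),
                      prop_independent = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$sex, res$cohort, res$year),
      c("sex", "cohort", "year", "n", "prop_independent")]
}

#' Headline value and range of a statistic over repeated runs
#'
#' The reporting convention for uncertainty: the first run's value is the
#' headline, and the min-max range over all runs quantifies Monte-Carlo
#' spread.
#'
#' @param results A `simulation_results`.
#' @param statistic Function mapping one run result to a named numeric
#'   vector (or scalar).
#' @return Data.frame `statistic`, `headline`, `min`, `max`.
#' @export
range_over_runs <- function(results, statistic) {
  vals <- lapply(results$runs, statistic)
  m <- do.call(rbind, lapply(vals, function(v) {
    v <- unlist(v)
    if (is.null(names(v))) names(v) <- paste0("stat", seq_along(v))
    v
  }))
  data.frame(statistic = colnames(m), headline = m[1, ],
             min = apply(m, 2, min), max = apply(m, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}
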