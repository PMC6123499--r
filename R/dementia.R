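#' Generate a dementia allocation probability table
#'
#' Dementia is not simulated dynamically: it is allocated probabilistically
#' outside the monthly loop, conditional on age group, MMSE cognition
#' category and residence. The synthetic table is logistic in an age-group
#' index and a cognitive-severity index, with a care-home increment, so the
#' probabilities are monotone non-decreasing in age group and in severity
#' by construction.
#'
#' @param params A [truth_params()] object (its `dementia` element) or a
#'   list with `base`, `age_step`, `severity_step`, `care_home` (logit
#'   scale).
#' @param age_groups Ordered labels of the age groups, youngest first.
#' @return Object of class `dementia_table`: data.frame with `age_group`,
#'   `cognition`, `residence`, `prob`.
#' @export
generate_dementia_table <- function(params = truth_params(),
                                    age_groups = c("35-64", "65-74", "75-84", "85+")) {
  d <- if (inherits(params, "truth_params")) params$dementia else params
  grid <- expand.grid(age_group = age_groups,
                      cognition = cognition_levels(),
                      residence = c("community", "care_home"),
                      stringsAsFactors = FALSE)
  age_idx <- match(grid$age_group, age_groups) - 1
  # severity index: normal=0 ... severe=3
  sev_idx <- 3 - (match(grid$cognition, cognition_levels()) - 1)
  grid$prob <- .plogis(d$base + d$age_step * age_idx +
                         d$severity_step * sev_idx +
                         d$care_home * (grid$residence == "care_home"))
  if (any(grid$prob < 0 | grid$prob > 1)) .stopf("probability outside [0,1]")
  structure(grid, class = c("dementia_table", "data.frame"))
}

# age group of the dementia table for each individual
.dementia_age_group <- function(age_years, age_groups) {
  lo <- as.numeric(sub("[-+].*$", "", age_groups))
  idx <- findInterval(age_years, lo)
  idx[idx == 0L] <- 1L
  age_groups[idx]
}

#' Allocate dementia to a population snapshot
#'
#' Draws dementia status per individual as a Bernoulli variable with the
#' probability of their age-group x cognition x residence cell. Applied to
#' output-year snapshots, never inside the monthly loop, and alters no
#' other field. Dead individuals are left untouched.
#'
#' @param population Data.frame of individual states.
#' @param dementia_table A [generate_dementia_table()] table.
#' @return The population with `dementia` filled in for alive individuals.
#' @export
allocate_dementia <- function(population, dementia_table) {
  if (!nrow(population)) return(population)
  age_groups <- unique(dementia_table$age_group)
  key <- paste(dementia_table$age_group, dementia_table$cognition,
               dementia_table$residence)
  prob <- dementia_table$prob
  names(prob) <- key
  alive <- which(population$alive)
  grp <- .dementia_age_group(population$age_months[alive] / 12, age_groups)
  k <- paste(grp, categorise_mmse(population$mmse[alive]),
             population$residence[alive])
  p <- prob[k]
  if (anyNA(p)) {
    .stopf("dementia table does not cover cell(s): %s",
           paste(utils::head(unique(k[is.na(p)]), 3), collapse = "; "))
  }
  population$dementia[alive] <- .rbern(as.numeric(p))
  population
}
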