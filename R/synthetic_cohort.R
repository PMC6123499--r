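#' @title Synthetic study extracts with known ground truth
#' @description
#' The generator stands in for pooled longitudinal survey extracts: one row
#' per individual with baseline characteristics, a 2-year follow-up subject
#' to attrition, and a positive sampling weight. All quantities are drawn
#' from the gradients and logits in a [truth_params()] object, so every
#' generated dataset has a known generative truth against which fitted
#' transition models can be checked.
#' @name synthetic_cohort
NULL

# columns that constitute an individual state
.state_cols <- function() {
  c("id", "sex", "age_months", "education", "occupation", "smoking",
    "bmi_class", "physical_activity", disease_names(), "vision_impairment",
    "hearing_impairment", "mmse", "physical_dependency", "residence",
    "dementia", "alive", "weight")
}

# draw baseline states from the prevalence gradients
.draw_baseline <- function(n, params, study_label) {
  pv <- params$prevalence
  amin <- params$ages$min
  amax <- params$ages$max
  ages <- amin:amax
  w <- exp(-params$ages$decay * (ages - amin))
  age_years <- sample(ages, n, replace = TRUE, prob = w)
  age_months <- age_years * 12L + sample(0:11, n, replace = TRUE)

  female <- .rbern(.prev_p(pv$female, age_years, 0))
  sex <- ifelse(female, "female", "male")
  male <- as.numeric(!female)

  p_hi <- .prev_p(pv$education_high, age_years, male)
  p_mid <- .prev_p(pv$education_mid, age_years, male)
  u <- stats::runif(n)
  education <- ifelse(u < p_hi, "high", ifelse(u < p_hi + p_mid, "mid", "low"))
  occupation <- ifelse(
    .rbern(pmin(1, .prev_p(pv$occupation_non_manual, age_years, male) +
                  0.2 * (education == "high"))),
    "non_manual", "manual")

  p_cur <- .prev_p(pv$smoking_current, age_years, male)
  p_for <- .prev_p(pv$smoking_former, age_years, male)
  u <- stats::runif(n)
  smoking <- ifelse(u < p_cur, "current",
                    ifelse(u < p_cur + p_for, "former", "never"))

  p_ob <- .prev_p(pv$bmi_obese, age_years, male)
  p_ow <- .prev_p(pv$bmi_overweight, age_years, male)
  u <- stats::runif(n)
  bmi_class <- ifelse(u < p_ob, "obese",
                      ifelse(u < p_ob + p_ow, "overweight", "normal"))

  p_lo <- .prev_p(pv$pa_low, age_years, male)
  p_hi2 <- .prev_p(pv$pa_high, age_years, male)
  u <- stats::runif(n)
  physical_activity <- ifelse(u < p_lo, "low",
                              ifelse(u < p_lo + p_hi2, "high", "medium"))

  out <- data.frame(
    id = paste0(study_label, "_", seq_len(n)),
    sex = sex, age_months = as.integer(age_months),
    education = education, occupation = occupation,
    smoking = smoking, bmi_class = bmi_class,
    physical_activity = physical_activity,
    stringsAsFactors = FALSE
  )
  for (d in disease_names()) {
    out[[d]] <- .rbern(.prev_p(pv[[d]], age_years, male))
  }

  ord3 <- function(p_some, p_sev) {
    u <- stats::runif(n)
    ifelse(u < p_sev, "severe", ifelse(u < p_sev + p_some, "some", "none"))
  }
  out$vision_impairment <- ord3(.prev_p(pv$vision_some, age_years, male),
                                .prev_p(pv$vision_severe, age_years, male))
  out$hearing_impairment <- ord3(.prev_p(pv$hearing_some, age_years, male),
                                 .prev_p(pv$hearing_severe, age_years, male))

  p_sev <- .prev_p(pv$cog_severe, age_years, male)
  p_mod <- .prev_p(pv$cog_moderate, age_years, male)
  p_mld <- .prev_p(pv$cog_mild, age_years, male)
  u <- stats::runif(n)
  cog <- ifelse(u < p_sev, "severe",
                ifelse(u < p_sev + p_mod, "moderate",
                       ifelse(u < p_sev + p_mod + p_mld, "mild", "normal")))
  out$mmse <- .draw_mmse_in_category(cog)

  p_h <- .prev_p(pv$dep_high, age_years, male)
  p_m <- .prev_p(pv$dep_medium, age_years, male)
  p_l <- .prev_p(pv$dep_low, age_years, male)
  u <- stats::runif(n)
  out$physical_dependency <- ifelse(
    u < p_h, "high",
    ifelse(u < p_h + p_m, "medium",
           ifelse(u < p_h + p_m + p_l, "low", "independent")))

  out$residence <- ifelse(.rbern(.prev_p(pv$care_home, age_years, male)),
                          "care_home", "community")
  out$dementia <- FALSE
  out$alive <- TRUE
  out$weight <- stats::rlnorm(n, params$weights$meanlog, params$weights$sdlog)
  out[.state_cols()]
}

# draw an MMSE score uniformly within a cognition category's range
.draw_mmse_in_category <- function(cog) {
  lo <- c(severe = 0L, moderate = 10L, mild = 21L, normal = 27L)[cog]
  hi <- c(severe = 9L, moderate = 20L, mild = 26L, normal = 30L)[cog]
  as.integer(lo + floor(stats::runif(length(cog)) * (hi - lo + 1L)))
}

# apply one biennial ground-truth transition step. All transition
# probabilities are evaluated on the frozen baseline state (the structure a
# two-wave GLM estimates); each model then moves its at-risk individuals.
.apply_biennial_truth <- function(pop, params) {
  reg <- transition_registry()
  frozen <- pop
  out <- pop
  for (i in seq_len(nrow(reg))) {
    key <- reg$key[i]
    beta <- params$transitions[[key]]
    chr <- reg$characteristic[i]
    col <- if (chr == "cognition") "mmse" else chr
    cur <- if (chr == "cognition") {
      categorise_mmse(frozen$mmse)
    } else if (col %in% disease_names()) {
      as.character(frozen[[col]])
    } else {
      frozen[[col]]
    }
    at_risk <- which(cur == reg$from[i])
    if (!length(at_risk)) next
    covs <- setdiff(names(beta), "(Intercept)")
    lp <- rep(beta[["(Intercept)"]], length(at_risk))
    if (length(covs)) {
      X <- build_covariates(frozen[at_risk, , drop = FALSE], covs)
      lp <- lp + as.vector(X %*% beta[covs])
    }
    move <- at_risk[.rbern(.plogis(lp))]
    if (!length(move)) next
    if (chr == "cognition") {
      out$mmse[move] <- .draw_mmse_in_category(rep(reg$to[i], length(move)))
    } else if (col %in% disease_names()) {
      out[[col]][move] <- as.logical(reg$to[i])
    } else {
      out[[col]][move] <- reg$to[i]
    }
  }
  out
}

#' Generate a two-wave synthetic study extract
#'
#' Draws `n` baseline individuals from the prevalence gradients in `params`,
#' applies one biennial ground-truth transition step to produce the 2-year
#' follow-up, and removes followed-up rows missing-at-random given age
#' (attrition). Follow-up age is baseline age plus 24 months. Weights are
#' positive lognormal draws.
#'
#' @param n Number of individuals (>= 1).
#' @param study_label Short label; prefixes the individual ids.
#' @param params A [truth_params()] object.
#' @param seed Integer seed; the same seed reproduces the extract exactly.
#' @return An object of class `study_extract`: list with `study_label`,
#'   `baseline` (data.frame, one row per individual), `followup`
#'   (data.frame, rows only for non-attrited individuals, ages advanced 24
#'   months), and `params` echo.
#' @export
generate_study_extract <- function(n, study_label = "study", params = truth_params(),
                                   seed = 1L) {
  if (!inherits(params, "truth_params")) params <- truth_params(params)
  if (n < 1) .stopf("n must be >= 1")
  set.seed(seed)
  base <- .draw_baseline(n, params, study_label)
  fu <- .apply_biennial_truth(base, params)
  fu$age_months <- fu$age_months + 24L
  age_years <- base$age_months / 12
  p_attr <- .plogis(.qlogis(max(params$attrition$rate, 1e-12)) +
                      params$attrition$age_slope * (age_years - 65))
  if (params$attrition$rate == 0) p_attr <- rep(0, n)
  keep <- !.rbern(p_attr)
  structure(list(study_label = study_label, baseline = base,
                 followup = fu[keep, , drop = FALSE], seed = seed),
            class = "study_extract")
}

#' @export
print.study_extract <- function(x, ...) {
  cat(sprintf("<study_extract '%s': n=%d baseline, %d followed up>\n",
              x$study_label, nrow(x$baseline), nrow(x$followup)))
  invisible(x)
}

#' Pool study extracts into one weighted baseline table
#'
#' @param extracts List of `study_extract` objects.
#' @return Data.frame of pooled baseline rows with a `study` column and the
#'   study-specific `weight`.
#' @export
pool_extracts <- function(extracts) {
  if (!length(extracts)) .stopf("no extracts supplied")
  rows <- lapply(extracts, function(e) {
    b <- e$baseline
    b$study <- e$study_label
    b
  })
  do.call(rbind, rows)
}

#' Rake weights to age-band by sex population margins
#'
#' Iterative proportional fitting: alternately scales weights so that the
#' weighted age-band totals and the weighted sex totals match the target
#' margins, until both sets of margins are reproduced to within `tol`
#' (relative) or `max_iter` sweeps.
#'
#' @param pop Data.frame with `age_months`, `sex` and `weight` columns.
#' @param target_margins Data.frame with columns `age_band`, `sex`, `count`
#'   giving target population counts per cell.
#' @param breaks Age-band lower bounds passed to [age_band()].
#' @param tol Relative convergence tolerance on every margin cell.
#' @param max_iter Sweep cap.
#' @return `pop` with `weight` replaced by the raked weights.
#' @export
rake_weights <- function(pop, target_margins, breaks = c(35, 45, 55, 65, 75, 85),
                         tol = 1e-10, max_iter = 100L) {
  pop$age_band <- age_band(pop$age_months / 12, breaks)
  cell <- paste(pop$age_band, pop$sex)
  tgt_cell <- paste(target_margins$age_band, target_margins$sex)
  if (any(!cell %in% tgt_cell)) {
    .stopf("margins do not cover cell(s): %s",
           paste(utils::head(unique(cell[!cell %in% tgt_cell]), 3),
                 collapse = ", "))
  }
  target <- target_margins$count
  names(target) <- tgt_cell
  occupied <- tgt_cell %in% cell
  if (any(target[!occupied] > 0)) {
    .stopf("empty sample cell with non-zero target margin: %s",
           paste(utils::head(tgt_cell[!occupied & target > 0], 3),
                 collapse = ", "))
  }
  # with a full age-band x sex cross-classification IPF reduces to direct
  # cell post-stratification, reached in one sweep; the loop guards tol
  w <- pop$weight
  for (iter in seq_len(max_iter)) {
    tot <- tapply(w, cell, sum)
    ratio <- target[names(tot)] / tot
    w <- w * ratio[cell]
    tot <- tapply(w, cell, sum)
    err <- max(abs(tot - target[names(tot)]) / pmax(target[names(tot)], 1))
    if (err < tol) break
  }
  pop$weight <- as.numeric(w)
  pop$age_band <- NULL
  pop
}

#' Build the simulation base population
#'
#' Pools the study extracts with their study-specific weights, rakes the
#' pooled weights to the target age-band by sex population margins, clones
#' each row `round(weight)` times (round-half-to-even) so that all
#' individuals carry unit weights, and finally draws a simple random sample
#' of `round(sampling_fraction * clones)` rows. The returned individuals all
#' have `weight == 1`; the implied scaling factor back to population units
#' is `1 / sampling_fraction`.
#'
#' @param extracts List of `study_extract` objects.
#' @param target_margins Data.frame `age_band`, `sex`, `count` (see
#'   [rake_weights()]; [default_margins()] supplies a synthetic schedule).
#' @param sampling_fraction Fraction in (0, 1] of the cloned rows to keep.
#' @param seed Integer seed for the subsample.
#' @param breaks Age-band lower bounds.
#' @return Data.frame of individual states with unit weights and fresh ids;
#'   attribute `scaling_factor` gives the population multiplier.
#' @export
build_base_population <- function(extracts, target_margins,
                                  sampling_fraction = 0.01, seed = 1L,
                                  breaks = c(35, 45, 55, 65, 75, 85)) {
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    .stopf("sampling_fraction must be in (0, 1]")
  }
  pooled <- pool_extracts(extracts)
  raked <- rake_weights(pooled, target_margins, breaks)
  reps <- pmax(.round_even(raked$weight), 0L)
  idx <- rep.int(seq_len(nrow(raked)), reps)
  set.seed(seed)
  m <- .round_even(sampling_fraction * length(idx))
  take <- if (m >= length(idx)) idx else idx[sample.int(length(idx), m)]
  out <- raked[take, , drop = FALSE]
  out$weight <- 1
  out$id <- sprintf("ind_%06d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "scaling_factor") <- 1 / sampling_fraction
  out
}

#' Synthetic age-band by sex population margins
#'
#' A smooth, demographically plausible age-sex schedule (exponentially
#' declining with age, with a female surplus growing at older ages) used as
#' the default raking target.
#'
#' @param total Total population across all cells.
#' @param breaks Age-band lower bounds.
#' @return Data.frame with `age_band`, `sex`, `count`.
#' @export
default_margins <- function(total = 3e6, breaks = c(35, 45, 55, 65, 75, 85)) {
  ages <- 35:99
  dens <- exp(-0.018 * (ages - 35))
  band <- age_band(ages, breaks)
  female_share <- .plogis(0.0 + 0.010 * (ages - 65))
  per_age <- dens / sum(dens) * total
  df <- rbind(
    data.frame(age_band = band, sex = "female", count = per_age * female_share),
    data.frame(age_band = band, sex = "male", count = per_age * (1 - female_share))
  )
  agg <- stats::aggregate(count ~ age_band + sex, df, sum)
  agg[order(agg$sex, agg$age_band), ]
}
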