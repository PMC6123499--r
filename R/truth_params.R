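#' Registry of stochastic characteristic transitions
#'
#' Every stochastic characteristic (all except age, sex, education and
#' occupation) is advanced by one or more adjacent-step transition models.
#' Ordered characteristics (cognition, sensory impairments, physical
#' dependency, body-mass class, physical activity) move one severity step at
#' a time; recovery models take a state to the next less severe category.
#' Chronic diseases are absorbing except depression, which has a recovery
#' model, matching the set of characteristics for which recovery is
#' modelled: low/medium/high physical dependency, mild and moderate
#' cognitive impairment, depression, and visual and hearing impairment.
#'
#' @return A data.frame with one row per transition model: `characteristic`,
#'   `from`, `to`, `direction` (`"incidence"` for onset/worsening,
#'   `"recovery"` for improvement), and `key` (unique label
#'   `characteristic:from>to`).
#' @export
transition_registry <- function() {
  r <- rbind(
    c("smoking", "never", "current", "incidence"),
    c("smoking", "current", "former", "recovery"),
    c("smoking", "former", "current", "incidence"),
    c("bmi_class", "normal", "overweight", "incidence"),
    c("bmi_class", "overweight", "obese", "incidence"),
    c("bmi_class", "obese", "overweight", "recovery"),
    c("bmi_class", "overweight", "normal", "recovery"),
    c("physical_activity", "high", "medium", "incidence"),
    c("physical_activity", "medium", "low", "incidence"),
    c("physical_activity", "low", "medium", "recovery"),
    c("physical_activity", "medium", "high", "recovery"),
    c("chd", "FALSE", "TRUE", "incidence"),
    c("stroke", "FALSE", "TRUE", "incidence"),
    c("hypertension", "FALSE", "TRUE", "incidence"),
    c("diabetes", "FALSE", "TRUE", "incidence"),
    c("arthritis", "FALSE", "TRUE", "incidence"),
    c("cancer", "FALSE", "TRUE", "incidence"),
    c("respiratory", "FALSE", "TRUE", "incidence"),
    c("depression", "FALSE", "TRUE", "incidence"),
    c("depression", "TRUE", "FALSE", "recovery"),
    c("vision_impairment", "none", "some", "incidence"),
    c("vision_impairment", "some", "severe", "incidence"),
    c("vision_impairment", "some", "none", "recovery"),
    c("vision_impairment", "severe", "some", "recovery"),
    c("hearing_impairment", "none", "some", "incidence"),
    c("hearing_impairment", "some", "severe", "incidence"),
    c("hearing_impairment", "some", "none", "recovery"),
    c("hearing_impairment", "severe", "some", "recovery"),
    c("cognition", "normal", "mild", "incidence"),
    c("cognition", "mild", "moderate", "incidence"),
    c("cognition", "moderate", "severe", "incidence"),
    c("cognition", "mild", "normal", "recovery"),
    c("cognition", "moderate", "mild", "recovery"),
    c("physical_dependency", "independent", "low", "incidence"),
    c("physical_dependency", "low", "medium", "incidence"),
    c("physical_dependency", "medium", "high", "incidence"),
    c("physical_dependency", "low", "independent", "recovery"),
    c("physical_dependency", "medium", "low", "recovery"),
    c("physical_dependency", "high", "medium", "recovery")
  )
  out <- data.frame(characteristic = r[, 1], from = r[, 2], to = r[, 3],
                    direction = r[, 4], stringsAsFactors = FALSE)
  out$key <- paste0(out$characteristic, ":", out$from, ">", out$to)
  out
}

#' Names of the eight chronic diseases tracked per individual
#' @return Character vector of disease column names.
#' @export
disease_names <- function() {
  c("chd", "stroke", "hypertension", "diabetes", "arthritis", "cancer",
    "respiratory", "depression")
}

# covariate registry: name -> function(pop) giving a numeric vector.
# Age enters in years centred at 65; cognition dummies come from the MMSE.
.covariate_registry <- function() {
  dis <- disease_names()
  base <- list(
    age_c = function(p) p$age_months / 12 - 65,
    age_c2 = function(p) (p$age_months / 12 - 65)^2 / 100,
    sex_male = function(p) as.numeric(p$sex == "male"),
    n_diseases = function(p) {
      rowSums(as.matrix(as.data.frame(p[disease_names()])))
    },
    cog_mild = function(p) as.numeric(categorise_mmse(p$mmse) == "mild"),
    cog_moderate = function(p) {
      as.numeric(categorise_mmse(p$mmse) == "moderate")
    },
    smoking_current = function(p) as.numeric(p$smoking == "current"),
    bmi_obese = function(p) as.numeric(p$bmi_class == "obese"),
    pa_low = function(p) as.numeric(p$physical_activity == "low"),
    vision_any = function(p) as.numeric(p$vision_impairment != "none"),
    hearing_any = function(p) as.numeric(p$hearing_impairment != "none")
  )
  for (d in dis) {
    base[[d]] <- local({
      dd <- d
      function(p) as.numeric(p[[dd]])
    })
  }
  base
}

#' Build covariate columns from an individual-state table
#'
#' @param pop Data.frame of individual states (see [generate_study_extract()]).
#' @param covariates Character vector of covariate names from the registry
#'   (`age_c`, `age_c2`, `sex_male`, `n_diseases`, `cog_mild`,
#'   `cog_moderate`, `smoking_current`, `bmi_obese`, `pa_low`, `vision_any`,
#'   `hearing_any`, and each disease indicator).
#' @return Numeric matrix with one column per covariate.
#' @export
build_covariates <- function(pop, covariates) {
  reg <- .covariate_registry()
  unknown <- setdiff(covariates, names(reg))
  if (length(unknown)) {
    .stopf("unknown covariate(s): %s", paste(unknown, collapse = ", "))
  }
  m <- vapply(covariates, function(nm) reg[[nm]](pop), numeric(nrow(pop)))
  if (nrow(pop) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, covariates))
  colnames(m) <- covariates
  m
}

# default ground-truth biennial transition logits. Each entry is a named
# coefficient vector; the linear predictor is (Intercept) + sum(coef * cov).
.default_transition_truth <- function() {
  co <- function(p0, age, male, ndis = NULL) {
    v <- c(stats::qlogis(p0), age, male)
    names(v) <- c("(Intercept)", "age_c", "sex_male")
    if (!is.null(ndis)) v <- c(v, n_diseases = ndis)
    v
  }
  list(
    "smoking:never>current" = co(0.010, -0.020, 0.20),
    "smoking:current>former" = co(0.150, 0.020, 0.00),
    "smoking:former>current" = co(0.050, -0.010, 0.00),
    "bmi_class:normal>overweight" = co(0.150, -0.010, 0.10),
    "bmi_class:overweight>obese" = co(0.080, -0.010, -0.10),
    "bmi_class:obese>overweight" = co(0.080, 0.010, 0.00),
    "bmi_class:overweight>normal" = co(0.060, 0.010, 0.00),
    "physical_activity:high>medium" = co(0.120, 0.040, -0.10),
    "physical_activity:medium>low" = co(0.100, 0.050, -0.10),
    "physical_activity:low>medium" = co(0.100, -0.030, 0.10),
    "physical_activity:medium>high" = co(0.080, -0.030, 0.10),
    "chd:FALSE>TRUE" = co(0.020, 0.050, 0.30),
    "stroke:FALSE>TRUE" = co(0.015, 0.060, 0.25),
    "hypertension:FALSE>TRUE" = co(0.080, 0.030, 0.10),
    "diabetes:FALSE>TRUE" = co(0.030, 0.030, 0.20),
    "arthritis:FALSE>TRUE" = co(0.060, 0.040, -0.30),
    "cancer:FALSE>TRUE" = co(0.025, 0.050, 0.15),
    "respiratory:FALSE>TRUE" = co(0.020, 0.020, 0.10),
    "depression:FALSE>TRUE" = co(0.050, 0.000, -0.30),
    "depression:TRUE>FALSE" = co(0.300, -0.010, 0.10),
    "vision_impairment:none>some" = co(0.040, 0.060, -0.10),
    "vision_impairment:some>severe" = co(0.050, 0.050, 0.00),
    "vision_impairment:some>none" = co(0.150, -0.020, 0.00),
    "vision_impairment:severe>some" = co(0.080, -0.020, 0.00),
    "hearing_impairment:none>some" = co(0.050, 0.060, 0.30),
    "hearing_impairment:some>severe" = co(0.050, 0.050, 0.10),
    "hearing_impairment:some>none" = co(0.120, -0.020, 0.00),
    "hearing_impairment:severe>some" = co(0.070, -0.020, 0.00),
    "cognition:normal>mild" = co(0.060, 0.070, 0.00),
    "cognition:mild>moderate" = co(0.080, 0.080, 0.00),
    "cognition:moderate>severe" = co(0.120, 0.080, 0.00),
    "cognition:mild>normal" = co(0.250, -0.030, 0.00),
    "cognition:moderate>mild" = co(0.100, -0.030, 0.00),
    "physical_dependency:independent>low" = co(0.050, 0.070, -0.20, 0.25),
    "physical_dependency:low>medium" = co(0.070, 0.070, -0.10, 0.20),
    "physical_dependency:medium>high" = co(0.100, 0.060, 0.00, 0.20),
    "physical_dependency:low>independent" = co(0.200, -0.040, 0.20),
    "physical_dependency:medium>low" = co(0.120, -0.040, 0.20),
    "physical_dependency:high>medium" = co(0.070, -0.030, 0.10)
  )
}

# baseline prevalence gradients (logit scale, age in years). Each binary or
# top-category probability is plogis(b0 + b_age * (age - ref) + b_male*male).
.default_prevalence <- function() {
  g <- function(b0, b_age, b_male = 0, ref = 35) {
    c(b0 = b0, b_age = b_age, b_male = b_male, ref = ref)
  }
  list(
    female = g(0.00, 0.010, ref = 65),
    education_high = g(0.60, -0.030),
    education_mid = g(0.20, -0.010),
    occupation_non_manual = g(0.20, 0.000),
    smoking_current = g(-0.80, -0.030, 0.20, ref = 50),
    smoking_former = g(-1.00, 0.030, 0.20, ref = 40),
    bmi_obese = g(-1.30, 0.010, 0.00, ref = 50),
    bmi_overweight = g(-0.40, 0.005, 0.20, ref = 50),
    pa_low = g(-2.00, 0.050, -0.10, ref = 65),
    pa_high = g(-0.50, -0.030, 0.10, ref = 65),
    chd = g(-5.00, 0.070, 0.40),
    stroke = g(-5.50, 0.070, 0.25),
    hypertension = g(-3.00, 0.060, 0.10),
    diabetes = g(-4.00, 0.050, 0.20),
    arthritis = g(-3.20, 0.060, -0.40),
    cancer = g(-4.50, 0.050, 0.10),
    respiratory = g(-3.30, 0.020, 0.10),
    depression = g(-2.00, 0.005, -0.40),
    vision_some = g(-3.50, 0.050, -0.10),
    vision_severe = g(-6.00, 0.070, 0.00),
    hearing_some = g(-3.50, 0.060, 0.30),
    hearing_severe = g(-6.00, 0.080, 0.20),
    cog_mild = g(-4.00, 0.060, 0.00),
    cog_moderate = g(-7.00, 0.080, 0.00),
    cog_severe = g(-9.00, 0.090, 0.00),
    dep_low = g(-3.50, 0.060, -0.20),
    dep_medium = g(-6.00, 0.070, -0.10),
    dep_high = g(-6.50, 0.070, 0.00),
    care_home = g(-8.00, 0.100, -0.20)
  )
}

#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles everything needed to simulate, with known truth, what the real
#' pooled longitudinal studies would provide: age-sex baseline prevalence
#' gradients for every characteristic, biennial transition logits for every
#' model in [transition_registry()], an attrition model, sampling-weight and
#' age-structure parameters, and the Gompertz-Makeham mortality schedule
#' behind the synthetic lifetable. The object is plain (named numeric
#' vectors only) so that it serialises losslessly to JSON beside each
#' generated dataset, enabling parameter-recovery tests.
#'
#' @param override Optional named list merged over the defaults (deep merge);
#'   e.g. `truth_params(list(attrition = list(rate = 0)))`.
#' @return An object of class `truth_params`: a list with elements
#'   `prevalence`, `transitions`, `attrition` (`rate`, 2-year loss
#'   probability, and `age_slope` on the logit), `weights` (`meanlog`,
#'   `sdlog` of the lognormal sampling weights), `ages` (`min`, `max`,
#'   `decay` of the exponential age density), `mortality` (Gompertz-Makeham
#'   `a_male`, `a_female`, `b`, `c`), and `dementia` (allocation-table
#'   gradients).
#' @export
truth_params <- function(override = NULL) {
  p <- list(
    prevalence = .default_prevalence(),
    transitions = .default_transition_truth(),
    attrition = list(rate = 0.15, age_slope = 0.01),
    weights = list(meanlog = 0, sdlog = 0.5),
    ages = list(min = 35, max = 99, decay = 0.018),
    mortality = list(a_male = 7.5e-4, a_female = 5.25e-4, b = 0.095,
                     c = 2e-4),
    dementia = list(base = -4.0, age_step = 0.9, severity_step = 1.6,
                    care_home = 0.8)
  )
  p <- .merge_params(p, override)
  .validate_truth(p)
  structure(p, class = "truth_params")
}

.validate_truth <- function(p) {
  reg <- transition_registry()
  missing <- setdiff(reg$key, names(p$transitions))
  if (length(missing)) {
    .stopf("truth params missing transition(s): %s",
           paste(utils::head(missing, 4), collapse = ", "))
  }
  for (k in names(p$transitions)) {
    v <- p$transitions[[k]]
    if (!is.numeric(v) || is.null(names(v)) || !"(Intercept)" %in% names(v)) {
      .stopf("transition '%s' must be a named numeric vector with (Intercept)", k)
    }
  }
  if (p$attrition$rate < 0 || p$attrition$rate >= 1) {
    .stopf("attrition rate must be in [0,1)")
  }
  if (p$mortality$b <= 0) .stopf("Gompertz slope must be > 0")
  invisible(p)
}

# evaluate a prevalence gradient at given ages/sex
.prev_p <- function(gr, age_years, male) {
  .plogis(gr["b0"] + gr["b_age"] * (age_years - gr["ref"]) +
            gr["b_male"] * male)
}
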