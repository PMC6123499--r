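#' Convert a biennial probability to the monthly scale
#'
#' Under a constant hazard within the 2-year window, the monthly transition
#' probability m satisfies \eqn{1 - (1 - m)^{24} = p}; this returns
#' \eqn{m = 1 - (1 - p)^{1/24}}. Vectorised.
#'
#' @param p_biennial Probability (or vector) in \[0, 1\] over two years.
#' @return Monthly probability in \[0, 1\].
#' @export
biennial_to_monthly <- function(p_biennial) {
  if (any(is.na(p_biennial)) || any(p_biennial < 0 | p_biennial > 1)) {
    .stopf("biennial probability must be in [0, 1]")
  }
  1 - (1 - p_biennial)^(1 / 24)
}

#' Convert an annual survival probability to the monthly scale
#'
#' Returns \eqn{s^{1/12}}, so that twelve consecutive monthly survivals
#' compound exactly to the annual probability. Vectorised.
#'
#' @param s_annual Annual survival probability (or vector) in (0, 1\].
#' @return Monthly survival probability in (0, 1\].
#' @export
annual_survival_to_monthly <- function(s_annual) {
  if (any(is.na(s_annual)) || any(s_annual <= 0 | s_annual > 1)) {
    .stopf("annual survival must be in (0, 1]")
  }
  s_annual^(1 / 12)
}

#' Default covariate lists per characteristic
#'
#' Age (years, centred at 65), its square (scaled by 100) and sex enter
#' every model. Physical-dependency models additionally take the chronic
#' disease count, cognitive impairment, physical inactivity, obesity and
#' sensory impairment - the disease and sociodemographic risk-factor set
#' for dependency transitions.
#'
#' @return Named list: `default` plus per-characteristic overrides.
#' @export
default_covariate_config <- function() {
  list(
    default = c("age_c", "age_c2", "sex_male"),
    physical_dependency = c("age_c", "age_c2", "sex_male", "n_diseases",
                            "cog_mild", "cog_moderate", "pa_low",
                            "bmi_obese", "vision_any", "hearing_any")
  )
}

# covariates for one characteristic/direction under a config; recovery
# models keep the core set only
.covariates_for <- function(config, characteristic, direction) {
  if (direction == "recovery") return(config$default)
  config[[characteristic]] %||% config$default
}

# at-risk rows of the pooled panel for one transition: baseline in
# from-state with follow-up observed; outcome = reached to-state
.panel_at_risk <- function(panel, characteristic, from, to) {
  rows <- lapply(panel, function(e) {
    b <- e$baseline
    f <- e$followup
    m <- match(b$id, f$id)
    seen <- !is.na(m)
    b <- b[seen, , drop = FALSE]
    f <- f[m[seen], , drop = FALSE]
    cur <- if (characteristic == "cognition") categorise_mmse(b$mmse)
           else as.character(b[[characteristic]])
    nxt <- if (characteristic == "cognition") categorise_mmse(f$mmse)
           else as.character(f[[characteristic]])
    at <- cur == from
    b <- b[at, , drop = FALSE]
    b$.outcome <- as.numeric(nxt[at] == to)
    b$study <- e$study_label
    b
  })
  do.call(rbind, rows)
}

#' Fit one transition model from two-wave panel data
#'
#' Weighted logistic regression of the 2-year state change on baseline
#' covariates, pooling the study extracts with their study-specific
#' weights (normalised to mean one, making the fit invariant to uniform
#' weight rescaling). Age and sex are always included. Individuals lost to
#' follow-up are censored. Dementia is never a covariate.
#'
#' @param panel List of `study_extract` objects (or one).
#' @param characteristic Characteristic name, e.g. `"stroke"`,
#'   `"physical_dependency"`, `"cognition"`.
#' @param from,to Baseline and target states of the modelled step (see
#'   [transition_registry()]).
#' @param covariates Character vector of covariate names; defaults come
#'   from [default_covariate_config()].
#' @param min_at_risk Minimum number of at-risk individuals.
#' @return Object of class `transition_model`: coefficients and standard
#'   errors on the logit (biennial) scale, covariate list, direction, and
#'   fit metadata (`n`, `events`).
#' @export
fit_transition_model <- function(panel, characteristic, from, to,
                                 covariates = NULL, min_at_risk = 50L) {
  if (inherits(panel, "study_extract")) panel <- list(panel)
  reg <- transition_registry()
  hit <- reg[reg$characteristic == characteristic & reg$from == from &
               reg$to == to, ]
  direction <- if (nrow(hit)) hit$direction else "incidence"
  if (is.null(covariates)) {
    covariates <- .covariates_for(default_covariate_config(), characteristic,
                                  direction)
  }
  if (any(grepl("dementia", covariates))) {
    .stopf("dementia may not be a covariate of transition models")
  }
  d <- .panel_at_risk(panel, characteristic, from, to)
  if (is.null(d) || nrow(d) < min_at_risk) {
    .stopf("too few at-risk individuals (%d) for %s:%s>%s",
           if (is.null(d)) 0L else nrow(d), characteristic, from, to)
  }
  ev <- sum(d$.outcome)
  if (ev == 0 || ev == nrow(d)) {
    .stopf("zero-event (or all-event) transition for %s:%s>%s: cannot estimate",
           characteristic, from, to)
  }
  X <- build_covariates(d, covariates)
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    .stopf("covariate(s) constant over the at-risk panel for %s:%s>%s: %s",
           characteristic, from, to,
           paste(colnames(X)[const], collapse = ", "))
  }
  w <- d$weight / mean(d$weight)
  df <- data.frame(.outcome = d$.outcome, X, check.names = FALSE)
  fml <- stats::as.formula(paste(".outcome ~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::quasibinomial(), data = df, weights = w)
  )
  beta <- stats::coef(fit)
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    .stopf("estimation failed (possible separation) for %s:%s>%s",
           characteristic, from, to)
  }
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(characteristic = characteristic, from = from, to = to,
                 direction = direction, coefficients = beta, se = se,
                 covariates = covariates, n = nrow(d), events = ev),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model %s:%s>%s (%s), n=%d, events=%d>\n",
              x$characteristic, x$from, x$to, x$direction, x$n, x$events))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit every registry transition model
#'
#' @param panel List of `study_extract` objects.
#' @param covariate_config See [default_covariate_config()].
#' @param min_at_risk Minimum at-risk individuals per model.
#' @return Object of class `transition_model_set`: named list of
#'   [fit_transition_model()] results keyed `characteristic:from>to`.
#' @export
fit_transition_models <- function(panel, covariate_config = default_covariate_config(),
                                  min_at_risk = 50L) {
  reg <- transition_registry()
  out <- vector("list", nrow(reg))
  names(out) <- reg$key
  for (i in seq_len(nrow(reg))) {
    covs <- .covariates_for(covariate_config, reg$characteristic[i],
                            reg$direction[i])
    out[[i]] <- fit_transition_model(panel, reg$characteristic[i],
                                     reg$from[i], reg$to[i], covs,
                                     min_at_risk)
  }
  structure(out, class = "transition_model_set")
}

#' Build a transition model from known coefficients
#'
#' Constructs a `transition_model` directly from a coefficient vector on
#' the biennial logit scale, bypassing estimation - used for toy
#' configurations and for simulating from ground truth.
#'
#' @param characteristic,from,to As in [fit_transition_model()].
#' @param coefficients Named numeric vector including `"(Intercept)"`.
#' @param direction `"incidence"` or `"recovery"`.
#' @return A `transition_model`.
#' @export
make_transition_model <- function(characteristic, from, to, coefficients,
                                  direction = "incidence") {
  if (!"(Intercept)" %in% names(coefficients)) {
    .stopf("coefficients must include (Intercept)")
  }
  structure(list(characteristic = characteristic, from = from, to = to,
                 direction = direction, coefficients = coefficients,
                 se = rep(NA_real_, length(coefficients)),
                 covariates = setdiff(names(coefficients), "(Intercept)"),
                 n = NA_integer_, events = NA_integer_),
            class = "transition_model")
}

#' Monthly transition probability for individual states
#'
#' Evaluates the model's linear predictor on the state(s), inverse-logit to
#' the biennial probability, then rescales to the monthly probability used
#' by the simulation engine via [biennial_to_monthly()].
#'
#' @param model A `transition_model`.
#' @param state Data.frame of one or more individual states.
#' @return Numeric vector of monthly probabilities in \[0, 1\].
#' @export
predict_transition <- function(model, state) {
  beta <- model$coefficients
  covs <- setdiff(names(beta), "(Intercept)")
  lp <- rep(beta[["(Intercept)"]], nrow(state))
  if (length(covs)) {
    X <- build_covariates(state, covs)
    lp <- lp + as.vector(X %*% beta[covs])
  }
  biennial_to_monthly(.plogis(lp))
}

#' Serialise / restore a transition model set as JSON
#'
#' @param models A `transition_model_set` (or plain list of
#'   `transition_model`s).
#' @param path File path.
#' @return `read_models` returns the `transition_model_set`;
#'   `write_models` returns `path` invisibly.
#' @export
write_models <- function(models, path) {
  doc <- lapply(models, function(m) {
    list(characteristic = m$characteristic, from = m$from, to = m$to,
         direction = m$direction,
         coefficients = as.list(m$coefficients),
         se = as.list(m$se), covariates = m$covariates,
         n = m$n, events = m$events)
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  doc <- jsonlite::read_json(path)
  out <- lapply(doc, function(m) {
    structure(list(characteristic = m$characteristic, from = m$from,
                   to = m$to, direction = m$direction,
                   coefficients = unlist(m$coefficients),
                   se = vapply(m$se, function(x) {
                     if (is.null(x)) NA_real_ else as.numeric(x)
                   }, numeric(1)),
                   covariates = as.character(unlist(m$covariates)),
                   n = m$n %||% NA_integer_,
                   events = m$events %||% NA_integer_),
              class = "transition_model")
  })
  names(out) <- names(doc)
  structure(out, class = "transition_model_set")
}
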