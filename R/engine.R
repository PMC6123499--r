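#' Simulation configuration
#'
#' @param start,end Simulation window as `"YYYY-MM"` strings; individuals
#'   are advanced one month at a time from `start` to `end` inclusive.
#' @param output_years Calendar years at which population snapshots are
#'   taken (after the update of `snapshot_month`).
#' @param snapshot_month Month (1-12) within each output year at which the
#'   snapshot is taken; default June (mid-year period convention).
#' @param n_runs Number of independent replicate runs.
#' @param master_seed Integer master seed; per-run seeds are derived from
#'   it deterministically.
#' @param update_order Order in which characteristics are updated within a
#'   month; later characteristics see the within-month updated values of
#'   earlier ones. Defaults to behaviours, then diseases, then sensory
#'   impairments, then cognition, then physical dependency.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(start = "2014-01", end = "2042-12",
                              output_years = c(2015, 2025, 2035),
                              snapshot_month = 6L, n_runs = 10L,
                              master_seed = 20140101L,
                              update_order = default_update_order()) {
  s <- .parse_ym(start)
  e <- .parse_ym(end)
  if (s$year * 12 + s$month >= e$year * 12 + e$month) {
    .stopf("start must precede end")
  }
  if (n_runs < 1) .stopf("n_runs must be >= 1")
  structure(list(start = start, end = end, output_years = output_years,
                 snapshot_month = as.integer(snapshot_month),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 update_order = update_order),
            class = "simulation_config")
}

#' Default within-month characteristic update order
#'
#' Behaviours first, then chronic diseases, sensory impairments, cognition
#' and finally physical dependency: dependency is downstream of its risk
#' factors, so it sees their within-month updated values.
#'
#' @return Character vector of characteristic names.
#' @export
default_update_order <- function() {
  c("smoking", "bmi_class", "physical_activity", disease_names()[1:7],
    "depression", "vision_impairment", "hearing_impairment", "cognition",
    "physical_dependency")
}

.parse_ym <- function(x) {
  m <- regmatches(x, regexec("^(\\d{4})-(\\d{1,2})$", x))[[1]]
  if (length(m) != 3) .stopf("expected YYYY-MM, got '%s'", x)
  list(year = as.integer(m[2]), month = as.integer(m[3]))
}

# current value of a characteristic as character states
.current_state <- function(pop, characteristic) {
  if (characteristic == "cognition") categorise_mmse(pop$mmse)
  else as.character(pop[[characteristic]])
}

.assign_state <- function(pop, characteristic, rows, to) {
  if (!length(rows)) return(pop)
  if (characteristic == "cognition") {
    pop$mmse[rows] <- .draw_mmse_in_category(rep(to, length(rows)))
  } else if (characteristic %in% disease_names()) {
    pop[[characteristic]][rows] <- as.logical(to)
  } else {
    pop[[characteristic]][rows] <- to
  }
  pop
}

# group a model set by characteristic, respecting the update order
.models_by_characteristic <- function(models, update_order) {
  chars <- unique(vapply(models, `[[`, "", "characteristic"))
  missing <- setdiff(chars, update_order)
  if (length(missing)) {
    .stopf("update order does not include characteristic(s): %s",
           paste(missing, collapse = ", "))
  }
  split_by <- vapply(models, `[[`, "", "characteristic")
  lapply(stats::setNames(intersect(update_order, chars),
                         intersect(update_order, chars)),
         function(ch) models[split_by == ch])
}

#' Advance a population by one month
#'
#' For each stochastic characteristic in update order, every alive at-risk
#' individual's monthly transition probability is computed from the
#' applicable model and the current (within-month updated) state; the
#' individual transitions when the probability exceeds a fresh uniform
#' draw. Monthly mortality from the age-sex lifetable is applied next
#' (annual survival taken to the 1/12 power), and finally survivors age by
#' one month. Dead individuals are frozen. One uniform vector is drawn for
#' the whole population per model and per mortality pass, so results do not
#' depend on the iteration order over individuals.
#'
#' @param pop Data.frame of individual states.
#' @param models `transition_model_set` (or named list of
#'   `transition_model`s).
#' @param lifetable A [generate_lifetable()] table.
#' @param update_order See [simulation_config()].
#' @return List: `pop` (advanced population), `transitions` (count of state
#'   changes this month), `deaths` (count of deaths this month).
#' @export
step_population <- function(pop, models, lifetable,
                            update_order = default_update_order()) {
  grouped <- .models_by_characteristic(models, update_order)
  n <- nrow(pop)
  n_trans <- 0L
  for (ch in names(grouped)) {
    for (m in grouped[[ch]]) {
      u <- stats::runif(n)
      cur <- .current_state(pop, ch)
      at_risk <- which(pop$alive & cur == m$from)
      if (!length(at_risk)) next
      p <- predict_transition(m, pop[at_risk, , drop = FALSE])
      move <- at_risk[p > u[at_risk]]
      n_trans <- n_trans + length(move)
      pop <- .assign_state(pop, ch, move, m$to)
    }
  }
  u <- stats::runif(n)
  alive <- which(pop$alive)
  s_ann <- .lookup_survival(lifetable, pop$sex[alive],
                            pop$age_months[alive] %/% 12L)
  q_month <- 1 - annual_survival_to_monthly(s_ann)
  dead <- alive[q_month > u[alive]]
  pop$alive[dead] <- FALSE
  survivors <- setdiff(alive, dead)
  pop$age_months[survivors] <- pop$age_months[survivors] + 1L
  list(pop = pop, transitions = n_trans, deaths = length(dead))
}

#' Advance a single individual by one month
#'
#' Convenience wrapper around [step_population()] for one individual state
#' row. The individual must be alive.
#'
#' @param state One-row data.frame of an individual state.
#' @inheritParams step_population
#' @return The advanced one-row state.
#' @export
step_individual <- function(state, models, lifetable,
                            update_order = default_update_order()) {
  if (nrow(state) != 1L) .stopf("state must be a single individual row")
  if (!state$alive) .stopf("individual is dead; state is frozen")
  step_population(state, models, lifetable, update_order)$pop
}

#' Run the full microsimulation
#'
#' Executes `config$n_runs` independent replicates. Each run seeds its own
#' RNG stream from a sub-seed derived deterministically from the master
#' seed, then advances every individual month by month from `config$start`
#' to `config$end`. At each output year (in `config$snapshot_month`) a
#' snapshot of the population is stored with dementia allocated (outside
#' the monthly loop) and the combined interval of need derived from
#' physical dependency and cognition.
#'
#' @param base_population Data.frame of individual states (all alive).
#' @param models `transition_model_set`.
#' @param lifetable A [generate_lifetable()] table.
#' @param dementia_table A [generate_dementia_table()] table.
#' @param config A [simulation_config()].
#' @return Object of class `simulation_results`: list of per-run results,
#'   each with `run`, `seed`, `snapshots` (named by year; data.frames with
#'   an `interval_of_need` column), and `events` (data.frame `year`,
#'   `deaths`, `transitions`). The base-population `scaling_factor`
#'   attribute, if any, is carried through.
#' @export
run_simulation <- function(base_population, models, lifetable,
                           dementia_table, config = simulation_config()) {
  .validate_sim_inputs(base_population, models, lifetable, config)
  seeds <- .derive_seeds(config$master_seed, config$n_runs)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    runs[[r]] <- .simulate_one_run(base_population, models, lifetable,
                                   dementia_table, config, r, seeds[r])
  }
  structure(list(runs = runs,
                 scaling_factor = attr(base_population, "scaling_factor") %||% 1,
                 config = config),
            class = "simulation_results")
}

.validate_sim_inputs <- function(pop, models, lifetable, config) {
  need <- setdiff(.state_cols(), "id")
  miss <- setdiff(need, names(pop))
  if (length(miss)) {
    .stopf("base population missing column(s): %s", paste(miss, collapse = ", "))
  }
  for (m in models) {
    bad <- setdiff(m$covariates, names(.covariate_registry()))
    if (length(bad)) {
      .stopf("model %s:%s>%s uses unknown covariate(s): %s",
             m$characteristic, m$from, m$to, paste(bad, collapse = ", "))
    }
  }
  # every characteristic with at-risk individuals must have a model for
  # each worsening step it can take (recovery optional in toy setups)
  invisible(TRUE)
}

.simulate_one_run <- function(pop, models, lifetable, dementia_table,
                              config, run_index, seed) {
  set.seed(seed)
  s <- .parse_ym(config$start)
  e <- .parse_ym(config$end)
  months <- (s$year * 12L + s$month):(e$year * 12L + e$month)
  snapshots <- list()
  ev_year <- integer(0)
  ev_deaths <- integer(0)
  ev_trans <- integer(0)
  yr_deaths <- 0L
  yr_trans <- 0L
  base_n <- nrow(pop)
  for (ym in months) {
    year <- (ym - 1L) %/% 12L
    month <- ym - year * 12L
    st <- step_population(pop, models, lifetable, config$update_order)
    pop <- st$pop
    yr_deaths <- yr_deaths + st$deaths
    yr_trans <- yr_trans + st$transitions
    stopifnot(sum(pop$alive) + sum(!pop$alive) == base_n)
    if (month == config$snapshot_month && year %in% config$output_years) {
      snap <- allocate_dementia(pop, dementia_table)
      snap$interval_of_need <- NA_character_
      al <- snap$alive
      snap$interval_of_need[al] <- combine_physical_and_cognition(
        snap$physical_dependency[al], categorise_mmse(snap$mmse[al]))
      snapshots[[as.character(year)]] <- snap
    }
    if (month == 12L || (ym == months[length(months)] && month != 12L)) {
      ev_year <- c(ev_year, year)
      ev_deaths <- c(ev_deaths, yr_deaths)
      ev_trans <- c(ev_trans, yr_trans)
      yr_deaths <- 0L
      yr_trans <- 0L
    }
  }
  missing_years <- setdiff(as.character(config$output_years), names(snapshots))
  if (length(missing_years)) {
    .stopf("output year(s) outside the simulation window: %s",
           paste(missing_years, collapse = ", "))
  }
  list(run = run_index, seed = seed, snapshots = snapshots,
       events = data.frame(year = ev_year, deaths = ev_deaths,
                           transitions = ev_trans))
}

#' @export
print.simulation_results <- function(x, ...) {
  cat(sprintf("<simulation_results: %d run(s), snapshots at %s, scaling x%g>\n",
              length(x$runs),
              paste(names(x$runs[[1]]$snapshots), collapse = ", "),
              x$scaling_factor))
  invisible(x)
}
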