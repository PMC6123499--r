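# model set whose transitions never fire
null_models <- function() {
  list(make_transition_model("depression", "FALSE", "TRUE",
                             c("(Intercept)" = -40)))
}

test_that("with no transitions and full survival only age advances", {
  pop <- toy_population(5, age_years = 70)
  set.seed(1)
  st <- step_population(pop, null_models(), const_lifetable(0))
  out <- st$pop
  expect_equal(out$age_months, pop$age_months + 1L)
  expect_equal(st$deaths, 0L)
  expect_equal(st$transitions, 0L)
  out$age_months <- pop$age_months
  expect_identical(out, pop)
})

test_that("certain death freezes every field", {
  pop <- toy_population(20, age_years = 80)
  lt <- const_lifetable(0)
  lt$survival <- .Machine$double.xmin
  set.seed(2)
  st <- step_population(pop, null_models(), lt)
  expect_true(all(!st$pop$alive))
  expect_equal(st$deaths, 20L)
  # a further step leaves the dead untouched, including age
  st2 <- step_population(st$pop, null_models(), lt)
  expect_identical(st2$pop, st$pop)
  expect_equal(st2$deaths, 0L)
  expect_error(step_individual(st$pop[1, ], null_models(), lt), "frozen")
})

test_that("step_individual advances a single row like the population step", {
  ind <- toy_population(1, age_years = 65)
  set.seed(3)
  out <- step_individual(ind, null_models(), const_lifetable(0))
  expect_equal(out$age_months, ind$age_months + 1L)
})

test_that("absorbing two-state occupancy matches the matrix-power oracle", {
  p_monthly <- 0.03
  p_biennial <- 1 - (1 - p_monthly)^24
  m <- make_transition_model("diabetes", "FALSE", "TRUE",
                             c("(Intercept)" = stats::qlogis(p_biennial)))
  n <- 10000
  k <- 24
  pop <- toy_population(n, age_years = 70)
  lt <- const_lifetable(0)
  set.seed(4)
  for (i in seq_len(k)) pop <- step_population(pop, list(m), lt)$pop
  # analytic occupancy: P^k applied to (1, 0)
  P <- matrix(c(1 - p_monthly, p_monthly, 0, 1), 2, 2, byrow = TRUE)
  Pk <- diag(2)
  for (i in seq_len(k)) Pk <- Pk %*% P
  expected <- Pk[1, 2]
  observed <- mean(pop$diabetes)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("reversible two-state occupancy matches the sequential-update chain", {
  # incidence then recovery within a month: the month transition matrix is
  # [[1 - m1(1-m2), m1(1-m2)], [m2, 1-m2]] under the update order
  m1 <- 0.05
  m2 <- 0.08
  mk <- function(p, from, to) {
    make_transition_model("depression", from, to,
                          c("(Intercept)" = stats::qlogis(1 - (1 - p)^24)))
  }
  models <- list(mk(m1, "FALSE", "TRUE"), mk(m2, "TRUE", "FALSE"))
  n <- 10000
  k <- 12
  pop <- toy_population(n, age_years = 70, depression = rep(c(TRUE, FALSE), n / 2))
  lt <- const_lifetable(0)
  set.seed(5)
  for (i in seq_len(k)) pop <- step_population(pop, models, lt)$pop
  P <- matrix(c(1 - m1 * (1 - m2), m1 * (1 - m2),
                m2, 1 - m2), 2, 2, byrow = TRUE)
  dist <- c(0.5, 0.5)
  for (i in seq_len(k)) dist <- dist %*% P
  observed <- mean(pop$depression)
  se <- sqrt(dist[2] * (1 - dist[2]) / n)
  expect_lt(abs(observed - dist[2]), 3 * se)
})

test_that("with only mortality active, cohort survivorship matches l_x", {
  lt <- generate_lifetable()
  n <- 10000
  pop <- toy_population(n, age_years = 65, sex = "male")
  set.seed(6)
  for (i in seq_len(120)) pop <- step_population(pop, null_models(), lt)$pop
  expected <- lt$l_x[lt$sex == "male" & lt$age == 75] /
    lt$l_x[lt$sex == "male" & lt$age == 65]
  observed <- mean(pop$alive)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("dementia allocation follows the cell probabilities and touches nothing else", {
  pop <- toy_population(10000, age_years = 80, mmse = 15)  # moderate, 75-84
  dt <- flat_dementia_table(0)
  set.seed(7)
  out <- allocate_dementia(pop, dt)
  expect_false(any(out$dementia))

  dt$prob <- 1
  expect_true(all(allocate_dementia(pop, dt)$dementia))

  p <- 0.3
  dt$prob <- p
  out <- allocate_dementia(pop, dt)
  expect_lt(abs(sum(out$dementia) - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  out$dementia <- pop$dementia
  expect_identical(out, pop)

  # dead individuals are untouched
  pop$alive[1:10] <- FALSE
  dt$prob <- 1
  out <- allocate_dementia(pop, dt)
  expect_false(any(out$dementia[1:10]))

  # uncovered cell errors
  dt2 <- dt[dt$residence != "care_home", ]
  pop$residence[11] <- "care_home"
  pop$alive <- TRUE
  expect_error(allocate_dementia(pop, dt2), "does not cover")
})

test_that("identical master seeds give byte-identical results", {
  ex <- generate_study_extract(1500, "s", seed = 71)
  models <- list(
    make_transition_model("stroke", "FALSE", "TRUE",
                          c("(Intercept)" = -3, age_c = 0.05)),
    make_transition_model("physical_dependency", "independent", "low",
                          c("(Intercept)" = -2.5, age_c = 0.06)))
  lt <- generate_lifetable()
  dt <- flat_dementia_table(0.1)
  cfg <- simulation_config(start = "2014-01", end = "2016-12",
                           output_years = c(2015, 2016), n_runs = 2,
                           master_seed = 99)
  base <- ex$baseline
  r1 <- run_simulation(base, models, lt, dt, cfg)
  r2 <- run_simulation(base, models, lt, dt, cfg)
  expect_identical(r1, r2)
  r3 <- run_simulation(base, models, lt, dt,
                       simulation_config(start = "2014-01", end = "2016-12",
                                         output_years = c(2015, 2016),
                                         n_runs = 2, master_seed = 100))
  expect_false(identical(r1$runs[[1]]$snapshots, r3$runs[[1]]$snapshots))
})

test_that("population accounting holds: alive plus cumulative deaths is the base size", {
  ex <- generate_study_extract(800, "s", seed = 72)
  lt <- generate_lifetable()
  # end the window at the snapshot month so the event log and the
  # snapshot describe the same instant
  cfg <- simulation_config(end = "2017-06", output_years = 2017, n_runs = 1,
                           master_seed = 5)
  res <- run_simulation(ex$baseline, null_models(), lt,
                        flat_dementia_table(0), cfg)
  snap <- res$runs[[1]]$snapshots[["2017"]]
  expect_equal(nrow(snap), 800)
  expect_equal(sum(snap$alive) + sum(res$runs[[1]]$events$deaths), 800)
  # snapshot interval of need partitions the alive population
  expect_false(anyNA(snap$interval_of_need[snap$alive]))
  expect_true(all(snap$interval_of_need[snap$alive] %in% ion_levels()))
  expect_true(all(is.na(snap$interval_of_need[!snap$alive])))
})

test_that("raising disease incidence weakly increases the disease burden (paired seeds)", {
  ex <- generate_study_extract(2000, "s", seed = 73)
  base <- ex$baseline
  lt <- generate_lifetable()
  dt <- flat_dementia_table(0)
  mk_models <- function(bump) {
    lapply(disease_names()[1:7], function(d) {
      make_transition_model(d, "FALSE", "TRUE",
                            c("(Intercept)" = -3 + bump, age_c = 0.05))
    })
  }
  cfg <- simulation_config(end = "2016-12", output_years = 2016, n_runs = 1,
                           master_seed = 11)
  s_lo <- run_simulation(base, mk_models(0), lt, dt, cfg)$runs[[1]]$snapshots[["2016"]]
  s_hi <- run_simulation(base, mk_models(0.7), lt, dt, cfg)$runs[[1]]$snapshots[["2016"]]
  count <- function(s) {
    sum(as.matrix(as.data.frame(s[s$alive, disease_names()[1:7]])))
  }
  expect_gte(count(s_hi), count(s_lo))
})

test_that("a configured output year outside the window aborts with context", {
  ex <- generate_study_extract(100, "s", seed = 74)
  expect_error(
    run_simulation(ex$baseline, null_models(), generate_lifetable(),
                   flat_dementia_table(0),
                   simulation_config(end = "2015-12", output_years = 2020,
                                     n_runs = 1)),
    "output year")
})

test_that("a model with an unknown covariate is rejected up front", {
  ex <- generate_study_extract(100, "s", seed = 75)
  bad <- make_transition_model("stroke", "FALSE", "TRUE",
                               c("(Intercept)" = -3, nonexistent = 1))
  expect_error(
    run_simulation(ex$baseline, list(bad), generate_lifetable(),
                   flat_dementia_table(0),
                   simulation_config(end = "2015-12", output_years = 2015,
                                     n_runs = 1)),
    "unknown covariate")
})
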