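# wrap hand-built snapshots in the result structure the reporters expect
fake_results <- function(snapshots_by_run, scaling = 1) {
  runs <- lapply(seq_along(snapshots_by_run), function(r) {
    list(run = r, seed = r, snapshots = snapshots_by_run[[r]],
         events = data.frame())
  })
  structure(list(runs = runs, scaling_factor = scaling, config = NULL),
            class = "simulation_results")
}

hand_snapshot <- function() {
  s <- toy_population(10, age_years = 70)
  s$age_months <- as.integer(c(66, 68, 70, 72, 76, 80, 84, 86, 90, 50) * 12)
  s$sex <- rep(c("male", "female"), 5)
  s$physical_dependency <- c("independent", "low", "medium", "high",
                             "independent", "low", "independent", "high",
                             "medium", "low")
  s$mmse <- as.integer(c(30, 28, 25, 15, 5, 30, 30, 22, 9, 30))
  s$stroke <- c(TRUE, rep(FALSE, 9))
  s$diabetes <- c(TRUE, TRUE, rep(FALSE, 8))
  s$arthritis <- c(TRUE, rep(FALSE, 9))
  s$dementia <- c(rep(FALSE, 9), TRUE)
  s$alive <- c(rep(TRUE, 9), TRUE)
  s$interval_of_need <- combine_physical_and_cognition(
    s$physical_dependency, categorise_mmse(s$mmse))
  s
}

test_that("tabulation reproduces a hand tally", {
  s <- hand_snapshot()
  res <- fake_results(list(list("2015" = s)), scaling = 100)
  cube <- tabulate_runs(res)
  expect_equal(attr(cube, "scaling_factor"), 100)
  # the under-65 row is excluded, so 9 individuals are counted
  expect_equal(sum(cube$count), 9)
  # row 1: male 66, independent, 3 diseases
  got <- cube[cube$sex == "male" & cube$age_band == "65-74" &
                cube$disease_stratum == "3+", ]
  expect_equal(sum(got$count), 1)
  expect_equal(got$interval_of_need, "independent")
  # individual 5 (male 76, mmse 5): severe cognition forces high
  got <- cube[cube$age_band == "75-84" & cube$sex == "male", ]
  expect_true("high" %in% got$interval_of_need)
  # margins: summing over all indices but year returns the alive 65+ total
  expect_equal(cube_margin(cube, "year")$count, 9)
  # dependency margin partitions the population
  m <- cube_margin(cube, c("year", "interval_of_need"))
  expect_equal(sum(m$count), 9)
  expect_setequal(m$interval_of_need,
                  c("independent", "low", "medium", "high"))
})

test_that("empty populations give an all-zero cube", {
  s <- hand_snapshot()[0, ]
  cube <- tabulate_runs(fake_results(list(list("2015" = s))))
  expect_equal(nrow(cube), 0)
  expect_equal(sum(cube$count), 0)
})

test_that("relative change matches the published worked examples", {
  expect_equal(relative_change(3655, 5602), 53.3)
  expect_equal(relative_change(1591, 2778), 74.6)
  expect_equal(relative_change(100, 100), 0)
  expect_equal(relative_change(200, 100), -50)
  expect_error(relative_change(0, 5), "undefined")
})

test_that("proportion of life expectancy matches the published worked examples", {
  expect_equal(proportion_of_le(1.2, 18.7), 6.4)
  expect_equal(proportion_of_le(2.0, 21.1), 9.5)
  expect_equal(proportion_of_le(0, 20), 0)
  expect_error(proportion_of_le(1, 0), "must be > 0")
})

test_that("sullivan factorises for constant prevalence", {
  lt <- generate_lifetable()
  ages <- 65:max(lt$age)
  cpv <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    do.call(rbind, lapply(ages, function(a) {
      data.frame(sex = sx, age = a, level = ion_levels(),
                 prop = c(0.4, 0.3, 0.2, 0.1))
    }))
  }))
  he <- sullivan(cpv, lt, from_age = 65)
  for (sx in c("male", "female")) {
    tot <- life_expectancy(lt, 65, sx)
    sub <- he[he$sex == sx, ]
    expect_equal(sub$years, c(0.4, 0.3, 0.2, 0.1) * tot, tolerance = 1e-9)
    expect_equal(sub$total_le[1], tot, tolerance = 1e-12)
  }
})

test_that("all-independent prevalence puts all years independent", {
  lt <- generate_lifetable()
  ages <- 65:max(lt$age)
  pv <- do.call(rbind, lapply(ages, function(a) {
    data.frame(sex = "male", age = a, level = ion_levels(),
               prop = c(1, 0, 0, 0))
  }))
  he <- sullivan(pv, lt)
  expect_equal(he$years[he$level == "independent"], he$total_le[1],
               tolerance = 1e-12)
  expect_equal(sum(he$years[he$level != "independent"]), 0)
})

test_that("sullivan reproduces a three-age hand calculation", {
  lt <- structure(data.frame(
    sex = "male", age = 65:67,
    survival = c(0.9, 0.8, 0.5),
    l_x = c(1000, 900, 720),
    L_x = c(950, 810, 720 / (-log(0.5)))),
    class = c("lifetable", "data.frame"))
  pv <- data.frame(sex = "male",
                   age = rep(65:67, each = 4),
                   level = rep(ion_levels(), 3),
                   prop = c(0.7, 0.2, 0.1, 0,
                            0.6, 0.2, 0.1, 0.1,
                            0.5, 0.3, 0.1, 0.1))
  he <- sullivan(pv, lt, from_age = 65)
  L3 <- 720 / (-log(0.5))
  tot <- (950 + 810 + L3) / 1000
  ind <- (0.7 * 950 + 0.6 * 810 + 0.5 * L3) / 1000
  high <- (0 * 950 + 0.1 * 810 + 0.1 * L3) / 1000
  expect_equal(he$total_le[1], tot, tolerance = 1e-12)
  expect_equal(he$years[he$level == "independent"], ind, tolerance = 1e-12)
  expect_equal(he$years[he$level == "high"], high, tolerance = 1e-12)
})

test_that("sullivan rejects prevalence that does not sum to one", {
  lt <- generate_lifetable()
  ages <- 65:max(lt$age)
  pv <- do.call(rbind, lapply(ages, function(a) {
    data.frame(sex = "male", age = a, level = ion_levels(),
               prop = c(0.5, 0.3, 0.2, 0.1))
  }))
  expect_error(sullivan(pv, lt), "sum to 1")
})

test_that("state expectancies conserve total life expectancy (random inputs)", {
  set.seed(99)
  for (i in 1:100) {
    lt <- generate_lifetable(list(a_male = stats::runif(1, 1e-4, 2e-3),
                                  a_female = stats::runif(1, 1e-4, 2e-3),
                                  b = stats::runif(1, 0.05, 0.13),
                                  c = stats::runif(1, 0, 1e-3)))
    ages <- 65:max(lt$age)
    pr <- matrix(stats::rgamma(4 * length(ages), 1), ncol = 4)
    pr <- pr / rowSums(pr)
    pv <- data.frame(sex = "male", age = rep(ages, each = 4),
                     level = rep(ion_levels(), length(ages)),
                     prop = as.vector(t(pr)))
    he <- sullivan(pv, lt)
    expect_lt(abs(sum(he$years) - he$total_le[1]), 1e-9)
  }
})

test_that("uniformly lower survival strictly lowers life expectancy", {
  lt1 <- generate_lifetable()
  lt2 <- lt1
  lt2$survival <- lt2$survival * 0.98
  # rebuild survivorship from the degraded survival schedule
  for (sx in c("male", "female")) {
    idx <- which(lt2$sex == sx)
    s <- lt2$survival[idx]
    l <- 100000 * c(1, cumprod(s[-length(s)]))
    L <- c((l[-length(l)] + l[-1]) / 2, l[length(l)] / (-log(s[length(s)])))
    lt2$l_x[idx] <- l
    lt2$L_x[idx] <- L
  }
  expect_lt(life_expectancy(lt2, 65, "male"), life_expectancy(lt1, 65, "male"))
  expect_lt(life_expectancy(lt2, 65, "female"),
            life_expectancy(lt1, 65, "female"))
})

test_that("dependency prevalence sums to one and smooths sparse ages", {
  s <- hand_snapshot()
  pv <- dependency_prevalence(s, ages = 65:90, min_cell = 30)
  sums <- tapply(pv$prop, paste(pv$sex, pv$age), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_setequal(unique(pv$age), 65:90)
})

test_that("cohort traces follow a scripted toy population", {
  mk <- function(year, dep_levels) {
    s <- toy_population(length(dep_levels), age_years = 70, sex = "male")
    # all born in year-70, a single 5-year cohort
    s$physical_dependency <- dep_levels
    s$interval_of_need <- dep_levels
    s
  }
  snaps1 <- list("2015" = mk(2015, c("independent", "independent", "low", "high")),
                 "2020" = mk(2020, c("independent", "low", "low", "high")))
  tr <- cohort_trace(fake_results(list(snaps1)))
  expect_equal(nrow(tr), 2)
  expect_equal(tr$prop_independent[tr$year == 2015], 0.5)
  expect_equal(tr$prop_independent[tr$year == 2020], 0.25)
  # an immortal transition-free population gives flat traces
  snaps2 <- list("2015" = mk(2015, rep("independent", 4)),
                 "2020" = mk(2020, rep("independent", 4)))
  tr2 <- cohort_trace(fake_results(list(snaps2)))
  expect_equal(unique(tr2$prop_independent), 1)
  # a cohort not yet fully 65 at a year is suppressed
  # age 65 in 2015: born 1950, cohort 1950-1954 still partly under 65
  s_young <- toy_population(3, age_years = 65, sex = "male")
  s_young$interval_of_need <- "independent"
  tr3 <- cohort_trace(fake_results(list(list("2015" = s_young))))
  expect_equal(nrow(tr3), 0)
})

test_that("run ranges contain the headline and are permutation-stable", {
  snaps <- lapply(c(10, 14, 12), function(k) {
    s <- toy_population(k, age_years = 70)
    s$interval_of_need <- "independent"
    list("2015" = s)
  })
  res <- fake_results(snaps)
  stat <- function(rr) c(n65 = sum(rr$snapshots[["2015"]]$alive))
  r <- range_over_runs(res, stat)
  expect_equal(r$headline, 10)
  expect_equal(r$min, 10)
  expect_equal(r$max, 14)
  expect_true(r$headline >= r$min && r$headline <= r$max)
  res_perm <- fake_results(snaps[c(2, 3, 1)])
  r2 <- range_over_runs(res_perm, stat)
  expect_equal(r2$min, r$min)
  expect_equal(r2$max, r$max)
  expect_equal(r2$headline, 14)
  # single run collapses to the value
  r1 <- range_over_runs(fake_results(snaps[1]), stat)
  expect_true(r1$headline == r1$min && r1$headline == r1$max)
})
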