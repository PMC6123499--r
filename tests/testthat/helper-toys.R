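# A minimal valid population of identical individuals, for engine toys.
toy_population <- function(n, age_years = 70, sex = "male",
                           mmse = 30L, physical_dependency = "independent",
                           depression = FALSE, residence = "community") {
  pop <- data.frame(
    id = sprintf("t%05d", seq_len(n)), sex = sex,
    age_months = as.integer(age_years * 12), education = "mid",
    occupation = "manual", smoking = "never", bmi_class = "normal",
    physical_activity = "medium",
    chd = FALSE, stroke = FALSE, hypertension = FALSE, diabetes = FALSE,
    arthritis = FALSE, cancer = FALSE, respiratory = FALSE,
    depression = depression,
    vision_impairment = "none", hearing_impairment = "none",
    mmse = as.integer(mmse), physical_dependency = physical_dependency,
    residence = residence, dementia = FALSE, alive = TRUE, weight = 1,
    stringsAsFactors = FALSE)
  pop
}

# lifetable with constant annual survival exp(-c) at every age
const_lifetable <- function(c = 0) {
  generate_lifetable(list(a_male = 0, a_female = 0, b = 0.1, c = c))
}

# dementia table with a single probability everywhere
flat_dementia_table <- function(p) {
  dt <- generate_dementia_table()
  dt$prob <- p
  dt
}

# ground truth with every transition switched off
zero_transition_truth <- function(extra = NULL) {
  tr <- lapply(truth_params()$transitions,
               function(v) c("(Intercept)" = -30))
  truth_params(.merge(list(transitions = tr), extra))
}

.merge <- function(a, b) if (is.null(b)) a else utils::modifyList(a, b)
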