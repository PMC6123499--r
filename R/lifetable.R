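#' Generate a synthetic age-sex lifetable
#'
#' Annual all-cause survival probabilities by sex and single year of age
#' from a Gompertz-Makeham hazard \eqn{\mu(x) = a e^{b(x-35)} + c}, with the
#' female level parameter below the male one so that female survival
#' dominates at every age. The table carries the derived survivorship
#' columns: \eqn{l_x} (survivors to exact age x, radix 100 000 at 35),
#' \eqn{L_x} (person-years in the interval, midpoint assumption
#' \eqn{(l_x + l_{x+1})/2}), and an open terminal interval at `max_age`
#' closed by \eqn{L_\omega = l_\omega / \mu_\omega}.
#'
#' @param params A [truth_params()] object (its `mortality` element) or a
#'   list with `a_male`, `a_female`, `b`, `c`.
#' @param max_age Terminal (open) age of the table.
#' @return Object of class `lifetable`: data.frame with `sex`, `age`,
#'   `survival`, `l_x`, `L_x`.
#' @export
generate_lifetable <- function(params = truth_params(), max_age = 105L) {
  m <- if (inherits(params, "truth_params")) params$mortality else params
  if (m$b <= 0) .stopf("Gompertz slope must be > 0")
  ages <- 35:max_age
  cum_haz <- function(a, x) {
    # integral of a*exp(b*(t-35)) + c from 35 to x
    a / m$b * (exp(m$b * (x - 35)) - 1) + m$c * (x - 35)
  }
  build <- function(sex, a) {
    s <- exp(-(cum_haz(a, ages + 1) - cum_haz(a, ages)))
    s <- pmin(pmax(s, 1e-12), 1)
    l <- 100000 * c(1, cumprod(s[-length(s)]))
    L <- c((l[-length(l)] + l[-1]) / 2, NA)
    haz_term <- -log(s[length(s)])
    L[length(L)] <- l[length(l)] / haz_term
    data.frame(sex = sex, age = ages, survival = s, l_x = l, L_x = L,
               stringsAsFactors = FALSE)
  }
  out <- rbind(build("female", m$a_female), build("male", m$a_male))
  structure(out, class = c("lifetable", "data.frame"))
}

#' Period life expectancy from a lifetable
#'
#' @param lt A `lifetable`.
#' @param from_age Exact age at which expectancy is evaluated.
#' @param sex `"male"` or `"female"`.
#' @return Remaining life expectancy in years:
#'   \eqn{\sum_{x \ge a} L_x / l_a}.
#' @export
life_expectancy <- function(lt, from_age = 65, sex = "male") {
  sub <- lt[lt$sex == sex & lt$age >= from_age, ]
  if (!nrow(sub)) .stopf("lifetable does not cover age %s for %s", from_age, sex)
  sum(sub$L_x) / sub$l_x[sub$age == from_age]
}

# annual survival probability for each individual (sex, completed years);
# ages beyond the terminal row reuse the terminal survival probability
.lookup_survival <- function(lt, sex, age_years) {
  key <- paste(lt$sex, lt$age)
  s <- lt$survival
  names(s) <- key
  amax <- max(lt$age)
  a <- pmin(pmax(age_years, min(lt$age)), amax)
  as.numeric(s[paste(sex, a)])
}
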