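`%||%` <- function(a, b) if (is.null(a)) b else a

# deep-merge override lists into defaults (modifyList, recursing into lists)
.merge_params <- function(defaults, override) {
  if (is.null(override)) return(defaults)
  utils::modifyList(defaults, override)
}

.plogis <- stats::plogis
.qlogis <- stats::qlogis

# Bernoulli draws from the current RNG stream
.rbern <- function(p) stats::runif(length(p)) < p

#' Age bands used for pooling margins and reporting
#'
#' @param age_years Numeric vector of ages in years.
#' @param breaks Lower bounds of the bands; the last band is open-ended.
#' @return Character vector of band labels such as `"35-44"`, `"85+"`.
#' @export
age_band <- function(age_years, breaks = c(35, 45, 55, 65, 75, 85)) {
  idx <- findInterval(age_years, breaks)
  idx[idx == 0L] <- NA_integer_
  labs <- c(paste0(breaks[-length(breaks)], "-", breaks[-1] - 1),
            paste0(breaks[length(breaks)], "+"))
  labs[idx]
}

# round-half-to-even to integer (base round() already does banker's rounding)
.round_even <- function(x) as.integer(round(x))

# derive a vector of independent 31-bit sub-seeds from one master seed
.derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
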