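#' Exponential growth of a cell population
#'
#' Expected population size under the exponential growth law
#' \eqn{N(t) = N_0 \cdot 2^{t/T_d}}, where \eqn{T_d} is the doubling time.
#' The co-culture design assumes pure exponential growth over the short
#' (~3 day) assay window, so no carrying-capacity term is included.
#'
#' @param n0 Starting cell count (>= 0).
#' @param doubling_time_h Doubling time in hours (> 0).
#' @param t Elapsed time in hours (>= 0).
#' @param stochastic If `TRUE`, draw the realised count from a Poisson
#'   distribution centred on the expectation (uses the current RNG state).
#' @return Expected (or realised, if `stochastic`) cell count.
#' @examples
#' grow_population(100, 24, 24)   # one doubling -> 200
#' grow_population(800, 23.8, 72) # ~6511
#' @export
grow_population <- function(n0, doubling_time_h, t, stochastic = FALSE) {
  if (any(n0 < 0)) stop("'n0' must be >= 0", call. = FALSE)
  if (any(doubling_time_h <= 0))
    stop("'doubling_time_h' must be > 0", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  expected <- n0 * 2^(t / doubling_time_h)
  if (stochastic) rpois(length(expected), expected) else expected
}

#' Estimate a doubling time from a growth series
#'
#' Least-squares fit of \eqn{\log_2(\mathrm{count})} against time; the
#' doubling time is the reciprocal of the fitted slope, with a standard error
#' propagated from the slope's (delta method).
#'
#' @param times Time points in hours (>= 3 values).
#' @param counts Cell counts (> 0) at those times.
#' @return A list of class `growth_estimate` with `doubling_time_h`, `se_h`,
#'   and `r_squared`.
#' @examples
#' estimate_doubling_time(c(0, 24, 48), c(100, 200, 400)) # 24 h
#' @export
estimate_doubling_time <- function(times, counts) {
  if (length(times) < 3 || length(counts) != length(times))
    stop("need >= 3 matched time points", call. = FALSE)
  if (any(counts <= 0)) stop("counts must be > 0", call. = FALSE)
  fit <- lm(log2(counts) ~ times)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("no growth: fitted slope of log2(count) vs time is <= 0",
         call. = FALSE)
  # summary() warns on noise-free series (perfect fit); that is a valid input
  sm <- suppressWarnings(summary(fit))
  structure(list(
    doubling_time_h = 1 / slope,
    se_h = sm$coefficients[2, 2] / slope^2,
    r_squared = sm$r.squared
  ), class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  cat(sprintf("Doubling time: %.2f h (SE %.2f h, R^2 %.4f)\n",
              x$doubling_time_h, x$se_h, x$r_squared))
  invisible(x)
}

#' Predict final co-culture composition from seeding counts
#'
#' Grows each population independently at its own doubling time and returns
#' the normalised final fractions, i.e.
#' \eqn{f_i = n_i 2^{T/T_{d,i}} / \sum_j n_j 2^{T/T_{d,j}}}.
#'
#' @param seed_counts Named numeric vector of seeded counts per population.
#' @param doubling_times Doubling times (hours), same order/names.
#' @param duration_h Culture duration in hours.
#' @return Named numeric vector of final fractions summing to 1.
#' @examples
#' predict_final_composition(c(fa2n4 = 1500, huh7 = 800), c(43.5, 23.8), 72)
#' @export
predict_final_composition <- function(seed_counts, doubling_times,
                                      duration_h) {
  if (any(seed_counts <= 0) || any(doubling_times <= 0) || duration_h < 0)
    stop("seed counts and doubling times must be positive, duration >= 0",
         call. = FALSE)
  final <- seed_counts * 2^(duration_h / doubling_times)
  final / sum(final)
}

#' Solve seeding fractions for a target final composition
#'
#' Closed-form inverse of [predict_final_composition()] for two populations:
#' given both doubling times and the culture duration, returns the seeding
#' fractions that yield `target_final_fraction` for the first population.
#'
#' @param doubling_times Length-2 doubling times (hours), first entry is the
#'   population whose final fraction is targeted.
#' @param duration_h Culture duration in hours.
#' @param target_final_fraction Desired final fraction of population 1,
#'   in (0, 1).
#' @return Length-2 numeric vector of seeding fractions summing to 1.
#' @export
design_seeding_ratio <- function(doubling_times, duration_h,
                                 target_final_fraction) {
  if (length(doubling_times) != 2 || any(doubling_times <= 0))
    stop("'doubling_times' must be two positive values", call. = FALSE)
  f <- target_final_fraction
  if (!is.numeric(f) || length(f) != 1 || f <= 0 || f >= 1)
    stop("'target_final_fraction' must be in (0, 1)", call. = FALSE)
  g <- 2^(duration_h / doubling_times)   # per-population growth factors
  # n1 g1 / (n1 g1 + n2 g2) = f  =>  n1/n2 = (f/(1-f)) * g2/g1
  ratio <- (f / (1 - f)) * g[2] / g[1]
  n1 <- ratio / (1 + ratio)
  c(n1, 1 - n1)
}
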