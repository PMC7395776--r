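#' Age-specific population rates table
#'
#' Per-age population disease incidence and competing (other-cause)
#' mortality, both in events per person-year on a contiguous one-year age
#' grid. Competing mortality must already exclude deaths from the disease
#' itself.
#'
#' @param age integer age grid (contiguous).
#' @param incidence disease incidence per person-year.
#' @param competing_mortality other-cause mortality per person-year.
#' @return data frame classed \code{rates_table}.
#' @export
rates_table <- function(age, incidence, competing_mortality) {
  age <- as.integer(age)
  if (length(age) < 2L || any(diff(age) != 1L))
    stop("age grid must be contiguous")
  stopifnot(length(incidence) == length(age),
            length(competing_mortality) == length(age))
  if (any(incidence < 0) || any(competing_mortality < 0))
    stop("rates must be non-negative")
  if (any(incidence >= 1) || any(competing_mortality >= 1))
    stop("annual rates must be below 1")
  structure(data.frame(age = age, incidence = incidence,
                       competing_mortality = competing_mortality),
            class = c("rates_table", "data.frame"))
}

#' Read a rates table from CSV
#'
#' Expects columns \code{age}, \code{incidence}, \code{competing_mortality}.
#' With \code{per100k = TRUE} the rate columns are divided by 1e5 on read.
#'
#' @param path CSV path.
#' @param per100k are rates per 100,000 person-years rather than per
#'   person-year?
#' @return a [rates_table()].
#' @export
read_rates_table <- function(path, per100k = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "incidence", "competing_mortality")
  if (!all(need %in% names(x)))
    stop("rates CSV must carry columns: ", paste(need, collapse = ", "))
  k <- if (per100k) 1e5 else 1
  rates_table(x$age, x$incidence / k, x$competing_mortality / k)
}

#' Write a rates table to CSV
#'
#' @param rates a [rates_table()].
#' @param path output path.
#' @export
write_rates_table <- function(rates, path) {
  utils::write.csv(as.data.frame(rates), path, row.names = FALSE)
  invisible(path)
}

#' Risk group set
#'
#' Population fractions and relative risks for a partition of the
#' population into PRS percentile groups. Odds ratios are used as relative
#' risks, which is adequate when annual risks are low.
#'
#' @param fraction population fraction per group (sums to 1).
#' @param relative_risk positive relative risk per group.
#' @param label group labels (e.g. percentile ranges).
#' @return data frame classed \code{risk_group_set}.
#' @export
risk_group_set <- function(fraction, relative_risk,
                           label = sprintf("g%d", seq_along(fraction))) {
  stopifnot(length(fraction) == length(relative_risk),
            length(label) == length(fraction))
  if (abs(sum(fraction) - 1) > 1e-8) stop("group fractions must sum to 1")
  if (any(fraction <= 0)) stop("group fractions must be positive")
  if (any(relative_risk <= 0)) stop("relative risks must be positive")
  structure(data.frame(label = label, fraction = fraction,
                       relative_risk = relative_risk,
                       stringsAsFactors = FALSE),
            class = c("risk_group_set", "data.frame"))
}

#' Percentile risk groups implied by a polygenic model
#'
#' Partitions the PRS distribution into equal-or-unequal percentile bins
#' and assigns each bin the mean relative risk of its truncated
#' standard-normal range under log-linear risk
#' \eqn{\exp(\gamma z)}: the bin mean divided by the population mean
#' \eqn{\exp(\gamma^2/2)} is
#' \eqn{[\Phi(b-\gamma)-\Phi(a-\gamma)]/[\Phi(b)-\Phi(a)]}, so the
#' fraction-weighted mean relative risk is exactly 1.
#'
#' @param model a [polygenic_model()].
#' @param boundaries cumulative-fraction cut points from 0 to 1; either a
#'   full vector or implied by \code{centile_width}.
#' @param centile_width equal bin width as a fraction (e.g. 0.001 for
#'   0.1\% centiles); must divide 1.
#' @return a [risk_group_set()].
#' @export
centile_risk_groups <- function(model, boundaries = NULL,
                                centile_width = 0.001) {
  if (is.null(boundaries)) {
    k <- 1 / centile_width
    if (abs(k - round(k)) > 1e-9)
      stop("centile_width must divide 100%")
    boundaries <- seq(0, 1, length.out = round(k) + 1)
  }
  stopifnot(all(diff(boundaries) > 0), boundaries[1] == 0,
            boundaries[length(boundaries)] == 1)
  z <- stats::qnorm(boundaries)
  f <- diff(stats::pnorm(z))
  rr <- diff(stats::pnorm(z - model$gamma)) / f
  labs <- paste0(100 * boundaries[-length(boundaries)], "-",
                 100 * boundaries[-1], "%")
  risk_group_set(f, rr, labs)
}

#' Calibrate group-specific hazards to population incidence
#'
#' Forward age recursion: at each age \eqn{u} the baseline hazard is
#' \deqn{\lambda^*(u) = \lambda_{pop}(u) \frac{\sum_g f_g S_g(u)}
#'   {\sum_g f_g S_g(u) r_g},}
#' the group hazard is \eqn{\lambda_g(u) = r_g \lambda^*(u)}, and
#' disease-free survival updates as
#' \eqn{S_g(u+1) = S_g(u)(1 - \lambda_g(u))}. By construction the
#' survivor-weighted mean of the group hazards equals the population
#' incidence exactly at every age, which is the stated calibration
#' constraint; on a discrete grid the recursion satisfies it without a
#' fixed-point loop.
#'
#' @param rates a [rates_table()].
#' @param groups a [risk_group_set()].
#' @return classed list \code{group_risk_curve} with \code{ages},
#'   \code{lambda} (ages x groups hazards), \code{S} (disease-free survival
#'   entering each age), \code{S_m} (competing-mortality survival entering
#'   each age) and the group set.
#' @export
calibrate_group_hazards <- function(rates, groups) {
  ages <- rates$age
  n_age <- length(ages)
  n_g <- nrow(groups)
  f <- groups$fraction
  r <- groups$relative_risk
  lambda <- matrix(0, n_age, n_g)
  S <- matrix(0, n_age, n_g)
  S_m <- numeric(n_age)
  s <- rep(1, n_g)
  sm <- 1
  for (u in seq_len(n_age)) {
    S[u, ] <- s
    S_m[u] <- sm
    lam_star <- rates$incidence[u] * sum(f * s) / sum(f * s * r)
    lam_g <- r * lam_star
    if (any(lam_g >= 1))
      stop("relative risk too extreme: group hazard >= 1 at age ", ages[u])
    lambda[u, ] <- lam_g
    s <- s * (1 - lam_g)
    sm <- sm * (1 - rates$competing_mortality[u])
  }
  structure(list(ages = ages, lambda = lambda, S = S, S_m = S_m,
                 groups = groups),
            class = "group_risk_curve")
}

#' @export
print.group_risk_curve <- function(x, ...) {
  cat(sprintf("group_risk_curve: %d groups, ages %d-%d\n",
              nrow(x$groups), min(x$ages), max(x$ages)))
  invisible(x)
}

.age_index <- function(curve, age) {
  i <- match(age, curve$ages)
  if (is.na(i)) stop("age ", age, " outside the rate grid")
  i
}

#' Cumulative absolute risk between two ages
#'
#' \eqn{AR_g = \sum_{u=from}^{to-1} \lambda_g(u) S_g(u) S_m(u)} with both
#' survival functions renormalised to 1 at \code{from_age}, i.e. the risk
#' of developing disease in \code{[from_age, to_age)} conditional on being
#' alive and disease-free at \code{from_age}, accounting for competing
#' mortality.
#'
#' @param curve a [calibrate_group_hazards()] result.
#' @param from_age,to_age integer ages on the grid,
#'   \code{from_age < to_age}; \code{to_age} may be one past the last grid
#'   age.
#' @return named numeric vector of per-group cumulative risks.
#' @export
cumulative_risk <- function(curve, from_age, to_age) {
  if (from_age >= to_age) stop("from_age must be below to_age")
  i0 <- .age_index(curve, from_age)
  i1 <- if (to_age == max(curve$ages) + 1L) length(curve$ages) else
    .age_index(curve, to_age) - 1L
  idx <- i0:i1
  base_S <- curve$S[i0, ]
  base_m <- curve$S_m[i0]
  ar <- colSums(curve$lambda[idx, , drop = FALSE] *
                  sweep(curve$S[idx, , drop = FALSE], 2, base_S, "/") *
                  (curve$S_m[idx] / base_m))
  names(ar) <- curve$groups$label
  ar
}

#' Ten-year absolute risk from a given age
#'
#' @param curve a [calibrate_group_hazards()] result.
#' @param age index age; \code{age + 10} must be within (or one past) the
#'   grid.
#' @return per-group 10-year risks conditional on being alive and
#'   disease-free at \code{age}.
#' @export
ten_year_risk <- function(curve, age) {
  cumulative_risk(curve, age, age + 10L)
}

#' First age at which the 10-year risk reaches a threshold
#'
#' Scans integer ages in \code{age_range} and returns, per group, the
#' smallest age whose 10-year absolute risk is at least \code{threshold},
#' or NA ("never reached") if none qualifies.
#'
#' @param curve a [calibrate_group_hazards()] result.
#' @param threshold 10-year risk threshold in (0,1); e.g. 0.023, the
#'   10-year risk of a 50-year-old woman of European ancestry.
#' @param age_range inclusive scan range (default 20-70).
#' @return named integer vector (NA = never reached).
#' @export
age_at_threshold <- function(curve, threshold = 0.023,
                             age_range = c(20, 70)) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  ages <- seq(max(age_range[1], min(curve$ages)),
              min(age_range[2], max(curve$ages) + 1L - 10L))
  if (!length(ages)) stop("empty age range")
  out <- rep(NA_integer_, nrow(curve$groups))
  names(out) <- curve$groups$label
  pending <- rep(TRUE, length(out))
  for (a in ages) {
    risk <- ten_year_risk(curve, a)
    hit <- pending & risk >= threshold
    out[hit] <- a
    pending <- pending & !hit
    if (!any(pending)) break
  }
  out
}

#' Screening eligibility under a risk threshold
#'
#' Builds fine PRS centile groups from the polygenic model, calibrates
#' their hazards to the population rates, and declares a centile eligible
#' if its maximum 10-year absolute risk over \code{age_range} reaches
#' \code{threshold}. Returns the population fraction eligible and the
#' fraction of all (lifetime, calibrated) cases accruing to eligible
#' centiles.
#'
#' @param model a [polygenic_model()].
#' @param rates a [rates_table()].
#' @param threshold 10-year risk threshold (default 0.023).
#' @param centile_width centile bin width as a fraction (default 0.001,
#'   i.e. 0.1\% centiles).
#' @param age_range ages scanned for the maximum 10-year risk.
#' @return list with \code{fraction_population},
#'   \code{fraction_cases_captured}, \code{eligible} (logical per centile),
#'   \code{groups} and \code{curve}.
#' @export
screening_eligibility <- function(model, rates, threshold = 0.023,
                                  centile_width = 0.001,
                                  age_range = c(20, 70)) {
  groups <- centile_risk_groups(model, centile_width = centile_width)
  curve <- calibrate_group_hazards(rates, groups)
  ages <- seq(max(age_range[1], min(curve$ages)),
              min(age_range[2], max(curve$ages) + 1L - 10L))
  max_risk <- rep(0, nrow(groups))
  for (a in ages) max_risk <- pmax(max_risk, ten_year_risk(curve, a))
  eligible <- max_risk >= threshold
  # lifetime case mass per group under the calibrated hazards
  case_mass <- groups$fraction *
    colSums(curve$lambda * curve$S * curve$S_m)
  list(fraction_population = sum(groups$fraction[eligible]),
       fraction_cases_captured = if (sum(case_mass) > 0)
         sum(case_mass[eligible]) / sum(case_mass) else NA_real_,
       eligible = eligible, groups = groups, curve = curve)
}

#' Percentile-group absolute-risk summary
#'
#' Convenience wrapper producing, for a set of percentile groups, the
#' lifetime risk (to the end of the rate grid) and the age at which the
#' 10-year risk first reaches the screening threshold.
#'
#' @param rates a [rates_table()].
#' @param groups a [risk_group_set()].
#' @param threshold 10-year risk threshold.
#' @param age_range threshold scan range.
#' @return data frame: group label, relative risk, lifetime risk,
#'   threshold age (NA = never reached).
#' @export
absolute_risk_summary <- function(rates, groups, threshold = 0.023,
                                  age_range = c(20, 70)) {
  curve <- calibrate_group_hazards(rates, groups)
  lifetime <- cumulative_risk(curve, min(curve$ages), max(curve$ages) + 1L)
  thr_age <- age_at_threshold(curve, threshold, age_range)
  data.frame(label = groups$label,
             relative_risk = groups$relative_risk,
             lifetime_risk = unname(lifetime),
             threshold_age = unname(thr_age),
             stringsAsFactors = FALSE)
}
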