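# hand recursion oracle: survival-weighted calibration + Eq-5 style sum
brute_calibrate <- function(inc, mort, f, r) {
  n <- length(inc)
  g <- length(f)
  S <- rep(1, g); Sm <- 1
  lam <- matrix(0, n, g); Smat <- matrix(0, n, g); Smv <- numeric(n)
  for (u in seq_len(n)) {
    Smat[u, ] <- S; Smv[u] <- Sm
    ls <- inc[u] * sum(f * S) / sum(f * S * r)
    lam[u, ] <- r * ls
    S <- S * (1 - r * ls)
    Sm <- Sm * (1 - mort[u])
  }
  list(lambda = lam, S = Smat, S_m = Smv)
}

test_that("calibration hands back population incidence when all risks are 1", {
  rates <- gen_rates_table(ages = 30:79)
  g <- risk_group_set(c(0.25, 0.75), c(1, 1))
  curve <- calibrate_group_hazards(rates, g)
  expect_equal(curve$lambda[, 1], rates$incidence)
  expect_equal(curve$lambda[, 2], rates$incidence)
})

test_that("first-age hazards match the hand-worked two-group example", {
  rates <- rates_table(50:52, incidence = c(0.02, 0.02, 0.02),
                       competing_mortality = rep(0, 3))
  g <- risk_group_set(c(0.5, 0.5), c(1, 3))
  curve <- calibrate_group_hazards(rates, g)
  expect_equal(curve$lambda[1, ], c(0.01, 0.03))
})

test_that("survivor-weighted calibration identity holds exactly for random inputs", {
  set.seed(20)
  for (rep in 1:12) {
    ages <- 20:(20 + sample(30:60, 1))
    inc <- runif(length(ages), 0, 0.02)
    mort <- runif(length(ages), 0, 0.03)
    k <- sample(2:8, 1)
    f <- as.numeric(rmultinom(1, 1000, runif(k, 0.5, 2))) / 1000
    while (any(f == 0)) f <- as.numeric(rmultinom(1, 1000, runif(k, 0.5, 2))) / 1000
    r <- exp(rnorm(k, 0, 0.6))
    rates <- rates_table(ages, inc, mort)
    groups <- risk_group_set(f, r)
    curve <- calibrate_group_hazards(rates, groups)

    # identity at every age, to near machine precision
    wmean <- rowSums(sweep(curve$lambda * curve$S, 2, f, "*")) /
      rowSums(sweep(curve$S, 2, f, "*"))
    expect_lt(max(abs(wmean - inc)), 1e-12)

    # whole-population risk equals the direct single-population computation
    ar_groups <- sum(f * cumulative_risk(curve, min(ages), max(ages) + 1L))
    direct <- calibrate_group_hazards(rates, risk_group_set(1, 1))
    ar_direct <- unname(cumulative_risk(direct, min(ages), max(ages) + 1L))
    expect_lt(abs(ar_groups - ar_direct), 1e-10)

    # and both match the independent brute recursion
    b <- brute_calibrate(inc, mort, f, r)
    expect_equal(curve$lambda, b$lambda, tolerance = 1e-12)
  }
})

test_that("extreme relative risks that push a hazard past 1 are an error", {
  rates <- rates_table(40:45, rep(0.2, 6), rep(0, 6))
  g <- risk_group_set(c(0.99, 0.01), c(1, 200))
  expect_error(calibrate_group_hazards(rates, g), "too extreme")
})

test_that("cumulative risk follows the discrete product and responds to mortality", {
  zero <- calibrate_group_hazards(rates_table(20:79, rep(0, 60), rep(0, 60)),
                                  risk_group_set(1, 1))
  expect_equal(unname(cumulative_risk(zero, 20, 80)), 0)

  flat <- calibrate_group_hazards(
    rates_table(20:79, rep(0.001, 60), rep(0, 60)), risk_group_set(1, 1))
  expect_equal(unname(cumulative_risk(flat, 20, 80)), 1 - 0.999^60,
               tolerance = 1e-12)

  with_mort <- calibrate_group_hazards(
    rates_table(20:79, rep(0.001, 60), rep(0.01, 60)), risk_group_set(1, 1))
  expect_lt(unname(cumulative_risk(with_mort, 20, 80)),
            unname(cumulative_risk(flat, 20, 80)))

  expect_error(cumulative_risk(flat, 50, 50), "below")
  expect_error(cumulative_risk(flat, 10, 30), "outside")

  # doubling small rates roughly doubles lifetime risk (first order)
  dbl <- calibrate_group_hazards(
    rates_table(20:79, rep(0.002, 60), rep(0, 60)), risk_group_set(1, 1))
  ratio <- unname(cumulative_risk(dbl, 20, 80)) /
    unname(cumulative_risk(flat, 20, 80))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("ten-year risks match the geometric product and are monotone in risk", {
  flat <- calibrate_group_hazards(
    rates_table(20:79, rep(0.0023, 60), rep(0, 60)),
    risk_group_set(1, 1))
  expect_equal(unname(ten_year_risk(flat, 40)), 1 - (1 - 0.0023)^10,
               tolerance = 1e-12)
  expect_equal(unname(ten_year_risk(flat, 40)), 0.0227, tolerance = 0.005)

  rates <- gen_rates_table()
  curve <- calibrate_group_hazards(rates, risk_group_set(c(.5, .5), c(1, 2)))
  for (a in seq(20, 70, by = 10)) {
    r <- ten_year_risk(curve, a)
    expect_gte(r[2], r[1])
  }
})

test_that("threshold ages: never reached on zero rates, first age at threshold 0", {
  zero <- calibrate_group_hazards(rates_table(20:79, rep(0, 60), rep(0, 60)),
                                  risk_group_set(c(.5, .5), c(1, 2)))
  expect_true(all(is.na(age_at_threshold(zero, 0.023))))

  rates <- gen_rates_table()
  curve <- calibrate_group_hazards(rates, risk_group_set(c(.5, .5), c(1, 2)))
  expect_equal(unname(age_at_threshold(curve, 1e-12)), c(20L, 20L))

  # crossing age agrees with a direct scan of independently recomputed risks
  thr <- age_at_threshold(curve, 0.023)
  b <- brute_calibrate(rates$incidence, rates$competing_mortality,
                       c(.5, .5), c(1, 2))
  risk10 <- function(g, a) {
    i <- a - 20 + 1
    idx <- i:(i + 9)
    sum(b$lambda[idx, g] * b$S[idx, g] * b$S_m[idx]) / (b$S[i, g] * b$S_m[i])
  }
  for (gr in 1:2) {
    ages <- 20:70
    hit <- ages[vapply(ages, function(a) risk10(gr, a) >= 0.023, logical(1))]
    expect_equal(unname(thr[gr]), if (length(hit)) hit[1] else NA_integer_)
  }
})

test_that("doubled incidence never delays threshold crossing", {
  rates <- gen_rates_table()
  doubled <- rates_table(rates$age, 2 * rates$incidence,
                         rates$competing_mortality)
  g <- centile_risk_groups(polygenic_model(gamma = log(1.48)),
                           boundaries = bin_scheme()$boundaries)
  a1 <- age_at_threshold(calibrate_group_hazards(rates, g), 0.023)
  a2 <- age_at_threshold(calibrate_group_hazards(doubled, g), 0.023)
  reached <- !is.na(a1)
  expect_true(all(!is.na(a2[reached])))
  expect_true(all(a2[reached] <= a1[reached]))
})

test_that("centile groups conserve mean relative risk and total mass", {
  m <- polygenic_model(gamma = log(1.48))
  g <- centile_risk_groups(m, centile_width = 0.001)
  expect_equal(nrow(g), 1000)
  expect_equal(sum(g$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(g$fraction * g$relative_risk), 1, tolerance = 1e-9)
  expect_true(all(diff(g$relative_risk) > 0))
  expect_error(centile_risk_groups(m, centile_width = 0.003), "divide")
})

test_that("screening eligibility: degenerate thresholds and the null model", {
  rates <- gen_rates_table()
  all_in <- screening_eligibility(polygenic_model(gamma = log(1.48)), rates,
                                  threshold = 1e-12, centile_width = 0.01)
  expect_equal(all_in$fraction_population, 1)
  expect_equal(all_in$fraction_cases_captured, 1)

  null <- screening_eligibility(polygenic_model(gamma = 0), rates,
                                threshold = 0.023, centile_width = 0.01)
  expect_true(null$fraction_population %in% c(0, 1))
  expect_equal(null$fraction_cases_captured, null$fraction_population)
})

test_that("cases captured by eligible centiles matches a microsimulation", {
  m <- polygenic_model(gamma = log(1.48))
  rates <- gen_rates_table()
  elig <- screening_eligibility(m, rates, threshold = 0.023,
                                centile_width = 0.01)
  expect_gt(elig$fraction_population, 0.05)
  expect_lt(elig$fraction_population, 0.6)
  expect_gt(elig$fraction_cases_captured, elig$fraction_population)

  mc <- micro_cases_captured(elig$curve, elig$eligible, n = 150000, seed = 6)
  expect_lt(abs(mc - elig$fraction_cases_captured), 0.03)
})

test_that("rates tables round-trip through CSV including the per-100k flag", {
  rates <- gen_rates_table(ages = 25:60)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rates_table(rates, path)
  back <- read_rates_table(path)
  expect_equal(back$incidence, rates$incidence, tolerance = 1e-12)

  scaled <- data.frame(age = rates$age, incidence = rates$incidence * 1e5,
                       competing_mortality = rates$competing_mortality * 1e5)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(scaled, p2, row.names = FALSE)
  back2 <- read_rates_table(p2, per100k = TRUE)
  expect_equal(back2$incidence, rates$incidence, tolerance = 1e-12)
})
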