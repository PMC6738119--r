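test_that("growth_spec validates its arguments", {
  expect_error(growth_spec("power"), "alpha")
  expect_error(growth_spec("power", alpha = 1.2), "alpha")
  expect_error(growth_spec("exponential", alpha = 0.5), "power")
  expect_error(growth_spec("exponential", K = 1e6), "Gompertz")
  expect_equal(growth_spec("gompertz")$K, 1e6)
})

test_that("forward_volume matches hand-evaluated closed forms", {
  expect_equal(forward_volume(growth_spec("exponential"), 100,
                              log(2) / 100, 100), 200)
  expect_equal(forward_volume(growth_spec("power", alpha = 0.5),
                              100, 0.2, 100), (10 + 0.5 * 0.2 * 100)^2)
  for (spec in list(growth_spec("exponential"),
                    growth_spec("power", alpha = 0.5),
                    growth_spec("power", alpha = 2 / 3),
                    growth_spec("gompertz"))) {
    expect_equal(forward_volume(spec, 123.4, 0.05, 0), 123.4)
  }
  expect_error(forward_volume(growth_spec("power", alpha = 0.5),
                              100, -1, 100), "regressed past zero")
})

test_that("invert_rate matches hand-evaluated closed forms", {
  expect_equal(invert_rate(growth_spec("exponential"), 100, 200, 100),
               log(2) / 100)
  expect_equal(invert_rate(growth_spec("gompertz", K = 1e6), 100, 200, 100),
               -log(log(5000) / log(10000)) / 100)
  expect_equal(invert_rate(growth_spec("gompertz", K = 1e6), 100, 200, 100),
               7.8236e-4, tolerance = 1e-4)
  expect_equal(invert_rate(growth_spec("power", alpha = 2 / 3),
                           1000, 8000, 30), 1.0)
  # cohort-mean volumes over the mean 18-month interval give the printed
  # mean rate 0.08 at two decimals
  r <- invert_rate(growth_spec("power", alpha = 0.5), 2742, 5573,
                   18 * days_per_month())
  expect_equal(r, 2 * (sqrt(5573) - sqrt(2742)) / (18 * 30.44))
  expect_equal(round(r, 2), 0.08)
  # zero growth gives rate zero under every law
  for (spec in list(growth_spec("exponential"),
                    growth_spec("power", alpha = 0.5),
                    growth_spec("gompertz"))) {
    expect_equal(invert_rate(spec, 500, 500, 300), 0)
  }
  expect_error(invert_rate(growth_spec("gompertz", K = 100), 99, 150, 10),
               "K")
})

test_that("invert and forward are exact inverses over random tuples", {
  set.seed(42)
  n <- 1000
  laws <- sample(c("exponential", "power_half", "power_two_thirds",
                   "gompertz"), n, replace = TRUE)
  v0 <- exp(runif(n, log(10), log(1e5)))
  r_true <- runif(n, 1e-5, 0.5)
  t <- runif(n, 1, 2000)
  grid <- default_model_grid(K = 1e7)
  rel_err <- numeric(n)
  for (i in seq_len(n)) {
    spec <- grid$laws[[laws[i]]]
    # keep exponential/Gompertz rates in a range where volumes stay finite
    r_i <- if (laws[i] %in% c("exponential", "gompertz")) {
      r_true[i] / 100
    } else {
      r_true[i]
    }
    v1 <- forward_volume(spec, v0[i], r_i, t[i])
    if (laws[i] == "gompertz" && v1 >= spec$K) next
    r_back <- invert_rate(spec, v0[i], v1, t[i])
    rel_err[i] <- abs(r_back - r_i) / r_i
  }
  expect_lt(max(rel_err), 1e-9)
})

test_that("invert_rate is monotone in v1 and in dt", {
  for (spec in list(growth_spec("exponential"),
                    growth_spec("power", alpha = 0.5),
                    growth_spec("gompertz"))) {
    v1s <- seq(150, 900, by = 50)
    rates <- invert_rate(spec, 100, v1s, 365)
    expect_true(all(diff(rates) > 0))
    dts <- seq(30, 730, by = 50)
    rates_dt <- invert_rate(spec, 100, 400, dts)
    expect_true(all(diff(rates_dt) < 0))
  }
})

test_that("rates scale correctly under volume rescaling", {
  v0 <- 321; v1 <- 987; dt <- 400; s <- 7.5
  expect_equal(invert_rate(growth_spec("exponential"), s * v0, s * v1, dt),
               invert_rate(growth_spec("exponential"), v0, v1, dt))
  for (alpha in c(0.5, 2 / 3)) {
    spec <- growth_spec("power", alpha = alpha)
    expect_equal(invert_rate(spec, s * v0, s * v1, dt),
                 s^(1 - alpha) * invert_rate(spec, v0, v1, dt))
  }
})

test_that("Gompertz approaches the exponential law as K grows", {
  v0 <- 200; v1 <- 800; dt <- 500
  r_exp <- invert_rate(growth_spec("exponential"), v0, v1, dt)
  err <- vapply(c(1e6, 1e9, 1e12), function(K) {
    rg <- invert_rate(growth_spec("gompertz", K = K), v0, v1, dt)
    abs(rg * log(K / v0) - r_exp)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("cohort_rates maps invert_rate with per-record diagnostics", {
  cohort <- toy_cohort()
  spec <- growth_spec("power", alpha = 0.5)
  rr <- cohort_rates(cohort, "sphere", spec)
  expect_equal(nrow(rr), 3L)
  v0 <- lesion_volume(cohort$screen_dim_major, cohort$screen_dim_minor,
                      "sphere")
  v1 <- lesion_volume(cohort$diag_dim_major, cohort$diag_dim_minor,
                      "sphere")
  expect_equal(rr$rate, invert_rate(spec, v0, v1, cohort$interval_days))
  # a record with missing interval yields NA + diagnostic, not a drop
  df <- toy_cohort_df(); df$interval_days[2] <- NA
  rr2 <- cohort_rates(as_cohort(df), "sphere", spec)
  expect_equal(nrow(rr2), 3L)
  expect_true(is.na(rr2$rate[2]))
  expect_match(rr2$note[2], "interval")
  # identical screening/diagnostic dimensions give rate zero
  df3 <- toy_cohort_df()
  df3$diag_dim_major <- df3$screen_dim_major
  df3$diag_dim_minor <- df3$screen_dim_minor
  expect_equal(cohort_rates(as_cohort(df3), "sphere", spec)$rate,
               rep(0, 3))
  # shrinkage is retained and flagged
  df4 <- toy_cohort_df()
  df4$diag_dim_major <- df4$screen_dim_major * 0.8
  df4$diag_dim_minor <- df4$screen_dim_minor * 0.8
  rr4 <- cohort_rates(as_cohort(df4), "sphere", spec)
  expect_true(all(rr4$rate < 0))
  expect_match(rr4$note, "shrinkage")
})

test_that("tumour_age back-dates volumes and inverts forward_volume", {
  spec <- growth_spec("power", alpha = 0.5)
  # bounded slow-group rate applied to the mean diagnostic volume
  expect_equal(tumour_age(spec, 5573, 0.04593, 0),
               2 * sqrt(5573) / 0.04593)
  expect_equal(tumour_age(spec, 5573, 0.04593, 0), 3250.5, tolerance = 1e-4)
  expect_equal(tumour_age(spec, 500, 0.1, 500), 0)
  # round trip through forward_volume for every law
  for (s in list(growth_spec("exponential"),
                 growth_spec("power", alpha = 2 / 3),
                 growth_spec("gompertz"))) {
    v1 <- forward_volume(s, 150, 0.002, 700)
    expect_equal(tumour_age(s, v1, 0.002, 150), 700)
  }
  expect_error(tumour_age(spec, 100, -0.1, 0), "positive")
  expect_error(tumour_age(growth_spec("exponential"), 100, 0.1, 0),
               "v_inception")
})
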