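test_that("coupled logistic maps are seed-deterministic with declared truth", {
  s1 <- coupled_logistic(seed = 4)
  s2 <- coupled_logistic(seed = 4)
  expect_identical(s1$A$values, s2$A$values)
  expect_identical(s1$B$values, s2$B$values)
  expect_false(identical(s1$A$values, coupled_logistic(seed = 5)$A$values))

  expect_identical(s1$truth, data.frame(from = "B", to = "A"))
  free <- coupled_logistic(beta_ab = 0, beta_ba = 0, seed = 4)
  expect_identical(nrow(free$truth), 0L)
  both <- coupled_logistic(beta_ab = 0.3, beta_ba = 0.1, seed = 4)
  expect_identical(nrow(both$truth), 2L)

  expect_true(all(s1$A$values > 0 & s1$A$values < 1))
  expect_true(all(s1$B$values > 0 & s1$B$values < 1))
  expect_length(s1$A, 45L)
})

test_that("the logistic recurrence matches an independent hand iteration", {
  sys <- coupled_logistic(r_a = 3.8, r_b = 3.7, beta_ab = 0.3, beta_ba = 0,
                          n = 5, seed = 31, burn_in = 300)
  # replay the generator's draw and recurrence with an explicit loop
  set.seed(31L)
  a <- runif(1, 0.2, 0.8)
  b <- runif(1, 0.2, 0.8)
  hist_a <- a; hist_b <- b
  for (t in 1:304) {
    a_new <- a * (3.8 - 3.8 * a - 0.3 * b)
    b_new <- b * (3.7 - 3.7 * b - 0 * a)
    a <- a_new; b <- b_new
    hist_a <- c(hist_a, a); hist_b <- c(hist_b, b)
  }
  expect_equal(rev(sys$A$values), hist_a[301:305], tolerance = 1e-14)
  expect_equal(rev(sys$B$values), hist_b[301:305], tolerance = 1e-14)
})

test_that("divergent logistic parameters are rejected", {
  expect_error(coupled_logistic(r_a = 4.2, seed = 1), "chaotic regime")
})

test_that("the phanerozoic-like bundle has the documented shape and structure", {
  b <- phanerozoic_like(seed = 3)
  for (nm in c("driver", "response", "total_burial", "cs_ratio")) {
    expect_s3_class(b[[nm]], "paleo_ts")
    expect_length(b[[nm]], 45L)
    expect_equal(range(b[[nm]]$ages), c(0, 541))
  }
  expect_true(all(b$total_burial$values > 0))
  expect_identical(b$truth, data.frame(from = "driver", to = "response"))
  expect_identical(nrow(phanerozoic_like(seed = 3, coupling = 0)$truth), 0L)

  # C/S minimum sits in the oldest third of the record
  cs <- b$cs_ratio
  oldest_third <- cs$ages >= max(cs$ages) * 2 / 3
  expect_true(oldest_third[which.min(cs$values)])

  # seed determinism and round-trippable file format
  b2 <- phanerozoic_like(seed = 3)
  expect_identical(b$driver$values, b2$driver$values)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series(b$cs_ratio, f)
  expect_identical(read_series(f)$values, b$cs_ratio$values)
})

test_that("AR(1) null pairs have the requested autocorrelation and are independent", {
  # phi = 0: white noise, lag-1 autocorrelation within 2/sqrt(n)
  w <- ar1_null(phi = 0, n = 200, seed = 8)
  expect_lt(abs(acf(w$A$values, lag.max = 1, plot = FALSE)$acf[2]),
            2 / sqrt(200))

  # phi = 0.6: sample lag-1 autocorrelation within +/- 0.2 for n = 200
  for (s in 1:10) {
    p <- ar1_null(phi = 0.6, n = 200, seed = s)
    expect_lt(abs(acf(p$A$values, lag.max = 1, plot = FALSE)$acf[2] - 0.6), 0.2)
  }

  # independence: lag-0 cross-correlation centred on zero across seeds,
  # with most draws inside the 2/sqrt(n) band
  cors <- vapply(1:25, function(s) {
    p <- ar1_null(phi = 0.5, n = 200, seed = s)
    cor(p$A$values, p$B$values)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  expect_gte(mean(abs(cors) < 2 / sqrt(200)), 0.8)

  expect_error(ar1_null(phi = 1), "phi")
})

test_that("detection power rises with coupling strength in the phanerozoic generator", {
  power_at <- function(cp) {
    mean(vapply(1:20, function(s) {
      b <- phanerozoic_like(seed = s, coupling = cp)
      ccm_significance(normalize_series(b$response), b$driver, E = 3,
                       n_surrogates = 100, seed = s + 100)$significant
    }, logical(1)))
  }
  p <- c(power_at(0), power_at(1), power_at(2))
  # monotone non-decreasing up to Monte-Carlo noise; strong coupling clearly
  # beats the uncoupled rejection rate
  expect_gte(p[3], p[1] + 0.4)
  expect_gte(p[2], p[1])
})
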