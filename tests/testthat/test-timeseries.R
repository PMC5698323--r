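test_that("series files parse, validate, and round-trip regardless of row order", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_Ma,value", "0,1.0", "11,2.0"), f)
  ts <- read_series(f, name = "demo")
  expect_s3_class(ts, "paleo_ts")
  expect_length(ts, 2L)
  expect_equal(ts$values, c(1, 2))

  # shuffled rows give the same series as sorted input
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# comment", "300,3.5", "0,1.25", "150,-2.0"), f2)
  shuffled <- read_series(f2, name = "demo")
  expect_equal(shuffled$ages, c(0, 150, 300))
  expect_equal(shuffled$values, c(1.25, -2.0, 3.5))

  # whitespace-delimited autodetection
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1.0", "11 2.0"), f3)
  expect_equal(read_series(f3)$values, c(1, 2))

  # full-precision round trip
  set.seed(1)
  orig <- paleo_ts(sort(runif(20, 0, 541)), rnorm(20), name = "rt")
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_series(orig, f4)
  back <- read_series(f4, name = "rt")
  expect_identical(back$ages, orig$ages)
  expect_identical(back$values, orig$values)
})

test_that("malformed input files fail with the offending row named", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1.0", "11,2.0", "11,3.0"), f)
  expect_error(read_series(f), "duplicate age 11")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1.0", "oops,2.0", "22,3.0"), f2)
  expect_error(read_series(f2), "line 2")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("0,1.0", f3)
  expect_error(read_series(f3), "at least 2")
})

test_that("constructor enforces the series invariants", {
  expect_error(paleo_ts(c(0, 10, 10), 1:3), "duplicate")
  expect_error(paleo_ts(c(0, 10), c(1, NA)), "finite")
  expect_error(paleo_ts(c(0, Inf), c(1, 2)), "finite")
  expect_error(paleo_ts(c(-5, 10), c(1, 2)), "non-negative")
  # any input order is stored ascending
  ts <- paleo_ts(c(300, 0, 150), c(3, 1, 2))
  expect_identical(ts$ages, c(0, 150, 300))
})

test_that("interpolation is knot-exact and matches simple closed forms", {
  s <- paleo_ts(c(0, 10), c(0, 10))
  expect_equal(interpolate_series(s, 5)$values, 5)

  set.seed(2)
  src <- paleo_ts(seq(0, 100, by = 10), rnorm(11))
  for (m in c("linear", "cubic")) {
    at_knots <- interpolate_series(src, src$ages, method = m)
    if (m == "linear") expect_identical(at_knots$values, src$values)
    else expect_equal(at_knots$values, src$values, tolerance = 1e-12)
  }

  # cubic interpolation reproduces a cubic polynomial away from the knots
  p <- function(x) 2 - x + 0.5 * x^2 - 0.03 * x^3
  knots <- c(0, 9, 21, 30, 42, 50)
  src2 <- paleo_ts(knots, p(knots))
  off <- c(3.7, 14.2, 25.5, 36.1, 47.9)
  got <- interpolate_series(src2, off, method = "cubic")$values
  expect_equal(got, p(off), tolerance = 1e-6)

  expect_error(interpolate_series(s, 11), "extrapolation")
  expect_error(interpolate_series(s, c(5, 5)), "duplicate")
})

test_that("linear interpolation is monotone between knots; cubic may overshoot", {
  step <- paleo_ts(c(0, 10, 20, 30), c(0, 0, 1, 1))
  fine <- seq(0, 30, by = 0.5)
  lin <- interpolate_series(step, fine, "linear")$values
  expect_true(all(lin >= 0 & lin <= 1))
  expect_true(all(diff(lin) >= 0))
  cub <- interpolate_series(step, fine, "cubic")$values
  expect_true(max(cub) > 1 || min(cub) < 0)
})

test_that("alignment projects onto the base grid and is idempotent", {
  set.seed(3)
  dense <- paleo_ts(seq(0, 541, by = 5), sin(seq(0, 541, by = 5) / 50))
  base <- paleo_ts(c(10, 250, 530), c(1, 2, 3), name = "base")

  out <- align_series(list(dense, base), base)
  expect_length(out[[1]], 3L)
  expect_identical(out[[1]]$ages, base$ages)
  # the base itself passes through unchanged
  expect_identical(out[[2]]$values, base$values)

  # aligning twice onto the same base equals aligning once
  twice <- align_series(out, base)
  expect_identical(twice[[1]]$values, out[[1]]$values)

  # identical series aligned to one of them stay unchanged
  same <- align_series(list(base, base), base)
  expect_identical(same[[1]]$values, base$values)
  expect_identical(same[[2]]$values, base$values)
})

test_that("alignment never extrapolates: trims with a warning or errors by name", {
  short <- paleo_ts(c(100, 300), c(1, 2), name = "shorty")
  base <- paleo_ts(c(0, 150, 250, 400), c(1, 1, 1, 1), name = "base")
  expect_warning(out <- align_series(list(short, base), base), "trimmed")
  expect_identical(attr(out, "grid"), c(150, 250))
  expect_error(
    align_series(list(short, base), base, trim = FALSE),
    "shorty"
  )
})

test_that("linear and cubic alignment of a smooth noisy series agree within the noise scale", {
  set.seed(4)
  ages <- seq(0, 541, by = 4)
  noise_sd <- 0.1
  smooth <- paleo_ts(ages, sin(ages / 60) + rnorm(length(ages), 0, noise_sd))
  base <- paleo_ts(seq(10, 530, length.out = 45), numeric(45) + 1)
  lin <- align_series(list(smooth), base, method = "linear")[[1]]
  cub <- align_series(list(smooth), base, method = "cubic")[[1]]
  expect_lt(max(abs(lin$values - cub$values)), noise_sd)
})

test_that("normalization divides by the chosen statistic and is idempotent", {
  s <- paleo_ts(c(0, 10), c(2, 4))
  expect_equal(normalize_series(s, "max")$values, c(0.5, 1.0))
  expect_equal(normalize_series(s, "mean")$values, c(2 / 3, 4 / 3))
  expect_equal(mean(normalize_series(s, "mean")$values), 1)

  set.seed(5)
  r <- paleo_ts(demo_grid(20), runif(20, 1, 5))
  once <- normalize_series(r, "mean")
  expect_equal(normalize_series(once, "mean")$values, once$values)

  z <- paleo_ts(c(0, 10), c(-1, 1))
  expect_error(normalize_series(z, "mean"), "zero")
})
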