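test_that("curve reader normalises direction and rejects bad files", {
  tmp <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# toy curve", "200,300,10", "100,200,10", "0,100,10"), tmp)
  cv <- read_cal_curve(tmp)
  expect_s3_class(cv, "cal_curve")
  expect_equal(nrow(cv), 3)
  expect_equal(cv$cal_bp, c(0, 100, 200))

  writeLines(c("0,100,10", "100,200,-5"), tmp)
  expect_error(read_cal_curve(tmp), "non-positive errors")

  writeLines(c("0,100,10", "0,150,10"), tmp)
  expect_error(read_cal_curve(tmp), "monotone")

  writeLines(c("0,100,10", "oops"), tmp)
  expect_error(read_cal_curve(tmp), "line 2")
})

test_that("date filter drops big errors and aggregates, keeps the boundary", {
  d <- data.frame(lab_code = c("L1", "L2", "L3", "L4"),
                  site_id = "S", level_id = "a",
                  c14_age = c(8000, 8000, 8000, 8000),
                  sigma = c(120, 100, 40, 60),
                  material_class = c("short_lived", "short_lived",
                                     "aggregate", "unknown"))
  kept <- suppressMessages(filter_c14_dates(d))
  expect_setequal(kept$lab_code, c("L2", "L4"))
  expect_message(filter_c14_dates(d[1, ]), "error 120 > 100")
  expect_message(filter_c14_dates(d[3, ]), "aggregate")
})

test_that("calibration on the identity curve recovers a normalised Gaussian", {
  cv <- identity_cal_curve(cal_min = 6000, cal_max = 10000, step = 5,
                           sigma = 1)
  d <- calibrate_date(8000, 50, cv)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  expect_equal(d$mode, 8000)
  expect_equal(d$median, 8000)
  # symmetric about the mode
  i_lo <- match(7950, d$grid)
  i_hi <- match(8050, d$grid)
  expect_equal(d$prob[i_lo], d$prob[i_hi], tolerance = 1e-12)
  # HPD mass just reaches the two-sigma level
  mass <- sum(d$prob[d$two_sigma])
  expect_gte(mass, 0.954)
  expect_lte(mass, 0.959)
  # the two-sigma set is the analytic +/- 1.96 sigma interval (sigma_tot
  # ~ sqrt(50^2 + 1)); discreteness allows a couple of years of slack
  rng <- range(d$grid[d$two_sigma])
  expect_lt(abs(rng[1] - 7902), 3)
  expect_lt(abs(rng[2] - 8098), 3)
  # shift equivariance on the identity curve
  d2 <- calibrate_date(8137, 50, cv)
  expect_equal(d2$mode, 8137)
  expect_error(calibrate_date(20000, 50, cv), "outside the curve")
})

test_that("calibration matches the closed form on a non-identity linear curve", {
  # curve c14 = 0.5 * cal + 1000: a date y +/- s has posterior
  # N(2 (y - 1000), 2 sqrt(s^2 + tau^2)) in calendar age
  grid <- seq(6000, 10000, by = 5)
  cv <- structure(
    data.frame(cal_bp = grid, c14_bp = 0.5 * grid + 1000,
               sigma_curve = rep(2, length(grid))),
    class = c("cal_curve", "data.frame"))
  d <- calibrate_date(5000, 50, cv)
  expect_equal(d$mode, 8000)
  sd_cal <- 2 * sqrt(50^2 + 2^2)
  expected <- dnorm(d$grid, 8000, sd_cal)
  expected <- expected / sum(expected)
  expect_lt(max(abs(d$prob - expected)), 1e-6)
})

test_that("time bins tile the range in closed 200-year sets", {
  b <- time_bins()
  expect_equal(nrow(b), 9)
  expect_equal(b$label[1], "8600-8401")
  expect_equal(b$label[9], "7000-6801")
  expect_true(all(b$start - b$end == 199))
  # contiguous, no overlap
  expect_equal(b$end[-9] - 1L, b$start[-1])
  expect_error(time_bins(8600, 6800, 200), "whole number")
})

test_that("bin assignment follows the probability-mass rule", {
  cv <- identity_cal_curve(cal_min = 6000, cal_max = 10000)
  bins <- time_bins()
  # date centred on a bin boundary: mass splits ~50/50, both bins assigned
  d_split <- data.frame(lab_code = "L1", site_id = "S", level_id = "x",
                        c14_age = 8400, sigma = 40,
                        material_class = "short_lived")
  m <- assign_time_bins(d_split, cv, bins)
  expect_equal(m$bins, "8600-8401;8400-8201")
  # date well inside one bin: exactly that bin
  d_in <- data.frame(lab_code = "L2", site_id = "S", level_id = "y",
                     c14_age = 8500, sigma = 30,
                     material_class = "short_lived")
  expect_equal(assign_time_bins(d_in, cv, bins)$bins, "8600-8401")
  # per-date OR combination across a context's dates
  d_two <- data.frame(lab_code = c("L3", "L4"), site_id = "S",
                      level_id = "z", c14_age = c(8500, 8300),
                      sigma = c(30, 30),
                      material_class = "short_lived")
  expect_equal(assign_time_bins(d_two, cv, bins)$bins,
               "8600-8401;8400-8201")
})

test_that("bin assignment is monotone in the threshold", {
  cv <- identity_cal_curve(cal_min = 6000, cal_max = 10000)
  bins <- time_bins()
  set.seed(7)
  for (i in 1:10) {
    age <- round(runif(1, 7100, 8500))
    sig <- round(runif(1, 20, 100))
    d <- data.frame(lab_code = "L", site_id = "S", level_id = "l",
                    c14_age = age, sigma = sig,
                    material_class = "short_lived")
    lo <- assign_time_bins(d, cv, bins, threshold = 0.20)
    hi <- suppressWarnings(assign_time_bins(d, cv, bins, threshold = 0.50))
    lo_bins <- strsplit(lo$bins, ";")[[1]]
    hi_bins <- if (is.null(hi)) character(0) else strsplit(hi$bins, ";")[[1]]
    expect_true(all(hi_bins %in% lo_bins))
    # threshold <= 0.5 on two-sigma-renormalised mass within range:
    # at least one bin always qualifies
    expect_gte(length(lo_bins), 1)
  }
})

test_that("printed time frames map onto bins by the overlap rule", {
  bins <- time_bins()
  fr <- frames_to_bins(c("8600-8401", "8600-8201", "8200-7601",
                         "7400-7200", "7800-7600", "7000-6800"), bins)
  expect_equal(fr[[1]], "8600-8401")
  expect_equal(fr[[2]], c("8600-8401", "8400-8201"))
  expect_equal(fr[[3]], c("8200-8001", "8000-7801", "7800-7601"))
  # frames whose printed endpoint is one year off the grid stay in one bin
  expect_equal(fr[[4]], "7400-7201")
  expect_equal(fr[[5]], "7800-7601")
  expect_equal(fr[[6]], "7000-6801")
  expect_error(frames_to_bins("84008001", bins), "malformed")
})
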