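test_that("the model evaluates to the background at t = 0 and t -> Inf", {
  expect_equal(mariottiEval(0, 6, 2.8, 125, 15), 15)
  expect_equal(mariottiEval(1e9, 6, 2.8, 125, 15), 15)
  # direct evaluation at the SNB19 peak time: 36 * 0.9781 * 0.9180 + 15
  expect_equal(mariottiEval(10.70, 6, 2.8, 125, 15),
               36 * (1 - exp(-10.70 / 2.8)) * exp(-10.70 / 125) + 15)
  expect_equal(mariottiEval(10.70, 6, 2.8, 125, 15), 47.323, tolerance = 1e-4)
  expect_error(mariottiEval(-1, 6, 2.8, 125, 15), "non-negative")
  # the count never falls below the background
  tt <- seq(0, 2000, by = 7)
  expect_true(all(mariottiEval(tt, 4, 5, 200, 11) >= 11))
})

test_that("the analytic peak time matches the numeric maximum", {
  expect_equal(mariottiPeakTime(3, 3), 3 * log(2))
  numericPeak <- function(tau1, tau2) {
    stats::optimize(function(t) (1 - exp(-t / tau1)) * exp(-t / tau2),
                    c(0, 20 * tau1 * log(1 + tau2 / tau1)),
                    maximum = TRUE, tol = 1e-8)$maximum
  }
  # printed time constants of the two glioblastoma lines
  expect_equal(mariottiPeakTime(2.8, 125), 10.698, tolerance = 1e-4)
  expect_equal(mariottiPeakTime(8.4, 326), 30.946, tolerance = 1e-4)
  for (tau1 in c(1, 2.8, 5, 10))
    for (tau2 in c(50, 125, 326, 500))
      expect_lt(abs(mariottiPeakTime(tau1, tau2) - numericPeak(tau1, tau2)),
                0.01)
  expect_error(mariottiPeakTime(0, 10), "positive")
})

test_that("noiseless simulate-and-fit recovers the parameters", {
  tt <- c(0, 2, 5, 10, 20, 45, 90, 180, 360, 720, 1080, 1440)
  truth <- c(A = 6, tau1 = 2.8, tau2 = 125, R = 15)
  d <- simulateKinetics(tt, 6, 2.8, 125, 15, noiseSd = 0)
  expect_equal(d$count, mariottiEval(tt, 6, 2.8, 125, 15))
  fit <- fitMariotti(d$time, d$count)
  expect_true(fit@converged)
  expect_true(all(abs(fit@params - truth) / truth < 0.01))
  expect_equal(fit@peakTime, mariottiPeakTime(fit@params[["tau1"]],
                                              fit@params[["tau2"]]))
})

test_that("a constant series fits as pure background (A ~ 0)", {
  fit <- fitMariotti(c(0, 10, 100, 1000), rep(15, 4))
  expect_true(fit@converged)
  expect_lt(fit@params[["A"]], 1e-6)
  expect_equal(fit@params[["R"]], 15)
})

test_that("fitting validates its inputs", {
  expect_error(fitMariotti(c(0, 1, 2), c(1, 2, 3)), "at least 4")
  expect_error(fitMariotti(c(0, 2, 1, 3), c(1, 2, 3, 4)), "increasing")
  expect_error(fitMariotti(0:3, c(-1, 2, 3, 4)), "non-negative")
  expect_error(fitMariotti(0:3, 1:4, se = c(1, 1)), "se must")
})

test_that("simulation is deterministic per seed and unbiased in the mean", {
  tt <- c(0, 5, 15, 60, 240)
  a <- simulateKinetics(tt, 6, 2.8, 125, 15, noiseSd = 2, seed = 42)
  b <- simulateKinetics(tt, 6, 2.8, 125, 15, noiseSd = 2, seed = 42)
  expect_identical(a, b)
  cc <- simulateKinetics(tt, 6, 2.8, 125, 15, noiseSd = 2, seed = 43)
  expect_false(identical(a, cc))
  # law of large numbers at one time point (mu >> sd, clipping negligible)
  d <- simulateKinetics(rep(10.7, 1e4), 6, 2.8, 125, 15, noiseSd = 2,
                        seed = 7)
  expect_equal(mean(d$count), mariottiEval(10.7, 6, 2.8, 125, 15),
               tolerance = 0.005)
})

test_that("kinetics TSV round trip feeds the fit", {
  tt <- c(0, 5, 10, 20, 45, 90, 180, 360, 720, 1440)
  d <- simulateKinetics(tt, 5, 3, 150, 12, noiseSd = 0)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(time_min = d$time, mean_foci = d$count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- runKinetics(path)
  expect_true(rep$converged)
  expect_equal(rep$tau2, 150, tolerance = 0.01)
  expect_equal(rep$peakTime, mariottiPeakTime(rep$tau1, rep$tau2))
  # under-determined series is a parameter error
  path3 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(t = c(0, 10, 30), y = c(1, 2, 3)), path3,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(runKinetics(path3), "at least 4")
  unlink(c(path, path3))
})
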