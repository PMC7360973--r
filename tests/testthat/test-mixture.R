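test_that("trimerComposition matches hand values and the enumeration oracle", {
  f <- fractions(trimerComposition(2, 1))
  expect_equal(unname(f), c(8, 12, 6, 1) / 27, tolerance = 1e-12)
  expect_equal(unname(fractions(trimerComposition(1, 0))), c(1, 0, 0, 0))
  expect_equal(unname(fractions(trimerComposition(1, 1))),
               c(0.125, 0.375, 0.375, 0.125))

  withr::with_seed(7, {
    for (i in 1:100) {
      a <- runif(1, 0, 10); b <- runif(1, 0, 10)
      if (a + b == 0) next
      expect_equal(fractions(trimerComposition(a, b)),
                   oracleComposition(a, b), tolerance = 1e-12)
    }
  })
  expect_error(trimerComposition(0, 0), "positive sum")
  expect_error(trimerComposition(-1, 2), "non-negative")
})

test_that("compositions are exchange-symmetric and sum to one", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- runif(1, 0, 5); b <- runif(1, 0, 5)
      if (a + b == 0) next
      f_ab <- fractions(trimerComposition(a, b))
      f_ba <- fractions(trimerComposition(b, a))
      expect_equal(unname(f_ab), rev(unname(f_ba)), tolerance = 1e-12)
      expect_equal(sum(f_ab), 1, tolerance = 1e-12)
    }
  })
})

test_that("mixtureSignal reduces to its limiting cases", {
  t <- seq(0, 100, by = 0.5)
  k <- c(0.005, 0.02, 0.05)
  # pure 0-site homotrimer never dissociates
  f0only <- c(f3 = 0, f2 = 0, f1 = 0, f0 = 1)
  expect_equal(mixtureSignal(t, k, f0only, 200, 80, 7), rep(200, length(t)))
  # pure wild type: identical to the delay-exponential at k3
  f3only <- trimerComposition(1, 0)
  expect_equal(mixtureSignal(t, k, f3only, 200, 80, 7),
               delayExponential(t, 200, 80, k[3], 7))
  # equal rates: delay-exponential scaled by the dissociable fraction
  comp <- trimerComposition(1, 2)
  f <- fractions(comp)
  keq <- c(0.04, 0.04, 0.04)
  expected <- 80 + (200 - 80) *
    (f[["f0"]] + (1 - f[["f0"]]) *
       ifelse(t <= 7, 1, exp(-0.04 * (t - 7))))
  expect_equal(mixtureSignal(t, keq, comp, 200, 80, 7), expected,
               tolerance = 1e-12)
})

test_that("mixtureSignal equals y_max during the lag for every composition", {
  withr::with_seed(13, {
    for (i in 1:20) {
      comp <- trimerComposition(runif(1, 0, 3), runif(1, 0, 3))
      tlag <- runif(5, 0, 7)
      expect_equal(mixtureSignal(tlag, c(0.01, 0.03, 0.08), comp,
                                 200, 80, 7),
                   rep(200, 5), tolerance = 1e-12)
    }
  })
})

test_that("nullPrediction amplitudes follow the composition algebra", {
  t <- c(0, 50, 1e6)
  # pure wild type: single-site null equals the full wild-type curve
  wt <- trimerComposition(1, 0)
  expect_equal(nullPrediction("single_site_null", t, wt, 0.05, 200, 80, 7),
               delayExponential(t, 200, 80, 0.05, 7))
  # ratio 1:2 -> decaying fractions (1/3)^3 and 1 - (2/3)^3
  comp <- trimerComposition(1, 2)
  y3 <- nullPrediction("three_sites_null", 1e9, comp, 0.05, 200, 80, 7)
  expect_equal((200 - y3) / (200 - 80), 1 / 27, tolerance = 1e-9)
  y1 <- nullPrediction("single_site_null", 1e9, comp, 0.05, 200, 80, 7)
  expect_equal((200 - y1) / (200 - 80), 1 - 8 / 27, tolerance = 1e-9)
  expect_error(nullPrediction("bogus", t, comp, 0.05, 200, 80, 7),
               "unknown variant")
})

test_that("globalFitMixture round-trips a noiseless 5-ratio design", {
  traces <- genMixtureExperiment(noiseSd = 0, seed = 1)
  fit <- globalFitMixture(traces)
  expect_true(converged(fit))
  expect_equal(unname(rates(fit)), c(0.005, 0.02, 0.05),
               tolerance = 1e-5)
  expect_equal(fit@perTrace$y_max, rep(200, 5), tolerance = 1e-4)
  expect_equal(fit@perTrace$t0[1:4], rep(7, 4), tolerance = 1e-3)
})

test_that("globalFitMixture flags non-identifiable rates", {
  one <- genMixtureExperiment(ratios = list(c(1, 0)), noiseSd = 0,
                              seed = 2)
  fit <- globalFitMixture(one)
  expect_true(converged(fit))
  expect_match(fit@message, "under-determined")
  expect_true(is.infinite(stderrs(fit)[["k1"]]))
  expect_true(is.infinite(stderrs(fit)[["k2"]]))
  expect_false(is.infinite(stderrs(fit)[["k3"]]))
  expect_equal(rates(fit)[["k3"]], 0.05, tolerance = 1e-4)
})

test_that("fitted rates preserve the generating order under noise", {
  ok <- vapply(1:20, function(s) {
    k <- rates(globalFitMixture(genMixtureExperiment(noiseSd = 2.4,
                                                     seed = s)))
    k[["k1"]] < k[["k2"]] && k[["k2"]] < k[["k3"]]
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("compareModels prefers the generating variant", {
  # well-separated rates: the multi-rate model must win
  trs <- genMixtureExperiment(noiseSd = 2.4, seed = 5)
  tab <- compareModels(trs)$table
  expect_equal(tab$variant[tab$preferred], "full")
  aic <- setNames(tab$aic, tab$variant)
  expect_lt(aic[["full"]], aic[["single_site_null"]])
  expect_lt(aic[["full"]], aic[["three_sites_null"]])

  # data generated from the three-sites-required null
  traces3 <- withr::with_seed(6, lapply(
    list(c(1, 0), c(2, 1), c(1, 1), c(1, 2)), function(r) {
      comp <- trimerComposition(r[1], r[2])
      mu <- nullPrediction("three_sites_null", 0:100, comp, 0.05,
                           200, 80, 7)
      KineticTrace(0:100, mu + rnorm(101, 0, 2.4), ratio = r,
                   label = paste(r, collapse = ":"))
    }))
  tab3 <- compareModels(traces3)$table
  aic3 <- setNames(tab3$aic, tab3$variant)
  expect_lt(aic3[["three_sites_null"]], aic3[["single_site_null"]])
})

test_that("equal-rate data leaves the single-site null competitive", {
  daic <- vapply(1:10, function(s) {
    trs <- genMixtureExperiment(rates = c(0.05, 0.05, 0.05),
                                noiseSd = 2.4, seed = s)
    tab <- compareModels(trs)$table
    aic <- setNames(tab$aic, tab$variant)
    aic[["single_site_null"]] - aic[["full"]]
  }, 0)
  expect_lte(median(daic), 2)
})
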