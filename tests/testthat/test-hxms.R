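test_that("centroidMass is the intensity-weighted mean", {
  expect_equal(centroidMass(c(1250, 1251), c(1, 3)), 1250.75)
  # symmetric envelope -> its center of symmetry
  m <- 1246:1254
  i <- c(1, 2, 4, 7, 9, 7, 4, 2, 1)
  expect_equal(centroidMass(m, i), 1250)
  expect_error(centroidMass(c(1, 2, 3, 4), c(0, 0, 0, 0)), "positive")
})

test_that("centroidMass is scale-invariant and translation-equivariant", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      m <- sort(runif(10, 1000, 1010))
      i <- runif(10, 0, 5)
      c0 <- centroidMass(m, i)
      expect_equal(centroidMass(m, 7.3 * i), c0, tolerance = 1e-12)
      expect_equal(centroidMass(m + 11.5, i), c0 + 11.5,
                   tolerance = 1e-9)
    }
  })
})

test_that("maxExchangeable applies the length-2-prolines rule", {
  expect_equal(maxExchangeable("NRILGVKRKC"), 8)
  expect_equal(maxExchangeable("GVKRKIPLMLNC"), 9)
  # prolines in the first two positions do not subtract twice
  expect_equal(maxExchangeable("PPAAA"), 3)
  expect_equal(maxExchangeable("APAPA"), 2)
  expect_error(maxExchangeable("AP"), "too short")
})

test_that("correctBackExchange converts centroids to deuteron counts", {
  r <- correctBackExchange(1250.60, 1250.00, 1256.00, nMax = 10)
  expect_equal(r$deuterons, 1.0)
  expect_equal(r$relative, 0.1)
  expect_equal(correctBackExchange(1250, 1250, 1256, 10)$deuterons, 0)
  full <- correctBackExchange(1256, 1250, 1256, 10)
  expect_equal(full$deuterons, 10)
  expect_equal(full$relative, 1)
  expect_error(correctBackExchange(1251, 1250, 1250, 10), "exceed")
})

test_that("correctBackExchange is invariant under mass-axis rescaling", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      und <- runif(1, 1000, 2000)
      fd <- und + runif(1, 2, 12)
      obs <- und + runif(1, 0, fd - und)
      a <- runif(1, 0.5, 2); b <- runif(1, -100, 100)
      d0 <- correctBackExchange(obs, und, fd, 8)$deuterons
      d1 <- correctBackExchange(a * obs + b, a * und + b, a * fd + b,
                                8)$deuterons
      expect_equal(d1, d0, tolerance = 1e-9)
    }
  })
})

test_that("differenceTable computes protection differences and flags", {
  peptides <- paste0("pep", 1:4)
  make_side <- function(means, sd, seed) withr::with_seed(seed,
    do.call(rbind, lapply(seq_along(peptides), function(i)
      data.frame(peptide_id = peptides[i],
                 deuterons = rnorm(3, means[i], sd)))))
  ref <- make_side(c(3, 4, 5, 2), 0.05, 21)
  cond <- make_side(c(3, 4, 5 - 0.8, 2), 0.05, 22)  # pep3 protected
  res <- differenceTable(cond, ref)
  d <- res$differences
  expect_equal(nrow(d), 4)
  p3 <- d[d$peptide_id == "pep3", ]
  expect_true(p3$significant)
  expect_lt(abs(p3$dD - (-0.8)), 0.1)
  expect_false(any(d$significant[d$peptide_id != "pep3"]))
  expect_equal(nrow(res$unmatched), 0)
})

test_that("identical conditions give zero differences, none significant", {
  side <- data.frame(peptide_id = rep(c("a", "b"), each = 3),
                     deuterons = c(1.0, 1.1, 0.9, 3.0, 3.1, 2.9))
  res <- differenceTable(side, side)
  expect_equal(res$differences$dD, c(0, 0))
  expect_false(any(res$differences$significant))
})

test_that("unmatched peptides are listed, not dropped", {
  cond <- data.frame(peptide_id = rep("a", 3), deuterons = 1:3)
  ref <- data.frame(peptide_id = rep(c("a", "b"), each = 3),
                    deuterons = rep(1:3, 2))
  res <- differenceTable(cond, ref)
  expect_equal(res$unmatched$peptide_id, "b")
  expect_equal(res$unmatched$side, "reference_only")
})

test_that("fitBimodal round-trips a noiseless bimodal envelope", {
  env <- genEnvelope(pHigh = 0.3, noiseSd = 0, seed = 1)
  fit <- fitBimodal(env)
  expect_true(converged(fit))
  expect_equal(fit@pHigh, 0.3, tolerance = 1e-6)
  expect_equal(fit@muLow, 1252, tolerance = 1e-6)
  expect_equal(fit@muHigh, 1255, tolerance = 1e-6)
  expect_equal(fit@sigmaLow, 0.6, tolerance = 1e-5)
  expect_equal(fit@flag, "")
})

test_that("fitBimodal recovers p and subpopulation deuteration under noise", {
  res <- vapply(1:25, function(s) {
    f <- fitBimodal(genEnvelope(pHigh = 0.3, noiseSd = 0.01, seed = s),
                    undeut = 1250, fulldeut = 1258)
    c(f@pHigh, f@relLow, f@relHigh)
  }, numeric(3))
  expect_true(all(abs(res[1, ] - 0.3) < 0.05))
  # generated means 1252 / 1255 against refs 1250 / 1258
  expect_true(all(abs(res[2, ] - 0.25) < 0.05))
  expect_true(all(abs(res[3, ] - 0.625) < 0.05))
})

test_that("single-Gaussian data is flagged effectively unimodal", {
  env <- genEnvelope(pHigh = 0, noiseSd = 0.01, seed = 9)
  fit <- fitBimodal(env)
  expect_true(converged(fit))
  expect_true(fit@pHigh < 0.02 || fit@pHigh > 0.98)
  expect_equal(fit@flag, "effectively unimodal")
  # total weight concentrates in one mode
  expect_lt(min(fit@pHigh, 1 - fit@pHigh), 0.02)
})

test_that("subpopulationSummary aggregates and flags raised conditions", {
  fits <- data.frame(
    peptide_id = "159-168",
    condition = rep(c("baseline", "chaperones+ATP"), each = 3),
    p_high = c(0.25, 0.30, 0.35, 0.10, 0.12, 0.11))
  # relabel so baseline is the low one
  fits$p_high <- c(0.10, 0.12, 0.11, 0.24, 0.26, 0.25)
  s <- subpopulationSummary(fits, reference = "baseline")
  base <- s[s$condition == "baseline", ]
  expect_equal(base$mean_p_high, 0.11, tolerance = 1e-9)
  raised <- s[s$condition == "chaperones+ATP", ]
  expect_true(raised$flagged)
  expect_false(base$flagged)

  # hand-checked mean/SD aggregation
  s2 <- subpopulationSummary(data.frame(
    peptide_id = "x", condition = "c1", p_high = c(0.25, 0.30, 0.35)),
    reference = "c1")
  expect_equal(s2$mean_p_high, 0.30)
  expect_equal(s2$sd_p_high, 0.05, tolerance = 1e-9)

  # identical conditions -> no flags
  same <- data.frame(peptide_id = "x",
                     condition = rep(c("a", "b"), each = 3),
                     p_high = rep(c(0.1, 0.12, 0.11), 2))
  expect_false(any(subpopulationSummary(same, reference = "a")$flagged))
})

test_that("chaperone-raised subpopulations are detected at study effect sizes", {
  # baseline p = 0.10 vs chaperones+ATP p = 0.25, sigma = 0.02, n = 3
  fits <- withr::with_seed(31, data.frame(
    peptide_id = "176-189",
    condition = rep(c("baseline", "chaperones+ATP"), each = 3),
    p_high = c(rnorm(3, 0.10, 0.02), rnorm(3, 0.25, 0.02))))
  s <- subpopulationSummary(fits, reference = "baseline")
  expect_true(s$flagged[s$condition == "chaperones+ATP"])
})
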