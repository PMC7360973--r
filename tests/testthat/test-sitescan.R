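test_that("windowScores matches direct evaluation on toy matrices", {
  zero <- constantMatrix(0)
  p <- windowScores("AAAAAALAAAAAA", zero)
  expect_equal(centers(p), 7L)
  expect_equal(scores(p), 0)

  minus1 <- constantMatrix(-1)
  p2 <- windowScores(strrep("A", 20), minus1)
  expect_equal(centers(p2), 7:14)
  expect_equal(scores(p2), rep(-13, 8))

  # single nonzero entry: L at offset 0 scores -7
  e <- matrix(0, 20, 13, dimnames = list(aaAlphabet, as.character(-6:6)))
  e["L", "0"] <- -7
  sm <- ScoringMatrix(e)
  p3 <- windowScores("AAAAAALAAAAAA", sm)
  expect_equal(scores(p3), -7)
  p4 <- windowScores(paste0(strrep("A", 8), "L", strrep("A", 8)), sm)
  expect_equal(scores(p4)[centers(p4) == 9], -7)
  expect_equal(scores(p4)[centers(p4) != 9], rep(0, 4))

  expect_error(windowScores("AAAA", zero), "shorter than window")
})

test_that("windowScores and callSites agree with the brute-force oracle", {
  for (i in 1:100) {
    sq <- randomSequence(seed = 1000 + i,
                         length = sample(13:80, 1))
    sm <- randomToyMatrix(seed = 2000 + i)
    p <- windowScores(sq, sm)
    o <- oracleWindowScores(sq, sm@entries)
    expect_equal(centers(p), o$centers)
    expect_equal(scores(p), o$scores, tolerance = 1e-12)

    thr <- betweenThreshold(o$scores, 0.3)
    sites <- callSites(p, threshold = thr)
    osites <- oracleCallSites(o$centers, o$scores, thr)
    expect_equal(nrow(sites), length(osites))
    if (length(osites)) {
      expect_equal(sites$start,
                   vapply(osites, `[[`, 0, "start"))
      expect_equal(sites$end, vapply(osites, `[[`, 0, "end"))
    }
  }
})

test_that("callSites applies the inclusive threshold rule", {
  p <- ScoreProfile("s", 7:12, c(0, -4, -6, -6, -4, 0))
  sites <- callSites(p, threshold = -5)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 9)
  expect_equal(sites$end, 10)
  expect_equal(sites$min_score, -6)

  # a score exactly at the threshold is a site
  pb <- ScoreProfile("s", 7:9, c(0, -5, 0))
  sb <- callSites(pb, threshold = -5)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$start, 8)

  expect_equal(nrow(callSites(ScoreProfile("s", 7:9, c(0, 1, 2)))), 0)
})

test_that("countSitesInRange counts below-threshold centers in a range", {
  p <- ScoreProfile("s", 180:210,
                    ifelse(180:210 %in% c(182, 190, 205), -6, 0))
  expect_equal(as.integer(countSitesInRange(p, c(180, 200))), 2L)
  expect_equal(as.integer(countSitesInRange(p, c(201, 214))), 1L)
  expect_equal(attr(countSitesInRange(p, c(180, 200)), "runs"), 2L)

  alllow <- ScoreProfile("s", 7:20, rep(-13, 14))
  expect_equal(as.integer(countSitesInRange(alllow, c(9, 18))), 10L)
  expect_equal(attr(countSitesInRange(alllow, c(9, 18)), "runs"), 1L)

  expect_warning(n <- countSitesInRange(p, c(500, 510)),
                 "does not overlap")
  expect_equal(as.integer(n), 0L)
})

test_that("rescoreVariant is the identity without edits and tracks linearity", {
  sm <- randomToyMatrix(seed = 77)
  sq <- randomSequence(seed = 78, length = 40)
  p0 <- windowScores(sq, sm)
  expect_equal(scores(rescoreVariant(sq, sm)), scores(p0))
  # substituting a residue for itself changes nothing
  same <- substring(sq, 20, 20)
  expect_equal(scores(rescoreVariant(sq, sm,
                                     substitutions = setNames(same, "20"))),
               scores(p0))
})

test_that("additivity: a substitution shifts exactly the overlapping windows", {
  # toy matrix where S scores +2 and I/L/V score -2 at every offset
  e <- matrix(0, 20, 13, dimnames = list(aaAlphabet, as.character(-6:6)))
  e["S", ] <- 2
  e[c("I", "L", "V"), ] <- -2
  sm <- ScoringMatrix(e)
  sq <- paste0(strrep("A", 10), "ILV", strrep("A", 10))  # I at 11..13
  p0 <- windowScores(sq, sm)
  p1 <- rescoreVariant(sq, sm,
                       substitutions = c("11" = "S", "12" = "S",
                                         "13" = "S"))
  d <- scores(p1) - scores(p0)
  ctr <- centers(p0)
  # each I/L/V -> S raises any window containing it by 4; triple overlap
  overlap <- vapply(ctr, function(cc)
    sum(abs(cc - 11:13) <= 6), 0L)
  expect_equal(d, 4 * overlap)
  expect_true(all(d[overlap == 3] == 12))

  # generic single-substitution additivity against a random matrix
  smr <- randomToyMatrix(seed = 5)
  sqr <- randomSequence(seed = 6, length = 30)
  pos <- 15L
  new <- "W"
  old <- substring(sqr, pos, pos)
  pr0 <- windowScores(sqr, smr)
  pr1 <- rescoreVariant(sqr, smr, substitutions = setNames(new, pos))
  for (j in seq_along(centers(pr0))) {
    cc <- centers(pr0)[j]
    off <- pos - cc
    expected <- if (abs(off) <= 6)
      smr@entries[new, as.character(off)] -
        smr@entries[old, as.character(off)] else 0
    expect_equal(scores(pr1)[j] - scores(pr0)[j], expected,
                 tolerance = 1e-12)
  }
})

test_that("deletions excise residues but keep original numbering", {
  sm <- constantMatrix(-1)
  sq <- strrep("A", 40)
  p <- rescoreVariant(sq, sm, deletions = list(c(20, 29)), seqId = "del")
  # 30 residues survive; centers 7..24 in variant coordinates map to
  # original numbering with the 20-29 gap
  expect_equal(length(centers(p)), 18)
  expect_false(any(centers(p) %in% 20:29))
  expect_true(all(scores(p) == -13))
  expect_error(rescoreVariant(sq, sm, deletions = list(c(35, 50))),
               "invalid deletion")
  expect_error(rescoreVariant(strrep("A", 20), sm,
                              deletions = list(c(1, 10))),
               "shorter than window")
})

test_that("reversal symmetry holds iff the matrix is offset-symmetric", {
  revseq <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  sq <- randomSequence(seed = 91, length = 31)

  # symmetric matrix: entries identical across mirrored offsets
  base <- randomToyMatrix(seed = 92)@entries
  symm <- (base + base[, 13:1]) / 2
  colnames(symm) <- as.character(-6:6)
  smS <- ScoringMatrix(symm)
  pf <- windowScores(sq, smS)
  pr <- windowScores(revseq(sq), smS)
  expect_equal(scores(pf), rev(scores(pr)), tolerance = 1e-12)

  # asymmetric matrix: symmetry must fail
  asym <- base
  asym["A", "-6"] <- asym["A", "-6"] + 50
  smA <- ScoringMatrix(asym)
  pa <- windowScores(sq, smA)
  pb <- windowScores(revseq(sq), smA)
  expect_false(isTRUE(all.equal(scores(pa), rev(scores(pb)))))
})
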