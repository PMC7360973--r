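# Independent oracles, deliberately naive, used to cross-check the
# closed-form / vectorized implementations.

# Bound complex by bisection on Kd = (L - x)(R - x) / x.
oracleBound <- function(L, R, Kd) {
  if (L == 0 || R == 0) return(0)
  f <- function(x) (L - x) * (R - x) / x - Kd
  stats::uniroot(f, c(1e-15, min(L, R) * (1 - 1e-12)),
                 tol = 1e-14)$root
}

# Trimer composition by exhaustive enumeration of the 2^3 ordered
# monomer triples, each slot wild-type with probability a / (a + b).
oracleComposition <- function(a, b) {
  p <- a / (a + b)
  out <- c(f3 = 0, f2 = 0, f1 = 0, f0 = 0)
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    slots <- c(i, j, k)  # 1 = wild-type monomer
    pr <- prod(ifelse(slots == 1, p, 1 - p))
    nwt <- sum(slots)
    out[4 - nwt] <- out[4 - nwt] + pr
  }
  out
}

# Window scores by explicit per-window loops (no vectorization).
oracleWindowScores <- function(sequence, entries) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  centers <- 7:(L - 6)
  scores <- numeric(length(centers))
  for (ci in seq_along(centers)) {
    s <- 0
    for (off in -6:6)
      s <- s + entries[chars[centers[ci] + off], as.character(off)]
    scores[ci] <- s
  }
  list(centers = centers, scores = scores)
}

# Site calling by a plain position scan over the profile.
oracleCallSites <- function(centers, scores, threshold) {
  sites <- list()
  in_run <- FALSE
  for (i in seq_along(centers)) {
    if (scores[i] <= threshold) {
      if (!in_run) {
        sites[[length(sites) + 1]] <- c(start = centers[i],
                                        end = centers[i])
        in_run <- TRUE
      } else {
        sites[[length(sites)]]["end"] <- centers[i]
      }
    } else in_run <- FALSE
  }
  sites
}

aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomToyMatrix <- function(seed, scale = 3) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(260, sd = scale), 20, 13,
                dimnames = list(aaAlphabet, as.character(-6:6)))
    ScoringMatrix(m, name = paste0("toy", seed))
  })
}

randomSequence <- function(seed, length = 60) {
  withr::with_seed(seed,
    paste(sample(aaAlphabet, length, replace = TRUE), collapse = ""))
}

# A threshold strictly between two attained score values, so that no
# score ties it and float summation order cannot flip the comparison.
betweenThreshold <- function(scores, frac = 0.3) {
  so <- sort(unique(scores))
  if (length(so) == 1L) return(so[1] + 1)
  k <- max(1L, min(length(so) - 1L, ceiling(frac * length(so))))
  (so[k] + so[k + 1L]) / 2
}

constantMatrix <- function(value, name = "constant") {
  ScoringMatrix(matrix(value, 20, 13,
                       dimnames = list(aaAlphabet, as.character(-6:6))),
                name = name)
}
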