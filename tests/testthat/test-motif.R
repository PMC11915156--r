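# Cysteine-centered windows and pLogo-style binomial enrichment.

test_that("window extraction pads truncated flanks with '-'", {
  db15 <- Biostrings::AAStringSet(c(P1 = "AAAAAAACGGGGGGG"))
  expect_equal(extractWindow(db15, "P1", 8), "AAAAAAACGGGGGGG")

  db <- Biostrings::AAStringSet(c(P1 = "MACDEFKG"))
  expect_equal(extractWindow(db, "P1", 3), "-----MACDEFKG--")

  dbEnd <- Biostrings::AAStringSet(c(P1 = "MADEFKGC"))
  expect_equal(extractWindow(dbEnd, "P1", 8), "MADEFKGC-------")

  expect_error(extractWindow(db, "P1", 2), "not a cysteine")
})

test_that("background frequencies count non-pad residues per position", {
  p1 <- backgroundFrequencies("AAAAAAACAAAAAAA")
  expect_true(all(p1["A", ] == 1))

  p2 <- backgroundFrequencies(c("AAAAAAACAAAAAAA", "AAAAAAACGAAAAAA"))
  expect_equal(unname(p2["A", "1"]), 0.5)
  expect_equal(unname(p2["G", "1"]), 0.5)
  expect_equal(unname(p2["A", "-1"]), 1)

  # pads excluded from numerator and denominator
  p3 <- backgroundFrequencies(c("-------CAAAAAAA", "GGGGGGGCAAAAAAA"))
  expect_true(all(p3["G", 1:7] == 1))

  # a position that is all pads is degenerate
  expect_error(backgroundFrequencies("-------CAAAAAAA"), "no non-pad")
})

test_that("uniform background is recovered within binomial error", {
  set.seed(5)
  alpha <- aminoAcidAlphabet()
  windows <- drawWindows(spikedBackground("K", 0.05), 10000)
  # overwrite with a truly uniform draw
  windows <- vapply(seq_len(10000), function(i) {
    paste(c(sample(alpha, 7, TRUE), "C", sample(alpha, 7, TRUE)),
          collapse = "")
  }, "")
  p <- backgroundFrequencies(windows)
  tol <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_true(all(abs(p - 0.05) <= tol))
})

test_that("plogoScore matches closed forms and the enumeration oracle", {
  expect_equal(plogoScore(5, 5, 0.1), 5, tolerance = 1e-12)
  expect_equal(plogoScore(0, 5, 0.1), log10(0.9^5), tolerance = 1e-12)

  # direct tail-summation oracle
  oracle <- function(k, N, p) {
    upper <- sum(choose(N, k:N) * p^(k:N) * (1 - p)^(N - (k:N)))
    lower <- sum(choose(N, 0:k) * p^(0:k) * (1 - p)^(N - (0:k)))
    if (k / N >= p) -log10(upper) else log10(lower)
  }
  expect_equal(plogoScore(3, 10, 0.05), oracle(3, 10, 0.05),
               tolerance = 1e-12)

  for (p in c(0.01, 0.2)) {
    for (N in c(1, 7, 19)) {
      k <- 0:N
      expect_equal(plogoScore(k, N, p),
                   vapply(k, oracle, 0, N = N, p = p), tolerance = 1e-9)
    }
  }
  expect_error(plogoScore(2, 5, 0), "in \\(0, 1\\)")
  expect_error(plogoScore(6, 5, 0.1), "0 <= k <= N")
})

test_that("the enrichment side of plogoScore is monotone in k", {
  for (p in c(0.05, 0.3)) {
    N <- 40
    k <- ceiling(N * p):N
    s <- plogoScore(k, N, p)
    expect_true(all(diff(s) >= 0))
  }
})

test_that("the Bonferroni threshold reproduces the published cutoff", {
  expect_equal(round(significanceThreshold(0.05, 20, 14), 2), 3.75)
  expect_equal(significanceThreshold(1, 1, 1), 0)
  expect_equal(significanceThreshold(0.05, 20, 1), -log10(0.0025))
})

test_that("PWM counts partition foreground windows per position", {
  set.seed(9)
  bg <- spikedBackground("K", 0.05)
  fg <- drawWindows(bg, 50, "K", -1, 20)
  # put pads at the N-terminal flank of a few windows
  substr(fg[1:5], 1, 3) <- "---"
  pwm <- buildPwm(fg, bg)
  expect_equal(colSums(pwmCounts(pwm)), setNames(
    c(45, 45, 45, rep(50, 11)), as.character(flankPositions())))
  expect_equal(unname(pwmCounts(pwm)["K", "-1"]) >= 20, TRUE)
})

test_that("heatmap reordering permutes rows without changing values", {
  set.seed(10)
  bg <- spikedBackground("K", 0.05)
  pwm <- buildPwm(drawWindows(bg, 30), bg)
  s <- pwmScores(pwm)
  expect_equal(pwmHeatmapMatrix(pwm, aminoAcidAlphabet()), s)
  rev <- pwmHeatmapMatrix(pwm, rev(aminoAcidAlphabet()))
  expect_equal(rev, s[20:1, ])
  prop <- pwmHeatmapMatrix(pwm)
  expect_equal(rownames(prop)[1:5], c("K", "R", "H", "D", "E"))
  expect_equal(sort(as.vector(prop)), sort(as.vector(s)))
  expect_error(pwmHeatmapMatrix(pwm, c("K", "K", aminoAcidAlphabet()[1:18])),
               "permutation")
})

test_that("a planted lysine at -1 is recovered as significant", {
  set.seed(12)
  bg <- spikedBackground("K", 0.05)
  fg <- drawWindows(bg, 100, "K", -1, 60)
  pwm <- buildPwm(fg, bg)
  expect_gt(pwmScores(pwm)["K", "-1"], 3.75)
  expect_true(any(significantCells(pwm)$residue == "K" &
                  significantCells(pwm)$position == -1))
})

test_that("planted acidic residues around reduced sites are recovered", {
  set.seed(13)
  alpha <- aminoAcidAlphabet()
  p <- rep(1 / 20, 20)
  names(p) <- alpha
  bg <- matrix(p, 20, 14, dimnames = list(alpha,
                                          as.character(flankPositions())))
  fg <- drawWindows(bg, 120, "D", -2, 60)
  fg2 <- drawWindows(bg, 120, "E", 2, 60)
  pwmD <- buildPwm(fg, bg)
  pwmE <- buildPwm(fg2, bg)
  expect_gt(pwmScores(pwmD)["D", "-2"], significanceThreshold())
  expect_gt(pwmScores(pwmE)["E", "2"], significanceThreshold())
})
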