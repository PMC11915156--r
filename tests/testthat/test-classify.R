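# Redox classification of cysteine observations and percentage summaries.

test_that("mass tags resolve to the redox state they encode", {
  map <- defaultModificationMap()
  expect_equal(modificationLabel(map, "NEM"), "reduced")
  expect_equal(modificationLabel(map, "BPM"), "oxidized")
  expect_equal(modificationLabel(map, "125.05"), "reduced")
  expect_equal(modificationLabel(map, "548.28"), "oxidized")
  expect_equal(modificationLabel(map, "125.06"), "reduced")  # within 0.02 Da
  expect_true(is.na(modificationLabel(map, "999.99")))
  expect_true(is.na(modificationLabel(map, "iodoacetamide")))
})

test_that("cysteines classify per PSM and deduplicate per replicate", {
  db <- tinyDb()
  psms <- list(
    makePsm("ACDEFK", "P001", modsOf(2, "NEM")),
    makePsm("ACDEFK", "P001", modsOf(2, "NEM")),        # duplicate PSM
    makePsm("CCRGGAAK", "P002", modsOf(1, "BPM"), "Cold", 2),
    makePsm("ACDEFK", "P001"))                          # untagged cysteine
  sites <- classifySites(psms, db)
  df <- siteTable(sites)
  # reduced P001:3, oxidized P002:4, untagged P002:5, untagged P001:3
  expect_equal(nrow(df), 4L)
  expect_equal(df$label[df$accession == "P001" & df$replicate == 1 &
                        df$condition == "RT" & df$label != "unlabeled"],
               "reduced")
  # BPM-tagged C at peptide index 1 of CCRGGAAK maps to P002 position 4
  ox <- df[df$label == "oxidized", ]
  expect_equal(ox$accession, "P002")
  expect_equal(ox$position, 4L)
  # untagged C in second peptide at index 2 -> unlabeled at position 5
  expect_true(any(df$label == "unlabeled"))
})

test_that("a residue tagged with both classes in one PSM is dropped and logged", {
  db <- tinyDb()
  psms <- list(makePsm("ACDEFK", "P001",
                       modsOf(c(2, 2), c("NEM", "BPM"))))
  sites <- classifySites(psms, db)
  expect_equal(nrow(siteTable(sites)), 0L)
  expect_length(siteLog(sites)$conflicts, 1L)
})

test_that("both labels from different PSMs of one replicate coexist", {
  db <- tinyDb()
  psms <- list(makePsm("ACDEFK", "P001", modsOf(2, "NEM")),
               makePsm("ACDEFK", "P001", modsOf(2, "BPM")))
  df <- siteTable(classifySites(psms, db))
  expect_equal(sort(df$label), c("oxidized", "reduced"))
  expect_equal(unique(df$position), 3L)
})

test_that("classification is invariant to PSM order and symmetric in labels", {
  db <- tinyDb()
  psms <- list(
    makePsm("ACDEFK", "P001", modsOf(2, "NEM")),
    makePsm("CCRGGAAK", "P002", modsOf(2, "BPM"), "Cold", 2),
    makePsm("GGAAKW", "P002", condition = "Cold", replicate = 3),
    makePsm("ACDEFK", "P001", modsOf(2, "BPM"), "RT", 3))
  ordered <- siteTable(classifySites(psms, db))
  shuffled <- siteTable(classifySites(psms[c(3, 1, 4, 2)], db))
  sorter <- function(d) {
    d <- d[order(d$accession, d$position, d$label, d$condition,
                 d$replicate), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(sorter(ordered), sorter(shuffled))

  swapped <- ModificationMap(c(NEM = "oxidized", BPM = "reduced"),
                             c(NEM = 125.05, BPM = 548.28))
  a <- siteTable(classifySites(psms, db))
  b <- siteTable(classifySites(psms, db, modMap = swapped))
  expect_equal(sum(a$label == "oxidized"), sum(b$label == "reduced"))
  expect_equal(sum(a$label == "reduced"), sum(b$label == "oxidized"))
})

test_that("ambiguous multi-offset peptides are excluded by default only", {
  db <- Biostrings::AAStringSet(c(P1 = "ACACW"))
  psms <- list(makePsm("AC", "P1", modsOf(2, "NEM")))
  strict <- classifySites(psms, db)
  expect_equal(nrow(siteTable(strict)), 0L)
  expect_length(siteLog(strict)$skipped, 1L)
  lax <- classifySites(psms, db, dropAmbiguous = FALSE)
  expect_equal(sort(siteTable(lax)$position), c(2L, 4L))
  expect_true(all(siteTable(lax)$ambiguous))
})

test_that("percentages are exact and sum to 100 per replicate", {
  obs <- plantedSiteSet(list(c(10L, 85L, 5L)), "RT")
  sites <- RedoxSiteSet(obs)
  pct <- suppressWarnings(percentRedox(sites, c("RT", "RT")))
  expect_equal(pct$perReplicate$pct_oxidized, 10)
  expect_equal(pct$perReplicate$pct_reduced, 85)
  expect_equal(pct$perReplicate$pct_unlabeled, 5)

  set.seed(3)
  for (i in 1:5) {
    counts <- lapply(1:3, function(r) sample(1:60, 3))
    sites <- RedoxSiteSet(rbind(plantedSiteSet(counts, "RT"),
                                plantedSiteSet(counts, "Cold")))
    pr <- percentRedox(sites)$perReplicate
    sums <- pr$pct_oxidized + pr$pct_reduced + pr$pct_unlabeled
    expect_equal(sums, rep(100, nrow(pr)), tolerance = 1e-9)
  }
})

test_that("group mean, SEM and Student's t match the closed form", {
  rt <- list(c(10L, 85L, 5L), c(20L, 75L, 5L), c(15L, 80L, 5L))
  cold <- list(c(30L, 65L, 5L), c(25L, 70L, 5L), c(35L, 60L, 5L))
  sites <- RedoxSiteSet(rbind(plantedSiteSet(rt, "RT"),
                              plantedSiteSet(cold, "Cold")))
  pct <- percentRedox(sites)

  # Independent closed-form oracle on the six oxidized percentages.
  x <- c(10, 20, 15)
  y <- c(30, 25, 35)
  oracleMean <- c(mean(x), mean(y))
  oracleSem <- c(sd(x), sd(y)) / sqrt(3)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  oracleT <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  oracleP <- 2 * pt(-abs(oracleT), 4)

  gs <- pct$groupSummary
  expect_equal(gs$mean[gs$category == "oxidized"], oracleMean)
  expect_equal(gs$sem[gs$category == "oxidized"], oracleSem)
  tt <- pct$tests[pct$tests$category == "oxidized", ]
  expect_equal(tt$t, oracleT, tolerance = 1e-12)
  expect_equal(tt$p, oracleP, tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1", {
  counts <- list(c(10L, 40L, 0L), c(10L, 40L, 0L), c(10L, 40L, 0L))
  sites <- RedoxSiteSet(rbind(plantedSiteSet(counts, "RT"),
                              plantedSiteSet(counts, "Cold")))
  tests <- percentRedox(sites)$tests
  expect_equal(tests$t[tests$category == "oxidized"], 0)
  expect_equal(tests$p[tests$category == "oxidized"], 1)
})
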