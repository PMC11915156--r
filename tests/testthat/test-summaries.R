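# Subcellular localization join and compartment percentages.

test_that("compartment terms normalise onto the controlled vocabulary", {
  expect_equal(normalizeCompartment("Mitochondria"), "mitochondrion")
  expect_equal(normalizeCompartment("mitochondrion"), "mitochondrion")
  expect_equal(normalizeCompartment("Plasm membrane"), "plasma membrane")
  expect_equal(normalizeCompartment("Golgi"), "Golgi apparatus")
  expect_equal(normalizeCompartment("Extracellular space"),
               "extracellular space")
  expect_true(is.na(normalizeCompartment("ribosome")))
})

test_that("localization tables expand to long form with warnings on unknowns", {
  path <- writeTsv(data.frame(
    accession = c("P1", "P2", "P3"),
    compartments = c("Mitochondria;Cytosol", "Nucleus", "ribosome"),
    stringsAsFactors = FALSE))
  expect_warning(loc <- readLocalization(path), "ribosome")
  expect_equal(nrow(loc), 3L)
  expect_setequal(loc$compartment[loc$accession == "P1"],
                  c("mitochondrion", "cytosol"))
})

test_that("multi-localized sites count once per compartment", {
  loc <- data.frame(accession = c("P1", "P1", "P2"),
                    compartment = c("mitochondrion", "cytosol", "nucleus"),
                    stringsAsFactors = FALSE)
  obs <- data.frame(accession = c("P1", "P2", "P9"), position = c(3L, 5L, 7L),
                    label = "reduced", condition = "RT", replicate = 1L,
                    ambiguous = FALSE, stringsAsFactors = FALSE)
  expect_warning(localized <- joinLocalization(obs, loc), "unannotated")
  expect_equal(nrow(localized), 3L)  # P1 twice, P2 once
  expect_equal(nrow(attr(localized, "unannotated")), 1L)

  # with one compartment each, records equal sites
  loc1 <- data.frame(accession = c("P1", "P2", "P9"),
                     compartment = "cytosol", stringsAsFactors = FALSE)
  expect_equal(nrow(joinLocalization(obs, loc1)), 3L)
})

test_that("multi-localization inflates counts, never deflates", {
  set.seed(31)
  obs <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(accession = paste0("P", i), position = 10L,
               label = sample(c("oxidized", "reduced"), 1),
               condition = "RT", replicate = 1L, ambiguous = FALSE,
               stringsAsFactors = FALSE)
  }))
  loc <- do.call(rbind, lapply(1:20, function(i) {
    k <- sample(1:3, 1)
    data.frame(accession = paste0("P", i),
               compartment = sample(compartmentVocabulary(), k),
               stringsAsFactors = FALSE)
  }))
  localized <- joinLocalization(obs, loc)
  expect_gte(nrow(localized), nrow(obs))
  # restricting to single-compartment proteins partitions the sites
  single <- names(which(table(loc$accession) == 1))
  part <- localized[localized$accession %in% single, ]
  expect_equal(nrow(part), sum(obs$accession %in% single))
})

test_that("compartment percentages use labeled sites only", {
  obs <- rbind(
    data.frame(accession = paste0("P", 1:2), position = 1L,
               label = "oxidized", condition = "RT", replicate = 1L,
               ambiguous = FALSE),
    data.frame(accession = paste0("P", 3:10), position = 1L,
               label = "reduced", condition = "RT", replicate = 1L,
               ambiguous = FALSE),
    data.frame(accession = "P11", position = 1L, label = "unlabeled",
               condition = "RT", replicate = 1L, ambiguous = FALSE))
  loc <- data.frame(accession = paste0("P", 1:11),
                    compartment = "cytosol", stringsAsFactors = FALSE)
  localized <- joinLocalization(obs, loc)
  out <- compartmentPercentages(localized, conditions = c("RT", "RT"))
  expect_equal(out$perReplicate$pct_oxidized, 20)
  expect_equal(out$perReplicate$n_oxidized + out$perReplicate$n_reduced, 10)

  allRed <- localized[localized$label == "reduced", ]
  out2 <- compartmentPercentages(allRed, conditions = c("RT", "RT"))
  expect_equal(out2$perReplicate$pct_oxidized, 0)
})

test_that("per-replicate mode reports mean, SEM and the cold shift", {
  mk <- function(nOx, nRed, cond, rep) rbind(
    if (nOx) data.frame(accession = paste0("OX", seq_len(nOx)),
                        position = 1L, label = "oxidized", condition = cond,
                        replicate = rep, ambiguous = FALSE),
    if (nRed) data.frame(accession = paste0("RD", seq_len(nRed)),
                         position = 1L, label = "reduced", condition = cond,
                         replicate = rep, ambiguous = FALSE))
  obs <- rbind(mk(1, 9, "RT", 1L), mk(2, 8, "RT", 2L), mk(3, 7, "RT", 3L),
               mk(2, 8, "Cold", 1L), mk(3, 7, "Cold", 2L),
               mk(4, 6, "Cold", 3L))
  loc <- data.frame(accession = unique(obs$accession),
                    compartment = "mitochondrion", stringsAsFactors = FALSE)
  out <- compartmentPercentages(joinLocalization(obs, loc))
  expect_equal(out$summary$mean_pct_oxidized, c(20, 30))
  expect_equal(out$shift$delta_pct_oxidized, 10)
  expect_equal(out$summary$sem_pct_oxidized,
               rep(sd(c(10, 20, 30)) / sqrt(3), 2))
  # pooled mode deduplicates sites across replicates: union of distinct
  # oxidized accessions is 3 (RT) and 4 (Cold) against 9 and 8 reduced
  pooled <- compartmentPercentages(joinLocalization(obs, loc),
                                   mode = "pooled")
  expect_equal(sort(pooled$summary$pct_oxidized), c(25, 100 / 3))
})
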