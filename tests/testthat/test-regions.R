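# Reproducibility rule and the 15-region Venn algebra.

test_that("the 2-of-3 rule selects sites detected twice in one category", {
  obs <- data.frame(
    accession = "P1", position = 10L,
    label = "reduced", condition = "RT",
    replicate = c(1L, 2L), ambiguous = FALSE, stringsAsFactors = FALSE)
  third <- data.frame(accession = "P1", position = 10L, label = "reduced",
                      condition = "RT", replicate = 3L, ambiguous = FALSE)
  singleton <- data.frame(accession = "P2", position = 5L, label = "reduced",
                          condition = "RT", replicate = 1L, ambiguous = FALSE)
  sites <- RedoxSiteSet(rbind(obs, third[0, ], singleton))
  rep <- reproducibleSites(sites)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$accession, "P1")
  expect_equal(rep$n_replicates, 2L)
})

test_that("a site can be reproducible in both categories at once", {
  # reduced in replicates {1,2}, oxidized in {2,3}: brute-force the rule
  # over every (label, replicate) detection to confirm both pass
  det <- expand.grid(label = c("reduced", "oxidized"), replicate = 1:3,
                     stringsAsFactors = FALSE)
  det$present <- with(det, (label == "reduced" & replicate %in% c(1, 2)) |
                        (label == "oxidized" & replicate %in% c(2, 3)))
  oracle <- vapply(split(det, det$label),
                   function(d) sum(d$present) >= 2, TRUE)
  expect_true(all(oracle))

  obs <- det[det$present, c("label", "replicate")]
  obs$accession <- "P1"
  obs$position <- 10L
  obs$condition <- "RT"
  obs$ambiguous <- FALSE
  rep <- reproducibleSites(RedoxSiteSet(obs))
  expect_equal(sort(rep$label), c("oxidized", "reduced"))
})

test_that("unlabeled observations never become reproducible and thresholds validate", {
  obs <- data.frame(accession = "P1", position = 10L, label = "unlabeled",
                    condition = "RT", replicate = 1:3, ambiguous = FALSE)
  expect_equal(nrow(reproducibleSites(RedoxSiteSet(obs))), 0L)
  expect_error(reproducibleSites(RedoxSiteSet(obs), minReplicates = 4),
               "exceeds")
})

test_that("all 15 realizable patterns map to distinct regions with the right classes", {
  subsets <- list(character(0), "oxidized", "reduced",
                  c("oxidized", "reduced"))
  seen <- character(0)
  classCount <- c(dynamic = 0, reactive = 0, rt_exclusive = 0,
                  cold_exclusive = 0, stable = 0)
  for (rt in subsets) for (cold in subsets) {
    if (!length(rt) && !length(cold)) {
      expect_error(assignRegion(rt, cold), "not realizable")
      next
    }
    a <- assignRegion(rt, cold)
    seen <- c(seen, a$region)
    for (cl in a$classes) classCount[cl] <- classCount[cl] + 1
    # class semantics recomputed independently
    if (!length(cold)) expect_equal(a$classes, "rt_exclusive")
    if (!length(rt)) expect_equal(a$classes, "cold_exclusive")
    if (length(rt) && length(cold) && setequal(rt, cold)) {
      expect_equal(a$classes, "stable")
    }
    if (length(rt) && length(cold) && !setequal(rt, cold)) {
      expect_true("dynamic" %in% a$classes)
    }
  }
  expect_equal(sort(seen), LETTERS[1:15])
  expect_equal(classCount,
               c(dynamic = 6, reactive = 3, rt_exclusive = 3,
                 cold_exclusive = 3, stable = 3))
})

test_that("the published region definitions hold", {
  # L: reduced under RT, oxidized under cold
  L <- assignRegion("reduced", "oxidized")
  expect_equal(L$region, "L")
  expect_setequal(L$classes, c("dynamic", "reactive"))
  # M: reduced & oxidized under RT, oxidized under cold
  M <- assignRegion(c("oxidized", "reduced"), "oxidized")
  expect_equal(M$region, "M")
  expect_setequal(M$classes, c("dynamic", "reactive"))
  # N: reduced under RT, reduced & oxidized under cold
  N <- assignRegion("reduced", c("oxidized", "reduced"))
  expect_equal(N$region, "N")
  expect_setequal(N$classes, c("dynamic", "reactive"))
  # stable and exclusive examples
  expect_equal(assignRegion("reduced", "reduced")$classes, "stable")
  A <- assignRegion("oxidized", character(0))
  expect_true(A$region %in% c("A", "B", "C"))
  expect_equal(A$classes, "rt_exclusive")
})

test_that("region counts partition the reproducible site keys", {
  pat <- regionPatterns()
  sets <- list(none = character(0), ox = "oxidized", red = "reduced",
               oxred = c("oxidized", "reduced"))
  # one site per pattern
  repro <- do.call(rbind, lapply(seq_len(nrow(pat)), function(i) {
    entries <- rbind(
      if (length(sets[[pat$rt[i]]]))
        data.frame(condition = "RT", label = sets[[pat$rt[i]]]),
      if (length(sets[[pat$cold[i]]]))
        data.frame(condition = "Cold", label = sets[[pat$cold[i]]]))
    data.frame(accession = paste0("P", i), position = 10L,
               condition = entries$condition, label = entries$label,
               n_replicates = 2L, stringsAsFactors = FALSE)
  }))
  asn <- siteRegions(repro)
  expect_equal(nrow(asn), 15L)
  vc <- vennCounts(asn)
  expect_equal(sum(vc$regions), vc$nSites)
  expect_equal(unname(vc$regions[pat$region]), rep(1L, 15))
  expect_equal(unname(vc$classes),
               c(6L, 3L, 3L, 3L, 3L))
})

test_that("dynamic-pattern planting yields 6 dynamic and 3 reactive", {
  dyn <- regionPatterns()
  dyn <- dyn[grepl("dynamic", dyn$classes), ]
  expect_equal(nrow(dyn), 6L)
  repro <- expandRegionTable(data.frame(
    accession = paste0("D", seq_len(6)), position = 1:6,
    region = dyn$region, stringsAsFactors = FALSE))
  asn <- siteRegions(repro)
  vc <- vennCounts(asn)
  expect_equal(unname(vc$classes["dynamic"]), 6L)
  expect_equal(unname(vc$classes["reactive"]), 3L)
  expect_equal(nrow(reactiveSites(asn)), 3L)
})

test_that("empty input gives all-zero counts", {
  vc <- vennCounts(siteRegions(reproducibleSites(RedoxSiteSet(
    data.frame(accession = character(0), position = integer(0),
               label = character(0), condition = character(0),
               replicate = integer(0), ambiguous = logical(0))))))
  expect_true(all(vc$regions == 0L))
  expect_true(all(vc$classes == 0L))
  expect_equal(vc$nSites, 0L)
})

test_that("protein-level counts deduplicate sites in the same region", {
  repro <- expandRegionTable(data.frame(
    accession = c("P1", "P1", "P2"), position = c(10L, 20L, 5L),
    region = c("L", "L", "L"), stringsAsFactors = FALSE))
  vc <- vennCounts(siteRegions(repro))
  expect_equal(unname(vc$regions["L"]), 3L)
  expect_equal(unname(vc$proteins["L"]), 2L)
})

test_that("reproducibility output is invariant under replicate relabeling", {
  set.seed(21)
  obs <- do.call(rbind, lapply(1:30, function(i) {
    reps <- sample(1:3, sample(1:3, 1))
    data.frame(accession = paste0("P", i %% 7), position = i,
               label = sample(c("oxidized", "reduced"), 1),
               condition = sample(c("RT", "Cold"), 1), replicate = reps,
               ambiguous = FALSE, stringsAsFactors = FALSE)
  }))
  a <- reproducibleSites(RedoxSiteSet(obs))
  relabeled <- obs
  relabeled$replicate <- c(3L, 1L, 2L)[relabeled$replicate]
  b <- reproducibleSites(RedoxSiteSet(relabeled))
  expect_equal(a[, c("accession", "position", "condition", "label",
                     "n_replicates")],
               b[, c("accession", "position", "condition", "label",
                     "n_replicates")])
})
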