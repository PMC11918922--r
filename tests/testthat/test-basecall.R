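test_that("callBase applies the strict depth, quality and majority rules", {
  t <- callThresholds()                       # 5 / 25 / 0.95
  expect_identical(callBase(rep("A", 5), rep(30, 5), t), "A")
  expect_identical(callBase(rep("A", 4), rep(40, 4), t), NA_character_)
  expect_identical(callBase(c(rep("A", 94), rep("G", 6)), rep(30, 100), t),
                   NA_character_)             # 0.94 < 0.95
  expect_identical(callBase(c(rep("A", 19), "G"), rep(30, 20), t), "A")
  # boundary: quality 24 reads are discarded, 25 kept
  expect_identical(callBase(rep("A", 5), rep(24, 5), t), NA_character_)
  expect_identical(callBase(rep("A", 5), rep(25, 5), t), "A")
  # string-encoded observations behave identically
  expect_identical(callBase("AAAAA", "30,30,30,30,30", t), "A")
  expect_identical(callBase(character(0), integer(0), t), NA_character_)
})

test_that("callBase is invariant under permutation of the observations", {
  set.seed(99)
  t <- callThresholds()
  for (k in 1:50) {
    n <- sample(1:30, 1)
    b <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c(0.7, 0.1, 0.1, 0.1))
    q <- sample(15:45, n, replace = TRUE)
    ref <- callBase(b, q, t)
    perm <- sample(n)
    expect_identical(callBase(b[perm], q[perm], t), ref)
  }
})

test_that("raising depth or majority thresholds never adds a call", {
  # at a fixed quality floor, stricter depth/majority can only lose calls
  set.seed(7)
  for (k in 1:100) {
    n <- sample(1:25, 1)
    b <- sample(c("A", "G"), n, replace = TRUE, prob = c(0.8, 0.2))
    q <- sample(20:40, n, replace = TRUE)
    minQ <- sample(20:30, 1)
    loose <- callThresholds(minDepth = sample(1:3, 1), minQuality = minQ,
                            baseMajority = runif(1, 0.51, 0.8))
    strict <- callThresholds(minDepth = loose$minDepth + sample(0:4, 1),
                             minQuality = minQ,
                             baseMajority = min(1, loose$baseMajority +
                                                  runif(1, 0, 0.2)))
    strictCall <- callBase(b, q, strict)
    if (!is.na(strictCall))
      expect_identical(callBase(b, q, loose), strictCall)
  }
})

test_that("the quality floor is not monotone: removing noisy reads can rescue a call", {
  # raising minQuality discards the discordant read and the majority passes;
  # this is the intended effect of quality filtering, so the monotonicity
  # property is stated over depth and majority only
  b <- c(rep("A", 5), "G")
  q <- c(rep(30, 5), 22)
  expect_identical(callBase(b, q, callThresholds(5, 20, 0.95)), NA_character_)
  expect_identical(callBase(b, q, callThresholds(5, 25, 0.95)), "A")
})

test_that("discovery needs a single qualifying non-reference read", {
  refA <- c("100" = "A")
  one <- data.frame(sample = "S1", position = 100L, bases = "G",
                    quals = "30")
  expect_equal(discoverVariants(one, refA)$position, 100L)
  low <- data.frame(sample = "S1", position = 100L, bases = "G",
                    quals = "20")
  expect_equal(nrow(discoverVariants(low, refA)), 0L)
  expect_error(discoverVariants(one, c("7" = "A")), "reference allele")
})

test_that("discovery on noiseless simulation matches the covered truth sites", {
  cfg <- quickConfig(seed = 17, missingness = c(ModAdmix = 0.3, AncNAM = 0.7,
                                                ModNAM = 0.2))
  tr <- simulateTree(cfg)
  p <- simulatePileups(tr, cfg)
  refA <- stats::setNames(tr@sites$refAllele, tr@sites$position)
  disc <- discoverVariants(p, refA, catalog = tr@sites)
  carried <- sort(unique(unlist(lapply(names(tr@sampleTips),
                                       trueDerivedSites, truth = tr))))
  coveredDerived <- sort(unique(p$position[mapply(function(s, pos)
    pos %in% trueDerivedSites(tr, s), p$sample, p$position)]))
  expect_identical(disc$position, intersect(carried, coveredDerived))
  # discovery mode is a superset of strict calling on the same pileups
  cm <- buildCallMatrix(p, annotateVariants(disc))
  strictDerived <- siteInfo(cm)$position[
    rowSums(calls(cm) == "D", na.rm = TRUE) > 0]
  expect_true(all(strictDerived %in% disc$position))
})

test_that("annotation tiers, novel identifiers and stability behave as specified", {
  sites <- data.frame(position = c(10L, 20L, 30L, 40L),
                      refAllele = "A", altAllele = "G")
  ann <- data.frame(position = c(10L, 10L, 20L),
                    name = c("M3", "rs123", NA),
                    tier = c("database_tree", "rs_id", "gnomad"))
  out <- annotateVariants(sites, ann, novelPrefix = "ZK")
  expect_identical(out$name, c("M3", "20-gnomAD", "ZK1", "ZK2"))
  expect_identical(out$tier, c("database_tree", "gnomad", "novel", "novel"))
  # novel ids numbered in ascending position order regardless of input order
  shuffled <- annotateVariants(sites[c(4, 3, 1, 2), ], ann)
  expect_identical(shuffled$name[shuffled$position == 30L], "ZK1")
  expect_identical(shuffled$name[shuffled$position == 40L], "ZK2")
  # re-annotation is a no-op on the name/tier columns
  again <- annotateVariants(out, ann)
  expect_identical(again$name, out$name)
  expect_identical(again$tier, out$tier)
  # same-tier conflict: first-listed source wins, flagged
  conf <- data.frame(position = c(10L, 10L), name = c("M3", "M3alt"),
                     tier = "database_tree")
  expect_warning(res <- annotateVariants(sites, conf), "conflict")
  expect_identical(res$name[1], "M3")
})

test_that("call matrix drops monomorphic sites and respects strict depth", {
  m <- data.frame(sample = c("S1", "S2", "S1"),
                  position = c(5L, 5L, 9L),
                  bases = c("AAAAA", "AAAAA", "G"),
                  quals = c("30,30,30,30,30", "30,30,30,30,30", "30"))
  sites <- data.frame(position = c(5L, 9L), refAllele = "A",
                      altAllele = "G", proxyBase = "G",
                      ancestralAllele = "A", class = "SNP",
                      name = c("x5", "x9"))
  cm <- buildCallMatrix(m, sites)
  # site 5: unanimous ancestral -> dropped; site 9: one read -> missing cell,
  # derived nowhere -> dropped too
  expect_equal(nrow(calls(cm)), 0L)
  cmAll <- buildCallMatrix(m, sites, dropMonomorphic = FALSE)
  expect_identical(calls(cmAll)["x9", "S1"], NA_character_)
  expect_identical(calls(cmAll)["x5", "S2"], "A")
})

test_that("off-allele calls become missing and are counted", {
  m <- data.frame(sample = c("S1", "S2"), position = 5L,
                  bases = c("TTTTT", "GGGGG"),
                  quals = "30,30,30,30,30")
  sites <- data.frame(position = 5L, refAllele = "A", altAllele = "G",
                      proxyBase = "G", ancestralAllele = "A",
                      class = "SNP", name = "x5")
  cm <- buildCallMatrix(m, sites)
  expect_identical(calls(cm)["x5", "S1"], NA_character_)
  expect_identical(calls(cm)["x5", "S2"], "D")
  expect_equal(S4Vectors::metadata(cm)$offAlleleCells, 1L)
})

test_that("noiseless full-coverage matrix equals the truth indicator", {
  cfg <- quickConfig(nBranches = 10, seed = 31)
  tr <- simulateTree(cfg)
  p <- simulatePileups(tr, cfg)
  sites <- tr@sites
  sites$ancestralAllele <- sites$refAllele
  cm <- buildCallMatrix(p, sites)
  truthM <- truthCallMatrix(tr)
  got <- calls(cm)
  want <- calls(truthM)[paste0("pos", siteInfo(cm)$position),
                        colnames(got), drop = FALSE]
  expect_false(anyNA(got))
  expect_identical(unname(got), unname(want))
})
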