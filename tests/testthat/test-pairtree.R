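test_that("pair classification reproduces the canonical patterns", {
  m <- stateMatrix(i = "DDAA", j = "DDAA")
  expect_identical(classifyPair(m, "i", "j")$relation, "equivalent")
  m <- stateMatrix(i = "DDAA", j = "DAAA")
  pr <- classifyPair(m, "i", "j")
  expect_identical(pr$relation, "i_above_j")
  expect_equal(unlist(pr[c("n11", "n10", "n01", "n00")]),
               c(n11 = 1L, n10 = 1L, n01 = 0L, n00 = 2L))
  m <- stateMatrix(i = "DADA", j = "ADDA")
  expect_identical(classifyPair(m, "i", "j")$relation, "contradictory")
  m <- stateMatrix(i = "DDAA", j = "AADD")
  expect_identical(classifyPair(m, "i", "j")$relation, "disjoint")
  # overlap below min_informative -> uninformative
  m <- stateMatrix(i = "D...", j = "D...")
  expect_identical(classifyPair(m, "i", "j")$relation, "uninformative")
  # all-ancestral overlap -> uninformative
  m <- stateMatrix(i = "AA..", j = "AA..")
  expect_identical(classifyPair(m, "i", "j")$relation, "uninformative")
})

test_that("classifyPair is symmetric under swapping the sites", {
  swap <- c(equivalent = "equivalent", i_above_j = "j_above_i",
            j_above_i = "i_above_j", disjoint = "disjoint",
            contradictory = "contradictory",
            uninformative = "uninformative")
  set.seed(4)
  for (k in 1:60) {
    m <- randomStateMatrix(2, sample(3:10, 1), missing = runif(1, 0, 0.5))
    a <- classifyPair(m, 1L, 2L)
    b <- classifyPair(m, 2L, 1L)
    expect_identical(b$relation, unname(swap[a$relation]))
    expect_equal(c(b$n11, b$n10, b$n01, b$n00),
                 c(a$n11, a$n01, a$n10, a$n00))
  }
})

test_that("classifyPairs agrees with the brute-force carrier-set oracle", {
  set.seed(12)
  for (k in 1:300) {
    m <- randomStateMatrix(sample(2:8, 1), sample(2:10, 1),
                           missing = runif(1, 0, 0.5))
    rel <- classifyPairs(m)
    for (r in seq_len(nrow(rel))) {
      expect_identical(rel$relation[r],
                       bruteRelation(m[rel$i[r], ], m[rel$j[r], ]),
                       info = sprintf("case %d pair %d-%d", k,
                                      rel$i[r], rel$j[r]))
    }
  }
})

test_that("contradiction filtering removes the most-contradicted sites first", {
  # clean input: nothing removed
  m <- stateMatrix(a = "DDDD", b = "DDAA", c = "DAAA")
  rel <- classifyPairs(m)
  fc <- filterContradictory(rel, nrow(m))
  expect_identical(fc$kept, 1:3)
  expect_equal(nrow(fc$removed), 0L)
  # two sites contradicting only each other: exactly one removed, site order
  m <- stateMatrix(a = "DADA", b = "ADDA")
  fc <- filterContradictory(classifyPairs(m), 2L)
  expect_identical(fc$kept, 2L)
  expect_identical(fc$removed$site, 1L)
  # a hub contradicting several mutually clean sites is the one removed
  m <- stateMatrix(p1 = "DDDAAAAA", p2 = "DDAAAAAA", p3 = "AAADDDAA",
                   p4 = "AAADDAAA", hub = "DAADAADA")
  fc <- filterContradictory(classifyPairs(m), nrow(m))
  expect_identical(fc$removed$site_name, "hub")
  expect_identical(fc$kept, 1:4)
})

test_that("equivalence grouping forms clusters and flags inconsistent ones", {
  m <- stateMatrix(a = "DDAA", b = "DDAA", c = "DDAA", d = "DAAA",
                   e = "AADD")
  rel <- classifyPairs(m)
  ge <- groupEquivalent(1:5, rel)
  sizes <- sort(lengths(ge$clusters))
  expect_identical(sizes, c(1L, 1L, 3L))
  expect_true(list(1:3) %in% ge$clusters ||
              any(vapply(ge$clusters, setequal, TRUE, y = 1:3)))
  expect_equal(nrow(ge$ambiguous), 0L)
  # members equivalent via missing data but disagreeing about a third site:
  # a sees c as disjoint, b sees itself above c -> cluster {a,b} is ambiguous
  m2 <- stateMatrix(a = "DD.AAA", b = "DDD.AA", c = "AADDAA")
  rel2 <- classifyPairs(m2)
  expect_identical(rel2$relation[rel2$site_i == "a" & rel2$site_j == "b"],
                   "equivalent")
  expect_identical(rel2$relation[rel2$site_i == "a" & rel2$site_j == "c"],
                   "disjoint")
  expect_identical(rel2$relation[rel2$site_i == "b" & rel2$site_j == "c"],
                   "i_above_j")
  ge2 <- groupEquivalent(1:3, rel2)
  expect_setequal(ge2$ambiguous$site_name, c("a", "b"))
  expect_false(any(vapply(ge2$clusters, function(cl) 1L %in% cl, TRUE)))
})

test_that("hierarchy assembly produces forced chains and sibling splits", {
  # nested carrier sets {1,2,3,4} > {1,2} > {1} -> chain of three branches
  m <- stateMatrix(top = "DDDDA", mid = "DDAAA", tip = "DAAAA")
  bt <- buildHierarchy(list(1L, 2L, 3L), toCallMatrix(m))
  b <- branchTable(bt)
  expect_equal(nrow(b), 3L)
  expect_identical(unlist(b$snps[b$parent == "ROOT"]), "top")
  chain <- b$id[match(c("top", "mid", "tip"),
                      vapply(b$snps, `[[`, "", 1L))]
  expect_identical(b$parent[match(chain[2], b$id)], chain[1])
  expect_identical(b$parent[match(chain[3], b$id)], chain[2])
  # two disjoint clusters under one ancestor -> siblings
  m <- stateMatrix(anc = "DDDDA", l = "DDAAA", r = "AADDA")
  bt <- buildHierarchy(list(1L, 2L, 3L), toCallMatrix(m))
  b <- branchTable(bt)
  ancId <- b$id[vapply(b$snps, identical, TRUE, y = "anc")]
  expect_identical(b$parent[vapply(b$snps, identical, TRUE, y = "l")], ancId)
  expect_identical(b$parent[vapply(b$snps, identical, TRUE, y = "r")], ancId)
  # siblings ordered by descending carrier count
  expect_identical(unlist(b$snps[b$parent == ancId][1]), "l")
})

test_that("a multi-mutation branch becomes one cluster matching the truth", {
  cfg <- quickConfig(nBranches = 5, mutationsPerBranch = 5, seed = 23)
  tr <- simulateTree(cfg)
  cm <- truthCallMatrix(tr)
  bt <- inferTree(cm)
  mt <- matchBranchesToTruth(bt, tr)
  expect_false(anyNA(mt))
  b <- branchTable(bt)
  for (i in seq_len(nrow(b)))
    expect_setequal(b$snps[[i]], paste0("pos", tr@branchMutations[[mt[i]]]))
})

test_that("complete noiseless data is recovered exactly across seeds", {
  for (seed in c(101, 202, 303)) {
    cfg <- quickConfig(nBranches = 12,
                       nSamples = c(ModAdmix = 20, AncNAM = 15, ModNAM = 15),
                       seed = seed)
    tr <- simulateTree(cfg)
    cm <- truthCallMatrix(tr)
    bt <- inferTree(cm)
    expect_equal(nrow(removedVariants(bt)), 0L)
    expect_true(isomorphicToTruth(bt, tr))
    expect_equal(nrow(auditTree(bt, cm)), 0L)
    # deterministic: rebuilding gives the identical object
    expect_identical(branchTable(inferTree(cm)), branchTable(bt))
  }
})

test_that("an injected recurrent site is removed as contradictory", {
  cfg <- quickConfig(nBranches = 12,
                     nSamples = c(ModAdmix = 20, AncNAM = 15, ModNAM = 15),
                     seed = 77)
  inj <- injectRecurrentSite(simulateTree(cfg))
  expect_false(is.null(inj))
  cm <- truthCallMatrix(inj$truth)
  bt <- inferTree(cm)
  rem <- removedVariants(bt)
  expect_identical(rem$site, paste0("pos", inj$position))
  expect_identical(rem$reason, "contradictory")
  expect_true(isomorphicToTruth(bt, simulateTree(cfg)))
})

test_that("adding samples never turns a contradictory pair clean", {
  set.seed(31)
  for (k in 1:40) {
    m <- randomStateMatrix(2, 8, missing = 0.3)
    base <- classifyPair(m, 1L, 2L)$relation
    if (base != "contradictory") next
    extra <- randomStateMatrix(2, 4, missing = 0.3)
    expect_identical(classifyPair(cbind(m, extra), 1L, 2L)$relation,
                     "contradictory")
  }
})

test_that("singleton sites uninformative against placed clusters are tip-placed", {
  # site `solo` is called only in sample S1, missing elsewhere: relations to
  # every placed cluster are uninformative; its carrier sits under `tip`
  m <- stateMatrix(top = "DDDDA", tip = "DDAAA", solo = "D....")
  bt <- inferTree(toCallMatrix(m), minInformative = 2L)
  b <- branchTable(bt)
  soloRow <- which(vapply(b$snps, identical, TRUE, y = "solo"))
  expect_length(soloRow, 1L)
  expect_identical(b$flag[soloRow], "tip-placed")
  tipId <- b$id[vapply(b$snps, identical, TRUE, y = "tip")]
  expect_identical(b$parent[soloRow], tipId)
})
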