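# helper: a small inferred tree built from a state matrix through the full
# pairtree path, with named sites
inferFrom <- function(m, positions = NULL) inferTree(toCallMatrix(m, positions))

test_that("reference tree parsing validates structure and names rows in errors", {
  chain <- data.frame(branch = c("Q1", "Q1b", "Q1b1"),
                      parent = c("", "Q1", "Q1b"),
                      snps = c("L472", "M346", "L53"))
  ref <- loadReferenceTree(chain)
  expect_equal(nrow(ref), 3L)
  expect_identical(ref$parent, c("ROOT", "Q1", "Q1b"))
  expect_identical(ref$snps[[3]], "L53")
  expect_error(loadReferenceTree(data.frame(
    branch = "A", parent = "Zed", snps = "M1")), "Zed")
  expect_error(loadReferenceTree(data.frame(
    branch = c("A", "B"), parent = c("", "A"), snps = c("M1", "M1"))),
    "M1")
  expect_error(loadReferenceTree(data.frame(
    branch = c("A", "B"), parent = c("B", "A"), snps = c("M1", "M2"))),
    "cycle")
})

test_that("the packaged haplogroup-Q backbone parses to the stated nesting", {
  path <- system.file("extdata", "q_backbone_reference.tsv",
                      package = "Ylineage")
  ref <- loadReferenceTree(path)
  expect_equal(nrow(ref), 6L)
  # Q1b1-L53 is a sublineage of Q1b-M346
  anc <- character(0); b <- "Q1b1-L53"
  while (b != "ROOT") {
    b <- ref$parent[match(b, ref$branch)]
    anc <- c(anc, b)
  }
  expect_true("Q1b-M346" %in% anc)
  expect_true("Q-M242" %in% anc)
  expect_identical(ref$snps[[match("Q1b1a1a-M3", ref$branch)]], "M3")
})

test_that("anchoring to an empty reference returns the inferred tree as novel", {
  m <- stateMatrix(a = "DDDA", b = "DDAA")
  bt <- inferFrom(m)
  merged <- anchorTree(bt, NULL)
  expect_identical(branchTable(merged), branchTable(bt))
  expect_setequal(novelBranches(merged), branchTable(bt)$id)
})

test_that("an inferred chain anchors under the matching reference branch", {
  # inferred: M3 above ZK7; reference knows M3's lineage
  m <- stateMatrix(M3 = "DDDA", ZK7 = "DDAA")
  bt <- inferFrom(m)
  ref <- loadReferenceTree(system.file("extdata",
                                       "q_backbone_reference.tsv",
                                       package = "Ylineage"))
  merged <- anchorTree(bt, ref, keepUnobserved = FALSE)
  b <- branchTable(merged)
  expect_true("Q1b1a1a-M3" %in% b$id)
  expect_false("Q1b1a1a1-M848" %in% b$id)   # unobserved tip dropped
  expect_identical(b$provenance[match("Q1b1a1a-M3", b$id)], "both")
  novel <- b[b$provenance == "inferred", ]
  expect_equal(nrow(novel), 1L)
  expect_identical(novel$snps[[1]], "ZK7")
  expect_identical(novel$parent, "Q1b1a1a-M3")
  # pass-through database nodes retain their reference parents
  expect_identical(b$parent[match("Q1b-M346", b$id)], "Q1-L472")
  # naming: first novel child of Q1b1a1a-M3 -> Q1b1a1a1-ZK7
  named <- nameBranches(merged)
  nb <- branchTable(named)
  expect_identical(nb$name[match(novel$id, nb$id)], "Q1b1a1a1-ZK7")
  expect_false(anyDuplicated(nb$name) > 0)
})

test_that("existing child ordinals are skipped when naming novel siblings", {
  # reference already has Q1b1a1a1-M848 under Q1b1a1a-M3: the novel sibling
  # must take ordinal 2; two novel siblings take distinct ordinals
  m <- stateMatrix(M3 = "DDDDA", M848 = "DDAAA", ZK9 = "AADDA",
                   ZK2 = "AAADA")
  bt <- inferFrom(m)
  ref <- loadReferenceTree(system.file("extdata",
                                       "q_backbone_reference.tsv",
                                       package = "Ylineage"))
  named <- nameBranches(anchorTree(bt, ref))
  nb <- branchTable(named)
  zk9 <- nb$name[vapply(nb$snps, identical, TRUE, y = "ZK9")]
  zk2 <- nb$name[vapply(nb$snps, identical, TRUE, y = "ZK2")]
  expect_identical(zk9, "Q1b1a1a2-ZK9")   # sibling of M848 (ordinal 1 taken)
  expect_identical(zk2, "Q1b1a1a2a-ZK2")  # child of the ZK9 branch
})

test_that("root-level novel branches take the configured haplogroup prefix", {
  m <- stateMatrix(zz = "DDAA")
  named <- nameBranches(anchorTree(inferFrom(m), NULL), rootLabel = "Q")
  expect_identical(branchTable(named)$name, "Q1-zz")
})

test_that("anchoring is idempotent", {
  m <- stateMatrix(M3 = "DDDA", ZK7 = "DDAA", ZK8 = "DAAA")
  ref <- loadReferenceTree(system.file("extdata",
                                       "q_backbone_reference.tsv",
                                       package = "Ylineage"))
  once <- anchorTree(inferFrom(m), ref)
  twice <- anchorTree(once, ref)
  expect_identical(branchTable(twice), branchTable(once))
})

test_that("a cluster matching unrelated reference branches is left unanchored", {
  # one inferred cluster carries SNPs of two reference branches that are not
  # on one ancestor line (M3 under Q1b1 vs a parallel branch)
  ref <- loadReferenceTree(data.frame(
    branch = c("Q1", "Q1a", "Q1b"), parent = c("", "Q1", "Q1"),
    snps = c("L472", "M25", "M346")))
  m <- stateMatrix(M25 = "DDAA", M346 = "DDAA", L472 = "DDDA")
  merged <- anchorTree(inferFrom(m), ref)
  b <- branchTable(merged)
  conf <- attr(merged, "conflicts")
  expect_gt(nrow(conf), 0L)
  expect_true(any(removedVariants(merged)$reason == "unanchored"))
  expect_setequal(
    removedVariants(merged)$site[removedVariants(merged)$reason ==
                                 "unanchored"], c("M25", "M346"))
  # the anchored part still contains the clean Q1 match
  expect_identical(b$provenance[match("Q1", b$id)], "both")
})

test_that("every matrix SNP lands in the tree, the removal report or the conflicts", {
  cfg <- quickConfig(nBranches = 14, seed = 55, recurrenceRate = 0,
                     nSamples = c(ModAdmix = 20, AncNAM = 10, ModNAM = 10))
  tr <- simulateTree(cfg)
  inj <- injectRecurrentSite(tr)
  cm <- truthCallMatrix(inj$truth)
  merged <- anchorTree(inferTree(cm), NULL)
  inTree <- unlist(branchTable(merged)$snps)
  inReport <- removedVariants(merged)$site
  everySnp <- rownames(calls(cm))
  expect_setequal(c(inTree, inReport), everySnp)
  expect_equal(length(intersect(inTree, inReport)), 0L)
})

test_that("half-named simulation: unnamed true branches are exactly the novel set", {
  cfg <- quickConfig(nBranches = 12, seed = 91,
                     nSamples = c(ModAdmix = 18, AncNAM = 12, ModNAM = 12))
  tr <- simulateTree(cfg)
  cm <- truthCallMatrix(tr)
  bt <- inferTree(cm)
  expect_true(isomorphicToTruth(bt, tr))
  # name every other true branch in a fixture reference (parent = nearest
  # named ancestor), one defining SNP each
  ids <- tr@branches$id
  namedTruth <- ids[seq_along(ids) %% 2L == 1L]
  nearest <- function(id) {
    p <- tr@branches$parent[match(id, ids)]
    while (p != "ROOT" && !p %in% namedTruth)
      p <- tr@branches$parent[match(p, ids)]
    if (p == "ROOT") "" else paste0("HG_", p)
  }
  ref <- loadReferenceTree(data.frame(
    branch = paste0("HG_", namedTruth),
    parent = vapply(namedTruth, nearest, ""),
    snps = vapply(tr@branchMutations[namedTruth],
                  function(p) paste0("pos", p[1]), "")))
  merged <- anchorTree(bt, ref)
  mt <- matchBranchesToTruth(merged, tr)
  novel <- novelBranches(merged)
  b <- branchTable(merged)
  expect_setequal(mt[match(novel, b$id)], setdiff(ids, namedTruth))
  expect_setequal(mt[b$provenance == "both"], namedTruth)
  # provenance != database count equals branches absent from the reference
  expect_equal(sum(b$provenance != "database"), nrow(tr@branches))
})
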