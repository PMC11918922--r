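# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

# character state matrix from per-site strings: "D", "A", "." (missing)
stateMatrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) {
    z <- strsplit(r, "")[[1L]]
    z[z == "."] <- NA_character_
    z
  }))
  rownames(m) <- if (is.null(names(rows)))
    paste0("s", seq_along(rows)) else names(rows)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

toCallMatrix <- function(m, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(nrow(m)) * 10L
  YCallMatrix(m, data.frame(name = rownames(m), position = positions,
                            refAllele = "A", altAllele = "G",
                            ancestralAllele = "A", derivedAllele = "G",
                            proxyBase = "G", class = "SNP",
                            stringsAsFactors = FALSE))
}

# small, fully observed, noiseless simulation settings; overridable
quickConfig <- function(nBranches = 8L,
                        nSamples = c(ModAdmix = 6L, AncNAM = 4L, ModNAM = 4L),
                        mutationsPerBranch = 2,
                        recurrenceRate = 0,
                        depthMean = c(ModAdmix = 30, AncNAM = 30, ModNAM = 30),
                        depthDispersion = c(ModAdmix = 50, AncNAM = 50,
                                            ModNAM = 50),
                        missingness = c(ModAdmix = 0, AncNAM = 0, ModNAM = 0),
                        baseErrorRate = 0,
                        coverAllBranches = TRUE,
                        seed = 1L, ...) {
  simConfig(nBranches = nBranches, nSamples = nSamples,
            mutationsPerBranch = mutationsPerBranch,
            recurrenceRate = recurrenceRate, depthMean = depthMean,
            depthDispersion = depthDispersion, missingness = missingness,
            baseErrorRate = baseErrorRate,
            coverAllBranches = coverAllBranches, seed = seed, ...)
}

# call matrix implied directly by the ground truth (the noiseless limit)
truthCallMatrix <- function(truth, naFraction = 0, seed = NULL) {
  sites <- truth@sites
  samples <- names(truth@sampleTips)
  m <- vapply(samples, function(s)
    ifelse(sites$position %in% trueDerivedSites(truth, s), "D", "A"),
    character(nrow(sites)))
  rownames(m) <- paste0("pos", sites$position)
  if (naFraction > 0) {
    if (!is.null(seed)) set.seed(seed)
    m[matrix(runif(length(m)) < naFraction, nrow(m))] <- NA_character_
  }
  keep <- rowSums(m == "D", na.rm = TRUE) > 0L
  sites$name <- rownames(m)
  sites$ancestralAllele <- sites$refAllele
  sites$derivedAllele <- sites$altAllele
  YCallMatrix(m[keep, , drop = FALSE], sites[keep, , drop = FALSE])
}

# independent pairwise-relation oracle: explicit carrier-set comparison over
# the jointly called samples (never uses the count-threshold rule)
bruteRelation <- function(ci, cj, minInformative = 2L) {
  both <- which(!is.na(ci) & !is.na(cj))
  if (length(both) < minInformative) return("uninformative")
  Ci <- both[ci[both] == "D"]
  Cj <- both[cj[both] == "D"]
  if (!length(Ci) && !length(Cj)) return("uninformative")
  if (!length(Ci) || !length(Cj)) return("uninformative")
  inter <- intersect(Ci, Cj)
  if (!length(inter)) return("disjoint")
  if (setequal(Ci, Cj)) return("equivalent")
  if (all(Cj %in% Ci)) return("i_above_j")
  if (all(Ci %in% Cj)) return("j_above_i")
  "contradictory"
}

# random state matrix generator for property tests
randomStateMatrix <- function(nSites, nSamples, missing = 0.3) {
  m <- matrix(sample(c("A", "D"), nSites * nSamples, replace = TRUE),
              nrow = nSites,
              dimnames = list(paste0("s", seq_len(nSites)),
                              paste0("S", seq_len(nSamples))))
  m[matrix(runif(length(m)) < missing, nSites)] <- NA_character_
  m
}

# map each recovered branch to the truth branch with identical SNP content
# (NA where unmatched); names are "pos<position>" as in truthCallMatrix
matchBranchesToTruth <- function(tree, truth) {
  bm <- lapply(truth@branchMutations, function(p) sort(paste0("pos", p)))
  b <- branchTable(tree)
  vapply(b$snps, function(s) {
    hit <- which(vapply(bm, setequal, TRUE, y = sort(s)))
    if (length(hit) == 1L) names(bm)[hit] else NA_character_
  }, "")
}

# TRUE when the recovered tree is isomorphic to the generating tree under
# the SNP-content branch matching
isomorphicToTruth <- function(tree, truth) {
  b <- branchTable(tree)
  mt <- matchBranchesToTruth(tree, truth)
  if (anyNA(mt) || nrow(b) != nrow(truth@branches)) return(FALSE)
  tp <- stats::setNames(truth@branches$parent, truth@branches$id)
  all(vapply(seq_len(nrow(b)), function(i) {
    want <- tp[[mt[i]]]
    if (b$parent[i] == "ROOT") want == "ROOT"
    else identical(unname(mt[match(b$parent[i], b$id)]), want)
  }, TRUE))
}

# place one extra site on two incomparable branches A, B chosen so that the
# recurrent site contradicts as many placed ancestor sites as possible
# (ancestors of one branch off the other's root path): greedy filtering then
# removes exactly the recurrent site. Returns the modified truth and the new
# position, or NULL when the topology offers no pair with >= 2 such sites.
injectRecurrentSite <- function(truth) {
  br <- truth@branches
  anc <- function(id) setdiff(.pathOf(br, id), id)
  best <- NULL; bestScore <- 1L
  for (a in br$id) for (b in br$id) {
    if (a >= b) next
    if (b %in% .pathOf(br, a) || a %in% .pathOf(br, b)) next
    exclusive <- c(setdiff(anc(a), .pathOf(br, b)),
                   setdiff(anc(b), .pathOf(br, a)))
    score <- sum(lengths(truth@branchMutations[exclusive]))
    if (score > bestScore) { best <- c(a, b); bestScore <- score }
  }
  if (is.null(best)) return(NULL)
  pos <- max(truth@sites$position) + 1L
  for (id in best)
    truth@branchMutations[[id]] <- sort(c(truth@branchMutations[[id]], pos))
  truth@recurrentSites <- sort(c(truth@recurrentSites, pos))
  truth@sites <- rbind(truth@sites, data.frame(
    position = pos, refAllele = "A", altAllele = "G", proxyBase = "G",
    class = "SNP", recurrent = TRUE))
  list(truth = truth, position = pos)
}

.pathOf <- function(branches, id) {
  path <- character(0)
  while (id != "ROOT") {
    path <- c(id, path)
    id <- branches$parent[match(id, branches$id)]
  }
  path
}

# two-pass standard deviation, independent of stats::sd's implementation path
bruteSd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1))
}

# Pearson r and two-sided p via the explicit covariance / t-transform formulas
brutePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}
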