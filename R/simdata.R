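## Synthetic haploid lineage + capture-sequencing simulator.
## The generator emulates the cohort structure the analysis assumes: three
## sample groups with very different per-site coverage (ancient samples miss
## most sites), mutations placed on the branches of a random rooted tree,
## rare recurrent mutations, and per-read sequencing error.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: a ~300-branch haplogroup
#' tree; 130 modern-admixed, 104 ancient-indigenous and 43 modern-indigenous
#' samples; group missingness reflecting mean covered fractions of roughly
#' 9.9 Mb, 1.2 Mb and 13.2 Mb of a 7.45 Mb-scale target (ancient samples cover
#' about ten times fewer bases than modern ones); ~1% recurrent sites; ~6% of
#' sites labelled InDel-class for tally bookkeeping.
#'
#' @param nBranches number of branches in the generating tree (>= 2)
#' @param nSamples named integer vector: samples per group; names must be
#'   \code{ModAdmix}, \code{AncNAM}, \code{ModNAM}
#' @param mutationsPerBranch Poisson mean of mutations per branch (min 1
#'   enforced per branch)
#' @param recurrenceRate probability a site is independently placed on a
#'   second branch (off any shared root-to-tip path)
#' @param depthMean,depthDispersion named numeric vectors per group: mean and
#'   dispersion (negative-binomial \code{size}) of read depth at covered sites
#' @param missingness named numeric vector per group: probability a site is
#'   entirely uncovered in a sample
#' @param baseErrorRate probability a read reports a wrong base
#' @param qualityMean,qualitySd phred quality model for simulated reads
#' @param targetSpan length-2 integer: 1-based interval positions are drawn
#'   from (without replacement for non-recurrent sites)
#' @param indelFraction fraction of sites labelled InDel-class (bookkeeping
#'   only; read evidence stays single-base)
#' @param coverAllBranches attach the first \code{nBranches} samples one per
#'   branch (deterministically) before uniform attachment, realising the
#'   "every branch carries a sample" condition recovery experiments assume;
#'   default FALSE (fully uniform attachment)
#' @param seed master seed; every operation derives its own sub-stream
#' @return a validated list of class \code{ylineage_sim_config}
#' @export
simConfig <- function(nBranches = 300L,
                      nSamples = c(ModAdmix = 130L, AncNAM = 104L, ModNAM = 43L),
                      mutationsPerBranch = 11,
                      recurrenceRate = 0.01,
                      depthMean = c(ModAdmix = 10, AncNAM = 5, ModNAM = 30),
                      depthDispersion = c(ModAdmix = 2, AncNAM = 1, ModNAM = 2),
                      missingness = c(ModAdmix = 0.32, AncNAM = 0.92, ModNAM = 0.10),
                      baseErrorRate = 0.002,
                      qualityMean = 37, qualitySd = 3,
                      targetSpan = c(1L, 7450000L),
                      indelFraction = 0.064,
                      coverAllBranches = FALSE,
                      seed = 1L) {
  groups <- c("ModAdmix", "AncNAM", "ModNAM")
  cfg <- list(nBranches = as.integer(nBranches),
              nSamples = nSamples[groups],
              mutationsPerBranch = mutationsPerBranch,
              recurrenceRate = recurrenceRate,
              depthMean = depthMean[groups],
              depthDispersion = depthDispersion[groups],
              missingness = missingness[groups],
              baseErrorRate = baseErrorRate,
              qualityMean = qualityMean, qualitySd = qualitySd,
              targetSpan = as.integer(targetSpan),
              indelFraction = indelFraction,
              coverAllBranches = isTRUE(coverAllBranches),
              seed = as.integer(seed))
  names(cfg$nSamples) <- names(cfg$depthMean) <-
    names(cfg$depthDispersion) <- names(cfg$missingness) <- groups
  if (is.na(cfg$nBranches) || cfg$nBranches < 2L)
    .stopf("nBranches must be >= 2")
  if (any(is.na(cfg$nSamples)) || any(cfg$nSamples < 0L))
    .stopf("nSamples must be non-negative for groups %s",
           paste(groups, collapse = ", "))
  probs <- c(cfg$recurrenceRate, cfg$missingness, cfg$baseErrorRate,
             cfg$indelFraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    .stopf("all probabilities must lie in [0, 1]")
  if (any(is.na(cfg$depthMean)) || any(cfg$depthMean <= 0))
    .stopf("depth means must be > 0")
  if (cfg$mutationsPerBranch <= 0) .stopf("mutationsPerBranch must be > 0")
  if (length(cfg$targetSpan) != 2L || diff(cfg$targetSpan) <= 0)
    .stopf("targetSpan must be an increasing 1-based interval")
  class(cfg) <- "ylineage_sim_config"
  cfg
}

## TRUE if branch a is an ancestor of b (or equal) in the branch table
.onOnePath <- function(branches, a, b) {
  a %in% .pathToRoot(branches, b) || b %in% .pathToRoot(branches, a)
}

#' Simulate a rooted lineage tree with branch-placed mutations
#'
#' Grows a tree by iterative uniform-random attachment (first branch hangs off
#' the implicit root; every later branch attaches to a uniformly chosen
#' existing branch), places \code{max(1, Poisson(mutationsPerBranch))} mutation
#' sites on each branch at distinct coordinates, flags a \code{recurrenceRate}
#' fraction of sites recurrent by placing them on a second branch that is
#' neither the first nor on one root-to-tip path with it, and attaches every
#' requested sample to a uniformly chosen branch (internal branches allowed).
#'
#' @param config a \code{\link{simConfig}}
#' @return a \linkS4class{SimTruth}
#' @export
simulateTree <- function(config) {
  stopifnot(inherits(config, "ylineage_sim_config"))
  set.seed(.subSeed(config$seed, 1L))
  nb <- config$nBranches
  ids <- sprintf("b%03d", seq_len(nb))
  parent <- c("ROOT", ids[vapply(seq_len(nb - 1L),
                                 function(i) sample.int(i, 1L), 1L)])
  branches <- data.frame(id = ids, parent = parent, stringsAsFactors = FALSE)

  nmut <- pmax(1L, stats::rpois(nb, config$mutationsPerBranch))
  span <- config$targetSpan
  pos <- sort(sample(seq.int(span[1L], span[2L]), sum(nmut)))
  pos <- sample(pos)                       # random branch assignment order
  branchMutations <- split(pos, rep(ids, nmut))[ids]
  branchMutations <- lapply(branchMutations, sort)

  ## recurrent placements: same coordinate independently on a second branch
  recurrent <- integer(0)
  recFlag <- stats::runif(length(pos)) < config$recurrenceRate
  siteBranch <- rep(ids, nmut)              # aligned with pos
  names(siteBranch) <- as.character(pos)
  for (k in which(recFlag)) {
    b1 <- siteBranch[[k]]
    cand <- ids[!vapply(ids, function(b2)
      b2 == b1 || .onOnePath(branches, b1, b2), TRUE)]
    if (!length(cand)) next                # chain topology: nowhere valid
    b2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
    branchMutations[[b2]] <- sort(c(branchMutations[[b2]], pos[k]))
    recurrent <- c(recurrent, pos[k])
  }

  ## samples: uniform attachment, internal branches included; optionally one
  ## sample per branch first so every branch is observed
  prefixes <- c(ModAdmix = "MA", AncNAM = "AN", ModNAM = "MN")
  sampleIds <- character(0); sampleGroups <- character(0)
  for (g in names(config$nSamples)) {
    n <- config$nSamples[[g]]
    if (n == 0L) next
    sid <- sprintf("%s%03d", prefixes[[g]], seq_len(n))
    sampleIds <- c(sampleIds, sid)
    sampleGroups <- c(sampleGroups, stats::setNames(rep(g, n), sid))
  }
  ntot <- length(sampleIds)
  tips <- ids[sample.int(nb, ntot, replace = TRUE)]
  if (config$coverAllBranches && ntot) {
    k <- min(nb, ntot)
    tips[seq_len(k)] <- ids[seq_len(k)]
  }
  sampleTips <- stats::setNames(tips, sampleIds)

  allPos <- sort(unique(unlist(branchMutations, use.names = FALSE)))
  proxy <- sample(c("C", "G", "T"), length(allPos), replace = TRUE)
  isIndel <- stats::runif(length(allPos)) < config$indelFraction
  sites <- data.frame(position = allPos,
                      refAllele = "A",
                      altAllele = ifelse(isIndel, paste0("A", proxy), proxy),
                      proxyBase = proxy,
                      class = ifelse(isIndel, "InDel", "SNP"),
                      recurrent = allPos %in% recurrent,
                      stringsAsFactors = FALSE)

  new("SimTruth", branches = branches, branchMutations = branchMutations,
      sampleTips = sampleTips, sampleGroups = sampleGroups, sites = sites,
      recurrentSites = sort(unique(recurrent)))
}

#' Simulate pileup evidence for every sample and site
#'
#' For every sample x catalog site, with probability
#' \code{1 - missingness[group]} the site is covered and a pileup column is
#' emitted; uncovered sites emit nothing (the dominant condition for ancient
#' samples). A covered column has depth \code{1 + NegBin(mu = depthMean - 1,
#' size = dispersion)} (depth is at least one read, so coverage is governed by
#' the missingness probability alone), bases equal to the sample's true allele
#' flipped to a uniformly chosen other base with probability
#' \code{baseErrorRate}, and phred qualities drawn from a rounded normal
#' clamped to [2, 60].
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{simulateTree}}
#' @param config the same \code{\link{simConfig}}
#' @return data.frame of pileup columns: \code{sample}, \code{position},
#'   \code{bases} (string, one character per read), \code{quals}
#'   (comma-separated integers)
#' @export
simulatePileups <- function(truth, config) {
  stopifnot(is(truth, "SimTruth"), inherits(config, "ylineage_sim_config"))
  set.seed(.subSeed(config$seed, 2L))
  sites <- truth@sites
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  out <- vector("list", length(truth@sampleTips))
  names(out) <- names(truth@sampleTips)
  for (s in names(truth@sampleTips)) {
    g <- truth@sampleGroups[[s]]
    if (!g %in% names(config$missingness) || is.na(config$missingness[[g]]))
      .stopf("unknown group label '%s' for sample %s", g, s)
    covered <- stats::runif(nrow(sites)) >= config$missingness[[g]]
    if (!any(covered)) next
    idx <- which(covered)
    depth <- 1L + stats::rnbinom(length(idx),
                                 mu = max(config$depthMean[[g]] - 1, 1e-3),
                                 size = config$depthDispersion[[g]])
    derived <- sites$position[idx] %in% trueDerivedSites(truth, s)
    trueBase <- ifelse(derived, sites$proxyBase[idx], sites$refAllele[idx])
    reads <- rep(trueBase, depth)
    err <- which(stats::runif(length(reads)) < config$baseErrorRate)
    if (length(err))
      reads[err] <- vapply(reads[err],
                           function(b) sample(other[[b]], 1L), "")
    quals <- pmin(60L, pmax(2L, as.integer(round(
      stats::rnorm(length(reads), config$qualityMean, config$qualitySd)))))
    col <- rep(seq_along(idx), depth)
    out[[s]] <- data.frame(
      sample = s,
      position = sites$position[idx],
      bases = vapply(split(reads, col), paste, "", collapse = ""),
      quals = vapply(split(quals, col), paste, "", collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample = character(0), position = integer(0),
                      bases = character(0), quals = character(0))
  rownames(res) <- NULL
  res
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write pileup columns as a tab-separated table
#' @param pileups data.frame from \code{\link{simulatePileups}}
#' @param path output file
#' @export
writePileups <- function(pileups, path) {
  utils::write.table(pileups, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pileup table written by \code{\link{writePileups}}
#' @param path input file
#' @return pileup data.frame
#' @export
readPileups <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character",
                                   "character"), stringsAsFactors = FALSE)
}

#' Write a minimal haploid VCF of the simulated evidence
#'
#' One pseudo-contig \code{chrY}, 1-based positions, FORMAT \code{GT:DP:AD}.
#' Per sample and site, \code{AD} counts reads supporting the reference and
#' alternate allele among reads at or above \code{minQuality} (reads of other
#' bases contribute to \code{DP} only); \code{GT} is the modal allele (\code{.}
#' when no qualifying reads). The per-read base-quality floor is applied at
#' write time because a VCF carries allele depths, not per-read qualities.
#'
#' @param pileups pileup data.frame
#' @param sites site catalog with \code{position}, \code{refAllele},
#'   \code{altAllele}, \code{proxyBase}
#' @param samples sample ids defining the column order
#' @param path output file
#' @param minQuality base-quality floor applied when counting allele depths
#' @export
writeHaploidVcf <- function(pileups, sites, samples, path, minQuality = 25L) {
  key <- paste(pileups$sample, pileups$position)
  lut <- stats::setNames(seq_len(nrow(pileups)), key)
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chrY>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$position[i]
    cells <- vapply(samples, function(s) {
      j <- lut[paste(s, p)]
      if (is.na(j)) return("./.:0:0,0")
      b <- .splitBases(pileups$bases[j])
      q <- .splitInts(pileups$quals[j])
      b <- b[q >= minQuality]
      nref <- sum(b == sites$refAllele[i])
      nalt <- sum(b == sites$proxyBase[i])
      gt <- if (nref == 0L && nalt == 0L) "."
            else if (nalt > nref) "1" else "0"
      sprintf("%s:%d:%d,%d", gt, length(b), nref, nalt)
    }, "")
    paste(c("chrY", p, ".", sites$refAllele[i], sites$altAllele[i], ".",
            "PASS", ".", "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read a minimal haploid VCF back into pileup-like evidence
#'
#' Parses with \code{VariantAnnotation::readVcf} and reconstructs one pileup
#' column per sample x site from the \code{AD} field: \code{AD[1]} reads of the
#' reference base and \code{AD[2]} reads of the alternate proxy base (first
#' base of the ALT string differing from REF), all at the stated nominal
#' quality (the writer already applied its base-quality floor).
#'
#' @param path VCF file
#' @param quality nominal phred quality assigned to reconstructed reads
#' @return list with \code{pileups} (data.frame) and \code{sites} (catalog
#'   data.frame: position, refAllele, altAllele, proxyBase, class)
#' @export
readHaploidVcf <- function(path, quality = 37L) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- vapply(as.list(rr$ALT), function(a) as.character(a)[1L], "")
  proxy <- .proxyBase(ref, alt)
  ad <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(vcf)
  out <- list(); k <- 0L
  for (j in seq_along(samples)) {
    for (i in seq_along(pos)) {
      cnt <- ad[i, j][[1L]]
      if (length(cnt) < 2L || sum(cnt, na.rm = TRUE) == 0L) next
      k <- k + 1L
      n <- c(cnt[1L], cnt[2L])
      out[[k]] <- data.frame(
        sample = samples[j], position = pos[i],
        bases = paste(rep(c(substr(ref[i], 1L, 1L), proxy[i]), n),
                      collapse = ""),
        quals = paste(rep(quality, sum(n)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  sites <- data.frame(position = pos, refAllele = ref, altAllele = alt,
                      proxyBase = proxy,
                      class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                                     "SNP", "InDel"),
                      stringsAsFactors = FALSE)
  pile <- if (k) do.call(rbind, out) else
    data.frame(sample = character(0), position = integer(0),
               bases = character(0), quals = character(0))
  list(pileups = pile, sites = sites)
}

## newick text for a branch table (ids as labels); polytomies kept
.branchNewick <- function(branches) {
  kids <- split(branches$id, branches$parent)
  fmt <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) return(id)
    paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")", id)
  }
  top <- kids[["ROOT"]]
  paste0("(", paste(vapply(top, fmt, ""), collapse = ","), ")ROOT;")
}

#' Write simulation ground truth
#'
#' Writes the generating tree as newick (branch ids as labels, rooted at a
#' \code{ROOT} node) and the branch-to-mutation map as TSV.
#'
#' @param truth a \linkS4class{SimTruth}
#' @param dir output directory (created if needed)
#' @return invisibly, the two file paths
#' @export
writeTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nwk <- file.path(dir, "truth_tree.nwk")
  writeLines(.branchNewick(truth@branches), nwk)
  tsv <- file.path(dir, "truth_mutations.tsv")
  df <- data.frame(
    branch = names(truth@branchMutations),
    positions = vapply(truth@branchMutations, paste, "", collapse = ","))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nwk, tsv))
}
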