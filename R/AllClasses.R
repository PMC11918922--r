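#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## ---------------------------------------------------------------------------
## YCallMatrix: samples x variant sites with haploid calls
## ---------------------------------------------------------------------------

#' Haploid call matrix of ancestral/derived states
#'
#' A \code{YCallMatrix} holds the central object of the pipeline: for every
#' variant site (rows) and sample (columns) one of three states --
#' \code{"A"} (ancestral allele called), \code{"D"} (derived allele called) or
#' \code{NA} (missing: insufficient or conflicting read evidence). It extends
#' \linkS4class{SummarizedExperiment}, so the usual accessors
#' (\code{assay}, \code{rowData}, \code{colnames}, subsetting) apply; site
#' annotation (position, alleles, variant class, name, name tier) lives in
#' \code{rowData}.
#'
#' @seealso \code{\link{buildCallMatrix}}, \code{\link{classifyPairs}}
#' @exportClass YCallMatrix
setClass("YCallMatrix", contains = "SummarizedExperiment")

setValidity("YCallMatrix", function(object) {
  if (!"call" %in% SummarizedExperiment::assayNames(object))
    return("assay 'call' is required")
  cc <- SummarizedExperiment::assay(object, "call")
  bad <- !(is.na(cc) | cc == "A" | cc == "D")
  if (any(bad))
    return("call values must be 'A', 'D' or NA")
  rd <- rowData(object)
  if (!all(c("position", "ancestralAllele", "derivedAllele") %in% colnames(rd)))
    return("rowData must contain position, ancestralAllele, derivedAllele")
  TRUE
})

#' Construct a YCallMatrix
#'
#' @param calls character matrix, sites x samples, values \code{"A"},
#'   \code{"D"} or \code{NA}. Row names are site names, column names sample
#'   identifiers.
#' @param sites data.frame of site annotation, one row per matrix row; must
#'   contain \code{position}, \code{ancestralAllele}, \code{derivedAllele};
#'   typically also \code{refAllele}, \code{altAllele}, \code{class},
#'   \code{name}, \code{tier}.
#' @return a \linkS4class{YCallMatrix}
#' @export
YCallMatrix <- function(calls, sites) {
  calls <- as.matrix(calls)
  sites <- as.data.frame(sites)
  stopifnot(nrow(calls) == nrow(sites))
  if (is.null(rownames(calls)) && !is.null(sites$name))
    rownames(calls) <- sites$name
  se <- SummarizedExperiment(assays = list(call = calls),
                             rowData = DataFrame(sites))
  new("YCallMatrix", se)
}

#' @describeIn YCallMatrix the call matrix (sites x samples)
#' @param x a YCallMatrix
#' @export
calls <- function(x) SummarizedExperiment::assay(x, "call")

#' @describeIn YCallMatrix site annotation as a data.frame
#' @export
siteInfo <- function(x) as.data.frame(rowData(x))

setMethod("show", "YCallMatrix", function(object) {
  cc <- calls(object)
  nd <- sum(cc == "D", na.rm = TRUE)
  nm <- mean(is.na(cc))
  cat(sprintf("YCallMatrix: %d sites x %d samples\n", nrow(cc), ncol(cc)))
  cat(sprintf("  derived calls: %d; missing: %.1f%%\n", nd, 100 * nm))
})

## ---------------------------------------------------------------------------
## BranchTree: rooted hierarchy of SNP-defined branches
## ---------------------------------------------------------------------------

#' Rooted hierarchy of SNP-defined branches
#'
#' Each branch is defined by one or more equivalent SNPs and points to a
#' parent branch (or the implicit root, encoded \code{"ROOT"}). Branches carry
#' provenance -- \code{"inferred"} (from the call matrix only),
#' \code{"database"} (reference-tree only, no observed SNP) or \code{"both"}
#' -- and, after anchoring/naming, a lineage label. Variants removed during
#' tree construction are retained in a report accessible with
#' \code{\link{removedVariants}}.
#'
#' @slot branches data.frame with columns \code{id}, \code{parent},
#'   \code{name}, \code{provenance}, \code{nCarriers}, \code{flag} and
#'   list-columns \code{snps}, \code{carriers}.
#' @slot removed data.frame of removed variants: \code{site}, \code{reason}
#'   (\code{"contradictory"}, \code{"ambiguous"} or \code{"unanchored"}),
#'   \code{detail}.
#' @exportClass BranchTree
setClass("BranchTree",
         representation(branches = "data.frame", removed = "data.frame"))

setValidity("BranchTree", function(object) {
  b <- object@branches
  need <- c("id", "parent", "name", "provenance", "nCarriers", "flag",
            "snps", "carriers")
  if (!all(need %in% colnames(b)))
    return(paste("branch table must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(b$id)) return("branch ids must be unique")
  if (nrow(b) && !all(b$parent %in% c("ROOT", b$id)))
    return("every parent must be ROOT or an existing branch id")
  ## no cycles: repeated parent-hops must reach ROOT
  if (nrow(b)) {
    idx <- stats::setNames(seq_len(nrow(b)), b$id)
    for (i in seq_len(nrow(b))) {
      seen <- integer(0); j <- i
      while (b$parent[j] != "ROOT") {
        if (j %in% seen) return("parent links contain a cycle")
        seen <- c(seen, j)
        j <- idx[[b$parent[j]]]
      }
    }
    sn <- unlist(b$snps, use.names = FALSE)
    if (anyDuplicated(sn)) return("SNP sets of distinct branches must be disjoint")
  }
  TRUE
})

## internal constructor with consistent column handling
.newBranchTree <- function(branches, removed = NULL) {
  if (is.null(removed))
    removed <- data.frame(site = character(0), reason = character(0),
                          detail = character(0), stringsAsFactors = FALSE)
  if (nrow(branches) == 0L)
    branches <- data.frame(id = character(0), parent = character(0),
                           name = character(0), provenance = character(0),
                           nCarriers = integer(0), flag = character(0),
                           snps = I(list()), carriers = I(list()))
  new("BranchTree", branches = branches, removed = removed)
}

#' @describeIn BranchTree branch table (one row per branch; list-columns
#'   \code{snps} and \code{carriers})
#' @param x a BranchTree
#' @export
branchTable <- function(x) x@branches

#' @describeIn BranchTree report of variants removed while building or
#'   anchoring the tree
#' @export
removedVariants <- function(x) x@removed

#' @describeIn BranchTree ids of branches absent from the reference tree
#'   (provenance \code{"inferred"})
#' @export
novelBranches <- function(x) x@branches$id[x@branches$provenance == "inferred"]

#' @describeIn BranchTree depth of every branch (root children = 1)
#' @export
branchDepths <- function(x) {
  b <- x@branches
  d <- stats::setNames(rep(NA_integer_, nrow(b)), b$id)
  depth1 <- function(id) {
    if (!is.na(d[[id]])) return(d[[id]])
    p <- b$parent[match(id, b$id)]
    d[[id]] <<- if (p == "ROOT") 1L else depth1(p) + 1L
    d[[id]]
  }
  for (id in b$id) depth1(id)
  d
}

setMethod("show", "BranchTree", function(object) {
  b <- object@branches
  cat(sprintf("BranchTree: %d branches, %d SNPs\n",
              nrow(b), length(unlist(b$snps))))
  tab <- table(b$provenance)
  if (length(tab))
    cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (nrow(object@removed))
    cat(sprintf("  removed variants: %d (%s)\n", nrow(object@removed),
                paste(names(table(object@removed$reason)),
                      table(object@removed$reason), sep = "=", collapse = ", ")))
})

## path of branch ids from root down to (and including) id
.pathToRoot <- function(branches, id) {
  path <- character(0)
  while (id != "ROOT") {
    path <- c(id, path)
    id <- branches$parent[match(id, branches$id)]
  }
  path
}

## ---------------------------------------------------------------------------
## SimTruth: generating tree + ground truth of a simulation
## ---------------------------------------------------------------------------

#' Ground truth of a simulated Y lineage cohort
#'
#' Produced by \code{\link{simulateTree}}; records the generating branch
#' hierarchy, the mutations placed on each branch, which branch every sample
#' sits on, the site catalog (alleles, variant class, recurrence flags) and
#' each sample's group label. Used as the oracle in recovery tests.
#'
#' @slot branches data.frame: \code{id}, \code{parent} (\code{"ROOT"} marks
#'   children of the implicit root).
#' @slot branchMutations named list: branch id -> integer positions mutated on
#'   that branch.
#' @slot sampleTips named character: sample id -> branch id.
#' @slot sampleGroups named character: sample id -> group label.
#' @slot sites data.frame site catalog: \code{position}, \code{refAllele},
#'   \code{altAllele}, \code{proxyBase}, \code{class}, \code{recurrent}.
#' @slot recurrentSites integer positions placed independently on two branches.
#' @exportClass SimTruth
setClass("SimTruth",
         representation(branches = "data.frame", branchMutations = "list",
                        sampleTips = "character", sampleGroups = "character",
                        sites = "data.frame", recurrentSites = "integer"))

setValidity("SimTruth", function(object) {
  if (!all(names(object@branchMutations) %in% object@branches$id))
    return("branchMutations names must be branch ids")
  if (!all(object@sampleTips %in% object@branches$id))
    return("sampleTips must map to branch ids")
  nonrec <- setdiff(unlist(object@branchMutations), object@recurrentSites)
  if (anyDuplicated(nonrec))
    return("non-recurrent sites must appear on exactly one branch")
  TRUE
})

#' True derived-site positions of one simulated sample
#'
#' Union of the mutations on every branch along the sample's root-to-tip path
#' (recurrent placements included through the same union).
#'
#' @param truth a \linkS4class{SimTruth}
#' @param sample sample identifier
#' @return sorted integer vector of positions
#' @export
trueDerivedSites <- function(truth, sample) {
  tip <- truth@sampleTips[[sample]]
  path <- .pathToRoot(truth@branches, tip)
  sort(unique(unlist(truth@branchMutations[path], use.names = FALSE)))
}

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d branches, %d sites (%d recurrent), %d samples\n",
              nrow(object@branches), nrow(object@sites),
              length(object@recurrentSites), length(object@sampleTips)))
})
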