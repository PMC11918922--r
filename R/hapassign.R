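## Per-sample haplogroup assignment on a (merged) branch tree, and
## resolution comparison between marker panels.

## per-branch support of one sample's named calls
.branchSupport <- function(snps, sampleCalls) {
  typed <- sampleCalls[intersect(snps, names(sampleCalls))]
  typed <- typed[!is.na(typed)]
  nDer <- sum(typed == "D")
  list(nTyped = length(typed), nDer = nDer,
       nAnc = length(typed) - nDer)
}

#' Assign samples to their deepest supported branch
#'
#' Walks each sample root-to-tip. A branch is \emph{supported} when at least
#' one of its defining SNPs is called derived and the fraction of its typed
#' defining SNPs called derived is at least \code{minSupport}; a branch whose
#' typed defining SNPs are all ancestral \emph{blocks} descent; an entirely
#' untyped branch is passable but unsupported (missing data is not
#' contradiction). The assignment is the deepest supported branch reachable
#' through non-blocked branches. If two supported branches tie at maximal
#' depth on diverging paths (possible only with conflicting calls), the
#' deepest supported branch on the path to their common ancestor is reported
#' and the sample flagged \code{tie}. Samples supporting no branch are
#' \code{failed_qc}.
#'
#' @param x a \linkS4class{YCallMatrix} whose row names are SNP names shared
#'   with the tree
#' @param tree a \linkS4class{BranchTree}
#' @param minSupport minimum derived fraction among typed defining SNPs
#'   (default 0.95, mirroring the strict base-majority ethos of the caller)
#' @return data.frame: \code{sample}, \code{branch} (id), \code{haplogroup}
#'   (branch name if set), \code{depth} (root = 0, so first branch = 1),
#'   \code{support} (derived fraction of typed path-defining SNPs),
#'   \code{conflicts} (typed path-defining SNPs called ancestral),
#'   \code{status} (\code{assigned}/\code{failed_qc}), \code{flag}
#' @export
assignHaplogroups <- function(x, tree, minSupport = 0.95) {
  m <- calls(x)
  b <- branchTable(tree)
  depths <- if (nrow(b)) branchDepths(tree) else integer(0)
  kids <- split(b$id, b$parent)
  out <- vector("list", ncol(m))
  for (k in seq_len(ncol(m))) {
    s <- colnames(m)[k]
    sampleCalls <- m[, k]
    sup <- lapply(b$snps, .branchSupport, sampleCalls = sampleCalls)
    supported <- vapply(sup, function(z)
      z$nDer >= 1L && (z$nDer / z$nTyped) >= minSupport, TRUE)
    blocked <- vapply(sup, function(z)
      z$nTyped >= 1L && z$nDer == 0L, TRUE)
    ## reachable: every branch on the path root->branch is non-blocked
    reachable <- rep(FALSE, nrow(b))
    walk <- function(id) {
      i <- match(id, b$id)
      if (blocked[i]) return(invisible())
      reachable[i] <<- TRUE
      for (ch in kids[[id]]) walk(ch)
    }
    for (top in kids[["ROOT"]]) walk(top)
    cand <- which(supported & reachable)
    if (!length(cand)) {
      out[[k]] <- data.frame(sample = s, branch = NA_character_,
                             haplogroup = NA_character_, depth = 0L,
                             support = NA_real_, conflicts = NA_integer_,
                             status = "failed_qc", flag = "")
      next
    }
    dmax <- max(depths[cand])
    deepest <- cand[depths[cand] == dmax]
    flag <- ""
    if (length(deepest) > 1L) {
      ## conflicting calls: fall back to the deepest supported branch on the
      ## shared root path of the tied branches
      paths <- lapply(b$id[deepest], .pathToRoot, branches = b)
      common <- Reduce(intersect, paths)
      onCommon <- cand[b$id[cand] %in% common]
      flag <- "tie"
      if (length(onCommon)) {
        dmax <- max(depths[onCommon])
        deepest <- onCommon[depths[onCommon] == dmax][1L]
      } else {
        deepest <- deepest[1L]            # no supported common ancestor
      }
    }
    i <- deepest[1L]
    path <- .pathToRoot(b, b$id[i])
    pathSup <- lapply(b$snps[match(path, b$id)], .branchSupport,
                      sampleCalls = sampleCalls)
    nTyped <- sum(vapply(pathSup, `[[`, 0L, "nTyped"))
    nDer <- sum(vapply(pathSup, `[[`, 0L, "nDer"))
    out[[k]] <- data.frame(
      sample = s, branch = b$id[i],
      haplogroup = if (is.na(b$name[i])) b$id[i] else b$name[i],
      depth = as.integer(depths[i]),
      support = if (nTyped) nDer / nTyped else NA_real_,
      conflicts = as.integer(nTyped - nDer),
      status = "assigned", flag = flag)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare assignment resolution between two marker panels
#'
#' Summarises, per panel, the number of samples assigned and the number of
#' distinct branches used, and per sample the depth gain of the high panel
#' over the low panel. When \code{nested = TRUE} (the high panel's marker set
#' contains the low panel's and calls agree at shared markers) every depth
#' delta must be non-negative; violations stop with an error when
#' \code{strict = TRUE}, otherwise they are flagged in the per-sample table.
#'
#' @param low,high assignment data.frames from
#'   \code{\link{assignHaplogroups}} over the same samples
#' @param nested is the low panel a subset of the high panel?
#' @param strict stop on a negative delta under \code{nested}
#' @return list with \code{panels} (data.frame: panel, nAssigned,
#'   nBranches) and \code{samples} (data.frame: sample, depthLow, depthHigh,
#'   delta, violation)
#' @export
resolutionReport <- function(low, high, nested = FALSE, strict = nested) {
  if (!setequal(low$sample, high$sample))
    .stopf("assignment sets cover different samples")
  low <- low[order(low$sample), ]
  high <- high[match(low$sample, high$sample), ]
  panels <- data.frame(
    panel = c("low", "high"),
    nAssigned = c(sum(low$status == "assigned"),
                  sum(high$status == "assigned")),
    nBranches = c(length(unique(low$branch[low$status == "assigned"])),
                  length(unique(high$branch[high$status == "assigned"]))))
  samples <- data.frame(sample = low$sample,
                        depthLow = low$depth, depthHigh = high$depth,
                        delta = high$depth - low$depth)
  samples$violation <- nested & samples$delta < 0L &
    low$status == "assigned" & high$status == "assigned"
  if (strict && any(samples$violation))
    .stopf("depth decreased for sample(s) %s despite nested panels",
           paste(samples$sample[samples$violation], collapse = ", "))
  list(panels = panels, samples = samples)
}

#' Write haplogroup assignments as TSV
#' @param assignments data.frame from \code{\link{assignHaplogroups}}
#' @param path output file
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
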