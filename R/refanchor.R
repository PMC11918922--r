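## Anchoring an inferred branch hierarchy to a named reference tree
## (ISOGG/YFull-style tabular: branch, parent, defining SNPs), with
## lineage-based nomenclature for novel branches.

#' Load a reference haplogroup tree
#'
#' Tab-separated with header \code{branch}, \code{parent}, \code{snps}
#' (comma-separated defining SNP names). \code{parent} empty, \code{NA} or
#' \code{"ROOT"} marks a root branch. Validated: every parent must exist, SNP
#' names must be unique across rows, parent links must be acyclic; violations
#' raise an error naming the offending row.
#'
#' @param path file path, or a data.frame with the same columns
#' @return reference tree data.frame: \code{branch}, \code{parent},
#'   \code{snps} (list-column of SNP name vectors)
#' @export
loadReferenceTree <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, quote = "")
  if (!all(c("branch", "parent", "snps") %in% colnames(df)))
    .stopf("reference tree needs columns branch, parent, snps")
  df$parent[is.na(df$parent) | !nzchar(df$parent)] <- "ROOT"
  snps <- lapply(strsplit(as.character(df$snps), ",", fixed = TRUE),
                 function(s) sort(trimws(s[nzchar(trimws(s))])))
  if (anyDuplicated(df$branch))
    .stopf("duplicate branch name '%s'", df$branch[duplicated(df$branch)][1L])
  orphan <- !(df$parent %in% c("ROOT", df$branch))
  if (any(orphan))
    .stopf("row %d ('%s'): parent '%s' is not defined",
           which(orphan)[1L], df$branch[orphan][1L], df$parent[orphan][1L])
  flat <- unlist(snps)
  if (anyDuplicated(flat))
    .stopf("SNP name '%s' defined on more than one branch",
           flat[duplicated(flat)][1L])
  if (any(!vapply(snps, length, 0L)))
    .stopf("row %d ('%s'): no defining SNPs",
           which(!vapply(snps, length, 0L))[1L],
           df$branch[!vapply(snps, length, 0L)][1L])
  ## cycle check by walking each branch to ROOT
  for (i in seq_len(nrow(df))) {
    seen <- character(0); b <- df$branch[i]
    while (b != "ROOT") {
      if (b %in% seen)
        .stopf("row %d ('%s'): parent links form a cycle", i, df$branch[i])
      seen <- c(seen, b)
      b <- df$parent[match(b, df$branch)]
    }
  }
  out <- data.frame(branch = df$branch, parent = df$parent,
                    stringsAsFactors = FALSE)
  out$snps <- snps
  out
}

## depth of a reference branch (root children = 1)
.refDepth <- function(ref, b) {
  d <- 0L
  while (b != "ROOT") { d <- d + 1L; b <- ref$parent[match(b, ref$branch)] }
  d
}

#' Anchor an inferred hierarchy to a reference tree
#'
#' Inferred branches sharing at least one SNP name with a reference branch
#' adopt that branch's lineage name and provenance \code{"both"}; when an
#' inferred branch matches several reference branches lying on one ancestor
#' line (the matrix could not separate them) it anchors to the deepest;
#' matches to reference branches not on one line are an anchoring conflict --
#' the branch is left out of the tree and reported as \code{unanchored}.
#' Reference branches with no observed SNP are retained as pass-through nodes
#' (provenance \code{"database"}) unless \code{keepUnobserved = FALSE}.
#' Inferred-only branches keep their inferred parent, mapped into the merged
#' tree; where the inferred nesting of two anchored branches disagrees with
#' the reference ordering, the reference wins and the conflict is recorded in
#' the result's metadata-style \code{conflicts} attribute with carrier
#' counts. With an empty reference the result is the inferred tree, all
#' branches novel.
#'
#' @param inferred a \linkS4class{BranchTree} from \code{\link{inferTree}}
#' @param ref reference tree from \code{\link{loadReferenceTree}} (or NULL /
#'   zero rows for none)
#' @param keepUnobserved keep reference branches unobserved in the matrix as
#'   pass-through nodes (default TRUE)
#' @return a \linkS4class{BranchTree}; novel branches have provenance
#'   \code{"inferred"} (see \code{\link{novelBranches}}); conflicts, if any,
#'   in \code{attr(tree, "conflicts")} (data.frame)
#' @export
anchorTree <- function(inferred, ref = NULL, keepUnobserved = TRUE) {
  ib <- branchTable(inferred)
  removed <- removedVariants(inferred)
  if (is.null(ref) || nrow(ref) == 0L) {
    out <- .newBranchTree(ib, removed)
    attr(out, "conflicts") <- data.frame()
    return(out)
  }

  ## match inferred branches to reference branches by shared SNP names
  refOf <- rep(NA_character_, nrow(ib))
  conflicts <- data.frame(branch = character(0), detail = character(0),
                          nCarriers = integer(0))
  unanchored <- integer(0)
  for (i in seq_len(nrow(ib))) {
    hits <- ref$branch[vapply(ref$snps, function(s)
      any(s %in% ib$snps[[i]]), TRUE)]
    if (!length(hits)) next
    if (length(hits) > 1L) {
      ## on one ancestor line -> deepest; otherwise conflict
      line <- all(vapply(hits, function(a) all(vapply(hits, function(b) {
        p <- b
        repeat {
          if (p == a) return(TRUE)
          p <- ref$parent[match(p, ref$branch)]
          if (is.na(p) || p == "ROOT") break
        }
        p <- a
        repeat {
          if (p == b) return(TRUE)
          p <- ref$parent[match(p, ref$branch)]
          if (is.na(p) || p == "ROOT") break
        }
        FALSE
      }, TRUE)), TRUE))
      if (!line) {
        unanchored <- c(unanchored, i)
        conflicts <- rbind(conflicts, data.frame(
          branch = ib$id[i],
          detail = sprintf("SNPs match unrelated reference branches %s",
                           paste(hits, collapse = "+")),
          nCarriers = ib$nCarriers[i]))
        next
      }
      hits <- hits[which.max(vapply(hits, .refDepth, 0L, ref = ref))]
    }
    refOf[i] <- hits
  }
  if (anyDuplicated(stats::na.omit(refOf))) {
    ## two inferred branches on one reference branch: keep the larger carrier
    ## set anchored, treat the other as inferred-only under it
    for (rb in unique(refOf[duplicated(refOf) & !is.na(refOf)])) {
      cand <- which(refOf == rb)
      keepI <- cand[order(-ib$nCarriers[cand])][1L]
      refOf[setdiff(cand, keepI)] <- NA_character_
    }
  }

  keepRows <- setdiff(seq_len(nrow(ib)), unanchored)
  anchored <- !is.na(refOf)

  ## merged node set: reference branches + inferred-only branches
  usedRef <- stats::na.omit(unique(refOf))
  refRows <- if (keepUnobserved) seq_len(nrow(ref))
             else which(ref$branch %in% usedRef |
                        vapply(ref$branch, function(b) {
                          ## ancestors of used branches stay as scaffolding
                          any(vapply(usedRef, function(u) {
                            p <- u
                            while (p != "ROOT") {
                              if (p == b) return(TRUE)
                              p <- ref$parent[match(p, ref$branch)]
                            }
                            FALSE
                          }, TRUE))
                        }, TRUE))

  nodes <- list()
  for (r in refRows) {
    rb <- ref$branch[r]
    i <- match(rb, refOf)
    obs <- !is.na(i) && i %in% keepRows && ib$nCarriers[i] > 0L
    nodes[[rb]] <- data.frame(
      id = rb, parent = ref$parent[r], name = rb,
      provenance = if (obs) "both" else "database",
      nCarriers = if (obs) ib$nCarriers[i] else 0L,
      flag = if (obs) ib$flag[i] else "",
      snps = I(list(if (obs) sort(unique(c(ib$snps[[i]], ref$snps[[r]])))
                    else ref$snps[[r]])),
      carriers = I(list(if (obs) ib$carriers[[i]] else character(0))),
      stringsAsFactors = FALSE)
  }
  ## map an inferred branch id to its merged node id
  mapId <- function(i) if (!is.na(refOf[i])) refOf[i] else ib$id[i]
  for (i in keepRows) {
    if (anchored[i]) next
    ## parent: image of nearest retained inferred ancestor, else ROOT
    p <- ib$parent[i]
    while (p != "ROOT") {
      pi <- match(p, ib$id)
      if (pi %in% keepRows) break
      p <- ib$parent[pi]
    }
    parent <- if (p == "ROOT") "ROOT" else mapId(match(p, ib$id))
    nodes[[ib$id[i]]] <- data.frame(
      id = ib$id[i], parent = parent, name = ib$name[i],
      provenance = "inferred", nCarriers = ib$nCarriers[i],
      flag = ib$flag[i], snps = I(ib$snps[i]), carriers = I(ib$carriers[i]),
      stringsAsFactors = FALSE)
  }

  ## reference ordering wins for anchored branches: log disagreements
  for (i in which(anchored)) {
    p <- ib$parent[i]
    if (p == "ROOT") next
    pi <- match(p, ib$id)
    if (is.na(pi) || !anchored[pi]) next
    refParentLine <- character(0)
    b <- refOf[i]
    while (b != "ROOT") {
      b <- ref$parent[match(b, ref$branch)]
      refParentLine <- c(refParentLine, b)
    }
    if (!(refOf[pi] %in% refParentLine))
      conflicts <- rbind(conflicts, data.frame(
        branch = refOf[i],
        detail = sprintf(
          "inferred nesting under %s contradicts reference (parent %s kept)",
          refOf[pi], ref$parent[match(refOf[i], ref$branch)]),
        nCarriers = ib$nCarriers[i]))
  }

  branches <- do.call(rbind, nodes)
  rownames(branches) <- NULL

  ## keep the finer inferred nesting where it refines the reference: a
  ## reference tree often skips levels, and novel branches insert between a
  ## reference branch and its reference parent; only a true disagreement
  ## (inferred parent off the reference parent line) falls back to the
  ## reference ordering (logged above)
  isAncestor <- function(anc, id) {
    if (anc == "ROOT") return(TRUE)
    while (id != "ROOT") {
      id <- branches$parent[match(id, branches$id)]
      if (identical(id, anc)) return(TRUE)
    }
    FALSE
  }
  for (i in which(anchored)) {
    if (!(i %in% keepRows)) next
    nodeId <- refOf[i]
    p <- ib$parent[i]
    while (p != "ROOT") {
      pi <- match(p, ib$id)
      if (pi %in% keepRows) break
      p <- ib$parent[pi]
    }
    if (p == "ROOT") next
    infP <- mapId(match(p, ib$id))
    refP <- branches$parent[match(nodeId, branches$id)]
    if (identical(infP, refP)) next
    if (isAncestor(refP, infP) && !isAncestor(nodeId, infP))
      branches$parent[match(nodeId, branches$id)] <- infP
  }
  if (length(unanchored))
    removed <- rbind(removed, data.frame(
      site = unlist(ib$snps[unanchored]), reason = "unanchored",
      detail = "anchoring conflict: matches unrelated reference branches"))
  out <- .newBranchTree(branches, removed)
  attr(out, "conflicts") <- conflicts
  out
}

## next lineage ordinal: labels alternate digits and letters along the path
.nextOrdinal <- function(parentLabel, taken) {
  lastChar <- substr(parentLabel, nchar(parentLabel), nchar(parentLabel))
  useDigit <- !grepl("[0-9]", lastChar)    # letter (or root prefix) -> digit
  if (useDigit) {
    nums <- suppressWarnings(as.integer(taken[grepl("^[0-9]+$", taken)]))
    as.character(if (length(nums)) max(nums) + 1L else 1L)
  } else {
    lets <- taken[grepl("^[a-z]+$", taken)]
    n <- if (length(lets))
      max(vapply(lets, function(x) match(x, letters), 0L), na.rm = TRUE) + 1L
    else 1L
    if (n <= 26L) letters[n] else paste0("a", letters[n - 26L])
  }
}

#' Assign lineage-based names to novel branches
#'
#' Each novel (provenance \code{"inferred"}) branch receives its parent's
#' lineage label extended by the next free child ordinal, alternating digits
#' and letters along the path in the Y Chromosome Consortium style
#' (Q, Q1, Q1b, Q1b1, ...), suffixed with the hyphenated name of its
#' alphabetically first defining SNP (e.g. \code{Q1b1a1a1-ZK7}). Ordinals
#' continue after any ordinals already taken by named siblings; siblings are
#' processed in the tree's deterministic sibling order, so names are unique
#' and reproducible. Root-level novel branches are prefixed with
#' \code{rootLabel}.
#'
#' @param tree a \linkS4class{BranchTree} from \code{\link{anchorTree}}
#' @param rootLabel haplogroup letter used as the lineage label of the
#'   implicit root (default \code{"Q"})
#' @return the tree with \code{name} filled for every branch
#' @export
nameBranches <- function(tree, rootLabel = "Q") {
  b <- branchTable(tree)
  if (!nrow(b)) return(tree)
  lineageOf <- function(name) sub("-.*$", "", name)
  ## process in path order so parents are always named first
  depths <- branchDepths(tree)
  for (i in order(depths[b$id])) {
    if (!is.na(b$name[i]) && nzchar(b$name[i])) next
    p <- b$parent[i]
    parentLabel <- if (p == "ROOT") rootLabel
                   else lineageOf(b$name[match(p, b$id)])
    sibs <- which(b$parent == b$parent[i])
    sibNames <- stats::na.omit(b$name[sibs])
    taken <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                  parentLabel)),
                 "", lineageOf(sibNames))
    taken <- taken[nzchar(taken)]
    ord <- .nextOrdinal(parentLabel, taken)
    snp <- sort(b$snps[[i]])[1L]
    b$name[i] <- paste0(parentLabel, ord, "-", snp)
  }
  out <- .newBranchTree(b, removedVariants(tree))
  attr(out, "conflicts") <- attr(tree, "conflicts")
  out
}
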