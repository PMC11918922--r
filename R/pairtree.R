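## Pairwise phylogenetic classification of binary variants under missing
## data, contradiction/ambiguity filtering, and assembly of the surviving
## variants into a rooted branch hierarchy. Everything here is deterministic
## in the input matrix.

.REL <- c("equivalent", "i_above_j", "j_above_i", "disjoint",
          "contradictory", "uninformative")

## vectorized relation rule from the four joint counts
.relationFromCounts <- function(n11, n10, n01, n00, minInformative) {
  rel <- rep("uninformative", length(n11))
  ok <- (n11 + n10 + n01 + n00) >= minInformative
  rel[ok & n11 > 0 & n10 == 0 & n01 == 0] <- "equivalent"
  rel[ok & n11 > 0 & n10 > 0 & n01 == 0] <- "i_above_j"
  rel[ok & n11 > 0 & n10 == 0 & n01 > 0] <- "j_above_i"
  rel[ok & n11 == 0 & n10 > 0 & n01 > 0] <- "disjoint"
  rel[ok & n11 > 0 & n10 > 0 & n01 > 0] <- "contradictory"
  rel
}

## joint-count matrices for a character state matrix (rows = sites)
.pairCounts <- function(m) {
  D <- (m == "D"); D[is.na(D)] <- FALSE; storage.mode(D) <- "numeric"
  A <- (m == "A"); A[is.na(A)] <- FALSE; storage.mode(A) <- "numeric"
  list(n11 = tcrossprod(D), n10 = tcrossprod(D, A),
       n01 = tcrossprod(A, D), n00 = tcrossprod(A))
}

#' Classify the phylogenetic relationship of all site pairs
#'
#' For every unordered pair of sites, counts samples called at both sites in
#' the four joint states (\code{n11}: derived/derived, \code{n10}:
#' derived/ancestral, \code{n01}, \code{n00}) and assigns a relation:
#' \code{equivalent} (co-occurring carriers only), \code{i_above_j} /
#' \code{j_above_i} (nested carrier sets), \code{disjoint},
#' \code{contradictory} (all three of n11, n10, n01 positive -- impossible on
#' a tree where each site mutated once), or \code{uninformative} (fewer than
#' \code{minInformative} jointly called samples, or no pattern above, e.g. no
#' derived observation in the overlap).
#'
#' @param x a \linkS4class{YCallMatrix} or character state matrix (sites x
#'   samples, values "A"/"D"/NA)
#' @param minInformative minimum number of jointly called samples for a pair
#'   to be classifiable (default 2)
#' @return data.frame with columns \code{i}, \code{j} (site indices, i < j),
#'   \code{site_i}, \code{site_j}, \code{n11}, \code{n10}, \code{n01},
#'   \code{n00}, \code{relation}
#' @export
classifyPairs <- function(x, minInformative = 2L) {
  m <- if (is(x, "YCallMatrix")) calls(x) else x
  if (nrow(m) < 2L)
    return(data.frame(i = integer(0), j = integer(0), site_i = character(0),
                      site_j = character(0), n11 = integer(0),
                      n10 = integer(0), n01 = integer(0), n00 = integer(0),
                      relation = character(0)))
  cnt <- .pairCounts(m)
  ut <- which(upper.tri(cnt$n11), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  n11 <- cnt$n11[ut]; n10 <- cnt$n10[ut]
  n01 <- cnt$n01[ut]; n00 <- cnt$n00[ut]
  nm <- rownames(m)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(m)))
  data.frame(i = i, j = j, site_i = nm[i], site_j = nm[j],
             n11 = as.integer(n11), n10 = as.integer(n10),
             n01 = as.integer(n01), n00 = as.integer(n00),
             relation = .relationFromCounts(n11, n10, n01, n00,
                                            minInformative),
             stringsAsFactors = FALSE)
}

#' Classify one site pair
#'
#' Single-pair form of \code{\link{classifyPairs}}; symmetric under swapping
#' \code{i} and \code{j} (counts transpose, \code{i_above_j} and
#' \code{j_above_i} exchange).
#'
#' @param x a \linkS4class{YCallMatrix} or state matrix
#' @param i,j site indices or row names (i != j)
#' @param minInformative see \code{\link{classifyPairs}}
#' @return one-row data.frame as in \code{\link{classifyPairs}} (with i, j in
#'   the order given)
#' @export
classifyPair <- function(x, i, j, minInformative = 2L) {
  m <- if (is(x, "YCallMatrix")) calls(x) else x
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, rownames(m))
  stopifnot(i != j)
  ci <- m[i, ]; cj <- m[j, ]
  both <- !is.na(ci) & !is.na(cj)
  n11 <- sum(ci[both] == "D" & cj[both] == "D")
  n10 <- sum(ci[both] == "D" & cj[both] == "A")
  n01 <- sum(ci[both] == "A" & cj[both] == "D")
  n00 <- sum(ci[both] == "A" & cj[both] == "A")
  nm <- rownames(m)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(m)))
  data.frame(i = i, j = j, site_i = nm[i], site_j = nm[j],
             n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             relation = .relationFromCounts(n11, n10, n01, n00,
                                            minInformative),
             stringsAsFactors = FALSE)
}

#' Remove variants with contradictory pairwise relationships
#'
#' Greedy iterative removal: while contradictory pairs remain, remove the
#' site participating in the largest number of contradictory relations (ties
#' broken by ascending site position, i.e. matrix row order), and drop all
#' its pairs. Removed sites are reported with the contradiction count they
#' had at removal.
#'
#' @param relations pair table from \code{\link{classifyPairs}}
#' @param nSites number of sites in the matrix the relations came from
#' @return list with \code{kept} (integer site indices) and \code{removed}
#'   (data.frame: \code{site} index, \code{site_name}, \code{nContradictions})
#' @export
filterContradictory <- function(relations, nSites) {
  removed <- data.frame(site = integer(0), site_name = character(0),
                        nContradictions = integer(0))
  active <- rep(TRUE, nSites)
  contra <- relations[relations$relation == "contradictory", , drop = FALSE]
  nameOf <- function(s) {
    k <- match(s, relations$i)
    if (!is.na(k)) return(relations$site_i[k])
    k <- match(s, relations$j)
    if (!is.na(k)) relations$site_j[k] else as.character(s)
  }
  while (nrow(contra)) {
    cnt <- table(factor(c(contra$i, contra$j), levels = seq_len(nSites)))
    worst <- which.max(cnt)             # which.max: first (lowest index) tie
    active[worst] <- FALSE
    removed <- rbind(removed,
                     data.frame(site = as.integer(worst),
                                site_name = nameOf(worst),
                                nContradictions = as.integer(max(cnt))))
    contra <- contra[contra$i != worst & contra$j != worst, , drop = FALSE]
  }
  list(kept = which(active), removed = removed)
}

#' Group equivalent variants into branch-defining clusters
#'
#' Transitive closure over pairwise \code{equivalent} relations among the
#' kept sites (union-find). A cluster whose members disagree about any third
#' kept site -- one member nested or equivalent, another disjoint, relative
#' to that site (uninformative members ignored) -- admits no single placement
#' and is flagged ambiguous and removed.
#'
#' @param kept integer site indices surviving contradiction filtering
#' @param relations pair table from \code{\link{classifyPairs}}
#' @return list with \code{clusters} (list of integer site-index vectors) and
#'   \code{ambiguous} (data.frame: \code{site}, \code{site_name},
#'   \code{detail})
#' @export
groupEquivalent <- function(kept, relations) {
  parent <- stats::setNames(kept, kept)
  find <- function(a) {
    while (parent[[as.character(a)]] != a) a <- parent[[as.character(a)]]
    a
  }
  rel <- relations[relations$i %in% kept & relations$j %in% kept, ,
                   drop = FALSE]
  eq <- rel[rel$relation == "equivalent", , drop = FALSE]
  for (k in seq_len(nrow(eq))) {
    ra <- find(eq$i[k]); rb <- find(eq$j[k])
    if (ra != rb) parent[[as.character(max(ra, rb))]] <- min(ra, rb)
  }
  roots <- vapply(kept, find, 0)
  clusters <- split(kept, roots)
  names(clusters) <- NULL

  ## directed relation of each member to third sites, as seen from the member
  lookup <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(rel))) {
    r <- rel$relation[k]
    if (r %in% c("uninformative", "contradictory")) next
    assign(paste(rel$i[k], rel$j[k]), r, envir = lookup)
    swap <- c(equivalent = "equivalent", i_above_j = "j_above_i",
              j_above_i = "i_above_j", disjoint = "disjoint")[[r]]
    assign(paste(rel$j[k], rel$i[k]), swap, envir = lookup)
  }
  ambiguous <- data.frame(site = integer(0), site_name = character(0),
                          detail = character(0))
  ok <- rep(TRUE, length(clusters))
  siteName <- function(s) {
    k <- match(s, relations$i)
    if (!is.na(k)) return(relations$site_i[k])
    k <- match(s, relations$j)
    if (!is.na(k)) relations$site_j[k] else as.character(s)
  }
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    if (length(cl) < 2L) next
    others <- setdiff(kept, cl)
    for (third in others) {
      views <- unique(unlist(lapply(cl, function(s) {
        key <- paste(s, third)
        if (exists(key, envir = lookup)) get(key, envir = lookup) else NULL
      })))
      if (length(views) > 1L) {
        ok[ci] <- FALSE
        ambiguous <- rbind(ambiguous, data.frame(
          site = cl, site_name = vapply(cl, siteName, ""),
          detail = sprintf("inconsistent relations to site %s (%s)",
                           siteName(third), paste(views, collapse = "/"))))
        break
      }
    }
  }
  list(clusters = clusters[ok], ambiguous = ambiguous)
}

## pooled cluster profile: derived if any member derived, ancestral if any
## member ancestral (equivalence guarantees no sample is both), else missing
.clusterProfiles <- function(m, clusters) {
  t(vapply(clusters, function(cl) {
    sub <- m[cl, , drop = FALSE]
    anyD <- colSums(sub == "D", na.rm = TRUE) > 0L
    anyA <- colSums(sub == "A", na.rm = TRUE) > 0L
    ifelse(anyD, "D", ifelse(anyA, "A", NA_character_))
  }, character(ncol(m))))
}

#' Assemble filtered clusters into a rooted branch hierarchy
#'
#' Clusters are pooled into carrier profiles and classified pairwise with the
#' same relation rule. The above/below relations form a DAG whose transitive
#' reduction yields each cluster's parent: the unique immediate dominator
#' among its ancestors. Clusters whose ancestors are not totally ordered
#' (no unique immediate dominator -- the placement is ambiguous) are dropped
#' and reported. Clusters with no ancestors become children of the implicit
#' root. Single-carrier clusters uninformative against every placed cluster
#' are attached as leaves under the deepest placed cluster carrying their
#' sample and flagged \code{tip-placed}. Siblings are ordered by descending
#' carrier count, then ascending minimum site position; branch ids are
#' assigned in preorder.
#'
#' @param clusters list of integer site-index vectors from
#'   \code{\link{groupEquivalent}}
#' @param x the \linkS4class{YCallMatrix} (or state matrix) the clusters
#'   index into
#' @param minInformative as in \code{\link{classifyPairs}}
#' @param removed optional data.frame of already-removed variants to carry
#'   into the result's removal report
#' @return a \linkS4class{BranchTree} with provenance \code{"inferred"}
#' @export
buildHierarchy <- function(clusters, x, minInformative = 2L, removed = NULL) {
  m <- if (is(x, "YCallMatrix")) calls(x) else x
  positions <- if (is(x, "YCallMatrix")) siteInfo(x)$position
               else seq_len(nrow(m))
  nm <- rownames(m)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(m)))
  report <- if (is.null(removed))
    data.frame(site = character(0), reason = character(0),
               detail = character(0)) else removed

  if (!length(clusters)) return(.newBranchTree(NULL, report))

  repeat {
    prof <- .clusterProfiles(m, clusters)
    rownames(prof) <- as.character(seq_along(clusters))
    rel <- classifyPairs(prof, minInformative)
    ## pooled coverage can reveal equivalence between clusters: merge and redo
    eq <- rel[rel$relation == "equivalent", , drop = FALSE]
    if (!nrow(eq)) break
    tgt <- seq_along(clusters)
    for (k in seq_len(nrow(eq))) {
      a <- min(tgt[eq$i[k]], tgt[eq$j[k]])
      tgt[c(eq$i[k], eq$j[k])] <- a
    }
    clusters <- lapply(split(seq_along(clusters), tgt),
                       function(g) sort(unlist(clusters[g])))
    names(clusters) <- NULL
    if (nrow(eq) == 0L) break
  }

  ## cluster-level contradictions should not survive site-level filtering;
  ## drop the smaller-carrier cluster defensively and report it
  contra <- rel[rel$relation == "contradictory", , drop = FALSE]
  if (nrow(contra)) {
    nc <- rowSums(prof == "D", na.rm = TRUE)
    dropIdx <- unique(vapply(seq_len(nrow(contra)), function(k) {
      a <- contra$i[k]; b <- contra$j[k]
      if (nc[a] < nc[b]) a else b
    }, 0L))
    for (d in dropIdx)
      report <- rbind(report, data.frame(
        site = nm[clusters[[d]]], reason = "contradictory",
        detail = "cluster-level contradiction"))
    clusters <- clusters[-dropIdx]
    prof <- .clusterProfiles(m, clusters)
    rownames(prof) <- as.character(seq_along(clusters))
    rel <- classifyPairs(prof, minInformative)
  }

  nC <- length(clusters)
  if (!nC) return(.newBranchTree(NULL, report))
  above <- matrix(FALSE, nC, nC)        # above[a, b]: a is ancestor of b
  for (k in seq_len(nrow(rel))) {
    if (rel$relation[k] == "i_above_j") above[rel$i[k], rel$j[k]] <- TRUE
    if (rel$relation[k] == "j_above_i") above[rel$j[k], rel$i[k]] <- TRUE
  }
  nCar <- rowSums(prof == "D", na.rm = TRUE)
  minPos <- vapply(clusters, function(cl) min(positions[cl]), 0)

  parentOf <- rep(NA_integer_, nC)      # NA = root child, -1 = dropped
  for (b in seq_len(nC)) {
    anc <- which(above[, b])
    if (!length(anc)) next
    imm <- anc[vapply(anc, function(a)
      all(above[setdiff(anc, a), a]), TRUE)]
    if (length(imm) == 1L) parentOf[b] <- imm
    else {
      parentOf[b] <- -1L
      report <- rbind(report, data.frame(
        site = nm[clusters[[b]]], reason = "ambiguous",
        detail = "no unique immediate ancestor"))
    }
  }

  ## tip placement: singleton carriers uninformative against every kept
  ## cluster get attached under the deepest placed cluster carrying their
  ## sample instead of floating at the root
  placed <- which(parentOf != -1L | is.na(parentOf))
  placed <- setdiff(seq_len(nC), which(parentOf == -1L))
  depth <- function(b) {
    d <- 0L
    while (!is.na(b <- parentOf[b])) { if (b == -1L) return(NA_integer_); d <- d + 1L }
    d
  }
  tipFlag <- rep("", nC)
  for (b in placed) {
    if (nCar[b] != 1L || !is.na(parentOf[b])) next
    others <- setdiff(placed, b)
    if (!length(others)) next
    rels <- vapply(others, function(o) {
      k <- which((rel$i == b & rel$j == o) | (rel$i == o & rel$j == b))
      rel$relation[k]
    }, "")
    if (!all(rels == "uninformative")) next
    carrier <- which(prof[b, ] == "D")
    host <- others[vapply(others, function(o)
      !is.na(prof[o, carrier]) && prof[o, carrier] == "D", TRUE)]
    if (!length(host)) next
    hd <- vapply(host, depth, 0L)
    best <- host[order(-hd, -nCar[host], minPos[host])][1L]
    parentOf[b] <- best
    tipFlag[b] <- "tip-placed"
  }

  keep <- setdiff(seq_len(nC), which(parentOf == -1L))
  ## preorder with sibling ordering: descending carriers, ascending position
  childOf <- function(p) {
    ch <- keep[!is.na(parentOf[keep]) & parentOf[keep] == p]
    ch[order(-nCar[ch], minPos[ch])]
  }
  rootKids <- keep[is.na(parentOf[keep])]
  rootKids <- rootKids[order(-nCar[rootKids], minPos[rootKids])]
  ord <- integer(0)
  walk <- function(b) {
    ord <<- c(ord, b)
    for (ch in childOf(b)) walk(ch)
  }
  for (b in rootKids) walk(b)

  ids <- stats::setNames(sprintf("B%03d", seq_along(ord)), ord)
  branches <- data.frame(
    id = unname(ids[as.character(ord)]),
    parent = vapply(ord, function(b) {
      p <- parentOf[b]
      if (is.na(p)) "ROOT" else unname(ids[[as.character(p)]])
    }, ""),
    name = NA_character_,
    provenance = "inferred",
    nCarriers = as.integer(nCar[ord]),
    flag = tipFlag[ord],
    snps = I(lapply(ord, function(b) sort(nm[clusters[[b]]]))),
    carriers = I(lapply(ord, function(b)
      colnames(m)[which(prof[b, ] == "D")])),
    stringsAsFactors = FALSE)
  .newBranchTree(branches, report)
}

#' Infer a branch hierarchy from a call matrix
#'
#' Convenience pipeline: \code{\link{classifyPairs}} ->
#' \code{\link{filterContradictory}} -> \code{\link{groupEquivalent}} ->
#' \code{\link{buildHierarchy}}, accumulating every removed variant into the
#' tree's removal report.
#'
#' @param x a \linkS4class{YCallMatrix}
#' @param minInformative see \code{\link{classifyPairs}}
#' @return a \linkS4class{BranchTree}
#' @export
inferTree <- function(x, minInformative = 2L) {
  m <- calls(x)
  nm <- rownames(m)
  rel <- classifyPairs(x, minInformative)
  fc <- filterContradictory(rel, nrow(m))
  ge <- groupEquivalent(fc$kept, rel)
  removed <- rbind(
    if (nrow(fc$removed)) data.frame(
      site = fc$removed$site_name, reason = "contradictory",
      detail = sprintf("%d contradictory pairs", fc$removed$nContradictions))
    else NULL,
    if (nrow(ge$ambiguous)) data.frame(
      site = ge$ambiguous$site_name, reason = "ambiguous",
      detail = ge$ambiguous$detail)
    else NULL)
  if (is.null(removed))
    removed <- data.frame(site = character(0), reason = character(0),
                          detail = character(0))
  buildHierarchy(ge$clusters, x, minInformative, removed)
}

#' Audit a tree's parent/child links against the pairwise evidence
#'
#' Recomputes the pooled-profile relation for every ancestor/descendant
#' branch pair and reports links whose pairwise count pattern contradicts the
#' asserted nesting (descendant not nested under ancestor: relation
#' \code{contradictory}, \code{disjoint}, or nesting in the wrong direction).
#'
#' @param tree a \linkS4class{BranchTree}
#' @param x the \linkS4class{YCallMatrix} the tree was built from
#' @param minInformative as in \code{\link{classifyPairs}}
#' @return data.frame of violations (empty when the tree is consistent)
#' @export
auditTree <- function(tree, x, minInformative = 2L) {
  m <- if (is(x, "YCallMatrix")) calls(x) else x
  b <- branchTable(tree)
  viol <- data.frame(ancestor = character(0), descendant = character(0),
                     relation = character(0))
  if (!nrow(b)) return(viol)
  idx <- lapply(b$snps, function(s) match(s, rownames(m)))
  prof <- .clusterProfiles(m, lapply(idx, function(i) i[!is.na(i)]))
  for (d in seq_len(nrow(b))) {
    path <- setdiff(.pathToRoot(b, b$id[d]), b$id[d])
    for (a in match(path, b$id)) {
      pr <- classifyPairs(prof[c(a, d), , drop = FALSE], minInformative)
      if (pr$relation %in% c("contradictory", "disjoint", "j_above_i"))
        viol <- rbind(viol, data.frame(ancestor = b$id[a],
                                       descendant = b$id[d],
                                       relation = pr$relation))
    }
  }
  viol
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write a branch tree as parent-child TSV (and optionally newick and a
#' removed-variants report)
#'
#' @param tree a \linkS4class{BranchTree}
#' @param path TSV output: branch, parent, name, provenance, nCarriers, flag,
#'   snps (comma-separated)
#' @param newickPath optional newick output (branch ids as labels)
#' @param removedPath optional removed-variants report TSV
#' @export
writeBranchTree <- function(tree, path, newickPath = NULL,
                            removedPath = NULL) {
  b <- branchTable(tree)
  df <- data.frame(branch = b$id, parent = b$parent, name = b$name,
                   provenance = b$provenance, nCarriers = b$nCarriers,
                   flag = b$flag,
                   snps = vapply(b$snps, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(newickPath))
    writeLines(.branchNewick(b), newickPath)
  if (!is.null(removedPath))
    utils::write.table(removedVariants(tree), removedPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a branch tree written by \code{\link{writeBranchTree}}
#' @param path TSV file
#' @return a \linkS4class{BranchTree}
#' @export
readBranchTree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  branches <- data.frame(
    id = df$branch, parent = df$parent, name = df$name,
    provenance = df$provenance, nCarriers = df$nCarriers,
    flag = ifelse(is.na(df$flag), "", df$flag),
    snps = I(lapply(strsplit(df$snps, ",", fixed = TRUE), sort)),
    carriers = I(rep(list(character(0)), nrow(df))),
    stringsAsFactors = FALSE)
  .newBranchTree(branches)
}
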