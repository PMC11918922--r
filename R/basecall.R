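## Haploid threshold-based variant calling: discovery of variable positions,
## tiered annotation, and the strictly filtered ancestral/derived/missing
## call matrix that all downstream tree building consumes.

#' Base-calling thresholds
#'
#' Strict defaults: a base is called only from reads of quality >= 25, with at
#' least five such reads, of which at least 95\% must agree. Discovery mode
#' (\code{discoveryThresholds()}) relaxes depth to one read and drops the
#' majority requirement to just above one half so that any modal base with a
#' single qualifying read can be reported.
#'
#' All boundaries are inclusive: quality >= \code{minQuality}, surviving depth
#' >= \code{minDepth}, modal-base fraction >= \code{baseMajority}.
#'
#' @param minDepth minimum number of quality-surviving reads (>= 1)
#' @param minQuality minimum per-read phred quality
#' @param baseMajority minimum fraction of surviving reads agreeing on the
#'   modal base; must exceed 0.5
#' @return a validated list of class \code{ylineage_thresholds}
#' @export
callThresholds <- function(minDepth = 5L, minQuality = 25L,
                           baseMajority = 0.95) {
  if (minDepth < 1L) .stopf("minDepth must be >= 1")
  if (baseMajority <= 0.5 || baseMajority > 1)
    .stopf("baseMajority must lie in (0.5, 1]")
  structure(list(minDepth = as.integer(minDepth),
                 minQuality = as.integer(minQuality),
                 baseMajority = baseMajority),
            class = "ylineage_thresholds")
}

#' @rdname callThresholds
#' @export
discoveryThresholds <- function() callThresholds(1L, 25L, 0.5 + 1e-9)

#' Call a haploid base from one pileup column
#'
#' Discards observations below the quality floor; if fewer than
#' \code{minDepth} reads survive, the call is missing. Otherwise the modal
#' base is returned when its frequency among surviving reads is at least
#' \code{baseMajority}, else missing. Modal ties cannot reach a majority
#' above 0.5, so tied columns are always missing.
#'
#' @param bases character vector of observed bases (or a single string, one
#'   character per read)
#' @param quals integer vector of phred qualities (or comma-separated string)
#' @param t thresholds from \code{\link{callThresholds}}
#' @return the called base, or \code{NA_character_} when missing
#' @export
callBase <- function(bases, quals, t = callThresholds()) {
  if (length(bases) == 1L && (is.na(bases) || nchar(bases) != 1L))
    bases <- .splitBases(bases)
  if (is.character(quals) && length(quals) == 1L) quals <- .splitInts(quals)
  if (length(bases) != length(quals))
    .stopf("bases and quals must have equal length")
  keep <- quals >= t$minQuality
  bases <- bases[keep]
  if (length(bases) < t$minDepth) return(NA_character_)
  tab <- table(bases)
  f <- max(tab) / length(bases)
  if (f >= t$baseMajority && sum(tab == max(tab)) == 1L)
    names(tab)[which.max(tab)]
  else NA_character_
}

#' Discover variable positions from pileup evidence
#'
#' A site is discovered when at least one sample has at least one read of
#' quality >= \code{minQuality} supporting a non-reference allele. The
#' alternate allele recorded is the most frequent qualifying non-reference
#' base across the cohort (ties by base order). Variant class is \code{"SNP"}
#' for single-base ref/alt; a site catalog (e.g. from the simulator or a VCF)
#' may be supplied to carry multi-base InDel-class alleles through.
#'
#' @param pileups pileup data.frame (\code{sample}, \code{position},
#'   \code{bases}, \code{quals})
#' @param refAlleles named character vector: position -> reference base
#' @param minQuality per-read quality floor (discovery mode: depth of one)
#' @param catalog optional site catalog data.frame with \code{position},
#'   \code{altAllele}, \code{class} overriding the single-base inference
#' @return data.frame of discovered sites: \code{position}, \code{refAllele},
#'   \code{altAllele}, \code{proxyBase}, \code{class}, \code{ancestralAllele}
#' @export
discoverVariants <- function(pileups, refAlleles, minQuality = 25L,
                             catalog = NULL) {
  posKey <- as.character(pileups$position)
  if (any(!posKey %in% names(refAlleles)))
    .stopf("position %s has no reference allele",
           posKey[!posKey %in% names(refAlleles)][1L])
  hits <- list()
  for (i in seq_len(nrow(pileups))) {
    b <- .splitBases(pileups$bases[i])
    q <- .splitInts(pileups$quals[i])
    b <- b[q >= minQuality]
    ref <- refAlleles[[posKey[i]]]
    nonref <- b[b != ref]
    if (length(nonref))
      hits[[length(hits) + 1L]] <-
        data.frame(position = pileups$position[i], base = nonref)
  }
  if (!length(hits))
    return(data.frame(position = integer(0), refAllele = character(0),
                      altAllele = character(0), proxyBase = character(0),
                      class = character(0), ancestralAllele = character(0)))
  ev <- do.call(rbind, hits)
  alt <- vapply(split(ev$base, ev$position), function(b) {
    tab <- sort(table(b), decreasing = TRUE)
    names(tab)[1L]
  }, "")
  pos <- as.integer(names(alt))
  o <- order(pos)
  sites <- data.frame(position = pos[o],
                      refAllele = unname(refAlleles[as.character(pos[o])]),
                      altAllele = unname(alt[o]),
                      proxyBase = unname(alt[o]),
                      class = "SNP",
                      stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    m <- match(sites$position, catalog$position)
    hit <- !is.na(m)
    sites$altAllele[hit] <- catalog$altAllele[m[hit]]
    sites$class[hit] <- catalog$class[m[hit]]
    if (!is.null(catalog$proxyBase))
      sites$proxyBase[hit] <- catalog$proxyBase[m[hit]]
  }
  sites$ancestralAllele <- sites$refAllele
  sites
}

#' Annotate variant sites with tiered names
#'
#' Each site takes the name from the highest-priority tier covering its
#' position, in the fixed order \code{database_tree > publication > rs_id >
#' gnomad}; unmatched sites get sequential novel identifiers
#' (\code{prefix1, prefix2, ...}) in ascending position order. Within one
#' tier, the first-listed source wins and any disagreement is flagged with a
#' warning. gnomAD-tier sites without an explicit name are labelled
#' \code{"<position>-gnomAD"}. Re-annotating an annotated site table with the
#' same sources is a no-op.
#'
#' @param sites site data.frame (needs \code{position})
#' @param annotations data.frame with columns \code{position}, \code{name},
#'   \code{tier} (and optionally \code{source}); may be NULL
#' @param novelPrefix prefix for novel identifiers
#' @return \code{sites} with \code{name} and \code{tier} columns filled
#' @export
annotateVariants <- function(sites, annotations = NULL, novelPrefix = "ZK") {
  tiers <- c("database_tree", "publication", "rs_id", "gnomad")
  sites$name <- NA_character_
  sites$tier <- NA_character_
  if (!is.null(annotations) && nrow(annotations)) {
    if (!all(annotations$tier %in% tiers))
      .stopf("unknown annotation tier '%s'",
             setdiff(annotations$tier, tiers)[1L])
    if (is.null(annotations$name)) annotations$name <- NA_character_
    gn <- annotations$tier == "gnomad" & (is.na(annotations$name) |
                                          !nzchar(annotations$name))
    annotations$name[gn] <- paste0(annotations$position[gn], "-gnomAD")
    for (tier in tiers) {
      tab <- annotations[annotations$tier == tier, , drop = FALSE]
      if (!nrow(tab)) next
      dup <- duplicated(tab$position)
      if (any(dup)) {
        conf <- tab$position[dup][tab$name[dup] !=
          tab$name[match(tab$position[dup], tab$position)]]
        if (length(conf))
          warning(sprintf(
            "annotation conflict in tier %s at position(s) %s; first source kept",
            tier, paste(unique(conf), collapse = ", ")), call. = FALSE)
        tab <- tab[!dup, , drop = FALSE]
      }
      open <- is.na(sites$name)
      m <- match(sites$position[open], tab$position)
      hit <- which(open)[!is.na(m)]
      sites$name[hit] <- tab$name[m[!is.na(m)]]
      sites$tier[hit] <- tier
    }
  }
  novel <- which(is.na(sites$name))
  if (length(novel)) {
    novel <- novel[order(sites$position[novel])]
    sites$name[novel] <- paste0(novelPrefix, seq_along(novel))
    sites$tier[novel] <- "novel"
  }
  sites
}

#' Build the strictly filtered call matrix
#'
#' Applies \code{\link{callBase}} to every sample x site pileup column, maps
#' the called base to ancestral/derived via the site's ancestral allele
#' (default: the reference allele; the derived state is the site's proxy
#' base), and drops sites derived in zero samples, so every retained site is
#' polymorphic within the cohort. A called base matching neither configured
#' allele is treated as missing for that cell and counted in the returned
#' object's metadata (\code{offAlleleCells}).
#'
#' @param pileups pileup data.frame
#' @param sites site table (from \code{\link{discoverVariants}},
#'   \code{\link{readPositionFile}} or a simulator catalog); needs
#'   \code{position}, \code{ancestralAllele} (or \code{refAllele}) and
#'   \code{proxyBase} (or \code{derivedAllele}); a \code{name} column is used
#'   for row names when present
#' @param samples sample identifiers defining columns; defaults to the
#'   samples seen in \code{pileups}
#' @param t thresholds from \code{\link{callThresholds}}
#' @param dropMonomorphic drop sites with no derived carrier (default TRUE)
#' @return a \linkS4class{YCallMatrix}
#' @export
buildCallMatrix <- function(pileups, sites, samples = NULL,
                            t = callThresholds(), dropMonomorphic = TRUE) {
  if (is.null(samples)) samples <- sort(unique(pileups$sample))
  if (is.null(sites$ancestralAllele)) sites$ancestralAllele <- sites$refAllele
  if (is.null(sites$proxyBase))
    sites$proxyBase <- .proxyBase(sites$ancestralAllele, sites$derivedAllele)
  if (is.null(sites$derivedAllele))
    sites$derivedAllele <- if (!is.null(sites$altAllele)) sites$altAllele
                           else sites$proxyBase
  if (is.null(sites$name)) sites$name <- paste0("pos", sites$position)
  sites <- sites[order(sites$position), , drop = FALSE]
  mat <- matrix(NA_character_, nrow = nrow(sites), ncol = length(samples),
                dimnames = list(sites$name, samples))
  off <- 0L
  lut <- split(seq_len(nrow(pileups)),
               list(factor(pileups$sample, levels = samples),
                    factor(pileups$position, levels = sites$position)),
               drop = TRUE)
  for (key in names(lut)) {
    i <- lut[[key]][1L]
    s <- pileups$sample[i]
    si <- match(pileups$position[i], sites$position)
    if (is.na(si) || !s %in% samples) next
    b <- callBase(pileups$bases[i], pileups$quals[i], t)
    if (is.na(b)) next
    anc <- substr(sites$ancestralAllele[si], 1L, 1L)
    der <- sites$proxyBase[si]
    if (b == anc) mat[si, s] <- "A"
    else if (b == der) mat[si, s] <- "D"
    else off <- off + 1L
  }
  keep <- if (dropMonomorphic)
    rowSums(mat == "D", na.rm = TRUE) > 0L else rep(TRUE, nrow(mat))
  cm <- YCallMatrix(mat[keep, , drop = FALSE],
                    sites[keep, , drop = FALSE])
  S4Vectors::metadata(cm)$offAlleleCells <- off
  S4Vectors::metadata(cm)$thresholds <- unclass(t)
  cm
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

#' Read a marker position file
#'
#' Tab-separated, headerless: marker name, chromosome, 1-based position,
#' ancestral allele, derived allele (the layout used by Y-SNP calling
#' position files).
#'
#' @param path input file
#' @return site data.frame with \code{name}, \code{position},
#'   \code{ancestralAllele}, \code{derivedAllele}, \code{proxyBase},
#'   \code{refAllele}, \code{altAllele}, \code{class}
#' @export
readPositionFile <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("name", "chrom", "position",
                                        "ancestralAllele", "derivedAllele"))
  data.frame(name = df$name, position = as.integer(df$position),
             refAllele = df$ancestralAllele,
             altAllele = df$derivedAllele,
             ancestralAllele = df$ancestralAllele,
             derivedAllele = df$derivedAllele,
             proxyBase = .proxyBase(df$ancestralAllele, df$derivedAllele),
             class = ifelse(nchar(df$ancestralAllele) == 1L &
                            nchar(df$derivedAllele) == 1L, "SNP", "InDel"),
             stringsAsFactors = FALSE)
}

#' Write a call matrix as TSV (samples x sites, values A/D/.)
#' @param x a \linkS4class{YCallMatrix}
#' @param path output file
#' @param annotationPath optional path for a per-site annotation TSV
#' @export
writeCallMatrix <- function(x, path, annotationPath = NULL) {
  m <- t(calls(x))
  m[is.na(m)] <- "."
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath))
    utils::write.table(siteInfo(x), annotationPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call matrix TSV written by \code{\link{writeCallMatrix}}
#' @param path matrix file
#' @param annotationPath optional annotation TSV restoring site metadata
#' @return a \linkS4class{YCallMatrix}
#' @export
readCallMatrix <- function(path, annotationPath = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$sample
  m[m == "."] <- NA_character_
  if (!is.null(annotationPath)) {
    sites <- utils::read.table(annotationPath, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  } else {
    sites <- data.frame(name = rownames(m),
                        position = seq_len(nrow(m)),
                        ancestralAllele = "A", derivedAllele = "N",
                        stringsAsFactors = FALSE)
  }
  YCallMatrix(m, sites)
}
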