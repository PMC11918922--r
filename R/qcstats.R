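## Capture-specificity QC, coverage/concentration statistics, and
## cohort-level variant summaries (group partition, singletons, class
## tallies, fold changes).

#' On-target to off-target capture specificity
#'
#' @param meta sample metadata data.frame with \code{on_target} and
#'   \code{off_target} base counts
#' @return numeric vector of ratios; \code{NA} (undefined) where
#'   \code{off_target} is zero
#' @export
captureSpecificity <- function(meta) {
  ifelse(meta$off_target > 0, meta$on_target / meta$off_target, NA_real_)
}

#' Moving-window statistics of capture specificity over DNA concentration
#'
#' Samples are sorted by increasing DNA concentration (ties by sample id) and
#' summarised in sliding (stride-1) windows of \code{window} samples; a
#' trailing partial window is excluded. Per window: arithmetic mean of the
#' specificities, their variation (sample standard deviation by default;
#' variance or coefficient of variation selectable) and the mean
#' concentration.
#'
#' @param meta data.frame with \code{sample}, \code{concentration},
#'   \code{on_target}, \code{off_target}
#' @param window window size (default 5)
#' @param variation one of \code{"sd"}, \code{"var"}, \code{"cv"}
#' @return data.frame: \code{window}, \code{members} (comma-separated sample
#'   ids), \code{mean_ratio}, \code{variation}, \code{mean_concentration}
#' @export
windowStats <- function(meta, window = 5L, variation = c("sd", "var", "cv")) {
  variation <- match.arg(variation)
  meta <- meta[!is.na(meta$concentration), , drop = FALSE]
  if (nrow(meta) < window)
    .stopf("need at least %d samples with a concentration, got %d",
           window, nrow(meta))
  meta <- meta[order(meta$concentration, meta$sample), , drop = FALSE]
  ratio <- captureSpecificity(meta)
  n <- nrow(meta) - window + 1L
  vfun <- switch(variation, sd = stats::sd, var = stats::var,
                 cv = function(x) stats::sd(x) / mean(x))
  out <- lapply(seq_len(n), function(w) {
    idx <- w:(w + window - 1L)
    data.frame(window = w,
               members = paste(meta$sample[idx], collapse = ","),
               mean_ratio = mean(ratio[idx]),
               variation = vfun(ratio[idx]),
               mean_concentration = mean(meta$concentration[idx]))
  })
  do.call(rbind, out)
}

#' Concentration threshold for stable capture specificity
#'
#' The mean DNA concentration of the window with the highest variation; ties
#' resolved toward the lowest mean concentration.
#'
#' @param windows data.frame from \code{\link{windowStats}}
#' @return threshold concentration (ng/uL)
#' @export
concentrationThreshold <- function(windows) {
  if (!nrow(windows)) .stopf("no windows")
  top <- windows[windows$variation == max(windows$variation), , drop = FALSE]
  min(top$mean_concentration)
}

#' Pearson correlation of DNA concentration and capture specificity
#'
#' @param meta data.frame with \code{concentration}, \code{on_target},
#'   \code{off_target}
#' @return list: \code{r}, \code{p} (two-sided, t transform), \code{n};
#'   \code{r = NA} (undefined) when either variable has zero variance
#' @export
concentrationCorrelation <- function(meta) {
  ratio <- captureSpecificity(meta)
  ok <- !is.na(ratio) & !is.na(meta$concentration)
  x <- meta$concentration[ok]; y <- ratio[ok]
  if (length(x) < 3L) .stopf("need at least 3 samples with both fields")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Partition variants by the sample groups carrying them
#'
#' Each variant falls in exactly one of the seven non-empty subsets of
#' \{ModAdmix, AncNAM, ModNAM\} according to which groups contain at least
#' one derived carrier. Variants with no derived carrier (violating the
#' matrix invariant) are excluded and counted separately.
#'
#' @param x a \linkS4class{YCallMatrix}
#' @param groups named character vector: sample id -> group label
#' @return data.frame: \code{cell} (e.g. \code{"ModAdmix+ModNAM"}),
#'   \code{count}, \code{percent} (of partitioned variants, half away from
#'   zero to the nearest integer); attribute \code{"excluded"} gives the
#'   number of zero-carrier variants
#' @export
groupPartition <- function(x, groups) {
  m <- calls(x)
  if (any(!colnames(m) %in% names(groups)))
    .stopf("sample %s has no group label",
           setdiff(colnames(m), names(groups))[1L])
  glev <- c("ModAdmix", "AncNAM", "ModNAM")
  g <- groups[colnames(m)]
  der <- m == "D"; der[is.na(der)] <- FALSE
  inGroup <- vapply(glev, function(gr)
    rowSums(der[, g == gr, drop = FALSE]) > 0L, logical(nrow(m)))
  if (nrow(m) == 1L) inGroup <- matrix(inGroup, nrow = 1L,
                                       dimnames = list(NULL, glev))
  cellOf <- apply(inGroup, 1L, function(z) paste(glev[z], collapse = "+"))
  excluded <- sum(cellOf == "")
  cellOf <- cellOf[cellOf != ""]
  allCells <- unlist(lapply(seq_along(glev), function(k)
    utils::combn(glev, k, paste, collapse = "+", simplify = FALSE)),
    use.names = FALSE)
  cnt <- table(factor(cellOf, levels = allCells))
  out <- data.frame(cell = names(cnt), count = as.integer(cnt))
  out$percent <- if (sum(out$count))
    roundHalfAway(100 * out$count / sum(out$count)) else 0
  attr(out, "excluded") <- excluded
  out
}

#' Singleton variants (derived in exactly one sample)
#'
#' @param x a \linkS4class{YCallMatrix}
#' @return list: \code{count}, \code{total}, \code{percent} (rounded half
#'   away from zero to the nearest integer; \code{NA} for an empty matrix)
#' @export
singletonStats <- function(x) {
  m <- calls(x)
  if (!nrow(m)) return(list(count = 0L, total = 0L, percent = NA_real_))
  nCar <- rowSums(m == "D", na.rm = TRUE)
  count <- sum(nCar == 1L)
  list(count = count, total = nrow(m),
       percent = roundHalfAway(100 * count / nrow(m)))
}

#' Tally variants by class
#'
#' @param sites site data.frame with a \code{class} column (values
#'   \code{"SNP"} / \code{"InDel"})
#' @return list: \code{n_total}, \code{n_snp}, \code{n_indel}
#' @export
classTally <- function(sites) {
  list(n_total = nrow(sites),
       n_snp = sum(sites$class == "SNP"),
       n_indel = sum(sites$class == "InDel"))
}

#' Fold change rounded to the nearest integer
#'
#' @param a,b numerator and denominator
#' @return \code{round(a / b)} half away from zero; \code{NA} when
#'   \code{b == 0}
#' @export
foldChange <- function(a, b) {
  if (b == 0) return(NA_real_)
  roundHalfAway(a / b)
}

#' Write a QC summary (TSV + JSON-style list)
#'
#' @param meta sample metadata data.frame
#' @param x optional \linkS4class{YCallMatrix} for cohort variant statistics
#' @param groups named group vector (required with \code{x})
#' @param window window size for \code{\link{windowStats}}
#' @param variation variation measure
#' @return list with \code{specificity} (per-sample), \code{windows},
#'   \code{threshold}, \code{correlation} and, when \code{x} is given,
#'   \code{partition} and \code{singletons}
#' @export
qcReport <- function(meta, x = NULL, groups = NULL, window = 5L,
                     variation = "sd") {
  res <- list(
    specificity = data.frame(sample = meta$sample,
                             ratio = captureSpecificity(meta)))
  if (sum(!is.na(meta$concentration)) >= window) {
    res$windows <- windowStats(meta, window, variation)
    res$threshold <- concentrationThreshold(res$windows)
    res$correlation <- concentrationCorrelation(meta)
  }
  if (!is.null(x)) {
    res$partition <- groupPartition(x, groups)
    res$singletons <- singletonStats(x)
  }
  res
}
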