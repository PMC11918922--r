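## Small internal helpers shared across modules.

## round() uses banker's rounding; reported percentages and fold changes use
## round-half-away-from-zero, the convention of the summary tables we emit.
roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Split "30,28,41" -> integer vector; tolerant of empty strings.
.splitInts <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

.splitBases <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## single-base proxy for a (possibly multi-base) derived allele: the first
## base differing from the reference's first base, so the proxy never
## collides with the ancestral state
.proxyBase <- function(ref, alt) {
  mapply(function(r, a) {
    ab <- strsplit(a, "")[[1L]]
    d <- ab[ab != substr(r, 1L, 1L)]
    if (length(d)) d[1L] else ab[length(ab)]
  }, ref, alt, USE.NAMES = FALSE)
}

## Deterministic sub-seed derivation: one master seed, one stream per
## operation. Kept well below .Machine$integer.max.
.subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}
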