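# Evaluation statistics: CDS-support sensitivity, extrapolated
# false-positive rate FP-hat, the Poisson zero-count bound and the
# maximal exon offset.

#' Reference constants for the false-positive extrapolation
#'
#' Defaults: `N = 3.22e9` bp (human genome size), `n1 = 62.348e6` and
#' `n2 = 56.197e6` bp (total lengths of the human-like and mouse-like
#' sequence sets of the reference evaluation).
#'
#' @param N Reference genome size in bp.
#' @param n1,n2 Total bp of the two compared sequence sets.
#' @return Named list of constants.
#' @export
evalConstants <- function(N = 3.22e9, n1 = 62.348e6, n2 = 56.197e6) {
  stopifnot(N > 0, n1 > 0, n2 > 0)
  # doubles throughout: products like n1 * n2 overflow integer storage
  list(N = as.numeric(N), n1 = as.numeric(n1), n2 = as.numeric(n2))
}

#' CDS-support sensitivity of a seed set
#'
#' A seed `(S1, i, S2, j)` supports a CDS with (internal, 0-based
#' half-open) range `[a, b)` on `S1` iff `a <= i < b` and `(S1, S2)` is
#' an annotated homologous pair; the second position `j` is not required
#' to be homologous. Sensitivity is the fraction of CDS with at least one
#' supporting seed.
#'
#' @param x A pairwise [SeedSet-class]; the first coordinate column is
#'   the genome whose CDS are evaluated.
#' @param annot A [GeneAnnot-class] (CDS on first-genome sequences plus
#'   homologous pairs `seqId1` first genome, `seqId2` second genome).
#' @param excludeCds Optional integer vector of CDS row indices to leave
#'   out (e.g. exons known to be unanchorable).
#' @return List: `sensitivity` in `[0, 1]`, `supported` count, `total`
#'   count, and `perCds` data.frame with a logical `supported` column.
#' @export
seedSensitivity <- function(x, annot, excludeCds = NULL) {
  if (nGenomes(x) != 2) stop("sensitivity is defined for pairwise seeds")
  cds <- cdsIntervals(annot)
  if (!is.null(excludeCds) && length(excludeCds))
    cds <- cds[-excludeCds, , drop = FALSE]
  if (nrow(cds) == 0) stop("no CDS to evaluate")
  pairs <- homologPairs(annot)
  pairKey <- c(paste(pairs$seqId1, pairs$seqId2, sep = "\r"),
               paste(pairs$seqId2, pairs$seqId1, sep = "\r"))
  df <- as.data.frame(x)
  homol <- paste(df$seqId1, df$seqId2, sep = "\r") %in% pairKey
  sdt <- data.table(seqId = df$seqId1[homol], pos = df$pos1[homol])
  supported <- logical(nrow(cds))
  if (nrow(sdt) > 0) {
    cdt <- data.table(seqId = cds$seqId, lo = cds$start, hi = cds$end - 1,
                      row = seq_len(nrow(cds)))
    hits <- cdt[sdt, on = .(seqId, lo <= pos, hi >= pos), nomatch = NULL,
                .(row)]
    supported[unique(hits$row)] <- TRUE
  }
  list(sensitivity = mean(supported), supported = sum(supported),
       total = nrow(cds),
       perCds = cbind(cds, supported = supported))
}

#' Extrapolated false-positive rate FP-hat
#'
#' `FPhat = nFp * N / (n1 * n2)`: the observed false-positive seed count
#' rescaled to false seeds per genome position if two genomes of size `N`
#' were compared.
#'
#' @param nFp Observed false-positive count (>= 0).
#' @param consts Constants from [evalConstants()].
#' @return FP-hat (double).
#' @examples
#' fpHat(13035210)   # ~ 12 with the default constants
#' @export
fpHat <- function(nFp, consts = evalConstants()) {
  stopifnot(nFp >= 0)
  nFp * consts$N / (consts$n1 * consts$n2)
}

#' One-sided Poisson upper bound on FP-hat
#'
#' For an observed false-positive count (typically 0), returns the upper
#' end of the one-sided `1 - alpha` confidence interval for the Poisson
#' mean, converted to the FP-hat scale. For zero observations the bound
#' on the count is `-log(alpha)` (4.605 at `alpha = 0.01`); general
#' counts use the exact gamma-quantile bound.
#'
#' @param observed Observed count (default 0).
#' @param alpha Complement of the confidence level, in (0, 1).
#' @param consts Constants from [evalConstants()].
#' @return List: `countBound` (upper bound on the count) and `fpHatBound`.
#' @examples
#' poissonZeroUpperBound()$fpHatBound   # ~ 4.2e-6
#' @export
poissonZeroUpperBound <- function(observed = 0, alpha = 0.01,
                                  consts = evalConstants()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(observed >= 0)
  countBound <- if (observed == 0) -log(alpha)
                else qgamma(1 - alpha, shape = observed + 1)
  list(countBound = countBound, fpHatBound = fpHat(countBound, consts))
}

#' Maximal exon offset between two orthologous genes
#'
#' For genes with the same number `n` of CDS, with starts `a1[i]` and
#' `a2[i]` in the two genomes, the maximal exon offset is
#' `Omega = max_i |(a1[i] - a1[1]) - (a2[i] - a2[1])|`: the cumulative
#' effect of intron indels on relative exon positions — the offset a
#' tile of size `F` must absorb for the gene's seeds to share one tile.
#'
#' @param starts1,starts2 CDS start coordinates (equal length, `n >= 1`;
#'   any common shift per gene cancels).
#' @return Omega in bp.
#' @examples
#' maxExonOffset(c(0, 1000, 5000), c(0, 1200, 4500))   # 500
#' @export
maxExonOffset <- function(starts1, starts2) {
  if (length(starts1) != length(starts2))
    stop("both genes must have the same number of CDS")
  if (length(starts1) < 1) stop("need at least one CDS")
  max(abs((starts1 - starts1[1]) - (starts2 - starts2[1])))
}

#' Relative reduction of a rate
#'
#' `(before - after) / before`; used e.g. for the relative reduction in
#' false negatives between two methods.
#'
#' @param before,after Rates or counts, `before > 0`.
#' @return Relative reduction (double).
#' @export
relativeReduction <- function(before, after) {
  stopifnot(before > 0)
  (before - after) / before
}

#' Count false-positive seeds
#'
#' Operational definition: any seed whose sequence pair belongs to the
#' designated negative (random) set is a false positive; no reference
#' alignment is consulted.
#'
#' @param x A pairwise [SeedSet-class].
#' @param negativeIds Character vector of sequence ids forming the
#'   negative set, or `NULL` to count all seeds (the usual case when the
#'   whole run was on random sequences).
#' @return Integer count.
#' @export
countFalsePositives <- function(x, negativeIds = NULL) {
  if (is.null(negativeIds)) return(length(x))
  df <- as.data.frame(x)
  sum(df$seqId1 %in% negativeIds & df$seqId2 %in% negativeIds)
}
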