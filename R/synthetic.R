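# Synthetic test data: i.i.d. uniform random genome pairs (the negative
# set for false-positive estimation) and planted orthologous gene pairs
# with conserved exons (positives), with truth annotations.

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Split a total length into near-equal parts
#'
#' Deterministically splits `total` bp into `n` integer lengths differing
#' by at most 1 and summing exactly to `total`.
#' @param total Total bp.
#' @param n Number of parts.
#' @export
splitTotalLength <- function(total, n) {
  base <- total %/% n
  extra <- total - base * n
  c(rep(base + 1, extra), rep(base, n - extra))
}

#' Simulate the negative set: i.i.d. uniform random sequence pairs
#'
#' For each pair, two sequences of independent uniformly distributed
#' nucleotides are generated (no masking, no ambiguity) and labelled with
#' opposing genome labels. Any seed later found between the two sets is a
#' false positive by construction.
#'
#' @param lengths1,lengths2 Per-sequence lengths (bp) of the two sets;
#'   recycled against each other, so the sets are paired.
#' @param genomeLabels Two genome labels.
#' @param rngSeed RNG seed; same seed, same sequences.
#' @param idPrefix Prefixes for sequence ids.
#' @return List: `seqs1`, `seqs2` ([MaskedSeqSet-class]) and `pairs`
#'   (data.frame of the paired ids).
#' @export
simulateNegativePairs <- function(lengths1, lengths2,
                                  genomeLabels = c("rnd1", "rnd2"),
                                  rngSeed = NULL,
                                  idPrefix = c("neg1_", "neg2_")) {
  n <- max(length(lengths1), length(lengths2))
  lengths1 <- rep_len(lengths1, n)
  lengths2 <- rep_len(lengths2, n)
  .withSeed(rngSeed, {
    s1 <- vapply(lengths1, .randomDna, character(1))
    s2 <- vapply(lengths2, .randomDna, character(1))
    names(s1) <- paste0(idPrefix[1], seq_len(n))
    names(s2) <- paste0(idPrefix[2], seq_len(n))
    list(seqs1 = maskedSeqSet(s1, genomeLabels[1]),
         seqs2 = maskedSeqSet(s2, genomeLabels[2]),
         pairs = data.frame(seqId1 = names(s1), seqId2 = names(s2),
                            stringsAsFactors = FALSE))
  })
}

#' Reference-scale negative set
#'
#' The negative set of the reference evaluation: 705 sequence pairs with
#' total lengths 62.348 Mb and 56.197 Mb. `scale` shrinks both totals
#' linearly (e.g. `scale = 0.1` for a desk-scale run; expected random
#' match counts then shrink by `scale^2`).
#'
#' @param scale Linear scale factor in (0, 1].
#' @param nPairs Number of sequence pairs (default 705).
#' @inheritParams simulateNegativePairs
#' @return As [simulateNegativePairs()].
#' @export
referenceNegativeSet <- function(scale = 1, nPairs = 705,
                                 genomeLabels = c("rnd1", "rnd2"),
                                 rngSeed = NULL) {
  stopifnot(scale > 0, scale <= 1)
  n1 <- round(62.348e6 * scale)
  n2 <- round(56.197e6 * scale)
  simulateNegativePairs(splitTotalLength(n1, nPairs),
                        splitTotalLength(n2, nPairs),
                        genomeLabels = genomeLabels, rngSeed = rngSeed)
}

#' Simulation configuration for planted ortholog pairs
#'
#' Defaults model a vertebrate-like gene region pair: multi-exon genes
#' whose exons are copied between the genomes at per-base identity 0.85
#' (substitutions only, uniform over the three alternative bases), with
#' introns drawn independently per genome from `intronRange` (so intron
#' length differences accumulate into exon offsets) and flanks from
#' `flankRange`.
#'
#' @param nGenes Number of ortholog gene pairs.
#' @param exonCountRange Min/max exons per gene.
#' @param exonLengthRange Min/max exon length (bp); the default mean of
#'   ~155 bp mirrors typical uninterrupted CDS fragment lengths in
#'   human-mouse orthologs.
#' @param identity Per-base exon copy identity in `[0, 1]`.
#' @param intronRange1,intronRange2 Intron length ranges per genome.
#' @param flankRange Flank length range (bp).
#' @return Config list.
#' @export
simConfig <- function(nGenes = 20, exonCountRange = c(4, 10),
                      exonLengthRange = c(60, 250), identity = 0.85,
                      intronRange1 = c(500, 1500),
                      intronRange2 = c(500, 1500),
                      flankRange = c(5000, 10000)) {
  stopifnot(identity >= 0, identity <= 1, nGenes >= 1,
            all(exonCountRange >= 1), all(exonLengthRange >= 1),
            all(intronRange1 >= 1), all(intronRange2 >= 1),
            all(flankRange >= 0))
  list(nGenes = nGenes, exonCountRange = exonCountRange,
       exonLengthRange = exonLengthRange, identity = identity,
       intronRange1 = intronRange1, intronRange2 = intronRange2,
       flankRange = flankRange)
}

# copy a sequence applying i.i.d. substitutions at rate (1 - identity),
# uniform over the three alternative bases
.mutateCopy <- function(s, identity) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) > identity
  if (any(hit)) {
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3)
    colnames(alt) <- NULL
    base <- match(ch[hit], c("A", "C", "G", "T"))
    pick <- sample.int(3, sum(hit), replace = TRUE)
    ch[hit] <- alt[cbind(pick, base)]
  }
  paste(ch, collapse = "")
}

.runifInt <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Simulate one planted ortholog gene pair
#'
#' Draws exon sequences once; genome 1 carries them as drawn, genome 2 a
#' copy with i.i.d. substitutions at rate `1 - identity`, so `identity`
#' is the pairwise per-base match probability of the two observed exon
#' copies. Introns and flanks are drawn independently per genome from
#' their length ranges, so the realized maximal exon offset (Omega) is
#' nonzero. Emits the two sequences, the CDS truth intervals (0-based
#' half-open) and the realized Omega.
#'
#' @param config From [simConfig()].
#' @param geneIndex Index used in sequence ids.
#' @param idPrefix Prefixes for the two genome sequence ids.
#' @return List: `seq1`, `seq2` (residue strings), `cds1`, `cds2`
#'   (data.frames `start`,`end`), `omega` (bp).
#' @export
simulateOrthologPair <- function(config = simConfig(), geneIndex = 1,
                                 idPrefix = c("geneA_", "geneB_")) {
  nEx <- .runifInt(1, config$exonCountRange)
  exLens <- .runifInt(nEx, config$exonLengthRange)
  exons <- vapply(exLens, .randomDna, character(1))
  buildGenome <- function(which) {
    intronRange <- if (which == 1) config$intronRange1 else config$intronRange2
    flanks <- .runifInt(2, config$flankRange)
    introns <- if (nEx > 1) .runifInt(nEx - 1, intronRange) else integer(0)
    # identity is the pairwise per-base match probability between the two
    # observed copies: genome 1 carries the exon as drawn, genome 2 a copy
    # substituted at rate 1 - identity
    exCopies <- if (which == 1) exons
                else vapply(exons, .mutateCopy, character(1),
                            identity = config$identity)
    pieces <- character(2 * nEx + 1)
    pieces[1] <- .randomDna(flanks[1])
    starts <- numeric(nEx)
    at <- flanks[1]
    for (e in seq_len(nEx)) {
      starts[e] <- at
      pieces[2 * e] <- exCopies[e]
      at <- at + exLens[e]
      if (e < nEx) {
        pieces[2 * e + 1] <- .randomDna(introns[e])
        at <- at + introns[e]
      }
    }
    pieces[2 * nEx + 1] <- .randomDna(flanks[2])
    list(seq = paste(pieces, collapse = ""),
         cds = data.frame(start = starts, end = starts + exLens))
  }
  g1 <- buildGenome(1)
  g2 <- buildGenome(2)
  list(seq1 = g1$seq, seq2 = g2$seq, cds1 = g1$cds, cds2 = g2$cds,
       omega = maxExonOffset(g1$cds$start, g2$cds$start),
       id1 = paste0(idPrefix[1], geneIndex),
       id2 = paste0(idPrefix[2], geneIndex))
}

#' Simulate a set of planted ortholog gene pairs with truth
#'
#' Each gene pair becomes its own sequence pair (one gene region per
#' sequence, as in per-gene evaluation sets). Returns the sequences of
#' both genomes, the truth annotation ([GeneAnnot-class]: first-genome
#' CDS plus homologous pair links) and the realized per-gene Omega.
#'
#' @param config From [simConfig()].
#' @param genomeLabels Two genome labels.
#' @param rngSeed RNG seed.
#' @return List: `seqs1`, `seqs2`, `annot`, `cds2` (second-genome truth),
#'   `omega` (numeric per gene).
#' @export
simulateOrthologSet <- function(config = simConfig(),
                                genomeLabels = c("simA", "simB"),
                                rngSeed = NULL) {
  .withSeed(rngSeed, {
    genes <- lapply(seq_len(config$nGenes), function(i)
      simulateOrthologPair(config, geneIndex = i))
    s1 <- setNames(vapply(genes, `[[`, "", "seq1"),
                   vapply(genes, `[[`, "", "id1"))
    s2 <- setNames(vapply(genes, `[[`, "", "seq2"),
                   vapply(genes, `[[`, "", "id2"))
    cds1 <- rbindlist(lapply(genes, function(g)
      data.table(seqId = g$id1, start = g$cds1$start, end = g$cds1$end)))
    cds2 <- rbindlist(lapply(genes, function(g)
      data.table(seqId = g$id2, start = g$cds2$start, end = g$cds2$end)))
    pairs <- data.frame(seqId1 = names(s1), seqId2 = names(s2),
                        stringsAsFactors = FALSE)
    seqs1 <- maskedSeqSet(s1, genomeLabels[1])
    seqs2 <- maskedSeqSet(s2, genomeLabels[2])
    list(seqs1 = seqs1, seqs2 = seqs2,
         annot = geneAnnot(as.data.frame(cds1), pairs,
                           seqLengths = seqLengths(seqs1)),
         cds2 = as.data.frame(cds2),
         omega = vapply(genes, `[[`, numeric(1), "omega"))
  })
}
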