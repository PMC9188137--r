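#' Read softmasked FASTA into a MaskedSeqSet
#'
#' Lowercase residues are flagged as softmasked, non-ACGT letters as
#' ambiguous; case is preserved internally so writing the set back yields
#' the identical file content.
#'
#' @param path FASTA file.
#' @param genome Genome label for the records: a single string, a named
#'   vector mapping sequence id to label, or `NULL` to use the file name
#'   without extension.
#' @return A [MaskedSeqSet-class], records in file order.
#' @export
readMaskedFasta <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(readBStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  # keep only the first word of each header as id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(genome)) {
    genome <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!is.null(names(genome))) {
    miss <- setdiff(names(seqs), names(genome))
    if (length(miss))
      stop("no genome label supplied for sequence(s): ",
           paste(miss, collapse = ", "))
    genome <- unname(genome[names(seqs)])
  }
  maskedSeqSet(seqs, genome)
}

#' Write a MaskedSeqSet as FASTA
#'
#' Residue case (softmask information) is written exactly as stored.
#' @param x A [MaskedSeqSet-class].
#' @param path Output file.
#' @param width Line width.
#' @export
writeMaskedFasta <- function(x, path, width = 70L) {
  writeXStringSet(x@seqs, path, width = width)
  invisible(path)
}

#' Construct gene annotations
#'
#' @param cds data.frame with columns `seqId`, `start`, `end`; coordinates
#'   0-based half-open.
#' @param pairs data.frame with columns `seqId1`, `seqId2` listing
#'   homologous sequence pairs (symmetric relation).
#' @param seqLengths Optional named lengths to validate intervals against.
#' @return A [GeneAnnot-class].
#' @export
geneAnnot <- function(cds, pairs, seqLengths = NULL) {
  cds <- as.data.frame(cds)
  pairs <- as.data.frame(pairs)
  if (nrow(cds) > 0 && !is.null(seqLengths)) {
    known <- cds$seqId %in% names(seqLengths)
    bad <- known & (cds$start < 0 | cds$end > seqLengths[cds$seqId])
    if (any(bad, na.rm = TRUE))
      stop("CDS interval(s) outside sequence bounds for: ",
           paste(unique(cds$seqId[which(bad)]), collapse = ", "))
  }
  new("GeneAnnot", cds = cds, pairs = pairs)
}

#' @describeIn geneAnnot CDS intervals (0-based half-open data.frame).
#' @param x A `GeneAnnot`.
#' @export
setMethod("cdsIntervals", "GeneAnnot", function(x) x@cds)

#' @describeIn geneAnnot Homologous sequence pairs.
#' @export
setMethod("homologPairs", "GeneAnnot", function(x) x@pairs)

setMethod("show", "GeneAnnot", function(object) {
  cat("GeneAnnot:", nrow(object@cds), "CDS interval(s) on",
      length(unique(object@cds$seqId)), "sequence(s);",
      nrow(object@pairs), "homologous pair(s)\n")
})

#' Read CDS features from GFF3
#'
#' Extracts features of type `CDS` and converts their 1-based inclusive
#' coordinates to the internal 0-based half-open convention. Features on
#' sequence ids not in `seqIds` (when given) are dropped with a warning
#' stating how many.
#'
#' @param path GFF3 file.
#' @param seqIds Optional character vector of known sequence ids.
#' @return data.frame with columns `seqId`, `start`, `end` (0-based
#'   half-open), suitable for [geneAnnot()].
#' @export
readCdsGff3 <- function(path, seqIds = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[!is.na(gr$type) & gr$type == "CDS"]
  out <- data.frame(seqId = as.character(GenomicRanges::seqnames(cds)),
                    start = GenomicRanges::start(cds) - 1L,  # 1-based -> 0-based
                    end = GenomicRanges::end(cds),           # inclusive -> exclusive
                    stringsAsFactors = FALSE)
  if (!is.null(seqIds)) {
    unknown <- !(out$seqId %in% seqIds)
    if (any(unknown))
      warning(sum(unknown), " CDS feature(s) on unknown sequence ids ignored")
    out <- out[!unknown, , drop = FALSE]
  }
  if (nrow(out) == 0) warning("no CDS features found in ", path)
  rownames(out) <- NULL
  out
}

#' Write CDS intervals as GFF3
#'
#' Inverse of [readCdsGff3()]: internal 0-based half-open intervals are
#' written as 1-based inclusive GFF3 `CDS` features.
#' @param cds data.frame with columns `seqId`, `start`, `end`.
#' @param path Output file.
#' @export
writeCdsGff3 <- function(cds, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = cds$seqId,
    ranges = IRanges::IRanges(start = cds$start + 1L, end = cds$end),
    type = "CDS", source = "geoseed", phase = 0L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a two-column homolog pair list (TSV)
#'
#' @param path TSV with columns `seqId1`, `seqId2` (header optional: a
#'   first line equal to `seqId1<TAB>seqId2` is skipped).
#' @export
readHomologPairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) && identical(strsplit(lines[1], "\t")[[1]],
                                 c("seqId1", "seqId2")))
    lines <- lines[-1]
  if (!length(lines))
    return(data.frame(seqId1 = character(0), seqId2 = character(0)))
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2))
    stop("homolog pair file must have exactly two tab-separated columns")
  data.frame(seqId1 = vapply(parts, `[`, "", 1),
             seqId2 = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}

# ---- seed TSV --------------------------------------------------------------

#' Write / read seeds as TSV
#'
#' Tab-separated, one `(seqId, pos)` column pair per genome, then
#' `pattern` and `stage`; a header line records the genome label of each
#' coordinate pair so that `readSeeds(writeSeeds(x)) == x`.
#'
#' @param x A [SeedSet-class].
#' @param path Output/input file.
#' @return `writeSeeds` the path, invisibly; `readSeeds` a `SeedSet`.
#' @export
writeSeeds <- function(x, path) {
  s <- nGenomes(x)
  header <- c(rbind(paste0("seqId:", x@genomeLabels),
                    paste0("pos:", x@genomeLabels)), "pattern", "stage")
  df <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (length(x) > 0) {
    cols <- c(unlist(lapply(seq_len(s), function(g) paste0(c("seqId", "pos"), g))),
              "pattern", "stage")
    write.table(df[, cols], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, na = ".")
  }
  invisible(path)
}

#' @rdname writeSeeds
#' @export
readSeeds <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty seed file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  seqCols <- grep("^seqId:", header)
  posCols <- grep("^pos:", header)
  if (length(seqCols) < 2 || length(seqCols) != length(posCols))
    stop("seed TSV header must have one seqId:/pos: column pair per genome")
  labels <- sub("^seqId:", "", header[seqCols])
  stageCol <- match("stage", header)
  patCol <- match("pattern", header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(.emptySeedSet(labels))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad))
    stop("ragged seed TSV row ", bad[1] + 1L, " in ", path)
  m <- do.call(rbind, parts)
  positions <- matrix(as.numeric(m[, posCols, drop = FALSE]), nrow = nrow(m))
  if (anyNA(positions)) stop("non-numeric position in seed TSV ", path)
  pat <- if (!is.na(patCol)) { p <- m[, patCol]; p[p == "."] <- NA; p }
         else rep(NA_character_, nrow(m))
  stage <- if (!is.na(stageCol)) m[1, stageCol] else "candidate"
  seedSet(m[, seqCols, drop = FALSE], positions, labels,
          pattern = pat, stage = stage)
}
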