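# Composite pipeline: simulate/read -> find -> filter (M4 and/or
# geometric hashing) -> evaluate, with a manifest of effective parameters.

.defaultRunConfig <- function() {
  list(
    rngSeed = 1L,
    find = list(method = "spaced", k = NULL, patternsFile = NULL,
                patternsWeight = 15, maxPerKmer = 10, maskFilter = TRUE),
    m4 = list(enabled = FALSE, D = 1000, tau = 2, span = NULL,
              countSelf = TRUE),
    ghash = list(enabled = FALSE, tileSize = 10000, nSubTiles = 50,
                 chunkLength = 400, pNorm = 6, tauScore = 0,
                 calibrate = FALSE, calibrateNrep = 3, calibrateMargin = 1.5),
    evaluate = list(N = 3.22e9)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the seed finding and filtering pipeline
#'
#' Stages in order: obtain input (FASTA files, pre-built objects, or a
#' simulation request), seed finding (contiguous or spaced), optional
#' neighbouring-matches filter, optional geometric hashing (with optional
#' null-calibrated threshold), optional evaluation against annotations.
#' Per-stage seed counts are logged to stderr; seeds are written as TSV
#' after every stage so each stage is independently re-runnable from
#' file, and a manifest echoes every effective parameter.
#'
#' @param config Nested list (see `geoseed:::.defaultRunConfig()` for
#'   the shape and defaults) or path to a YAML file with the same
#'   structure. Input is given either as `config$input$fasta1/fasta2`
#'   (plus optional `gff`/`pairs` for evaluation) or as
#'   `config$input$simulate = list(type = "ortholog"|"negative", ...)`.
#' @param outDir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return List: `seeds` (final [SeedSet-class]), `counts` (per-stage
#'   seed counts), `summary` (evaluation results, when truth is
#'   available), `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(.defaultRunConfig(), config)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  logmsg <- function(...) message("[geoseed] ", ...)
  counts <- list()

  # ---- input ----
  annot <- NULL
  inp <- cfg$input
  if (is.null(inp)) stop("config$input is required (stage: input)")
  if (!is.null(inp$simulate)) {
    simcfg <- inp$simulate
    if (identical(simcfg$type, "negative")) {
      scale <- if (is.null(simcfg$scale)) 1 else simcfg$scale
      sim <- referenceNegativeSet(scale = scale,
                                  nPairs = simcfg$nPairs %||% 705,
                                  rngSeed = cfg$rngSeed)
      seqs1 <- sim$seqs1; seqs2 <- sim$seqs2
    } else {
      sc <- do.call(simConfig, simcfg[setdiff(names(simcfg), "type")])
      sim <- simulateOrthologSet(sc, rngSeed = cfg$rngSeed)
      seqs1 <- sim$seqs1; seqs2 <- sim$seqs2; annot <- sim$annot
    }
  } else if (!is.null(inp$seqs1)) {
    seqs1 <- inp$seqs1; seqs2 <- inp$seqs2
    annot <- inp$annot
  } else if (!is.null(inp$fasta1)) {
    if (!file.exists(inp$fasta1) || !file.exists(inp$fasta2))
      stop("input FASTA not found (stage: input)")
    seqs1 <- readMaskedFasta(inp$fasta1, genome = inp$genome1 %||% "genome1")
    seqs2 <- readMaskedFasta(inp$fasta2, genome = inp$genome2 %||% "genome2")
    if (!is.null(inp$gff) && !is.null(inp$pairs)) {
      cds <- readCdsGff3(inp$gff, seqIds = seqIds(seqs1))
      annot <- geneAnnot(cds, readHomologPairs(inp$pairs))
    }
  } else stop("config$input must give fasta1/fasta2, seqs1/seqs2, ",
              "or a simulate block (stage: input)")
  logmsg("input: ", length(seqs1), " + ", length(seqs2), " sequence(s), ",
         sum(seqLengths(seqs1)) + sum(seqLengths(seqs2)), " bp total")

  # ---- find ----
  fc <- cfg$find
  if (identical(fc$method, "contiguous")) {
    if (is.null(fc$k)) stop("contiguous finding needs find$k (stage: find)")
    patterns <- patternSet(seedPattern(strrep("1", fc$k)))
  } else if (!is.null(fc$patternsFile)) {
    patterns <- readPatternSet(fc$patternsFile)
  } else {
    patterns <- examplePatternSet(fc$patternsWeight)
  }
  seeds <- findSpacedSeeds(seqs1, seqs2, patterns,
                           maxPerKmer = fc$maxPerKmer,
                           maskFilter = fc$maskFilter,
                           rngSeed = cfg$rngSeed)
  counts$candidates <- length(seeds)
  logmsg("find: ", length(seeds), " candidate seed(s) [",
         length(patterns), " pattern(s), weight ", patternWeight(patterns),
         "]")
  .maybeWriteSeeds(seeds, outDir, "seeds_candidates.tsv")

  # ---- M4 ----
  if (isTRUE(cfg$m4$enabled)) {
    span <- cfg$m4$span %||% patternSpan(patterns)
    seeds <- filterNeighbouringSeeds(seeds, D = cfg$m4$D, tau = cfg$m4$tau,
                                     span = span,
                                     countSelf = cfg$m4$countSelf)
    counts$m4 <- length(seeds)
    logmsg("m4: ", length(seeds), " seed(s) after neighbouring-matches ",
           "filter (D=", cfg$m4$D, ", tau=", cfg$m4$tau, ")")
    .maybeWriteSeeds(seeds, outDir, "seeds_m4.tsv")
  }

  # ---- geometric hashing ----
  if (isTRUE(cfg$ghash$enabled)) {
    gcfg <- cfg$ghash
    params <- ghParams(gcfg$tileSize, gcfg$nSubTiles, gcfg$chunkLength, gcfg$pNorm,
                       gcfg$tauScore)
    if (isTRUE(gcfg$calibrate)) {
      tau <- calibrateScoreThreshold(
        unname(seqLengths(seqs1)), unname(seqLengths(seqs2)), patterns,
        params = params, maxPerKmer = fc$maxPerKmer,
        nrep = gcfg$calibrateNrep, margin = gcfg$calibrateMargin,
        rngSeed = cfg$rngSeed + 7777L)
      params@tauScore <- tau
      logmsg("ghash: calibrated tauScore = ", signif(tau, 4))
    }
    gh <- runGeometricHashing(
      seeds, c(seqLengths(seqs1), seqLengths(seqs2)), params,
      genomeTotals = c(sum(seqLengths(seqs1)), sum(seqLengths(seqs2))))
    seeds <- gh$seeds
    counts$ghash <- length(seeds)
    cfg$ghash$tauScoreEffective <- params@tauScore
    logmsg("ghash: ", length(seeds), " seed(s) from ",
           sum(gh$tiles$pass), "/", nrow(gh$tiles), " passing tile(s)")
    .maybeWriteSeeds(seeds, outDir, "seeds_ghash.tsv")
    if (!is.null(outDir))
      write.table(gh$tiles, file.path(outDir, "tiles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  # ---- evaluate ----
  summary <- list(finalSeeds = length(seeds))
  if (!is.null(annot)) {
    sens <- seedSensitivity(seeds, annot)
    summary$sensitivity <- sens$sensitivity
    summary$supportedCds <- sens$supported
    summary$totalCds <- sens$total
    logmsg("evaluate: sensitivity ", signif(sens$sensitivity, 4),
           " (", sens$supported, "/", sens$total, " CDS)")
  }
  consts <- evalConstants(N = cfg$evaluate$N,
                          n1 = sum(seqLengths(seqs1)),
                          n2 = sum(seqLengths(seqs2)))
  if (!is.null(inp$simulate) && identical(inp$simulate$type, "negative")) {
    summary$nFp <- length(seeds)
    summary$fpHat <- fpHat(length(seeds), consts)
    if (length(seeds) == 0)
      summary$fpHatUpperBound <- poissonZeroUpperBound(0, consts = consts)$fpHatBound
    logmsg("evaluate: #FP = ", summary$nFp, ", FP-hat = ",
           signif(summary$fpHat, 4))
  }

  # in-memory S4 inputs are echoed as size summaries, not serialized
  if (!is.null(cfg$input$seqs1)) {
    cfg$input <- list(seqs1 = list(n = length(seqs1),
                                   bp = sum(seqLengths(seqs1))),
                      seqs2 = list(n = length(seqs2),
                                   bp = sum(seqLengths(seqs2))),
                      annot = !is.null(annot))
  }
  manifest <- list(package = "geoseed",
                   version = as.character(utils::packageVersion("geoseed")),
                   config = cfg)
  if (!is.null(outDir)) {
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(seeds = seeds, counts = counts, summary = summary,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.maybeWriteSeeds <- function(seeds, outDir, name) {
  if (!is.null(outDir)) writeSeeds(seeds, file.path(outDir, name))
}
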