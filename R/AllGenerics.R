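#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @export
setGeneric("genomeLabels", function(x) standardGeneric("genomeLabels"))

#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @export
setGeneric("maskedPositions", function(x, id) standardGeneric("maskedPositions"))

#' @export
setGeneric("ambiguousPositions", function(x, id) standardGeneric("ambiguousPositions"))

#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @export
setGeneric("patternSpan", function(x) standardGeneric("patternSpan"))

#' @export
setGeneric("matchPositions", function(x) standardGeneric("matchPositions"))

#' @export
setGeneric("patternIds", function(x) standardGeneric("patternIds"))

#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))

#' @export
setGeneric("seedStage", function(x) standardGeneric("seedStage"))

#' @export
setGeneric("cdsIntervals", function(x) standardGeneric("cdsIntervals"))

#' @export
setGeneric("homologPairs", function(x) standardGeneric("homologPairs"))
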