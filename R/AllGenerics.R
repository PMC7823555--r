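#' @include utils.R
NULL

#' @export
setGeneric("nRepetitions", function(x) standardGeneric("nRepetitions"))

#' @export
setGeneric("flashOrder", function(x) standardGeneric("flashOrder"))

#' @export
setGeneric("flashIndex", function(x) standardGeneric("flashIndex"))

#' @export
setGeneric("repetitionIndex", function(x) standardGeneric("repetitionIndex"))

#' @export
setGeneric("characterIndex", function(x) standardGeneric("characterIndex"))

#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("spellerLayout", function(x) standardGeneric("spellerLayout"))

#' @export
setGeneric("targetChars", function(x) standardGeneric("targetChars"))

#' @export
setGeneric("scoreVector", function(x) standardGeneric("scoreVector"))

#' @export
setGeneric("encode", function(object, x, ...) standardGeneric("encode"))

#' @export
setGeneric("klTerm", function(object) standardGeneric("klTerm"))

#' @export
setGeneric("predictProb", function(object, x, ...) standardGeneric("predictProb"))

#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
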