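#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("exprPlatform", function(x) standardGeneric("exprPlatform"))

#' @rdname accessors
#' @export
setGeneric("sigName", function(x) standardGeneric("sigName"))

#' @rdname accessors
#' @export
setGeneric("sigGenes", function(x) standardGeneric("sigGenes"))

#' @rdname accessors
#' @export
setGeneric("sigDirection", function(x) standardGeneric("sigDirection"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))

#' @rdname accessors
#' @export
setGeneric("isZscored", function(x) standardGeneric("isZscored"))

#' @rdname accessors
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))

#' @rdname zscoreRows
#' @export
setGeneric("zscoreRows", function(x, ...) standardGeneric("zscoreRows"))

#' @rdname accessors
#' @export
setGeneric("highSamples", function(x) standardGeneric("highSamples"))

#' @rdname accessors
#' @export
setGeneric("lowSamples", function(x) standardGeneric("lowSamples"))

#' @rdname accessors
#' @export
setGeneric("ppepValues", function(x) standardGeneric("ppepValues"))

#' @rdname accessors
#' @export
setGeneric("ppepLong", function(x) standardGeneric("ppepLong"))
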