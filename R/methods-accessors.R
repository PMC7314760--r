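#' Accessors for rdikit classes
#'
#' Small accessor generics exposing slots of the package's S4 classes:
#' gene/sample identifiers and values of an \linkS4class{ExpressionMatrix},
#' the members of a \linkS4class{GeneSignature}, the rows of a
#' \linkS4class{ScoreMatrix}, the groups of an
#' \linkS4class{ExtremeSelection}, and the matrices of a
#' \linkS4class{PPEPMatrix}.
#'
#' @param x an rdikit object.
#' @return The corresponding slot value; \code{ppepLong} returns a
#'   long-format \code{data.frame} (pathway, contrast, p, adj_p, hits,
#'   transformed) where \code{adj_p} is a per-contrast Benjamini-Hochberg
#'   column provided for inspection only (never used for zeroing).
#' @name accessors
#' @aliases geneIds sampleIds exprValues exprPlatform sigName sigGenes
#'   sigDirection sourceLabel scoreValues signatureNames isZscored
#'   scoreParams highSamples lowSamples ppepValues ppepLong
NULL

#' @rdname accessors
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, 1L))

#' @rdname accessors
setMethod("exprPlatform", "ExpressionMatrix", function(x) x@platform)

#' @rdname accessors
setMethod("sigName", "GeneSignature", function(x) x@name)

#' @rdname accessors
setMethod("sigGenes", "GeneSignature", function(x) x@genes)

#' @rdname accessors
setMethod("sigDirection", "GeneSignature", function(x) x@direction)

#' @rdname accessors
setMethod("sourceLabel", "SignatureCollection", function(x) x@source_label)

#' @export
setMethod("length", "SignatureCollection",
          function(x) length(x@signatures))

#' @export
setMethod("names", "SignatureCollection",
          function(x) vapply(x@signatures, sigName, character(1)))

#' Extract a signature from a collection
#'
#' @param x a \linkS4class{SignatureCollection}.
#' @param i numeric index or signature name.
#' @param j,... unused.
#' @return \code{[[} returns a \linkS4class{GeneSignature}; \code{[} a
#'   subset \linkS4class{SignatureCollection}.
#' @export
setMethod("[[", "SignatureCollection", function(x, i, j, ...) {
  if (is.character(i)) {
    idx <- match(i, names(x))
    if (is.na(idx)) stop("no signature named '", i, "'")
    i <- idx
  }
  x@signatures[[i]]
})

#' @rdname cash-cash-sub-SignatureCollection-method
#' @param drop unused.
#' @export
setMethod("[", "SignatureCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, names(x))
    if (anyNA(idx))
      stop("no signature named '", paste(i[is.na(idx)], collapse = ", "), "'")
    i <- idx
  }
  initialize(x, signatures = x@signatures[i])
})

#' @rdname accessors
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
setMethod("signatureNames", "ScoreMatrix", function(x) rownames(x@scores))

#' @rdname accessors
setMethod("sampleIds", "ScoreMatrix", function(x) colnames(x@scores))

#' @rdname accessors
setMethod("isZscored", "ScoreMatrix", function(x) x@zscored)

#' @rdname accessors
setMethod("scoreParams", "ScoreMatrix", function(x) x@params)

#' @rdname accessors
setMethod("highSamples", "ExtremeSelection", function(x) x@high_samples)

#' @rdname accessors
setMethod("lowSamples", "ExtremeSelection", function(x) x@low_samples)

#' @rdname accessors
setMethod("sampleIds", "RdiTable", function(x) x@sample_ids)

#' @rdname accessors
setMethod("sampleIds", "SurvivalTable", function(x) x@sample_ids)

#' @rdname accessors
setMethod("ppepValues", "PPEPMatrix", function(x) x@transformed)

#' @rdname accessors
setMethod("ppepLong", "PPEPMatrix", function(x) {
  d <- dim(x@transformed)
  pw <- rownames(x@transformed)
  ct <- colnames(x@transformed)
  adj <- apply(x@p_values, 2L, p.adjust, method = "BH")
  if (is.null(dim(adj))) adj <- matrix(adj, nrow = d[1L])
  data.frame(
    pathway = rep(pw, times = d[2L]),
    contrast = rep(ct, each = d[1L]),
    p = as.vector(x@p_values),
    adj_p = as.vector(adj),
    hits = as.vector(x@hits),
    transformed = as.vector(x@transformed),
    stringsAsFactors = FALSE)
})

# ---------------------------------------------------------------------------
# show methods

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes\n", object@name,
              object@direction, length(object@genes)))
  g <- object@genes
  cat("  ", paste(head(g, 8L), collapse = ", "),
      if (length(g) > 8L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection of %d signature(s)", length(object)))
  if (nzchar(object@source_label))
    cat(sprintf(" [%s]", object@source_label))
  cat("\n")
  if (length(object)) {
    sz <- vapply(object@signatures, function(s) length(s@genes), integer(1))
    info <- paste0(names(object), " (", sz, ")")
    cat("  ", paste(head(info, 6L), collapse = ", "),
        if (length(object) > 6L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@platform))
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d signature(s) x %d sample(s)%s\n",
              nrow(object@scores), ncol(object@scores),
              if (object@zscored) " (z-scored)" else ""))
  cat(sprintf("  params: alpha = %g, normalize = %s\n",
              object@params@alpha, object@params@normalize))
})

setMethod("show", "RdiTable", function(object) {
  cat(sprintf("RdiTable [%s]: %d samples (%d dependent, %d independent)\n",
              object@source, length(object@sample_ids),
              sum(object@dependency_label == "dependent"),
              sum(object@dependency_label == "independent")))
})

setMethod("show", "SurvivalTable", function(object) {
  cat(sprintf("SurvivalTable: %d samples, %d events (%.0f%% censored)\n",
              length(object@sample_ids), sum(object@event),
              100 * mean(object@event == 0L)))
})

setMethod("show", "ExtremeSelection", function(object) {
  cat(sprintf("ExtremeSelection on '%s': top %d vs bottom %d samples\n",
              object@score_source, object@k, object@k))
})

setMethod("show", "RdiComparison", function(object) {
  cat(sprintf("RdiComparison (%s) over %d tables\n", object@method,
              nrow(object@correlation)))
  print(round(object@correlation, 3))
})

setMethod("show", "PPEPMatrix", function(object) {
  cat(sprintf(
    "PPEPMatrix: %d pathway(s) x %d contrast(s), background %d genes\n",
    nrow(object@transformed), ncol(object@transformed),
    object@background_size))
  cat(sprintf("  %d nonzero cell(s)\n", sum(object@transformed != 0)))
})

setMethod("show", "SurvivalAssoc", function(object) {
  cat(sprintf("SurvivalAssoc '%s' (n = %d)\n", object@score_name, object@n))
  cat(sprintf("  Cox beta = %.4f, p = %.3g\n", object@cox_beta,
              object@cox_p))
  cat(sprintf("  GoodCount = %d / %d cuts, perm p = %.3g (B = %d)\n",
              object@good_count, object@n_cuts, object@perm_p, object@B))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d genes x %d samples [%s], |G| = %d, beta = %g, sigma = %g, seed = %d\n",
    object@n_genes, object@n_samples, object@platform,
    object@signature_size, object@beta, object@sigma, object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: gradient over %d samples, %d signature genes, %d pathway genes\n",
    length(object@gradient), length(object@directions),
    length(object@pathway_genes)))
})
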