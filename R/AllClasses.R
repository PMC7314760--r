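#' @import methods
#' @import SummarizedExperiment
#' @importFrom stats coef cor p.adjust pchisq phyper pt quantile
#'   rexp rnbinom rnorm runif sd setNames uniroot var
#' @importFrom utils head read.delim write.table
NULL

.DIRECTIONS <- c("undirected", "up", "dn")
.PLATFORMS <- c("intensity", "counts")
.RDI_SOURCES <- c("SF1B", "SF7", "other")

# ---------------------------------------------------------------------------
# GeneSignature

#' GeneSignature: a named gene set
#'
#' A named set of gene symbols, optionally carrying a direction tag when the
#' set is the up- or down-regulated half of a directional signature (the
#' colon Ras-dependency signature, for instance, is published as separate
#' "Up" and "Dn" subsets).
#'
#' @slot name single character, the signature name.
#' @slot genes character vector of unique gene symbols (non-empty).
#' @slot direction one of \code{"undirected"}, \code{"up"}, \code{"dn"}.
#' @export
setClass("GeneSignature",
  slots = c(name = "character", genes = "character", direction = "character"),
  prototype = prototype(direction = "undirected")
)

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) < 1L)
    msg <- c(msg, "a signature must contain at least one gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes in signature")
  if (length(object@direction) != 1L || !object@direction %in% .DIRECTIONS)
    msg <- c(msg, "'direction' must be one of undirected/up/dn")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' Duplicate genes are removed, keeping first occurrence order.
#'
#' @param name signature name.
#' @param genes character vector of gene symbols.
#' @param direction \code{"undirected"} (default), \code{"up"} or \code{"dn"}.
#' @return A \linkS4class{GeneSignature}.
#' @examples
#' GeneSignature("S1", c("A", "B", "A"))
#' @export
GeneSignature <- function(name, genes, direction = "undirected") {
  new("GeneSignature", name = as.character(name),
      genes = unique(as.character(genes)), direction = direction)
}

# ---------------------------------------------------------------------------
# SignatureCollection

#' SignatureCollection: an ordered list of gene signatures
#'
#' @slot signatures list of \linkS4class{GeneSignature} with unique names.
#' @slot source_label free-text provenance label (e.g. the GMT file name).
#' @export
setClass("SignatureCollection",
  slots = c(signatures = "list", source_label = "character"),
  prototype = prototype(signatures = list(), source_label = "")
)

setValidity("SignatureCollection", function(object) {
  msg <- character()
  ok <- vapply(object@signatures, is, logical(1), class2 = "GeneSignature")
  if (!all(ok)) msg <- c(msg, "all elements must be GeneSignature objects")
  nms <- vapply(object@signatures, function(s) s@name, character(1))
  if (anyDuplicated(nms))
    msg <- c(msg, sprintf("duplicate signature name(s): %s",
                          paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureCollection
#'
#' @param signatures list of \linkS4class{GeneSignature}.
#' @param source_label provenance label.
#' @return A \linkS4class{SignatureCollection}.
#' @export
SignatureCollection <- function(signatures = list(), source_label = "") {
  new("SignatureCollection", signatures = signatures,
      source_label = source_label)
}

# ---------------------------------------------------------------------------
# ExpressionMatrix

#' ExpressionMatrix: genes x samples expression values
#'
#' A thin extension of \link[SummarizedExperiment]{SummarizedExperiment}
#' holding one assay \code{"exprs"} plus a platform tag. \code{"intensity"}
#' marks log-scale microarray-like values; \code{"counts"} marks
#' non-negative integer RNA-seq-like counts. The row (gene) universe of an
#' ExpressionMatrix is the background for all enrichment tests.
#'
#' @slot platform \code{"intensity"} or \code{"counts"}.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(platform = "character"),
  prototype = prototype(platform = "intensity")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .PLATFORMS)
    msg <- c(msg, "'platform' must be 'intensity' or 'counts'")
  if (length(SummarizedExperiment::assays(object)) < 1L)
    return(c(msg, "one assay 'exprs' is required"))
  v <- SummarizedExperiment::assay(object, 1L)
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!all(is.finite(v)))
    msg <- c(msg, "all expression values must be finite")
  if (identical(object@platform, "counts") && all(is.finite(v))) {
    if (any(v < 0)) msg <- c(msg, "counts platform requires values >= 0")
    if (any(v != round(v)))
      msg <- c(msg, "counts platform requires integral values")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param platform \code{"intensity"} (default) or \code{"counts"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, platform = c("intensity", "counts")) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionMatrix", se, platform = platform)
}

# ---------------------------------------------------------------------------
# SsgseaParams / ScoreMatrix

#' ssGSEA scoring parameters
#'
#' @slot alpha non-negative rank-weighting exponent (default 0.25).
#' @slot normalize \code{"range"} (divide all scores by max - min over the
#'   score matrix, the original ssGSEA convention) or \code{"none"}.
#' @slot min_set_size smallest usable signature after intersection with the
#'   measured universe; smaller signatures are skipped with a warning.
#' @export
setClass("SsgseaParams",
  slots = c(alpha = "numeric", normalize = "character",
            min_set_size = "integer"),
  prototype = prototype(alpha = 0.25, normalize = "range",
                        min_set_size = 1L)
)

setValidity("SsgseaParams", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
      object@alpha < 0)
    msg <- c(msg, "'alpha' must be a single finite value >= 0")
  if (!object@normalize %in% c("none", "range"))
    msg <- c(msg, "'normalize' must be 'none' or 'range'")
  if (object@min_set_size < 1L)
    msg <- c(msg, "'min_set_size' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct ssGSEA parameters
#'
#' Ties in within-sample expression are always broken deterministically by
#' gene id, so repeated runs and platforms agree bit-for-bit.
#'
#' @param alpha rank-weighting exponent, \eqn{\ge 0}.
#' @param normalize \code{"range"} or \code{"none"}.
#' @param min_set_size minimum usable signature size.
#' @return An \linkS4class{SsgseaParams}.
#' @export
ssgseaParams <- function(alpha = 0.25, normalize = c("range", "none"),
                         min_set_size = 1L) {
  new("SsgseaParams", alpha = alpha, normalize = match.arg(normalize),
      min_set_size = as.integer(min_set_size))
}

#' ScoreMatrix: signatures x samples enrichment scores
#'
#' The computational Ras-dependency index container: one row per scored
#' signature, one column per sample. \code{zscored = TRUE} marks a matrix
#' whose rows have been standardised (mean 0, sample SD 1).
#'
#' @slot scores numeric matrix, signatures x samples.
#' @slot zscored logical flag.
#' @slot params the \linkS4class{SsgseaParams} used.
#' @export
setClass("ScoreMatrix",
  slots = c(scores = "matrix", zscored = "logical", params = "SsgseaParams"),
  prototype = prototype(zscored = FALSE)
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "scores must have signature rownames and sample colnames")
  if (isTRUE(object@zscored) && nrow(s) && ncol(s) >= 2L) {
    mu <- rowMeans(s)
    sdv <- apply(s, 1L, sd)
    if (any(abs(mu) > 1e-9) || any(abs(sdv - 1) > 1e-6))
      msg <- c(msg, "zscored matrix rows must have mean 0 and unit SD")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RdiTable / SurvivalTable

#' RdiTable: experimentally measured Ras dependency indices
#'
#' One row per sample: a raw measured value, a dependent/independent label,
#' and the provenance tag of the published table it mimics. \code{"SF7"}
#' sources must be strictly positive so the log10 transform is defined.
#'
#' @slot sample_ids unique sample identifiers.
#' @slot raw_values finite measured values.
#' @slot dependency_label \code{"dependent"} or \code{"independent"}.
#' @slot source \code{"SF1B"}, \code{"SF7"} or \code{"other"}.
#' @export
setClass("RdiTable",
  slots = c(sample_ids = "character", raw_values = "numeric",
            dependency_label = "character", source = "character"),
  prototype = prototype(source = "other")
)

setValidity("RdiTable", function(object) {
  msg <- character()
  n <- length(object@sample_ids)
  if (anyDuplicated(object@sample_ids))
    msg <- c(msg, "duplicate sample ids")
  if (length(object@raw_values) != n ||
      length(object@dependency_label) != n)
    msg <- c(msg, "sample_ids, raw_values and dependency_label lengths differ")
  if (!all(is.finite(object@raw_values)))
    msg <- c(msg, "raw_values must be finite")
  if (!all(object@dependency_label %in% c("dependent", "independent")))
    msg <- c(msg, "labels must be 'dependent' or 'independent'")
  if (length(object@source) != 1L || !object@source %in% .RDI_SOURCES)
    msg <- c(msg, "source must be SF1B, SF7 or other")
  if (identical(object@source, "SF7") && any(object@raw_values <= 0))
    msg <- c(msg, "SF7-type raw values must be > 0 (log10 must be defined)")
  if (length(msg)) msg else TRUE
})

#' Construct an RdiTable
#'
#' @param sample_ids sample identifiers.
#' @param raw_values measured dependency values.
#' @param dependency_label per-sample \code{"dependent"}/\code{"independent"}.
#' @param source provenance: \code{"SF1B"}, \code{"SF7"} or \code{"other"}.
#' @return An \linkS4class{RdiTable}.
#' @export
RdiTable <- function(sample_ids, raw_values, dependency_label,
                     source = c("other", "SF1B", "SF7")) {
  new("RdiTable", sample_ids = as.character(sample_ids),
      raw_values = as.numeric(raw_values),
      dependency_label = as.character(dependency_label),
      source = match.arg(source))
}

#' SurvivalTable: right-censored survival outcomes
#'
#' @slot sample_ids unique sample identifiers.
#' @slot time positive follow-up times.
#' @slot event 1 = event observed, 0 = censored.
#' @export
setClass("SurvivalTable",
  slots = c(sample_ids = "character", time = "numeric", event = "integer")
)

setValidity("SurvivalTable", function(object) {
  msg <- character()
  n <- length(object@sample_ids)
  if (anyDuplicated(object@sample_ids)) msg <- c(msg, "duplicate sample ids")
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "field lengths differ")
  if (!all(is.finite(object@time)) || any(object@time <= 0))
    msg <- c(msg, "time must be finite and > 0")
  if (!all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalTable
#'
#' @param sample_ids sample identifiers.
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return A \linkS4class{SurvivalTable}.
#' @export
SurvivalTable <- function(sample_ids, time, event) {
  new("SurvivalTable", sample_ids = as.character(sample_ids),
      time = as.numeric(time), event = as.integer(event))
}

# ---------------------------------------------------------------------------
# ExtremeSelection

#' ExtremeSelection: top-k / bottom-k samples of a score
#'
#' Operationalises the Ras-dependent / Ras-independent extremes of the
#' dependency continuum as the k highest- and k lowest-scoring samples.
#'
#' @slot high_samples k sample ids with the highest scores.
#' @slot low_samples k sample ids with the lowest scores (disjoint).
#' @slot k group size.
#' @slot score_source name of the scoring signature.
#' @export
setClass("ExtremeSelection",
  slots = c(high_samples = "character", low_samples = "character",
            k = "integer", score_source = "character")
)

setValidity("ExtremeSelection", function(object) {
  msg <- character()
  if (length(object@high_samples) != object@k ||
      length(object@low_samples) != object@k)
    msg <- c(msg, "high/low group sizes must equal k")
  if (length(intersect(object@high_samples, object@low_samples)))
    msg <- c(msg, "high and low groups must be disjoint")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RdiComparison

#' RdiComparison: correlation matrix across score/RDI tables
#'
#' Pairwise correlations between per-sample value vectors (computational
#' scores and experimental RDIs), computed on pairwise-complete shared
#' samples, with the shared-sample count recorded per pair.
#'
#' @slot correlation symmetric correlation matrix (unit diagonal; NA where a
#'   pair shares fewer than 3 samples).
#' @slot n_shared matrix of pairwise-complete sample counts.
#' @slot method \code{"pearson"} or \code{"spearman"}.
#' @export
setClass("RdiComparison",
  slots = c(correlation = "matrix", n_shared = "matrix", method = "character")
)

setValidity("RdiComparison", function(object) {
  msg <- character()
  cc <- object@correlation
  if (nrow(cc) != ncol(cc)) msg <- c(msg, "correlation must be square")
  if (!all(dim(cc) == dim(object@n_shared)))
    msg <- c(msg, "n_shared dimensions must match correlation")
  fin <- cc[is.finite(cc)]
  if (length(fin) && (any(fin > 1 + 1e-12) || any(fin < -1 - 1e-12)))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!object@method %in% c("pearson", "spearman"))
    msg <- c(msg, "method must be pearson or spearman")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# PPEPMatrix

#' PPEPMatrix: pathway x contrast enrichment pattern
#'
#' The collective pathway-enrichment pattern: per (pathway, contrast) cell a
#' one-sided Fisher over-representation p-value, the hit-gene count, and the
#' transformed value \eqn{-\log_{10}(p)} zeroed whenever \eqn{p \ge 0.05} or
#' fewer than 2 hit genes support the cell.
#'
#' @slot transformed pathways x contrasts matrix of zeroed
#'   \eqn{-\log_{10}(p)} values.
#' @slot p_values matching matrix of raw p-values.
#' @slot hits matching matrix of hit-gene counts.
#' @slot background_size number of genes in the measured universe.
#' @slot collection_label provenance of the pathway collection.
#' @export
setClass("PPEPMatrix",
  slots = c(transformed = "matrix", p_values = "matrix", hits = "matrix",
            background_size = "integer", collection_label = "character")
)

setValidity("PPEPMatrix", function(object) {
  msg <- character()
  d <- dim(object@transformed)
  if (!all(dim(object@p_values) == d) || !all(dim(object@hits) == d))
    msg <- c(msg, "matrix dimensions must agree")
  if (anyDuplicated(rownames(object@transformed)) ||
      anyDuplicated(colnames(object@transformed)))
    msg <- c(msg, "pathway and contrast labels must be unique")
  bad <- (object@p_values >= 0.05 | object@hits < 2L) &
    object@transformed != 0
  if (any(bad))
    msg <- c(msg, "cells with p >= 0.05 or hits < 2 must be zeroed")
  nz <- object@transformed[object@transformed != 0]
  if (length(nz) && any(nz <= -log10(0.05)))
    msg <- c(msg, "nonzero transformed values must exceed -log10(0.05)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SurvivalAssoc

#' SurvivalAssoc: score vs survival association summary
#'
#' Result of the gradient (cutpoint) scan: a univariate Cox fit plus, over a
#' grid of score cutpoints, two-group log-rank tests; \code{good_count} is
#' the number of cutpoints significant at \code{alpha}, and \code{perm_p}
#' its permutation p-value (add-one smoothed).
#'
#' @slot score_name label of the scanned score.
#' @slot n number of samples used.
#' @slot cox_beta Cox log hazard ratio per unit score.
#' @slot cox_p Wald p-value of the Cox coefficient.
#' @slot good_count number of cutpoints with log-rank p < alpha.
#' @slot n_cuts number of admissible cutpoints scanned.
#' @slot perm_p permutation p-value for good_count.
#' @slot B number of permutations behind perm_p.
#' @slot params scan settings (quantile window, min group fraction, alpha).
#' @slot cuts long per-cut table (cut, n_high, n_low, logrank_p).
#' @export
setClass("SurvivalAssoc",
  slots = c(score_name = "character", n = "integer", cox_beta = "numeric",
            cox_p = "numeric", good_count = "integer", n_cuts = "integer",
            perm_p = "numeric", B = "integer", params = "list",
            cuts = "data.frame")
)

setValidity("SurvivalAssoc", function(object) {
  msg <- character()
  if (object@good_count > object@n_cuts)
    msg <- c(msg, "good_count cannot exceed n_cuts")
  if (is.finite(object@perm_p) &&
      (object@perm_p < 1 / (object@B + 1) - 1e-12 || object@perm_p > 1))
    msg <- c(msg, "perm_p must lie in [1/(B+1), 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SimConfig / SimTruth

#' SimConfig: synthetic-data generator settings
#'
#' Defines a gene x sample simulation in which a latent per-sample
#' dependency gradient coordinately shifts the genes of a planted signature,
#' optionally shifts a planted pathway, and optionally drives survival
#' hazard. See \code{\link{simConfig}}.
#'
#' @slot n_genes,n_samples matrix dimensions.
#' @slot signature_size number of planted signature genes.
#' @slot beta gradient-to-signature effect size (log2 units per unit
#'   gradient).
#' @slot sigma residual SD on the log2 scale.
#' @slot platform \code{"intensity"} or \code{"counts"}.
#' @slot frac_down fraction of signature genes with negative direction.
#' @slot pathway_spec empty list, or list(size, log2_shift) for a planted
#'   pathway.
#' @slot survival_spec empty list, or list(hr, censoring) for survival
#'   generation.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  slots = c(n_genes = "integer", n_samples = "integer",
            signature_size = "integer", beta = "numeric", sigma = "numeric",
            platform = "character", frac_down = "numeric",
            pathway_spec = "list", survival_spec = "list", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_genes < 2L || object@n_samples < 2L)
    msg <- c(msg, "need at least 2 genes and 2 samples")
  if (object@signature_size >= object@n_genes)
    msg <- c(msg, "signature_size must be < n_genes")
  if (object@signature_size < 1L)
    msg <- c(msg, "signature_size must be >= 1")
  if (object@frac_down < 0 || object@frac_down > 1)
    msg <- c(msg, "frac_down must lie in [0, 1]")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (!object@platform %in% .PLATFORMS)
    msg <- c(msg, "platform must be intensity or counts")
  if (length(object@pathway_spec) &&
      !all(c("size", "log2_shift") %in% names(object@pathway_spec)))
    msg <- c(msg, "pathway_spec needs 'size' and 'log2_shift'")
  if (length(object@pathway_spec) &&
      isTRUE(object@pathway_spec$size + object@signature_size >=
               object@n_genes))
    msg <- c(msg, "planted pathway + signature must fit inside n_genes")
  if (length(object@survival_spec)) {
    if (!all(c("hr", "censoring") %in% names(object@survival_spec)))
      msg <- c(msg, "survival_spec needs 'hr' and 'censoring'")
    else if (object@survival_spec$hr <= 0)
      msg <- c(msg, "hazard ratio must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults describe the reference simulated cohort used throughout the
#' package tests: 2000 genes x 60 samples, a 50-gene signature shifted by
#' beta = 1 log2 unit per unit gradient against residual SD 0.5, half the
#' signature genes down-regulated.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param signature_size planted signature size.
#' @param beta effect size (log2 units per unit of the latent gradient).
#' @param sigma residual SD (log2 scale).
#' @param platform \code{"intensity"} or \code{"counts"}.
#' @param frac_down fraction of signature genes pointing down.
#' @param pathway_spec optional \code{list(size =, log2_shift =)} planting a
#'   pathway whose genes track the gradient.
#' @param survival_spec optional \code{list(hr =, censoring =)}: hazard
#'   ratio per SD of gradient and target censoring fraction.
#' @param seed RNG seed.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' simConfig(n_genes = 200, n_samples = 20, signature_size = 10, seed = 7)
#' @export
simConfig <- function(n_genes = 2000L, n_samples = 60L,
                      signature_size = 50L, beta = 1, sigma = 0.5,
                      platform = c("intensity", "counts"), frac_down = 0.5,
                      pathway_spec = list(), survival_spec = list(),
                      seed = 1L) {
  new("SimConfig", n_genes = as.integer(n_genes),
      n_samples = as.integer(n_samples),
      signature_size = as.integer(signature_size),
      beta = as.numeric(beta), sigma = as.numeric(sigma),
      platform = match.arg(platform), frac_down = as.numeric(frac_down),
      pathway_spec = pathway_spec, survival_spec = survival_spec,
      seed = as.integer(seed))
}

#' SimTruth: planted ground truth of a simulated dataset
#'
#' @slot gradient named per-sample latent dependency gradient in [-1, 1].
#' @slot directions named +1/-1 vector over the planted signature genes.
#' @slot pathway_genes genes of the planted pathway (may be empty).
#' @slot pathway_shift log2 shift of the planted pathway between gradient
#'   extremes (0 when no pathway planted).
#' @slot linear_predictor named per-sample survival linear predictor
#'   (empty when no survival spec).
#' @export
setClass("SimTruth",
  slots = c(gradient = "numeric", directions = "numeric",
            pathway_genes = "character", pathway_shift = "numeric",
            linear_predictor = "numeric"),
  prototype = prototype(pathway_genes = character(), pathway_shift = 0,
                        linear_predictor = numeric())
)
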