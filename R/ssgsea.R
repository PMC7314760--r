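# Single-sample GSEA: the per-sample enrichment score behind the
# computational Ras dependency index.
#
# For one sample, genes are ranked by expression (highest expression gets
# rank N; ties broken by gene id so scores are reproducible across runs and
# platforms). Walking the ordering from highest to lowest, the score is the
# summed difference between the rank-weighted ECDF of the in-set genes and
# the uniform ECDF of the out-of-set genes:
#
#   ES = sum_i [ P_in(i) - P_out(i) ]
#   P_in(i)  = sum_{set genes seen by i} rank^alpha / sum_{set genes} rank^alpha
#   P_out(i) = (# non-set genes seen by i) / (N - m)
#
# A positive ES means the signature is coordinately up-regulated in that
# sample, a negative ES coordinately down-regulated.

# ES values for all signatures in one sample, given the walk order.
# memb: list of logical vectors over genes; w: rank^alpha along the walk.
.esOneSample <- function(ord, memb, w, N) {
  vapply(memb, function(mb) {
    ind <- mb[ord]
    m <- sum(ind)
    win <- w * ind
    sum(cumsum(win) / sum(win) - cumsum(!ind) / (N - m))
  }, numeric(1))
}

#' Score samples against gene signatures (ssGSEA)
#'
#' Computes the per-sample enrichment score of each signature in
#' \code{collection} against \code{expr}. Signature genes absent from the
#' expression matrix are silently dropped; signatures whose measured overlap
#' is below \code{min_set_size}, or that cover the whole gene universe (the
#' out-of-set walk would be undefined), are skipped with a warning. With
#' \code{normalize = "range"} all scores are divided by (max - min) over
#' the whole score matrix.
#'
#' @param expr an \linkS4class{ExpressionMatrix}. Count matrices are scored
#'   on their raw counts; scores depend only on within-sample ranks, so any
#'   monotone normalisation yields identical scores.
#' @param collection a \linkS4class{SignatureCollection} or a single
#'   \linkS4class{GeneSignature}.
#' @param params an \linkS4class{SsgseaParams} (see
#'   \code{\link{ssgseaParams}}).
#' @param uppercase upper-case signature genes before matching.
#' @return A \linkS4class{ScoreMatrix} (signatures x samples).
#' @examples
#' m <- matrix(c(4, 3, 2, 1), 4, 1,
#'             dimnames = list(paste0("g", 1:4), "s1"))
#' sig <- GeneSignature("top", "g1")
#' scoreValues(ssgseaScore(ExpressionMatrix(m), sig,
#'                         ssgseaParams(normalize = "none")))  # ES = 2
#' @export
ssgseaScore <- function(expr, collection, params = ssgseaParams(),
                        uppercase = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"), is(params, "SsgseaParams"))
  if (is(collection, "GeneSignature"))
    collection <- SignatureCollection(list(collection))
  stopifnot(is(collection, "SignatureCollection"))
  vals <- exprValues(expr)
  N <- nrow(vals)
  gid <- rownames(vals)
  const <- which(apply(vals, 2L, function(v) max(v) == min(v)))
  if (length(const))
    stop("all-constant expression in sample(s): ",
         paste(colnames(vals)[const], collapse = ", "),
         " (ranking undefined)")

  gidN <- .normGenes(gid, uppercase)
  memb <- list()
  for (i in seq_len(length(collection))) {
    s <- collection[[i]]
    g <- intersect(.normGenes(sigGenes(s), uppercase), gidN)
    m <- length(g)
    if (m < params@min_set_size) {
      warning(sprintf(
        "skipping signature '%s': %d measured gene(s) < min_set_size %d",
        sigName(s), m, params@min_set_size))
      next
    }
    if (m >= N) {
      warning(sprintf(
        "skipping signature '%s': covers the whole gene universe",
        sigName(s)))
      next
    }
    memb[[sigName(s)]] <- gidN %in% g
  }
  if (!length(memb))
    stop("no scorable signatures after filtering")

  w <- (N - seq_len(N) + 1L)^params@alpha
  es <- matrix(NA_real_, nrow = length(memb), ncol = ncol(vals),
               dimnames = list(names(memb), colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    ord <- order(-vals[, j], gid)
    es[, j] <- .esOneSample(ord, memb, w, N)
  }
  if (params@normalize == "range") {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
    else warning("score range is zero; skipping range normalization")
  }
  new("ScoreMatrix", scores = es, zscored = FALSE, params = params)
}

#' Combine directional signature halves into one score
#'
#' Scores the up- and down-regulated halves of a directional signature
#' separately, then combines them per sample as
#' \code{z(ES_up) - z(ES_dn)} (row z-scores, sample SD), so that a sample
#' coordinately high in the up genes and low in the down genes scores
#' highest. The separate Up/Dn rows are always retained alongside the
#' combined row. With a missing down subset the combined score degenerates
#' to \code{z(ES_up)}.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param signature_up \linkS4class{GeneSignature}, the up-regulated half.
#' @param signature_dn \linkS4class{GeneSignature} or NULL.
#' @param params an \linkS4class{SsgseaParams}.
#' @param combined_name row name for the combined score; default: the up
#'   name with its \code{_Up} suffix replaced by \code{_combined}.
#' @param uppercase upper-case signature genes before matching.
#' @return A \linkS4class{ScoreMatrix} with the Up row, the Dn row (when
#'   present) and the combined row.
#' @export
scoreDirectional <- function(expr, signature_up, signature_dn = NULL,
                             params = ssgseaParams(), combined_name = NULL,
                             uppercase = TRUE) {
  stopifnot(is(signature_up, "GeneSignature"))
  sigs <- list(signature_up)
  if (!is.null(signature_dn)) {
    stopifnot(is(signature_dn, "GeneSignature"))
    sigs <- c(sigs, list(signature_dn))
  }
  sm <- ssgseaScore(expr, SignatureCollection(sigs), params = params,
                    uppercase = uppercase)
  es <- scoreValues(sm)
  if (!sigName(signature_up) %in% rownames(es))
    stop("up subset was skipped; cannot form a combined score")
  zu <- zscoreValues(es[sigName(signature_up), ])
  zd <- if (!is.null(signature_dn) &&
            sigName(signature_dn) %in% rownames(es))
    zscoreValues(es[sigName(signature_dn), ])
  else 0
  comb <- zu - zd
  if (is.null(combined_name)) {
    combined_name <- sub("_Up$", "", sigName(signature_up),
                         ignore.case = TRUE)
    combined_name <- paste0(combined_name, "_combined")
  }
  out <- rbind(es, matrix(comb, nrow = 1L,
                          dimnames = list(combined_name, colnames(es))))
  new("ScoreMatrix", scores = out, zscored = FALSE, params = params)
}

#' Row-standardise a ScoreMatrix
#'
#' Converts each signature row to z-scores (mean 0, sample SD 1) across a
#' cohort of samples, the standardisation applied to both computational
#' scores and experimental RDI values before they are compared.
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @param cohort optional character vector of sample ids whose mean/SD
#'   define the standardisation (default: all samples).
#' @param ... unused.
#' @return A z-scored \linkS4class{ScoreMatrix} (same dimensions).
#' @name zscoreRows
#' @export
setMethod("zscoreRows", "ScoreMatrix", function(x, cohort = NULL, ...) {
  s <- scoreValues(x)
  z <- t(apply(s, 1L, zscoreValues, cohort = cohort))
  dimnames(z) <- dimnames(s)
  zs <- is.null(cohort) || setequal(cohort, colnames(s))
  new("ScoreMatrix", scores = z, zscored = zs, params = scoreParams(x))
})
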