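# Pairwise signature-overlap enrichment: for each unordered pair of gene
# sets, a one-sided Fisher exact test on the 2x2 table (overlap, a-only,
# b-only, neither) against the measured gene universe.

# One-sided over-representation p for a 2x2 table: P(X >= k) where
# X ~ Hypergeometric(white = K, black = N - K, drawn = n). Identical to
# fisher.test(..., alternative = "greater")$p.value.
.overRepP <- function(k, K, n, N) {
  stopifnot(N >= 1L, K <= N, n <= N, k <= min(K, n))
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Pairwise signature-overlap enrichment
#'
#' For every unordered pair of signatures in \code{collection}, counts the
#' shared genes and tests over-representation of the overlap with a
#' one-sided Fisher exact test, using the genes of the measured expression
#' universe as the background of the 2x2 contingency table. Signatures are
#' first intersected with the universe; a signature with an empty
#' intersection still yields rows (n = 0, p = 1) plus a warning.
#'
#' @param collection a \linkS4class{SignatureCollection}.
#' @param universe_genes character vector of background gene ids (typically
#'   \code{geneIds(expr)}), or an \linkS4class{ExpressionMatrix}.
#' @param alternative \code{"greater"} (over-enrichment, default) or
#'   \code{"two.sided"} (delegated to \code{\link[stats]{fisher.test}}).
#' @param uppercase upper-case ids before matching (default TRUE).
#' @return A \code{data.frame} with one row per unordered pair: sig_a,
#'   sig_b, n_a, n_b, n_overlap, n_background, p_value.
#' @examples
#' uni <- paste0("G", 1:20)
#' cc <- SignatureCollection(list(GeneSignature("A", paste0("G", 1:5)),
#'                                GeneSignature("B", paste0("G", 2:5))))
#' signatureOverlapMatrix(cc, uni)  # p = 16/15504
#' @export
signatureOverlapMatrix <- function(collection, universe_genes,
                                   alternative = c("greater", "two.sided"),
                                   uppercase = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(is(collection, "SignatureCollection"))
  if (is(universe_genes, "ExpressionMatrix"))
    universe_genes <- geneIds(universe_genes)
  universe <- unique(.normGenes(universe_genes, uppercase))
  if (!length(universe)) stop("universe must be non-empty")
  N <- length(universe)
  nms <- names(collection)
  sets <- lapply(seq_along(nms), function(i)
    intersect(.normGenes(sigGenes(collection[[i]]), uppercase), universe))
  empty <- nms[lengths(sets) == 0L]
  if (length(empty))
    warning("signature(s) with empty universe intersection: ",
            paste(empty, collapse = ", "))
  if (length(nms) < 2L)
    return(data.frame(sig_a = character(), sig_b = character(),
                      n_a = integer(), n_b = integer(),
                      n_overlap = integer(), n_background = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  pairs <- utils::combn(seq_along(nms), 2L)
  res <- apply(pairs, 2L, function(ij) {
    a <- sets[[ij[[1L]]]]; b <- sets[[ij[[2L]]]]
    k <- length(intersect(a, b))
    p <- if (alternative == "greater") {
      .overRepP(k, length(a), length(b), N)
    } else {
      m <- matrix(c(k, length(a) - k, length(b) - k,
                    N - length(a) - length(b) + k), 2L)
      stats::fisher.test(m, alternative = "two.sided")$p.value
    }
    c(n_a = length(a), n_b = length(b), n_overlap = k, p_value = p)
  })
  data.frame(sig_a = nms[pairs[1L, ]], sig_b = nms[pairs[2L, ]],
             n_a = as.integer(res["n_a", ]),
             n_b = as.integer(res["n_b", ]),
             n_overlap = as.integer(res["n_overlap", ]),
             n_background = N,
             p_value = res["p_value", ],
             stringsAsFactors = FALSE)
}

#' Render pairwise overlaps as a square matrix
#'
#' Upper triangle: enrichment p-values; lower triangle: overlap counts;
#' diagonal: signature sizes within the universe — the layout used for
#' published overlap tables.
#'
#' @param overlaps result of \code{\link{signatureOverlapMatrix}}.
#' @param sizes optional named vector of diagonal sizes; inferred from the
#'   pair rows when omitted.
#' @return A numeric matrix.
#' @export
overlapAsMatrix <- function(overlaps, sizes = NULL) {
  nms <- unique(c(overlaps$sig_a, overlaps$sig_b))
  m <- matrix(NA_real_, length(nms), length(nms),
              dimnames = list(nms, nms))
  for (r in seq_len(nrow(overlaps))) {
    i <- overlaps$sig_a[[r]]; j <- overlaps$sig_b[[r]]
    m[i, j] <- overlaps$p_value[[r]]
    m[j, i] <- overlaps$n_overlap[[r]]
    m[i, i] <- overlaps$n_a[[r]]
    m[j, j] <- overlaps$n_b[[r]]
  }
  if (!is.null(sizes)) diag(m)[names(sizes)] <- sizes
  m
}
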