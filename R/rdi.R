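# Computational RDI handling: z-score standardisation, the log10/sign
# transform of measured dependency tables, correlation matrices between
# score tables, and selection of the dependency extremes.

#' Standardise values to z-scores over a cohort
#'
#' Standardises \code{x} using the mean and sample SD (denominator n - 1)
#' of a reference cohort — all values by default, or a named subset, so a
#' score can be standardised "across the original cell lines" or "across
#' all lines" interchangeably.
#'
#' @param x numeric vector (named when \code{cohort} selects by name).
#' @param cohort NULL (use all values), or names/indices of the values
#'   whose mean/SD define the standardisation; all of \code{x} is
#'   transformed with those statistics.
#' @return Numeric vector of z-scores, same names as \code{x}.
#' @examples
#' zscoreValues(c(1, 2, 3))  # -1 0 1
#' @export
zscoreValues <- function(x, cohort = NULL) {
  ref <- if (is.null(cohort)) x else x[cohort]
  if (anyNA(ref)) stop("cohort selects missing values")
  if (length(ref) < 2L) stop("need >= 2 values to standardize")
  s <- sd(ref)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score")
  (x - mean(ref)) / s
}

#' Transform a measured RDI table onto the dependency scale
#'
#' Raw values are transformed by base-10 logarithm and multiplied by -1 for
#' Ras-dependent lines or +1 for Ras-independent lines, so that larger
#' transformed values mean stronger Ras dependency; the transformed values
#' are then standardised to z-scores across the table's samples (disable
#' with \code{standardize = FALSE} to inspect the pre-z values).
#'
#' @param rdi an \linkS4class{RdiTable} with strictly positive raw values.
#' @param standardize z-score the transformed values (default TRUE).
#' @return Named numeric vector (names = sample ids).
#' @examples
#' r <- RdiTable("c1", 0.1, "dependent", source = "SF7")
#' transformRdiSf7(r, standardize = FALSE)  # +1
#' @export
transformRdiSf7 <- function(rdi, standardize = TRUE) {
  stopifnot(is(rdi, "RdiTable"))
  bad <- which(rdi@raw_values <= 0)
  if (length(bad))
    stop("non-positive raw RDI value for sample(s): ",
         paste(rdi@sample_ids[bad], collapse = ", "))
  sgn <- ifelse(rdi@dependency_label == "dependent", -1, 1)
  t <- sgn * log10(rdi@raw_values)
  names(t) <- rdi@sample_ids
  if (standardize) zscoreValues(t) else t
}

#' Correlation matrix across score and RDI tables
#'
#' Pairwise correlations between named per-sample value vectors
#' (computational scores, transformed experimental RDIs, ...), each pair
#' computed on its pairwise-complete shared samples. Pairs sharing fewer
#' than 3 samples get a missing entry and a warning; the shared-sample
#' count is recorded per pair.
#'
#' @param tables named list of named numeric vectors.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return An \linkS4class{RdiComparison}.
#' @export
correlationMatrix <- function(tables, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(tables) < 2L) stop("need >= 2 tables")
  if (is.null(names(tables)) || anyDuplicated(names(tables)))
    stop("tables must have unique names")
  nt <- length(tables)
  nms <- names(tables)
  cc <- diag(1, nt); nmat <- matrix(0L, nt, nt)
  dimnames(cc) <- dimnames(nmat) <- list(nms, nms)
  for (i in seq_len(nt)) {
    xi <- tables[[i]]
    nmat[i, i] <- sum(is.finite(xi))
    for (j in seq_len(nt)) {
      if (j <= i) next
      xj <- tables[[j]]
      shared <- intersect(names(xi)[is.finite(xi)],
                          names(xj)[is.finite(xj)])
      nmat[i, j] <- nmat[j, i] <- length(shared)
      if (length(shared) < 3L) {
        warning(sprintf("pair (%s, %s) shares %d sample(s) (< 3): set NA",
                        nms[[i]], nms[[j]], length(shared)))
        cc[i, j] <- cc[j, i] <- NA_real_
      } else {
        cc[i, j] <- cc[j, i] <- cor(xi[shared], xj[shared],
                                    method = method)
      }
    }
  }
  new("RdiComparison", correlation = cc, n_shared = nmat, method = method)
}

#' Select the dependency extremes of a score
#'
#' Returns the k highest-scoring (putatively Ras-dependent) and k
#' lowest-scoring (putatively Ras-independent) samples. Boundary ties are
#' broken by sample id (lexicographically smaller id selected first), so
#' selections are deterministic; the two groups are always disjoint.
#'
#' @param scores named numeric vector of per-sample scores, or a
#'   \linkS4class{ScoreMatrix} (then \code{signature} picks the row).
#' @param k group size (needs at least 2k samples).
#' @param signature row name when \code{scores} is a ScoreMatrix; default
#'   the first row.
#' @param score_source label stored in the result.
#' @return An \linkS4class{ExtremeSelection}.
#' @examples
#' s <- c(s1 = 5, s2 = 1, s3 = 3, s4 = 2, s5 = 4)
#' selectExtremes(s, k = 2)  # high {s1,s5}, low {s2,s4}
#' @export
selectExtremes <- function(scores, k, signature = NULL,
                           score_source = NULL) {
  if (is(scores, "ScoreMatrix")) {
    sv <- scoreValues(scores)
    if (is.null(signature)) signature <- rownames(sv)[[1L]]
    if (is.null(score_source)) score_source <- signature
    scores <- sv[signature, ]
  }
  if (is.null(score_source)) score_source <- "score"
  k <- as.integer(k)
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must carry unique sample names")
  n <- length(scores)
  if (n < 2L * k)
    stop(sprintf("need >= %d samples for k = %d (have %d)", 2L * k, k, n))
  ids <- names(scores)
  high <- ids[order(-scores, ids)][seq_len(k)]
  rest <- setdiff(ids, high)
  low <- rest[order(scores[rest], rest)][seq_len(k)]
  new("ExtremeSelection", high_samples = high, low_samples = low, k = k,
      score_source = score_source)
}

#' Per-group extreme selection with a pooled contrast
#'
#' Applies \code{\link{selectExtremes}} within each tissue (or other)
#' group, and adds a pooled contrast combining all per-group highs against
#' all per-group lows — the "Hi_vs_Lo pooled" design used when several
#' tissue types are analysed together.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param k per-group group size.
#' @param groups named character/factor of group labels, aligned by sample
#'   name to \code{scores}.
#' @param score_source label stored in the results.
#' @return Named list of \linkS4class{ExtremeSelection}: one per group plus
#'   \code{"pooled"}.
#' @export
selectExtremesByGroup <- function(scores, k, groups,
                                  score_source = "score") {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  miss <- setdiff(names(scores), names(groups))
  if (length(miss))
    stop("no group label for sample(s): ", paste(miss, collapse = ", "))
  gl <- split(names(scores), as.character(groups[names(scores)]))
  sel <- lapply(gl, function(ids)
    selectExtremes(scores[ids], k, score_source = score_source))
  pooled <- new("ExtremeSelection",
                high_samples = unlist(lapply(sel, highSamples),
                                      use.names = FALSE),
                low_samples = unlist(lapply(sel, lowSamples),
                                     use.names = FALSE),
                k = as.integer(k * length(sel)),
                score_source = score_source)
  c(sel, list(pooled = pooled))
}
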