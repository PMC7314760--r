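# Differential expression between dependency extremes. The internal default
# test is a per-gene Welch two-sample t-test with Benjamini-Hochberg
# adjustment — a deliberately simple, method-agnostic default; externally
# computed lists (limma, DESeq2, edgeR, limma-voom, ...) flow in through
# importDegList(), so the downstream pathway analysis does not depend on
# any one DE method.

#' DEG thresholds
#'
#' @param adj_p_max maximum BH-adjusted p (default 0.05).
#' @param min_fold_change minimum linear fold change (default 1.5; applied
#'   as |log2 fold change| >= log2(min_fold_change)).
#' @return A list of class \code{"DegThresholds"}.
#' @export
degThresholds <- function(adj_p_max = 0.05, min_fold_change = 1.5) {
  if (!(adj_p_max > 0 && adj_p_max <= 1))
    stop("adj_p_max must lie in (0, 1]")
  if (min_fold_change < 1) stop("min_fold_change must be >= 1")
  structure(list(adj_p_max = adj_p_max,
                 min_fold_change = min_fold_change),
            class = "DegThresholds")
}

#' Contrast label in the High-vs-Low naming convention
#'
#' E.g. \code{contrastLabel("L")} with default thresholds gives
#' \code{"L_High_vs_L_Low_AdjP0_05FC1_5"}.
#'
#' @param group group/tissue prefix.
#' @param thresholds a \code{\link{degThresholds}} list.
#' @return Single character label.
#' @export
contrastLabel <- function(group, thresholds = degThresholds()) {
  fmt <- function(x) gsub(".", "_", format(x, trim = TRUE), fixed = TRUE)
  sprintf("%s_High_vs_%s_Low_AdjP%sFC%s", group, group,
          fmt(thresholds$adj_p_max), fmt(thresholds$min_fold_change))
}

# Vectorised Welch two-sample t-test over matrix rows.
# Returns data.frame(diff, t, df, p). Cross-checked against stats::t.test
# in the test suite.
.welchRows <- function(x_high, x_low) {
  n1 <- ncol(x_high); n2 <- ncol(x_low)
  m1 <- rowMeans(x_high); m2 <- rowMeans(x_low)
  v1 <- rowSums((x_high - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x_low - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tt), df)
  data.frame(diff = m1 - m2, t = tt, df = df, p = p)
}

.cpmLog2 <- function(counts, pseudo = 0.5) {
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  log2(cpm + pseudo)
}

#' Differential expression between extreme groups
#'
#' Per-gene Welch two-sample t-test of the high group against the low
#' group. Intensity-platform values are tested as given (assumed log
#' scale), with \code{log2_fc = mean(high) - mean(low)}; count matrices are
#' first transformed to \code{log2(CPM + 0.5)}. Genes with zero variance in
#' both groups are excluded from testing (their ids are attached as
#' attribute \code{"excluded_genes"}). P-values are Benjamini-Hochberg
#' adjusted over the tested genes, and records are filtered to
#' \code{adj_p <= adj_p_max} and \code{|log2_fc| >= log2(min_fold_change)}
#' unless \code{filter = FALSE}.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param selection an \linkS4class{ExtremeSelection} (both groups >= 2).
#' @param thresholds a \code{\link{degThresholds}} list.
#' @param filter apply the thresholds (default TRUE); when FALSE the full
#'   tested table is returned.
#' @return \code{data.frame} with columns gene, log2_fc, p, adj_p,
#'   direction (\code{"up_in_high"} / \code{"down_in_high"}); attributes
#'   \code{"n_tested"} and \code{"excluded_genes"}.
#' @export
differentialExpression <- function(expr, selection,
                                   thresholds = degThresholds(),
                                   filter = TRUE) {
  stopifnot(is(expr, "ExpressionMatrix"),
            is(selection, "ExtremeSelection"),
            inherits(thresholds, "DegThresholds"))
  hi <- highSamples(selection); lo <- lowSamples(selection)
  if (length(hi) < 2L || length(lo) < 2L)
    stop("both groups need >= 2 samples")
  miss <- setdiff(c(hi, lo), sampleIds(expr))
  if (length(miss))
    stop("selected sample(s) absent from expression matrix: ",
         paste(miss, collapse = ", "))
  vals <- exprValues(expr)
  if (exprPlatform(expr) == "counts") vals <- .cpmLog2(vals)
  xh <- vals[, hi, drop = FALSE]
  xl <- vals[, lo, drop = FALSE]
  novar <- apply(xh, 1L, var) == 0 & apply(xl, 1L, var) == 0
  excluded <- rownames(vals)[novar]
  if (any(novar)) {
    message(sum(novar), " gene(s) with zero variance in both groups excluded")
    xh <- xh[!novar, , drop = FALSE]
    xl <- xl[!novar, , drop = FALSE]
  }
  if (!nrow(xh)) stop("no testable genes left")
  w <- .welchRows(xh, xl)
  res <- data.frame(
    gene = rownames(xh),
    log2_fc = w$diff,
    p = w$p,
    adj_p = p.adjust(w$p, method = "BH"),
    stringsAsFactors = FALSE)
  res$direction <- ifelse(res$log2_fc > 0, "up_in_high", "down_in_high")
  n_tested <- nrow(res)
  if (filter) {
    res <- res[res$adj_p <= thresholds$adj_p_max &
                 abs(res$log2_fc) >= log2(thresholds$min_fold_change), ,
               drop = FALSE]
    res <- res[order(res$p, res$gene), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "excluded_genes") <- excluded
  res
}

#' Import an externally computed DEG list
#'
#' Reads a TSV with required columns \code{gene}, \code{log2_fc}, \code{p},
#' \code{adj_p} (e.g. exported from limma, DESeq2 or edgeR), validates it
#' (adjusted p must be >= raw p), fills in the direction column, and
#' optionally re-applies thresholds.
#'
#' @param path TSV path.
#' @param thresholds optional \code{\link{degThresholds}} list to re-apply.
#' @param uppercase upper-case gene ids (default TRUE).
#' @return \code{data.frame} of validated DEG records.
#' @export
importDegList <- function(path, thresholds = NULL, uppercase = TRUE) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "log2_fc", "p", "adj_p")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty DEG table: ", path)
    df$direction <- character(0)
    return(df[c(need, "direction")])
  }
  bad <- which(df$adj_p < df$p)
  if (length(bad))
    stop(sprintf("adj_p < p at row %d (gene '%s')", bad[[1L]],
                 df$gene[[bad[[1L]]]]))
  if (any(df$p <= 0 | df$p > 1 | df$adj_p > 1))
    stop("p and adj_p must lie in (0, 1]")
  df$gene <- .normGenes(df$gene, uppercase)
  df$direction <- ifelse(df$log2_fc > 0, "up_in_high", "down_in_high")
  if (!is.null(thresholds)) {
    stopifnot(inherits(thresholds, "DegThresholds"))
    df <- df[df$adj_p <= thresholds$adj_p_max &
               abs(df$log2_fc) >= log2(thresholds$min_fold_change), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  df[c(need, "direction")]
}

#' Write a DEG table as TSV
#'
#' @param deg DEG \code{data.frame} (as from
#'   \code{\link{differentialExpression}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDegList <- function(deg, path) {
  write.table(deg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
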