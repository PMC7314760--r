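# PPEP: pathway-pattern analysis of DEG lists. Each DEG list (contrast) is
# tested for over-representation against every pathway of a collection with
# a one-sided Fisher exact test on the measured gene universe; p-values are
# transformed to -log10(p) and zeroed whenever p >= 0.05 or the cell is
# supported by fewer than 2 hit genes, giving the sparse pathway x contrast
# pattern matrix used for theme discovery. No multiple-testing correction
# enters the zeroing rule (a BH column is available in the long-format
# output for inspection only).

.PPEP_P_CUTOFF <- 0.05
.PPEP_MIN_HITS <- 2L

#' Fisher over-representation of a gene list in a pathway
#'
#' One-sided Fisher exact test (over-enrichment) on the 2x2 table (hit,
#' list-only, pathway-only, neither) over the measured gene universe. The
#' gene list and the pathway are both intersected with the universe first.
#' An empty gene list gives p = 1 with 0 hits.
#'
#' @param deg_genes character vector of gene ids (a DEG list).
#' @param pathway a \linkS4class{GeneSignature} or character vector.
#' @param universe background gene ids (the measured universe), or an
#'   \linkS4class{ExpressionMatrix}.
#' @param uppercase upper-case ids before matching.
#' @return \code{list(p =, hits =)}.
#' @examples
#' fisherEnrichment(paste0("G", 1:5), paste0("G", 2:5),
#'                  paste0("G", 1:20))  # p = 16/15504
#' @export
fisherEnrichment <- function(deg_genes, pathway, universe,
                             uppercase = TRUE) {
  if (is(universe, "ExpressionMatrix")) universe <- geneIds(universe)
  universe <- unique(.normGenes(universe, uppercase))
  if (!length(universe)) stop("universe must be non-empty")
  if (is(pathway, "GeneSignature")) pathway <- sigGenes(pathway)
  pw <- intersect(.normGenes(pathway, uppercase), universe)
  dg <- intersect(unique(.normGenes(deg_genes, uppercase)), universe)
  hits <- length(intersect(dg, pw))
  if (!length(dg)) return(list(p = 1, hits = 0L))
  list(p = .overRepP(hits, length(pw), length(dg), length(universe)),
       hits = as.integer(hits))
}

#' Assemble the PPEP pathway x contrast pattern matrix
#'
#' Runs \code{\link{fisherEnrichment}} for every (pathway, contrast) pair
#' and applies the transform \code{-log10(p)}, zeroing every cell with
#' \code{p >= 0.05} or fewer than 2 hit genes. Zeros stay explicit so
#' downstream heatmaps align across contrasts; rows that are zero
#' everywhere can be pruned with \code{prune_empty}.
#'
#' @param deg_lists named list; each element a character vector of DEG gene
#'   ids for one contrast (unique contrast names required).
#' @param collection pathway \linkS4class{SignatureCollection}.
#' @param universe background gene ids or \linkS4class{ExpressionMatrix}.
#' @param prune_empty drop all-zero pathway rows (default FALSE).
#' @param uppercase upper-case ids before matching.
#' @return A \linkS4class{PPEPMatrix}.
#' @export
ppepMatrix <- function(deg_lists, collection, universe,
                       prune_empty = FALSE, uppercase = TRUE) {
  stopifnot(is(collection, "SignatureCollection"))
  if (!length(deg_lists) || !length(collection))
    stop("need >= 1 DEG list and >= 1 pathway")
  if (is.null(names(deg_lists)) || anyDuplicated(names(deg_lists)))
    stop("duplicate or missing contrast names")
  if (is(universe, "ExpressionMatrix")) universe <- geneIds(universe)
  universe <- unique(.normGenes(universe, uppercase))
  pw_names <- names(collection)
  p <- h <- matrix(NA_real_, length(pw_names), length(deg_lists),
                   dimnames = list(pw_names, names(deg_lists)))
  for (j in seq_along(deg_lists)) {
    for (i in seq_along(pw_names)) {
      fe <- fisherEnrichment(deg_lists[[j]], collection[[i]], universe,
                             uppercase = uppercase)
      p[i, j] <- fe$p
      h[i, j] <- fe$hits
    }
  }
  tr <- ifelse(p < .PPEP_P_CUTOFF & h >= .PPEP_MIN_HITS, -log10(p), 0)
  if (prune_empty) {
    keep <- rowSums(tr != 0) > 0
    tr <- tr[keep, , drop = FALSE]
    p <- p[keep, , drop = FALSE]
    h <- h[keep, , drop = FALSE]
  }
  storage.mode(h) <- "integer"
  new("PPEPMatrix", transformed = tr, p_values = p, hits = h,
      background_size = length(universe),
      collection_label = sourceLabel(collection))
}

#' Retrieve the hit genes of a pathway from a DEG table
#'
#' Subsets a DEG record table (as produced by
#' \code{\link{differentialExpression}} or \code{\link{importDegList}}) to
#' the genes lying in the given pathway, keeping the direction annotation —
#' the gene-level view behind pathway overlays.
#'
#' @param deg_records DEG \code{data.frame} with columns gene, log2_fc, p,
#'   adj_p, direction.
#' @param pathway a \linkS4class{GeneSignature} or character vector.
#' @param uppercase upper-case ids before matching.
#' @return The matching subset of \code{deg_records} (possibly empty).
#' @export
extractPathwayDegs <- function(deg_records, pathway, uppercase = TRUE) {
  if (is(pathway, "GeneSignature")) pathway <- sigGenes(pathway)
  pw <- .normGenes(pathway, uppercase)
  out <- deg_records[.normGenes(deg_records$gene, uppercase) %in% pw, ,
                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a PPEPMatrix (grid + long companion)
#'
#' Writes the pathway x contrast grid of transformed values to \code{path}
#' and a long-format companion (pathway, contrast, p, adj_p, hits,
#' transformed) to \code{<path base>_long.tsv}.
#'
#' @param ppep a \linkS4class{PPEPMatrix}.
#' @param path output TSV path for the grid.
#' @return Invisibly, \code{path}.
#' @export
writePpepMatrix <- function(ppep, path) {
  stopifnot(is(ppep, "PPEPMatrix"))
  grid <- data.frame(pathway = rownames(ppepValues(ppep)),
                     ppepValues(ppep), check.names = FALSE,
                     stringsAsFactors = FALSE)
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  long_path <- sub("\\.tsv$", "", path)
  write.table(ppepLong(ppep), paste0(long_path, "_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
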