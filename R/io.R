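# Readers/writers for the plain-text formats the pipeline speaks: GMT gene
# sets, expression TSV/CSV/GCT, RDI tables, survival tables, DEG lists.
# Gene identifiers are upper-cased on read by default so that signatures and
# expression rows match by exact string comparison.

.normGenes <- function(x, uppercase = TRUE) {
  x <- trimws(as.character(x))
  if (uppercase) toupper(x) else x
}

#' Read a GMT gene-set file
#'
#' One gene set per line: name, description, then member genes, all
#' tab-separated. Duplicate genes within a line are dropped (first
#' occurrence kept). Set names ending in the up/down suffixes (default
#' \code{"_Up"} / \code{"_Dn"}, matched case-insensitively) are tagged with
#' the corresponding direction, mirroring how directional signatures are
#' published as separate subsets.
#'
#' @param path file path.
#' @param uppercase upper-case gene symbols on read (default TRUE).
#' @param up_suffix,dn_suffix name suffixes that mark directional subsets.
#' @return A \linkS4class{SignatureCollection}.
#' @export
readGmt <- function(path, uppercase = TRUE, up_suffix = "_Up",
                    dn_suffix = "_Dn") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(trimws(f))]
    if (length(f) < 3L)
      stop(sprintf(
        "malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
        i, length(f)))
    nm <- trimws(f[[1L]])
    dir <- "undirected"
    if (grepl(paste0(up_suffix, "$"), nm, ignore.case = TRUE)) dir <- "up"
    else if (grepl(paste0(dn_suffix, "$"), nm, ignore.case = TRUE))
      dir <- "dn"
    sigs[[i]] <- GeneSignature(nm, .normGenes(f[-c(1L, 2L)], uppercase),
                               direction = dir)
  }
  nms <- vapply(sigs, sigName, character(1))
  if (anyDuplicated(nms))
    stop("duplicate gene set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  SignatureCollection(sigs, source_label = basename(path))
}

#' Write a SignatureCollection as GMT
#'
#' @param collection a \linkS4class{SignatureCollection}.
#' @param path output file path.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled; default \code{"na"}).
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path, descriptions = "na") {
  stopifnot(is(collection, "SignatureCollection"))
  descriptions <- rep_len(descriptions, length(collection))
  lines <- vapply(seq_len(length(collection)), function(i) {
    s <- collection[[i]]
    paste(c(sigName(s), descriptions[[i]], sigGenes(s)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV/CSV or GCT
#'
#' Plain dialect: header row of sample ids, first column of gene ids.
#' GCT v1.2 dialect (detected from a first line starting with \code{#1.2},
#' or forced with \code{gct = TRUE}): two header lines are skipped and a
#' \code{Description} column, when present, is dropped. Duplicate gene rows
#' are collapsed to a single row by the rule in \code{collapse}:
#' \code{"max_mean"} keeps the row with the highest mean signal (the common
#' microarray convention), \code{"first"} keeps the first occurrence.
#'
#' @param path file path; \code{.csv} extension implies comma separation.
#' @param platform \code{"intensity"} or \code{"counts"}.
#' @param uppercase upper-case gene ids on read (default TRUE).
#' @param collapse duplicate-gene-row rule, \code{"max_mean"} or
#'   \code{"first"}.
#' @param gct force (or disable) GCT parsing; default auto-detect.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, platform = c("intensity", "counts"),
                           uppercase = TRUE,
                           collapse = c("max_mean", "first"), gct = NA) {
  platform <- match.arg(platform)
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L, warn = FALSE)
  if (is.na(gct)) gct <- startsWith(first, "#1.2")
  df <- read.delim(path, sep = sep, header = TRUE,
                   skip = if (gct) 2L else 0L, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs gene ids plus >= 1 sample")
  hdr <- colnames(df)          # before subsetting: [.data.frame dedupes
  drop_cols <- 1L
  if (gct && length(hdr) >= 2L && tolower(hdr[[2L]]) == "description")
    drop_cols <- c(1L, 2L)
  samp <- hdr[-drop_cols]
  if (anyDuplicated(samp))
    stop("duplicate sample id(s): ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  gene <- .normGenes(df[[1L]], uppercase)
  df <- df[-drop_cols]
  colnames(df) <- samp
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
                 dimnames = list(NULL, samp))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   df[[j]][bad[1L]], gene[bad[1L]], samp[[j]]))
    vals[, j] <- v
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene[bad[[1L]]], samp[bad[[2L]]]))
  }
  if (anyDuplicated(gene)) {
    keep <- switch(collapse,
      first = !duplicated(gene),
      max_mean = {
        mu <- rowMeans(vals)
        ord <- order(gene, -mu)  # best row first within each gene
        sel <- ord[!duplicated(gene[ord])]
        seq_len(nrow(vals)) %in% sel
      })
    vals <- vals[keep, , drop = FALSE]
    gene <- gene[keep]
  }
  rownames(vals) <- gene
  ExpressionMatrix(vals, platform = platform)
}

#' Write an ExpressionMatrix as TSV
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param path output path; first column \code{gene}, then one column per
#'   sample.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(expr, path) {
  stopifnot(is(expr, "ExpressionMatrix"))
  df <- data.frame(gene = geneIds(expr), exprValues(expr),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an RDI table
#'
#' TSV with columns \code{sample}, \code{value}, \code{label}
#' (dependent/independent) and optionally \code{source}.
#'
#' @param path file path.
#' @param source provenance override used when the file has no
#'   \code{source} column.
#' @return \code{readRdiTable}: an \linkS4class{RdiTable}.
#' @export
readRdiTable <- function(path, source = c("other", "SF1B", "SF7")) {
  source <- match.arg(source)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "value", "label")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("RDI table missing column(s): ", paste(miss, collapse = ", "))
  if ("source" %in% colnames(df) && nrow(df))
    source <- df$source[[1L]]
  RdiTable(df$sample, df$value, df$label, source = source)
}

#' @rdname readRdiTable
#' @param rdi an \linkS4class{RdiTable}.
#' @return \code{writeRdiTable}: invisibly, \code{path}.
#' @export
writeRdiTable <- function(rdi, path) {
  stopifnot(is(rdi, "RdiTable"))
  df <- data.frame(sample = rdi@sample_ids, value = rdi@raw_values,
                   label = rdi@dependency_label, source = rdi@source,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a survival table
#'
#' TSV with columns \code{sample}, \code{time} (> 0) and \code{event}
#' (1 = event, 0 = censored).
#'
#' @param path file path.
#' @return \code{readSurvivalTable}: a \linkS4class{SurvivalTable}.
#' @export
readSurvivalTable <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "time", "event"), colnames(df))
  if (length(miss))
    stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  SurvivalTable(df$sample, df$time, df$event)
}

#' @rdname readSurvivalTable
#' @param surv a \linkS4class{SurvivalTable}.
#' @return \code{writeSurvivalTable}: invisibly, \code{path}.
#' @export
writeSurvivalTable <- function(surv, path) {
  stopifnot(is(surv, "SurvivalTable"))
  df <- data.frame(sample = surv@sample_ids, time = surv@time,
                   event = surv@event, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ScoreMatrix as TSV (with a JSON parameter sidecar)
#'
#' Rows are signatures (any \code{_Up}/\code{_Dn} suffixes preserved),
#' columns are samples. A sidecar \code{<path>.json} records the scoring
#' parameters.
#'
#' @param scores a \linkS4class{ScoreMatrix}.
#' @param path output TSV path.
#' @param sidecar write the JSON parameter sidecar (default TRUE).
#' @return Invisibly, \code{path}.
#' @export
writeScoreMatrix <- function(scores, path, sidecar = TRUE) {
  stopifnot(is(scores, "ScoreMatrix"))
  df <- data.frame(signature = signatureNames(scores), scoreValues(scores),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    p <- scoreParams(scores)
    jsonlite::write_json(
      list(alpha = p@alpha, normalize = p@normalize,
           min_set_size = p@min_set_size, zscored = isZscored(scores)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a ScoreMatrix written by writeScoreMatrix
#'
#' @param path TSV path (first column \code{signature}).
#' @param params optional \linkS4class{SsgseaParams} to attach.
#' @return A \linkS4class{ScoreMatrix}.
#' @export
readScoreMatrix <- function(path, params = ssgseaParams()) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  new("ScoreMatrix", scores = m, zscored = FALSE, params = params)
}
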