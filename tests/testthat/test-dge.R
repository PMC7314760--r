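# Small fixed-size helper: expression with a known shift planted in the
# first n_shift genes between two 15-sample groups.
shiftedExpr <- function(n_genes = 400, n_shift = 40, shift = 1,
                        sigma = 0.5, n_per_group = 15, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  mu <- rnorm(n_genes, 7)
  x <- matrix(rnorm(n_genes * n, sd = sigma), n_genes, n) + mu
  hi <- seq_len(n_per_group)
  x[seq_len(n_shift), hi] <- x[seq_len(n_shift), hi] + shift
  e <- tinyExpr(x, genes = sprintf("G%04d", seq_len(n_genes)),
                samples = sprintf("s%02d", seq_len(n)))
  sel <- new("ExtremeSelection",
             high_samples = sprintf("s%02d", hi),
             low_samples = sprintf("s%02d", hi + n_per_group),
             k = as.integer(n_per_group), score_source = "planted")
  list(expr = e, sel = sel, true_genes = sprintf("G%04d", seq_len(n_shift)))
}

test_that("Welch t matches stats::t.test gene by gene", {
  fx <- shiftedExpr(n_genes = 25, n_shift = 5, seed = 3)
  deg <- differentialExpression(fx$expr, fx$sel, filter = FALSE)
  vals <- exprValues(fx$expr)
  for (g in sample(rownames(vals), 8)) {
    tt <- t.test(vals[g, highSamples(fx$sel)],
                 vals[g, lowSamples(fx$sel)])
    row <- deg[deg$gene == g, ]
    expect_equal(row$p, tt$p.value, tolerance = 1e-12)
    expect_equal(row$log2_fc,
                 unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
  }
  expect_equal(deg$adj_p, p.adjust(deg$p, "BH"), tolerance = 1e-15)
})

test_that("planted shift is recovered with high sensitivity and low FDR", {
  fx <- shiftedExpr(n_genes = 2000, n_shift = 100, shift = 1, seed = 8)
  deg <- differentialExpression(fx$expr, fx$sel)
  called <- deg$gene
  sens <- length(intersect(called, fx$true_genes)) / length(fx$true_genes)
  fdr <- if (length(called))
    length(setdiff(called, fx$true_genes)) / length(called) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)
  expect_true(all(deg$direction[deg$log2_fc > 0] == "up_in_high"))
  expect_true(all(deg$direction[deg$log2_fc < 0] == "down_in_high"))
})

test_that("null data rarely yields any DEG at the default thresholds", {
  hits <- vapply(1:10, function(s) {
    fx <- shiftedExpr(n_genes = 1000, n_shift = 0, seed = 100 + s)
    nrow(differentialExpression(fx$expr, fx$sel))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("swapping the groups flips directions and negates fold changes", {
  fx <- shiftedExpr(n_genes = 300, n_shift = 30, seed = 5)
  swapped <- new("ExtremeSelection",
                 high_samples = lowSamples(fx$sel),
                 low_samples = highSamples(fx$sel),
                 k = fx$sel@k, score_source = "planted")
  a <- differentialExpression(fx$expr, fx$sel, filter = FALSE)
  b <- differentialExpression(fx$expr, swapped, filter = FALSE)
  expect_equal(b$log2_fc, -a$log2_fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  flip <- c(up_in_high = "down_in_high", down_in_high = "up_in_high")
  expect_equal(b$direction, unname(flip[a$direction]))
})

test_that("count matrices are tested on log2(CPM + 0.5)", {
  set.seed(9)
  counts <- matrix(rnbinom(200 * 8, mu = 50, size = 10), 200, 8)
  e <- tinyExpr(counts, platform = "counts",
                samples = sprintf("s%02d", 1:8))
  sel <- new("ExtremeSelection", high_samples = sprintf("s%02d", 1:4),
             low_samples = sprintf("s%02d", 5:8), k = 4L,
             score_source = "x")
  deg <- differentialExpression(e, sel, filter = FALSE)
  lcpm <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 0.5)
  g <- 17
  tt <- t.test(lcpm[g, 1:4], lcpm[g, 5:8])
  expect_equal(deg$p[deg$gene == geneIds(e)[g]], tt$p.value,
               tolerance = 1e-12)
})

test_that("zero-variance genes are excluded and group sizes validated", {
  fx <- shiftedExpr(n_genes = 50, n_shift = 0, seed = 2)
  vals <- exprValues(fx$expr)
  vals["G0001", ] <- 3
  e <- ExpressionMatrix(vals)
  expect_message(deg <- differentialExpression(e, fx$sel, filter = FALSE),
                 "zero variance")
  expect_false("G0001" %in% deg$gene)
  expect_equal(attr(deg, "excluded_genes"), "G0001")

  tiny_sel <- new("ExtremeSelection", high_samples = "s01",
                  low_samples = "s16", k = 1L, score_source = "x")
  expect_error(differentialExpression(e, tiny_sel), ">= 2")
})

test_that("DEG import validates columns and re-applies thresholds", {
  d <- withr::local_tempdir()
  f <- file.path(d, "deg.tsv")
  df <- data.frame(gene = c("A", "B", "C"),
                   log2_fc = c(1.2, -0.2, -2),
                   p = c(0.001, 0.2, 0.004),
                   adj_p = c(0.01, 0.4, 0.02))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- importDegList(f)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$direction, c("up_in_high", "down_in_high",
                                "down_in_high"))
  filtered <- importDegList(f, thresholds = degThresholds())
  expect_setequal(filtered$gene, c("A", "C"))

  bad <- df; bad$adj_p[1] <- 0.0005
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(importDegList(f), "adj_p < p")

  write.table(df[0, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(empty <- importDegList(f), "empty")
  expect_equal(nrow(empty), 0L)

  write.table(df[c("gene", "p")], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(importDegList(f), "log2_fc")
})

test_that("contrast labels follow the High-vs-Low naming convention", {
  expect_equal(contrastLabel("L"), "L_High_vs_L_Low_AdjP0_05FC1_5")
  expect_equal(contrastLabel("Hi", degThresholds(0.01, 2)),
               "Hi_High_vs_Hi_Low_AdjP0_01FC2")
})

test_that("threshold constructor rejects nonsense", {
  expect_error(degThresholds(adj_p_max = 0), "0, 1")
  expect_error(degThresholds(min_fold_change = 0.5), ">= 1")
})
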