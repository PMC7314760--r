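test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simConfig(n_genes = 150, n_samples = 12, signature_size = 10,
                   seed = 5, pathway_spec = list(size = 15, log2_shift = 1),
                   survival_spec = list(hr = 2, censoring = 0.3))
  a <- makeExpression(cfg)
  b <- makeExpression(cfg)
  expect_identical(exprValues(a$expr), exprValues(b$expr))
  expect_identical(a$truth@gradient, b$truth@gradient)
  expect_identical(sigGenes(a$signature), sigGenes(b$signature))
  expect_identical(makeRdi(a$truth, 0.3, seed = 2)@raw_values,
                   makeRdi(b$truth, 0.3, seed = 2)@raw_values)
  s1 <- makeSurvival(a$truth, cfg@survival_spec, seed = 3)
  s2 <- makeSurvival(b$truth, cfg@survival_spec, seed = 3)
  expect_identical(s1@time, s2@time)
})

test_that("config validation runs before any sampling", {
  expect_error(simConfig(n_genes = 10, signature_size = 10), "< n_genes")
  expect_error(simConfig(sigma = 0), "sigma")
  expect_error(simConfig(frac_down = 1.2), "frac_down")
  expect_error(simConfig(pathway_spec = list(size = 10)), "log2_shift")
  expect_error(simConfig(survival_spec = list(hr = -1, censoring = 0)),
               "hazard")
})

test_that("counts platform satisfies the count-matrix invariants", {
  cfg <- simConfig(n_genes = 300, n_samples = 10, signature_size = 20,
                   platform = "counts", seed = 9)
  sim <- makeExpression(cfg)
  v <- exprValues(sim$expr)
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  expect_equal(exprPlatform(sim$expr), "counts")
  # library sizes concentrate around the 1e6 target
  expect_true(all(abs(colSums(v) / 1e6 - 1) < 0.2))
})

test_that("beta = 0 leaves signature genes exchangeable with background", {
  diffs <- vapply(1:15, function(s) {
    cfg <- simConfig(n_genes = 400, n_samples = 30, signature_size = 30,
                     beta = 0, seed = 300 + s)
    sim <- makeExpression(cfg)
    d <- sim$truth@gradient
    hi <- names(d)[d > median(d)]
    lo <- setdiff(names(d), hi)
    v <- exprValues(sim$expr)
    gd <- rowMeans(v[, hi]) - rowMeans(v[, lo])
    mean(gd[sigGenes(sim$signature)])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("signature direction split matches frac_down", {
  cfg <- simConfig(n_genes = 200, n_samples = 10, signature_size = 40,
                   frac_down = 0.25, seed = 8)
  sim <- makeExpression(cfg)
  expect_equal(sum(sim$truth@directions < 0), 10L)
  tc <- truthSignatures(sim$truth)
  expect_setequal(sigGenes(tc[["PlantedSig_Dn"]]),
                  names(sim$truth@directions)[sim$truth@directions < 0])
})

test_that("synthetic RDI is a monotone readout of the gradient", {
  cfg <- simConfig(n_genes = 100, n_samples = 25, signature_size = 10,
                   seed = 12)
  sim <- makeExpression(cfg)
  rdi0 <- makeRdi(sim$truth, noise_sd = 0, seed = 1)
  tr <- transformRdiSf7(rdi0)
  expect_equal(cor(tr, sim$truth@gradient, method = "spearman"), 1)
  expect_equal(rdi0@dependency_label,
               unname(ifelse(sim$truth@gradient > 0, "dependent",
                             "independent")))
})

test_that("survival times respond to the hazard ratio and censoring target", {
  cfg <- simConfig(n_genes = 50, n_samples = 200, signature_size = 5,
                   seed = 31)
  sim <- makeExpression(cfg)
  s0 <- makeSurvival(sim$truth, list(hr = 2, censoring = 0), seed = 2)
  expect_true(all(s0@event == 1L))
  s3 <- makeSurvival(sim$truth, list(hr = 2, censoring = 0.3), seed = 2)
  expect_lt(abs(mean(s3@event == 0L) - 0.3), 0.1)
  # high-gradient tercile dies earlier than low tercile
  d <- sim$truth@gradient
  ter <- cut(d, quantile(d, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE,
             labels = c("lo", "mid", "hi"))
  med <- tapply(s0@time, ter, median)
  expect_lt(med[["hi"]], med[["lo"]])
  expect_error(makeSurvival(sim$truth, list(hr = 0, censoring = 0.3)),
               "> 0")
})

test_that("decoy pathways avoid the planted structure", {
  cfg <- simConfig(n_genes = 800, n_samples = 10, signature_size = 20,
                   seed = 3, pathway_spec = list(size = 25, log2_shift = 1))
  sim <- makeExpression(cfg)
  pws <- makePathwayCollection(sim$truth, sim$expr, n_decoys = 10,
                               seed = 4)
  expect_length(pws, 11L)
  expect_setequal(sigGenes(pws[["PlantedPathway"]]),
                  sim$truth@pathway_genes)
  for (nm in setdiff(names(pws), "PlantedPathway")) {
    expect_length(intersect(sigGenes(pws[[nm]]),
                            sim$truth@pathway_genes), 0L)
    expect_length(intersect(sigGenes(pws[[nm]]),
                            names(sim$truth@directions)), 0L)
  }
  no_pw <- makeExpression(simConfig(n_genes = 100, n_samples = 10,
                                    signature_size = 5, seed = 1))
  expect_error(makePathwayCollection(no_pw$truth, no_pw$expr),
               "no planted pathway")
})
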