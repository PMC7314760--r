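noNorm <- function(alpha = 0.25) ssgseaParams(alpha = alpha,
                                              normalize = "none")

test_that("singleton set at the top/bottom of a 4-gene ranking gives +/- N/2", {
  e <- tinyExpr(c(4, 3, 2, 1))
  for (a in c(0, 0.25, 1, 2)) {
    expect_equal(unname(scoreValues(
      ssgseaScore(e, GeneSignature("top", "G01"), noNorm(a)))[1, 1]), 2)
    expect_equal(unname(scoreValues(
      ssgseaScore(e, GeneSignature("bot", "G04"), noNorm(a)))[1, 1]), -2)
  }
})

test_that("five-gene worked example matches the direct summation", {
  e <- tinyExpr(c(5, 4, 3, 2, 1))
  es <- scoreValues(ssgseaScore(e, GeneSignature("s", c("G01", "G03")),
                                noNorm(0.25)))[1, 1]
  w <- c(5, 3)^0.25
  manual <- (w[1] / sum(w) - 0) + (w[1] / sum(w) - 1 / 3) +
    (1 - 1 / 3) + (1 - 2 / 3) + (1 - 1)
  expect_equal(unname(es), manual, tolerance = 1e-12)
  expect_equal(unname(es), 1.7304, tolerance = 1e-4)
})

test_that("scores agree with the naive double-loop oracle on toy instances", {
  set.seed(7)
  for (N in c(3, 5, 8, 10)) {
    gid <- sprintf("G%02d", 1:N)
    x <- sample(N)                 # a random strict ordering
    e <- tinyExpr(matrix(x, ncol = 1), genes = gid)
    for (m in 1:(N - 1)) {
      set <- sample(gid, m)
      for (a in c(0, 0.25, 1.5)) {
        es <- scoreValues(ssgseaScore(e, GeneSignature("s", set),
                                      noNorm(a)))[1, 1]
        expect_equal(unname(es), ssgseaOracle(x, gid, set, a),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("scores are invariant to strictly increasing per-sample transforms", {
  set.seed(21)
  x <- matrix(rnorm(40, 7), 20, 2)
  e <- tinyExpr(x)
  sig <- GeneSignature("s", sprintf("G%02d", c(2, 5, 9, 17)))
  base <- scoreValues(ssgseaScore(e, sig, noNorm()))
  e2 <- tinyExpr(exp(x / 3) + 1)          # strictly increasing transform
  expect_equal(scoreValues(ssgseaScore(e2, sig, noNorm())), base,
               tolerance = 1e-12)
})

test_that("alpha = 0 reversal of a sample's ordering negates its score", {
  set.seed(3)
  for (rep in 1:10) {
    x <- sample(12)
    e <- tinyExpr(matrix(x, ncol = 1))
    set <- sample(sprintf("G%02d", 1:12), sample(1:11, 1))
    sig <- GeneSignature("s", set)
    es <- scoreValues(ssgseaScore(e, sig, noNorm(0)))[1, 1]
    er <- scoreValues(ssgseaScore(tinyExpr(matrix(-x, ncol = 1)), sig,
                                  noNorm(0)))[1, 1]
    expect_equal(unname(er), -unname(es), tolerance = 1e-12)
  }
})

test_that("unnormalized |ES| never exceeds N", {
  set.seed(9)
  x <- matrix(rnorm(25 * 4), 25, 4)
  e <- tinyExpr(x)
  cc <- SignatureCollection(lapply(1:5, function(i)
    GeneSignature(paste0("s", i),
                  sample(sprintf("G%02d", 1:25), sample(1:20, 1)))))
  es <- scoreValues(ssgseaScore(e, cc, noNorm(0.5)))
  expect_true(all(abs(es) <= 25))
})

test_that("unusable signatures are skipped with a warning, constants error", {
  e <- tinyExpr(matrix(c(3, 2, 1, 9, 8, 7), 3, 2))
  cc <- SignatureCollection(list(
    GeneSignature("ok", c("G01", "G03")),
    GeneSignature("alien", c("X1", "X2")),
    GeneSignature("whole", c("G01", "G02", "G03"))))
  expect_warning(expect_warning(
    sm <- ssgseaScore(e, cc, noNorm()), "alien"), "whole")
  expect_equal(signatureNames(sm), "ok")

  const <- tinyExpr(matrix(c(1, 2, 3, 5, 5, 5), 3, 2))
  expect_error(ssgseaScore(const, cc[["ok"]]), "s02")
})

test_that("range normalization only rescales scores globally", {
  set.seed(4)
  e <- tinyExpr(matrix(rnorm(60), 15, 4))
  cc <- SignatureCollection(list(
    GeneSignature("a", sprintf("G%02d", 1:4)),
    GeneSignature("b", sprintf("G%02d", 8:12))))
  raw <- scoreValues(ssgseaScore(e, cc, noNorm()))
  nrm <- scoreValues(ssgseaScore(e, cc, ssgseaParams(normalize = "range")))
  expect_equal(nrm, raw / (max(raw) - min(raw)), tolerance = 1e-12)
})

test_that("directional combination is z(up) - z(dn) with Up/Dn rows kept", {
  set.seed(13)
  e <- tinyExpr(matrix(rnorm(200, 7), 20, 10))
  up <- GeneSignature("Sig_Up", sprintf("G%02d", 1:4), direction = "up")
  dn <- GeneSignature("Sig_Dn", sprintf("G%02d", 10:13), direction = "dn")
  sm <- scoreDirectional(e, up, dn)
  expect_setequal(signatureNames(sm),
                  c("Sig_Up", "Sig_Dn", "Sig_combined"))
  es <- scoreValues(sm)
  expect_equal(es["Sig_combined", ],
               zscoreValues(es["Sig_Up", ]) - zscoreValues(es["Sig_Dn", ]),
               tolerance = 1e-12)

  # identical halves cancel exactly
  sm2 <- scoreDirectional(e, up, GeneSignature("Sig_Dn", sigGenes(up)))
  expect_equal(unname(scoreValues(sm2)["Sig_combined", ]), rep(0, 10),
               tolerance = 1e-12)

  # missing Dn subset degenerates to z(up)
  sm3 <- scoreDirectional(e, up, NULL)
  expect_equal(scoreValues(sm3)["Sig_combined", ],
               zscoreValues(scoreValues(sm3)["Sig_Up", ]),
               tolerance = 1e-12)
})

test_that("combined score tracks a planted gradient better than Dn alone", {
  sim <- makeExpression(simConfig(n_genes = 500, n_samples = 40,
                                  signature_size = 30, seed = 77))
  tc <- truthSignatures(sim$truth)
  sm <- scoreDirectional(sim$expr, tc[["PlantedSig_Up"]],
                         tc[["PlantedSig_Dn"]])
  es <- scoreValues(sm)
  d <- sim$truth@gradient
  r_comb <- cor(es["PlantedSig_combined", ], d, method = "spearman")
  r_dn <- cor(es["PlantedSig_Dn", ], d, method = "spearman")
  expect_gt(r_comb, abs(r_dn))
  expect_gt(r_comb, 0.8)
})

test_that("zscoreRows standardises rows (optionally over a cohort)", {
  set.seed(2)
  e <- tinyExpr(matrix(rnorm(80), 10, 8))
  sm <- ssgseaScore(e, GeneSignature("s", sprintf("G%02d", 1:3)))
  z <- zscoreRows(sm)
  expect_true(isZscored(z))
  expect_equal(unname(rowMeans(scoreValues(z))), 0, tolerance = 1e-12)
  expect_equal(unname(apply(scoreValues(z), 1, sd)), 1, tolerance = 1e-12)

  coh <- sprintf("s%02d", 1:4)
  zc <- zscoreRows(sm, cohort = coh)
  expect_false(isZscored(zc))
  expect_equal(unname(mean(scoreValues(zc)[1, coh])), 0, tolerance = 1e-12)
})
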