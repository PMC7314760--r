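# Synthetic-data generators. The data model mirrors what the scoring
# pipeline assumes about real cohorts: each sample carries a latent
# dependency gradient d in [-1, 1] (a continuum, not two discrete classes)
# that coordinately shifts the genes of a planted signature; optionally a
# planted pathway tracks the same gradient, and survival hazard depends on
# it. Every generator is seed-deterministic and returns the planted truth
# so recovery can be scored exactly.

#' Generate a synthetic expression cohort with planted structure
#'
#' Intensity platform: per-gene baselines \eqn{\mu_g \sim N(7, 1)} (log2
#' scale), a per-sample gradient \eqn{d_i \sim U(-1, 1)}, and values
#' \eqn{x_{gi} = \mu_g + \beta\,dir_g\,d_i + N(0, \sigma)} for signature
#' genes (\eqn{dir_g = \pm 1}), \eqn{x_{gi} = \mu_g + N(0, \sigma)}
#' otherwise. A planted pathway (disjoint from the signature) adds
#' \eqn{(s/2)\,d_i} to its genes, giving a log2 shift of \eqn{s} between
#' the gradient endpoints. Counts platform: the same log2 surface is
#' converted to Negative Binomial counts (dispersion 0.1) with per-sample
#' expected library size 1e6.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \code{list(expr =} \linkS4class{ExpressionMatrix}\code{,
#'   signature =} \linkS4class{GeneSignature}\code{, truth =}
#'   \linkS4class{SimTruth}\code{)}.
#' @examples
#' sim <- makeExpression(simConfig(n_genes = 100, n_samples = 10,
#'                                 signature_size = 8, seed = 3))
#' sim$expr
#' @export
makeExpression <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  ng <- config@n_genes; ns <- config@n_samples
  gid <- sprintf("G%05d", seq_len(ng))
  sid <- sprintf("S%04d", seq_len(ns))
  mu <- rnorm(ng, mean = 7, sd = 1)
  d <- runif(ns, -1, 1)
  names(d) <- sid

  sig_genes <- sample(gid, config@signature_size)
  n_dn <- round(config@frac_down * config@signature_size)
  dirs <- rep(1, config@signature_size)
  if (n_dn > 0) dirs[sample.int(config@signature_size, n_dn)] <- -1
  names(dirs) <- sig_genes

  x <- matrix(mu, nrow = ng, ncol = ns, dimnames = list(gid, sid))
  sig_idx <- match(sig_genes, gid)
  x[sig_idx, ] <- x[sig_idx, ] + config@beta * outer(dirs, d)

  pw_genes <- character()
  pw_shift <- 0
  if (length(config@pathway_spec)) {
    pw_shift <- config@pathway_spec$log2_shift
    pw_genes <- sample(setdiff(gid, sig_genes), config@pathway_spec$size)
    x[match(pw_genes, gid), ] <-
      x[match(pw_genes, gid), ] + outer(rep(pw_shift / 2, length(pw_genes)), d)
  }
  x <- x + matrix(rnorm(ng * ns, sd = config@sigma), ng, ns)

  lp <- numeric()
  if (length(config@survival_spec))
    lp <- log(config@survival_spec$hr) * d / sd(d)

  if (config@platform == "counts") {
    lambda <- 2^x
    lambda <- sweep(lambda, 2L, colSums(lambda), "/") * 1e6
    x <- matrix(rnbinom(ng * ns, mu = lambda, size = 1 / 0.1), ng, ns,
                dimnames = list(gid, sid))
  }
  list(expr = ExpressionMatrix(x, platform = config@platform),
       signature = GeneSignature("PlantedSig", sig_genes),
       truth = new("SimTruth", gradient = d, directions = dirs,
                   pathway_genes = pw_genes, pathway_shift = pw_shift,
                   linear_predictor = lp))
}

#' Split planted-truth directions into Up/Dn signature subsets
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param name base name for the subsets.
#' @return A \linkS4class{SignatureCollection} with \code{<name>_Up} and,
#'   when any gene points down, \code{<name>_Dn}.
#' @export
truthSignatures <- function(truth, name = "PlantedSig") {
  stopifnot(is(truth, "SimTruth"))
  up <- names(truth@directions)[truth@directions > 0]
  dn <- names(truth@directions)[truth@directions < 0]
  sigs <- list(GeneSignature(paste0(name, "_Up"), up, direction = "up"))
  if (length(dn))
    sigs <- c(sigs, list(GeneSignature(paste0(name, "_Dn"), dn,
                                       direction = "dn")))
  SignatureCollection(sigs, source_label = "synthetic")
}

#' Generate survival outcomes driven by the planted gradient
#'
#' Event times are exponential with hazard
#' \eqn{h_0 \exp(\log(HR)\, d_i / SD(d))}; censoring times are independent
#' Uniform(0, c) with c tuned numerically so the expected censoring
#' fraction matches \code{survival_spec$censoring}. With censoring 0 every
#' sample is an event.
#'
#' @param truth a \linkS4class{SimTruth} (gradient required).
#' @param survival_spec \code{list(hr =, censoring =)}: hazard ratio per SD
#'   of gradient and target censoring fraction in [0, 1).
#' @param seed RNG seed.
#' @param h0 baseline hazard (default 0.1).
#' @return A \linkS4class{SurvivalTable}.
#' @export
makeSurvival <- function(truth, survival_spec = list(hr = 2,
                                                     censoring = 0.3),
                         seed = 1L, h0 = 0.1) {
  stopifnot(is(truth, "SimTruth"))
  if (!all(c("hr", "censoring") %in% names(survival_spec)))
    stop("survival_spec needs 'hr' and 'censoring'")
  if (survival_spec$hr <= 0) stop("hazard ratio must be > 0")
  f <- survival_spec$censoring
  if (f < 0 || f >= 1) stop("censoring fraction must lie in [0, 1)")
  d <- truth@gradient
  set.seed(as.integer(seed))
  rate <- h0 * exp(log(survival_spec$hr) * d / sd(d))
  tev <- rexp(length(d), rate = rate)
  if (f == 0)
    return(SurvivalTable(names(d), tev, rep(1L, length(d))))
  # expected censoring fraction with C ~ U(0, cmax):
  # P(T_i > C) = (1 - exp(-rate_i * cmax)) / (rate_i * cmax)
  target <- function(cmax)
    mean((1 - exp(-rate * cmax)) / (rate * cmax)) - f
  cmax <- uniroot(target, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
  cens <- runif(length(d), 0, cmax)
  SurvivalTable(names(d), pmin(tev, cens), as.integer(tev <= cens))
}

#' Generate a synthetic measured RDI table
#'
#' Emulates an experimentally measured dependency readout as a noisy
#' monotone transform of the gradient: raw values
#' \eqn{10^{-\ell_i (d_i + N(0, noise\_sd))}} with \eqn{\ell_i = +1} and
#' label "dependent" when \eqn{d_i > 0}, \eqn{\ell_i = -1} and label
#' "independent" otherwise — i.e. the measured value shrinks with
#' dependency strength for dependent lines and grows with independency
#' strength for independent lines, so \code{\link{transformRdiSf7}}
#' (sign-by-label times log10) recovers \eqn{d_i} plus noise exactly
#' (Spearman 1 with the gradient at noise 0).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param noise_sd measurement noise SD on the log10 scale (>= 0).
#' @param seed RNG seed.
#' @return An \linkS4class{RdiTable} (source \code{"SF7"}).
#' @export
makeRdi <- function(truth, noise_sd = 0.3, seed = 1L) {
  stopifnot(is(truth, "SimTruth"), noise_sd >= 0)
  d <- truth@gradient
  set.seed(as.integer(seed))
  ell <- ifelse(d > 0, 1, -1)
  raw <- 10^(-ell * (d + rnorm(length(d), sd = noise_sd)))
  RdiTable(names(d), raw,
           ifelse(d > 0, "dependent", "independent"), source = "SF7")
}

#' Build a pathway collection around the planted pathway
#'
#' Returns the planted pathway plus decoy pathways of the same size drawn
#' from background genes (disjoint from both the planted signature and the
#' planted pathway), for end-to-end pathway-recovery experiments.
#'
#' @param truth a \linkS4class{SimTruth} with a planted pathway.
#' @param universe background gene ids or an
#'   \linkS4class{ExpressionMatrix}.
#' @param n_decoys number of decoy pathways (default 19).
#' @param seed RNG seed.
#' @return A \linkS4class{SignatureCollection}; the planted pathway is
#'   named \code{"PlantedPathway"}, decoys \code{"Decoy01"}, ...
#' @export
makePathwayCollection <- function(truth, universe, n_decoys = 19L,
                                  seed = 1L) {
  stopifnot(is(truth, "SimTruth"))
  if (!length(truth@pathway_genes))
    stop("truth carries no planted pathway")
  if (is(universe, "ExpressionMatrix")) universe <- geneIds(universe)
  size <- length(truth@pathway_genes)
  pool <- setdiff(universe,
                  c(truth@pathway_genes, names(truth@directions)))
  if (length(pool) < size * n_decoys)
    stop("universe too small for ", n_decoys, " decoys of size ", size)
  set.seed(as.integer(seed))
  decoy_genes <- split(sample(pool, size * n_decoys),
                       rep(seq_len(n_decoys), each = size))
  sigs <- c(list(GeneSignature("PlantedPathway", truth@pathway_genes)),
            lapply(seq_len(n_decoys), function(i)
              GeneSignature(sprintf("Decoy%02d", i), decoy_genes[[i]])))
  SignatureCollection(sigs, source_label = "synthetic")
}

#' Write a SimTruth as TSV
#'
#' One row per sample (gradient, linear predictor when present); the
#' signature directions and planted pathway genes go to sidecar files
#' \code{<base>_directions.tsv} and \code{<base>_pathway.txt}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  df <- data.frame(sample = names(truth@gradient),
                   gradient = unname(truth@gradient),
                   stringsAsFactors = FALSE)
  if (length(truth@linear_predictor))
    df$linear_predictor <- unname(truth@linear_predictor)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  base <- sub("\\.tsv$", "", path)
  write.table(
    data.frame(gene = names(truth@directions),
               direction = unname(truth@directions)),
    paste0(base, "_directions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (length(truth@pathway_genes))
    writeLines(truth@pathway_genes, paste0(base, "_pathway.txt"))
  invisible(path)
}
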