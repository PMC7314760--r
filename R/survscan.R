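# Score-vs-survival association: a univariate Cox proportional hazards fit
# (Breslow ties) plus a cutpoint scan — at every admissible score cutpoint
# the cohort is split into high/low groups and a two-group log-rank test is
# run; the number of significant cutpoints ("GoodCount") is calibrated by
# permutation. The scan is a documented simplified reconstruction of a
# gradient-scan survival method: the cut grid, group-size floor, alpha and
# permutation count are explicit parameters recorded in the output.

# Precompute the risk-set bookkeeping of a (time, event) sample so the
# log-rank statistic can be evaluated for many group labelings cheaply.
.prepLogrank <- function(time, event) {
  ord <- order(time)
  ee <- as.integer(event[ord])
  n <- length(ord)
  first <- which(!duplicated(time[ord]))   # first index of each unique time
  last <- c(first[-1L] - 1L, n)
  cs_e <- c(0L, cumsum(ee))               # cs_e[i + 1] = events in 1..i
  d <- cs_e[last + 1L] - cs_e[first]
  Y <- n - first + 1L                      # at risk at each unique time
  keep <- d > 0L                           # only event times contribute
  list(ord = ord, n = n, first = first[keep], last = last[keep],
       d = d[keep], Y = Y[keep], eventSorted = ee)
}

# Log-rank chi-square for group labels g (logical/0-1, original order).
.logrankStat <- function(prep, g) {
  gs <- as.integer(g)[prep$ord]
  cs_g <- c(0L, cumsum(gs))
  cs_ge <- c(0L, cumsum(gs * prep$eventSorted))
  # at risk / deaths in group 1 at each kept unique event time
  Y1 <- cs_g[prep$n + 1L] - cs_g[prep$first]
  d1 <- cs_ge[prep$last + 1L] - cs_ge[prep$first]
  frac <- Y1 / prep$Y
  U <- sum(d1 - prep$d * frac)
  V <- sum(ifelse(prep$Y > 1L,
                  prep$d * frac * (1 - frac) * (prep$Y - prep$d) /
                    (prep$Y - 1L), 0))
  if (V <= 0) return(c(chisq = 0, p = 1))
  chisq <- U^2 / V
  c(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test of two survival curves, the per-cut
#' test used inside \code{\link{gradientScan}}.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group logical or 0/1 group membership.
#' @return \code{list(chisq =, p =)} (chi-square on 1 df).
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(length(time) == length(event),
            length(time) == length(group))
  group <- as.logical(group)
  if (all(group) || !any(group)) stop("both groups must be non-empty")
  prep <- .prepLogrank(time, event)
  st <- .logrankStat(prep, group)
  list(chisq = unname(st[["chisq"]]), p = unname(st[["p"]]))
}

#' Univariate Cox proportional hazards association
#'
#' Fits a one-covariate Cox model of survival on the score (partial
#' likelihood, Breslow tie handling) and reports the coefficient and its
#' Wald p-value.
#'
#' @param score named numeric vector of per-sample scores.
#' @param survival a \linkS4class{SurvivalTable}; samples are matched by
#'   name to \code{score}.
#' @return \code{list(beta =, se =, p =, n =, n_events =)}.
#' @export
coxUnivariate <- function(score, survival) {
  stopifnot(is(survival, "SurvivalTable"))
  if (is.null(names(score))) stop("score must be named by sample id")
  common <- intersect(names(score), survival@sample_ids)
  if (length(common) < 3L) stop("fewer than 3 matched samples")
  idx <- match(common, survival@sample_ids)
  tt <- survival@time[idx]; ee <- survival@event[idx]
  sc <- as.numeric(score[common])
  if (sum(ee) < 2L) stop("need >= 2 events for a Cox fit")
  if (max(sc) == min(sc)) stop("degenerate gradient: score is constant")
  fit <- survival::coxph(survival::Surv(tt, ee) ~ sc, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50L))
  s <- summary(fit)
  list(beta = unname(coef(fit)[[1L]]),
       se = unname(s$coefficients[1L, "se(coef)"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]),
       n = length(common), n_events = sum(ee))
}

#' Cutpoint scan of a continuous score against survival
#'
#' Scans every split induced by the distinct score values inside the
#' \code{cut_quantiles} window (cuts are placed at midpoints between
#' adjacent distinct values, so score negation maps the scan onto itself)
#' that leaves both groups at least \code{min_frac} of the cohort; at each
#' cut, samples are split into score > cut vs score <= cut and a two-group
#' log-rank test is run.
#' \code{good_count} is the number of cutpoints with p < \code{alpha};
#' its permutation p-value is the add-one-smoothed fraction of \code{B}
#' score permutations whose good_count reaches the observed one. A
#' univariate Cox p-value over the continuous score is reported alongside.
#'
#' @param score named numeric per-sample score.
#' @param survival a \linkS4class{SurvivalTable}.
#' @param cut_quantiles quantile window of admissible cuts (default
#'   c(0.1, 0.9)).
#' @param min_frac minimum fraction of samples in each group (default 0.1).
#' @param alpha per-cut significance level (default 0.05).
#' @param B number of permutations (default 200; < 100 warns).
#' @param seed RNG seed for the permutations.
#' @param score_name label stored in the result.
#' @return A \linkS4class{SurvivalAssoc}.
#' @export
gradientScan <- function(score, survival, cut_quantiles = c(0.1, 0.9),
                         min_frac = 0.1, alpha = 0.05, B = 200L,
                         seed = 1L, score_name = "score") {
  stopifnot(is(survival, "SurvivalTable"))
  if (B < 100L) warning("B = ", B, " permutations (< 100) gives a coarse ",
                        "permutation p-value")
  cox <- coxUnivariate(score, survival)
  common <- intersect(names(score), survival@sample_ids)
  idx <- match(common, survival@sample_ids)
  tt <- survival@time[idx]; ee <- survival@event[idx]
  sc <- as.numeric(score[common])
  n <- length(sc)
  min_n <- max(1L, ceiling(min_frac * n))
  qs <- quantile(sc, cut_quantiles, names = FALSE)
  # midpoints between adjacent distinct score values: they induce exactly
  # the partitions of cutting at the distinct values themselves, but are
  # symmetric under score negation (no sample ever sits on a cut)
  v <- sort(unique(sc))
  if (length(v) < 2L) stop("no admissible cutpoints under the scan settings")
  cand <- (v[-1L] + v[-length(v)]) / 2
  cand <- cand[cand >= qs[[1L]] & cand <= qs[[2L]]]
  n_high <- vapply(cand, function(ct) sum(sc > ct), integer(1))
  ok <- n_high >= min_n & (n - n_high) >= min_n
  cuts <- cand[ok]
  if (!length(cuts)) stop("no admissible cutpoints under the scan settings")

  prep <- .prepLogrank(tt, ee)
  memb <- vapply(cuts, function(ct) sc > ct, logical(n))
  pvals <- apply(memb, 2L, function(g) .logrankStat(prep, g)[["p"]])
  good <- sum(pvals < alpha)

  B <- as.integer(B)
  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    gb <- 0L
    for (ci in seq_along(cuts)) {
      if (.logrankStat(prep, memb[perm, ci])[["p"]] < alpha)
        gb <- gb + 1L
    }
    if (gb >= good) exceed <- exceed + 1L
  }
  perm_p <- (1 + exceed) / (B + 1)

  new("SurvivalAssoc", score_name = score_name, n = as.integer(n),
      cox_beta = cox$beta, cox_p = cox$p, good_count = as.integer(good),
      n_cuts = length(cuts), perm_p = perm_p, B = B,
      params = list(cut_quantiles = cut_quantiles, min_frac = min_frac,
                    alpha = alpha),
      cuts = data.frame(cut = cuts,
                        n_high = n_high[ok],
                        n_low = n - n_high[ok],
                        logrank_p = unname(pvals)))
}

#' Write a SurvivalAssoc summary (plus per-cut table)
#'
#' @param assoc a \linkS4class{SurvivalAssoc}.
#' @param path output TSV path for the one-row summary; the per-cut long
#'   table goes to \code{<path base>_cuts.tsv}.
#' @return Invisibly, \code{path}.
#' @export
writeSurvivalAssoc <- function(assoc, path) {
  stopifnot(is(assoc, "SurvivalAssoc"))
  df <- data.frame(score = assoc@score_name, n = assoc@n,
                   cox_beta = assoc@cox_beta, cox_p = assoc@cox_p,
                   good_count = assoc@good_count, n_cuts = assoc@n_cuts,
                   perm_p = assoc@perm_p, B = assoc@B,
                   alpha = assoc@params$alpha,
                   cut_q_lo = assoc@params$cut_quantiles[[1L]],
                   cut_q_hi = assoc@params$cut_quantiles[[2L]],
                   min_frac = assoc@params$min_frac,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(assoc@cuts, paste0(sub("\\.tsv$", "", path), "_cuts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
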