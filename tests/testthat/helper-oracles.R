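# Independent oracles and tiny fixture builders used across the suite.

# Build a small intensity ExpressionMatrix from a vector/matrix.
tinyExpr <- function(vals, genes = NULL, samples = NULL,
                     platform = "intensity") {
  vals <- as.matrix(vals)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(vals)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(genes, samples)
  ExpressionMatrix(vals, platform = platform)
}

# Naive double-loop ssGSEA enrichment score for one sample: at every step i
# the in-set and out-of-set cumulative weights are recomputed from scratch.
ssgseaOracle <- function(x, gid, set, alpha) {
  N <- length(x)
  ord <- order(-x, gid)
  ranks <- N - seq_len(N) + 1L
  in_set <- gid[ord] %in% set
  m <- sum(in_set)
  denom <- sum(ranks[in_set]^alpha)
  es <- 0
  for (i in seq_len(N)) {
    pin <- 0; pout <- 0
    for (j in seq_len(i)) {
      if (in_set[j]) pin <- pin + ranks[j]^alpha
      else pout <- pout + 1
    }
    es <- es + pin / denom - pout / (N - m)
  }
  es
}

# Hypergeometric upper tail P(X >= k) by direct enumeration of the pmf.
hyperTailOracle <- function(k, K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(K, n)
  ks <- max(k, lo):hi
  if (k > hi) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# O(n^2) log-rank statistic by explicit risk-set enumeration.
logrankOracle <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ut) {
    Y <- sum(time >= t)
    Y1 <- sum(time >= t & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    U <- U + d1 - d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 0) return(list(chisq = 0, p = 1))
  list(chisq = U^2 / V, p = pchisq(U^2 / V, 1, lower.tail = FALSE))
}

# Directional combined score of a planted-truth signature.
combinedScore <- function(expr, truth) {
  tc <- truthSignatures(truth)
  sm <- scoreDirectional(expr, tc[["PlantedSig_Up"]],
                         if ("PlantedSig_Dn" %in% names(tc))
                           tc[["PlantedSig_Dn"]] else NULL)
  scoreValues(sm)["PlantedSig_combined", ]
}
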