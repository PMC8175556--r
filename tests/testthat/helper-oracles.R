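# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not from the code path it checks.

# two-sided Fisher P: enumerate all 2x2 tables with the observed margins,
# sum hypergeometric probabilities <= that of the observed table
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  a_obs <- tab[1, 1]
  a_all <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(a_all, c1, c2, r1)
  p_obs <- stats::dhyper(a_obs, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney P by enumerating every assignment of the
# pooled values to the two groups
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# BH step-up from the definition: q_(i) = min_{j >= i} m p_(j) / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# closed-form log odds ratio of a 2x2 (y,x) cell-count table:
# counts named n11 (y=1,x=1), n10 (y=1,x=0), n01 (y=0,x=1), n00 (y=0,x=0)
oracle_log_or <- function(n11, n10, n01, n00) {
  log((n11 * n00) / (n10 * n01))
}

# expand a 2x2 cell-count table into per-observation y and x vectors
expand_2x2 <- function(n11, n10, n01, n00) {
  list(y = c(rep(1, n11 + n10), rep(0, n01 + n00)),
       x = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)))
}

# two-loop drug-response oracle straight from the definition
oracle_drs <- function(expr, model) {
  genes <- intersect(names(model$correlations), rownames(expr))
  out <- numeric(ncol(expr))
  for (s in seq_len(ncol(expr))) {
    num <- 0; den <- 0
    for (g in genes) {
      num <- num + model$correlations[[g]] * expr[g, s]
      den <- den + model$correlations[[g]]
    }
    out[s] <- num / den
  }
  names(out) <- colnames(expr)
  out
}

# two-step pathway-score oracle: z-score each row in a loop, then average
# columns over the set genes
oracle_pathway <- function(expr, genes) {
  genes <- intersect(genes, rownames(expr))
  z <- expr[genes, , drop = FALSE]
  for (i in seq_len(nrow(z))) {
    z[i, ] <- (z[i, ] - mean(z[i, ])) / stats::sd(z[i, ])
  }
  apply(z, 2, mean)
}

# small deterministic clinical table for covariate tests
toy_clinical <- function() {
  data.frame(
    sample_id = sprintf("P%02d", 1:8),
    group = rep(c("AAM", "EAM"), 4),
    grade_group = c(1, 2, 3, 4, 5, 2, 3, 1),
    pt_stage = c("T2", "T3a", "T3b", "T4", "T2", "T3a", NA, "T2"),
    pn_stage = c("N0", "N1", "NX", "N0", "N1", "NX", "N0", "N0"),
    capra_s = c("Low", "High", NA, "Intermediate", "Low", "High", "Low", NA),
    psa = c(5.2, 7.9, 11.0, 6.5, 4.8, 10.1, 8.3, 6.0),
    stringsAsFactors = FALSE)
}
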