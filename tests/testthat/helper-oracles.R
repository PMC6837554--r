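# Independent brute-force oracles. These re-derive every statistic from its
# definition, without calling the package's code paths or the same stats::
# convenience wrappers the implementation uses.

# two-sided one-sample t-test of x against 0, from the t statistic and CDF
oracle_t_p <- function(x) {
  n <- length(x)
  t_stat <- mean(x) / (sd(x) / sqrt(n))
  2 * pt(-abs(t_stat), df = n - 1)
}

# weighted Stouffer-Liptak combination from its formula
oracle_stouffer <- function(z, w) sum(w * z) / sqrt(sum(w^2))

oracle_two_sided_normal_p <- function(z) 2 * (1 - pnorm(abs(z)))

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(m+n, m) assignments of the pooled ranks to the first group
oracle_wilcox_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Holm step-down from its definition
oracle_holm <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(1, (k - seq_len(k) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

# small screen design used across tests
toy_design <- function(n_proteins = 4, replicates = 3, n_peptides = 6,
                       comparisons = NULL) {
  if (is.null(comparisons)) {
    comparisons <- data.frame(test = "T", reference = "R",
                              replicates = replicates)
  }
  screen_design(
    comparisons,
    data.frame(protein_id = sprintf("P%02d", seq_len(n_proteins)),
               n_peptides = rep_len(n_peptides, n_proteins))
  )
}
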