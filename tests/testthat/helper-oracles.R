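# Independent oracles, deliberately coded without reference to the package
# implementations they check.

# brute-force KS-like walk: explicit O(N) loop over the ranked gene list
bf_walk_score <- function(z_col, genes, module_genes, tau = 1) {
  n <- length(z_col)
  ord <- order(-z_col, genes)
  ranked <- genes[ord]
  r <- abs(n / 2 - seq_len(n))
  in_mod <- ranked %in% module_genes
  m <- sum(in_mod)
  denom_in <- sum(r[in_mod]^tau)
  walk <- numeric(n)
  acc <- 0
  for (l in seq_len(n)) {
    acc <- acc + if (in_mod[l]) r[l]^tau / denom_in else -1 / (n - m)
    walk[l] <- acc
  }
  max(walk) + min(walk)
}

# two-sided Fisher exact p for a 2x2 by full enumeration of the
# hypergeometric support (sum of tables with probability <= observed)
enum_fisher_p <- function(tab) {
  k <- tab[1, 1]
  m <- sum(tab[1, ])   # margin of row 1
  n2 <- sum(tab[2, ])
  K <- sum(tab[, 1])   # margin of col 1
  support <- max(0, K - n2):min(m, K)
  probs <- vapply(support, function(x) {
    choose(m, x) * choose(n2, K - x) / choose(m + n2, K)
  }, numeric(1))
  obs <- probs[support == k]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# AUC as the normalized Mann-Whitney U statistic (ties count 1/2)
u_stat_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  comp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}

# small reusable synthetic cohort for end-to-end tests
tiny_cohort <- function(seed = 11L, n = c(AA = 25, EA = 50, NAA = 25),
                        n_hc = 12L, n_genes = 1300L,
                        effects = default_effect_table()) {
  cfg <- cohort_config(n_per_ancestry = n, n_hc = n_hc, seed = seed)
  meta <- generate_metadata(cfg)
  mods <- default_modules(n_genes, seed = seed + 1L)
  expr <- generate_expression(meta, mods, effects = effects,
                              n_genes = n_genes, seed = seed + 2L)
  list(meta = meta, modules = mods, expr = expr)
}
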