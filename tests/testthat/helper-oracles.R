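# Independent brute-force oracles, deliberately written from the definitions
# rather than sharing code with the package.

# AUC by exhaustive pair counting: concordant + half ties over all
# (lethal, indolent) pairs.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == "lethal"]
  neg <- scores[labels == "indolent"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p for a 2x2 table by full enumeration of the
# hypergeometric support using factorial ratios (choose), not dhyper.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Silhouette widths straight from the definition, one explicit double loop.
silhouette_brute_oracle <- function(d, groups) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(groups == groups[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- sum(d[i, same]) / length(same)
    b <- Inf
    for (g in setdiff(unique(groups), groups[i])) {
      others <- which(groups == g)
      b <- min(b, sum(d[i, others]) / length(others))
    }
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  s
}

# A small, fast, fully-specified synthetic cohort for unit tests.
tiny_sim_config <- function(seed = 1L, ...) {
  args <- list(n_lethal = 30L, n_indolent = 24L, n_genes = 200L,
               n_signal_genes = 30L, n_erg_signature_genes = 15L,
               n_stroma_genes = 10L, effect_size_delta = 2,
               n_lethal_subtypes = 1L, stroma_fraction = 4 / 54, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

random_small_table <- function() {
  matrix(sample(0:12, 4, replace = TRUE) + c(1, 0, 0, 1), 2, 2,
         dimnames = list(c("r1", "r2"), c("c1", "c2")))
}
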