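# Small in-code fixtures shared across tests.

# minimal well-formed table builder
make_tiny_table <- function(classes = c("benign", "benign", "pathogenic"),
                            scores = c(-0.5, -0.3, 0.5),
                            faf = c(1e-4, 0, NA)) {
  n <- length(classes)
  df <- data.frame(
    variant_id = sprintf("c.%dA>G", seq_len(n)),
    protein_change = sprintf("p.Ala%dVal", seq_len(n) + 1L),
    consensus_class = classes,
    BayesDel = scores,
    groupmax_faf = faf,
    stringsAsFactors = FALSE)
  variant_table(df)
}

# balanced two-class Gaussian variant table with optional VUS pool
make_gaussian_table <- function(n_path, n_benign, n_vus = 0L,
                                mu_b = -0.5, mu_p = 0.5, sigma = 0.35,
                                seed = 1L, tool = "BayesDel") {
  cfg <- synthetic_config(
    n_pathogenic = n_path, n_benign = n_benign, n_vus = n_vus,
    tools = stats::setNames(
      list(list(mu_benign = mu_b, mu_path = mu_p, sigma = sigma)), tool),
    faf_benign_common_fraction = 0, seed = seed)
  generate_variant_table(cfg)
}

# independent oracle: weighted Bernoulli log-likelihood
weighted_loglik <- function(beta, s, y, w) {
  eta <- beta[1] + beta[2] * s
  sum(w * (y * eta - log1p(exp(eta))))
}

# independent oracle: brute-force pairwise AUC
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

ref_tools <- c("CADD", "REVEL", "BayesDel", "AlphaMissense")
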