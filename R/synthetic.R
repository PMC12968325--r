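#' Synthetic dataset configuration
#'
#' Describes a synthetic single-gene missense dataset with the statistical
#' structure the calibration assumes: class-conditional (truncated) normal
#' score distributions per tool, a VUS pool with a latent pathogenic
#' fraction, residue positions enriched in a critical domain for pathogenic
#' variants, and a small common-frequency tail restricted to benign
#' variants.
#'
#' Defaults emulate the reference PHOX2B study conditions: 33 pathogenic,
#' 81 benign and 392 uncertain variants over a 314-residue protein with the
#' homeodomain at codons 98-157 holding about 82% of pathogenic variants.
#' Per-tool class means follow the reference class summaries and the
#' class-conditional spread is solved from the reference AUC via the
#' binormal relation `sigma = (mu_path - mu_benign) / (sqrt(2) * qnorm(AUC))`.
#'
#' @param n_pathogenic,n_benign,n_vus class sizes.
#' @param vus_latent_pathogenic_fraction probability a VUS is latently
#'   pathogenic (default 0.12, near the fraction of VUSs the best tools
#'   predict pathogenic).
#' @param tools named list per tool: `list(mu_benign=, mu_path=, sigma=)`;
#'   an optional `sigma_path` permits unequal variances (no exact logistic
#'   oracle then).
#' @param protein_length number of residues (default 314).
#' @param domain a [domain_definition()].
#' @param domain_pathogenic_enrichment probability a pathogenic variant's
#'   residue lies in the domain (default 0.82).
#' @param faf_benign_common_fraction fraction of benign records given a FAF
#'   above `faf_threshold` (default 0.9); remaining benign records get FAF 0.
#' @param faf_threshold the frequency-rule threshold the common tail must
#'   exceed (default 1e-6).
#' @param domain_score_shift_sd in-domain mean shift, in units of sigma, for
#'   [generate_exhaustive_scores()] (default 2).
#' @param alts_per_position alternate substitutions per position in the
#'   exhaustive table (default 6).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pathogenic = 33L, n_benign = 81L,
                             n_vus = 392L,
                             vus_latent_pathogenic_fraction = 0.12,
                             tools = default_synthetic_tools(),
                             protein_length = 314L,
                             domain = domain_definition(),
                             domain_pathogenic_enrichment = 0.82,
                             faf_benign_common_fraction = 0.9,
                             faf_threshold = 1e-6,
                             domain_score_shift_sd = 2,
                             alts_per_position = 6L,
                             seed = 1L) {
  stopifnot(n_pathogenic >= 0L, n_benign >= 0L, n_vus >= 0L,
            vus_latent_pathogenic_fraction >= 0,
            vus_latent_pathogenic_fraction <= 1,
            domain_pathogenic_enrichment >= 0,
            domain_pathogenic_enrichment <= 1,
            faf_benign_common_fraction >= 0, faf_benign_common_fraction <= 1,
            protein_length > domain$end_codon, alts_per_position >= 1L)
  for (tl in names(tools)) {
    stopifnot(tools[[tl]]$sigma > 0)
  }
  structure(list(n_pathogenic = as.integer(n_pathogenic),
                 n_benign = as.integer(n_benign), n_vus = as.integer(n_vus),
                 vus_latent_pathogenic_fraction = vus_latent_pathogenic_fraction,
                 tools = tools, protein_length = as.integer(protein_length),
                 domain = domain,
                 domain_pathogenic_enrichment = domain_pathogenic_enrichment,
                 faf_benign_common_fraction = faf_benign_common_fraction,
                 faf_threshold = faf_threshold,
                 domain_score_shift_sd = domain_score_shift_sd,
                 alts_per_position = as.integer(alts_per_position),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_synthetic_tools <- function() {
  ref <- list(CADD = c(19.00, 29.00, 0.963),
              REVEL = c(0.36, 0.90, 0.982),
              BayesDel = c(-0.14, 0.49, 0.992),
              AlphaMissense = c(0.30, 0.96, 0.961))
  lapply(ref, function(v) {
    list(mu_benign = v[1], mu_path = v[2],
         sigma = (v[2] - v[1]) / (sqrt(2) * stats::qnorm(v[3])))
  })
}

# Truncated-normal sampler by inverse CDF; errors when the truncation window
# carries essentially no mass.
rtrunc_norm <- function(n, mu, sigma, lower, upper) {
  plo <- stats::pnorm((lower - mu) / sigma)
  phi <- stats::pnorm((upper - mu) / sigma)
  if (any(phi - plo < 1e-12)) {
    mu <- mu[which.min(phi - plo)][1]
    sigma <- sigma[which.min(phi - plo)][1]
    warning(sprintf("truncation window [%g, %g] carries almost no mass for N(%g, %g)",
                    lower, upper, mu, sigma), call. = FALSE)
    stop("impossible truncation: adjust the score distribution or domain",
         call. = FALSE)
  }
  mu + sigma * stats::qnorm(stats::runif(n, plo, phi))
}

#' Generate a synthetic variant table with hidden truth
#'
#' Draws scores from class-conditional truncated normals (VUSs from the
#' latent mixture), residue positions from the domain-enrichment model, and
#' allele frequencies per config. The latent class is stored in a `truth`
#' column that calibration code never reads; `consensus_class` is the truth
#' for known variants and `"vus"` for the uncertain pool. Reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param tool_ranges score domains used for truncation and table
#'   validation.
#' @return a [variant_table()] with extra column `truth`.
#' @export
generate_variant_table <- function(cfg,
                                   tool_ranges = default_tool_ranges()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_pathogenic + cfg$n_benign + cfg$n_vus
    consensus <- rep(c("pathogenic", "benign", "vus"),
                     c(cfg$n_pathogenic, cfg$n_benign, cfg$n_vus))
    truth <- consensus
    is_vus <- consensus == "vus"
    truth[is_vus] <- ifelse(
      stats::runif(sum(is_vus)) < cfg$vus_latent_pathogenic_fraction,
      "pathogenic", "benign")

    dom <- cfg$domain
    dom_pos <- dom$start_codon:dom$end_codon
    out_pos <- setdiff(2:cfg$protein_length, dom_pos)
    draw_pos <- function(is_path) {
      if (is_path && stats::runif(1) < cfg$domain_pathogenic_enrichment) {
        sample(dom_pos, 1L)
      } else if (is_path) {
        sample(out_pos, 1L)
      } else {
        sample(2:cfg$protein_length, 1L)
      }
    }
    ref_seq <- sample(AA3, cfg$protein_length, replace = TRUE)
    seen <- new.env(hash = TRUE)
    pos <- integer(n); ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      for (attempt in 1:200) {
        p <- draw_pos(truth[i] == "pathogenic")
        a <- sample(setdiff(AA3, ref_seq[p]), 1L)
        key <- paste0(p, a)
        if (is.null(seen[[key]])) { seen[[key]] <- TRUE; break }
        if (attempt == 200L) stop("could not draw a unique substitution",
                                  call. = FALSE)
      }
      pos[i] <- p; ref[i] <- ref_seq[p]; alt[i] <- a
    }

    df <- data.frame(variant_id = sprintf("synv%04d", seq_len(n)),
                     protein_change = format_protein_hgvs(ref, pos, alt),
                     ref_aa = ref, residue_index = pos, alt_aa = alt,
                     consensus_class = consensus, truth = truth,
                     stringsAsFactors = FALSE)
    for (tl in names(cfg$tools)) {
      tp <- cfg$tools[[tl]]
      rng <- tool_ranges[[tl]]
      mu <- ifelse(truth == "pathogenic", tp$mu_path, tp$mu_benign)
      sd_p <- if (!is.null(tp$sigma_path)) tp$sigma_path else tp$sigma
      sdv <- ifelse(truth == "pathogenic", sd_p, tp$sigma)
      df[[tl]] <- rtrunc_norm(n, mu, sdv, rng[1], rng[2])
    }
    faf <- rep(NA_real_, n)
    benign_idx <- which(consensus == "benign")
    n_common <- round(cfg$faf_benign_common_fraction * length(benign_idx))
    if (length(benign_idx) > 0L) {
      common <- benign_idx[seq_len(n_common)]
      faf[common] <- 10^stats::runif(length(common),
                                     log10(cfg$faf_threshold * 10),
                                     log10(1e-3))
      faf[setdiff(benign_idx, common)] <- 0
    }
    df$groupmax_faf <- faf
    variant_table(df, tool_ranges = tool_ranges)
  })
}

#' Exact logistic coefficients for equal-variance Gaussian classes
#'
#' For class-conditional scores `N(mu_benign, sigma^2)` and
#' `N(mu_path, sigma^2)` with prior pathogenic probability `prior`, the
#' Bayes posterior is exactly logistic with
#' `beta1 = (mu_path - mu_benign) / sigma^2` and
#' `beta0 = logit(prior) + (mu_benign^2 - mu_path^2) / (2 * sigma^2)`.
#' Serves as the independent oracle for parameter-recovery tests; the
#' truncation applied by the generator introduces a small bias at extreme
#' truncation.
#'
#' @param cfg a [synthetic_config()].
#' @param tool tool name.
#' @param prior prior probability of pathogenicity.
#' @return named numeric `c(beta0, beta1)`.
#' @export
theoretical_logistic_params <- function(cfg, tool, prior) {
  stopifnot(inherits(cfg, "synthetic_config"), prior > 0, prior < 1)
  tp <- cfg$tools[[tool]]
  if (is.null(tp)) stop("unknown tool: ", tool, call. = FALSE)
  if (!is.null(tp$sigma_path) && tp$sigma_path != tp$sigma) {
    stop("theoretical_logistic_params: oracle requires equal class variances",
         call. = FALSE)
  }
  beta1 <- (tp$mu_path - tp$mu_benign) / tp$sigma^2
  beta0 <- stats::qlogis(prior) +
    (tp$mu_benign^2 - tp$mu_path^2) / (2 * tp$sigma^2)
  c(beta0 = beta0, beta1 = beta1)
}

#' Generate an exhaustive per-position theoretical score table
#'
#' One row per (position 2..protein_length, alternate substitution), with
#' per-tool scores drawn around the benign baseline plus an in-domain mean
#' shift of `cfg$domain_score_shift_sd` standard deviations. A shift of 0
#' yields no enrichment (uniform p-values over seeds).
#'
#' @param cfg a [synthetic_config()].
#' @param tool_ranges score domains used for truncation.
#' @return data.frame with columns `position`, `alt_index`, and one column
#'   per tool; `(protein_length - 1) * alts_per_position` rows.
#' @export
generate_exhaustive_scores <- function(cfg,
                                       tool_ranges = default_tool_ranges()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(derive_seed(cfg$seed, 777L), {
    positions <- rep(2:cfg$protein_length, each = cfg$alts_per_position)
    alt_index <- rep(seq_len(cfg$alts_per_position),
                     times = cfg$protein_length - 1L)
    df <- data.frame(position = positions, alt_index = alt_index)
    inside <- in_domain(positions, cfg$domain)
    for (tl in names(cfg$tools)) {
      tp <- cfg$tools[[tl]]
      rng <- tool_ranges[[tl]]
      mu <- tp$mu_benign + cfg$domain_score_shift_sd * tp$sigma * inside
      df[[tl]] <- rtrunc_norm(length(positions), mu, tp$sigma, rng[1], rng[2])
    }
    df
  })
}
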