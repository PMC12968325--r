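#' Calibration configuration
#'
#' Collects the tunable parameters of the threshold calibration.
#'
#' The prior probability that a missense variant in the gene is pathogenic,
#' `p_path`, defaults to 0.0441 (the genome-wide missense estimate used by
#' the ClinGen-endorsed calibration), optionally inflated by
#' `(1 + p_missense_adjust)` to adjust for the exclusion of non-missense
#' variants; the adjustment defaults to 0. Likelihood-ratio targets per
#' strength level default to the exponential scale implied by the posterior
#' probability anchors 0.10 (supporting), 0.21 (moderate), 0.61 (strong)
#' and 0.98 (very strong) at the effective prior:
#' `LR = posterior odds / prior odds`. Both the posteriors and the LRs can
#' be overridden directly.
#'
#' @param p_path base prior probability of pathogenicity, in (0, 1).
#' @param p_missense_adjust nonnegative adjustment factor; the effective
#'   prior is `p_path * (1 + p_missense_adjust)`.
#' @param n_imputations number of imputation datasets (default 25).
#' @param z_one_sided one-sided normal quantile for the 95% bound on the
#'   log-odds (default 1.64, the printed constant of the method).
#' @param posterior_targets named posterior-probability anchors used to
#'   derive LR targets when `lr_targets` is `NULL`.
#' @param lr_targets optional named numeric vector of likelihood-ratio
#'   targets (`supporting`, `moderate`, `strong`, `very_strong`), strictly
#'   increasing.
#' @param seed integer seed governing every stochastic step.
#' @param irls_tol convergence tolerance of the iteratively reweighted
#'   least-squares fit (default 1e-8).
#' @param irls_max_iter iteration cap (default 100).
#' @param separation_bound absolute slope bound beyond which the fit is
#'   declared separated (default 100 per score unit).
#' @param ridge optional ridge stabiliser added to the information matrix
#'   (default 0 = off).
#' @param score_domains named list of per-tool score domains used for
#'   threshold root finding.
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(p_path = 0.0441,
                               p_missense_adjust = 0,
                               n_imputations = 25L,
                               z_one_sided = 1.64,
                               posterior_targets = c(supporting = 0.10,
                                                     moderate = 0.21,
                                                     strong = 0.61,
                                                     very_strong = 0.98),
                               lr_targets = NULL,
                               seed = 1L,
                               irls_tol = 1e-8,
                               irls_max_iter = 100L,
                               separation_bound = 100,
                               ridge = 0,
                               score_domains = default_tool_ranges()) {
  stopifnot(p_path > 0, p_path < 1, p_missense_adjust >= 0,
            n_imputations >= 1L, z_one_sided > 0,
            irls_tol > 0, irls_max_iter >= 1L, ridge >= 0)
  p_eff <- p_path * (1 + p_missense_adjust)
  stopifnot(p_eff < 1)
  if (is.null(lr_targets)) {
    post <- posterior_targets[STRENGTH_LEVELS]
    lr_targets <- (post / (1 - post)) / (p_eff / (1 - p_eff))
  }
  lr_targets <- lr_targets[STRENGTH_LEVELS]
  if (any(diff(lr_targets) <= 0)) {
    stop("lr_targets must be strictly increasing from supporting to very_strong",
         call. = FALSE)
  }
  if (lr_targets[[1L]] <= 1) {
    stop("supporting LR target must exceed 1; the posterior anchors are ",
         "inconsistent with a prior this large - supply lr_targets directly",
         call. = FALSE)
  }
  structure(list(p_path = p_path, p_missense_adjust = p_missense_adjust,
                 p_path_effective = p_eff,
                 n_imputations = as.integer(n_imputations),
                 z_one_sided = z_one_sided,
                 posterior_targets = posterior_targets,
                 lr_targets = lr_targets, seed = as.integer(seed),
                 irls_tol = irls_tol,
                 irls_max_iter = as.integer(irls_max_iter),
                 separation_bound = separation_bound, ridge = ridge,
                 score_domains = score_domains),
            class = "calibration_config")
}

#' Prior-matching weights for known pathogenic/benign variants
#'
#' Reweights the classified sample so that its effective pathogenic fraction
#' equals the population prior: pathogenic records receive
#' `p_path / p_path_samp` and benign records `(1 - p_path) / (1 - p_path_samp)`
#' where `p_path_samp` is the pathogenic fraction among classified records.
#'
#' @param labels character vector in `{"pathogenic", "benign"}`.
#' @param p_path population prior probability of pathogenicity, in (0, 1).
#' @return numeric weight per record.
#' @export
prior_matching_weights <- function(labels, p_path) {
  stopifnot(p_path > 0, p_path < 1)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("pathogenic", "benign"))
  if (length(bad) > 0L) {
    stop("prior_matching_weights: labels must be pathogenic/benign, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p_samp <- mean(labels == "pathogenic")
  if (p_samp == 0 || p_samp == 1) {
    stop("degenerate sample: both pathogenic and benign labels are required",
         call. = FALSE)
  }
  ifelse(labels == "pathogenic", p_path / p_samp, (1 - p_path) / (1 - p_samp))
}

#' Weighted logistic regression by iteratively reweighted least squares
#'
#' Maximises the weighted Bernoulli log-likelihood
#' `sum(w * (y * eta - log(1 + exp(eta))))` with `eta = beta0 + beta1 * s`.
#' The coefficient covariance is the inverse of the weighted Fisher
#' information at the optimum (dispersion fixed at 1, fractional case
#' weights allowed). Iterations whose slope magnitude exceeds
#' `cfg$separation_bound` abort with a separation error naming the tool;
#' setting `cfg$ridge > 0` penalises the information matrix as a stabiliser.
#'
#' @param scores numeric predictor (at least two distinct values).
#' @param labels binary response (0/1, or logical).
#' @param weights positive case weights.
#' @param cfg a [calibration_config()].
#' @param tool tool name used in error messages.
#' @return object of class `logistic_fit` with elements `beta0`, `beta1`,
#'   `var_beta0`, `var_beta1`, `cov_beta`, `converged`, `n_iter`, `n_obs`.
#' @export
fit_weighted_logistic <- function(scores, labels, weights = NULL,
                                  cfg = calibration_config(),
                                  tool = "score") {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), length(scores) == length(y))
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  if (is.null(weights)) weights <- rep(1, length(y)) else weights <- weights[keep]
  stopifnot(all(weights > 0))
  if (length(unique(scores)) < 2L) {
    stop("fit_weighted_logistic: need at least two distinct scores",
         call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("fit_weighted_logistic: both classes must be present", call. = FALSE)
  }
  x <- cbind(1, scores)
  beta <- c(stats::qlogis(min(max(stats::weighted.mean(y, weights), 1e-6),
                              1 - 1e-6)), 0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(x, weights * (y - p))) - cfg$ridge * beta
    wq <- weights * p * (1 - p)
    info <- crossprod(x, x * wq) + diag(cfg$ridge, 2L)
    step <- tryCatch(solve(info, g), error = function(e) {
      stop(sprintf("separation error for %s: Fisher information singular (fitted probabilities degenerate)",
                   tool), call. = FALSE)
    })
    beta_new <- beta + step
    if (!all(is.finite(beta_new)) ||
        abs(beta_new[2]) > cfg$separation_bound) {
      stop(sprintf("separation error for %s: slope exceeded bound %g during IRLS; classes may be perfectly separated (a ridge stabiliser can be enabled in the config)",
                   tool, cfg$separation_bound), call. = FALSE)
    }
    done <- max(abs(beta_new - beta)) < cfg$irls_tol
    beta <- beta_new
    if (done) { converged <- TRUE; break }
    if (iter >= cfg$irls_max_iter) break
  }
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(x, x * (weights * p * (1 - p))) + diag(cfg$ridge, 2L)
  vc <- solve(info)
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 var_beta0 = vc[1, 1], var_beta1 = vc[2, 2],
                 cov_beta = vc[1, 2], converged = converged,
                 n_iter = iter, n_obs = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: beta0 = %.4f (SE %.4f), beta1 = %.4f (SE %.4f), n = %d, %s in %d iter\n",
              x$beta0, sqrt(x$var_beta0), x$beta1, sqrt(x$var_beta1), x$n_obs,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Impute pathogenic/benign labels for VUSs
#'
#' Draws one Bernoulli label per VUS from its model probability of
#' pathogenicity. The random stream is derived from `seed` and the
#' imputation index so that imputations are reproducible and
#' order-independent; the caller's RNG state is left untouched.
#'
#' @param p_path_given_s probabilities in \[0, 1\], one per VUS.
#' @param seed integer base seed; `NULL` uses the current RNG stream.
#' @param imputation imputation index (>= 1) mixed into the stream.
#' @return integer vector of 0/1 labels (1 = pathogenic).
#' @export
impute_vus_labels <- function(p_path_given_s, seed = NULL, imputation = 1L) {
  p <- as.numeric(p_path_given_s)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("impute_vus_labels: probabilities must lie in [0, 1]", call. = FALSE)
  }
  draw <- function() stats::rbinom(length(p), 1L, p)
  if (is.null(seed)) return(draw())
  with_seed(derive_seed(seed, imputation), draw())
}

# Deterministic substream seed < 2^31 from (seed, index).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1299709) %%
               2147483629)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Weight of an imputed VUS
#'
#' A VUS whose model probability of pathogenicity is `p` contributes with
#' weight `2 * |0.5 - p|`: confidently classified VUSs count almost fully,
#' coin-flip VUSs not at all. Variants with known class carry weight 1.
#'
#' @param p_i probabilities in \[0, 1\].
#' @return weights in \[0, 1\].
#' @export
vus_weight <- function(p_i) {
  p <- as.numeric(p_i)
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop("vus_weight: probability outside [0, 1]", call. = FALSE)
  }
  2 * abs(0.5 - p)
}

#' Pool logistic fits across imputations by Rubin's rules
#'
#' Pooled coefficients are the means of the per-imputation coefficients; the
#' pooled covariance is the mean within-imputation covariance plus
#' `(1 + 1/m)` times the between-imputation covariance of the coefficient
#' vectors, applied elementwise to the full 2x2 matrix.
#'
#' @param fits list of `logistic_fit` objects (m >= 1).
#' @return object of class `c("pooled_fit", "logistic_fit")` with the
#'   `logistic_fit` fields plus `within_var`, `between_var` (length-2, for
#'   intercept and slope) and `m`.
#' @export
pool_rubin <- function(fits) {
  if (inherits(fits, "logistic_fit")) fits <- list(fits)
  m <- length(fits)
  if (m == 0L) stop("pool_rubin: no fits to pool", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "logistic_fit")))
  coefs <- t(vapply(fits, function(f) c(f$beta0, f$beta1), numeric(2L)))
  within <- Reduce(`+`, lapply(fits, function(f) {
    matrix(c(f$var_beta0, f$cov_beta, f$cov_beta, f$var_beta1), 2L)
  })) / m
  if (m == 1L) {
    warning("pool_rubin: single imputation; between-imputation variance set to 0",
            call. = FALSE)
    between <- matrix(0, 2L, 2L)
  } else {
    between <- stats::cov(coefs)
  }
  total <- within + (1 + 1 / m) * between
  qbar <- colMeans(coefs)
  structure(list(beta0 = qbar[1], beta1 = qbar[2],
                 var_beta0 = total[1, 1], var_beta1 = total[2, 2],
                 cov_beta = total[1, 2],
                 converged = all(vapply(fits, `[[`, TRUE, "converged")),
                 n_iter = max(vapply(fits, `[[`, 1L, "n_iter")),
                 n_obs = fits[[1L]]$n_obs,
                 within_var = c(within[1, 1], within[2, 2]),
                 between_var = c(between[1, 1], between[2, 2]),
                 m = m),
            class = c("pooled_fit", "logistic_fit"))
}

#' Positive likelihood ratio at a score
#'
#' Under the logistic model, the posterior odds of pathogenicity at score
#' `s` are `exp(beta0 + beta1 * s)`; dividing by the prior odds
#' `p_path / (1 - p_path)` gives the positive likelihood ratio
#' `lr+ = exp(beta0 + beta1 * s) * (1 - p_path) / p_path`.
#'
#' @param fit a `logistic_fit` or `pooled_fit`.
#' @param s score(s).
#' @param p_path prior probability of pathogenicity, in (0, 1).
#' @return positive likelihood ratio(s).
#' @export
lr_plus <- function(fit, s, p_path) {
  stopifnot(inherits(fit, "logistic_fit"), p_path > 0, p_path < 1)
  exp(fit$beta0 + fit$beta1 * s) * (1 - p_path) / p_path
}

#' Confidence-bounded likelihood ratio at a score
#'
#' For the pathogenic direction, the one-sided 95% lower bound of the
#' log-odds is used in place of the point estimate:
#' `exp(beta0 + beta1*s - z*sqrt(var0 + s^2*var1 + 2*s*cov)) * (1-p)/p`.
#' For the benign direction the odds are inverted and the upper bound used
#' (the sign in front of `z` flips):
#' `1 / (exp(beta0 + beta1*s + z*sqrt(.)) * (1-p)/p)`.
#'
#' @inheritParams lr_plus
#' @param z one-sided normal quantile (default 1.64).
#' @param direction `"pathogenic"` or `"benign"`.
#' @return bounded likelihood ratio(s), always <= the point estimate in the
#'   corresponding direction.
#' @export
lr_plus_lower_bound <- function(fit, s, p_path, z = 1.64,
                                direction = c("pathogenic", "benign")) {
  direction <- match.arg(direction)
  stopifnot(inherits(fit, "logistic_fit"), p_path > 0, p_path < 1, z > 0)
  if (fit$var_beta0 < 0 || fit$var_beta1 < 0) {
    stop("lr_plus_lower_bound: negative variance input", call. = FALSE)
  }
  q <- fit$var_beta0 + s^2 * fit$var_beta1 + 2 * s * fit$cov_beta
  q <- pmax(q, 0)  # guard against negligible negative values from rounding
  eta <- fit$beta0 + fit$beta1 * s
  prior_odds <- p_path / (1 - p_path)
  if (direction == "pathogenic") {
    exp(eta - z * sqrt(q)) / prior_odds
  } else {
    1 / (exp(eta + z * sqrt(q)) / prior_odds)
  }
}

#' Locate score thresholds for each evidence strength level
#'
#' For each pathogenic strength level, finds the score at which the bounded
#' likelihood ratio [lr_plus_lower_bound()] attains the level's LR target,
#' by bracketed one-dimensional root finding ([stats::uniroot()]) over the
#' tool's score domain; analogously for the benign direction with inverted
#' odds. Levels whose target is never attained within the domain are marked
#' unreachable. If the bounded LR crosses a target more than once the most
#' conservative root is chosen (largest for pathogenic, smallest for
#' benign) with a warning.
#'
#' @param fit a `pooled_fit` (or `logistic_fit`); the slope must be positive
#'   (higher score = more pathogenic).
#' @param cfg a [calibration_config()] supplying `lr_targets` and
#'   `z_one_sided`.
#' @param score_domain length-2 numeric; defaults to the tool's entry in
#'   `cfg$score_domains`.
#' @param tool tool name for the resulting table.
#' @param grid_n grid resolution for bracketing (default 4096).
#' @return a [threshold_table()].
#' @export
find_strength_thresholds <- function(fit, cfg, score_domain = NULL,
                                     tool = "score", grid_n = 4096L) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(score_domain)) score_domain <- cfg$score_domains[[tool]]
  stopifnot(is.numeric(score_domain), length(score_domain) == 2L,
            all(is.finite(score_domain)))
  if (fit$beta1 == 0) {
    stop("find_strength_thresholds: slope is zero, direction of pathogenicity unknown",
         call. = FALSE)
  }
  if (fit$beta1 < 0) {
    stop("find_strength_thresholds: negative slope; orient scores so that higher means more pathogenic",
         call. = FALSE)
  }
  p <- cfg$p_path_effective
  z <- cfg$z_one_sided
  grid <- seq(score_domain[1], score_domain[2], length.out = grid_n)
  solve_direction <- function(direction) {
    lb <- lr_plus_lower_bound(fit, grid, p, z, direction)
    vapply(STRENGTH_LEVELS, function(lv) {
      target <- cfg$lr_targets[[lv]]
      f <- log(lb) - log(target)
      if (all(f < 0)) return(NA_real_)          # never attained: unreachable
      if (all(f >= 0)) return(score_domain[if (direction == "pathogenic") 1L else 2L])
      sign_change <- which(f[-1] * f[-length(f)] <= 0)
      if (length(sign_change) > 1L) {
        warning(sprintf("multiple roots for %s %s threshold (%s); taking the most conservative",
                        tool, direction, lv), call. = FALSE)
      }
      pick <- if (direction == "pathogenic") max(sign_change) else min(sign_change)
      root <- stats::uniroot(function(s) {
        log(lr_plus_lower_bound(fit, s, p, z, direction)) - log(target)
      }, lower = grid[pick], upper = grid[pick + 1L], tol = 1e-10)$root
      root
    }, numeric(1L))
  }
  threshold_table(tool,
                  pathogenic = solve_direction("pathogenic"),
                  benign = solve_direction("benign"),
                  score_domain = score_domain)
}

#' Calibrate one prediction tool on a variant table
#'
#' Runs the four-step calibration end to end:
#' \enumerate{
#'   \item initial weighted logistic regression of pathogenicity on score
#'     over the variants with known class, with [prior_matching_weights()]
#'     matching the sample to the population prior;
#'   \item generation of `n_imputations` imputation datasets assigning each
#'     VUS a pathogenic/benign label drawn from its step-1 model
#'     probability;
#'   \item per-imputation weighted logistic regression over all variants
#'     (weight 1 for known-class variants, [vus_weight()] for VUSs);
#'   \item pooling of coefficients and covariance by [pool_rubin()].
#' }
#' Thresholds are then located with [find_strength_thresholds()]. Variants
#' missing the tool's score are excluded from the fit with a message.
#' Imputation fits that fail are dropped with a warning; an error is raised
#' if fewer than half survive.
#'
#' @param table a [variant_table()].
#' @param tool name of the score column to calibrate.
#' @param cfg a [calibration_config()].
#' @return object of class `tool_calibration`: list with `tool`,
#'   `initial_fit`, `pooled_fit`, `thresholds`, `p_path_given_s` (named by
#'   variant_id; step-1 probability for every scored variant), `m_used`,
#'   `config`.
#' @export
calibrate_tool <- function(table, tool, cfg = calibration_config()) {
  stopifnot(inherits(table, "variant_table"))
  if (!tool %in% names(table)) {
    stop("calibrate_tool: no score column for tool ", tool, call. = FALSE)
  }
  df <- as.data.frame(table)
  scored <- !is.na(df[[tool]])
  n_dropped <- sum(!scored)
  if (n_dropped > 0L) {
    message(sprintf("calibrate_tool: %d variant(s) missing %s scores excluded from this tool's fit",
                    n_dropped, tool))
  }
  df <- df[scored, , drop = FALSE]
  known <- df$consensus_class %in% c("pathogenic", "benign")
  if (length(unique(df$consensus_class[known])) < 2L) {
    stop("calibrate_tool: need both pathogenic and benign labelled variants",
         call. = FALSE)
  }
  p_eff <- cfg$p_path_effective

  # step 1: prior-matched fit on known-class variants
  w1 <- prior_matching_weights(df$consensus_class[known], p_eff)
  fit0 <- fit_weighted_logistic(df[[tool]][known],
                                df$consensus_class[known] == "pathogenic",
                                w1, cfg, tool = tool)
  p_all <- stats::plogis(fit0$beta0 + fit0$beta1 * df[[tool]])
  names(p_all) <- df$variant_id

  # VUSs in sorted-id order so imputation draws are row-order independent
  vus_idx <- which(!known)
  vus_idx <- vus_idx[order(df$variant_id[vus_idx])]
  p_vus <- p_all[vus_idx]

  if (length(vus_idx) == 0L) {
    fits <- replicate(cfg$n_imputations, fit0, simplify = FALSE)
  } else {
    fits <- vector("list", cfg$n_imputations)
    for (j in seq_len(cfg$n_imputations)) {
      y_vus <- impute_vus_labels(p_vus, seed = cfg$seed, imputation = j)
      y <- ifelse(df$consensus_class == "pathogenic", 1, 0)
      y[vus_idx] <- y_vus
      w <- rep(1, nrow(df))
      w[vus_idx] <- vus_weight(p_vus)
      usable <- w > 0  # coin-flip VUSs carry no information
      fits[[j]] <- tryCatch(
        fit_weighted_logistic(df[[tool]][usable], y[usable], w[usable],
                              cfg, tool = tool),
        error = function(e) e)
    }
    failed <- vapply(fits, inherits, TRUE, "error")
    if (any(failed)) {
      warning(sprintf("calibrate_tool: dropped %d of %d imputation fit(s) for %s",
                      sum(failed), cfg$n_imputations, tool), call. = FALSE)
      fits <- fits[!failed]
    }
    if (length(fits) < cfg$n_imputations / 2) {
      stop("calibrate_tool: fewer than half of the imputation fits converged for ",
           tool, call. = FALSE)
    }
  }
  pooled <- suppressWarnings(pool_rubin(fits))
  thresholds <- find_strength_thresholds(pooled, cfg,
                                         cfg$score_domains[[tool]],
                                         tool = tool)
  structure(list(tool = tool, initial_fit = fit0, pooled_fit = pooled,
                 thresholds = thresholds, p_path_given_s = p_all,
                 m_used = length(fits), config = cfg),
            class = "tool_calibration")
}

#' @export
print.tool_calibration <- function(x, ...) {
  cat(sprintf("calibration of %s (m = %d imputations, seed %d)\n",
              x$tool, x$m_used, x$config$seed))
  print(x$pooled_fit)
  print(x$thresholds)
  invisible(x)
}
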