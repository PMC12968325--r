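test_that("prior-matching weights rebalance the sample to the population prior", {
  labels <- rep(c("pathogenic", "benign"), c(33, 81))
  w <- prior_matching_weights(labels, p_path = 0.05)
  p_samp <- 33 / 114
  expect_equal(unique(w[labels == "pathogenic"]), 0.05 / p_samp)
  expect_equal(unique(w[labels == "benign"]), 0.95 / (1 - p_samp))
  expect_equal(unique(w[labels == "pathogenic"]), 0.1727, tolerance = 1e-3)
  expect_equal(unique(w[labels == "benign"]), 1.3370, tolerance = 1e-3)
  # weighted pathogenic fraction equals the prior
  expect_equal(sum(w[labels == "pathogenic"]) / sum(w), 0.05)

  expect_equal(unique(prior_matching_weights(labels, p_path = p_samp)), 1)
  expect_error(prior_matching_weights(rep("pathogenic", 5), 0.05),
               "degenerate")
})

test_that("IRLS finds the trivial solution when label is independent of score", {
  fit <- fit_weighted_logistic(c(0, 1, 0, 1), c(0, 0, 1, 1))
  expect_equal(fit$beta0, 0, tolerance = 1e-8)
  expect_equal(fit$beta1, 0, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("IRLS matches an independent optimizer of the weighted log-likelihood", {
  set.seed(11)
  for (k in 1:5) {
    s <- rnorm(10)
    y <- rbinom(10, 1, plogis(0.5 + s))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- runif(10, 0.2, 2)
    fit <- tryCatch(fit_weighted_logistic(s, y, w), error = function(e) NULL)
    if (is.null(fit)) next  # separable draw: no finite optimum to compare
    opt <- optim(c(0, 0), function(b) -weighted_loglik(b, s, y, w),
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(fit$beta0, opt$par[1], tolerance = 1e-3)
    expect_equal(fit$beta1, opt$par[2], tolerance = 1e-3)
  }
})

test_that("IRLS coefficients and covariance agree with glm as a second oracle", {
  set.seed(21)
  s <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.3 + 1.2 * s))
  w <- runif(40, 0.5, 1.5)
  fit <- fit_weighted_logistic(s, y, w)
  g <- suppressWarnings(glm(y ~ s, family = quasibinomial(), weights = w))
  expect_equal(fit$beta0, unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(fit$beta1, unname(coef(g)[2]), tolerance = 1e-6)
  vc <- summary(g)$cov.unscaled  # (X'WX)^-1, dispersion fixed at 1
  expect_equal(fit$var_beta0, vc[1, 1], tolerance = 1e-4)
  expect_equal(fit$var_beta1, vc[2, 2], tolerance = 1e-4)
  expect_equal(fit$cov_beta, vc[1, 2], tolerance = 1e-4)
})

test_that("perfect separation raises a separation error naming the tool", {
  expect_error(
    fit_weighted_logistic(c(-1, -1, 1, 1), c(0, 0, 1, 1), tool = "REVEL"),
    "separation error for REVEL")
})

test_that("VUS label imputation is Bernoulli with reproducible substreams", {
  expect_equal(impute_vus_labels(rep(1, 50), seed = 3), rep(1L, 50))
  expect_equal(impute_vus_labels(rep(0, 50), seed = 3), rep(0L, 50))
  draws <- impute_vus_labels(rep(0.3, 10000), seed = 9, imputation = 1)
  expect_lt(abs(mean(draws) - 0.3), 0.015)  # 3 binomial SDs
  expect_identical(draws, impute_vus_labels(rep(0.3, 10000), seed = 9,
                                            imputation = 1))
  expect_false(identical(draws, impute_vus_labels(rep(0.3, 10000), seed = 9,
                                                  imputation = 2)))
  expect_error(impute_vus_labels(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("VUS weights measure distance from the coin flip", {
  expect_equal(vus_weight(0.5), 0)
  expect_equal(vus_weight(1), 1)
  expect_equal(vus_weight(0.8), 0.6)
  expect_error(vus_weight(-0.1), "\\[0, 1\\]")
})

test_that("Rubin pooling combines within- and between-imputation variance", {
  mk_fit <- function(b0, b1, v0 = 0.5, v1 = 0.5, cv = 0) {
    structure(list(beta0 = b0, beta1 = b1, var_beta0 = v0, var_beta1 = v1,
                   cov_beta = cv, converged = TRUE, n_iter = 1L, n_obs = 10L),
              class = "logistic_fit")
  }
  # identical fits: between-variance zero, total equals within
  pool <- pool_rubin(list(mk_fit(1, 2), mk_fit(1, 2), mk_fit(1, 2)))
  expect_equal(pool$beta1, 2)
  expect_equal(pool$between_var, c(0, 0))
  expect_equal(pool$var_beta1, 0.5)

  # hand-computed two-imputation example: slopes {1, 3}, each var 0.5;
  # between-variance = 2, total = 0.5 + (1 + 1/2) * 2 = 3.5
  pool2 <- pool_rubin(list(mk_fit(0, 1), mk_fit(0, 3)))
  expect_equal(pool2$beta1, 2)
  expect_equal(pool2$var_beta1, 3.5)

  expect_error(pool_rubin(list()), "no fits")
  expect_warning(pool_rubin(list(mk_fit(1, 2))), "single imputation")

  # pooled covariance stays a valid covariance over random fit sets
  set.seed(31)
  for (k in 1:100) {
    m <- sample(2:6, 1)
    fits <- replicate(m, {
      a <- matrix(rnorm(4), 2); v <- crossprod(a)  # random PSD within-cov
      mk_fit(rnorm(1), rnorm(1), v[1, 1], v[2, 2], v[1, 2])
    }, simplify = FALSE)
    p <- pool_rubin(fits)
    expect_lte(abs(p$cov_beta),
               sqrt(p$var_beta0 * p$var_beta1) + 1e-12)
  }
})

test_that("the likelihood ratio is posterior odds over prior odds", {
  mk <- function(b0, b1, v0 = 0, v1 = 0, cv = 0)
    structure(list(beta0 = b0, beta1 = b1, var_beta0 = v0, var_beta1 = v1,
                   cov_beta = cv, converged = TRUE, n_iter = 1L, n_obs = 1L),
              class = "logistic_fit")
  # uninformative score at slope 0 with intercept at the prior logit
  f0 <- mk(qlogis(0.3), 0)
  expect_equal(lr_plus(f0, c(-2, 0, 5), 0.3), rep(1, 3))
  # hand arithmetic: exp(-3 + 2*1) * 0.9/0.1 = exp(-1) * 9
  expect_equal(lr_plus(mk(-3, 2), 1, 0.1), exp(-1) * 9, tolerance = 1e-10)
  expect_equal(lr_plus(mk(-3, 2), 1, 0.1), 3.3110, tolerance = 1e-4)
  # strictly increasing in s for positive slope
  s <- seq(-2, 2, length.out = 50)
  expect_true(all(diff(lr_plus(mk(-3, 2), s, 0.1)) > 0))
})

test_that("the confidence bound penalises the likelihood ratio correctly", {
  mk <- function(v0, v1, cv)
    structure(list(beta0 = -3, beta1 = 2, var_beta0 = v0, var_beta1 = v1,
                   cov_beta = cv, converged = TRUE, n_iter = 1L, n_obs = 1L),
              class = "logistic_fit")
  # zero covariance matrix: bound equals the point estimate
  expect_equal(lr_plus_lower_bound(mk(0, 0, 0), 1, 0.1),
               lr_plus(mk(0, 0, 0), 1, 0.1))
  # hand arithmetic: exp(-1 - 1.64 * sqrt(0.05)) * 9
  lb <- lr_plus_lower_bound(mk(0.04, 0.01, 0), 1, 0.1, z = 1.64)
  expect_equal(lb, exp(-1 - 1.64 * sqrt(0.05)) * 9, tolerance = 1e-10)
  expect_equal(lb, 2.2944, tolerance = 1e-4)
  # bound never exceeds the point estimate (pathogenic direction)
  s <- seq(-2, 2, length.out = 41)
  f <- mk(0.2, 0.1, 0.05)
  expect_true(all(lr_plus_lower_bound(f, s, 0.1) <= lr_plus(f, s, 0.1)))
  # benign direction: inverted odds with the upper bound
  expect_equal(lr_plus_lower_bound(mk(0.04, 0.01, 0), 1, 0.1,
                                   direction = "benign"),
               1 / (exp(-1 + 1.64 * sqrt(0.05)) * 9), tolerance = 1e-10)
  f_neg <- mk(-0.1, 0.01, 0)
  expect_error(lr_plus_lower_bound(f_neg, 1, 0.1), "negative variance")
})

test_that("root-found thresholds match the zero-covariance closed form", {
  fit <- structure(list(beta0 = -3, beta1 = 2, var_beta0 = 0, var_beta1 = 0,
                        cov_beta = 0, converged = TRUE, n_iter = 1L,
                        n_obs = 1L),
                   class = c("pooled_fit", "logistic_fit"))
  targets <- c(supporting = 2.41, moderate = 5.79, strong = 18.7,
               very_strong = 350)
  cfg <- calibration_config(p_path = 0.1, lr_targets = targets)
  tt <- find_strength_thresholds(fit, cfg, score_domain = c(-5, 5),
                                 tool = "toy")
  closed_form <- (log(targets * 0.1 / 0.9) + 3) / 2
  expect_equal(unname(tt$pathogenic), unname(closed_form), tolerance = 1e-6)
  expect_equal(tt$pathogenic[["strong"]], 1.8657, tolerance = 1e-4)
  # benign thresholds: inverted odds, closed form mirrors with 1/target
  closed_benign <- (log(0.1 / 0.9 / targets) + 3) / 2
  expect_equal(unname(tt$benign), unname(closed_benign), tolerance = 1e-6)
  # ordering invariants
  expect_true(all(diff(tt$pathogenic) > 0))
  expect_true(all(diff(tt$benign) < 0))
})

test_that("unattainable strength levels are marked unreachable", {
  fit <- structure(list(beta0 = -3, beta1 = 2, var_beta0 = 0.5,
                        var_beta1 = 0.2, cov_beta = 0, converged = TRUE,
                        n_iter = 1L, n_obs = 1L),
                   class = c("pooled_fit", "logistic_fit"))
  cfg <- calibration_config(p_path = 0.1,
                            lr_targets = c(supporting = 2.41, moderate = 5.79,
                                           strong = 33.53, very_strong = 1124))
  tt <- find_strength_thresholds(fit, cfg, score_domain = c(-1, 1),
                                 tool = "toy")
  # max attainable bounded LR over [-1, 1] is below the very strong target
  expect_true(is.na(tt$pathogenic[["very_strong"]]))
  expect_error(find_strength_thresholds(
    structure(list(beta0 = 0, beta1 = 0, var_beta0 = 0, var_beta1 = 0,
                   cov_beta = 0, converged = TRUE, n_iter = 1L, n_obs = 1L),
              class = "logistic_fit"), cfg, c(-1, 1)), "slope is zero")
})

test_that("calibration without VUSs collapses to the initial fit", {
  vt <- make_gaussian_table(40, 80, n_vus = 0, mu_b = 0, mu_p = 3,
                            sigma = 1.2, seed = 5, tool = "CADD")
  cfg <- calibration_config(seed = 5, n_imputations = 10)
  cal <- suppressWarnings(calibrate_tool(vt, "CADD", cfg))
  expect_equal(cal$pooled_fit$beta0, cal$initial_fit$beta0)
  expect_equal(cal$pooled_fit$beta1, cal$initial_fit$beta1)
  expect_equal(cal$pooled_fit$between_var, c(0, 0))
})

test_that("coin-flip VUSs contribute nothing: pooled fit equals the known-variant fit", {
  # symmetric design with p_path = 0.5 puts every VUS exactly at p = 0.5
  df <- data.frame(
    variant_id = sprintf("v%02d", 1:6),
    protein_change = sprintf("p.Ala%dVal", 2:7),
    consensus_class = c("benign", "benign", "pathogenic", "pathogenic",
                        "vus", "vus"),  # classes overlap on the score axis
    BayesDel = c(-0.4, 0.2, -0.2, 0.4, 0, 0),
    stringsAsFactors = FALSE)
  vt <- variant_table(df)
  cfg <- calibration_config(p_path = 0.5, n_imputations = 5, seed = 2,
                            lr_targets = c(supporting = 2.08, moderate = 4.33,
                                           strong = 18.7, very_strong = 350))
  cal <- suppressMessages(calibrate_tool(vt, "BayesDel", cfg))
  known_fit <- fit_weighted_logistic(
    vt$BayesDel[1:4], c(0, 0, 1, 1), rep(1, 4), cfg, tool = "BayesDel")
  expect_equal(cal$pooled_fit$beta0, known_fit$beta0, tolerance = 1e-8)
  expect_equal(cal$pooled_fit$beta1, known_fit$beta1, tolerance = 1e-8)
})

test_that("seeded calibration runs are bit-reproducible", {
  vt <- make_gaussian_table(30, 60, n_vus = 120, seed = 8)
  cfg <- calibration_config(seed = 123, n_imputations = 5)
  c1 <- suppressWarnings(calibrate_tool(vt, "BayesDel", cfg))
  c2 <- suppressWarnings(calibrate_tool(vt, "BayesDel", cfg))
  expect_identical(c1$pooled_fit, c2$pooled_fit)
  expect_identical(c1$thresholds, c2$thresholds)
})

test_that("calibration recovers the exact Gaussian-oracle coefficients at scale", {
  # means deep inside the CADD domain so truncation cannot bias the oracle
  cfg_syn <- synthetic_config(
    n_pathogenic = 500L, n_benign = 2000L, n_vus = 2500L,
    vus_latent_pathogenic_fraction = 0.2,
    tools = list(CADD = list(mu_benign = 25, mu_path = 30, sigma = 3)),
    faf_benign_common_fraction = 0, seed = 77L)
  vt <- generate_variant_table(cfg_syn)
  cfg <- calibration_config(p_path = 0.2, n_imputations = 10, seed = 77,
                            lr_targets = c(supporting = 2.08, moderate = 4.33,
                                           strong = 18.7, very_strong = 350))
  cal <- suppressWarnings(calibrate_tool(vt, "CADD", cfg))
  oracle <- theoretical_logistic_params(cfg_syn, "CADD", prior = 0.2)
  expect_lt(abs(cal$pooled_fit$beta1 - oracle[["beta1"]]),
            2 * sqrt(cal$pooled_fit$var_beta1))
  expect_lt(abs(cal$pooled_fit$beta0 - oracle[["beta0"]]),
            2 * sqrt(cal$pooled_fit$var_beta0))
})

test_that("likelihood-ratio targets default to the posterior anchors at the prior", {
  cfg <- calibration_config(p_path = 0.0441)
  prior_odds <- 0.0441 / (1 - 0.0441)
  expect_equal(cfg$lr_targets[["supporting"]], (0.1 / 0.9) / prior_odds)
  expect_equal(cfg$lr_targets[["very_strong"]], (0.98 / 0.02) / prior_odds)
  expect_error(calibration_config(lr_targets = c(supporting = 5,
                                                 moderate = 4, strong = 33,
                                                 very_strong = 1000)),
               "strictly increasing")
})
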