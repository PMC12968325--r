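#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the fraction of
#' (pathogenic, benign) pairs ordered correctly by the score, ties counting
#' one half.
#'
#' @param prob_or_score numeric scores or probabilities (higher = more
#'   pathogenic).
#' @param labels binary (1/TRUE = pathogenic).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(prob_or_score, labels) {
  y <- as.numeric(labels)
  stopifnot(length(prob_or_score) == length(y), all(y %in% c(0, 1)))
  keep <- !is.na(prob_or_score)
  s <- prob_or_score[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("auc undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(s)  # midranks
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Standard ROC stepping from (0, 0) to (1, 1) over descending score
#' thresholds; tied scores form a single step (rendered as a diagonal
#' segment). The trapezoid area under the returned polyline equals [auc()].
#'
#' @inheritParams auc
#' @param scores numeric scores (higher = more pathogenic).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`; the first row
#'   is the `(0, 0)` anchor with threshold `Inf`.
#' @export
roc_points <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  keep <- !is.na(scores)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("roc undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y[ord]
  # collapse tied thresholds into single steps
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  data.frame(threshold = c(Inf, s[last_of_tie]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Class score difference test
#'
#' Reports the class mean scores and a two-sided p-value for the difference.
#' The default test is Welch's two-sample t-test on the raw scores; a
#' Mann-Whitney (Wilcoxon rank-sum) alternative is selectable. With two
#' degenerate equal samples the p-value is 1 by convention.
#'
#' @param benign_scores,path_scores numeric vectors (>= 2 values each).
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @return list with `mean_benign`, `mean_path`, `p_value`, `method`.
#' @export
class_score_difference <- function(benign_scores, path_scores,
                                   method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  b <- benign_scores[!is.na(benign_scores)]
  p <- path_scores[!is.na(path_scores)]
  stopifnot(length(b) >= 2L, length(p) >= 2L)
  pv <- if (stats::sd(b) == 0 && stats::sd(p) == 0) {
    if (isTRUE(all.equal(mean(b), mean(p)))) 1 else 0
  } else if (method == "welch") {
    stats::t.test(p, b, var.equal = FALSE)$p.value
  } else {
    stats::wilcox.test(p, b, exact = FALSE)$p.value
  }
  list(mean_benign = mean(b), mean_path = mean(p), p_value = pv,
       method = method)
}

#' Repeated stratified hold-out AUC
#'
#' Per replicate, a stratified random `train_fraction` of each consensus
#' class (pathogenic/benign/VUS) forms the training set; the calibration
#' pipeline is run on it with a single imputation; the remaining known-class
#' variants form the test set and are scored by the model probability of
#' pathogenicity; the AUC of those probabilities against the known labels is
#' recorded. Sampling is keyed by sorted `variant_id`, so results do not
#' depend on row order. A replicate whose test set lacks a class is redrawn
#' (up to 10 times). If a training fit is perfectly separated (see
#' [fit_weighted_logistic()]) the replicate ranks test variants by the raw
#' score oriented by the class means, which is monotone-equivalent to any
#' logistic model.
#'
#' @param table a [variant_table()].
#' @param tool score column to evaluate.
#' @param cfg a [calibration_config()]; its seed drives the replicate
#'   sampling, and single-imputation models reuse its other settings.
#' @param n_replicates number of random splits (default 200).
#' @param train_fraction fraction of each class used for training
#'   (default 0.8).
#' @return object of class `auc_summary`: list with `tool`, `n_replicates`,
#'   `per_replicate_auc`, `mean_auc`, `train_fraction`, `seed`.
#' @export
repeated_holdout_auc <- function(table, tool, cfg = calibration_config(),
                                 n_replicates = 200L, train_fraction = 0.8) {
  stopifnot(inherits(table, "variant_table"),
            train_fraction > 0, train_fraction < 1, n_replicates >= 1L)
  df <- as.data.frame(table)
  df <- df[!is.na(df[[tool]]), , drop = FALSE]
  df <- df[order(df$variant_id), , drop = FALSE]
  cls <- df$consensus_class
  idx_by_class <- split(seq_len(nrow(df)), cls)
  cfg1 <- cfg
  cfg1$n_imputations <- 1L
  n_fallback <- 0L

  one_replicate <- function(rep_seed) {
    for (attempt in 1:10) {
      train_idx <- sort(unlist(lapply(seq_along(idx_by_class), function(k) {
        ix <- idx_by_class[[k]]
        n_tr <- round(train_fraction * length(ix))
        with_seed(derive_seed(rep_seed, attempt * 8L + k),
                  sample(ix, min(max(n_tr, 1L), length(ix))))
      })))
      test_idx <- setdiff(seq_len(nrow(df)), train_idx)
      test_idx <- test_idx[cls[test_idx] %in% c("pathogenic", "benign")]
      if (length(unique(cls[test_idx])) == 2L) break
      if (attempt == 10L) {
        stop("repeated_holdout_auc: could not draw a test set containing both classes",
             call. = FALSE)
      }
    }
    train <- variant_table(df[train_idx, , drop = FALSE],
                           tool_ranges = attr(table, "tool_ranges"),
                           transcript = attr(table, "transcript"))
    cfg_rep <- cfg1
    cfg_rep$seed <- rep_seed
    prob <- tryCatch({
      cal <- suppressWarnings(suppressMessages(
        calibrate_tool(train, tool, cfg_rep)))
      fit <- cal$pooled_fit
      stats::plogis(fit$beta0 + fit$beta1 * df[[tool]][test_idx])
    }, error = function(e) {
      if (!grepl("separation|fewer than half", conditionMessage(e))) stop(e)
      n_fallback <<- n_fallback + 1L
      mu_p <- mean(df[[tool]][train_idx][cls[train_idx] == "pathogenic"])
      mu_b <- mean(df[[tool]][train_idx][cls[train_idx] == "benign"])
      sign(mu_p - mu_b) * df[[tool]][test_idx]
    })
    auc(prob, cls[test_idx] == "pathogenic")
  }

  aucs <- vapply(seq_len(n_replicates), function(r) {
    one_replicate(derive_seed(cfg$seed, 100000L + r))
  }, numeric(1L))
  if (n_fallback > 0L) {
    message(sprintf("repeated_holdout_auc: %d replicate(s) fell back to raw-score ranking after separation",
                    n_fallback))
  }
  structure(list(tool = tool, n_replicates = n_replicates,
                 per_replicate_auc = aucs, mean_auc = mean(aucs),
                 train_fraction = train_fraction, seed = cfg$seed),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf("%s: mean AUC %.4f over %d stratified %d/%d hold-out replicates (SD %.4f)\n",
              x$tool, x$mean_auc, x$n_replicates,
              round(100 * x$train_fraction),
              round(100 * (1 - x$train_fraction)),
              stats::sd(x$per_replicate_auc)))
  invisible(x)
}
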