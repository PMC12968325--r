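STRENGTH_LEVELS <- c("supporting", "moderate", "strong", "very_strong")

#' Score threshold table for one prediction tool
#'
#' Per-direction, per-strength boundary scores partitioning a tool's score
#' domain into benign strength intervals, an indeterminate middle, and
#' pathogenic strength intervals. Endpoint semantics follow the bracket
#' convention of interval notation like `[0.30, 0.43)` for pathogenic and
#' `(-0.52, -0.22]` for benign: pathogenic intervals are closed at their
#' lower bound, benign intervals closed at their upper bound. A strength
#' level whose likelihood-ratio target is never attained within the score
#' domain is unreachable (`NA` boundary, rendered as an em dash).
#'
#' @param tool tool name.
#' @param pathogenic named numeric vector of boundaries for
#'   `supporting`, `moderate`, `strong`, `very_strong` (NA = unreachable);
#'   a score `s` earns pathogenic strength L when `s >=` the level-L boundary
#'   (strongest such level wins).
#' @param benign named numeric vector, same levels; a score earns benign
#'   strength L when `s <=` the level-L boundary (strongest level wins).
#' @param score_domain length-2 numeric `c(min, max)`.
#' @return object of class `threshold_table`.
#' @export
threshold_table <- function(tool, pathogenic, benign, score_domain) {
  pathogenic <- pathogenic[STRENGTH_LEVELS]
  benign <- benign[STRENGTH_LEVELS]
  names(pathogenic) <- names(benign) <- STRENGTH_LEVELS
  stopifnot(is.numeric(score_domain), length(score_domain) == 2L,
            score_domain[1] < score_domain[2])
  chk_monotone <- function(x, decreasing, what) {
    v <- x[!is.na(x)]
    if (length(v) > 1L) {
      ok <- if (decreasing) all(diff(v) <= 0) else all(diff(v) >= 0)
      if (!ok) stop("threshold table construction error: ", what,
                    " boundaries are not monotone in strength", call. = FALSE)
    }
  }
  chk_monotone(pathogenic, decreasing = FALSE, "pathogenic")
  chk_monotone(benign, decreasing = TRUE, "benign")
  # unreachability must be contiguous from the strong end
  chk_na_tail <- function(x, what) {
    nas <- is.na(x)
    if (any(nas) && !all(nas[which(nas)[1]:length(x)])) {
      stop("threshold table construction error: reachable ", what,
           " level above an unreachable one", call. = FALSE)
    }
  }
  chk_na_tail(pathogenic, "pathogenic")
  chk_na_tail(benign, "benign")
  if (!is.na(benign[["supporting"]]) && !is.na(pathogenic[["supporting"]]) &&
      benign[["supporting"]] >= pathogenic[["supporting"]]) {
    stop("threshold table construction error: benign and pathogenic ",
         "supporting intervals overlap", call. = FALSE)
  }
  structure(list(tool = tool, pathogenic = pathogenic, benign = benign,
                 score_domain = as.numeric(score_domain)),
            class = "threshold_table")
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("threshold_table for %s on [%g, %g]\n", x$tool,
              x$score_domain[1], x$score_domain[2]))
  fmt <- function(v) ifelse(is.na(v), "—", formatC(v, digits = 4,
                                                        format = "g"))
  cat("  benign (BP4):    ",
      paste(sprintf("%s ≤ %s", names(x$benign), fmt(x$benign)),
            collapse = ", "), "\n")
  cat("  pathogenic (PP3):",
      paste(sprintf("%s ≥ %s", names(x$pathogenic), fmt(x$pathogenic)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Render a threshold table using interval notation
#'
#' @param x a [threshold_table()].
#' @return data.frame with columns `direction`, `strength`, `interval`.
#' @export
format_threshold_intervals <- function(x) {
  stopifnot(inherits(x, "threshold_table"))
  b <- x$benign; p <- x$pathogenic
  rows <- list()
  # benign intervals, strongest first: very_strong is (min, b_vs], i.e. <= b_vs
  for (i in rev(seq_along(STRENGTH_LEVELS))) {
    lv <- STRENGTH_LEVELS[i]
    if (is.na(b[[lv]])) {
      iv <- "—"
    } else {
      lower <- if (i < length(STRENGTH_LEVELS) && !is.na(b[[i + 1L]])) {
        sprintf("(%g, %g]", b[[i + 1L]], b[[lv]])
      } else sprintf("≤ %g", b[[lv]])
      iv <- lower
    }
    rows[[length(rows) + 1L]] <- data.frame(direction = "benign",
                                            strength = lv, interval = iv)
  }
  for (i in seq_along(STRENGTH_LEVELS)) {
    lv <- STRENGTH_LEVELS[i]
    if (is.na(p[[lv]])) {
      iv <- "—"
    } else {
      iv <- if (i < length(STRENGTH_LEVELS) && !is.na(p[[i + 1L]])) {
        sprintf("[%g, %g)", p[[lv]], p[[i + 1L]])
      } else sprintf("≥ %g", p[[lv]])
    }
    rows[[length(rows) + 1L]] <- data.frame(direction = "pathogenic",
                                            strength = lv, interval = iv)
  }
  do.call(rbind, rows)
}

#' Reference score thresholds for PHOX2B missense interpretation
#'
#' The calibrated PP3/BP4 score threshold intervals for the four tools on
#' the PHOX2B reference dataset, as distributed with this package. These are
#' the boundaries behind intervals such as BayesDel pathogenic
#' `[0.25, 0.30)` supporting, `[0.30, 0.43)` moderate, `>= 0.43` strong.
#'
#' @param tool one of `"CADD"`, `"REVEL"`, `"BayesDel"`, `"AlphaMissense"`,
#'   or `NULL` (default) for a named list of all four.
#' @return a [threshold_table()] or named list of them.
#' @export
phox2b_reference_thresholds <- function(tool = NULL) {
  ranges <- default_tool_ranges()
  mk <- function(tl, path, ben) {
    threshold_table(tl,
                    pathogenic = stats::setNames(path, STRENGTH_LEVELS),
                    benign = stats::setNames(ben, STRENGTH_LEVELS),
                    score_domain = ranges[[tl]])
  }
  all <- list(
    CADD = mk("CADD", c(26.49, 27.33, 29.24, NA), c(23.54, 22.51, 20.41, 16.17)),
    REVEL = mk("REVEL", c(0.71, 0.77, 0.90, NA), c(0.48, 0.41, 0.26, NA)),
    BayesDel = mk("BayesDel", c(0.25, 0.30, 0.43, NA), c(0.01, -0.07, -0.22, -0.52)),
    AlphaMissense = mk("AlphaMissense", c(0.81, 0.88, NA, NA), c(0.48, 0.37, 0.15, NA))
  )
  if (is.null(tool)) all else all[[match.arg(tool, names(all))]]
}
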