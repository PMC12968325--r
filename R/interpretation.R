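# Point values of the exponential ACMG/AMP point scheme.
STRENGTH_POINTS <- c(supporting = 1L, moderate = 2L, strong = 4L,
                     very_strong = 8L)

#' Construct an evidence assignment
#'
#' One applied ACMG/AMP criterion with its strength and point value under
#' the exponential point scheme (supporting 1, moderate 2, strong 4, very
#' strong 8; negated for benign-direction codes). `code = "none"` with
#' strength `"indeterminate"` carries 0 points.
#'
#' @param code one of `"PP3"`, `"BP4"`, `"PM1"`, `"PM2"`, `"PM5"`, `"none"`.
#' @param strength one of `"supporting"`, `"moderate"`, `"strong"`,
#'   `"very_strong"`, `"indeterminate"`.
#' @return object of class `evidence_assignment` (a named list with `code`,
#'   `strength`, `points`).
#' @export
evidence_assignment <- function(code = c("PP3", "BP4", "PM1", "PM2", "PM5",
                                         "none"),
                                strength = c("supporting", "moderate",
                                             "strong", "very_strong",
                                             "indeterminate")) {
  code <- match.arg(code)
  strength <- match.arg(strength)
  if (code == "none" || strength == "indeterminate") {
    code <- "none"; strength <- "indeterminate"; points <- 0L
  } else {
    points <- STRENGTH_POINTS[[strength]]
    if (code == "BP4") points <- -points
  }
  structure(list(code = code, strength = strength, points = points),
            class = "evidence_assignment")
}

#' Assign PP3/BP4 evidence strength from a score
#'
#' Places each score in exactly one interval of the threshold table using
#' the bracket convention (pathogenic intervals closed at their lower bound,
#' benign intervals closed at their upper bound) and returns the
#' corresponding PP3/BP4 assignment, or an indeterminate assignment for
#' scores between the benign-supporting and pathogenic-supporting
#' boundaries. Total over the score domain: every score falls in exactly
#' one bin.
#'
#' @param score numeric score(s); values outside the score domain are
#'   clamped to it.
#' @param thresholds a [threshold_table()].
#' @return data.frame with one row per score: `code`, `strength`, `points`.
#' @export
assign_strength <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "threshold_table"))
  s <- pmin(pmax(as.numeric(score), thresholds$score_domain[1]),
            thresholds$score_domain[2])
  pth <- thresholds$pathogenic
  ben <- thresholds$benign
  out <- data.frame(code = rep("none", length(s)),
                    strength = rep("indeterminate", length(s)),
                    points = rep(0L, length(s)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(s)) {
    path_ok <- !is.na(pth) & s[i] >= pth
    ben_ok <- !is.na(ben) & s[i] <= ben
    if (any(path_ok)) {
      lv <- STRENGTH_LEVELS[max(which(path_ok))]
      out$code[i] <- "PP3"; out$strength[i] <- lv
      out$points[i] <- STRENGTH_POINTS[[lv]]
    } else if (any(ben_ok)) {
      lv <- STRENGTH_LEVELS[max(which(ben_ok))]
      out$code[i] <- "BP4"; out$strength[i] <- lv
      out$points[i] <- -STRENGTH_POINTS[[lv]]
    }
  }
  out
}

#' Tally VUS predictions by strength level
#'
#' Counts how many scored consensus VUSs fall in each BP4/PP3 strength bin
#' (plus the indeterminate middle) for one tool. Counts sum to the number
#' of VUSs carrying the tool's score.
#'
#' @param table a [variant_table()].
#' @param thresholds a [threshold_table()] for `tool`.
#' @param tool score column name.
#' @return named integer vector over `bp4_very_strong` .. `bp4_supporting`,
#'   `indeterminate`, `pp3_supporting` .. `pp3_very_strong`.
#' @export
tally_vus_strengths <- function(table, thresholds, tool) {
  stopifnot(inherits(table, "variant_table"))
  s <- table[[tool]][table$consensus_class == "vus"]
  s <- s[!is.na(s)]
  bins <- c(paste0("bp4_", rev(STRENGTH_LEVELS)), "indeterminate",
            paste0("pp3_", STRENGTH_LEVELS))
  counts <- stats::setNames(integer(length(bins)), bins)
  if (length(s) == 0L) return(counts)
  a <- assign_strength(s, thresholds)
  key <- ifelse(a$code == "PP3", paste0("pp3_", a$strength),
                ifelse(a$code == "BP4", paste0("bp4_", a$strength),
                       "indeterminate"))
  tab <- base::table(factor(key, levels = bins))
  counts[] <- as.integer(tab)
  counts
}

#' Combine ACMG/AMP evidence under the point scheme
#'
#' Sums evidence points and maps the total to a classification category:
#' total >= 10 pathogenic, 6..9 likely pathogenic, 0..5 VUS, -6..-1 likely
#' benign, <= -7 benign. When `cap_pm1_pp3` is on and both PM1 and PP3 are
#' applied, their joint contribution is capped at the equivalent of a
#' single strong criterion (4 points), per the ClinGen recommendation.
#'
#' @param evidence list of [evidence_assignment()] objects (at most one of
#'   PP3/BP4).
#' @param cap_pm1_pp3 apply the PM1+PP3 joint cap (default `TRUE`).
#' @return object of class `classification_result`: list with
#'   `total_points`, `category`, `applied_evidence`, `cap_applied`.
#' @export
combine_acmg_points <- function(evidence, cap_pm1_pp3 = TRUE) {
  if (inherits(evidence, "evidence_assignment")) evidence <- list(evidence)
  stopifnot(all(vapply(evidence, inherits, TRUE, "evidence_assignment")))
  codes <- vapply(evidence, `[[`, "", "code")
  if ("PP3" %in% codes && "BP4" %in% codes) {
    stop("contradictory evidence: PP3 and BP4 cannot both apply",
         call. = FALSE)
  }
  if (sum(codes %in% c("PP3", "BP4")) > 1L) {
    stop("at most one PP3/BP4 assignment may be supplied", call. = FALSE)
  }
  pts <- vapply(evidence, `[[`, 0L, "points")
  cap_applied <- FALSE
  if (cap_pm1_pp3 && "PM1" %in% codes && "PP3" %in% codes) {
    joint <- sum(pts[codes %in% c("PM1", "PP3")])
    capped <- min(joint, STRENGTH_POINTS[["strong"]])
    cap_applied <- capped < joint
    total <- sum(pts[!codes %in% c("PM1", "PP3")]) + capped
  } else {
    total <- sum(pts)
  }
  category <- if (total >= 10) "pathogenic"
  else if (total >= 6) "likely_pathogenic"
  else if (total >= 0) "vus"
  else if (total >= -6) "likely_benign"
  else "benign"
  structure(list(total_points = as.integer(total), category = category,
                 applied_evidence = evidence, cap_applied = cap_applied),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  ev <- vapply(x$applied_evidence, function(e) {
    if (e$code == "none") "none" else paste0(e$code, "_", e$strength)
  }, "")
  cat(sprintf("%s (%+d points%s): %s\n", x$category, x$total_points,
              if (x$cap_applied) ", PM1+PP3 cap applied" else "",
              paste(ev, collapse = " + ")))
  invisible(x)
}

#' Reclassify the VUS set with calibrated computational evidence
#'
#' For every consensus VUS with a score for `tool`: assigns PP3/BP4 from the
#' threshold table, adds the flagged PM1/PM2/PM5 criteria, combines points,
#' and appends the resulting category. PM1 defaults to homeodomain
#' membership when a `domain` is given; PM2 (supporting) defaults to a
#' missing or zero GroupMax FAF when `pm2_from_faf` is on. Known-class
#' variants keep their expert label and are not reassessed.
#'
#' @param table a [variant_table()].
#' @param thresholds a [threshold_table()] for `tool`.
#' @param tool score column name.
#' @param pm1 logical vector (length `nrow(table)`) or `NULL` to derive from
#'   `domain`.
#' @param pm2 logical vector or `NULL` to derive from FAF when
#'   `pm2_from_faf`.
#' @param pm5 logical vector (no default derivation; `NULL` = all FALSE).
#' @param domain optional [domain_definition()] used when `pm1` is `NULL`.
#' @param pm1_strength strength at which PM1 applies (default `"moderate"`).
#' @param pm2_from_faf derive PM2_supporting from absent/zero FAF
#'   (default `TRUE` when `pm2` is `NULL`).
#' @param cap_pm1_pp3 apply the PM1+PP3 cap (default `TRUE`).
#' @return the table with added columns `acmg_points`, `acmg_category`,
#'   `acmg_evidence` (NA for non-VUS records).
#' @export
reclassify_vus_set <- function(table, thresholds, tool,
                               pm1 = NULL, pm2 = NULL, pm5 = NULL,
                               domain = NULL, pm1_strength = "moderate",
                               pm2_from_faf = TRUE, cap_pm1_pp3 = TRUE) {
  stopifnot(inherits(table, "variant_table"))
  n <- nrow(table)
  if (is.null(pm1)) {
    pm1 <- if (!is.null(domain)) in_domain(table$residue_index, domain)
    else rep(FALSE, n)
  }
  if (is.null(pm2)) {
    pm2 <- if (pm2_from_faf) {
      is.na(table$groupmax_faf) | table$groupmax_faf == 0
    } else rep(FALSE, n)
  }
  if (is.null(pm5)) pm5 <- rep(FALSE, n)
  stopifnot(length(pm1) == n, length(pm2) == n, length(pm5) == n)

  table$acmg_points <- NA_integer_
  table$acmg_category <- NA_character_
  table$acmg_evidence <- NA_character_
  vus <- which(table$consensus_class == "vus" & !is.na(table[[tool]]))
  if (length(vus) == 0L) return(table)
  comp <- assign_strength(table[[tool]][vus], thresholds)
  for (k in seq_along(vus)) {
    i <- vus[k]
    ev <- list()
    if (comp$code[k] != "none") {
      ev <- c(ev, list(evidence_assignment(comp$code[k], comp$strength[k])))
    }
    if (pm1[i]) ev <- c(ev, list(evidence_assignment("PM1", pm1_strength)))
    if (pm2[i]) ev <- c(ev, list(evidence_assignment("PM2", "supporting")))
    if (pm5[i]) ev <- c(ev, list(evidence_assignment("PM5", "supporting")))
    res <- combine_acmg_points(ev, cap_pm1_pp3 = cap_pm1_pp3)
    table$acmg_points[i] <- res$total_points
    table$acmg_category[i] <- res$category
    table$acmg_evidence[i] <- paste(vapply(ev, function(e)
      paste0(e$code, "_", e$strength), ""), collapse = ";")
  }
  table
}
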