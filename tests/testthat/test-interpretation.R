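test_that("strength assignment follows the published interval conventions", {
  bd <- phox2b_reference_thresholds("BayesDel")
  # the consult-case BayesDel score reaches PP3 strong
  a <- assign_strength(0.572, bd)
  expect_equal(a$code, "PP3"); expect_equal(a$strength, "strong")
  # inside the indeterminate gap (0.01, 0.25)
  a2 <- assign_strength(0.10, bd)
  expect_equal(a2$code, "none"); expect_equal(a2$strength, "indeterminate")
  expect_equal(a2$points, 0L)
  # pathogenic intervals are closed at their lower bound
  rv <- phox2b_reference_thresholds("REVEL")
  a3 <- assign_strength(0.90, rv)
  expect_equal(a3$strength, "strong")
  a4 <- assign_strength(0.77, rv)
  expect_equal(a4$strength, "moderate")
  # benign intervals are closed at their upper bound: -0.22 is still strong
  a5 <- assign_strength(-0.22, bd)
  expect_equal(a5$code, "BP4"); expect_equal(a5$strength, "strong")
  a6 <- assign_strength(-0.219, bd)
  expect_equal(a6$strength, "moderate")
  # boundary of the supporting benign interval
  a7 <- assign_strength(0.01, bd)
  expect_equal(a7$code, "BP4"); expect_equal(a7$strength, "supporting")
})

test_that("every score falls in exactly one bin across the whole domain", {
  for (tl in ref_tools) {
    tt <- phox2b_reference_thresholds(tl)
    s <- withr::with_seed(5, runif(10000, tt$score_domain[1],
                                   tt$score_domain[2]))
    a <- assign_strength(s, tt)
    expect_equal(nrow(a), 10000L)
    expect_true(all(a$code %in% c("PP3", "BP4", "none")))
    # reconstruct bins independently and compare counts to a tally
    df <- data.frame(variant_id = sprintf("v%05d", seq_along(s)),
                     protein_change = sprintf("p.Ala%dVal",
                                              seq_along(s) %% 300 + 2L),
                     consensus_class = "vus", stringsAsFactors = FALSE)
    df[[tl]] <- s
    vt <- variant_table(df, validate = FALSE)
    counts <- tally_vus_strengths(vt, tt, tl)
    expect_equal(sum(counts), 10000L)
  }
})

test_that("unreachable levels never receive assignments", {
  am <- phox2b_reference_thresholds("AlphaMissense")
  a <- assign_strength(c(0.999, 1), am)  # top of domain: strong unreachable
  expect_true(all(a$strength == "moderate"))
  expect_true(all(a$code == "PP3"))
})

test_that("point combination reproduces the consult-case classification", {
  # PP3 strong (4) + PM5 supporting (1) + PM2 supporting (1) = 6 points
  ev <- list(evidence_assignment("PP3", "strong"),
             evidence_assignment("PM5", "supporting"),
             evidence_assignment("PM2", "supporting"))
  res <- combine_acmg_points(ev)
  expect_equal(res$total_points, 6L)
  expect_equal(res$category, "likely_pathogenic")
  expect_false(res$cap_applied)
})

test_that("the PM1+PP3 joint contribution is capped at one strong criterion", {
  ev <- list(evidence_assignment("PM1", "moderate"),
             evidence_assignment("PP3", "strong"))
  res <- combine_acmg_points(ev, cap_pm1_pp3 = TRUE)
  expect_equal(res$total_points, 4L)
  expect_equal(res$category, "vus")
  expect_true(res$cap_applied)
  # without the cap: 6 points, likely pathogenic
  res2 <- combine_acmg_points(ev, cap_pm1_pp3 = FALSE)
  expect_equal(res2$total_points, 6L)
  # PM1 + PP3_moderate (2 + 2 = 4) is not capped
  res3 <- combine_acmg_points(list(evidence_assignment("PM1", "moderate"),
                                   evidence_assignment("PP3", "moderate")))
  expect_equal(res3$total_points, 4L)
  expect_false(res3$cap_applied)
})

test_that("evidence combination handles empty, contradictory and benign input", {
  expect_equal(combine_acmg_points(list())$category, "vus")
  expect_equal(combine_acmg_points(list())$total_points, 0L)
  expect_error(combine_acmg_points(list(evidence_assignment("PP3", "strong"),
                                        evidence_assignment("BP4", "moderate"))),
               "contradictory")
  res <- combine_acmg_points(list(evidence_assignment("BP4", "moderate")))
  expect_equal(res$total_points, -2L)
  expect_equal(res$category, "likely_benign")
  res2 <- combine_acmg_points(list(evidence_assignment("BP4", "very_strong")))
  expect_equal(res2$category, "benign")
})

test_that("adding pathogenic-direction evidence never lowers the category", {
  rank_of <- function(cat) match(cat, c("benign", "likely_benign", "vus",
                                        "likely_pathogenic", "pathogenic"))
  base_sets <- list(
    list(),
    list(evidence_assignment("BP4", "moderate")),
    list(evidence_assignment("PP3", "supporting")),
    list(evidence_assignment("PP3", "strong"),
         evidence_assignment("PM2", "supporting")))
  for (ev in base_sets) {
    for (extra in list(evidence_assignment("PM2", "supporting"),
                       evidence_assignment("PM5", "supporting"),
                       evidence_assignment("PM1", "moderate"))) {
      before <- combine_acmg_points(ev)
      after <- combine_acmg_points(c(ev, list(extra)))
      expect_gte(rank_of(after$category), rank_of(before$category))
    }
  }
})

test_that("VUS reclassification applies calibrated evidence with flags", {
  bd <- phox2b_reference_thresholds("BayesDel")
  hd <- domain_definition()
  df <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    protein_change = c("p.Arg99Pro", "p.Ala200Val", "p.Ala210Val",
                       "p.Ala20Val"),
    consensus_class = c("vus", "vus", "vus", "pathogenic"),
    BayesDel = c(0.572, -0.1, 0.1, 0.6),     # strong / BP4 moderate / indet
    groupmax_faf = c(NA, 1e-4, NA, NA),
    stringsAsFactors = FALSE)
  vt <- variant_table(df)
  out <- reclassify_vus_set(vt, bd, "BayesDel", domain = hd,
                            pm5 = c(TRUE, FALSE, FALSE, FALSE))
  # consult-style case: homeodomain, absent from gnomAD, PP3 strong, PM5:
  # cap(PM1+PP3) = 4, + PM2 1 + PM5 1 = 6 -> likely pathogenic
  expect_equal(out$acmg_points[1], 6L)
  expect_equal(out$acmg_category[1], "likely_pathogenic")
  # BP4 moderate only: -2 -> likely benign
  expect_equal(out$acmg_points[2], -2L)
  expect_equal(out$acmg_category[2], "likely_benign")
  # indeterminate with only PM2 flag: 1 point -> stays VUS
  expect_equal(out$acmg_category[3], "vus")
  # known-class records are not reassessed
  expect_true(is.na(out$acmg_category[4]))
})
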