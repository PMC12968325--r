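#' Synthetic stand-in for the PHOX2B reference dataset
#'
#' A deterministic, fully synthetic 506-variant table that reproduces the
#' published summary structure of the PHOX2B missense reference dataset,
#' for use in examples and end-to-end validation when the original
#' per-variant data are not at hand. It is NOT the original dataset: every
#' score is constructed, not observed.
#'
#' Construction, entirely from published summary statistics:
#' \itemize{
#'   \item class sizes 33 pathogenic / 81 benign / 392 VUS;
#'   \item known-class scores per tool are deterministic truncated-normal
#'     quantile samples whose location is solved so the class sample mean
#'     equals the published class mean exactly, with spread solved from the
#'     published AUC via the binormal relation
#'     `sigma = (mu_p - mu_b) / (sqrt(2) * qnorm(AUC))`;
#'   \item residue positions place 27/33 pathogenic and 4/81 benign
#'     variants (at residues 108, 115, 125, 131) inside the homeodomain
#'     (codons 98-157);
#'   \item VUS scores per tool are placed inside the reference threshold
#'     intervals ([phox2b_reference_thresholds()]) with the published
#'     per-bin VUS counts, evenly spaced within each interval;
#'   \item GroupMax FAFs give most benign variants a common tail above the
#'     1e-6 frequency threshold; pathogenic variants are absent from the
#'     population data and VUSs are absent or at FAF bound 0.
#' }
#'
#' @return a [variant_table()] with 506 records.
#' @export
#' @examples
#' vt <- phox2b_synthetic_dataset()
#' mean(vt$BayesDel[vt$consensus_class == "benign"])   # -0.14
phox2b_synthetic_dataset <- function() {
  ranges <- default_tool_ranges()
  tools <- default_synthetic_tools()
  class_means <- list(CADD = c(benign = 19.00, pathogenic = 29.00),
                      REVEL = c(benign = 0.36, pathogenic = 0.90),
                      BayesDel = c(benign = -0.14, pathogenic = 0.49),
                      AlphaMissense = c(benign = 0.30, pathogenic = 0.96))
  n_path <- 33L; n_benign <- 81L; n_vus <- 392L

  # deterministic truncated-normal quantile sample with exact sample mean
  quantile_sample <- function(n, target_mean, sigma, lower, upper) {
    probs <- (seq_len(n) - 0.5) / n
    sample_at <- function(mu) {
      plo <- stats::pnorm((lower - mu) / sigma)
      phi <- stats::pnorm((upper - mu) / sigma)
      p <- pmin(pmax(plo + probs * (phi - plo), 1e-300), 1 - 1e-16)
      pmin(pmax(mu + sigma * stats::qnorm(p), lower), upper)
    }
    mu <- stats::uniroot(function(m) mean(sample_at(m)) - target_mean,
                         lower = target_mean - 8 * sigma,
                         upper = target_mean + 8 * sigma,
                         extendInt = "upX", tol = 1e-12)$root
    sample_at(mu)
  }

  known_scores <- function(cls, n) {
    out <- lapply(names(tools), function(tl) {
      quantile_sample(n, class_means[[tl]][[cls]], tools[[tl]]$sigma,
                      ranges[[tl]][1], ranges[[tl]][2])
    })
    stats::setNames(as.data.frame(out), names(tools))
  }

  # VUS strength-bin counts per tool (benign very strong .. pathogenic very
  # strong) and even placement inside the corresponding score intervals.
  vus_counts <- list(
    CADD          = c(79, 28, 51, 63, 101, 23, 34, 13, 0),
    REVEL         = c(0, 67, 131, 50, 94, 16, 22, 12, 0),
    BayesDel      = c(1, 91, 132, 51, 71, 12, 21, 13, 0),
    AlphaMissense = c(0, 104, 96, 28, 61, 22, 81, 0, 0)
  )
  vus_scores <- function(tl) {
    tt <- phox2b_reference_thresholds(tl)
    b <- tt$benign; p <- tt$pathogenic; rng <- tt$score_domain
    # interval edges in ascending score order: bp4 vs..supporting,
    # indeterminate, pp3 supporting..vs
    edges <- rbind(
      c(rng[1], if (!is.na(b[["very_strong"]])) b[["very_strong"]] else NA),
      c(b[["very_strong"]], b[["strong"]]),
      c(b[["strong"]], b[["moderate"]]),
      c(b[["moderate"]], b[["supporting"]]),
      c(b[["supporting"]], p[["supporting"]]),
      c(p[["supporting"]], p[["moderate"]]),
      c(p[["moderate"]], p[["strong"]]),
      c(p[["strong"]], p[["very_strong"]]),
      c(p[["very_strong"]], rng[2]))
    # replace NA edges for reachable outer bins by the domain limits
    edges[2, 1] <- if (is.na(edges[2, 1])) rng[1] else edges[2, 1]
    k <- vus_counts[[tl]]
    # top reachable pathogenic bin extends to the domain maximum
    top <- max(which(k > 0))
    edges[top, 2] <- if (is.na(edges[top, 2])) rng[2] else edges[top, 2]
    unlist(lapply(seq_along(k), function(i) {
      if (k[i] == 0L) return(numeric(0))
      a <- edges[i, 1]; bnd <- edges[i, 2]
      a + (seq_len(k[i]) - 0.5) / k[i] * (bnd - a)
    }))
  }

  # residue positions
  dom <- 98:157
  path_pos <- c(round(seq(99, 154, length.out = 27)),
                c(10, 40, 70, 200, 250, 300))
  benign_pos <- c(108, 115, 125, 131,
                  setdiff(round(seq(2, 314, length.out = 100)), 98:157)[1:77])
  vus_pos <- rep(2:314, length.out = n_vus)

  # uniqueness of protein_change is enforced across the whole table via a
  # shared registry; ref/alt codes are deterministic functions of position
  used <- character(0)
  build <- function(pos, cls, offset) {
    n <- length(pos)
    ref <- AA3[(pos * 7L) %% 20L + 1L]
    alt <- character(n)
    for (i in seq_len(n)) {
      for (salt in 0:200) {
        cand <- AA3[(pos[i] * 13L + salt + 3L) %% 20L + 1L]
        if (cand == ref[i]) next
        key <- paste0(pos[i], ".", cand)
        if (!key %in% used) { used <<- c(used, key); alt[i] <- cand; break }
      }
      if (alt[i] == "") stop("exhausted substitutions at position ", pos[i])
    }
    data.frame(variant_id = sprintf("sv%03d", offset + seq_len(n)),
               protein_change = format_protein_hgvs(ref, pos, alt),
               ref_aa = ref, residue_index = pos, alt_aa = alt,
               consensus_class = cls, stringsAsFactors = FALSE)
  }

  d_path <- cbind(build(path_pos, "pathogenic", 0L),
                  known_scores("pathogenic", n_path))
  d_ben <- cbind(build(benign_pos, "benign", n_path),
                 known_scores("benign", n_benign))
  d_vus <- build(vus_pos, "vus", n_path + n_benign)
  for (tl in names(tools)) d_vus[[tl]] <- vus_scores(tl)

  d_path$groupmax_faf <- NA_real_
  faf_common <- 10^seq(log10(2e-6), log10(1e-3), length.out = 77)
  d_ben$groupmax_faf <- c(rep(0, 4), faf_common)
  d_vus$groupmax_faf <- rep(c(NA_real_, NA_real_, NA_real_, 0),
                            length.out = n_vus)

  variant_table(rbind(d_path, d_ben, d_vus), tool_ranges = ranges)
}
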