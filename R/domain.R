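#' Define a protein domain by codon span
#'
#' The reference domain is the PHOX2B homeodomain, encoded by codons 98-157
#' inclusive, involved in dimerization, DNA binding and nuclear
#' localization.
#'
#' @param name domain name.
#' @param start_codon,end_codon inclusive 1-based codon bounds.
#' @return object of class `domain_definition`.
#' @export
#' @examples
#' hd <- domain_definition("homeodomain", 98, 157)
#' in_domain(99, hd)
domain_definition <- function(name = "homeodomain", start_codon = 98L,
                              end_codon = 157L) {
  stopifnot(start_codon >= 1L, start_codon <= end_codon)
  structure(list(name = name, start_codon = as.integer(start_codon),
                 end_codon = as.integer(end_codon)),
            class = "domain_definition")
}

#' Is a residue inside a domain?
#'
#' @param residue_index 1-based residue position(s).
#' @param domain a [domain_definition()].
#' @return logical vector; bounds are inclusive.
#' @export
in_domain <- function(residue_index, domain) {
  stopifnot(inherits(domain, "domain_definition"), all(residue_index >= 1L))
  residue_index >= domain$start_codon & residue_index <= domain$end_codon
}

#' Fraction of a consensus class falling inside a domain
#'
#' @param table a [variant_table()].
#' @param cls consensus class (`"pathogenic"`, `"benign"`, `"vus"`).
#' @param domain a [domain_definition()].
#' @return list with `numerator`, `denominator`, `fraction`.
#' @export
domain_class_fraction <- function(table, cls, domain) {
  stopifnot(inherits(table, "variant_table"),
            cls %in% CONSENSUS_CLASSES)
  idx <- table$residue_index[table$consensus_class == cls]
  if (length(idx) == 0L) {
    stop("domain_class_fraction: no records of class ", cls, call. = FALSE)
  }
  num <- sum(in_domain(idx, domain))
  list(numerator = num, denominator = length(idx),
       fraction = num / length(idx))
}

#' Score enrichment of theoretical variants inside a domain
#'
#' Compares the mean prediction score of all theoretical missense variants
#' at positions inside the domain with those outside, with a two-sided
#' Welch t-test. For nucleotide-level tools the table may contain several
#' rows per amino-acid substitution; `collapse = "amino_acid"` collapses
#' them to one value per (position, alt_aa) by their maximum before
#' testing.
#'
#' @param score_table data.frame with columns `position`, optional `ref_aa`,
#'   `alt_aa`, and one column per tool.
#' @param domain a [domain_definition()].
#' @param tool score column name.
#' @param collapse `"none"` (default; every row counted) or `"amino_acid"`.
#' @return list with `mean_in`, `mean_out`, `p_value`, `n_in`, `n_out`.
#' @export
domain_score_enrichment <- function(score_table, domain, tool,
                                    collapse = c("none", "amino_acid")) {
  collapse <- match.arg(collapse)
  stopifnot(is.data.frame(score_table), "position" %in% names(score_table),
            tool %in% names(score_table))
  df <- score_table[!is.na(score_table[[tool]]), , drop = FALSE]
  if (collapse == "amino_acid") {
    key <- paste(df$position, df$alt_aa)
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      g[[tool]][1L] <- max(g[[tool]])
      g[1L, , drop = FALSE]
    }))
  }
  inside <- in_domain(df$position, domain)
  s_in <- df[[tool]][inside]
  s_out <- df[[tool]][!inside]
  if (length(s_in) < 2L || length(s_out) < 2L) {
    stop("domain_score_enrichment: need at least two scored variants on each side",
         call. = FALSE)
  }
  tt <- stats::t.test(s_in, s_out, var.equal = FALSE)
  list(mean_in = mean(s_in), mean_out = mean(s_out), p_value = tt$p.value,
       n_in = length(s_in), n_out = length(s_out))
}
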