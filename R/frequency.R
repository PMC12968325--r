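#' Disease frequency model for the maximum tolerated allele frequency
#'
#' Parameters of the maximum credible population allele frequency
#' calculation. For the reference disease (CCHS) the conservatively chosen
#' values are: prevalence 1/100,000, penetrance 0.40, genetic heterogeneity
#' 0.75 (fraction of cases attributable to the gene), allelic heterogeneity
#' 0.10 (fraction of those cases attributable to any one variant class),
#' monoallelic (heterozygous) inheritance.
#'
#' @param prevalence disease prevalence, cases per individual, in (0, 1).
#' @param penetrance probability of disease given the genotype, in (0, 1].
#' @param genetic_heterogeneity proportion of cases caused by the gene, (0, 1].
#' @param allelic_heterogeneity proportion of the gene's cases attributable to
#'   the variant (class), (0, 1].
#' @param inheritance `"monoallelic"` (heterozygous carriers; allele frequency
#'   is half the genotype frequency) or `"biallelic"` (allele frequency is the
#'   square root of the genotype frequency).
#' @param round_sig_figs significant figures for the final rounding step
#'   (default 1); `NA` disables rounding.
#' @return an object of class `frequency_model`.
#' @export
#' @examples
#' m <- frequency_model(1e-5, 0.40, 0.75, 0.10)
#' max_tolerated_af(m)  # 1e-6, i.e. 0.0001%
frequency_model <- function(prevalence, penetrance,
                            genetic_heterogeneity = 1,
                            allelic_heterogeneity = 1,
                            inheritance = c("monoallelic", "biallelic"),
                            round_sig_figs = 1L) {
  inheritance <- match.arg(inheritance)
  stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
            prevalence > 0, prevalence < 1)
  if (!is.numeric(penetrance) || penetrance <= 0 || penetrance > 1) {
    stop("penetrance must lie in (0, 1]; zero penetrance would divide by zero",
         call. = FALSE)
  }
  stopifnot(genetic_heterogeneity > 0, genetic_heterogeneity <= 1,
            allelic_heterogeneity > 0, allelic_heterogeneity <= 1)
  if (!is.na(round_sig_figs)) {
    stopifnot(round_sig_figs >= 1)
    round_sig_figs <- as.integer(round_sig_figs)
  }
  structure(list(prevalence = prevalence, penetrance = penetrance,
                 genetic_heterogeneity = genetic_heterogeneity,
                 allelic_heterogeneity = allelic_heterogeneity,
                 inheritance = inheritance,
                 round_sig_figs = round_sig_figs),
            class = "frequency_model")
}

#' Maximum tolerated population allele frequency
#'
#' The maximum credible genotype frequency is
#' `prevalence * genetic_heterogeneity * allelic_heterogeneity / penetrance`;
#' for monoallelic (heterozygous) inheritance the allele frequency is half
#' that (each carrier contributes one of two alleles), for biallelic
#' inheritance its square root. The result is rounded up (conservatively:
#' a higher threshold reclassifies fewer variants as benign) to
#' `round_sig_figs` significant figures. With the reference CCHS parameters
#' this is 9.375e-7, rounded to 1e-6 (0.0001%).
#'
#' @param model a [frequency_model()].
#' @return allele frequency as a fraction.
#' @export
max_tolerated_af <- function(model) {
  stopifnot(inherits(model, "frequency_model"))
  genotype_freq <- model$prevalence * model$genetic_heterogeneity *
    model$allelic_heterogeneity / model$penetrance
  af <- switch(model$inheritance,
               monoallelic = genotype_freq / 2,
               biallelic = sqrt(genotype_freq))
  if (!is.na(model$round_sig_figs)) {
    af <- ceiling_signif(af, model$round_sig_figs)
  }
  af
}

# Conservative (upward) rounding to k significant figures: the threshold is
# a maximum tolerated frequency, so rounding up reclassifies fewer variants
# as benign (9.375e-7 -> 1e-6 at one significant figure).
ceiling_signif <- function(x, k) {
  if (x == 0) return(0)
  scale <- 10^(floor(log10(x)) - (k - 1))
  ceiling(x / scale - 1e-9) * scale  # guard exact representations
}

#' Apply the frequency-based benign rule
#'
#' Records whose GroupMax filtering allele frequency strictly exceeds the
#' maximum tolerated allele frequency are reassigned to the benign consensus
#' class ("exceeded" is a strict inequality: boundary equality does not
#' reclassify). A missing FAF is treated as not exceeding; an FAF of 0 means
#' present in gnomAD with FAF bound zero and never exceeds. A record already
#' labelled pathogenic is never silently overridden: a conflict warning is
#' emitted and the expert label kept.
#'
#' @param table a [variant_table()].
#' @param max_af threshold allele frequency (fraction), > 0; typically from
#'   [max_tolerated_af()].
#' @return the table with reassigned classes; the number of reassignments is
#'   attached as attribute `n_reassigned`.
#' @export
apply_frequency_benign_rule <- function(table, max_af) {
  stopifnot(inherits(table, "variant_table"),
            is.numeric(max_af), length(max_af) == 1L, max_af > 0)
  exceeds <- !is.na(table$groupmax_faf) & table$groupmax_faf > max_af
  conflict <- exceeds & table$consensus_class == "pathogenic"
  if (any(conflict)) {
    warning(sprintf("frequency rule conflict: %d pathogenic-labelled record(s) exceed the threshold and keep their expert label: %s",
                    sum(conflict),
                    paste(table$variant_id[conflict], collapse = ", ")),
            call. = FALSE)
  }
  reassign <- exceeds & table$consensus_class != "pathogenic" &
    table$consensus_class != "benign"
  table$consensus_class[reassign] <- "benign"
  attr(table, "n_reassigned") <- sum(reassign)
  table
}
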