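#' Read variants from a VCF (convenience input path)
#'
#' Builds a variant table from a VCF v4.2 file: per-tool scores are taken
#' from INFO keys named in `info_map`, the protein change from the INFO key
#' named by `protein_key`. The delimited-text path
#' ([read_variant_table()]) is canonical; this reader is a convenience for
#' annotated VCFs. Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @param info_map named character vector mapping tool names to INFO keys,
#'   e.g. `c(BayesDel = "BAYESDEL", REVEL = "REVEL")`.
#' @param protein_key INFO key holding the `p.` HGVS change.
#' @param class_key INFO key holding the consensus class (default
#'   `"CLASS"`); absent values become `"vus"`.
#' @param faf_key INFO key holding the GroupMax FAF (optional).
#' @inheritParams variant_table
#' @return a [variant_table()].
#' @export
read_variant_vcf <- function(path, info_map, protein_key = "PHGVS",
                             class_key = "CLASS", faf_key = "FAF",
                             tool_ranges = default_tool_ranges(),
                             transcript = "NM_003924.4") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_variant_vcf requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info_field <- function(key) {
    vcfR::extract.info(v, element = key)
  }
  df <- data.frame(
    variant_id = paste0(fix[, "CHROM"], ":", fix[, "POS"], fix[, "REF"],
                        ">", fix[, "ALT"]),
    protein_change = info_field(protein_key),
    stringsAsFactors = FALSE)
  cls <- info_field(class_key)
  df$consensus_class <- ifelse(is.na(cls) | cls == "", "vus", cls)
  faf <- suppressWarnings(as.numeric(info_field(faf_key)))
  df$groupmax_faf <- faf
  for (tl in names(info_map)) {
    df[[tl]] <- suppressWarnings(as.numeric(info_field(info_map[[tl]])))
  }
  variant_table(df, tool_ranges = tool_ranges, transcript = transcript)
}
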