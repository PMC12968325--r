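# Three-letter amino-acid codes accepted in protein HGVS (IUPAC standard 20).
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

CONSENSUS_CLASSES <- c("pathogenic", "benign", "vus")

#' Default prediction-tool score ranges
#'
#' Declared score domains for the four calibrated tools: CADD Phred
#' \[0, 60\], REVEL \[0, 1\], BayesDel noAF \[-1.3, 0.8\], AlphaMissense
#' \[0, 1\]. Used both for input validation and as the search domain for
#' threshold root finding.
#'
#' @return Named list of length-2 numeric vectors `c(min, max)`.
#' @export
default_tool_ranges <- function() {
  list(
    CADD          = c(0, 60),
    REVEL         = c(0, 1),
    BayesDel      = c(-1.3, 0.8),
    AlphaMissense = c(0, 1)
  )
}

#' Construct a validated variant table
#'
#' The canonical in-memory dataset: one row per curated missense variant with
#' identifiers, parsed protein change, per-tool prediction scores, gnomAD
#' GroupMax filtering allele frequency (FAF), and the expert consensus class.
#'
#' @param df data.frame with at least `variant_id`, `protein_change`,
#'   `consensus_class`, and one score column named after a tool in
#'   `tool_ranges`. `ref_aa`, `residue_index`, `alt_aa` are parsed from
#'   `protein_change` when absent. A `groupmax_faf` of 0 means present in
#'   gnomAD with FAF bound 0; `NA` means absent. An optional `truth` column
#'   (synthetic data only) is carried but never read by calibration code.
#' @param tool_ranges named list of score domains, see [default_tool_ranges()].
#' @param transcript transcript accession the protein coordinates refer to.
#' @param validate run invariant checks (default `TRUE`).
#' @return A `variant_table`: a data.frame with attributes `tool_ranges` and
#'   `transcript`.
#' @export
variant_table <- function(df, tool_ranges = default_tool_ranges(),
                          transcript = "NM_003924.4", validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- c("variant_id", "protein_change", "consensus_class")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("variant table schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tools <- intersect(names(tool_ranges), names(df))
  if (length(tools) == 0L) {
    stop("variant table schema error: no score column found; expected one of ",
         paste(names(tool_ranges), collapse = ", "), call. = FALSE)
  }
  if (!all(c("ref_aa", "residue_index", "alt_aa") %in% names(df))) {
    parsed <- parse_protein_hgvs(df$protein_change)
    df$ref_aa <- parsed$ref_aa
    df$residue_index <- parsed$residue_index
    df$alt_aa <- parsed$alt_aa
  }
  df$residue_index <- as.integer(df$residue_index)
  if (!"groupmax_faf" %in% names(df)) df$groupmax_faf <- NA_real_
  df$groupmax_faf <- as.numeric(df$groupmax_faf)
  if (!"is_snv_achievable" %in% names(df)) df$is_snv_achievable <- TRUE
  if (!"merged_from" %in% names(df)) df$merged_from <- df$variant_id
  df$consensus_class <- as.character(df$consensus_class)
  for (tl in tools) df[[tl]] <- as.numeric(df[[tl]])

  out <- structure(df,
                   tool_ranges = tool_ranges[names(tool_ranges)],
                   transcript = transcript,
                   class = c("variant_table", "data.frame"))
  if (validate) validate_variant_table(out)
  out
}

#' @rdname variant_table
#' @param x a `variant_table`.
#' @export
validate_variant_table <- function(x) {
  df <- as.data.frame(x)
  bad_class <- setdiff(unique(df$consensus_class), CONSENSUS_CLASSES)
  if (length(bad_class) > 0L) {
    stop("variant table schema error: consensus_class value(s) outside {",
         paste(CONSENSUS_CLASSES, collapse = ", "), "}: ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (any(df$residue_index < 2L, na.rm = TRUE)) {
    stop("residue_index < 2: initiator-codon substitutions are not missense",
         call. = FALSE)
  }
  if (any(df$ref_aa == df$alt_aa, na.rm = TRUE)) {
    stop("ref_aa equals alt_aa for at least one record", call. = FALSE)
  }
  ranges <- attr(x, "tool_ranges")
  for (tl in intersect(names(ranges), names(df))) {
    s <- df[[tl]]
    r <- ranges[[tl]]
    out_of_range <- which(!is.na(s) & (s < r[1] | s > r[2]))
    if (length(out_of_range) > 0L) {
      stop(sprintf("%s score out of declared range [%g, %g] for %d record(s), e.g. %s",
                   tl, r[1], r[2], length(out_of_range),
                   df$variant_id[out_of_range[1]]), call. = FALSE)
    }
  }
  if (any(!is.na(df$groupmax_faf) & df$groupmax_faf < 0)) {
    stop("groupmax_faf must be >= 0 or missing", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.variant_table <- function(x, ...) {
  cls <- table(factor(x$consensus_class, levels = CONSENSUS_CLASSES))
  cat(sprintf("variant_table: %d variants on %s (%d pathogenic, %d benign, %d VUS)\n",
              nrow(x), attr(x, "transcript"),
              cls[["pathogenic"]], cls[["benign"]], cls[["vus"]]))
  cat("tools:", paste(score_tools(x), collapse = ", "), "\n")
  NextMethod()
}

#' @export
`[.variant_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("variant_id", "protein_change", "consensus_class") %in%
            names(out))) {
    attr(out, "tool_ranges") <- attr(x, "tool_ranges")
    attr(out, "transcript") <- attr(x, "transcript")
    class(out) <- c("variant_table", "data.frame")
  } else if (is.data.frame(out)) {
    class(out) <- "data.frame"
  }
  out
}

#' Tools with score columns present in a variant table
#' @param x a `variant_table`.
#' @return character vector of tool names.
#' @export
score_tools <- function(x) {
  intersect(names(attr(x, "tool_ranges")), names(x))
}

#' Parse a protein HGVS missense change
#'
#' Accepts only substitutions written with three-letter amino-acid codes,
#' `p.<Ref><pos><Alt>` (e.g. `p.Arg99Pro`). One-letter codes, synonymous
#' `p.(=)`, frameshift and termination notation are rejected: callers must
#' not silently coerce non-missense notation.
#'
#' @param p_hgvs character vector of `p.` strings.
#' @return data.frame with columns `ref_aa`, `residue_index`, `alt_aa`.
#' @export
#' @examples
#' parse_protein_hgvs("p.Arg99Pro")
parse_protein_hgvs <- function(p_hgvs) {
  p_hgvs <- as.character(p_hgvs)
  m <- regmatches(p_hgvs,
                  regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", p_hgvs))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("protein HGVS parse error: not a three-letter missense substitution: ",
         paste(utils::head(p_hgvs[bad], 3L), collapse = ", "), call. = FALSE)
  }
  ref <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- vapply(m, `[`, "", 4L)
  bad_aa <- !(ref %in% AA3) | !(alt %in% AA3)
  if (any(bad_aa)) {
    stop("protein HGVS parse error: unknown amino-acid code in: ",
         paste(utils::head(p_hgvs[bad_aa], 3L), collapse = ", "), call. = FALSE)
  }
  data.frame(ref_aa = ref, residue_index = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Format a protein HGVS missense change
#'
#' Inverse of [parse_protein_hgvs()].
#'
#' @param ref_aa,alt_aa three-letter amino-acid codes.
#' @param residue_index 1-based protein position.
#' @return character vector `p.<Ref><pos><Alt>`.
#' @export
format_protein_hgvs <- function(ref_aa, residue_index, alt_aa) {
  stopifnot(all(ref_aa %in% AA3), all(alt_aa %in% AA3))
  sprintf("p.%s%d%s", ref_aa, as.integer(residue_index), alt_aa)
}

#' Read a variant table from delimited text
#'
#' @param path file path to a TSV or CSV with a header row naming at least
#'   `variant_id`, `protein_change`, `consensus_class` and one tool score
#'   column. Score cells that fail numeric parsing become missing scores with
#'   a warning; an FAF cell of "0" parses to 0 (present in gnomAD, FAF bound
#'   zero).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param column_map optional named character vector mapping file column names
#'   to canonical names, e.g. `c(BayesDel_noAF = "BayesDel")`.
#' @inheritParams variant_table
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path, dialect = c("tsv", "csv"),
                               column_map = NULL,
                               tool_ranges = default_tool_ranges(),
                               transcript = "NM_003924.4") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop("empty or unreadable variant table: ", path,
                             call. = FALSE))
  if (nrow(df) == 0L) stop("empty variant table: ", path, call. = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- column_map[names(df)[hit]]
  }
  numeric_cols <- intersect(c(names(tool_ranges), "groupmax_faf", "residue_index"),
                            names(df))
  for (cl in numeric_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    n_bad <- sum(is.na(val) & !is.na(raw) & nzchar(trimws(raw)) &
                   !trimws(raw) %in% c("NA", "-", "—", "."))
    if (n_bad > 0L) {
      warning(sprintf("%d unparseable value(s) in column '%s' set to missing",
                      n_bad, cl), call. = FALSE)
    }
    df[[cl]] <- val
  }
  if ("is_snv_achievable" %in% names(df)) {
    df$is_snv_achievable <- as.logical(df$is_snv_achievable)
  }
  variant_table(df, tool_ranges = tool_ranges, transcript = transcript)
}

#' Write a curated variant table as TSV
#'
#' Re-emits the table with the `merged_from` and `curation_flag` bookkeeping
#' columns.
#'
#' @param x a `variant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  df <- as.data.frame(x)
  if (!"curation_flag" %in% names(df)) df$curation_flag <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Can an amino-acid substitution arise from a single nucleotide change?
#'
#' Checks whether any single-base edit of `ref_codon` encodes `alt_aa`,
#' using the standard genetic code.
#'
#' @param ref_codon character vector of reference codons (e.g. "CGG").
#' @param alt_aa three-letter code of the substituted amino acid.
#' @return logical vector.
#' @export
snv_achievable <- function(ref_codon, alt_aa) {
  stopifnot(length(ref_codon) == length(alt_aa))
  code <- genetic_code_table()
  aa1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
           Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
           Tyr = "Y", Val = "V")
  mapply(function(codon, alt) {
    codon <- toupper(codon)
    if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
      stop("invalid codon: ", codon, call. = FALSE)
    }
    target <- aa1[[alt]]
    for (i in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(codon, i, i))) {
        mutated <- codon
        substr(mutated, i, i) <- b
        if (identical(unname(code[[mutated]]), target)) return(TRUE)
      }
    }
    FALSE
  }, ref_codon, alt_aa, USE.NAMES = FALSE)
}

# Standard genetic code as a named list codon -> one-letter AA ("*" = stop).
# Uses Biostrings::GENETIC_CODE when available, otherwise a built-in copy in
# the conventional TCAG order (TTT, TTC, TTA, TTG, TCT, ...).
genetic_code_table <- function() {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    return(as.list(Biostrings::GENETIC_CODE))
  }
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  stats::setNames(as.list(aa), codons)
}

#' Curate nucleotide-level variant rows into a variant table
#'
#' Applies the dataset curation rules: rows whose amino-acid substitution is
#' impossible via a single nucleotide variant are dropped (they have no
#' precomputed scores); distinct nucleotide changes producing the identical
#' amino-acid substitution, without differing predicted splice impact, are
#' merged to one record. Nucleotide-level scores (CADD, BayesDel) of merged
#' constituents are aggregated by their maximum (conservative toward
#' detecting pathogenicity) with a warning when the spread exceeds 10% of the
#' tool's range; amino-acid-level scores (REVEL, AlphaMissense) must agree
#' across constituents.
#'
#' @param df data.frame of nucleotide-level rows (same schema as
#'   [variant_table()]); must carry either a `ref_codon` column (achievability
#'   computed from the genetic code) or an explicit `is_snv_achievable`
#'   logical column.
#' @param nucleotide_level_tools tools whose scores are per nucleotide change.
#' @param aa_score_tol tolerance for agreement of amino-acid-level scores.
#' @inheritParams variant_table
#' @return a curated [variant_table()] with `merged_from` listing constituent
#'   nucleotide-level ids.
#' @export
curate <- function(df, tool_ranges = default_tool_ranges(),
                   transcript = "NM_003924.4",
                   nucleotide_level_tools = c("CADD", "BayesDel"),
                   aa_score_tol = 1e-6) {
  if (inherits(df, "variant_table")) df <- as.data.frame(df)
  stopifnot(is.data.frame(df))
  if (!all(c("ref_aa", "residue_index", "alt_aa") %in% names(df))) {
    parsed <- parse_protein_hgvs(df$protein_change)
    df$ref_aa <- parsed$ref_aa
    df$residue_index <- parsed$residue_index
    df$alt_aa <- parsed$alt_aa
  }
  if (!"is_snv_achievable" %in% names(df)) {
    if ("ref_codon" %in% names(df)) {
      df$is_snv_achievable <- snv_achievable(df$ref_codon, df$alt_aa)
    } else {
      stop("curate() needs a 'ref_codon' column or an explicit ",
           "'is_snv_achievable' logical column; achievability is never guessed",
           call. = FALSE)
    }
  }
  dropped <- df[!df$is_snv_achievable, , drop = FALSE]
  if (nrow(dropped) > 0L) {
    message(sprintf("curate: dropped %d record(s) not achievable by a single nucleotide variant: %s",
                    nrow(dropped), paste(dropped$variant_id, collapse = ", ")))
  }
  df <- df[df$is_snv_achievable, , drop = FALSE]
  if (nrow(df) == 0L) stop("curate: no SNV-achievable records remain",
                           call. = FALSE)
  if (!"merged_from" %in% names(df)) df$merged_from <- df$variant_id
  splice_key <- if ("splice_impact" %in% names(df)) {
    ifelse(is.na(df$splice_impact), "", as.character(df$splice_impact))
  } else rep("", nrow(df))
  key <- paste(df$protein_change, splice_key, sep = "\r")
  tools <- intersect(names(tool_ranges), names(df))
  aa_level <- setdiff(tools, nucleotide_level_tools)

  merged <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    grp <- df[idx, , drop = FALSE]
    rec <- grp[1L, , drop = FALSE]
    if (nrow(grp) > 1L) {
      if (length(unique(grp$consensus_class)) > 1L) {
        stop("curate conflict: constituents of ", rec$protein_change,
             " disagree on consensus_class", call. = FALSE)
      }
      for (tl in aa_level) {
        v <- grp[[tl]][!is.na(grp[[tl]])]
        if (length(v) > 1L && diff(range(v)) > aa_score_tol) {
          stop(sprintf("curate conflict: %s scores differ beyond tolerance for %s",
                       tl, rec$protein_change), call. = FALSE)
        }
        rec[[tl]] <- if (length(v)) v[1L] else NA_real_
      }
      for (tl in intersect(nucleotide_level_tools, tools)) {
        v <- grp[[tl]][!is.na(grp[[tl]])]
        if (length(v) > 1L &&
            diff(range(v)) > 0.1 * diff(tool_ranges[[tl]])) {
          warning(sprintf("curate: %s score spread %.3g across constituents of %s exceeds 10%% of the tool range; taking the maximum",
                          tl, diff(range(v)), rec$protein_change),
                  call. = FALSE)
        }
        rec[[tl]] <- if (length(v)) max(v) else NA_real_
      }
      if ("groupmax_faf" %in% names(grp)) {
        f <- grp$groupmax_faf[!is.na(grp$groupmax_faf)]
        rec$groupmax_faf <- if (length(f)) max(f) else NA_real_
      }
      rec$merged_from <- paste(unique(unlist(strsplit(grp$merged_from, ";"))),
                               collapse = ";")
    }
    rec
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$residue_index, out$protein_change), , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out, tool_ranges = tool_ranges, transcript = transcript)
}
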