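#' Cohort variant table
#'
#' A light wrapper around a data frame holding one row per (variant,
#' subject) observation, the substrate for the cohort-level searches:
#' recurrent previously-unreported protein-altering variants, and per-gene
#' burden comparisons against a control cohort.
#'
#' Required columns: `chrom`, `pos` (1-based), `ref`, `alt`, `subject`,
#' `gene`, `consequence`, `known` (logical: present in any reference
#' database), `genotype` (`"het"` or `"hom"`).
#'
#' @param df A data frame with the columns above.
#' @return The validated data frame with class `cohort_variants` prepended.
#' @export
cohort_variants <- function(df) {
  needed <- c("chrom", "pos", "ref", "alt", "subject", "gene",
              "consequence", "known", "genotype")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$known <- as.logical(df$known)
  norm <- normalize_alleles(df$pos, df$ref, df$alt)
  df$pos <- norm$pos; df$ref <- norm$ref; df$alt <- norm$alt
  key <- paste(df$chrom, df$pos, df$ref, df$alt, df$subject)
  if (anyDuplicated(key))
    stop("duplicate (variant, subject) pairs")
  class(df) <- c("cohort_variants", class(df))
  df
}

# Left-align and trim alleles to their minimal representation.  Without the
# flanking sequence a full left-shift is impossible; shared prefixes and
# suffixes are trimmed, which canonicalizes the padded forms VCF produces.
normalize_alleles <- function(pos, ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim common suffix, keep at least one base
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substring(r, nchar(r)) == substring(a, nchar(a))) {
      r <- substring(r, 1, nchar(r) - 1)
      a <- substring(a, 1, nchar(a) - 1)
    }
    # trim common prefix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substring(r, 1, 1) == substring(a, 1, 1)) {
      r <- substring(r, 2); a <- substring(a, 2); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Consequence classes counted as protein-altering
#'
#' @return Character vector of the default protein-altering consequence
#'   classes.
#' @export
protein_altering_classes <- function() {
  c("missense", "nonsense", "frameshift", "splice", "inframe_indel",
    "stop_loss")
}

#' Recurrent previously-unreported protein-altering variants
#'
#' Filters a cohort variant table to variants that are (a) protein-altering,
#' (b) absent from every reference database (`known == FALSE`), and (c)
#' carried by at least `min_subjects` distinct subjects; the search that
#' flags a recurrent novel mutation in a rare-disease cohort.
#'
#' @param table A [cohort_variants()] table.
#' @param min_subjects Minimum number of distinct carriers (default 2,
#'   i.e. "more than one subject").
#' @param classes Consequence classes treated as protein-altering.
#' @return A data frame with one row per qualifying variant (`chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `n_subjects`, `subjects`), sorted by
#'   descending carrier count then position; zero rows when none qualify.
#' @export
recurrent_novel_variants <- function(table, min_subjects = 2,
                                     classes = protein_altering_classes()) {
  stopifnot(inherits(table, "cohort_variants"), min_subjects >= 1)
  keep <- !table$known & table$consequence %in% classes
  t2 <- table[keep, , drop = FALSE]
  if (!nrow(t2)) return(empty_recurrent_result())
  key <- paste(t2$chrom, t2$pos, t2$ref, t2$alt, sep = ":")
  counts <- tapply(t2$subject, key, function(s) length(unique(s)))
  hits <- names(counts)[counts >= min_subjects]
  if (!length(hits)) return(empty_recurrent_result())
  rows <- lapply(hits, function(k) {
    sub <- t2[key == k, , drop = FALSE]
    data.frame(chrom = sub$chrom[1], pos = sub$pos[1], ref = sub$ref[1],
               alt = sub$alt[1], gene = sub$gene[1],
               n_subjects = length(unique(sub$subject)),
               subjects = paste(sort(unique(sub$subject)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_subjects, out$chrom, out$pos), , drop = FALSE]
}

empty_recurrent_result <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), n_subjects = integer(),
             subjects = character(), stringsAsFactors = FALSE)
}

#' Per-gene carrier burden test against a control cohort
#'
#' Two-sided Fisher exact test on the 2x2 table of qualifying-variant
#' carriers versus non-carriers in cases and controls, as used to ask
#' whether rare variants in a gene occur more often than expected by
#' chance.  Sidedness follows the usual convention of summing the
#' probabilities of all tables no more likely than the observed one.  The
#' `mode` label records how carriers were defined upstream (at least one
#' qualifying heterozygote for `dominant`; homozygous or two or more
#' qualifying variants for `recessive`) and does not change the arithmetic.
#'
#' @param case_carriers,case_n Carrier count and total in the case cohort.
#' @param ctrl_carriers,ctrl_n Carrier count and total in the control
#'   cohort.
#' @param mode `"dominant"` or `"recessive"` (label only).
#' @param n_genes Number of genes tested, for the Bonferroni adjustment
#'   (default 1, i.e. no adjustment).
#' @param gene Optional gene name carried through to the result.
#' @return A list of class `burden_result` with the counts, `p_value`,
#'   `p_adjusted`, `odds_ratio`, `mode` and `gene`.
#' @examples
#' gene_burden_test(5, 40, 0, 724, n_genes = 20000)
#' @export
gene_burden_test <- function(case_carriers, case_n, ctrl_carriers, ctrl_n,
                             mode = c("dominant", "recessive"),
                             n_genes = 1, gene = NA_character_) {
  mode <- match.arg(mode)
  if (case_n <= 0 || ctrl_n <= 0) stop("cohort totals must be positive")
  stopifnot(case_carriers >= 0, ctrl_carriers >= 0,
            case_carriers <= case_n, ctrl_carriers <= ctrl_n, n_genes >= 1)
  tab <- matrix(c(case_carriers, case_n - case_carriers,
                  ctrl_carriers, ctrl_n - ctrl_carriers),
                nrow = 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(list(gene = gene,
                 case_carriers = case_carriers, case_n = case_n,
                 ctrl_carriers = ctrl_carriers, ctrl_n = ctrl_n,
                 mode = mode,
                 p_value = ft$p.value,
                 p_adjusted = min(1, ft$p.value * n_genes),
                 odds_ratio = unname(ft$estimate)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Gene burden (", x$mode, ")",
      if (!is.na(x$gene)) paste0(" for ", x$gene), ": ",
      x$case_carriers, "/", x$case_n, " cases vs ",
      x$ctrl_carriers, "/", x$ctrl_n, " controls; p = ",
      format(x$p_value, digits = 3), " (adjusted ",
      format(x$p_adjusted, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Read a cohort variant table from TSV
#'
#' The TSV dialect mirrors the columns of [cohort_variants()].
#'
#' @param path TSV file path.
#' @return A [cohort_variants()] table.
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cohort_variants(df)
}

#' Read a minimal cohort VCF
#'
#' Reads CHROM/POS/REF/ALT and per-sample genotypes from a VCF (via the
#' vcfR package) and expands them into one row per carrier.  Annotation
#' columns the VCF cannot carry (`gene`, `consequence`, `known`) are taken
#' from INFO keys `GENE`, `CSQ` and `KNOWN` when present, otherwise filled
#' with defaults (`NA`, `"missense"`, `FALSE`).
#'
#' @param path VCF file path.
#' @return A [cohort_variants()] table.
#' @export
read_cohort_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package; use read_cohort_tsv()")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_field <- function(key, default) {
    val <- vcfR::extract.info(v, element = key)
    if (all(is.na(val))) rep(default, nrow(fix)) else val
  }
  gene <- info_field("GENE", NA_character_)
  csq <- info_field("CSQ", "missense")
  known <- tolower(info_field("KNOWN", "0")) %in% c("1", "true", "yes")
  gt <- vcfR::extract.gt(v, element = "GT")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    g <- gt[i, ]
    carrier <- !is.na(g) & g %in% c("0/1", "1/0", "0|1", "1|0", "1/1", "1|1")
    if (!any(carrier)) next
    hom <- g[carrier] %in% c("1/1", "1|1")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = fix$ALT[i],
      subject = names(g)[carrier], gene = gene[i], consequence = csq[i],
      known = known[i], genotype = ifelse(hom, "hom", "het"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no carriers found in VCF")
  cohort_variants(do.call(rbind, rows))
}
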