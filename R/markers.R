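#' Marker map around a focal variant
#'
#' Ordered biallelic markers flanking a focal variant, with the population
#' frequency of the ancestral (shared-haplotype) allele at each marker, a
#' uniform recombination rate, and a per-generation marker mutation rate.
#' This is the coordinate system for shared-interval detection and for the
#' haplotype-based mutation-age likelihood.
#'
#' Alleles are coded 0/1 throughout; `freq` is the population frequency of
#' the ancestral-haplotype allele at each marker (the probability that a
#' random chromosome matches the ancestral haplotype there by chance).
#'
#' @param id Character vector of marker identifiers.
#' @param pos_bp Strictly increasing 1-based physical positions.
#' @param freq Ancestral-allele frequencies, each in (0, 1).
#' @param focal_pos Position of the focal variant; must lie strictly
#'   between the first and last marker.
#' @param rate_cM_per_Mb Uniform recombination rate (default 2.9 cM/Mb).
#' @param mu_m Per-marker per-generation mutation rate (default 2e-8).
#' @return A data frame of class `marker_map` with attributes `focal_pos`,
#'   `rate_cM_per_Mb` and `mu_m`.
#' @export
marker_map <- function(id, pos_bp, freq, focal_pos,
                       rate_cM_per_Mb = 2.9, mu_m = 2e-8) {
  stopifnot(length(id) == length(pos_bp), length(freq) == length(pos_bp),
            all(diff(pos_bp) > 0), all(freq > 0), all(freq < 1),
            focal_pos > pos_bp[1], focal_pos < pos_bp[length(pos_bp)],
            !any(pos_bp == focal_pos),
            rate_cM_per_Mb > 0, mu_m >= 0, mu_m < 1)
  df <- data.frame(id = as.character(id), pos_bp = as.numeric(pos_bp),
                   freq = as.numeric(freq), stringsAsFactors = FALSE)
  attr(df, "focal_pos") <- as.numeric(focal_pos)
  attr(df, "rate_cM_per_Mb") <- rate_cM_per_Mb
  attr(df, "mu_m") <- mu_m
  class(df) <- c("marker_map", class(df))
  df
}

#' Recombination fraction between two points (Haldane)
#'
#' Converts a physical distance to a recombination fraction through the
#' genetic map `d = distance * rate` (Morgans) and Haldane's map function
#' `theta = (1 - exp(-2 d)) / 2`, which is monotone in distance and bounded
#' by 0.5.  At the sub-megabase distances relevant to shared-haplotype
#' dating the function is numerically linear.
#'
#' @param distance_bp Non-negative physical distance in bp.
#' @param rate_cM_per_Mb Recombination rate in cM/Mb (default 2.9).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' recomb_fraction(1e6, 2.9)  # 0.02818...
#' @export
recomb_fraction <- function(distance_bp, rate_cM_per_Mb = 2.9) {
  if (any(distance_bp < 0)) stop("distance must be non-negative")
  d_morgans <- distance_bp * rate_cM_per_Mb / 1e8  # cM/Mb -> M/bp
  (1 - exp(-2 * d_morgans)) / 2
}

# Split a marker map into its two sides, each ordered outward from the
# focal variant, with per-marker recombination fractions focal -> marker.
map_sides <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  focal <- attr(map, "focal_pos")
  rate <- attr(map, "rate_cM_per_Mb")
  left_idx <- rev(which(map$pos_bp < focal))   # outward: decreasing pos
  right_idx <- which(map$pos_bp > focal)       # outward: increasing pos
  side <- function(idx) {
    list(idx = idx,
         id = map$id[idx],
         pos = map$pos_bp[idx],
         freq = map$freq[idx],
         theta = recomb_fraction(abs(map$pos_bp[idx] - focal), rate))
  }
  list(left = side(left_idx), right = side(right_idx),
       mu_m = attr(map, "mu_m"), focal = focal)
}

#' Read a PLINK-style .map file
#'
#' Four whitespace-separated columns: chromosome, marker id, genetic
#' position (cM, ignored), physical position (bp).
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `id`, `cM`, `pos_bp`.
#' @export
read_plink_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "id", "cM", "pos_bp"))
  df$pos_bp <- as.numeric(df$pos_bp)
  df
}

#' Read phased haplotypes or unphased genotypes from TSV
#'
#' One row per subject: a `subject` column plus an `alleles` column with
#' 0/1 alleles separated by `|` (phased; one haplotype per row) or by `/`
#' (unphased genotypes, returned as 0/1/2 dosages).  An optional logical
#' `carries_focal` column marks focal-variant carriers.
#'
#' @param path File path.
#' @return A list with `subjects`, `alleles` (matrix, one row per subject)
#'   , `phased` (logical) and `carries_focal`.
#' @export
read_haplotypes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("subject", "alleles") %in% names(df)))
  phased <- grepl("|", df$alleles[1], fixed = TRUE)
  sep <- if (phased) "|" else "/"
  parts <- strsplit(df$alleles, sep, fixed = TRUE)
  lens <- vapply(parts, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("all subjects must be typed at the same markers")
  mat <- do.call(rbind, lapply(parts, as.integer))
  if (!phased) {
    # pairs like 0/1 per marker: columns come in marker-wise single fields
    # already split; unphased rows are dosage sums of two alleles per
    # marker, so the file stores dosages directly (0, 1 or 2)
    stopifnot(all(mat %in% 0:2))
  } else {
    stopifnot(all(mat %in% 0:1))
  }
  rownames(mat) <- df$subject
  cf <- if ("carries_focal" %in% names(df))
    as.logical(df$carries_focal) else rep(TRUE, nrow(df))
  list(subjects = df$subject, alleles = mat, phased = phased,
       carries_focal = cf)
}

#' Read an allele-frequency sidecar TSV
#'
#' Columns `id` and `freq`: marker identifier and ancestral-allele
#' frequency.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `freq`.
#' @export
read_marker_freqs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "freq") %in% names(df)))
  df
}
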