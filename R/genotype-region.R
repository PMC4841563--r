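#' Genotype region container
#'
#' A `genotype_region` holds the sample-by-variant minor-allele dosage matrix
#' of one genomic region (gene), together with the 1-based genomic positions
#' of its variants.  Dosage entries are 0, 1 or 2 copies of the coded allele
#' (missing entries allowed as `NA`); the per-variant minor allele frequency
#' is computed from the non-missing dosages.
#'
#' The functional expansion of genotype profiles needs more than 3 variants,
#' so downstream fitting refuses regions with fewer than 4 variants; the
#' constructor itself allows any positive number so that single-SNP
#' comparator models can reuse the container.
#'
#' @param dosage numeric matrix, n_samples x n_variants, entries in
#'   \{0, 1, 2\} or `NA`.
#' @param positions integer-ish vector of strictly increasing 1-based
#'   genomic coordinates, one per dosage column.
#' @param chrom chromosome label (length 1).
#' @param region_id region (gene) label.
#' @param sample_ids optional character vector of row labels.
#' @return An object of class `genotype_region` with fields `region_id`,
#'   `chrom`, `positions`, `dosage`, `maf`, `sample_ids`.
#' @examples
#' g <- genotype_region(matrix(c(0, 1, 2, 0, 0, 1, 2, 2,
#'                               1, 1, 0, 0, 2, 0, 1, 1), 4, 4),
#'                      positions = c(101, 205, 310, 480), chrom = "1")
#' g$maf
#' @export
genotype_region <- function(dosage, positions, chrom = "1",
                            region_id = "region", sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  positions <- as.numeric(positions)
  if (length(positions) != ncol(dosage))
    stop_mfrg("length(positions) must equal ncol(dosage)", "mfrg_bad_input")
  if (ncol(dosage) > 1 && any(diff(positions) <= 0))
    stop_mfrg("positions must be strictly increasing", "mfrg_bad_input")
  ok <- dosage[!is.na(dosage)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    stop_mfrg("dosage entries must be 0, 1, 2 or NA", "mfrg_bad_input")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids))
      sample_ids <- paste0("S", seq_len(nrow(dosage)))
  }
  rownames(dosage) <- sample_ids
  structure(
    list(region_id = as.character(region_id)[1],
         chrom = as.character(chrom)[1],
         positions = positions,
         dosage = dosage,
         maf = region_maf(dosage),
         sample_ids = sample_ids),
    class = "genotype_region")
}

# minor allele frequency per dosage column (orientation-agnostic: folded)
region_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.genotype_region <- function(x, ...) {
  cat(sprintf("genotype_region '%s' (chr%s): %d samples x %d variants, MAF %.4g-%.4g\n",
              x$region_id, x$chrom, nrow(x$dosage), ncol(x$dosage),
              min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.genotype_region <- function(x) dim(x$dosage)

#' Filter variants of a region by frequency and missingness
#'
#' Retains variants whose minor allele frequency lies in
#' `[maf_min, maf_max]` and whose missing fraction is at most `missing_max`,
#' preserving position order.  Used to form rare-only / common-only analysis
#' arms; the conventional defaults are rare = MAF < 0.01 and common =
#' MAF >= 0.05, but the bounds are free parameters here.
#'
#' @param region a [genotype_region()].
#' @param maf_min,maf_max inclusive MAF bounds, `0 <= maf_min <= maf_max <= 0.5`.
#' @param missing_max maximum tolerated per-variant missing fraction.
#' @return A `genotype_region` with the retained variants.
#' @export
filter_variants <- function(region, maf_min = 0, maf_max = 0.5,
                            missing_max = 1) {
  stopifnot(inherits(region, "genotype_region"))
  if (!(maf_min >= 0 && maf_min <= maf_max && maf_max <= 0.5))
    stop_mfrg("need 0 <= maf_min <= maf_max <= 0.5", "mfrg_bad_input")
  miss <- colMeans(is.na(region$dosage))
  keep <- region$maf >= maf_min & region$maf <= maf_max & miss <= missing_max
  if (!any(keep))
    stop_mfrg(sprintf("no variants left in region '%s' after filtering",
                      region$region_id), "mfrg_region_too_small")
  genotype_region(region$dosage[, keep, drop = FALSE],
                  region$positions[keep], region$chrom,
                  region$region_id, region$sample_ids)
}

# require the >3-variant rule for the functional expansion
check_region_size <- function(region, min_variants = 4) {
  if (ncol(region$dosage) < min_variants)
    stop_mfrg(sprintf(
      "region '%s' has %d variants; the eigenfunction expansion needs at least %d",
      region$region_id, ncol(region$dosage), min_variants),
      "mfrg_region_too_small")
  invisible(region)
}

stop_mfrg <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mfrg_error")))
}
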