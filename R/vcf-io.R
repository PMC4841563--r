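#' Gene window
#'
#' 1-based inclusive genomic interval used to cut a [genotype_region()] out
#' of a VCF.  BED input (0-based half-open) is converted on read by
#' [read_gene_windows()].
#'
#' @param gene_id gene label.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @export
gene_window <- function(gene_id, chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop_mfrg("window start > end", "mfrg_bad_input")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 start = start, end = end), class = "gene_window")
}

#' Read gene windows from BED or GFF3
#'
#' BED intervals (0-based, half-open) are converted to 1-based inclusive
#' coordinates; GFF3 rows of type `gene` are used as-is (already 1-based
#' inclusive), with the gene id taken from the `ID=` or `Name=` attribute.
#'
#' @param path BED (`.bed`) or GFF3 (`.gff`, `.gff3`) file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return list of [gene_window()] objects.
#' @export
read_gene_windows <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    ids <- if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0(tab[[1]], ":", tab[[2]] + 1, "-", tab[[3]])
    win <- Map(gene_window, ids, as.character(tab[[1]]),
               tab[[2]] + 1, tab[[3]])
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#",
                             quote = "")
    tab <- tab[tab[[3]] == "gene", , drop = FALSE]
    if (!nrow(tab)) stop_mfrg("no 'gene' rows in GFF3", "mfrg_bad_input")
    ids <- vapply(as.character(tab[[9]]), function(a) {
      m <- regmatches(a, regexec("(?:ID|Name)=([^;]+)", a))[[1]]
      if (length(m) == 2) m[2] else a
    }, character(1), USE.NAMES = FALSE)
    win <- Map(gene_window, ids, as.character(tab[[1]]), tab[[4]], tab[[5]])
  }
  names(win) <- vapply(win, `[[`, character(1), "gene_id")
  win
}

#' Read a genotype region from a VCF
#'
#' Extracts biallelic SNVs inside a [gene_window()] from a VCF (v4.x) file,
#' codes genotypes as allele-count dosages and returns a [genotype_region()].
#' By default the dosage counts the *minor* allele (a 0/1/2 genotype coding
#' does not by itself fix which allele is counted; counting the minor
#' allele makes the rare-variant semantics unambiguous); with
#' `orient = "alt"` the VCF ALT allele is counted instead.  Monomorphic
#' variants are removed; multiallelic sites are dropped.
#'
#' @param vcf_source path to a VCF file (plain text or bgzipped).
#' @param window a [gene_window()]; `NULL` keeps all sites.
#' @param sample_subset optional character vector of samples to keep (in the
#'   given order); an empty intersection is an error.
#' @param orient `"minor"` (default) or `"alt"` allele counting.
#' @param missing `"impute"` (replace missing dosages by their variant mean,
#'   2*MAF) or `"keep"` (leave `NA`).
#' @param min_variants minimum polymorphic variants required (default 4, the
#'   smallest region the functional expansion supports).
#' @return A [genotype_region()].
#' @export
read_region <- function(vcf_source, window = NULL, sample_subset = NULL,
                        orient = c("minor", "alt"),
                        missing = c("impute", "keep"),
                        min_variants = 4) {
  orient <- match.arg(orient)
  missing <- match.arg(missing)
  v <- vcfR::read.vcfR(vcf_source, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(window)) {
    keep <- keep & fix[, "CHROM"] == window$chrom &
      pos >= window$start & pos <= window$end
  }
  # biallelic SNVs only
  keep <- keep & !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (!any(keep))
    stop_mfrg("no biallelic SNVs in window", "mfrg_region_too_small")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  pos <- pos[keep]
  chrom <- if (is.null(window)) fix[keep, "CHROM"][1] else window$chrom
  if (!is.null(sample_subset)) {
    common <- intersect(sample_subset, colnames(gt))
    if (!length(common))
      stop_mfrg("no overlapping samples between VCF and subset",
                "mfrg_no_samples")
    gt <- gt[, common, drop = FALSE]
  }
  # allele counts from GT strings; any '.' in the call -> missing
  alt_count <- function(g) {
    out <- rep(NA_real_, length(g))
    g2 <- gsub("\\|", "/", g)
    out[g2 %in% c("0/0", "0")] <- 0
    out[g2 %in% c("0/1", "1/0")] <- 1
    out[g2 %in% c("1/1", "1")] <- 2
    out
  }
  dos <- t(apply(gt, 1, alt_count))          # variants x samples
  dos <- t(dos)                              # samples x variants
  rownames(dos) <- colnames(gt)
  # orient to minor allele
  p_alt <- colMeans(dos, na.rm = TRUE) / 2
  if (orient == "minor") {
    flip <- !is.na(p_alt) & p_alt > 0.5
    dos[, flip] <- 2 - dos[, flip]
  }
  # drop monomorphic (all non-missing equal)
  poly <- apply(dos, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && stats::var(x) > 0
  })
  dos <- dos[, poly, drop = FALSE]
  pos <- pos[poly]
  if (ncol(dos) < min_variants)
    stop_mfrg(sprintf("window has %d polymorphic variants; need at least %d",
                      ncol(dos), min_variants), "mfrg_region_too_small")
  if (missing == "impute" && anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)   # = 2*MAF under minor orientation
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
    # imputed entries are fractional, so assemble without the 0/1/2 check
    reg <- structure(
      list(region_id = if (is.null(window)) "region" else window$gene_id,
           chrom = chrom, positions = pos, dosage = dos,
           maf = region_maf(dos), sample_ids = rownames(dos)),
      class = "genotype_region")
    return(reg)
  }
  genotype_region(dos, pos, chrom,
                  if (is.null(window)) "region" else window$gene_id)
}

#' Write a genotype region as a minimal VCF
#'
#' Emits a plain-text VCF v4.2 with GT-only genotype columns in which the
#' ALT allele is the coded (dosage-counted) allele, so re-reading with
#' [read_region()] under minor-allele orientation round-trips the dosage
#' exactly (coded-allele frequencies never exceed 0.5).
#'
#' @param region a [genotype_region()] without missing entries.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_vcf <- function(region, path) {
  stopifnot(inherits(region, "genotype_region"))
  d <- region$dosage
  if (anyNA(d)) stop_mfrg("cannot write missing genotypes", "mfrg_bad_input")
  gtmap <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(region$chrom, format(region$positions[j], scientific = FALSE),
            paste0(region$region_id, "_", j), "A", "C", ".", "PASS", ".",
            "GT", gtmap[d[, j] + 1]), collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", region$sample_ids), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
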