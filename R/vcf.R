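#' Read phased haplotypes from a VCF region
#'
#' Extracts phased biallelic SNPs inside a genomic interval from a VCF 4.x
#' file and returns them as a [haplotype_matrix()]. Indels and multiallelic
#' records are dropped (and counted); genotypes must be phased (`|`) and
#' complete in strict mode. Ancestral-state polarity is set from the INFO
#' `AA` tag: when `AA` matches REF the 1 allele is derived as coded; when it
#' matches ALT the column is recoded so that 1 = derived; otherwise polarity
#' is unknown in strict mode, while lenient mode treats REF as ancestral.
#'
#' @param path VCF file, plain text or bgzip-compressed (a `.tbi` index is
#'   used for region queries when present)
#' @param region either a one-row gene table entry (columns `chrom`, `start`,
#'   `end`) or a length-3 vector `c(chrom, start, end)`; `NULL` reads the
#'   whole file
#' @param panel optional [read_panel()] result; every VCF sample must appear
#'   in it, and population labels are attached per haplotype
#' @param mode `"strict"` (default): unphased or missing genotypes in
#'   surviving records are errors and unpolarized sites keep `polarity =
#'   FALSE`; `"lenient"`: sites with missing calls are dropped and REF is
#'   assumed ancestral where `AA` is absent or invalid
#' @return a [haplotype_matrix()]; the numbers of dropped indel and
#'   multiallelic records are attached as attribute `dropped`
#' @export
read_vcf_region <- function(path, region = NULL, panel = NULL,
                            mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("VCF not found: ", path)
  if (!is.null(region)) {
    if (is.data.frame(region)) {
      stopifnot(nrow(region) == 1L)
      chrom <- region$chrom; start <- region$start; end <- region$end
    } else {
      chrom <- region[[1L]]
      start <- as.integer(region[[2L]]); end <- as.integer(region[[3L]])
    }
    which_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  } else {
    chrom <- NULL
    which_gr <- NULL
  }

  has_tabix <- grepl("\\.gz$", path) && file.exists(paste0(path, ".tbi"))
  vcf <- if (!is.null(which_gr) && has_tabix) {
    VariantAnnotation::readVcf(
      Rsamtools::TabixFile(path),
      param = VariantAnnotation::ScanVcfParam(which = which_gr))
  } else {
    VariantAnnotation::readVcf(path)
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  chr <- as.character(GenomicRanges::seqnames(rr))
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)

  keep <- rep(TRUE, length(pos))
  if (!is.null(which_gr) && !has_tabix)
    keep <- keep & chr == chrom & pos >= start & pos <= end
  in_region <- keep

  multi <- n_alt != 1L
  alt <- rep(NA_character_, length(pos))
  alt[!multi] <- as.character(unlist(altl[!multi]))
  snp <- !multi & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_multi <- sum(in_region & multi)
  n_indel <- sum(in_region & !multi & !snp)
  keep <- keep & snp

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field: ", path)
  samples <- colnames(gt)

  if (!is.null(panel)) {
    missing_panel <- setdiff(samples, panel$sample_id)
    if (length(missing_panel))
      stop("sample(s) present in VCF but absent from panel: ",
           paste(missing_panel, collapse = ", "))
    pops <- panel$population[match(samples, panel$sample_id)]
  } else {
    pops <- rep("POP1", length(samples))
  }

  idx <- which(keep)
  idx <- idx[order(pos[idx])]
  n_hap <- 2L * length(samples)

  if (length(idx) == 0L) {
    h <- haplotype_matrix(
      matrix(integer(0), nrow = n_hap, ncol = 0L),
      integer(0), chrom = if (is.null(chrom)) "." else chrom,
      polarity = logical(0),
      sample_ids = rep(samples, each = 2L),
      pop_labels = rep(pops, each = 2L))
    attr(h, "dropped") <- c(indel = n_indel, multiallelic = n_multi, missing = 0L)
    return(h)
  }

  gt <- gt[idx, , drop = FALSE]
  unphased <- grepl("/", gt, fixed = TRUE)
  if (any(unphased)) {
    if (mode == "strict")
      stop("unphased genotype(s) in surviving records, e.g. record at position ",
           pos[idx][which(rowSums(matrix(unphased, nrow = length(idx))) > 0)[1L]])
    gt <- gsub("/", "|", gt, fixed = TRUE)
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  miss_site <- rowSums(matrix(a1 == "." | a2 == ".", nrow = nrow(gt))) > 0L
  n_missing <- sum(miss_site)
  if (any(miss_site)) {
    if (mode == "strict")
      stop("missing genotype call(s) at position(s): ",
           paste(utils::head(pos[idx][miss_site], 5L), collapse = ", "))
    keep2 <- !miss_site
    idx <- idx[keep2]
    gt <- gt[keep2, , drop = FALSE]
    a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  }

  # interleave the two haplotypes of each sample on consecutive rows
  S <- length(idx)
  states <- matrix(0L, nrow = n_hap, ncol = S)
  m1 <- matrix(as.integer(a1 == "1"), nrow = S)
  m2 <- matrix(as.integer(a2 == "1"), nrow = S)
  states[seq(1L, n_hap, by = 2L), ] <- t(m1)
  states[seq(2L, n_hap, by = 2L), ] <- t(m2)

  aa <- VariantAnnotation::info(vcf)$AA
  polarity <- rep(mode == "lenient", S)
  if (!is.null(aa)) {
    aa <- toupper(sub("\\|.*$", "", as.character(aa)))[idx]
    aa[is.na(aa)] <- "."
    is_ref <- aa == ref[idx]
    is_alt <- aa == alt[idx]
    polarity[is_ref | is_alt] <- TRUE
    if (any(is_alt))                       # 1 must mean derived: flip columns
      states[, is_alt] <- 1L - states[, is_alt]
  }

  h <- haplotype_matrix(states, pos[idx],
                        chrom = if (is.null(chrom)) chr[idx[1L]] else chrom,
                        polarity = polarity,
                        sample_ids = rep(samples, each = 2L),
                        pop_labels = rep(pops, each = 2L))
  attr(h, "dropped") <- c(indel = n_indel, multiallelic = n_multi,
                          missing = n_missing)
  h
}

#' Write a haplotype matrix as a phased VCF
#'
#' Serializes a [haplotype_matrix()] to a minimal VCF 4.2 file with phased
#' genotypes and the INFO `AA` ancestral-allele tag. The 0 allele is written
#' as REF (`A`) and the 1 allele as ALT (`G`); at polarized sites `AA` equals
#' REF so that a round trip through [read_vcf_region()] recovers the states,
#' positions and polarity exactly.
#'
#' @param h a [haplotype_matrix()]
#' @param path output file path (plain text)
#' @return `path`, invisibly
#' @export
write_vcf <- function(h, path) {
  n_hap <- nrow(h$states)
  samples <- h$sample_ids[seq(1L, n_hap, by = 2L)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s>", h$chrom),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (ncol(h$states)) {
    g1 <- t(h$states[seq(1L, n_hap, by = 2L), , drop = FALSE])
    g2 <- t(h$states[seq(2L, n_hap, by = 2L), , drop = FALSE])
    gt <- matrix(paste(g1, g2, sep = "|"), nrow = ncol(h$states))
    lines <- paste(h$chrom, h$positions, ".", "A", "G", ".", "PASS",
                   ifelse(h$polarity, "AA=A", "AA=."), "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
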