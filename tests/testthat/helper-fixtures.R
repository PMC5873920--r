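# Text fixtures built at test time (no binary files in the repo).

write_test_panel <- function(path, samples, pops) {
  writeLines(c("sample_id\tpopulation",
               paste(samples, pops, sep = "\t")), path)
  path
}

# small VCF over 2 samples: 3 biallelic SNPs (one with AA = ALT), 1 indel,
# 1 triallelic SNP. Expected strict-mode haplotype matrix (rows NA1a, NA1b,
# NA2a, NA2b):
#   pos 100 (AA=A, no flip):  0 1 1 0
#   pos 200 (AA=T -> flip):   0 0 1 0
#   pos 300 (AA=.):           0 0 0 1   polarity FALSE
write_test_vcf <- function(path, unphased = FALSE) {
  gt300 <- if (unphased) c("0/0", "0/1") else c("0|0", "0|1")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr11>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA1\tNA2",
    "chr11\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|0",
    "chr11\t150\t.\tA\tAT\t.\tPASS\tAA=A\tGT\t0|0\t0|1",
    "chr11\t200\t.\tC\tT\t.\tPASS\tAA=T\tGT\t1|1\t0|1",
    "chr11\t250\t.\tG\tA,T\t.\tPASS\tAA=G\tGT\t1|0\t2|0",
    paste0("chr11\t300\t.\tT\tC\t.\tPASS\tAA=.\tGT\t",
           gt300[1], "\t", gt300[2])), path)
  path
}

test_panel_2 <- function(path) write_test_panel(path, c("NA1", "NA2"),
                                                c("AFR", "EUR"))

# shared, lazily-built expensive fixtures (nulls, studies) for the
# acceptance tests; keyed cache so criteria 5 and 6 reuse identical nulls
.shared <- new.env(parent = emptyenv())
shared_fixture <- function(key, builder) {
  if (!exists(key, envir = .shared, inherits = FALSE))
    assign(key, builder(), envir = .shared)
  get(key, envir = .shared)
}

# the scaled-down world used by the acceptance suite: 10% sample sizes,
# 5 kb genes, 10 kb nSL flanks (10% of the study's 100 kb)
scaled_sizes <- c(AFR = 66L, EUR = 50L, EAS = 50L)
acc_gene_len <- 5000L
acc_flank <- 10000L
acc_win_len <- acc_gene_len + 2L * acc_flank

shared_null <- function(statistic, length_bp, scope, n_sims = 500L) {
  key <- sprintf("null:%s:%d:%s:%d", statistic, length_bp, scope, n_sims)
  shared_fixture(key, function()
    null_distribution(demographic_model(), length_bp, n_sims, statistic,
                      scope, seed = 20240101L,
                      sample_sizes = scaled_sizes))
}
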