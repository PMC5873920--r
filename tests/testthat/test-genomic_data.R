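test_that("read_panel validates and counts populations", {
  p <- withr::local_tempfile(fileext = ".tsv")
  set.seed(1)
  write_test_panel(p,
                   sprintf("S%04d", 1:1668),
                   rep(c("AFR", "EUR", "EAS"), c(661, 503, 504)))
  panel <- read_panel(p, verbose = FALSE)
  expect_equal(nrow(panel), 1668L)
  expect_equal(as.integer(table(panel$population)[c("AFR", "EUR", "EAS")]),
               c(661L, 503L, 504L))

  one <- withr::local_tempfile(fileext = ".tsv")
  write_test_panel(one, "S1", "AFR")
  expect_equal(nrow(read_panel(one, verbose = FALSE)), 1L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tpopulation", empty)
  expect_error(read_panel(empty, verbose = FALSE), "no samples")

  dup <- withr::local_tempfile(fileext = ".tsv")
  write_test_panel(dup, c("S1", "S1"), c("AFR", "EUR"))
  expect_error(read_panel(dup, verbose = FALSE), "duplicate")

  bad <- withr::local_tempfile(fileext = ".tsv")
  write_test_panel(bad, c("S1", "S2"), c("AFR", "AMR"))
  expect_error(read_panel(bad, verbose = FALSE), "AMR")
})

test_that("read_gene_table validates coordinates and categories", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tchrom\tstart\tend\tcategory",
               "SIAE\tchr11\t124505533\t124543227\trecycling_degradation",
               "TINY\tchr1\t500\t500\tbiosynthesis"), f)
  tab <- read_gene_table(f)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$end[1] - tab$start[1] + 1L, 124543227L - 124505533L + 1L)
  expect_equal(tab$end[2] - tab$start[2] + 1L, 1L)   # single-bp region ok

  bad_cat <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tchrom\tstart\tend\tcategory",
               "CMAH\tchr6\t100\t200\tmodification"), bad_cat)
  expect_error(read_gene_table(bad_cat), "modification")
  expect_silent(read_gene_table(bad_cat, strict = FALSE))

  bad_coord <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tchrom\tstart\tend\tcategory",
               "X1\tchr1\t300\t200\tbiosynthesis"), bad_coord)
  expect_error(read_gene_table(bad_coord), "start > end")
})

test_that("apply_gene_filters removes X-linked genes and pseudogenes", {
  fixture <- system.file("extdata", "synthetic_candidate_genes.tsv",
                         package = "sweepscan")
  cand <- read_gene_table(fixture, strict = FALSE)
  expect_equal(nrow(cand), 58L)
  filt <- apply_gene_filters(cand)
  expect_equal(nrow(filt$retained), 55L)
  expect_setequal(filt$excluded$name, c("L1CAM", "RENBP", "CMAH"))

  clean <- cand[!(cand$name %in% c("L1CAM", "RENBP", "CMAH")), ]
  expect_identical(apply_gene_filters(clean)$retained, clean)

  allx <- clean
  allx$chrom <- "X"
  fx <- apply_gene_filters(allx)
  expect_equal(nrow(fx$retained), 0L)
  expect_equal(nrow(fx$excluded), nrow(allx))
})

test_that("read_vcf_region filters records and polarizes from AA", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  pan <- withr::local_tempfile(fileext = ".tsv")
  write_test_vcf(vcf)
  panel <- read_panel(test_panel_2(pan), verbose = FALSE)

  h <- read_vcf_region(vcf, c("chr11", 1, 1000), panel)
  expect_equal(dim(h$states), c(4L, 3L))
  expect_equal(h$positions, c(100L, 200L, 300L))
  expect_equal(attr(h, "dropped")[["indel"]], 1L)
  expect_equal(attr(h, "dropped")[["multiallelic"]], 1L)
  expect_equal(h$states[, 1], c(0L, 1L, 1L, 0L))
  expect_equal(h$states[, 2], c(0L, 0L, 1L, 0L))   # AA=ALT column recoded
  expect_equal(h$states[, 3], c(0L, 0L, 0L, 1L))
  expect_equal(h$polarity, c(TRUE, TRUE, FALSE))
  expect_equal(h$pop_labels, rep(c("AFR", "EUR"), each = 2L))

  # lenient mode treats REF as ancestral where AA is missing
  hl <- read_vcf_region(vcf, c("chr11", 1, 1000), panel, mode = "lenient")
  expect_true(all(hl$polarity))
  expect_equal(hl$states, h$states)

  # interval with no records
  h0 <- read_vcf_region(vcf, c("chr11", 400, 900), panel)
  expect_equal(n_sites(h0), 0L)
  expect_equal(n_haplotypes(h0), 4L)

  # unphased genotype in a surviving record is a strict-mode error
  vcf_u <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(vcf_u, unphased = TRUE)
  expect_error(read_vcf_region(vcf_u, c("chr11", 1, 1000), panel),
               "unphased")
  expect_silent(read_vcf_region(vcf_u, c("chr11", 1, 1000), panel,
                                mode = "lenient"))

  # VCF sample missing from the panel is named
  short <- withr::local_tempfile(fileext = ".tsv")
  write_test_panel(short, "NA1", "AFR")
  expect_error(read_vcf_region(vcf, c("chr11", 1, 1000),
                               read_panel(short, verbose = FALSE)),
               "NA2")
})

test_that("VCF round trip preserves states, positions and polarity", {
  set.seed(42)
  h <- rand_hapmat(8L, 12L)
  h$polarity[c(3, 7)] <- FALSE
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(h, out)
  h2 <- read_vcf_region(out, NULL, NULL)
  expect_equal(h2$states, h$states)
  expect_equal(h2$positions, h$positions)
  expect_equal(h2$polarity, h$polarity)

  # idempotence: writing and re-reading again changes nothing
  out2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(h2, out2)
  h3 <- read_vcf_region(out2, NULL, NULL)
  expect_equal(h3$states, h2$states)
})

test_that("population subsetting commutes with per-population statistics", {
  set.seed(7)
  pops <- rep(rep(c("AFR", "EUR"), each = 2L), 3L)
  h <- rand_hapmat(12L, 8L, pops = pops)
  sub <- subset_population(h, "AFR")
  direct <- h$states[h$pop_labels == "AFR", ]
  expect_equal(sub$states, direct)
  expect_equal(nucleotide_diversity(sub)$pi_total, oracle_pi(direct))
})
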