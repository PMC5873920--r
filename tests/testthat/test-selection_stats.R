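test_that("nucleotide diversity matches its definition", {
  # 4 identical haplotypes: no variation
  h0 <- haplotype_matrix(matrix(1L, 4, 3), c(10L, 20L, 30L))
  expect_equal(nucleotide_diversity(h0)$pi_total, 0)

  # one site with states (0,0,1,1): 4 of 6 pairs differ
  h1 <- haplotype_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1), 5L)
  expect_equal(nucleotide_diversity(h1)$pi_total, 4 / 6)

  # 2 haplotypes differing at 1 of 100 bp
  h2 <- haplotype_matrix(matrix(c(0L, 1L), 2, 1), 50L)
  expect_equal(nucleotide_diversity(h2, length_bp = 100)$pi_per_site, 0.01)

  expect_warning(out <- nucleotide_diversity(
    haplotype_matrix(matrix(0L, 0, 0), integer(0))), "undefined")
  expect_true(is.nan(out$pi_total))
})

test_that("pi equals the unbiased per-site heterozygosity sum", {
  set.seed(11)
  for (rep in 1:25) {
    n <- 2L * sample(2:6, 1)
    h <- rand_hapmat(n, sample(2:10, 1))
    p <- colMeans(h$states)
    expect_equal(nucleotide_diversity(h)$pi_total,
                 sum(2 * p * (1 - p) * n / (n - 1)), tolerance = 1e-12)
    expect_equal(nucleotide_diversity(h)$pi_total, oracle_pi(h$states),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the series-definition oracle", {
  # n = 10, 5 singleton sites carried by distinct haplotypes
  m <- matrix(0L, 10, 5)
  for (s in 1:5) m[s, s] <- 1L
  h <- haplotype_matrix(m, seq(10L, 50L, by = 10L))
  d <- tajimas_d(h)
  expect_lt(d$D, 0)
  expect_equal(d$D, oracle_tajd(m), tolerance = 1e-12)

  # monomorphic region
  h0 <- haplotype_matrix(matrix(0L, 4, 0), integer(0))
  d0 <- tajimas_d(h0)
  expect_true(is.nan(d0$D))
  expect_equal(attr(d0, "flag"), "monomorphic region")
})

test_that("D, pi, FST, H12 are invariant to row/column order and polarity", {
  set.seed(13)
  pops <- rep(rep(c("AFR", "EUR"), each = 3L), 2L)
  h <- rand_hapmat(12L, 9L, pops = pops)
  d0 <- tajimas_d(h)$D
  f0 <- wc_fst(h)$fst_weighted
  h12_0 <- h12(h)$H12

  perm_rows <- sample(12L)
  hp <- haplotype_matrix(h$states[perm_rows, ], h$positions,
                         pop_labels = h$pop_labels[perm_rows])
  expect_equal(tajimas_d(hp)$D, d0)
  expect_equal(wc_fst(hp)$fst_weighted, f0)
  expect_equal(h12(hp)$H12, h12_0)

  # polarity flip: recode alleles at some sites
  flip <- c(2L, 5L)
  st <- h$states
  st[, flip] <- 1L - st[, flip]
  hf <- haplotype_matrix(st, h$positions, pop_labels = h$pop_labels)
  expect_equal(tajimas_d(hf)$D, d0)
  expect_equal(nucleotide_diversity(hf)$pi_total,
               nucleotide_diversity(h)$pi_total)
  expect_equal(wc_fst(hf)$fst_weighted, f0)
  expect_equal(h12(hf)$H12, h12_0)
})

test_that("weighted FST is exact on forced configurations", {
  # two populations fixed for alternate alleles at every site
  st <- rbind(matrix(1L, 4, 3), matrix(0L, 4, 3))
  h <- haplotype_matrix(st, c(1L, 2L, 3L),
                        pop_labels = rep(c("AFR", "EUR"), each = 4L))
  expect_equal(wc_fst(h)$fst_weighted, 1)
  expect_equal(wc_fst(h)$fst_mean, 1)

  # identical haplotype sets in both populations: estimator <= 0
  base <- matrix(c(0L, 1L, 0L, 1L,
                   1L, 0L, 1L, 0L,
                   0L, 0L, 1L, 1L), 4, 3)
  h2 <- haplotype_matrix(rbind(base, base), c(5L, 10L, 15L),
                         pop_labels = rep(c("AFR", "EUR"), each = 4L))
  w <- wc_fst(h2)$fst_weighted
  expect_lte(w, 0)
  expect_equal(w, oracle_fst_weighted(h2$states, h2$pop_labels),
               tolerance = 1e-12)

  # a population with < 2 haplotypes is an error
  h3 <- haplotype_matrix(matrix(c(0L, 1L, 0L, 1L), 4, 1), 1L,
                         pop_labels = c("AFR", "AFR", "AFR", "EUR"))
  expect_error(wc_fst(h3), "EUR")
})

test_that("FST matches the component-formula oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:40) {
    k <- sample(2:3, 1)
    per <- 2L * sample(2:5, k, replace = TRUE)
    pops <- rep(paste0("P", seq_len(k)), per)
    h <- rand_hapmat(sum(per), sample(2:5, 1), pops = pops)
    g <- wc_fst(h)
    expect_equal(g$fst_weighted, oracle_fst_weighted(h$states, h$pop_labels),
                 tolerance = 1e-12)
  }
  # pairwise mode covers all pairs
  pops <- rep(c("AFR", "EUR", "EAS"), each = 4L)
  h <- rand_hapmat(12L, 5L, pops = pops)
  pw <- wc_fst(h, mode = "pairwise")
  expect_equal(nrow(pw), 3L)
  for (j in 1:3) {
    rows <- h$pop_labels %in% c(pw$pop1[j], pw$pop2[j])
    expect_equal(pw$fst_weighted[j],
                 oracle_fst_weighted(h$states[rows, ], h$pop_labels[rows]),
                 tolerance = 1e-12)
  }
})

test_that("nSL matches exhaustive pair enumeration", {
  # spec fixture: 4 haplotypes x 3 sites, focal site 2
  m <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L), c(0L, 0L, 1L))
  h <- haplotype_matrix(m, c(100L, 200L, 300L))
  sc <- nsl_scores(h, maf_cutoff = 0)
  orc <- oracle_nsl_site(m, 2L)
  row <- sc[sc$position == 200L, ]
  expect_equal(row$SL_A, orc$SL_A)
  expect_equal(row$SL_D, orc$SL_D)
  expect_equal(row$nsl, orc$nsl)
  expect_equal(row$nsl, 0)   # symmetric configuration

  # random matrices: exact agreement with enumeration at every scored site
  set.seed(19)
  for (rep in 1:30) {
    n <- 2L * sample(2:4, 1)
    S <- sample(3:10, 1)
    cap <- sample(c(2L, 100L), 1)
    h <- rand_hapmat(n, S)
    sc <- nsl_scores(h, maf_cutoff = 0, max_extend = cap)
    for (r in seq_len(nrow(sc))) {
      focal <- which(h$positions == sc$position[r])
      orc <- oracle_nsl_site(h$states, focal, cap = cap)
      expect_equal(sc$SL_A[r], orc$SL_A, tolerance = 1e-12)
      expect_equal(sc$SL_D[r], orc$SL_D, tolerance = 1e-12)
      expect_equal(sc$nsl[r], orc$nsl, tolerance = 1e-12)
    }
  }
})

test_that("nSL respects MAF cutoff, polarity and class-size rules", {
  set.seed(23)
  h <- rand_hapmat(200L, 6L)
  # site with one derived copy (frequency 0.005 < 0.01): never scored
  st <- h$states
  st[, 3] <- 0L; st[1, 3] <- 1L
  h2 <- haplotype_matrix(st, h$positions)
  sc <- nsl_scores(h2, maf_cutoff = 0.01)
  expect_false(h2$positions[3] %in% sc$position)

  # unpolarized site skipped
  h3 <- h
  h3$polarity[2] <- FALSE
  expect_false(h$positions[2] %in% nsl_scores(h3, maf_cutoff = 0)$position)

  # fewer than 2 sites: empty result
  h4 <- subset_sites(h, 1L)
  expect_equal(nrow(nsl_scores(h4)), 0L)
})

test_that("nSL tract caps are honoured", {
  set.seed(29)
  h <- rand_hapmat(8L, 10L)
  for (cap in c(1L, 3L)) {
    sc <- nsl_scores(h, maf_cutoff = 0, max_extend = cap)
    for (r in seq_len(nrow(sc))) {
      focal <- which(h$positions == sc$position[r])
      orc <- oracle_nsl_site(h$states, focal, cap = cap)
      expect_equal(sc$SL_A[r], orc$SL_A, tolerance = 1e-12)
      expect_equal(sc$SL_D[r], orc$SL_D, tolerance = 1e-12)
    }
  }
})

test_that("max_abs_nsl summarises the window", {
  sc <- data.frame(nsl = c(-2.1, 0.3, 1.7))
  expect_equal(max_abs_nsl(sc), 2.1)
  expect_equal(max_abs_nsl(data.frame(nsl = 0)), 0)
  expect_true(is.nan(max_abs_nsl(data.frame(nsl = numeric(0)))))
})

test_that("H12 follows the haplotype-spectrum formulas", {
  h <- haplotype_matrix(matrix(0L, 6, 2), c(1L, 2L))
  expect_equal(h12(h)$H12, 1)

  # frequencies (0.5, 0.5)
  st <- rbind(matrix(0L, 3, 1), matrix(1L, 3, 1))
  h2 <- haplotype_matrix(st, 1L)
  expect_equal(h12(h2)$H1, 0.5)
  expect_equal(h12(h2)$H12, 1)

  # frequencies (0.4, 0.3, 0.2, 0.1) over 10 haplotypes
  st3 <- matrix(0L, 10, 2)
  st3[5:7, 1] <- 1L                      # hap B x3
  st3[8:9, 2] <- 1L                      # hap C x2
  st3[10, ] <- c(1L, 1L)                 # hap D x1
  h3 <- haplotype_matrix(st3, c(1L, 2L))
  expect_equal(h12(h3)$H12, 0.7^2 + 0.04 + 0.01)

  # invariants on random fixtures
  set.seed(31)
  for (rep in 1:25) {
    h <- rand_hapmat(2L * sample(2:8, 1), sample(1:8, 1))
    sp <- h12(h)
    expect_equal(sum(sp$frequencies), 1)
    expect_gte(sp$H12, sp$H1)
    expect_lte(sp$H12, 1)
    p <- sp$frequencies
    p2 <- if (length(p) > 1) p[2] else 0
    expect_equal(sp$H12 - sp$H1, 2 * p[1] * p2, tolerance = 1e-12)
    orc <- oracle_h12(h$states)
    expect_equal(sp$H12, unname(orc["H12"]), tolerance = 1e-12)
  }

  # 0-site region
  h0 <- haplotype_matrix(matrix(0L, 4, 0), integer(0))
  expect_warning(sp0 <- h12(h0), "0-site")
  expect_equal(sp0$H12, 1)
})
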