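test_that("build_demography converts years to generations correctly", {
  mod <- demographic_model()
  sch <- build_demography(mod)
  # out-of-Africa at 51,000 / 25 = 2,040 generations (merge of OOA into AFR)
  expect_equal(unname(sch$events[3, "time"]), 2040)
  expect_equal(unname(sch$events[1, "time"]), 23000 / 25)
  expect_equal(unname(sch$events[4, "time"]), 148000 / 25)

  # doubling generation time halves all generation counts
  sch2 <- build_demography(demographic_model(gen_time = 50))
  expect_equal(sch2$events[, "time"], sch$events[, "time"] / 2)

  # zero growth: present-day sizes equal the founding sizes
  sch0 <- build_demography(demographic_model(r_eur = 0, r_eas = 0))
  expect_equal(sch0$N0, c(14474, 1032, 554))

  expect_error(demographic_model(t_ooa = 200000), "t_expand > t_ooa")
})

test_that("simulate_region honours seeds, polarity and degenerate rates", {
  mod <- constant_size_model(1000, mu = 0)
  h <- simulate_region(mod, 1000, c(POP1 = 5L), seed = 3)
  expect_equal(n_sites(h), 0L)          # no mutation, no sites

  mod2 <- constant_size_model(1000, mu = 1e-6, rec = 1e-8)
  h1 <- simulate_region(mod2, 5000, c(POP1 = 5L), seed = 11)
  h2 <- simulate_region(mod2, 5000, c(POP1 = 5L), seed = 11)
  expect_identical(h1$states, h2$states)
  expect_identical(h1$positions, h2$positions)
  h3 <- simulate_region(mod2, 5000, c(POP1 = 5L), seed = 12)
  expect_false(identical(h1$positions, h3$positions))

  expect_gt(n_sites(h1), 0L)
  expect_true(all(diff(h1$positions) > 0L))
  expect_true(all(h1$polarity))
  expect_true(all(h1$states %in% 0:1))
  # every simulated site is segregating
  k <- colSums(h1$states)
  expect_true(all(k > 0 & k < n_haplotypes(h1)))
})

test_that("simulator matches Watterson's closed forms at theta = 10", {
  # theta = 4 N mu L = 10 with N = 10000, L = 10000
  mod <- constant_size_model(10000, mu = 2.5e-8, rec = 0)
  set.seed(101)
  reps <- 400L
  S <- numeric(reps); PI <- numeric(reps)
  for (i in seq_len(reps)) {
    h <- simulate_region(mod, 10000, c(POP1 = 5L))
    S[i] <- n_sites(h)
    PI[i] <- nucleotide_diversity(h)$pi_total
  }
  a1 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - 10 * a1), 3 * sd(S) / sqrt(reps))
  expect_lt(abs(mean(PI) - 10), 3 * sd(PI) / sqrt(reps))
})

test_that("site frequency spectrum follows the 1/i neutral weighting", {
  # one randomly chosen site per replicate: sites within a replicate share a
  # genealogy, so pooling them all would overdisperse the chi-square
  mod <- constant_size_model(5000, mu = 1e-7, rec = 0)
  n <- 8L
  set.seed(103)
  counts <- integer(n - 1L)
  for (i in 1:2000) {
    h <- simulate_region(mod, 2000, c(POP1 = 4L))
    if (n_sites(h) == 0L) next
    k <- colSums(h$states)
    j <- k[sample.int(length(k), 1L)]
    counts[j] <- counts[j] + 1L
  }
  expected <- (1 / (1:(n - 1L))) / sum(1 / (1:(n - 1L)))
  gof <- suppressWarnings(stats::chisq.test(counts, p = expected))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated S and pi match msprime under the full 3-pop model", {
  # oracle use only: the pre-installed msprime configured identically
  script <- c(
    "import msprime, math",
    "mu, rec, gen = 2.36e-8, 1.0e-8, 25.0",
    "gs, go, ge = 23000/gen, 51000/gen, 148000/gen",
    "dem = msprime.Demography()",
    "dem.add_population(name='AFR', initial_size=14474)",
    "dem.add_population(name='EUR', initial_size=1032*math.exp(0.0038*gs), growth_rate=0.0038)",
    "dem.add_population(name='EAS', initial_size=554*math.exp(0.0048*gs), growth_rate=0.0048)",
    "dem.add_population(name='OOA', initial_size=1861)",
    "dem.add_population(name='AMH', initial_size=14474)",
    "dem.add_population_split(time=gs, derived=['EUR','EAS'], ancestral='OOA')",
    "dem.add_population_split(time=go, derived=['AFR','OOA'], ancestral='AMH')",
    "dem.add_population_parameters_change(time=ge, population='AMH', initial_size=7310)",
    "dem.sort_events()",
    "for i in range(300):",
    "    ts = msprime.sim_ancestry(samples={'AFR':66,'EUR':50,'EAS':50}, demography=dem,",
    "        sequence_length=5000, recombination_rate=rec, random_seed=900+i)",
    "    mts = msprime.sim_mutations(ts, rate=mu, random_seed=5900+i, discrete_genome=False)",
    "    print(mts.num_sites, float(mts.diversity(span_normalise=False)))")
  pyf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, pyf)
  out <- suppressWarnings(system2("python", pyf, stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 300, "msprime oracle unavailable")
  msp <- read.table(text = out)

  mod <- demographic_model()
  sims <- lapply(1:300, function(i)
    simulate_region(mod, 5000, c(AFR = 66L, EUR = 50L, EAS = 50L),
                    seed = 7000 + i))
  S <- vapply(sims, n_sites, integer(1))
  PI <- vapply(sims, function(h) nucleotide_diversity(h)$pi_total, numeric(1))
  ks_s <- suppressWarnings(stats::ks.test(S, msp$V1))
  ks_pi <- suppressWarnings(stats::ks.test(PI, msp$V2))
  expect_gt(ks_s$p.value, 0.01)
  expect_gt(ks_pi$p.value, 0.01)
})

test_that("null_distribution is deterministic and statistically sane", {
  mod <- constant_size_model(5000, mu = 1e-7, rec = 0)
  n1 <- null_distribution(mod, 2000, 5L, "pi", seed = 5,
                          sample_sizes = c(POP1 = 5L))
  n2 <- null_distribution(mod, 2000, 5L, "pi", seed = 5,
                          sample_sizes = c(POP1 = 5L))
  expect_identical(n1$values, n2$values)

  # D null under a constant-size model is near 0 (slightly negative)
  nd <- null_distribution(mod, 5000, 300L, "tajimas_d", seed = 6,
                          sample_sizes = c(POP1 = 10L))
  expect_lt(abs(mean(nd$values)), 0.2)

  # FST null under the split model with no migration is positive
  nf <- null_distribution(demographic_model(), 3000, 30L, "fst", seed = 7,
                          sample_sizes = c(AFR = 20L, EUR = 20L, EAS = 20L))
  expect_gt(mean(nf$values), 0)
})

test_that("null distributions round-trip through their TSV cache", {
  mod <- constant_size_model(2000, mu = 1e-7)
  nd <- null_distribution(mod, 1000, 8L, "h12", seed = 9,
                          sample_sizes = c(POP1 = 6L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_null_distribution(nd, f)
  back <- read_null_distribution(f)
  expect_equal(back$values, nd$values)
  expect_equal(back$statistic, "h12")
  expect_equal(back$n_sims, 8L)
})
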