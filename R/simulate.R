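#' Simulate a neutral phased haplotype sample
#'
#' Runs the built-in backwards coalescent with recombination under the given
#' demographic schedule and drops infinite-sites mutations on the resulting
#' genealogies. Returns a [haplotype_matrix()] with known polarity (the
#' simulation defines the ancestral state, so 1 = derived at every site).
#' Mutation positions are mapped to unique integer coordinates in
#' `[1, length_bp]`; the rare collisions after discretization are resolved by
#' redrawing the affected positions uniformly among free coordinates.
#'
#' @param schedule a schedule from [build_demography()] /
#'   [constant_size_model()], or a [demographic_model()] (converted
#'   internally)
#' @param length_bp region length in bp (>= 1)
#' @param sample_sizes named integer vector of diploid sample counts per
#'   population, in the schedule's population order (default the study's
#'   `c(AFR = 661, EUR = 503, EAS = 504)` for three-population schedules)
#' @param seed optional integer; when given, the RNG state is set locally so
#'   identical seeds give identical samples
#' @param chrom chromosome label for the output
#' @return a [haplotype_matrix()]
#' @export
simulate_region <- function(schedule, length_bp,
                            sample_sizes = NULL, seed = NULL, chrom = "sim") {
  if (inherits(schedule, "demographic_model"))
    schedule <- build_demography(schedule)
  length_bp <- as.numeric(length_bp)
  if (length_bp < 1) stop("length_bp must be >= 1")
  npop <- length(schedule$pops)
  if (is.null(sample_sizes)) {
    sample_sizes <- if (npop == 3L) c(AFR = 661L, EUR = 503L, EAS = 504L)
                    else stats::setNames(rep(10L, npop), schedule$pops)
  }
  if (length(sample_sizes) != npop)
    stop("sample_sizes must have one entry per population")
  if (!is.null(names(sample_sizes)) &&
      !identical(names(sample_sizes), schedule$pops))
    sample_sizes <- sample_sizes[schedule$pops]

  runner <- function() {
    sim <- coalescent_sim_cpp(as.integer(2L * sample_sizes), length_bp,
                              schedule$mu, schedule$rec,
                              as.numeric(schedule$N0),
                              as.numeric(schedule$growth),
                              schedule$events, schedule$migration)
    pos <- floor(sim$positions) + 1L
    pos[pos > length_bp] <- as.integer(length_bp)
    dup <- duplicated(pos)
    while (any(dup)) {
      free <- setdiff(seq_len(length_bp), pos[!dup])
      if (length(free) < sum(dup))
        stop("more segregating sites than base pairs in region")
      pos[dup] <- sample(free, sum(dup))
      dup <- duplicated(pos)
    }
    ord <- order(pos)
    states <- sim$states[, ord, drop = FALSE]
    ids <- sprintf("%s%04d", rep(schedule$pops, sample_sizes),
                   unlist(lapply(sample_sizes, seq_len)))
    haplotype_matrix(states, pos[ord], chrom = chrom, polarity = TRUE,
                     sample_ids = rep(ids, each = 2L),
                     pop_labels = rep(rep(schedule$pops, sample_sizes),
                                      each = 2L))
  }
  if (is.null(seed)) runner()
  else withr::with_seed(as.integer(seed), runner())
}

#' Null distribution of a statistic under neutrality
#'
#' Simulates `n_sims` neutral regions of the given length and computes one
#' statistic on each with exactly the code paths used for observed data.
#' Replicates where the statistic is undefined (e.g. Tajima's D on a
#' monomorphic region) are excluded from `values` and counted.
#'
#' @param schedule demographic schedule or [demographic_model()]
#' @param length_bp simulated region length (for `nsl_max`, pass gene length
#'   plus both flanks)
#' @param n_sims number of replicates
#' @param statistic one of `"pi"`, `"tajimas_d"`, `"fst"`, `"h12"`,
#'   `"nsl_max"`
#' @param scope population scope: `"pooled"` (pi, D, H12), `"global"` (fst)
#'   or a population code (`nsl_max`)
#' @param seed base seed; replicate `i` uses seed `(seed + i) mod 2^31 - 1`
#' @param sample_sizes per-population diploid counts (see
#'   [simulate_region()])
#' @param maf_cutoff MAF cutoff forwarded to [nsl_scores()]
#' @return object of class `null_distribution`: list with `statistic`,
#'   `scope`, `length_bp`, `values`, `n_sims`, `n_nan`, `seed`
#' @export
null_distribution <- function(schedule, length_bp, n_sims, statistic,
                              scope = NULL, seed = 1L, sample_sizes = NULL,
                              maf_cutoff = 0.01) {
  statistic <- match.arg(statistic,
                         c("pi", "tajimas_d", "fst", "h12", "nsl_max"))
  if (is.null(scope))
    scope <- switch(statistic, fst = "global", nsl_max = "EUR", "pooled")
  vals <- vapply(seq_len(n_sims), function(i) {
    h <- simulate_region(schedule, length_bp, sample_sizes,
                         seed = (as.integer(seed) + i) %% 2147483647L)
    compute_statistic(h, statistic, scope, maf_cutoff = maf_cutoff)
  }, numeric(1))
  ok <- is.finite(vals)
  if (!any(ok)) stop("statistic undefined under null in every replicate")
  structure(list(statistic = statistic, scope = scope,
                 length_bp = length_bp, values = vals[ok],
                 n_sims = n_sims, n_nan = sum(!ok), seed = seed),
            class = "null_distribution")
}

#' Compute one scan statistic on a haplotype matrix
#'
#' Shared dispatcher used for both observed data and simulated nulls, so that
#' empirical p-values compare like with like.
#'
#' @param h a [haplotype_matrix()]
#' @param statistic,scope as in [null_distribution()]
#' @param length_bp region length for per-site pi (defaults to span)
#' @param maf_cutoff MAF cutoff for nSL
#' @return a single numeric value (may be `NaN`)
#' @export
compute_statistic <- function(h, statistic, scope = "pooled",
                              length_bp = NULL, maf_cutoff = 0.01) {
  switch(statistic,
    pi = nucleotide_diversity(h, length_bp)$pi_per_site,
    tajimas_d = tajimas_d(h)$D,
    fst = wc_fst(h, mode = "global")$fst_weighted,
    h12 = suppressWarnings(h12(h)$H12),
    nsl_max = {
      sub <- if (scope %in% c("pooled", "global")) h
             else subset_population(h, scope)
      max_abs_nsl(nsl_scores(sub, maf_cutoff = maf_cutoff))
    },
    stop("unknown statistic: ", statistic))
}

#' Write / read a cached null distribution
#'
#' TSV with one simulated value per line, preceded by a single JSON header
#' line (prefixed `#`) recording the statistic, scope, length, seed and
#' replicate counts.
#'
#' @param null a [null_distribution()] object
#' @param path file path
#' @return `path` (write) or a `null_distribution` (read)
#' @export
write_null_distribution <- function(null, path) {
  hdr <- jsonlite::toJSON(null[c("statistic", "scope", "length_bp",
                                 "n_sims", "n_nan", "seed")],
                          auto_unbox = TRUE)
  writeLines(c(paste0("#", hdr), format(null$values, digits = 17)), path)
  invisible(path)
}

#' @rdname write_null_distribution
#' @export
read_null_distribution <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  structure(c(list(statistic = meta$statistic, scope = meta$scope,
                   length_bp = meta$length_bp,
                   values = as.numeric(lines[-1L]),
                   n_sims = meta$n_sims, n_nan = meta$n_nan,
                   seed = meta$seed)),
            class = "null_distribution")
}
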