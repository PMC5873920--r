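#' Scan run configuration
#'
#' Bundles paths, model and tuning parameters for [run_scan()]. Defaults are
#' the study's: 5,000 neutral replicates per gene length (2,500 for nSL),
#' a 100 kb nSL flank, MAF cutoff 0.01, and significance at 0.05.
#'
#' @param vcf,panel,genes input file paths
#' @param out_dir output directory
#' @param model a [demographic_model()]
#' @param n_sims neutral replicates for pi/D/FST/H12 nulls
#' @param n_sims_nsl neutral replicates for nSL nulls
#' @param flank_bp nSL window flank (bp)
#' @param maf_cutoff nSL MAF cutoff
#' @param alpha significance level
#' @param seed integer master seed
#' @param sample_sizes named diploid sample counts per population used for
#'   the simulated nulls; defaults to the panel's observed counts
#' @param mode polarity/missingness mode for VCF reading
#' @return list of class `run_config`
#' @export
run_config <- function(vcf, panel, genes, out_dir,
                       model = demographic_model(),
                       n_sims = 5000L, n_sims_nsl = 2500L,
                       flank_bp = 1e5, maf_cutoff = 0.01, alpha = 0.05,
                       seed = 1L, sample_sizes = NULL,
                       mode = c("strict", "lenient")) {
  stopifnot(n_sims >= 1L, n_sims_nsl >= 1L, flank_bp >= 0,
            alpha > 0, alpha < 1)
  structure(list(vcf = vcf, panel = panel, genes = genes, out_dir = out_dir,
                 model = model, n_sims = as.integer(n_sims),
                 n_sims_nsl = as.integer(n_sims_nsl),
                 flank_bp = flank_bp, maf_cutoff = maf_cutoff,
                 alpha = alpha, seed = as.integer(seed),
                 sample_sizes = sample_sizes, mode = match.arg(mode)),
            class = "run_config")
}

#' Run the full selection scan
#'
#' Orchestrates the analysis end to end: gene filtering, per-gene statistics
#' (pi, pooled Tajima's D, global + pairwise weighted FST, pooled H12,
#' per-population window max |nSL|), neutral null distributions at matching
#' region lengths, empirical p-values, and exact Mann-Whitney U category
#' comparisons for each measure. Null distributions are cached by
#' (statistic, region length, scope), so genes of equal length share one
#' null. Fully deterministic for a fixed `config$seed`.
#'
#' @param config a [run_config()]
#' @param populations population codes scanned for nSL
#' @return list with `stats` (per-gene statistics table), `results`
#'   (scan p-value table), `categories` (category comparison table),
#'   `manifest` (run metadata); the same tables are written as TSV/JSON
#'   under `config$out_dir`
#' @export
run_scan <- function(config, populations = c("AFR", "EUR", "EAS")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_panel(config$panel, verbose = FALSE)
  genes_raw <- read_gene_table(config$genes, strict = FALSE)
  filt <- apply_gene_filters(genes_raw)
  genes <- filt$retained
  unk <- !(genes$category %in% GENE_CATEGORIES)
  if (any(unk))
    stop("unknown category after filtering for gene(s): ",
         paste(genes$name[unk], collapse = ", "))
  message(sprintf("scan: %d genes retained (%d excluded)",
                  nrow(genes), nrow(filt$excluded)))

  sample_sizes <- config$sample_sizes
  if (is.null(sample_sizes)) {
    cnt <- table(factor(panel$population, levels = c("AFR", "EUR", "EAS")))
    sample_sizes <- stats::setNames(as.integer(cnt), names(cnt))
  }
  schedule <- build_demography(config$model)

  hap_source <- function(chrom, start, end)
    read_vcf_region(config$vcf, c(chrom, start, end), panel,
                    mode = config$mode)

  nulls <- new.env(parent = emptyenv())
  need <- unique(do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    len <- genes$end[i] - genes$start[i] + 1L
    wlen <- len + 2L * as.integer(config$flank_bp)
    rbind(data.frame(statistic = c("tajimas_d", "fst", "h12"),
                     length_bp = len,
                     scope = c("pooled", "global", "pooled")),
          data.frame(statistic = "nsl_max", length_bp = wlen,
                     scope = populations))
  })))
  for (j in seq_len(nrow(need))) {
    key <- null_key(need$statistic[j], need$length_bp[j], need$scope[j])
    if (exists(key, envir = nulls, inherits = FALSE)) next
    ns <- if (need$statistic[j] == "nsl_max") config$n_sims_nsl
          else config$n_sims
    message("null: ", key, " (", ns, " replicates)")
    assign(key,
           null_distribution(schedule, need$length_bp[j], ns,
                             need$statistic[j], need$scope[j],
                             seed = derive_seed(config$seed, j),
                             sample_sizes = sample_sizes,
                             maf_cutoff = config$maf_cutoff),
           envir = nulls)
  }

  results <- scan_genes(genes, hap_source, nulls, alpha = config$alpha,
                        flank_bp = config$flank_bp,
                        maf_cutoff = config$maf_cutoff,
                        populations = populations)

  stats_tab <- per_gene_statistics(genes, hap_source,
                                   flank_bp = config$flank_bp,
                                   maf_cutoff = config$maf_cutoff,
                                   populations = populations)

  cat_tabs <- lapply(unique(results$statistic), function(st) {
    sub <- results[results$statistic == st, ]
    if (st == "nsl_max") {
      do.call(rbind, lapply(populations, function(pop) {
        s2 <- sub[sub$scope == pop, ]
        pairwise_category_tests(s2$observed, s2$category,
                                statistic = paste0("nsl_max_", pop))
      }))
    } else {
      pairwise_category_tests(sub$observed, sub$category, statistic = st)
    }
  })
  categories <- do.call(rbind, cat_tabs)

  manifest <- list(seed = config$seed, n_sims = config$n_sims,
                   n_sims_nsl = config$n_sims_nsl,
                   flank_bp = config$flank_bp,
                   maf_cutoff = config$maf_cutoff, alpha = config$alpha,
                   sample_sizes = as.list(sample_sizes),
                   model = unclass(config$model)[
                     c("n_anc", "n_afr", "t_expand", "t_ooa", "t_split",
                       "n_eur0", "n_eas0", "n_ooa", "r_eur", "r_eas",
                       "mu", "rec", "gen_time")],
                   excluded_genes = filt$excluded,
                   n_null_nan = sum(vapply(ls(nulls), function(k)
                     get(k, envir = nulls)$n_nan, numeric(1))),
                   package_version = as.character(
                     utils::packageVersion("sweepscan")))

  res_out <- results
  res_out$p_display <- format_pvalue(res_out$p_value, res_out$n_valid_null)
  utils::write.table(stats_tab, file.path(config$out_dir, "statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res_out, file.path(config$out_dir, "pvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(categories, file.path(config$out_dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(stats = stats_tab, results = results, categories = categories,
       manifest = manifest, nulls = nulls)
}

# deterministic per-task seed derived from the master seed, kept < 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483647L)
}

#' Per-gene statistics table
#'
#' The descriptive table backing the scan: for each gene, segregating-site
#' count, per-site pi, pooled Tajima's D, weighted and mean global FST, all
#' pairwise weighted FST values, pooled H12 and per-population max |nSL|.
#'
#' @inheritParams run_scan
#' @param genes filtered gene table
#' @param hap_source function `(chrom, start, end) -> haplotype_matrix`
#' @param flank_bp,maf_cutoff nSL window and MAF settings
#' @return data.frame, one row per gene
#' @export
per_gene_statistics <- function(genes, hap_source, flank_bp = 1e5,
                                maf_cutoff = 0.01,
                                populations = c("AFR", "EUR", "EAS")) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    len <- g$end - g$start + 1L
    h <- hap_source(g$chrom, g$start, g$end)
    fst_g <- wc_fst(h, "global")
    fst_p <- wc_fst(h, "pairwise")
    row <- data.frame(
      gene = g$name, category = g$category, n_sites = n_sites(h),
      pi_per_site = nucleotide_diversity(h, len)$pi_per_site,
      tajimas_d = tajimas_d(h)$D,
      fst_weighted_global = fst_g$fst_weighted,
      fst_mean_global = fst_g$fst_mean,
      h12 = suppressWarnings(h12(h)$H12),
      stringsAsFactors = FALSE)
    for (j in seq_len(nrow(fst_p)))
      row[[sprintf("fst_weighted_%s_%s", fst_p$pop1[j], fst_p$pop2[j])]] <-
        fst_p$fst_weighted[j]
    hw <- hap_source(g$chrom, max(1L, g$start - flank_bp), g$end + flank_bp)
    for (pop in populations)
      row[[paste0("nsl_max_", pop)]] <-
        max_abs_nsl(nsl_scores(subset_population(hw, pop),
                               maf_cutoff = maf_cutoff))
    row
  })
  do.call(rbind, rows)
}
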