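#' Sweep planting configuration
#'
#' Describes how a selective sweep is planted into a neutral haplotype
#' matrix: a hard sweep copies one donor haplotype over a fraction of the
#' target population, a soft sweep copies two distinct donors over half that
#' fraction each.
#'
#' @param mode `"neutral"`, `"hard"` or `"soft"`
#' @param sweep_frequency target frequency of the sweeping class (hard) or
#'   combined frequency of the two classes (soft), in `(0, 1]`
#' @param population `"pooled"` or one of `AFR`, `EUR`, `EAS`
#' @return list of class `sweep_config`
#' @export
sweep_config <- function(mode = c("neutral", "hard", "soft"),
                         sweep_frequency = 0.9, population = "pooled") {
  mode <- match.arg(mode)
  if (mode != "neutral" &&
      (sweep_frequency <= 0 || sweep_frequency > 1))
    stop("sweep_frequency must be in (0, 1]")
  structure(list(mode = mode, sweep_frequency = sweep_frequency,
                 population = population,
                 n_sweep_haplotypes = switch(mode, soft = 2L, hard = 1L, 0L)),
            class = "sweep_config")
}

target_rows <- function(h, population) {
  if (identical(population, "pooled")) seq_len(nrow(h$states))
  else which(h$pop_labels == population)
}

#' Plant a hard selective sweep
#'
#' Copies one randomly chosen donor haplotype over a random fraction
#' `sweep_frequency` (rounded to nearest) of the target population's
#' haplotype rows, emulating a single beneficial haplotype risen to high
#' frequency. Positions, site count and polarity are untouched.
#'
#' @param h a neutral [haplotype_matrix()]
#' @param cfg a [sweep_config()] with `mode = "hard"`
#' @return the modified [haplotype_matrix()]
#' @export
plant_hard_sweep <- function(h, cfg) {
  stopifnot(inherits(cfg, "sweep_config"), cfg$mode == "hard")
  rows <- target_rows(h, cfg$population)
  n_copy <- round(cfg$sweep_frequency * length(rows))
  if (n_copy < 1L) stop("sweep_frequency rounds to 0 copies")
  donor <- sample(rows, 1L)
  recipients <- sample(rows, n_copy)
  h$states[recipients, ] <- matrix(h$states[donor, ], nrow = n_copy,
                                   ncol = ncol(h$states), byrow = TRUE)
  h
}

#' Plant a soft selective sweep
#'
#' Copies two distinct donor haplotypes over disjoint recipient sets of
#' `sweep_frequency / 2` of the target population each, emulating selection
#' on standing variation where two independent haplotypes rise together.
#'
#' @param h a neutral [haplotype_matrix()] with at least two distinct
#'   haplotypes in the target population
#' @param cfg a [sweep_config()] with `mode = "soft"`
#' @return the modified [haplotype_matrix()]
#' @export
plant_soft_sweep <- function(h, cfg) {
  stopifnot(inherits(cfg, "sweep_config"), cfg$mode == "soft")
  rows <- target_rows(h, cfg$population)
  key <- apply(h$states[rows, , drop = FALSE], 1L, paste, collapse = "")
  if (length(unique(key)) < 2L)
    stop("fewer than 2 distinct donor haplotypes in target population")
  n_copy <- round(cfg$sweep_frequency * length(rows))
  if (n_copy < 2L) stop("sweep_frequency rounds to 0 copies per donor")
  # draw order mirrors plant_hard_sweep (first donor, then recipients) so a
  # matched hard/soft pair planted from the same RNG state shares both the
  # first donor and the recipient set; the combined frequency is split as
  # evenly as the haplotype count allows
  d1 <- sample(rows, 1L)
  recipients <- sample(rows, n_copy)
  repeat {
    d2 <- sample(rows, 1L)
    if (!identical(h$states[d1, ], h$states[d2, ])) break
  }
  d1_hap <- h$states[d1, ]
  d2_hap <- h$states[d2, ]
  n1s <- ceiling(n_copy / 2)
  r1 <- recipients[seq_len(n1s)]
  r2 <- recipients[(n1s + 1L):n_copy]
  h$states[r1, ] <- matrix(d1_hap, nrow = length(r1),
                           ncol = ncol(h$states), byrow = TRUE)
  h$states[r2, ] <- matrix(d2_hap, nrow = length(r2),
                           ncol = ncol(h$states), byrow = TRUE)
  h
}

#' Generate a complete synthetic study
#'
#' Simulates neutral genes under the demographic model, plants hard and soft
#' sweeps according to the requested design, and writes a self-contained
#' study to disk: a phased multi-gene VCF with `AA` tags, a sample panel TSV,
#' a gene coordinate table (categories assigned round-robin) and a truth
#' table recording what was planted where. Genes are laid out end to end on
#' one synthetic chromosome with an intergenic gap.
#'
#' Sample sizes default to 10% of the study populations (66/50/50 diploids)
#' so the full pipeline runs at desk scale; pass
#' `sample_sizes = c(AFR = 661, EUR = 503, EAS = 504)` for the full design.
#'
#' @param out_dir output directory (created if needed)
#' @param n_neutral,n_hard,n_soft gene counts per mode
#' @param model a [demographic_model()]
#' @param gene_length gene length in bp (default 5000)
#' @param flank_bp flanking sequence simulated around each gene so nSL
#'   windows have data (default 10000)
#' @param sweep_frequency planted sweep frequency (default 0.9)
#' @param sweep_population population carrying the sweeps (default "pooled")
#' @param sample_sizes named diploid counts per population
#' @param seed integer seed; the study is byte-identical for a fixed seed
#' @return list with file paths `vcf`, `panel`, `genes`, `truth` and the
#'   in-memory list of per-gene haplotype matrices (`haps`, covering gene +
#'   flanks)
#' @export
generate_study <- function(out_dir, n_neutral = 4L, n_hard = 4L,
                           n_soft = 4L, model = demographic_model(),
                           gene_length = 5000L, flank_bp = 10000L,
                           sweep_frequency = 0.9,
                           sweep_population = "pooled",
                           sample_sizes = c(AFR = 66L, EUR = 50L, EAS = 50L),
                           seed = 1L) {
  stopifnot(n_neutral + n_hard + n_soft >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedule <- build_demography(model)
  modes <- rep(c("neutral", "hard", "soft"), c(n_neutral, n_hard, n_soft))
  n_genes <- length(modes)
  win_len <- gene_length + 2L * flank_bp
  gap <- 1000L

  haps <- vector("list", n_genes)
  gene_rows <- vector("list", n_genes)
  truth_rows <- vector("list", n_genes)
  offset <- 0L
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_genes)) {
      h <- simulate_region(schedule, win_len, sample_sizes,
                           chrom = "chrS")
      g_start <- flank_bp + 1L
      g_end <- flank_bp + gene_length
      if (modes[i] != "neutral") {
        cfg <- sweep_config(modes[i], sweep_frequency, sweep_population)
        planter <- switch(modes[i], hard = plant_hard_sweep,
                          soft = plant_soft_sweep)
        # whole-window copy: the swept haplotype carries its flanks with it
        h <- planter(h, cfg)
      }
      haps[[i]] <- h
      name <- sprintf("GENE%03d", i)
      gene_rows[[i]] <- data.frame(
        name = name, chrom = "chrS",
        start = offset + g_start, end = offset + g_end,
        category = GENE_CATEGORIES[(i - 1L) %% 4L + 1L],
        stringsAsFactors = FALSE)
      truth_rows[[i]] <- data.frame(
        gene = name, mode = modes[i],
        frequency = if (modes[i] == "neutral") NA_real_ else sweep_frequency,
        population = if (modes[i] == "neutral") NA_character_
                     else sweep_population,
        seed = seed, stringsAsFactors = FALSE)
      offset <- offset + win_len + gap
    }
  })

  genes <- do.call(rbind, gene_rows)
  truth <- do.call(rbind, truth_rows)

  # one multi-gene VCF: shift each window's positions by its offset
  combined <- haps
  off <- 0L
  for (i in seq_len(n_genes)) {
    combined[[i]]$positions <- haps[[i]]$positions + off
    off <- off + win_len + gap
  }
  all_states <- do.call(cbind, lapply(combined, `[[`, "states"))
  all_pos <- unlist(lapply(combined, `[[`, "positions"))
  h_all <- haplotype_matrix(all_states, all_pos, chrom = "chrS",
                            polarity = TRUE,
                            sample_ids = haps[[1L]]$sample_ids,
                            pop_labels = haps[[1L]]$pop_labels)

  vcf_path <- file.path(out_dir, "study.vcf")
  panel_path <- file.path(out_dir, "panel.tsv")
  genes_path <- file.path(out_dir, "genes.tsv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_vcf(h_all, vcf_path)
  sam <- h_all$sample_ids[c(TRUE, FALSE)]
  pop <- h_all$pop_labels[c(TRUE, FALSE)]
  utils::write.table(data.frame(sample_id = sam, population = pop),
                     panel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genes, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf_path, panel = panel_path, genes = genes_path,
       truth = truth_path, haps = haps, gene_table = genes,
       truth_table = truth, flank_bp = flank_bp,
       gene_length = gene_length, sample_sizes = sample_sizes)
}
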