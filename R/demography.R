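#' Three-population out-of-Africa demographic model
#'
#' Parameter container for the neutral null model: an ancestral African
#' population that expands at `t_expand`, an out-of-Africa bottleneck lineage
#' splitting off at `t_ooa`, and a Eurasian split at `t_split` followed by
#' exponential growth in the European and East Asian populations. Times are
#' given in years and converted to generations with `gen_time`.
#'
#' Two quantities are not stated in the study this model reproduces and
#' default to the values of the underlying demographic inference (Gravel et
#' al. 2011): the out-of-Africa bottleneck size `n_ooa = 1861` and the East
#' Asian founding size `n_eas0 = 554`. Both can be overridden.
#'
#' @param n_anc ancestral effective size (diploid), default 7310
#' @param n_afr post-expansion African size, default 14474
#' @param t_expand time of the African expansion, years ago (148000)
#' @param t_ooa time of the out-of-Africa migration, years ago (51000)
#' @param t_split time of the Eurasian split, years ago (23000)
#' @param n_eur0 European size at the split (bottleneck), default 1032
#' @param n_eas0 East Asian size at the split; not stated by the study,
#'   default 554 (from the cited demographic inference)
#' @param n_ooa out-of-Africa bottleneck size between `t_ooa` and `t_split`;
#'   not stated by the study, default 1861
#' @param r_eur,r_eas exponential growth rates per generation since the
#'   split (0.0038, 0.0048)
#' @param mu mutation rate per bp per generation (2.36e-8)
#' @param rec recombination rate per bp per generation (1.0e-8)
#' @param gen_time years per generation, default 25
#' @param migration optional backward migration rate matrix (3x3, rows/cols
#'   AFR, EUR, EAS); default all zero
#' @return object of class `demographic_model`
#' @export
demographic_model <- function(n_anc = 7310, n_afr = 14474,
                              t_expand = 148000, t_ooa = 51000,
                              t_split = 23000,
                              n_eur0 = 1032, n_eas0 = 554, n_ooa = 1861,
                              r_eur = 0.0038, r_eas = 0.0048,
                              mu = 2.36e-8, rec = 1.0e-8,
                              gen_time = 25,
                              migration = NULL) {
  sizes <- c(n_anc, n_afr, n_eur0, n_eas0, n_ooa)
  if (any(sizes < 2)) stop("all population sizes must be >= 2")
  if (!(t_expand > t_ooa && t_ooa > t_split && t_split > 0))
    stop("times must satisfy t_expand > t_ooa > t_split > 0")
  if (r_eur < 0 || r_eas < 0) stop("growth rates must be >= 0")
  if (mu < 0 || rec < 0) stop("mu and rec must be >= 0")
  if (is.null(migration)) migration <- matrix(0, 3, 3)
  stopifnot(all(dim(migration) == c(3, 3)))
  structure(list(n_anc = n_anc, n_afr = n_afr, t_expand = t_expand,
                 t_ooa = t_ooa, t_split = t_split, n_eur0 = n_eur0,
                 n_eas0 = n_eas0, n_ooa = n_ooa, r_eur = r_eur,
                 r_eas = r_eas, mu = mu, rec = rec, gen_time = gen_time,
                 migration = migration),
            class = "demographic_model")
}

#' Backwards-in-time epoch schedule
#'
#' Converts a [demographic_model()] into the event schedule the coalescent
#' engine consumes: present-day sizes (African size `n_afr`; European and
#' East Asian sizes grown forward from their founding sizes over the
#' post-split epoch), exponential shrinkage back to the split, a merge of the
#' East Asian into the European lineage at `t_split` (which then takes the
#' out-of-Africa bottleneck size), a merge into the African lineage at
#' `t_ooa`, and reversion of the African size to `n_anc` at `t_expand`.
#'
#' @param model a [demographic_model()]
#' @return list with `pops` (names), `N0` (present sizes), `growth`
#'   (backward decay rates), `events` (matrix: time in generations, type
#'   0=merge/1=size, pop index 0-based, argument, new growth) and `migration`
#' @export
build_demography <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  g_split <- model$t_split / model$gen_time
  g_ooa <- model$t_ooa / model$gen_time
  g_expand <- model$t_expand / model$gen_time
  if (!(g_expand > g_ooa && g_ooa > g_split))
    stop("inconsistent ordering of event times")
  N0 <- c(AFR = model$n_afr,
          EUR = model$n_eur0 * exp(model$r_eur * g_split),
          EAS = model$n_eas0 * exp(model$r_eas * g_split))
  growth <- c(0, model$r_eur, model$r_eas)
  events <- rbind(
    c(g_split, 0, 2, 1, 0),                    # EAS merges into EUR lineage
    c(g_split, 1, 1, model$n_ooa, 0),          # that lineage = OOA bottleneck
    c(g_ooa,   0, 1, 0, 0),                    # OOA merges into AFR
    c(g_expand, 1, 0, model$n_anc, 0))         # AFR reverts to ancestral size
  colnames(events) <- c("time", "type", "pop", "arg", "growth")
  list(pops = c("AFR", "EUR", "EAS"), N0 = unname(N0), growth = growth,
       events = events, migration = model$migration,
       mu = model$mu, rec = model$rec)
}

#' Single constant-size population model
#'
#' Convenience model for calibration experiments (e.g. checking the simulator
#' against Watterson's closed forms).
#'
#' @param n_e diploid effective size
#' @param mu,rec per-bp per-generation rates
#' @return a schedule list as returned by [build_demography()], with one
#'   population labelled `POP1`
#' @export
constant_size_model <- function(n_e, mu, rec = 0) {
  list(pops = "POP1", N0 = n_e, growth = 0,
       events = matrix(numeric(0), ncol = 5,
                       dimnames = list(NULL, c("time", "type", "pop",
                                               "arg", "growth"))),
       migration = matrix(0, 1, 1), mu = mu, rec = rec)
}
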