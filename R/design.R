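#' Study design for coalescent SNP simulation
#'
#' Bundles the demography and sampling constants of the simulation design:
#' an ancestral population splitting into the demes `split_time` generations
#' before present, uniform priors on the ancestral size and per-deme sizes
#' (haploid individuals), the number of unlinked SNPs to return, and the
#' per-deme haploid sample counts (two sequences per diploid individual,
#' nonzero only for sampled demes).
#'
#' @param demes a `deme_set`; sampled demes define the sequence counts.
#' @param n_snps number of SNP columns per simulated matrix (default 4364,
#'   the size of the empirical matrix the design mirrors).
#' @param split_time island-split time in generations (default 21000).
#' @param ancestral_ne_range uniform prior bounds on the ancestral haploid
#'   size (default 20000-50000).
#' @param deme_size_range uniform prior bounds on each deme's haploid size
#'   (default 5-100).
#' @param sequences_per_individual haploid sequences per sampled individual
#'   (default 2, diploids).
#' @return a `study_design`.
#' @export
study_design <- function(demes, n_snps = 4364, split_time = 21000,
                         ancestral_ne_range = c(20000, 50000),
                         deme_size_range = c(5, 100),
                         sequences_per_individual = 2L) {
  stopifnot(inherits(demes, "deme_set"), n_snps >= 1)
  sampling <- haploid_counts(demes, sequences_per_individual)
  if (sum(sampling) < 4)
    stop("design needs at least 4 sampled haploid sequences")
  structure(list(demes = demes, n_demes = nrow(demes),
                 split_time = split_time,
                 ancestral_ne_range = ancestral_ne_range,
                 deme_size_range = deme_size_range,
                 n_snps = as.integer(n_snps), sampling = sampling),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("study_design: %d demes (%d sampled, %d sequences), ",
                     "split %g generations, %d SNPs\n"),
              x$n_demes, sum(x$sampling > 0), sum(x$sampling),
              x$split_time, x$n_snps))
  invisible(x)
}

#' Draw simulation parameters from the design priors
#'
#' Independent uniform draws: ancestral haploid size, per-deme haploid
#' sizes, one landscape-effect weight per predictor in the model, and the
#' dispersal scalar. Uses the current RNG state; seed the session (or pass
#' draws through a corpus builder) for reproducibility.
#'
#' @param design a `study_design`.
#' @param model a `landscape_model`; only its predictors receive effect
#'   weights (the null model draws none).
#' @param effect_range uniform bounds for the landscape-effect weights
#'   (default 2-5; pass e.g. `c(5, 5)` to pin a fixed strong effect).
#' @param dispersal_range uniform bounds for the dispersal scalar
#'   (default 0.1-0.3).
#' @return a `parameter_draw` with `ancestral_ne`, `deme_sizes`,
#'   `effect_weights` (named), `dispersal`, and a `sim_seed` usable to seed
#'   the genotype simulation.
#' @export
sample_parameters <- function(design, model, effect_range = c(2, 5),
                              dispersal_range = c(0.1, 0.3)) {
  stopifnot(inherits(design, "study_design"),
            inherits(model, "landscape_model"))
  ew <- stats::setNames(
    runif(length(model$predictors), effect_range[1], effect_range[2]),
    model$predictors)
  structure(list(
    ancestral_ne = runif(1, design$ancestral_ne_range[1],
                         design$ancestral_ne_range[2]),
    deme_sizes = runif(design$n_demes, design$deme_size_range[1],
                       design$deme_size_range[2]),
    effect_weights = ew,
    dispersal = runif(1, dispersal_range[1], dispersal_range[2]),
    sim_seed = sample.int(.Machine$integer.max - 1L, 1)),
    class = "parameter_draw")
}
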