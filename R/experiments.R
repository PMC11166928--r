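#' Standard landscape and study designs
#'
#' `default_stacks()` generates one stack per predictor kind on a shared
#' grid. `mirror_design()` builds the empirical-mirror study design: 39
#' demes of which 9 carry genetic data, 52 diploid individuals split
#' 18/9/7/6/5/3/2/1/1 across the sampled demes (104 sequences), and 4364
#' SNPs. `reduced_design()` is the small design used for fast experiments:
#' 12 demes, 6 sampled with 5 individuals (10 sequences) each, 500 SNPs on
#' a 16 x 16 grid.
#'
#' @param grid_spec grid template (see [generate_layer_stack()]).
#' @param seed integer seed.
#' @param params per-kind generator parameter lists, named by kind.
#' @return `default_stacks()`: named list of `layer_stack`s.
#' @export
default_stacks <- function(grid_spec, seed = 1, params = list()) {
  kinds <- c("distance", "slope", "rivers", "habitat_shifts",
             "niche_suitability")
  stats::setNames(lapply(seq_along(kinds), function(i)
    generate_layer_stack(kinds[i], grid_spec, params[[kinds[i]]] %||% list(),
                         seed = seed + i)), kinds)
}

#' @rdname default_stacks
#' @param n_snps SNP columns per simulated matrix.
#' @export
mirror_design <- function(seed = 1, n_snps = 4364) {
  extent <- uniform_raster(24, 24, cell_size = 0.5)
  demes <- generate_deme_layout(39, 9, extent,
                                sample_size_scheme = c(18, 9, 7, 6, 5, 3, 2,
                                                       1, 1),
                                seed = seed)
  list(extent = extent, demes = demes,
       design = study_design(demes, n_snps = n_snps))
}

#' @rdname default_stacks
#' @export
reduced_design <- function(seed = 1, n_snps = 500) {
  extent <- uniform_raster(16, 16, cell_size = 0.5)
  demes <- generate_deme_layout(12, 6, extent,
                                sample_size_scheme = rep(5L, 6), seed = seed)
  list(extent = extent, demes = demes,
       design = study_design(demes, n_snps = n_snps))
}

#' Build a labeled training corpus of encoded SNP images
#'
#' For each landscape model and example: draw parameters from the priors,
#' build the per-epoch migration schedule, simulate the SNP matrix, and
#' encode it as a labeled image. Any stage failure is retried with a fresh
#' seed up to `max_retries` times. The per-example provenance (seeds and
#' scalar draws) is returned as a manifest, which fully determines
#' reproduction under the same master seed.
#'
#' @param design a `study_design`.
#' @param stacks named list of `layer_stack`s covering all predictors used.
#' @param n_per_model examples per model.
#' @param seed master seed.
#' @param models list of `landscape_model`s (default: all twelve).
#' @param effect_range,dispersal_range prior bounds passed to
#'   [sample_parameters()].
#' @param cap migration row-sum cap.
#' @param max_retries retries per example on simulation failure.
#' @return list with `images` (an `image_set`, labels = model ids) and
#'   `manifest` (data frame).
#' @export
build_training_corpus <- function(design, stacks, n_per_model, seed = 1,
                                  models = enumerate_models(),
                                  effect_range = c(2, 5),
                                  dispersal_range = c(0.1, 0.3), cap = 0.5,
                                  max_retries = 5L) {
  stopifnot(n_per_model >= 1)
  set.seed(seed)
  ex_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                length(models) * n_per_model),
                     length(models), n_per_model)
  images <- vector("list", length(models) * n_per_model)
  rows <- vector("list", length(models) * n_per_model)
  k <- 0L
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    for (ei in seq_len(n_per_model)) {
      ex_seed <- ex_seeds[mi, ei]
      img <- NULL
      for (try in seq_len(max_retries + 1L)) {
        res <- tryCatch({
          set.seed(ex_seed)
          draw <- sample_parameters(design, model, effect_range,
                                    dispersal_range)
          schedule <- build_migration_schedule(model, stacks, draw,
                                               design$demes,
                                               split_time = design$split_time,
                                               cap = cap)
          g <- simulate_genotypes(design, draw, schedule)
          g$label <- model$id
          list(img = encode_image(g), draw = draw)
        }, error = function(e) e)
        if (!inherits(res, "error")) {
          img <- res
          break
        }
        ex_seed <- ex_seed + 7919L # fresh retry seed
      }
      if (is.null(img))
        stop(sprintf("corpus error: model %d example %d failed %d times: %s",
                     model$id, ei, max_retries + 1L,
                     conditionMessage(res)))
      k <- k + 1L
      images[[k]] <- img$img
      rows[[k]] <- data.frame(model_id = model$id, example = ei,
                              seed = ex_seed,
                              ancestral_ne = img$draw$ancestral_ne,
                              dispersal = img$draw$dispersal)
    }
  }
  list(images = image_set(images), manifest = do.call(rbind, rows))
}

#' Reduced three-model self-classification experiment
#'
#' The fast analogue of the full 12-model run: isolation by distance versus
#' a strong slope effect versus a strong river barrier (landscape effects
#' pinned at 5), on the reduced design. A corpus of
#' `n_train + n_test` images per model is simulated, split by model, and a
#' classifier is trained and evaluated.
#'
#' @param seed master seed.
#' @param n_train,n_test images per model for training and testing.
#' @param n_snps SNPs per image.
#' @param n_filters classifier filter counts.
#' @param epochs training epochs.
#' @param batch_size training mini-batch (default 20 at this corpus size, so
#'   optimization gets enough update steps; the full-scale default is 100).
#' @return list with `report` (an `evaluation_report`), `calibration`,
#'   `classifier`, and `manifest`.
#' @export
run_self_classification <- function(seed = 1, n_train = 100L, n_test = 30L,
                                    n_snps = 500L, n_filters = c(8L, 16L),
                                    epochs = 10L, batch_size = 20L) {
  base <- reduced_design(seed = seed, n_snps = n_snps)
  stacks <- default_stacks(base$extent, seed = seed)
  models <- list(landscape_model(1L),
                 landscape_model(2L, "slope"),
                 landscape_model(3L, "rivers"))
  corpus <- build_training_corpus(base$design, stacks,
                                  n_per_model = n_train + n_test,
                                  seed = seed, models = models,
                                  effect_range = c(5, 5))
  parts <- split_dataset(corpus$images,
                         train_fraction = n_train / (n_train + n_test),
                         seed = seed)
  clf <- build_classifier(dim(corpus$images$x)[2:3], length(models),
                          n_filters = n_filters, seed = seed)
  clf <- train_classifier(clf, parts$train, seed = seed, epochs = epochs,
                          batch_size = batch_size)
  list(report = evaluate_classifier(clf, parts$test),
       calibration = calibration_report(clf, parts$test),
       classifier = clf, manifest = corpus$manifest)
}

#' Sampling-design sensitivity experiment
#'
#' Re-runs corpus building, training and evaluation under the four genetic
#' sampling schemes — 9 or 39 sampled demes crossed with 2 or 20 sequences
#' (1 or 10 diploid individuals) per deme — on one shared 39-deme landscape,
#' and reports the per-scheme accuracy. Richer sampling (more demes, more
#' sequences) is expected to dominate.
#'
#' @param seed master seed.
#' @param n_per_model simulated examples per model per scheme.
#' @param train_fraction train share of each scheme's corpus.
#' @param n_snps SNPs per image.
#' @param models candidate models (default: the reduced three-model set;
#'   landscape effects keep the standard U(2, 5) prior, the same conditions
#'   as the main corpus).
#' @param effect_range landscape-effect prior bounds.
#' @param n_filters,epochs,batch_size classifier budget.
#' @return list with `accuracy` (data frame: scheme, demes, sequences,
#'   accuracy %) and `reports`/`calibration` per scheme.
#' @export
run_sampling_experiment <- function(seed = 1, n_per_model = 400L,
                                    train_fraction = 0.75, n_snps = 30L,
                                    models = NULL, effect_range = c(2, 5),
                                    n_filters = c(4L, 8L), epochs = 10L,
                                    batch_size = 20L) {
  if (is.null(models))
    models <- list(landscape_model(1L), landscape_model(2L, "slope"),
                   landscape_model(3L, "rivers"))
  extent <- uniform_raster(16, 16, cell_size = 0.5)
  layout <- generate_deme_layout(39, 39, extent,
                                 sample_size_scheme = rep(1L, 39),
                                 seed = seed)
  stacks <- default_stacks(extent, seed = seed)
  set.seed(seed)
  nine <- sort(sample.int(39, 9))
  schemes <- data.frame(n_sampled = c(9, 9, 39, 39),
                        sequences = c(2, 20, 2, 20))
  reports <- list()
  calib <- list()
  acc <- numeric(nrow(schemes))
  for (i in seq_len(nrow(schemes))) {
    demes <- layout
    sampled <- if (schemes$n_sampled[i] == 9) layout$id %in% nine
               else rep(TRUE, 39)
    demes$sampled <- sampled
    demes$n_individuals <- ifelse(sampled, schemes$sequences[i] / 2L, 0L)
    design <- study_design(demes, n_snps = n_snps)
    res <- tryCatch({
      corpus <- build_training_corpus(design, stacks, n_per_model,
                                      seed = seed + i, models = models,
                                      effect_range = effect_range)
      parts <- split_dataset(corpus$images, train_fraction, seed = seed + i)
      clf <- build_classifier(dim(corpus$images$x)[2:3], length(models),
                              n_filters = n_filters, seed = seed + i)
      clf <- train_classifier(clf, parts$train, seed = seed + i,
                              epochs = epochs, batch_size = batch_size)
      list(report = evaluate_classifier(clf, parts$test),
           calibration = calibration_report(clf, parts$test))
    }, error = function(e) e)
    key <- sprintf("%dd_%ds", schemes$n_sampled[i], schemes$sequences[i])
    if (inherits(res, "error")) {
      warning(sprintf("scheme %s failed: %s", key, conditionMessage(res)))
      acc[i] <- NA_real_
    } else {
      reports[[key]] <- res$report
      calib[[key]] <- res$calibration
      acc[i] <- res$report$overall_accuracy
    }
  }
  list(accuracy = data.frame(scheme = sprintf("%dd_%ds", schemes$n_sampled,
                                              schemes$sequences),
                             demes = schemes$n_sampled,
                             sequences = schemes$sequences,
                             accuracy = acc),
       reports = reports, calibration = calib)
}

#' Read and write generator configuration
#'
#' All generator parameters (grid, deme layout, priors, classifier budget)
#' live in a plain YAML file with an explicit `seed` field.
#'
#' @param path YAML file path.
#' @param config a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(seed = 1L,
       grid = list(n_rows = 16L, n_cols = 16L, cell_size = 1),
       demes = list(n_total = 12L, n_sampled = 6L,
                    individuals_per_deme = 5L),
       layers = list(smoothing = 3, n_channels = 2L, rho = 0.85,
                     closed_fraction = 0.4),
       design = list(n_snps = 500L, split_time = 21000L,
                     ancestral_ne_range = c(20000L, 50000L),
                     deme_size_range = c(5L, 100L),
                     effect_range = c(2, 5), dispersal_range = c(0.1, 0.3),
                     migration_cap = 0.5, generation_time = 1),
       classifier = list(n_filters = c(8L, 16L), dense_units = c(100L, 40L),
                         batch_size = 100L, epochs = 10L, lr = 0.001))
}
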