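#' Enumerate the twelve candidate landscape models
#'
#' Every subset of the static predictors {slope, rivers} crossed with one of
#' {none, habitat shifts, niche suitability}; the two dynamic predictors are
#' built from the same environmental data and are never combined in a single
#' model. Model 1 (no predictors) is the isolation-by-distance null; since
#' IBD is a special case of IBR, geographic distance is implicit in every
#' model.
#'
#' @return list of `landscape_model` objects, ids 1-12 in the canonical
#'   order: 1 distance; 2 slope; 3 rivers; 4 habitat shifts; 5 niche
#'   suitability; 6 slope+rivers; 7 slope+habitat; 8 slope+niche;
#'   9 rivers+habitat; 10 rivers+niche; 11 slope+rivers+habitat;
#'   12 slope+rivers+niche.
#' @export
enumerate_models <- function() {
  preds <- list(
    character(0),
    "slope",
    "rivers",
    "habitat_shifts",
    "niche_suitability",
    c("slope", "rivers"),
    c("slope", "habitat_shifts"),
    c("slope", "niche_suitability"),
    c("rivers", "habitat_shifts"),
    c("rivers", "niche_suitability"),
    c("slope", "rivers", "habitat_shifts"),
    c("slope", "rivers", "niche_suitability"))
  lapply(seq_along(preds), function(i) landscape_model(i, preds[[i]]))
}

#' @rdname enumerate_models
#' @param id integer model id.
#' @param predictors character vector drawn from `"slope"`, `"rivers"`,
#'   `"habitat_shifts"`, `"niche_suitability"`.
#' @export
landscape_model <- function(id, predictors = character(0)) {
  allowed <- c("slope", "rivers", "habitat_shifts", "niche_suitability")
  if (!all(predictors %in% allowed))
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, allowed), collapse = ", "))
  if (all(c("habitat_shifts", "niche_suitability") %in% predictors))
    stop("habitat_shifts and niche_suitability are non-independent ",
         "hypotheses and cannot co-occur in one model")
  structure(list(id = as.integer(id), predictors = predictors),
            class = "landscape_model")
}

#' @export
print.landscape_model <- function(x, ...) {
  lab <- if (length(x$predictors) == 0) "geographic distance"
         else paste(x$predictors, collapse = " + ")
  cat(sprintf("landscape_model %d: %s\n", x$id, lab))
  invisible(x)
}
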