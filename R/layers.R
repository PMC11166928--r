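#' Synthetic spatial predictor layers
#'
#' Generates synthetic analogues of the five spatial predictors of gene
#' flow: a uniform geographic-distance layer, a slope field (gradient
#' magnitude of a smoothed random surface), river channels with
#' flow-accumulation-like values, a 21-slice stack of binary habitat
#' (open/closed) layers covering 21-0 kyr in 1000-year epochs, and a 7-slice
#' stack of niche-suitability layers (stored as resistance, 1 - suitability)
#' on the standard late-Quaternary time slices (21, 17-14.7, 14.7-12.9,
#' 12.9-11.7, 11.7-8.326, 8.326-4.2, 4.2-0 kyr, the last slice extended to
#' the present). Dynamic stacks evolve as a first-order autoregression on a
#' latent smooth field, so consecutive slices are more alike than distant
#' ones. All non-negative layers are min-max scaled to \[0, 1\].
#'
#' @param kind one of `"distance"`, `"slope"`, `"rivers"`,
#'   `"habitat_shifts"`, `"niche_suitability"`.
#' @param grid_spec a `raster_grid` template, or a list with `n_rows`,
#'   `n_cols` and optionally `cell_size`, `origin`.
#' @param params named list of generator parameters: `smoothing` (Gaussian
#'   kernel sd in cells, default 3), `n_channels` (rivers, default 2),
#'   `channel_fraction` (rivers; 0 forces an all-zero layer), `rho`
#'   (AR(1) coefficient between consecutive dynamic slices, default 0.85),
#'   `closed_fraction` (habitat, default 0.4).
#' @param seed integer seed; generation is reproducible bit-for-bit.
#' @return a `layer_stack`: list with `kind`, `layers` (list of
#'   `raster_grid`, oldest slice first for dynamic kinds) and `epoch_years`
#'   (list of `c(start_kyr, end_kyr)` per layer, times before present).
#' @export
generate_layer_stack <- function(kind, grid_spec, params = list(), seed = 1) {
  kinds <- c("distance", "slope", "rivers", "habitat_shifts",
             "niche_suitability")
  if (!kind %in% kinds)
    stop("unknown layer kind: ", kind, " (expected one of ",
         paste(kinds, collapse = ", "), ")")
  g <- as_grid_spec(grid_spec)
  set.seed(seed)
  smoothing <- params$smoothing %||% 3
  rho <- params$rho %||% 0.85

  mk <- function(values) raster_grid(values, g$cell_size, g$origin)

  layers <- switch(kind,
    distance = list(mk(matrix(1, g$n_rows, g$n_cols))),
    slope = {
      z <- smooth_field(g$n_rows, g$n_cols, smoothing)
      gx <- cbind(z[, 2] - z[, 1], (z[, -(1:2), drop = FALSE] -
             z[, seq_len(g$n_cols - 2), drop = FALSE]) / 2,
             z[, g$n_cols] - z[, g$n_cols - 1])
      gy <- rbind(z[2, ] - z[1, ], (z[-(1:2), , drop = FALSE] -
             z[seq_len(g$n_rows - 2), , drop = FALSE]) / 2,
             z[g$n_rows, ] - z[g$n_rows - 1, ])
      list(normalize01(mk(sqrt(gx^2 + gy^2))))
    },
    rivers = {
      n_channels <- params$n_channels %||% 2L
      if (!is.null(params$channel_fraction) && params$channel_fraction == 0)
        n_channels <- 0L
      flow <- matrix(0, g$n_rows, g$n_cols)
      for (ch in seq_len(n_channels)) {
        horizontal <- runif(1) < 0.5
        len <- if (horizontal) g$n_cols else g$n_rows
        across <- if (horizontal) g$n_rows else g$n_cols
        pos <- sample.int(across, 1)
        for (s in seq_len(len)) {
          if (horizontal) flow[pos, s] <- flow[pos, s] + s
          else flow[s, pos] <- flow[s, pos] + s
          pos <- min(max(pos + sample(-1:1, 1), 1L), across)
        }
      }
      lyr <- mk(flow)
      list(if (n_channels > 0) normalize01(lyr) else lyr)
    },
    habitat_shifts = {
      closed_fraction <- params$closed_fraction %||% 0.4
      lat <- smooth_field(g$n_rows, g$n_cols, smoothing)
      out <- vector("list", 21L)
      for (t in seq_len(21L)) {
        if (t > 1)
          lat <- rho * lat + sqrt(1 - rho^2) *
            smooth_field(g$n_rows, g$n_cols, smoothing)
        closed <- lat > quantile(lat, 1 - closed_fraction)
        out[[t]] <- mk(matrix(as.numeric(closed), g$n_rows, g$n_cols))
      }
      out
    },
    niche_suitability = {
      lat <- smooth_field(g$n_rows, g$n_cols, smoothing)
      out <- vector("list", 7L)
      for (t in seq_len(7L)) {
        if (t > 1)
          lat <- rho * lat + sqrt(1 - rho^2) *
            smooth_field(g$n_rows, g$n_cols, smoothing)
        z <- (lat - mean(lat)) / stats::sd(lat)
        suit <- stats::pnorm(z)
        out[[t]] <- mk(1 - suit) # resistance rises where suitability falls
      }
      out
    })

  epoch_years <- switch(kind,
    habitat_shifts = lapply(21:1, function(k) c(k, k - 1)),
    niche_suitability = list(c(21, 17), c(17, 14.7), c(14.7, 12.9),
                             c(12.9, 11.7), c(11.7, 8.326), c(8.326, 4.2),
                             c(4.2, 0)),
    list(c(21, 0)))

  structure(list(kind = kind, layers = layers, epoch_years = epoch_years),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("layer_stack '%s': %d layer(s), %d x %d cells\n", x$kind,
              length(x$layers), x$layers[[1]]$n_rows, x$layers[[1]]$n_cols))
  invisible(x)
}

as_grid_spec <- function(grid_spec) {
  if (inherits(grid_spec, "raster_grid"))
    return(list(n_rows = grid_spec$n_rows, n_cols = grid_spec$n_cols,
                cell_size = grid_spec$cell_size, origin = grid_spec$origin))
  list(n_rows = grid_spec$n_rows, n_cols = grid_spec$n_cols,
       cell_size = grid_spec$cell_size %||% 1,
       origin = grid_spec$origin %||% c(0, 0))
}

# Gaussian-smoothed white noise (separable kernel, edge-renormalized).
smooth_field <- function(n_rows, n_cols, sigma = 3) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma <= 0) return(z)
  h <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  z <- conv1d(z, k)        # along rows (vertical)
  t(conv1d(t(z), k))       # along columns (horizontal)
}

conv1d <- function(z, k) {
  h <- (length(k) - 1L) / 2L
  n <- nrow(z)
  acc <- matrix(0, n, ncol(z))
  wt <- matrix(0, n, ncol(z))
  for (o in -h:h) {
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    w <- k[o + h + 1L]
    acc[ok, ] <- acc[ok, ] + w * z[src[ok], , drop = FALSE]
    wt[ok, ] <- wt[ok, ] + w
  }
  acc / wt
}

# Slice a stack to the single layer covering a generation interval
# [start_gen, end_gen) before present. Static stacks return their only layer.
stack_at_epoch <- function(stack, start_gen, end_gen, generation_time = 1) {
  if (length(stack$layers) == 1L) idx <- 1L
  else {
    mid_kyr <- (start_gen + end_gen) / 2 * generation_time / 1000
    idx <- which(vapply(stack$epoch_years, function(e)
      mid_kyr <= e[1] && mid_kyr >= e[2], logical(1)))[1]
    if (is.na(idx))
      stop(sprintf("no %s layer covers %g-%g generations", stack$kind,
                   start_gen, end_gen))
  }
  structure(list(kind = stack$kind, layers = stack$layers[idx],
                 epoch_years = stack$epoch_years[idx]),
            class = "layer_stack")
}

#' Composite resistance surface
#'
#' Combines single-epoch predictor layers into one resistance raster:
#' every non-distance layer is min-max normalized to \[0, 1\] and added with
#' its landscape-effect weight on top of an implicit all-ones baseline
#' (the geographic-distance layer), so the cell value is
#' `1 + sum_k w_k * layer_k`. With no non-distance layers the result is the
#' pure isolation-by-distance surface of 1s; every cell is >= 1.
#'
#' @param stacks list of single-layer `layer_stack`s (slice dynamic stacks
#'   to one epoch first); a distance stack may be included but adds nothing
#'   beyond the baseline.
#' @param weights named numeric vector of landscape effects, one per
#'   non-distance kind present.
#' @return a `raster_grid` resistance surface.
#' @export
composite_resistance <- function(stacks, weights = numeric()) {
  if (length(stacks) == 0)
    stop("composite_resistance needs at least one layer for the grid geometry")
  template <- stacks[[1]]$layers[[1]]
  stacks <- Filter(function(s) s$kind != "distance", stacks)
  out <- matrix(1, template$n_rows, template$n_cols)
  mask <- template$nodata_mask
  for (s in stacks) {
    if (length(s$layers) != 1L)
      stop("slice dynamic stacks to a single epoch before composing")
    lyr <- s$layers[[1]]
    if (!same_geometry(lyr, template))
      stop("composition error: layer geometries differ")
    w <- if (s$kind %in% names(weights)) weights[[s$kind]] else NA_real_
    if (is.na(w))
      stop("no weight supplied for predictor '", s$kind, "'")
    out <- out + w * normalize01(lyr)$values
    mask <- mask | lyr$nodata_mask
  }
  out[mask] <- 0
  raster_grid(out, template$cell_size, template$origin, nodata_mask = mask)
}

# Pure-IBD helper: uniform resistance of 1 on the template geometry.
ibd_surface <- function(template) {
  uniform_raster(template$n_rows, template$n_cols, 1, template$cell_size,
                 template$origin)
}
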