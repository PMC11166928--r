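#' Least-cost resistance distances among demes
#'
#' Builds the 8-connected lattice graph over unmasked raster cells, with the
#' cost of a step between adjacent cells equal to the mean of the two cell
#' resistances times the step length (1 for rook moves, sqrt(2) for diagonal
#' moves, in cell units), and returns the matrix of minimal accumulated path
#' costs between all deme pairs (Dijkstra shortest paths, via igraph). On a
#' uniform resistance surface of 1 this is the 8-connected geometric
#' distance, i.e. the isolation-by-distance special case.
#'
#' @param raster a `raster_grid` of strictly positive resistances on
#'   unmasked cells.
#' @param demes a `deme_set`; all demes must sit on unmasked cells.
#' @return symmetric numeric matrix (demes x demes) with zero diagonal,
#'   with deme ids as dimnames.
#' @export
least_cost_distances <- function(raster, demes) {
  stopifnot(inherits(raster, "raster_grid"))
  nr <- raster$n_rows
  nc <- raster$n_cols
  open <- !raster$nodata_mask
  if (any(raster$values[open] <= 0))
    stop("resistance values must be strictly positive on unmasked cells")
  if (any(raster$nodata_mask[cbind(demes$row, demes$col)]))
    stop("all demes must fall on unmasked cells")

  idx <- function(r, c) (c - 1L) * nr + r # column-major cell id
  steps <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                c(1L, -1L, sqrt(2)))
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  rr <- row(raster$values); cc <- col(raster$values)
  for (s in steps) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc & open
    ok[ok] <- open[cbind(r2[ok], c2[ok])]
    a <- idx(rr[ok], cc[ok]); b <- idx(r2[ok], c2[ok])
    from <- c(from, a); to <- c(to, b)
    wt <- c(wt, (raster$values[ok] + raster$values[cbind(r2[ok], c2[ok])]) /
              2 * s[3] * raster$cell_size)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < nr * nc)
    g <- igraph::add_vertices(g, nr * nc - igraph::vcount(g))
  cells <- idx(demes$row, demes$col)
  dmat <- igraph::distances(g, v = cells, to = cells, weights = wt,
                            algorithm = "dijkstra")
  if (any(!is.finite(dmat))) {
    bad <- which(!is.finite(dmat), arr.ind = TRUE)[1, ]
    stop(sprintf("demes %d and %d are disconnected by the nodata mask",
                 demes$id[bad[1]], demes$id[bad[2]]))
  }
  dimnames(dmat) <- list(demes$id, demes$id)
  dmat
}

#' Convert resistance distances to per-generation migration rates
#'
#' Applies the cubic decay `m_ij = dispersal * (1 / x_ij)^3` to each
#' off-diagonal resistance distance. A weaker (squared) decay produces
#' migration high enough to erase genetic structure, hence the cubic
#' exponent. If any row sum of the resulting matrix exceeds `cap`
#' (a valid per-generation emigration bound), the whole matrix is rescaled
#' uniformly so the largest row sum equals `cap`; uniform rescaling keeps
#' the matrix symmetric. `cap = Inf` disables the bound; `cap = 0` yields
#' complete isolation.
#'
#' @param x_matrix symmetric matrix of resistance distances, zero diagonal,
#'   positive off-diagonals.
#' @param dispersal dispersal scalar multiplying the converted matrix
#'   (drawn from U(0.1, 0.3) in the standard design).
#' @param cap maximum allowed row sum (default 0.5).
#' @return symmetric migration matrix with zero diagonal.
#' @export
resistance_to_migration <- function(x_matrix, dispersal, cap = 0.5) {
  x <- as.matrix(x_matrix)
  off <- row(x) != col(x)
  if (any(x[off] <= 0))
    stop("co-located demes: off-diagonal resistance distances must be > 0")
  m <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  m[off] <- dispersal * (1 / x[off])^3
  if (cap == 0) {
    m[] <- 0
  } else if (is.finite(cap)) {
    rs <- max(rowSums(m))
    if (rs > cap) m <- m * (cap / rs)
  }
  m
}

# Epoch table (generations before present, most recent epoch first) for a
# landscape model under a given generation time in years.
model_epochs <- function(model, split_time = 21000, generation_time = 1) {
  slice_gen <- function(kyr) kyr * 1000 / generation_time
  if ("habitat_shifts" %in% model$predictors) {
    bounds <- slice_gen(0:21)
  } else if ("niche_suitability" %in% model$predictors) {
    bounds <- slice_gen(c(0, 4.2, 8.326, 11.7, 12.9, 14.7, 17, 21))
  } else {
    bounds <- slice_gen(c(0, 21))
  }
  bounds <- pmin(bounds, split_time)
  data.frame(start_gen = bounds[-length(bounds)], end_gen = bounds[-1])
}

#' Build a per-epoch migration schedule for a landscape model
#'
#' For each historical epoch implied by the model's dynamic predictors
#' (21 epochs of 1000 years for habitat shifts, 7 climate time slices for
#' niche suitability, a single epoch otherwise), composes the model's
#' predictor layers into a resistance surface with the drawn landscape
#' effects, computes least-cost distances among demes, and converts them to
#' a per-generation migration matrix with the drawn dispersal scalar.
#'
#' @param model a `landscape_model` (see [enumerate_models()]).
#' @param stacks named list of `layer_stack`s covering, at minimum, the
#'   model's predictors plus `"distance"`.
#' @param draw a `parameter_draw` from [sample_parameters()] (supplies
#'   `effect_weights` and `dispersal`).
#' @param demes a `deme_set`.
#' @param split_time island-split time in generations.
#' @param generation_time generation time in years (default 1, so the
#'   21 kyr split is 21,000 generations).
#' @param cap migration-rate row-sum cap (see
#'   [resistance_to_migration()]).
#' @return a `migration_schedule`: list with `epochs` (each `start_gen`,
#'   `end_gen`, `matrix`) ordered from the present backwards, tiling
#'   `[0, split_time]`, plus the `dispersal` used.
#' @export
build_migration_schedule <- function(model, stacks, draw, demes,
                                     split_time = 21000,
                                     generation_time = 1, cap = 0.5) {
  missing <- setdiff(model$predictors, names(stacks))
  if (length(missing) > 0)
    stop("configuration error: model needs predictor stack(s) ",
         paste(missing, collapse = ", "))
  if (!"distance" %in% names(stacks))
    stop("configuration error: a distance stack is required for geometry")
  ep <- model_epochs(model, split_time, generation_time)
  epochs <- vector("list", nrow(ep))
  for (i in seq_len(nrow(ep))) {
    sliced <- lapply(stacks[c("distance", model$predictors)], stack_at_epoch,
                     start_gen = ep$start_gen[i], end_gen = ep$end_gen[i],
                     generation_time = generation_time)
    surface <- composite_resistance(sliced, draw$effect_weights)
    x <- least_cost_distances(surface, demes)
    epochs[[i]] <- list(start_gen = ep$start_gen[i], end_gen = ep$end_gen[i],
                        matrix = resistance_to_migration(x, draw$dispersal,
                                                         cap = cap))
  }
  structure(list(epochs = epochs, dispersal = draw$dispersal,
                 split_time = split_time),
            class = "migration_schedule")
}

#' @export
print.migration_schedule <- function(x, ...) {
  cat(sprintf("migration_schedule: %d epoch(s) tiling [0, %g] generations\n",
              length(x$epochs), x$split_time))
  invisible(x)
}

#' Write / read migration matrices and schedules
#'
#' Matrices are written as TSV with deme-id headers; a schedule is written
#' as a JSON index of epochs plus one TSV per epoch matrix.
#'
#' @param m matrix with deme-id dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(data.frame(deme = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$deme
  m
}

#' @rdname write_matrix_tsv
#' @param schedule a `migration_schedule`.
#' @param dir output directory.
#' @export
write_schedule <- function(schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- lapply(seq_along(schedule$epochs), function(i) {
    e <- schedule$epochs[[i]]
    mp <- file.path(dir, sprintf("epoch_%02d.tsv", i))
    write_matrix_tsv(e$matrix, mp)
    list(start_gen = e$start_gen, end_gen = e$end_gen,
         matrix_path = basename(mp))
  })
  jsonlite::write_json(list(split_time = schedule$split_time,
                            dispersal = schedule$dispersal, epochs = idx),
                       file.path(dir, "schedule.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
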