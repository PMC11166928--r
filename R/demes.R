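#' Deme layouts
#'
#' A `deme_set` is a data frame of demes (local populations) with columns
#' `id`, `x`, `y`, `row`, `col`, `sampled`, `n_individuals`. Sampled demes
#' contribute sequences to the genetic data; unsampled demes still shape the
#' migration landscape.
#'
#' `generate_deme_layout()` places `n_total` demes uniformly at random on
#' unmasked raster cells with a minimum pairwise separation of 2 cell widths
#' (no two demes share or abut a cell), flags a random subset of `n_sampled`
#' demes as carrying genetic data, and assigns them the per-deme individual
#' counts in `sample_size_scheme` (in ascending order of deme id).
#'
#' @param n_total total number of demes.
#' @param n_sampled number of demes with genetic data.
#' @param extent a `raster_grid` defining the landscape extent.
#' @param sample_size_scheme integer vector of length `n_sampled`: diploid
#'   individuals per sampled deme.
#' @param seed integer seed; the layout is reproducible bit-for-bit.
#' @param min_separation minimum pairwise Euclidean separation, in cells.
#' @return a `deme_set`.
#' @export
generate_deme_layout <- function(n_total, n_sampled, extent,
                                 sample_size_scheme, seed,
                                 min_separation = 2) {
  stopifnot(inherits(extent, "raster_grid"))
  if (n_sampled > n_total)
    stop("n_sampled cannot exceed n_total")
  if (length(sample_size_scheme) != n_sampled)
    stop("sample_size_scheme must have one entry per sampled deme")
  if (n_sampled > 0 && any(sample_size_scheme < 1))
    stop("sampled demes need at least 1 individual")
  set.seed(seed)

  open <- which(!extent$nodata_mask, arr.ind = TRUE)
  cand <- open[sample.int(nrow(open)), , drop = FALSE]
  chosen <- matrix(NA_integer_, 0, 2)
  for (i in seq_len(nrow(cand))) {
    if (nrow(chosen) == n_total) break
    p <- cand[i, ]
    if (nrow(chosen) > 0) {
      d2 <- (chosen[, 1] - p[1])^2 + (chosen[, 2] - p[2])^2
      if (min(d2) < min_separation^2) next
    }
    chosen <- rbind(chosen, p)
  }
  if (nrow(chosen) < n_total)
    stop(sprintf("extent too small: placed %d of %d demes at separation >= %g",
                 nrow(chosen), n_total, min_separation))

  xy <- cell_center(extent, chosen[, 1], chosen[, 2])
  sampled <- rep(FALSE, n_total)
  sampled[sort(sample.int(n_total, n_sampled))] <- TRUE
  n_ind <- integer(n_total)
  n_ind[sampled] <- as.integer(sample_size_scheme)

  demes <- data.frame(id = seq_len(n_total), x = xy[, "x"], y = xy[, "y"],
                      row = as.integer(chosen[, 1]),
                      col = as.integer(chosen[, 2]),
                      sampled = sampled, n_individuals = n_ind)
  rownames(demes) <- NULL
  class(demes) <- c("deme_set", "data.frame")
  demes
}

#' @rdname generate_deme_layout
#' @param demes a `deme_set`.
#' @param path TSV file path (columns id, x, y, sampled, n_individuals).
#' @export
write_demes_tsv <- function(demes, path) {
  write.table(demes[, c("id", "x", "y", "sampled", "n_individuals")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname generate_deme_layout
#' @param extent_raster raster used to recover cell indices when reading.
#' @export
read_demes_tsv <- function(path, extent_raster = NULL) {
  d <- read.delim(path)
  d$sampled <- as.logical(d$sampled)
  if (!is.null(extent_raster)) {
    rc <- coord_to_cell(extent_raster, d$x, d$y)
    d$row <- rc[, "row"]
    d$col <- rc[, "col"]
  }
  class(d) <- c("deme_set", "data.frame")
  d
}

# Haploid sequence counts per deme (2 per diploid individual).
haploid_counts <- function(demes, sequences_per_individual = 2L) {
  as.integer(demes$n_individuals) * as.integer(sequences_per_individual)
}
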