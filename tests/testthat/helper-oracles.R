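# Independent oracles used to cross-check the package implementations.

# Grid shortest-path oracle: plain iterative relaxation (Bellman-Ford style)
# over 8-neighbour moves until a fixed point; no priority queue, no igraph.
oracle_grid_distance <- function(values, from, to, cell_size = 1) {
  nr <- nrow(values)
  nc <- ncol(values)
  dist <- matrix(Inf, nr, nc)
  dist[from[1], from[2]] <- 0
  moves <- rbind(c(-1, -1, sqrt(2)), c(-1, 0, 1), c(-1, 1, sqrt(2)),
                 c(0, -1, 1), c(0, 1, 1),
                 c(1, -1, sqrt(2)), c(1, 0, 1), c(1, 1, sqrt(2)))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cl in seq_len(nc)) {
      if (!is.finite(dist[r, cl])) next
      for (m in seq_len(nrow(moves))) {
        r2 <- r + moves[m, 1]
        c2 <- cl + moves[m, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        w <- (values[r, cl] + values[r2, c2]) / 2 * moves[m, 3] * cell_size
        if (dist[r, cl] + w < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- dist[r, cl] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[to[1], to[2]]
}

# Per-SNP Hudson FST written out longhand from allele counts, looped site by
# site (ratio of averages).
oracle_hudson_fst <- function(g1, g2) {
  n1 <- nrow(g1)
  n2 <- nrow(g2)
  num <- 0
  den <- 0
  for (s in seq_len(ncol(g1))) {
    c1 <- sum(g1[, s])
    c2 <- sum(g2[, s])
    p1 <- c1 / n1
    p2 <- c2 / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# Deme set placed by hand on a raster (cells given as row/col pairs).
manual_demes <- function(raster, cells, sampled = NULL, n_individuals = NULL) {
  n <- nrow(cells)
  if (is.null(sampled)) sampled <- rep(TRUE, n)
  if (is.null(n_individuals)) n_individuals <- ifelse(sampled, 1L, 0L)
  xy <- landcnn:::cell_center(raster, cells[, 1], cells[, 2])
  d <- data.frame(id = seq_len(n), x = xy[, "x"], y = xy[, "y"],
                  row = as.integer(cells[, 1]), col = as.integer(cells[, 2]),
                  sampled = sampled, n_individuals = as.integer(n_individuals))
  class(d) <- c("deme_set", "data.frame")
  d
}

# Single-epoch migration schedule from an explicit matrix.
manual_schedule <- function(m, split_time = 21000, dispersal = NA_real_) {
  structure(list(epochs = list(list(start_gen = 0, end_gen = split_time,
                                    matrix = m)),
                 dispersal = dispersal, split_time = split_time),
            class = "migration_schedule")
}

# Two-deme study design with explicit haploid sample counts.
two_deme_design <- function(n_seq = c(10L, 10L), n_snps = 100L,
                            split_time = 21000) {
  r <- landcnn::uniform_raster(8, 8)
  demes <- manual_demes(r, cbind(c(2, 6), c(2, 6)),
                        n_individuals = n_seq / 2L)
  landcnn::study_design(demes, n_snps = n_snps, split_time = split_time)
}

# Parameter draw with everything pinned.
manual_draw <- function(n_demes, deme_size = 50, ancestral_ne = 30000,
                        effect_weights = numeric(0), dispersal = 0.2,
                        sim_seed = 1L) {
  structure(list(ancestral_ne = ancestral_ne,
                 deme_sizes = rep(deme_size, n_demes),
                 effect_weights = effect_weights, dispersal = dispersal,
                 sim_seed = sim_seed),
            class = "parameter_draw")
}
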