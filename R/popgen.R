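#' Pairwise Hudson's FST among demes
#'
#' Hudson's estimator in its ratio-of-averages form: per SNP, with sample
#' allele frequencies p1, p2 and haploid sample sizes n1, n2,
#' numerator `(p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`
#' and denominator `p1 (1 - p2) + p2 (1 - p1)`; FST for a deme pair is the
#' sum of numerators over SNPs divided by the sum of denominators. Small
#' negative values are expected from the unbiased numerator. Demes with
#' fewer than two sequences get NA rows/columns rather than fabricated
#' values.
#'
#' @param g a `genotype_matrix`.
#' @return symmetric matrix with zero diagonal and attribute
#'   `estimator = "hudson"`, deme ids as dimnames.
#' @export
pairwise_fst <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  demes <- sort(unique(g$meta$deme_id))
  D <- length(demes)
  n <- vapply(demes, function(d) sum(g$meta$deme_id == d), numeric(1))
  p <- matrix(0, D, ncol(g$geno))
  for (i in seq_len(D))
    p[i, ] <- colMeans(g$geno[g$meta$deme_id == demes[i], , drop = FALSE])
  fst <- matrix(0, D, D, dimnames = list(demes, demes))
  for (i in seq_len(D - 1)) for (j in (i + 1):D) {
    if (n[i] < 2 || n[j] < 2) {
      fst[i, j] <- fst[j, i] <- NA_real_
      next
    }
    num <- (p[i, ] - p[j, ])^2 -
      p[i, ] * (1 - p[i, ]) / (n[i] - 1) -
      p[j, ] * (1 - p[j, ]) / (n[j] - 1)
    den <- p[i, ] * (1 - p[j, ]) + p[j, ] * (1 - p[i, ])
    fst[i, j] <- fst[j, i] <- sum(num) / sum(den)
  }
  attr(fst, "estimator") <- "hudson"
  fst
}

#' Mean expected and observed heterozygosity
#'
#' He is the sample-size-corrected expected heterozygosity averaged over
#' SNPs, `2 p (1 - p) n / (n - 1)` with n the haploid sample size; Ho is the
#' fraction of heterozygous individuals per SNP (sequences paired into
#' diploids by `individual_id`), averaged over SNPs.
#'
#' @param g a `genotype_matrix` whose sequences pair into diploids.
#' @return list with `He` and `Ho`.
#' @export
heterozygosity <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$geno)
  p <- colMeans(g$geno)
  he <- mean(2 * p * (1 - p)) * n / (n - 1)
  ind <- split(seq_len(n), g$meta$individual_id)
  if (any(lengths(ind) != 2))
    stop("pairing error: each individual needs exactly 2 sequences")
  a1 <- g$geno[vapply(ind, `[`, integer(1), 1), , drop = FALSE]
  a2 <- g$geno[vapply(ind, `[`, integer(1), 2), , drop = FALSE]
  list(He = he, Ho = mean(colMeans(a1 != a2)))
}

#' PCA plausibility check of an observed FST matrix against simulations
#'
#' Vectorizes the lower triangles of the simulated pairwise-FST matrices,
#' fits a PCA, projects the target matrix, and asks whether the target's
#' first two scores fall inside the convex hull of the simulated scores and
#' within each PC's min-max range. This operationalizes the visual check
#' that simulations span the variation seen in the observed data.
#'
#' @param sim_fsts list (length >= 10) of simulated FST matrices over the
#'   same demes.
#' @param target the observed FST matrix.
#' @return list with `match` (logical), `in_hull`, `in_range`, `scores`
#'   (target PC1/PC2), `dist_centroid`, `dist_nearest`, and `degenerate`
#'   (TRUE when the simulated cloud has no spread, in which case `match`
#'   falls back to near-equality with the cloud).
#' @export
pca_match <- function(sim_fsts, target) {
  if (length(sim_fsts) < 10)
    stop("need at least 10 simulated FST matrices")
  vec <- function(m) m[lower.tri(m)]
  X <- do.call(rbind, lapply(sim_fsts, vec))
  y <- vec(as.matrix(target))
  if (length(y) != ncol(X)) stop("target and simulations must share demes")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) {
    eq <- sqrt(sum((y - X[1, ])^2)) < 1e-8
    return(list(match = eq, in_hull = eq, in_range = eq,
                scores = c(0, 0), dist_centroid = NA_real_,
                dist_nearest = NA_real_, degenerate = TRUE))
  }
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pca$x))
  s_sim <- pca$x[, seq_len(k), drop = FALSE]
  s_tgt <- predict(pca, matrix(y, 1))[, seq_len(k)]
  if (k == 1L) {
    in_range <- s_tgt[1] >= min(s_sim[, 1]) & s_tgt[1] <= max(s_sim[, 1])
    in_hull <- in_range
  } else {
    in_range <- all(s_tgt >= apply(s_sim, 2, min) &
                    s_tgt <= apply(s_sim, 2, max))
    in_hull <- point_in_hull(s_sim, s_tgt)
  }
  cent <- colMeans(s_sim)
  list(match = in_hull && in_range, in_hull = in_hull, in_range = in_range,
       scores = s_tgt,
       dist_centroid = sqrt(sum((s_tgt - cent)^2)),
       dist_nearest = sqrt(min(rowSums(sweep(s_sim, 2, s_tgt)^2))),
       degenerate = FALSE)
}

# Point-in-convex-hull test in 2-D via consistent cross-product signs along
# the hull boundary (points on the boundary count as inside).
point_in_hull <- function(pts, p) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n == 1) return(sqrt(sum((p - hull[1, ])^2)) < 1e-12)
  if (n == 2) { # degenerate hull: a segment
    a <- hull[1, ]; b <- hull[2, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    t <- sum((p - a) * (b - a)) / sum((b - a)^2)
    return(abs(cross) < 1e-10 && t >= 0 && t <= 1)
  }
  sgn <- numeric(n)
  for (i in seq_len(n)) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1 else i + 1, ]
    sgn[i] <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }
  all(sgn >= -1e-12) || all(sgn <= 1e-12)
}
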