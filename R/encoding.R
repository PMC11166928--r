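#' Encode a genotype matrix as a deterministic binary SNP image
#'
#' The classifier input: per column the majority allele is recoded to 0 and
#' the minority to 1 (an exact 50/50 tie leaves allele 0 as the major),
#' columns are then stably sorted by descending frequency of 1s, and rows
#' (haploid sequences) are sorted by (deme id, individual id, sequence id)
#' so that each deme forms a contiguous block in ascending deme order. The
#' encoding is idempotent; the model label is carried through.
#'
#' @param g a `genotype_matrix` with every column polymorphic.
#' @return a `snp_image`: list with `pixels` (0/1 integer matrix),
#'   `row_manifest` (ordered sequence/individual/deme tags) and `label`.
#' @export
encode_image <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  geno <- g$geno
  if (nrow(geno) < 1 || ncol(geno) < 1) stop("empty genotype matrix")
  cnt <- colSums(geno)
  if (any(cnt == 0 | cnt == nrow(geno)))
    stop("encoding error: monomorphic column(s) present")
  flip <- cnt > nrow(geno) / 2
  geno[, flip] <- 1L - geno[, flip]
  cnt[flip] <- nrow(geno) - cnt[flip]
  col_order <- order(-cnt) # stable: ties keep their original order
  row_order <- order(g$meta$deme_id, g$meta$individual_id,
                     g$meta$sequence_id)
  structure(list(pixels = geno[row_order, col_order, drop = FALSE],
                 row_manifest = g$meta[row_order, , drop = FALSE],
                 label = g$label),
            class = "snp_image")
}

#' @export
print.snp_image <- function(x, ...) {
  cat(sprintf("snp_image: %d x %d pixels%s\n", nrow(x$pixels),
              ncol(x$pixels),
              if (is.na(x$label)) "" else sprintf(" (model %d)", x$label)))
  invisible(x)
}

#' Bundle encoded images into a classifier-ready set
#'
#' Stacks equally shaped `snp_image`s into one numeric array with a label
#' vector, the container consumed by [split_dataset()] and the classifier.
#'
#' @param images list of `snp_image`s of identical dimensions.
#' @return an `image_set`: list with `x` (array n x height x width) and
#'   `labels` (integer vector, NA for unlabeled images).
#' @export
image_set <- function(images) {
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("all images in a set must share the same shape")
  x <- array(0, dim = c(length(images), dims[1, 1], dims[2, 1]))
  for (i in seq_along(images)) x[i, , ] <- images[[i]]$pixels
  labels <- vapply(images, function(im) as.integer(im$label %||% NA),
                   integer(1))
  structure(list(x = x, labels = labels), class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("image_set: %d images of %d x %d (%d labeled)\n",
              d[1], d[2], d[3], sum(!is.na(x$labels))))
  invisible(x)
}

subset_image_set <- function(set, idx) {
  structure(list(x = set$x[idx, , , drop = FALSE], labels = set$labels[idx]),
            class = "image_set")
}
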