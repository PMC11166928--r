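#' Simulate unlinked biallelic SNPs under a migration schedule
#'
#' Runs the structured coalescent: within each epoch of `schedule`, lineages
#' coalesce within demes (haploid sizes from `draw`) and migrate between
#' demes at the epoch's backward rates; at the split time all demes merge
#' into the ancestral population. Sites are independent genealogies with one
#' mutation placed uniformly on the branches; sites monomorphic among the
#' sampled sequences are discarded and topped up until exactly
#' `design$n_snps` polymorphic columns are obtained. Columns are coded 0 for
#' the major and 1 for the minor allele; rows are haploid sequences from
#' sampled demes only, in ascending deme order.
#'
#' @param design a `study_design`.
#' @param draw a `parameter_draw`; its `sim_seed` seeds the simulation
#'   unless `seed` is given.
#' @param schedule a `migration_schedule` whose epochs tile
#'   `[0, design$split_time]`.
#' @param seed optional integer overriding `draw$sim_seed`.
#' @param max_tries_factor bound on discarded sites per requested site
#'   before a yield error is raised.
#' @return a `genotype_matrix`: list with `geno` (0/1 integer matrix,
#'   sequences x SNPs), `meta` (sequence_id, individual_id, deme_id) and
#'   `label` (model id, or NA for empirical data).
#' @export
simulate_genotypes <- function(design, draw, schedule, seed = NULL,
                               max_tries_factor = 10L) {
  stopifnot(inherits(design, "study_design"),
            inherits(draw, "parameter_draw"),
            inherits(schedule, "migration_schedule"))
  ep <- schedule$epochs
  starts <- vapply(ep, `[[`, numeric(1), "start_gen")
  ends <- vapply(ep, `[[`, numeric(1), "end_gen")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; ep <- ep[o]
  if (starts[1] != 0 || ends[length(ep)] != design$split_time ||
      (length(ep) > 1 && any(starts[-1] != ends[-length(ep)])))
    stop("schedule epochs must tile [0, split_time] generations")

  set.seed(seed %||% draw$sim_seed)
  geno <- .sim_snp_sites(design$sampling, draw$deme_sizes,
                         draw$ancestral_ne, ends,
                         lapply(ep, `[[`, "matrix"), design$split_time,
                         design$n_snps, as.integer(max_tries_factor))

  keep <- design$sampling > 0
  deme_id <- rep(design$demes$id[keep], design$sampling[keep])
  seqs_per_ind <- design$sampling[keep] / design$demes$n_individuals[keep]
  individual <- rep(seq_len(sum(design$demes$n_individuals[keep])),
                    each = unique(seqs_per_ind)[1])
  meta <- data.frame(sequence_id = seq_len(nrow(geno)),
                     individual_id = individual, deme_id = deme_id)
  genotype_matrix(geno, meta, label = NA_integer_)
}

#' @rdname simulate_genotypes
#' @param geno 0/1 integer matrix, sequences x SNPs.
#' @param meta data frame with `sequence_id`, `individual_id`, `deme_id`.
#' @param label model id (integer) or NA.
#' @export
genotype_matrix <- function(geno, meta, label = NA_integer_) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L))) stop("genotypes must be coded 0/1")
  if (nrow(meta) != nrow(geno)) stop("meta rows must match sequences")
  structure(list(geno = geno, meta = meta, label = label),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sequences x %d SNPs, %d demes%s\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$meta$deme_id)),
              if (is.na(x$label)) "" else sprintf(" (model %d)", x$label)))
  invisible(x)
}

#' Write simulated genotypes as VCF plus a sample map
#'
#' One pseudo-contig with one record per SNP; consecutive sequence pairs of
#' an individual form its two phased alleles. A sidecar TSV maps sequences
#' to individuals, demes and the model label.
#'
#' @param g a `genotype_matrix`.
#' @param path VCF output path; the sidecar map is written next to it as
#'   `<path>.samples.tsv`.
#' @export
write_genotypes_vcf <- function(g, path) {
  ind <- split(seq_len(nrow(g$geno)), g$meta$individual_id)
  gt <- vapply(ind, function(rows) {
    if (length(rows) == 2)
      paste(g$geno[rows[1], ], g$geno[rows[2], ], sep = "|")
    else as.character(g$geno[rows[1], ])
  }, character(ncol(g$geno)))
  samples <- paste0("ind", names(ind))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=sim1>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(g$geno)), function(s)
    paste(c("sim1", s, sprintf("snp%d", s), "A", "T", ".", "PASS", ".",
            "GT", gt[s, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  map <- cbind(g$meta, model_label = g$label)
  write.table(map, paste0(path, ".samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
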