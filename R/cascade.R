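#' Cascade configuration
#'
#' Bundles the tunable parameters of the variant-prioritization cascade.
#' Defaults follow the proband analysis settings; `mode = "family"`
#' tightens the rarity threshold to 3% so that only the rarest deleterious
#' variants segregating in a family are retained.
#'
#' @param min_quality Minimum genotype quality; a variant is kept when
#'   every non-missing genotype among the samples in scope has quality at
#'   least this value (boundary inclusive).
#' @param max_pop_freq Rarity threshold as a fraction; a variant observed
#'   at a frequency greater than or equal to this value in any listed
#'   source is excluded (boundary exclusive for keeping).
#' @param freq_sources Names of the population-frequency sources consulted;
#'   must match columns of the variant set's `af` matrix.
#' @param keep_impacts Impact categories retained by the deleteriousness
#'   filter.
#' @param keep_clinical_flags Clinical evidence flags that retain a variant
#'   regardless of impact category.
#' @param gene_blacklist Symbols of hypervariable genes whose variants are
#'   removed in the final stage (empty by default; the set is an input,
#'   not package data).
#' @param max_splice_offset Splice-category variants qualify as
#'   deleterious only when their recorded intronic offset is at most this
#'   many bases (default 2).
#' @param mode `"proband"` (15% rarity) or `"family"` (3% rarity).
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(min_quality = 20,
                           max_pop_freq = if (mode == "family") 0.03 else 0.15,
                           freq_sources = c("AF_1KG", "AF_CG", "AF_ESP"),
                           keep_impacts = c("missense", "frameshift",
                                            "inframe_indel", "stop_change",
                                            "splice", "mirna_binding",
                                            "mirna_deleterious",
                                            "structural"),
                           keep_clinical_flags = c("pathogenic",
                                                   "possibly_pathogenic",
                                                   "unknown_significance",
                                                   "gof_literature",
                                                   "gene_fusion",
                                                   "inferred_activating",
                                                   "bsift_gof"),
                           gene_blacklist = character(0),
                           max_splice_offset = 2,
                           mode = c("proband", "family")) {
  mode <- match.arg(mode)
  if (!(max_pop_freq > 0 && max_pop_freq <= 1))
    stop("max_pop_freq must lie in (0, 1]")
  if (min_quality < 0) stop("min_quality must be >= 0")
  structure(list(min_quality = min_quality, max_pop_freq = max_pop_freq,
                 freq_sources = freq_sources, keep_impacts = keep_impacts,
                 keep_clinical_flags = keep_clinical_flags,
                 gene_blacklist = gene_blacklist,
                 max_splice_offset = max_splice_offset, mode = mode),
            class = "cascade_config")
}

## samples whose genotypes count for the quality / segregation rules:
## the pedigree (or cohort manifest) when given, otherwise every column.
scope_samples <- function(x, samples = NULL) {
  if (is.null(samples)) return(sample_ids(x))
  if (inherits(samples, "pedigree")) samples <- samples$sample_id
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing))
    stop("samples absent from variant set: ", paste(missing, collapse = ", "))
  samples
}

#' Quality filter
#'
#' Keeps variants whose genotype quality is at least `min_quality` in all
#' samples in scope.  Qualities of missing genotypes are ignored here;
#' missingness is penalized later by the segregation engines.
#'
#' @param x A `variant_set`.
#' @param min_quality Inclusive threshold (default 20).
#' @param samples Optional sample manifest (character vector or
#'   `pedigree`) restricting which genotype columns are evaluated.
#' @return The filtered `variant_set`.
#' @export
filter_quality <- function(x, min_quality = 20, samples = NULL) {
  sm <- scope_samples(x, samples)
  if (n_variants(x) == 0 || length(sm) == 0) return(x)
  gq <- x$gq[, sm, drop = FALSE]
  gq[is.na(x$gt[, sm, drop = FALSE])] <- NA
  ok <- apply(gq, 1, function(q) all(q[!is.na(q)] >= min_quality))
  x[ok]
}

#' Rarity filter
#'
#' Excludes a variant when its allele frequency in any of the listed
#' population sources is greater than or equal to `max_pop_freq`.
#' Variants absent from every source are kept: absence from the reference
#' panels is evidence of rarity, and truly private mutations never appear
#' in them.
#'
#' @param x A `variant_set`.
#' @param max_pop_freq Exclusion threshold as a fraction (default 0.15).
#' @param freq_sources Sources consulted; defaults to all columns of the
#'   `af` matrix.  Unknown source names are an error.
#' @return The filtered `variant_set`.
#' @export
filter_rarity <- function(x, max_pop_freq = 0.15, freq_sources = NULL) {
  if (is.null(freq_sources)) freq_sources <- colnames(x$af)
  if (n_variants(x) == 0) return(x)
  unknown <- setdiff(freq_sources, colnames(x$af))
  if (length(unknown))
    stop("unknown frequency source(s): ", paste(unknown, collapse = ", "))
  if (length(freq_sources) == 0) return(x)
  af <- x$af[, freq_sources, drop = FALSE]
  common <- apply(af, 1, function(f) any(!is.na(f) & f >= max_pop_freq))
  x[!common]
}

#' Deleteriousness filter
#'
#' Keeps a variant when its impact category is in `keep_impacts` or any of
#' its clinical flags is in `keep_clinical_flags`.  Splice-category
#' variants qualify through the impact route only when their recorded
#' intronic offset is at most `max_splice_offset` bases (an `NA` offset is
#' treated as at the exon boundary, i.e. qualifying).
#'
#' @param x A `variant_set`.
#' @param keep_impacts,keep_clinical_flags,max_splice_offset See
#'   [cascade_config()].
#' @return The filtered `variant_set`.
#' @export
filter_deleterious <- function(x,
                               keep_impacts = cascade_config()$keep_impacts,
                               keep_clinical_flags =
                                 cascade_config()$keep_clinical_flags,
                               max_splice_offset = 2) {
  if (n_variants(x) == 0) return(x)
  imp_ok <- x$info$impact %in% keep_impacts
  splice <- x$info$impact == "splice"
  off <- x$info$splice_offset
  imp_ok[splice] <- imp_ok[splice] &
    (is.na(off[splice]) | off[splice] <= max_splice_offset)
  flag_ok <- vapply(x$info$clinical_flags, function(f) {
    length(intersect(split_field(f), keep_clinical_flags)) > 0
  }, logical(1), USE.NAMES = FALSE)
  x[imp_ok | flag_ok]
}

#' Hypervariable-gene filter
#'
#' Removes variants lying in blacklisted genes (genes that recur as
#' artifacts across exome studies).  A variant annotated to several genes
#' is removed when any of them is blacklisted.
#'
#' @param x A `variant_set`.
#' @param gene_blacklist Character vector of gene symbols.
#' @return The filtered `variant_set`.
#' @export
filter_gene_blacklist <- function(x, gene_blacklist = character(0)) {
  if (n_variants(x) == 0 || length(gene_blacklist) == 0) return(x)
  hit <- vapply(x$info$genes, function(g) {
    length(intersect(split_field(g), gene_blacklist)) > 0
  }, logical(1), USE.NAMES = FALSE)
  x[!hit]
}

#' Run the full prioritization cascade
#'
#' Applies quality, rarity, deleteriousness and gene-blacklist filters in
#' order (the stages are pure predicates, so membership of the final set
#' does not depend on the order; the fixed order gives comparable
#' per-stage accounting across runs).
#'
#' @param x A `variant_set`.
#' @param config A [cascade_config()].
#' @param samples Optional sample manifest for the quality stage.
#' @return A list of class `cascade_report` with elements `stages` (data
#'   frame: stage, n_in, n_out) and `survivors` (a `variant_set`, sorted
#'   by chromosome and start).
#' @export
run_cascade <- function(x, config = cascade_config(), samples = NULL) {
  stopifnot(inherits(x, "variant_set"), inherits(config, "cascade_config"))
  stages <- list(
    quality = function(v) filter_quality(v, config$min_quality, samples),
    rarity = function(v) filter_rarity(v, config$max_pop_freq,
                                       config$freq_sources),
    deleteriousness = function(v)
      filter_deleterious(v, config$keep_impacts, config$keep_clinical_flags,
                         config$max_splice_offset),
    gene_blacklist = function(v)
      filter_gene_blacklist(v, config$gene_blacklist)
  )
  acc <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0))
  cur <- x
  for (nm in names(stages)) {
    n_in <- n_variants(cur)
    cur <- stages[[nm]](cur)
    acc <- rbind(acc, data.frame(stage = nm, n_in = n_in,
                                 n_out = n_variants(cur)))
  }
  ord <- order(cur$info$chrom, cur$info$start)
  structure(list(stages = acc, survivors = cur[ord]),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("<cascade_report>\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Tally genes recurrently hit across probands
#'
#' Counts, per gene, how many probands carry at least one surviving
#' variant in that gene, after removing any variant (matched on position
#' and alleles) that also appears in an exclusion set (e.g. the unaffected
#' members of the sequenced families).
#'
#' @param proband_sets List of `variant_set` objects, one per proband
#'   (each typically the survivors of a cascade run).
#' @param exclusion_sets List of `variant_set` objects; variants present
#'   in any of them are discarded before tallying.
#' @param min_probands Minimum number of probands a gene must be hit in.
#' @return Data frame with columns `gene` and `n_probands`, sorted by
#'   descending count.
#' @export
recurrence_tally <- function(proband_sets, exclusion_sets = list(),
                             min_probands = 2) {
  excl <- unique(unlist(lapply(exclusion_sets, function(s)
    variant_key(s$info, "position_alleles"))))
  per_gene <- lapply(proband_sets, function(s) {
    keys <- variant_key(s$info, "position_alleles")
    keep <- !keys %in% excl
    unique(unlist(lapply(s$info$genes[keep], split_field)))
  })
  counts <- table(unlist(per_gene))
  counts <- counts[counts >= min_probands]
  out <- data.frame(gene = names(counts),
                    n_probands = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_probands, out$gene), ]
  rownames(out) <- NULL
  out
}
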