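## Inheritance-model engines over a pedigree.
##
## Shared conventions:
##  * genotypes are alternate-allele copy counts from the variant set;
##  * a variant with a missing genotype in ANY pedigree member fails every
##    model (the filtering philosophy demands calls in all samples);
##  * "absent in unaffected" means genotype ref, not merely non-homozygous
##    (strictest reading; mildly affected carriers should be coded
##    affected in the pedigree, not unaffected).

seg_hit_row <- function(model, gene, variant_ids, carrier_map) {
  data.frame(model = model, gene = gene,
             variants = join_field(variant_ids),
             n_variants = length(variant_ids),
             carriers = carrier_map, stringsAsFactors = FALSE)
}

carrier_string <- function(gt_row) {
  paste(sprintf("%s=%s", names(gt_row), zygosity(gt_row)), collapse = ";")
}

empty_hits <- function() {
  structure(data.frame(model = character(0), gene = character(0),
                       variants = character(0), n_variants = integer(0),
                       carriers = character(0), stringsAsFactors = FALSE),
            class = c("segregation_hits", "data.frame"))
}

as_hits <- function(rows) {
  if (length(rows) == 0) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("segregation_hits", "data.frame")
  out
}

## genotype submatrix over the pedigree members, erroring on absentees
ped_genotypes <- function(x, ped) {
  stopifnot(inherits(x, "variant_set"), inherits(ped, "pedigree"))
  missing <- setdiff(ped$sample_id, sample_ids(x))
  if (length(missing))
    stop("pedigree member(s) absent from variant set: ",
         paste(missing, collapse = ", "))
  x$gt[, ped$sample_id, drop = FALSE]
}

first_gene <- function(genes) {
  g <- split_field(genes)
  if (length(g) == 0) NA_character_ else g[1]
}

#' Recessive segregation
#'
#' Returns variants homozygous for the alternate allele in every affected
#' member and not homozygous (het or ref) in every unaffected member.
#'
#' @param x A `variant_set` (typically cascade survivors).
#' @param ped A `pedigree` with at least one affected member.
#' @return A `segregation_hits` data frame (one row per variant) with
#'   columns `model`, `gene`, `variants`, `n_variants`, `carriers`.
#' @export
recessive_hits <- function(x, ped) {
  aff <- affected_ids(ped); una <- unaffected_ids(ped)
  if (length(aff) == 0) stop("pedigree has no affected member")
  gt <- ped_genotypes(x, ped)
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    if (anyNA(g)) next
    if (all(g[aff] == 2) && all(g[una] != 2))
      rows[[length(rows) + 1L]] <- seg_hit_row(
        "recessive", first_gene(x$info$genes[i]), x$info$id[i],
        carrier_string(g))
  }
  as_hits(rows)
}

#' Compound-heterozygous segregation
#'
#' For each gene, returns unordered variant pairs (v1, v2) where v1 is
#' heterozygous in exactly one parent and absent in the other, v2 is
#' heterozygous in the other parent and absent in the first, every
#' affected child is heterozygous for both, and no unaffected member
#' carries both.  Phase is inferred from parental origin only; the
#' operation therefore requires both parents to be genotyped.
#'
#' @param x A `variant_set`.
#' @param ped A `pedigree` in which the affected members share one father
#'   and one mother, both present in the variant set.
#' @return A `segregation_hits` data frame, one row per qualifying pair
#'   (`n_variants == 2`).
#' @export
compound_het_hits <- function(x, ped) {
  aff <- affected_ids(ped)
  if (length(aff) == 0) stop("pedigree has no affected member")
  kids <- ped[ped$sample_id %in% aff & !is.na(ped$father_id) &
                !is.na(ped$mother_id), ]
  if (nrow(kids) == 0)
    stop("no affected member has both parents in the pedigree")
  father <- unique(kids$father_id); mother <- unique(kids$mother_id)
  if (length(father) != 1 || length(mother) != 1)
    stop("affected members must share one father and one mother")
  gt <- ped_genotypes(x, ped)
  una <- unaffected_ids(ped)
  children <- kids$sample_id

  complete <- !apply(gt, 1, anyNA)
  pat <- complete & gt[, father] == 1 & gt[, mother] == 0
  mat <- complete & gt[, mother] == 1 & gt[, father] == 0

  gene_lists <- lapply(x$info$genes, split_field)
  rows <- list()
  for (i in which(pat)) {
    for (j in which(mat)) {
      if (i == j) next
      shared <- intersect(gene_lists[[i]], gene_lists[[j]])
      if (length(shared) == 0) next
      if (!all(gt[i, children] == 1) || !all(gt[j, children] == 1)) next
      both <- gt[i, una] > 0 & gt[j, una] > 0
      if (any(both)) next
      ids <- sort(c(x$info$id[i], x$info$id[j]))
      rows[[length(rows) + 1L]] <- seg_hit_row(
        "compound_het", shared[1], ids,
        paste(carrier_string(gt[i, ]), carrier_string(gt[j, ]), sep = " | "))
    }
  }
  hits <- as_hits(rows)
  hits[!duplicated(hits$variants), ]
}

#' Dominant segregation
#'
#' Returns variants carried by every affected member (heterozygous, or
#' homozygous when `allow_homozygous_affected`) and absent (genotype ref)
#' in every unaffected member.  Homozygous affected carriers arise under
#' dominant inheritance when an affected parent is homozygous; they are
#' retained by default.
#'
#' @param x A `variant_set`.
#' @param ped A `pedigree`.
#' @param allow_homozygous_affected Accept homozygous-alt genotypes in
#'   affected members (default `TRUE`).
#' @return A `segregation_hits` data frame.
#' @export
dominant_hits <- function(x, ped, allow_homozygous_affected = TRUE) {
  aff <- affected_ids(ped); una <- unaffected_ids(ped)
  gt <- ped_genotypes(x, ped)
  ok_aff <- if (allow_homozygous_affected) c(1, 2) else 1
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    if (anyNA(g)) next
    if (all(g[aff] %in% ok_aff) && all(g[una] == 0))
      rows[[length(rows) + 1L]] <- seg_hit_row(
        "dominant", first_gene(x$info$genes[i]), x$info$id[i],
        carrier_string(g))
  }
  as_hits(rows)
}

#' De novo segregation
#'
#' Returns variants absent (ref) in both parents and heterozygous in every
#' member of `required_affected` (e.g. both affected twins).
#'
#' @param x A `variant_set`.
#' @param ped A `pedigree`; the members of `required_affected` must share
#'   two genotyped, unaffected parents.
#' @param required_affected Sample ids that must all carry the variant.
#' @return A `segregation_hits` data frame.
#' @export
de_novo_hits <- function(x, ped, required_affected = affected_ids(ped)) {
  if (!all(required_affected %in% ped$sample_id))
    stop("required_affected contains samples not in the pedigree")
  rows_req <- ped[ped$sample_id %in% required_affected, ]
  parents <- unique(c(rows_req$father_id, rows_req$mother_id))
  parents <- parents[!is.na(parents)]
  if (length(parents) != 2)
    stop("required_affected members must share two pedigree parents")
  pstat <- ped$affected[match(parents, ped$sample_id)]
  if (any(is.na(pstat)) || any(pstat))
    stop("de novo model requires both parents unaffected")
  gt <- ped_genotypes(x, ped)
  rows <- list()
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    if (anyNA(g)) next
    if (all(g[parents] == 0) && all(g[required_affected] == 1))
      rows[[length(rows) + 1L]] <- seg_hit_row(
        "de_novo", first_gene(x$info$genes[i]), x$info$id[i],
        carrier_string(g))
  }
  as_hits(rows)
}

#' Homozygous-rare hits for a single proband
#'
#' Returns the homozygous-alt variants of a single-sample set, flagged by
#' whether their gene is in a supplied list of known disease genes.
#'
#' @param x A `variant_set` with exactly one sample.
#' @param known_genes Character vector of known hearing-loss gene symbols.
#' @return A `segregation_hits` data frame with an extra logical column
#'   `in_known_gene`.
#' @export
homozygous_rare_hits <- function(x, known_genes = character(0)) {
  if (ncol(x$gt) != 1)
    stop("homozygous_rare_hits expects a single-sample variant set")
  rows <- list(); known <- logical(0)
  for (i in seq_len(n_variants(x))) {
    g <- x$gt[i, ]
    if (is.na(g) || g != 2) next
    genes <- split_field(x$info$genes[i])
    rows[[length(rows) + 1L]] <- seg_hit_row(
      "homozygous", first_gene(x$info$genes[i]), x$info$id[i],
      carrier_string(x$gt[i, ]))
    known <- c(known, length(intersect(genes, known_genes)) > 0)
  }
  hits <- as_hits(rows)
  hits$in_known_gene <- known
  hits
}

#' Gene interaction networks
#'
#' An undirected network over gene symbols with a set of anchor genes
#' (e.g. genes already known to cause the phenotype).  Anchors missing
#' from the edge list are added as isolated nodes so that "distance 0 =
#' is an anchor" always holds.
#'
#' @param edges Two-column data frame (or matrix) of gene symbol pairs.
#' @param anchors Character vector of anchor gene symbols.
#' @return A list of class `gene_network` with elements `graph`
#'   (an igraph object) and `anchors`.
#' @export
gene_network <- function(edges, anchors) {
  em <- as.matrix(edges[, 1:2])
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)
  missing <- setdiff(anchors, igraph::V(g)$name)
  if (length(missing)) {
    message("anchor gene(s) absent from edge list, added as isolated: ",
            paste(missing, collapse = ", "))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  structure(list(graph = g, anchors = anchors), class = "gene_network")
}

#' Filter hits by network proximity to anchor genes
#'
#' Keeps hits whose gene lies within `max_distance` edges (shortest path)
#' of any anchor gene; distance 0 means the gene is itself an anchor.
#' Genes absent from the network are treated as infinitely distant.
#'
#' @param hits A `segregation_hits` data frame.
#' @param network A [gene_network()].
#' @param max_distance Maximum shortest-path distance (>= 0).
#' @return The filtered `segregation_hits`.
#' @export
network_proximity_filter <- function(hits, network, max_distance = 1) {
  stopifnot(inherits(network, "gene_network"), max_distance >= 0)
  if (nrow(hits) == 0) return(hits)
  nodes <- igraph::V(network$graph)$name
  dist_to_anchor <- function(gene) {
    if (!gene %in% nodes) {
      message("gene absent from network, treated as unreachable: ", gene)
      return(Inf)
    }
    d <- igraph::distances(network$graph, v = gene,
                           to = intersect(network$anchors, nodes))
    if (length(d) == 0) Inf else min(d)
  }
  d <- vapply(hits$gene, dist_to_anchor, numeric(1))
  out <- hits[!is.na(d) & d <= max_distance, ]
  rownames(out) <- NULL
  out
}
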