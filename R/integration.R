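#' Overlay CNV calls and point variants at configured loci
#'
#' Flags compound lesions: a sample carrying both a heterozygous deletion
#' overlapping a locus and at least one heterozygous point variant in a
#' gene of that locus.  This is the DFNB1 pattern, where a deletion of the
#' regulatory region of a gene on one haplotype may compound with a point
#' mutation of the gene; whether the two lesions are in cis or trans
#' cannot be resolved from call data, so phase is always reported as
#' `"unresolved"`.
#'
#' @param cnv_calls A `cnv_calls` data frame.
#' @param variants A `variant_set` (typically cascade survivors or
#'   otherwise pre-filtered variants).
#' @param loci Data frame with columns `name`, `chrom`, `start`, `end`
#'   (0-based half-open) and `genes` (comma-joined member gene symbols).
#' @return A data frame of class `compound_lesions`: `sample_id`, `locus`,
#'   `cnv`, `variants`, `n_variants`, `phase`.
#' @export
overlay_cnv_snv <- function(cnv_calls, variants, loci) {
  stopifnot(inherits(variants, "variant_set"))
  cnv_build <- attr(cnv_calls, "build") %||% "unknown"
  if (!identical(cnv_build, variants$build))
    stop(sprintf("genome builds differ: CNV calls on '%s', variants on '%s'",
                 cnv_build, variants$build))
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  loci$chrom <- norm_chrom(loci$chrom)
  out <- list()
  gene_lists <- lapply(variants$info$genes, split_field)
  for (li in seq_len(nrow(loci))) {
    members <- split_field(loci$genes[li])
    loss <- cnv_calls[cnv_calls$state == "loss" &
                        cnv_calls$chrom == loci$chrom[li] &
                        cnv_calls$start < loci$end[li] &
                        cnv_calls$end > loci$start[li], ]
    if (nrow(loss) == 0) next
    in_locus_gene <- vapply(gene_lists, function(g)
      length(intersect(g, members)) > 0, logical(1))
    for (s in unique(loss$sample_id)) {
      if (!s %in% sample_ids(variants)) next
      het <- !is.na(variants$gt[, s]) & variants$gt[, s] == 1 & in_locus_gene
      if (!any(het)) next
      dels <- loss[loss$sample_id == s, ]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, locus = loci$name[li],
        cnv = paste(sprintf("%s:%s-%s", dels$chrom,
                            format(dels$start + 1, scientific = FALSE),
                            format(dels$end, scientific = FALSE)),
                    collapse = ","),
        variants = join_field(variants$info$id[het]),
        n_variants = sum(het), phase = "unresolved",
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), locus = character(0),
               cnv = character(0), variants = character(0),
               n_variants = integer(0), phase = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("compound_lesions", "data.frame")
  res
}

#' Run the configured analysis pipeline
#'
#' Orchestrates the exome arm (read VCF(s) and pedigree, optional
#' dual-caller consensus, prioritization cascade, segregation models), the
#' CNV arm (read case/control calls, evidence-tier filter, region / gene /
#' pathway association and load test) and the compound-lesion overlay, and
#' writes every result table plus a provenance log to `out_dir`.
#' Re-running with the same configuration and seed reproduces byte-
#' identical outputs.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognized blocks:
#'   \describe{
#'     \item{out_dir}{Output directory (required).}
#'     \item{seed}{Integer seed recorded in the provenance log.}
#'     \item{family}{`vcf`, optional `vcf_b` (second caller, intersected),
#'       `ped`, `models` (subset of recessive / compound_het / dominant /
#'       de_novo), optional `mode`, `max_pop_freq`, `min_quality`,
#'       `gene_blacklist`, `required_affected`, `build`.}
#'     \item{cnv}{`cases_bed`, `controls_bed`, optional `genes_bed`,
#'       `gmt`, `n_cases`, `n_controls`, `evidence` ("both"/"any"),
#'       `state`, `max_p`, `differential_threshold`, `flank`, `build`.}
#'     \item{overlay}{`loci`: data frame or list of locus blocks with
#'       `name`, `chrom`, `start`, `end`, `genes`.}
#'   }
#' @return Invisibly, a list with the in-memory results and the paths of
#'   the written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  missing_keys <- setdiff("out_dir", names(config))
  if (is.null(config[["family"]]) && is.null(config[["cnv"]]))
    missing_keys <- c(missing_keys, "family|cnv (at least one arm)")
  if (length(missing_keys))
    stop("pipeline config is missing: ", paste(missing_keys, collapse = ", "))
  out_dir <- config[["out_dir"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config[["seed"]] %||% 1L
  paths <- character(0)
  results <- list()
  write_tsv <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }

  if (!is.null(config[["family"]])) {
    fc <- config[["family"]]
    build <- fc[["build"]] %||% "unknown"
    vs <- read_variants(fc[["vcf"]], caller_label = fc[["caller"]] %||% "A",
                        build = build)
    if (!is.null(fc[["vcf_b"]])) {
      vs_b <- read_variants(fc[["vcf_b"]], caller_label = "B", build = build)
      vs <- intersect_callsets(vs, vs_b)
    }
    ped <- read_pedigree(fc[["ped"]])
    cfg <- cascade_config(
      min_quality = fc[["min_quality"]] %||% 20,
      max_pop_freq = fc[["max_pop_freq"]] %||% 0.03,
      gene_blacklist = fc[["gene_blacklist"]] %||% character(0),
      mode = fc[["mode"]] %||% "family")
    rep <- run_cascade(vs, cfg, samples = ped)
    write_tsv(rep$stages, "cascade_report.tsv")
    p <- file.path(out_dir, "survivors.vcf")
    write_variants(rep$survivors, p)
    paths[["survivors.vcf"]] <- p
    hits <- lapply(fc[["models"]] %||% "recessive", function(m) {
      switch(m,
             recessive = recessive_hits(rep$survivors, ped),
             compound_het = compound_het_hits(rep$survivors, ped),
             dominant = dominant_hits(rep$survivors, ped),
             de_novo = de_novo_hits(
               rep$survivors, ped,
               fc[["required_affected"]] %||% affected_ids(ped)),
             stop("unknown segregation model: ", m))
    })
    hits <- do.call(rbind, hits)
    write_tsv(hits, "segregation_hits.tsv")
    results$cascade <- rep
    results$hits <- hits
    results$pedigree <- ped
  }

  if (!is.null(config[["cnv"]])) {
    cc <- config[["cnv"]]
    build <- cc[["build"]] %||% "unknown"
    cases <- read_cnv_calls(cc[["cases_bed"]], group = "case", build = build)
    controls <- read_cnv_calls(cc[["controls_bed"]], group = "control",
                               build = build)
    tier <- cc[["evidence"]] %||% "any"
    cases_t <- cnv_evidence_filter(cases, tier)
    controls_t <- cnv_evidence_filter(controls, tier)
    n_cases <- cc[["n_cases"]] %||% length(unique(cases$sample_id))
    n_controls <- cc[["n_controls"]] %||% length(unique(controls$sample_id))
    reg <- region_association(
      cases_t, controls_t, state = cc[["state"]] %||% "loss",
      n_cases = n_cases, n_controls = n_controls,
      max_p = cc[["max_p"]] %||% 0.05,
      differential_threshold = cc[["differential_threshold"]] %||% 0)
    write_tsv(reg, "region_assoc.tsv")
    results$region <- reg
    all_calls <- rbind(cases_t, controls_t)
    attr(all_calls, "build") <- build
    if (!is.null(cc[["genes_bed"]])) {
      gm <- read_gene_models(cc[["genes_bed"]], build = build)
      ga <- gene_association(all_calls, gm, flank = cc[["flank"]] %||% 10000,
                             n_cases = n_cases, n_controls = n_controls)
      write_tsv(ga, "gene_assoc.tsv")
      results$gene <- ga
      if (!is.null(cc[["gmt"]])) {
        pa <- pathway_association(all_calls, gm, read_gene_sets(cc[["gmt"]]),
                                  flank = cc[["flank"]] %||% 10000,
                                  n_cases = n_cases,
                                  n_controls = n_controls)
        write_tsv(pa, "pathway_assoc.tsv")
        results$pathway <- pa
      }
    }
    load_rep <- cnv_load_test(cases_t, controls_t)
    write_tsv(load_rep$per_sample, "cnv_load.tsv")
    results$load <- load_rep
    results$cnv_calls <- all_calls
  }

  if (!is.null(config$overlay)) {
    if (is.null(results$cascade) || is.null(results$cnv_calls))
      stop("overlay requires both the family and cnv arms")
    loci <- config[["overlay"]][["loci"]]
    if (!is.data.frame(loci))
      loci <- do.call(rbind, lapply(loci, function(l)
        data.frame(name = l$name, chrom = l$chrom, start = l$start,
                   end = l$end,
                   genes = paste(unlist(l$genes), collapse = ","),
                   stringsAsFactors = FALSE)))
    lesions <- overlay_cnv_snv(results$cnv_calls,
                               results$cascade$survivors, loci)
    write_tsv(lesions, "lesions.tsv")
    results$lesions <- lesions
  }

  prov <- list(
    seed = seed,
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = as.list(tools::md5sum(unlist(paths))))
  names(prov$outputs) <- basename(names(prov$outputs))
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["provenance.json"]] <- prov_path
  invisible(c(results, list(paths = paths)))
}
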