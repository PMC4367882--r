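## Synthetic-data generators.
##
## These emulate the statistical structure the analysis assumes — Mendelian
## transmission in small pedigrees with a planted causal variant, a
## case-control CNV cohort with one differentially carried deletion over a
## Poisson background, and Gaussian probe-noise LRR tracks — so that every
## stage of the pipeline can be exercised and scored without any external
## data.  Every generator is a pure function of (parameters, seed).

# approximate autosome lengths (bp) used to place background CNVs
autosome_lengths <- function() {
  stats::setNames(
    c(247e6, 243e6, 199e6, 191e6, 181e6, 171e6, 159e6, 146e6, 140e6,
      135e6, 134e6, 132e6, 114e6, 106e6, 100e6, 89e6, 79e6, 76e6, 63e6,
      62e6, 47e6, 50e6),
    paste0("chr", 1:22))
}

sim_pedigree_for_model <- function(model) {
  switch(model,
    recessive = ,
    compound_het = pedigree(data.frame(
      sample_id = c("FA", "MO", "C1", "C2", "C3"),
      father_id = c(NA, NA, "FA", "FA", "FA"),
      mother_id = c(NA, NA, "MO", "MO", "MO"),
      sex = c("male", "female", "male", "male", "female"),
      affected = c(FALSE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)),
    dominant = pedigree(data.frame(
      sample_id = c("FA", "MO", "C1", "C2"),
      father_id = c(NA, NA, "FA", "FA"),
      mother_id = c(NA, NA, "MO", "MO"),
      sex = c("male", "female", "male", "male"),
      affected = c(FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE)),
    de_novo = pedigree(data.frame(
      sample_id = c("FA", "MO", "T1", "T2"),
      father_id = c(NA, NA, "FA", "FA"),
      mother_id = c(NA, NA, "MO", "MO"),
      sex = c("male", "female", "female", "female"),
      affected = c(FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)),
    stop("invalid model: ", model))
}

## genotype vectors (FA, MO, children...) satisfying each model exactly
planted_genotypes <- function(model, ped) {
  switch(model,
    recessive = list(stats::setNames(c(1L, 1L, 2L, 2L, 2L), ped$sample_id)),
    compound_het = list(
      stats::setNames(c(1L, 0L, 1L, 1L, 1L), ped$sample_id),
      stats::setNames(c(0L, 1L, 1L, 1L, 1L), ped$sample_id)),
    dominant = list(stats::setNames(c(0L, 1L, 1L, 1L), ped$sample_id)),
    de_novo = list(stats::setNames(c(0L, 0L, 1L, 1L), ped$sample_id)))
}

#' Simulate a pedigree VCF with a planted causal variant
#'
#' Builds a 4-5-member pedigree, plants causal genotypes that satisfy the
#' requested inheritance model exactly (e.g. compound het: one variant
#' heterozygous in the father, the other in the mother, all affected
#' children heterozygous for both), and adds background variants whose
#' parental genotypes are drawn at a sampled population allele frequency
#' and transmitted to the children by Mendelian sampling.  Annotations
#' (population frequencies, impact categories, genotype qualities) are
#' drawn from mixtures chosen so that each cascade stage rejects a
#' non-trivial fraction of the background.
#'
#' @param model `"recessive"`, `"compound_het"`, `"dominant"` or
#'   `"de_novo"`.
#' @param n_background Number of background variants (default 300).
#' @param af_spectrum Function `n -> n` allele frequencies in \[0, 1\]
#'   (default `rbeta(n, 0.4, 2)`: most variants rare, some common).
#' @param quality_dist Function `n -> n` genotype qualities (default
#'   `N(35, 8)` truncated at 0, so a tail of calls fails the quality 20
#'   cut).
#' @param seed Integer seed; identical seeds give identical output.
#' @param dir If non-`NULL`, write `sim.vcf`, `sim.ped` and
#'   `manifest.json` into this directory.
#' @return List with `variants` (a `variant_set`), `pedigree`, `manifest`
#'   (planted truth: ids, gene, model, seed) and, when written, `paths`.
#' @export
simulate_pedigree_vcf <- function(model = c("recessive", "compound_het",
                                            "dominant", "de_novo"),
                                  n_background = 300,
                                  af_spectrum = function(n) stats::rbeta(n, 0.4, 2),
                                  quality_dist = function(n)
                                    pmax(0, round(stats::rnorm(n, 35, 8), 1)),
                                  seed = 1, dir = NULL) {
  model <- match.arg(model)
  ped <- sim_pedigree_for_model(model)
  with_seed(seed, {
    n_s <- nrow(ped)
    planted <- planted_genotypes(model, ped)
    n_pl <- length(planted)
    n <- n_background + n_pl

    chrom_pool <- names(autosome_lengths())
    chrom <- sample(chrom_pool, n, replace = TRUE,
                    prob = autosome_lengths() / sum(autosome_lengths()))
    pos <- floor(stats::runif(n, 1, autosome_lengths()[chrom] - 10))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

    impact_pool <- c("missense", "synonymous", "intronic", "utr",
                     "frameshift", "splice", "stop_change", "other")
    impact_prob <- c(0.15, 0.25, 0.22, 0.15, 0.04, 0.06, 0.03, 0.10)
    impact <- sample(impact_pool, n, replace = TRUE, prob = impact_prob)
    splice_offset <- ifelse(impact == "splice",
                            sample(1:8, n, replace = TRUE), NA_real_)
    gene_pool <- sprintf("BG%03d", 1:120)
    genes <- sample(gene_pool, n, replace = TRUE)

    af_true <- af_spectrum(n)
    sources <- c("AF_1KG", "AF_CG", "AF_ESP")
    af <- matrix(NA_real_, n, 3, dimnames = list(NULL, sources))
    for (j in 1:3) {
      observed <- stats::runif(n) < 0.85
      af[observed, j] <- round(af_true[observed], 6)
    }

    gt <- matrix(NA_integer_, n, n_s,
                 dimnames = list(NULL, ped$sample_id))
    founders <- ped$sample_id[is.na(ped$father_id)]
    kids <- ped[!is.na(ped$father_id), ]
    for (i in seq_len(n)) {
      gt[i, founders] <- stats::rbinom(length(founders), 2, af_true[i])
      for (k in seq_len(nrow(kids))) {
        pa <- stats::rbinom(1, 1, gt[i, kids$father_id[k]] / 2)
        ma <- stats::rbinom(1, 1, gt[i, kids$mother_id[k]] / 2)
        gt[i, kids$sample_id[k]] <- pa + ma
      }
    }
    gq <- matrix(quality_dist(n * n_s), n, n_s,
                 dimnames = list(NULL, ped$sample_id))

    # planted causal variant(s): rare, damaging, confidently called
    idx <- seq_len(n_pl)
    causal_gene <- "CAUSAL"
    for (k in idx) {
      chrom[k] <- "chr20"
      pos[k] <- 33e6 + k * 5e4
      impact[k] <- "missense"
      splice_offset[k] <- NA_real_
      genes[k] <- causal_gene
      af[k, ] <- NA_real_
      gt[k, ] <- planted[[k]][ped$sample_id]
      gq[k, ] <- round(stats::runif(n_s, 40, 60), 1)
    }

    info <- data.frame(chrom = chrom, start = pos - 1,
                       end = pos - 1 + nchar(ref), ref = ref, alt = alt,
                       impact = impact, splice_offset = splice_offset,
                       genes = genes, clinical_flags = "",
                       caller = "simulated", stringsAsFactors = FALSE)
    vs <- variant_set(info, gt, gq, af, build = "hg19")
    ord <- order(vs$info$chrom, vs$info$start, vs$info$id)
    planted_ids <- vs$info$id[idx]
    vs <- vs[ord]

    manifest <- list(seed = seed, model = model,
                     planted_ids = planted_ids,
                     planted_gene = causal_gene,
                     n_background = n_background,
                     samples = ped$sample_id)
    out <- list(variants = vs, pedigree = ped, manifest = manifest)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$paths <- c(vcf = write_variants(vs, file.path(dir, "sim.vcf")),
                     ped = write_pedigree(ped, file.path(dir, "sim.ped")),
                     manifest = {
                       p <- file.path(dir, "manifest.json")
                       jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                            digits = NA)
                       p
                     })
    }
    out
  })
}

#' Simulate a case-control CNV cohort with a planted associated deletion
#'
#' Each sample independently carries the planted deletion with its group's
#' probability; carrier intervals are jittered outwards around the planted
#' region, with the jitter re-anchored so that the smallest region of
#' overlap of the carriers equals the planted region exactly.  Background
#' calls per sample are Poisson, placed uniformly over the autosomes with
#' log-normal sizes (median 10 kb) and random loss/gain states.  Planted
#' carrier deletions are emitted under both algorithm labels; background
#' calls receive one algorithm at random and are duplicated under the
#' other with probability 1/2.
#'
#' @param n_cases,n_controls Cohort sizes (defaults 149 / 157, the
#'   analyzed-cohort denominators).
#' @param planted_region A [genomic_interval()]; default is the chr16
#'   deletion region of the shipped fixture.
#' @param p_case,p_control Carrier probabilities (defaults 23/149 and
#'   7/157).
#' @param background_rate Mean background calls per sample (default 1).
#' @param size_meanlog,size_sdlog Log-normal size parameters for
#'   background calls (default median 10 kb).
#' @param seed Integer seed.
#' @param dir If non-`NULL`, write `cases.bed`, `controls.bed` and
#'   `manifest.json` there.
#' @return List with `case_calls`, `control_calls` (class `cnv_calls`),
#'   `manifest` and, when written, `paths`.
#' @export
simulate_cnv_cohort <- function(n_cases = 149, n_controls = 157,
                                planted_region =
                                  interval_from_printed("chr16", 14956245,
                                                        15028783, "hg18"),
                                p_case = 23 / 149, p_control = 7 / 157,
                                background_rate = 1,
                                size_meanlog = log(1e4), size_sdlog = 1,
                                seed = 1, dir = NULL) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1)
  with_seed(seed, {
    lens <- autosome_lengths()
    one_group <- function(n, p, group) {
      samples <- sprintf("%s%03d", group, seq_len(n))
      carrier <- stats::runif(n) < p
      rows <- list()
      if (any(carrier)) {
        idx <- which(carrier)
        jl <- floor(stats::rexp(length(idx), 1 / 5000))
        jr <- floor(stats::rexp(length(idx), 1 / 5000))
        jl <- jl - min(jl); jr <- jr - min(jr)   # anchor the SRO bounds
        for (k in seq_along(idx)) {
          for (alg in c("A", "B"))
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = planted_region$chrom,
              start = planted_region$start - jl[k],
              end = planted_region$end + jr[k],
              sample_id = samples[idx[k]], state = "loss",
              algorithm = alg, stringsAsFactors = FALSE)
        }
      }
      n_bg <- stats::rpois(n, background_rate)
      for (s in which(n_bg > 0)) {
        for (b in seq_len(n_bg[s])) {
          chrom <- sample(names(lens), 1, prob = lens / sum(lens))
          size <- max(1000, round(stats::rlnorm(1, size_meanlog, size_sdlog)))
          start <- floor(stats::runif(1, 0, lens[chrom] - size))
          algs <- if (stats::runif(1) < 0.5) c("A", "B") else
            sample(c("A", "B"), 1)
          state <- sample(c("loss", "gain"), 1)
          for (alg in algs)
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, start = start, end = start + size,
              sample_id = samples[s], state = state, algorithm = alg,
              stringsAsFactors = FALSE)
        }
      }
      calls <- if (length(rows)) do.call(rbind, rows) else
        data.frame(chrom = character(0), start = numeric(0),
                   end = numeric(0), sample_id = character(0),
                   state = character(0), algorithm = character(0),
                   stringsAsFactors = FALSE)
      calls$group <- rep(if (group == "case") "case" else "control",
                         nrow(calls))
      attr(calls, "build") <- planted_region$build
      class(calls) <- c("cnv_calls", "data.frame")
      list(calls = calls, samples = samples,
           carriers = samples[carrier])
    }
    cases <- one_group(n_cases, p_case, "case")
    controls <- one_group(n_controls, p_control, "control")
    manifest <- list(
      seed = seed,
      planted_region = list(chrom = planted_region$chrom,
                            start = planted_region$start,
                            end = planted_region$end,
                            build = planted_region$build),
      p_case = p_case, p_control = p_control,
      background_rate = background_rate,
      case_samples = cases$samples, control_samples = controls$samples,
      case_carriers = cases$carriers, control_carriers = controls$carriers)
    out <- list(case_calls = cases$calls, control_calls = controls$calls,
                manifest = manifest)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$paths <- c(
        cases = write_cnv_calls(cases$calls, file.path(dir, "cases.bed")),
        controls = write_cnv_calls(controls$calls,
                                   file.path(dir, "controls.bed")),
        manifest = {
          p <- file.path(dir, "manifest.json")
          jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
          p
        })
    }
    out
  })
}

#' Simulate a log-R-ratio probe track
#'
#' Gaussian probe noise around zero with optional embedded mean-shift
#' segments (negative shifts for losses, positive for gains) on a single
#' chromosome with evenly spaced, strictly increasing probe positions.
#'
#' @param n_probes Number of probes (>= 2).
#' @param noise_sd Probe noise standard deviation.
#' @param segments Optional data frame with columns `first_probe`,
#'   `last_probe` (1-based probe indices, inclusive) and `shift`.
#' @param chrom Chromosome label.
#' @param spacing Probe spacing in bp.
#' @param seed Integer seed.
#' @return An [lrr_track()].
#' @export
simulate_lrr_track <- function(n_probes, noise_sd = 0.1, segments = NULL,
                               chrom = "chr1", spacing = 1000, seed = 1) {
  stopifnot(n_probes >= 2)
  with_seed(seed, {
    lrr <- stats::rnorm(n_probes, 0, noise_sd)
    if (!is.null(segments)) {
      for (i in seq_len(nrow(segments))) {
        r <- segments$first_probe[i]:segments$last_probe[i]
        lrr[r] <- lrr[r] + segments$shift[i]
      }
    }
    lrr_track(data.frame(chrom = chrom,
                         pos = spacing * seq_len(n_probes), lrr = lrr))
  })
}
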