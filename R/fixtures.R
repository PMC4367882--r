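#' Desk-scale worked-example fixtures
#'
#' Builds, purely from numbers printed in the published record of the
#' study this pipeline reanalyzes, the small fixtures used as worked
#' examples and regression anchors:
#'
#' * `table3` — the 14 candidate variants of the dominant family (mother
#'   and two affected sons genotyped as printed; unaffected father
#'   reference) plus 6 synthetic decoy variants that violate dominant
#'   segregation (ids prefixed `SYN_DECOY_`; the published table shows
#'   only the survivors, so the rejected candidates must be synthesized).
#'   Genotype qualities are synthetic constants above the quality cut.
#' * `family1` — the compound-heterozygous family: two heterozygous
#'   missense variants in *MYH7B*, one paternal, one maternal, all three
#'   affected children heterozygous for both, plus 3 synthetic decoys
#'   that do not segregate.  Variant positions within *MYH7B* are
#'   synthetic placeholders (the published record gives protein-level
#'   coordinates only).
#' * `chr16` — the case-control deletion cohort at the chr16 region
#'   (printed bounds 14,956,245-15,028,783, hg18): 23 case and 7 control
#'   carriers called by both algorithms, plus 17 case and 8 control
#'   carriers called by a single algorithm (40 / 15 under the "any"
#'   tier), over analyzed denominators of 149 cases and 157 controls.
#'   Interval jitter around the printed bounds is synthetic, anchored so
#'   the smallest region of overlap reproduces the printed bounds.
#' * `strc` — the printed smallest region of overlap of the *STRC*
#'   deletions, chr15:41,639,153-41,709,787 (hg18).
#'
#' @param dir If non-`NULL`, also write `table3.vcf/.ped`,
#'   `family1.vcf/.ped`, `chr16_cases.bed`, `chr16_controls.bed` there.
#' @return A named list with elements `table3` (variants, pedigree),
#'   `family1` (variants, pedigree), `chr16` (case_calls, control_calls,
#'   region, n_cases, n_controls) and `strc` (a `genomic_interval`).
#' @export
snhl_fixtures <- function(dir = NULL) {
  table3 <- table3_fixture()
  family1 <- family1_fixture()
  chr16 <- chr16_fixture()
  strc <- interval_from_printed("chr15", 41639153, 41709787, build = "hg18")
  out <- list(table3 = table3, family1 = family1, chr16 = chr16,
              strc = strc)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_variants(table3$variants, file.path(dir, "table3.vcf"))
    write_pedigree(table3$pedigree, file.path(dir, "table3.ped"), "F3")
    write_variants(family1$variants, file.path(dir, "family1.vcf"))
    write_pedigree(family1$pedigree, file.path(dir, "family1.ped"), "F1")
    write_cnv_calls(chr16$case_calls, file.path(dir, "chr16_cases.bed"))
    write_cnv_calls(chr16$control_calls,
                    file.path(dir, "chr16_controls.bed"))
  }
  out
}

table3_fixture <- function() {
  ped <- pedigree(data.frame(
    sample_id = c("F3.1", "F3.2", "F3.3", "F3.4"),
    father_id = c(NA, NA, "F3.1", "F3.1"),
    mother_id = c(NA, NA, "F3.2", "F3.2"),
    sex = c("male", "female", "male", "male"),
    affected = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))

  # chrom, 1-based position (hg19), ref, alt, gene(s), impact,
  # genotypes mother / son1 / son2 (father reference), 1000G freq (%)
  printed <- list(
    list("chr1", 908929, "C", "T", "PLEKHN1", "missense", 1, 1, 1, 0.27),
    list("chr1", 3440753, "G", "A", "MEGF6", "missense", 1, 1, 1, 0.51),
    list("chr1", 15546259, "G", "A", "TMEM51", "utr", 1, 1, 1, NA),
    list("chr1", 68649258, "C", "T", "WLS,mir-1262", "mirna_deleterious",
         1, 1, 1, 0.65),
    list("chr1", 234742618, "G", "A", "IRF2BP2", "utr", 1, 1, 1, 0.33),
    list("chr1", 245772651, "C", "G", "KIF26B", "missense", 2, 1, 1, 2.52),
    list("chr2", 68546588, "C", "A", "CNRIP1", "utr", 1, 1, 1, 2.35),
    list("chr2", 86439256, "A", "T", "MRPL35", "intronic", 1, 1, 1, 0.14),
    list("chr2", 97531651, "G", "A", "SEMA4C", "missense", 1, 1, 1, NA),
    list("chr2", 99978074, "A", "T", "EIF5B", "missense", 1, 1, 1, NA),
    list("chr2", 109087823, "AAA", "A", "GCC2", "inframe_indel",
         1, 1, 1, NA),
    list("chr2", 111875388, "C", "T", "ACOXL", "missense", 2, 1, 1, 0.72),
    list("chr2", 233630577, "G", "A", "GIGYF2,KCNJ13", "utr", 1, 1, 1,
         0.65),
    list("chr2", 242742842, "A", "G", "GAL3ST2", "missense", 1, 1, 1,
         0.05))

  # synthetic decoys violating dominant segregation (not printed data)
  decoys <- list(
    # carried by the unaffected father
    list("chr3", 1000001, "A", "G", "SYNGENE1", "missense", 1, 1, 1, NA,
         1L),
    list("chr3", 2000001, "C", "T", "SYNGENE2", "missense", 1, 1, 1, NA,
         2L),
    # absent in one affected member
    list("chr4", 1000001, "G", "A", "SYNGENE3", "missense", 0, 1, 1, NA,
         0L),
    list("chr4", 2000001, "T", "C", "SYNGENE4", "missense", 1, 1, 0, NA,
         0L),
    # missing call in one affected member
    list("chr5", 1000001, "A", "C", "SYNGENE5", "missense", 1, NA, 1, NA,
         0L),
    # carried by nobody
    list("chr5", 2000001, "G", "T", "SYNGENE6", "missense", 0, 0, 0, NA,
         0L))

  rows <- c(printed, decoys)
  info <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(
      id = if (i <= length(printed)) sprintf("T3_%02d", i) else
        sprintf("SYN_DECOY_%d", i - length(printed)),
      chrom = r[[1]], start = r[[2]] - 1,
      end = r[[2]] - 1 + nchar(r[[3]]), ref = r[[3]], alt = r[[4]],
      impact = r[[6]], splice_offset = NA_real_, genes = r[[5]],
      clinical_flags = "", caller = "consensus", stringsAsFactors = FALSE)
  }))
  gt <- t(vapply(rows, function(r) {
    father <- if (length(r) >= 11) r[[11]] else 0L
    as.integer(c(father, r[[7]], r[[8]], r[[9]]))
  }, integer(4)))
  colnames(gt) <- ped$sample_id
  gq <- matrix(45, nrow(gt), 4, dimnames = list(NULL, ped$sample_id))
  af <- matrix(NA_real_, nrow(gt), 3,
               dimnames = list(NULL, c("AF_1KG", "AF_CG", "AF_ESP")))
  af[, "AF_1KG"] <- vapply(rows, function(r)
    if (is.na(r[[10]])) NA_real_ else r[[10]] / 100, numeric(1))
  list(variants = variant_set(info, gt, gq, af, build = "hg19"),
       pedigree = ped)
}

family1_fixture <- function() {
  ped <- pedigree(data.frame(
    sample_id = c("F1.1", "F1.2", "F1.3", "F1.4", "F1.5"),
    father_id = c(NA, NA, "F1.1", "F1.1", "F1.1"),
    mother_id = c(NA, NA, "F1.2", "F1.2", "F1.2"),
    sex = c("male", "female", "male", "male", "female"),
    affected = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))
  # father, mother, three affected children
  rows <- list(
    # paternal MYH7B missense (position within gene synthetic)
    list("MYH7B_v1_paternal", "chr20", 33581000, "G", "A", "MYH7B",
         c(1, 0, 1, 1, 1), c(NA, NA, NA)),
    # maternal MYH7B missense; printed population frequencies 0.05%/0.01%
    list("MYH7B_v2_maternal", "chr20", 33574000, "G", "A", "MYH7B",
         c(0, 1, 1, 1, 1), c(0.0005, NA, 0.0001)),
    # synthetic decoys that do not segregate
    list("SYN_DECOY_1", "chr5", 1000001, "A", "G", "SYNGENE1",
         c(1, 0, 1, 0, 0), c(NA, NA, NA)),
    list("SYN_DECOY_2", "chr7", 1000001, "C", "T", "SYNGENE2",
         c(0, 1, 0, 1, 1), c(NA, NA, NA)),
    list("SYN_DECOY_3", "chr11", 1000001, "G", "A", "SYNGENE3",
         c(0, 1, 0, 0, 0), c(NA, NA, NA)))
  info <- do.call(rbind, lapply(rows, function(r) data.frame(
    id = r[[1]], chrom = r[[2]], start = r[[3]] - 1, end = r[[3]],
    ref = r[[4]], alt = r[[5]], impact = "missense",
    splice_offset = NA_real_, genes = r[[6]], clinical_flags = "",
    caller = "consensus", stringsAsFactors = FALSE)))
  gt <- t(vapply(rows, function(r) as.integer(r[[7]]), integer(5)))
  colnames(gt) <- ped$sample_id
  gq <- matrix(50, nrow(gt), 5, dimnames = list(NULL, ped$sample_id))
  af <- t(vapply(rows, function(r) r[[8]], numeric(3)))
  colnames(af) <- c("AF_1KG", "AF_CG", "AF_ESP")
  list(variants = variant_set(info, gt, gq, af, build = "hg19"),
       pedigree = ped)
}

chr16_fixture <- function() {
  region <- interval_from_printed("chr16", 14956245, 15028783,
                                  build = "hg18")
  # deterministic synthetic jitter; offsets include 0 on each side so the
  # carriers' smallest region of overlap equals the printed bounds
  jitter <- function(k) {
    c(left = ((k * 37) %% 7) * 3000, right = ((k * 53) %% 5) * 4000)
  }
  carrier_rows <- function(samples, algs, group) {
    do.call(rbind, lapply(seq_along(samples), function(k) {
      j <- jitter(k)
      do.call(rbind, lapply(algs, function(alg) data.frame(
        chrom = region$chrom, start = region$start - j["left"],
        end = region$end + j["right"], sample_id = samples[k],
        state = "loss", algorithm = alg, group = group,
        stringsAsFactors = FALSE)))
    }))
  }
  cases <- rbind(
    carrier_rows(sprintf("case%03d", 1:23), c("A", "B"), "case"),
    carrier_rows(sprintf("case%03d", 24:40), "A", "case"))
  controls <- rbind(
    carrier_rows(sprintf("control%03d", 1:7), c("A", "B"), "control"),
    carrier_rows(sprintf("control%03d", 8:15), "A", "control"))
  # a little off-target background so state/region filters are exercised
  bg <- function(sample, group, start, state) data.frame(
    chrom = "chr16", start = start, end = start + 20000,
    sample_id = sample, state = state, algorithm = "A", group = group,
    stringsAsFactors = FALSE)
  cases <- rbind(cases, bg("case050", "case", 60e6, "gain"),
                 bg("case051", "case", 70e6, "loss"))
  controls <- rbind(controls, bg("control050", "control", 60e6, "gain"))
  finish <- function(d) {
    rownames(d) <- NULL
    attr(d, "build") <- "hg18"
    class(d) <- c("cnv_calls", "data.frame")
    d
  }
  list(case_calls = finish(cases), control_calls = finish(controls),
       region = region, n_cases = 149, n_controls = 157)
}
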