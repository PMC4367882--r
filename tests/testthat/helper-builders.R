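# Shared in-code fixture builders.

# quick variant_set from a genotype matrix (variants x samples)
make_vs <- function(gt, genes = sprintf("G%d", seq_len(nrow(gt))),
                    impact = "missense", gq = 30, af = NULL,
                    chrom = "chr1", splice_offset = NA_real_,
                    clinical_flags = "", build = "unknown") {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  info <- data.frame(
    chrom = rep_len(chrom, n), start = seq_len(n) * 100,
    end = seq_len(n) * 100 + 1, ref = "A", alt = "G",
    impact = rep_len(impact, n),
    splice_offset = rep_len(splice_offset, n),
    genes = rep_len(genes, n),
    clinical_flags = rep_len(clinical_flags, n),
    stringsAsFactors = FALSE)
  if (is.matrix(gq)) gqm <- gq else
    gqm <- matrix(gq, n, ncol(gt), dimnames = dimnames(gt))
  variant_set(info, gt, gqm, af, build = build)
}

# two unaffected parents, three affected children
quintet_ped <- function() {
  pedigree(data.frame(
    sample_id = c("FA", "MO", "C1", "C2", "C3"),
    father_id = c(NA, NA, "FA", "FA", "FA"),
    mother_id = c(NA, NA, "MO", "MO", "MO"),
    sex = c("male", "female", "male", "male", "female"),
    affected = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

# unaffected parents, two affected twins
quartet_ped <- function() {
  pedigree(data.frame(
    sample_id = c("FA", "MO", "T1", "T2"),
    father_id = c(NA, NA, "FA", "FA"),
    mother_id = c(NA, NA, "MO", "MO"),
    sex = c("male", "female", "female", "female"),
    affected = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

make_calls <- function(df, group = "case", build = "unknown") {
  df$sample_id <- as.character(df$sample_id)
  if (is.null(df$state)) df$state <- "loss"
  if (is.null(df$algorithm)) df$algorithm <- "A"
  df$group <- group
  attr(df, "build") <- build
  class(df) <- c("cnv_calls", "data.frame")
  df
}

# independent Fisher enumeration oracle (combinatorial route, not dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1), numeric(1))
  obs <- probs[ks == a]
  sum(probs[probs <= obs * (1 + 1e-9)])
}
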