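#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed
#' table (with relative tolerance 1e-9 on the comparison, so that ties in
#' probability are counted into the tail).
#'
#' @param a,b,c,d Non-negative integer cells: `a`/`b` case carriers and
#'   non-carriers, `c`/`d` control carriers and non-carriers.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 + r2 == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a d) / (b c)` with the logit-scale interval
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any single
#' cell is zero, 0.5 is added to all four cells (Haldane-Anscombe) and the
#' result is flagged; when both cells of a diagonal are zero the odds
#' ratio is undefined and an error is raised.
#'
#' @inheritParams fisher_exact_two_sided
#' @return A list with `or`, `ci_low`, `ci_high` and logical `haldane`.
#' @examples
#' odds_ratio(23, 126, 7, 150)$or  # 3.91 to 2 dp
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if ((a == 0 && d == 0) || (b == 0 && c == 0))
    stop("odds ratio undefined: both cells of a diagonal are zero")
  haldane <- any(cells == 0)
  if (haldane) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci_low = or * exp(-1.959964 * se),
       ci_high = or * exp(1.959964 * se), haldane = haldane)
}

## assemble one association row and, at the end, BH-correct a batch
assoc_row <- function(unit, a, n_cases, c, n_controls) {
  b <- n_cases - a; d <- n_controls - c
  orr <- tryCatch(odds_ratio(a, b, c, d),
                  error = function(e) list(or = NA_real_, ci_low = NA_real_,
                                           ci_high = NA_real_))
  data.frame(unit = unit, a = a, b = b, c = c, d = d,
             case_freq = a / n_cases, control_freq = c / n_controls,
             p = fisher_exact_two_sided(a, b, c, d),
             or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
             stringsAsFactors = FALSE)
}

finish_assoc <- function(rows) {
  if (length(rows) == 0)
    return(data.frame(unit = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      case_freq = numeric(0), control_freq = numeric(0),
                      p = numeric(0), q = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("unit", "a", "b", "c", "d", "case_freq", "control_freq",
                 "p", "q", "or", "ci_low", "ci_high")]
  out <- out[order(out$p, out$unit), ]
  rownames(out) <- NULL
  out
}

#' Smallest region of overlap (SRO)
#'
#' The maximal interval contained in every one of a set of pairwise
#' overlapping CNV calls on one chromosome: `[max(starts), min(ends))`.
#'
#' @param calls A `cnv_calls` data frame (or any data frame with `chrom`,
#'   `start`, `end`, and optionally `state` columns); all calls must be on
#'   one chromosome and of one state.
#' @return A [genomic_interval()].
#' @export
smallest_region_of_overlap <- function(calls) {
  if (nrow(calls) == 0) stop("no calls supplied")
  if (length(unique(calls$chrom)) != 1)
    stop("calls span several chromosomes")
  if (!is.null(calls$state) && length(unique(calls$state)) != 1)
    stop("calls mix copy-number states")
  s <- max(calls$start); e <- min(calls$end)
  if (e <= s) {
    ## identify a disjoint pair for the diagnostic
    i <- which.max(calls$start); j <- which.min(calls$end)
    stop(sprintf(
      "calls do not all overlap: e.g. records %d [%d,%d) and %d [%d,%d)",
      i, calls$start[i], calls$end[i], j, calls$start[j], calls$end[j]))
  }
  genomic_interval(calls$chrom[1], s, e,
                   build = attr(calls, "build") %||% "unknown")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Filter CNV calls by dual-algorithm evidence tier
#'
#' `"both"` keeps, per sample, the calls of the first algorithm label that
#' are confirmed by a same-state call of another algorithm with at least
#' 1 bp overlap (the dual-caller consensus used for the high-confidence
#' carrier tier); `"any"` keeps every call (single-algorithm evidence is
#' enough).
#'
#' @param calls A `cnv_calls` data frame.
#' @param tier `"both"` or `"any"`.
#' @return The filtered `cnv_calls`.
#' @export
cnv_evidence_filter <- function(calls, tier = c("both", "any")) {
  tier <- match.arg(tier)
  if (tier == "any" || nrow(calls) == 0) return(calls)
  algs <- sort(unique(calls$algorithm))
  if (length(algs) < 2) {
    out <- calls[0, ]
    warning("only one algorithm label present; 'both' tier is empty",
            call. = FALSE)
    return(out)
  }
  ref <- calls$algorithm == algs[1]
  keep <- logical(nrow(calls))
  for (i in which(ref)) {
    others <- calls$sample_id == calls$sample_id[i] &
      calls$chrom == calls$chrom[i] & calls$state == calls$state[i] &
      calls$algorithm != calls$algorithm[i] &
      calls$start < calls$end[i] & calls$end > calls$start[i]
    keep[i] <- any(others)
  }
  out <- calls[keep, ]
  rownames(out) <- NULL
  out
}

#' Genomic-region case-control association
#'
#' Tests constant-frequency regions for differential CNV carriership:
#'
#' 1. all call breakpoints on a chromosome partition it into atomic
#'    intervals;
#' 2. each atom's carrier set is the samples with >= 1 bp overlap;
#' 3. contiguous atoms with identical case and control carrier sets are
#'    merged, so each reported region has constant frequency and carrier
#'    membership throughout (a segment whose frequency changes is split);
#' 4. each merged region gets a two-sided Fisher exact test and regions
#'    are corrected with Benjamini-Hochberg FDR (the q column);
#' 5. regions with `p <= max_p` and case/control frequency difference at
#'    least `differential_threshold` are reported.
#'
#' @param case_calls,control_calls `cnv_calls` data frames, already
#'   restricted to the state of interest (an error otherwise).
#' @param state Copy-number state tested, `"loss"` or `"gain"`; calls of
#'   the other state are dropped.
#' @param n_cases,n_controls Analyzed-cohort denominators (numbers of
#'   samples passing QC).  Default: distinct samples present in each call
#'   set — supply the manifest counts explicitly when samples may have
#'   zero calls.
#' @param max_p Maximum Fisher p-value reported.
#' @param differential_threshold Minimum absolute difference between case
#'   and control carrier frequencies.
#' @return Data frame with columns `unit` (printed 1-based region),
#'   `chrom`, `start`, `end`, carrier cells `a`-`d`, frequencies, `p`,
#'   `q`, `or`, `ci_low`, `ci_high`.  The unfiltered region table is
#'   attached as attribute `"all_regions"`.
#' @export
region_association <- function(case_calls, control_calls, state = "loss",
                               n_cases = NULL, n_controls = NULL,
                               max_p = 0.05, differential_threshold = 0) {
  case_calls <- case_calls[case_calls$state == state, ]
  control_calls <- control_calls[control_calls$state == state, ]
  if (is.null(n_cases)) n_cases <- length(unique(case_calls$sample_id))
  if (is.null(n_controls)) n_controls <- length(unique(control_calls$sample_id))
  if (n_cases == 0 || n_controls == 0)
    stop("zero samples in one of the groups")
  all <- rbind(
    data.frame(chrom = case_calls$chrom, start = case_calls$start,
               end = case_calls$end, sample_id = case_calls$sample_id,
               group = "case", stringsAsFactors = FALSE),
    data.frame(chrom = control_calls$chrom, start = control_calls$start,
               end = control_calls$end, sample_id = control_calls$sample_id,
               group = "control", stringsAsFactors = FALSE))
  regions <- list()
  for (chrom in unique(all$chrom)) {
    cc <- all[all$chrom == chrom, ]
    bp <- sort(unique(c(cc$start, cc$end)))
    if (length(bp) < 2) next
    atoms <- data.frame(start = bp[-length(bp)], end = bp[-1])
    prev <- NULL
    for (k in seq_len(nrow(atoms))) {
      ov <- cc$start < atoms$end[k] & cc$end > atoms$start[k]
      cas <- sort(unique(cc$sample_id[ov & cc$group == "case"]))
      ctl <- sort(unique(cc$sample_id[ov & cc$group == "control"]))
      if (length(cas) + length(ctl) == 0) { prev <- NULL; next }
      key <- paste(paste(cas, collapse = ","), paste(ctl, collapse = ","),
                   sep = "|")
      if (!is.null(prev) && prev$key == key &&
          prev$end == atoms$start[k]) {
        prev$end <- atoms$end[k]
        regions[[length(regions)]] <- prev
      } else {
        prev <- list(chrom = chrom, start = atoms$start[k],
                     end = atoms$end[k], key = key,
                     n_case = length(cas), n_control = length(ctl))
        regions[[length(regions) + 1L]] <- prev
      }
    }
  }
  rows <- lapply(regions, function(r) {
    row <- assoc_row(sprintf("%s:%s-%s", r$chrom,
                             format(r$start + 1, scientific = FALSE),
                             format(r$end, scientific = FALSE)),
                     r$n_case, n_cases, r$n_control, n_controls)
    cbind(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                     stringsAsFactors = FALSE), row)
  })
  out <- if (length(rows) == 0) finish_assoc(rows) else {
    tab <- do.call(rbind, rows)
    tab$q <- stats::p.adjust(tab$p, method = "BH")
    tab <- tab[order(tab$p, tab$unit),
               c("unit", "chrom", "start", "end", "a", "b", "c", "d",
                 "case_freq", "control_freq", "p", "q", "or", "ci_low",
                 "ci_high")]
    rownames(tab) <- NULL
    tab
  }
  keep <- out$p <= max_p &
    abs(out$case_freq - out$control_freq) >= differential_threshold
  res <- out[keep, ]
  rownames(res) <- NULL
  attr(res, "all_regions") <- out
  res
}

## (gene, sample) pairs with >= min_overlap bp between a sample's calls
## and the flanked gene span
gene_sample_overlaps <- function(calls, gene_models, flank = 10000,
                                 min_overlap = 1) {
  if (nrow(calls) == 0 || nrow(gene_models) == 0)
    return(data.frame(symbol = character(0), sample_id = character(0),
                      group = character(0), stringsAsFactors = FALSE))
  g_gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(start = pmax(0, gene_models$start - flank) + 1,
                     end = gene_models$end + flank))
  c_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(start = calls$start + 1, end = calls$end))
  # disjoint seqlevels between calls and gene models are routine
  # (genome-wide calls vs a handful of genes); silence that advisory
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(c_gr, g_gr, minoverlap = min_overlap))
  out <- data.frame(
    symbol = gene_models$symbol[S4Vectors::subjectHits(hits)],
    sample_id = calls$sample_id[S4Vectors::queryHits(hits)],
    group = calls$group[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  unique(out)
}

#' Gene-level case-control CNV association
#'
#' A sample is a carrier for a gene when any of its CNV calls overlaps the
#' gene span extended by `flank` bp on each side by at least `min_overlap`
#' bp.  Carrier counts per gene are Fisher-tested and BH-corrected; genes
#' with no carrier in either group are not tested.
#'
#' @param all_calls A `cnv_calls` data frame carrying a `group` column
#'   with values `"case"`/`"control"`.
#' @param gene_models Data frame from [read_gene_models()].
#' @param flank Flank in bp added both sides of each gene (default 10 kb).
#' @param min_overlap Minimum overlap in bp (default 1).
#' @inheritParams region_association
#' @return Association data frame as in [region_association()], with gene
#'   symbols in `unit`.
#' @export
gene_association <- function(all_calls, gene_models, flank = 10000,
                             min_overlap = 1, n_cases = NULL,
                             n_controls = NULL) {
  if (is.null(n_cases))
    n_cases <- length(unique(all_calls$sample_id[all_calls$group == "case"]))
  if (is.null(n_controls))
    n_controls <- length(unique(all_calls$sample_id[all_calls$group == "control"]))
  if (n_cases == 0 || n_controls == 0)
    stop("zero samples in one of the groups")
  ov <- gene_sample_overlaps(all_calls, gene_models, flank, min_overlap)
  rows <- lapply(split(ov, ov$symbol), function(d) {
    assoc_row(d$symbol[1], sum(d$group == "case"), n_cases,
              sum(d$group == "control"), n_controls)
  })
  finish_assoc(rows)
}

#' Pathway-level case-control CNV association
#'
#' In each sample a pathway counts as affected when at least one of its
#' member genes is CNV-affected for that sample (gene rule of
#' [gene_association()]).  Pathways whose members cannot be resolved
#' against the gene models are skipped with a warning.
#'
#' @param pathways Named list of gene-symbol vectors ([read_gene_sets()]).
#' @inheritParams gene_association
#' @return Association data frame with pathway names in `unit`.
#' @export
pathway_association <- function(all_calls, gene_models, pathways,
                                flank = 10000, min_overlap = 1,
                                n_cases = NULL, n_controls = NULL) {
  if (is.null(n_cases))
    n_cases <- length(unique(all_calls$sample_id[all_calls$group == "case"]))
  if (is.null(n_controls))
    n_controls <- length(unique(all_calls$sample_id[all_calls$group == "control"]))
  if (n_cases == 0 || n_controls == 0)
    stop("zero samples in one of the groups")
  ov <- gene_sample_overlaps(all_calls, gene_models, flank, min_overlap)
  rows <- list()
  for (nm in names(pathways)) {
    members <- intersect(pathways[[nm]], gene_models$symbol)
    if (length(members) == 0) {
      warning("pathway '", nm, "' has no member resolvable against the ",
              "gene models; skipped", call. = FALSE)
      next
    }
    hit <- ov[ov$symbol %in% members, ]
    affected <- unique(hit[, c("sample_id", "group")])
    rows[[length(rows) + 1L]] <- assoc_row(
      nm, sum(affected$group == "case"), n_cases,
      sum(affected$group == "control"), n_controls)
  }
  finish_assoc(rows)
}

#' Case-control CNV load comparison
#'
#' Computes per-sample CNV burden — number of calls, total affected bp,
#' and, when a gene set is supplied, the number of set genes affected —
#' and compares cases with controls by a two-sided Wilcoxon rank-sum test
#' on the call counts (and on affected bp).  When every sample has an
#' identical burden the test is degenerate and p is reported as 1.
#'
#' @param case_calls,control_calls `cnv_calls` data frames.
#' @param case_samples,control_samples Sample rosters; samples without
#'   calls enter with zero burden.  Default: distinct samples in the call
#'   sets.
#' @param gene_set Optional character vector of gene symbols whose
#'   per-sample affected count is also reported (requires `gene_models`).
#' @param gene_models Gene models for the `gene_set` count.
#' @param flank Flank used for the gene-set count (default 10 kb).
#' @return A list of class `cnv_load_report`: `per_sample` data frame,
#'   group medians, and the rank-sum statistic and p-values.
#' @export
cnv_load_test <- function(case_calls, control_calls,
                          case_samples = NULL, control_samples = NULL,
                          gene_set = NULL, gene_models = NULL,
                          flank = 10000) {
  if (is.null(case_samples)) case_samples <- unique(case_calls$sample_id)
  if (is.null(control_samples)) control_samples <- unique(control_calls$sample_id)
  burden <- function(calls, samples, group) {
    n <- vapply(samples, function(s) sum(calls$sample_id == s), integer(1))
    bp <- vapply(samples, function(s) {
      sum(calls$end[calls$sample_id == s] - calls$start[calls$sample_id == s])
    }, numeric(1))
    d <- data.frame(sample_id = samples, group = group, n_calls = n,
                    total_bp = bp, stringsAsFactors = FALSE)
    if (!is.null(gene_set)) {
      if (is.null(gene_models))
        stop("gene_set requires gene_models")
      gm <- gene_models[gene_models$symbol %in% gene_set, ]
      calls$group <- group
      ov <- gene_sample_overlaps(calls, gm, flank, 1)
      d$n_set_genes <- vapply(samples, function(s)
        length(unique(ov$symbol[ov$sample_id == s])), integer(1))
    }
    d
  }
  per <- rbind(burden(case_calls, case_samples, "case"),
               burden(control_calls, control_samples, "control"))
  rownames(per) <- NULL
  rank_sum_p <- function(metric) {
    x <- per[[metric]][per$group == "case"]
    y <- per[[metric]][per$group == "control"]
    if (stats::var(c(x, y)) == 0)
      return(list(stat = length(x) * length(y) / 2, p = 1))
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(stat = unname(w$statistic), p = w$p.value)
  }
  counts <- rank_sum_p("n_calls")
  bp <- rank_sum_p("total_bp")
  structure(list(
    per_sample = per,
    median_case = stats::median(per$n_calls[per$group == "case"]),
    median_control = stats::median(per$n_calls[per$group == "control"]),
    statistic = counts$stat, p = counts$p, p_total_bp = bp$p),
    class = "cnv_load_report")
}

#' @export
print.cnv_load_report <- function(x, ...) {
  cat(sprintf(
    "<cnv_load_report> median calls/sample: cases %.1f vs controls %.1f; W = %.1f, p = %.3g\n",
    x$median_case, x$median_control, x$statistic, x$p))
  invisible(x)
}
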