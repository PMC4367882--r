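test_that("smallest region of overlap is the max-start/min-end interval", {
  calls <- make_calls(data.frame(
    chrom = "chr1", start = c(0, 50, 80), end = c(100, 150, 120),
    sample_id = c("a", "b", "c")))
  sro <- smallest_region_of_overlap(calls)
  expect_equal(c(sro$start, sro$end), c(80, 100))
  # single interval -> itself
  one <- make_calls(data.frame(chrom = "chr1", start = 5, end = 9,
                               sample_id = "a"))
  sro1 <- smallest_region_of_overlap(one)
  expect_equal(c(sro1$start, sro1$end), c(5, 9))
  # disjoint pair -> error naming the records
  bad <- make_calls(data.frame(chrom = "chr1", start = c(0, 200),
                               end = c(100, 300), sample_id = c("a", "b")))
  expect_error(smallest_region_of_overlap(bad), "do not all overlap")
  expect_error(smallest_region_of_overlap(bad[0, ]), "no calls")
})

test_that("SRO agrees with an iterative intersection oracle and is monotone", {
  set.seed(13)
  for (rep_i in 1:30) {
    n <- sample(2:8, 1)
    start <- sample.int(1000, n)
    len <- sample(500:1500, n, replace = TRUE)
    calls <- make_calls(data.frame(chrom = "chr3", start = start,
                                   end = start + len,
                                   sample_id = letters[1:n]))
    # oracle: iterative IRanges intersection
    ir <- IRanges::IRanges(start = calls$start + 1, end = calls$end)
    common <- Reduce(IRanges::intersect, split(ir, seq_len(n)))
    if (length(common) == 0) {
      expect_error(smallest_region_of_overlap(calls), "overlap")
    } else {
      sro <- smallest_region_of_overlap(calls)
      expect_equal(sro$start + 1, IRanges::start(common))
      expect_equal(sro$end, IRanges::end(common))
      # contained in every input; extending an input never shrinks it
      expect_true(all(calls$start <= sro$start & calls$end >= sro$end))
      wider <- calls; wider$start[1] <- wider$start[1] - 100
      sro2 <- smallest_region_of_overlap(wider)
      expect_lte(sro2$start, sro$start)
      expect_gte(sro2$end, sro$end)
    }
  }
})

test_that("chr16 worked-example fixture reproduces the printed SRO and carrier tiers", {
  fx <- snhl_fixtures()
  both_cases <- cnv_evidence_filter(fx$chr16$case_calls, "both")
  both_controls <- cnv_evidence_filter(fx$chr16$control_calls, "both")
  region <- fx$chr16$region
  carriers <- function(calls) {
    unique(calls$sample_id[calls$chrom == region$chrom &
                             calls$start < region$end &
                             calls$end > region$start])
  }
  expect_equal(length(carriers(both_cases)), 23)
  expect_equal(length(carriers(both_controls)), 7)
  expect_equal(length(carriers(fx$chr16$case_calls[
    fx$chr16$case_calls$state == "loss", ])), 40)
  expect_equal(length(carriers(fx$chr16$control_calls[
    fx$chr16$control_calls$state == "loss", ])), 15)
  sro <- smallest_region_of_overlap(both_cases[
    both_cases$start < region$end & both_cases$end > region$start, ])
  expect_equal(sro$start + 1, 14956245)
  expect_equal(sro$end, 15028783)
})

test_that("two-sided Fisher matches enumeration on forced tables", {
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_two_sided(4, 0, 0, 4), 2 / 70)  # = 1/35
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher agrees with combinatorial enumeration and fisher.test on 500 random tables", {
  set.seed(12)
  for (i in 1:500) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    p <- fisher_exact_two_sided(a, b, c, d)
    expect_equal(p, fisher_oracle(a, b, c, d), tolerance = 1e-9)
    expect_equal(p, fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-6)
  }
})

test_that("odds ratio reproduces the printed deletion effect sizes", {
  both <- odds_ratio(23, 149 - 23, 7, 150)
  expect_equal(round(both$or, 2), 3.91)
  expect_equal(round(both$ci_low, 2), 1.62)
  expect_equal(both$ci_high, 9.40, tolerance = 0.005)
  any_tier <- odds_ratio(40, 149 - 40, 15, 157 - 15)
  expect_equal(round(any_tier$or, 2), 3.47)
  expect_equal(any_tier$ci_low, 1.82, tolerance = 0.005)
  expect_equal(any_tier$ci_high, 6.60, tolerance = 0.005)
})

test_that("odds ratio identities, zero-cell handling and errors", {
  expect_equal(odds_ratio(10, 20, 5, 10)$or, 1)  # a/b == c/d
  set.seed(2)
  for (i in 1:20) {
    cells <- sample(1:50, 4)
    o1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])$or
    o2 <- odds_ratio(cells[3], cells[4], cells[1], cells[2])$or
    expect_equal(o1 * o2, 1)
  }
  z <- odds_ratio(5, 0, 2, 7)
  expect_true(z$haldane)
  expect_equal(z$or, (5.5 * 7.5) / (0.5 * 2.5))
  expect_error(odds_ratio(0, 3, 4, 0), "diagonal")
  expect_error(odds_ratio(3, 0, 0, 4), "diagonal")
})

test_that("region association finds a fully penetrant deletion with the exact p", {
  cases <- make_calls(data.frame(chrom = "chr1", start = 100, end = 200,
                                 sample_id = paste0("ca", 1:4)), "case")
  controls <- make_calls(data.frame(chrom = "chr1", start = 5000,
                                    end = 5100,
                                    sample_id = "co1"), "control")
  res <- region_association(cases, controls, n_cases = 4, n_controls = 4,
                            max_p = 0.05)
  hit <- res[res$start == 100, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, 200)
  expect_equal(hit$a, 4); expect_equal(hit$c, 0)
  expect_equal(hit$p, 2 / choose(8, 4))  # exhaustive hypergeometric: 1/35
})

test_that("identical case and control call sets yield no differential region", {
  calls <- data.frame(chrom = "chr2", start = c(10, 50), end = c(100, 80),
                      sample_id = c("s1", "s2"))
  res <- region_association(make_calls(calls, "case"),
                            make_calls(calls, "control"),
                            n_cases = 2, n_controls = 2,
                            max_p = 1, differential_threshold = 0.01)
  expect_equal(nrow(res), 0)
})

test_that("reported regions tile without overlap and have constant carrier sets", {
  sim <- simulate_cnv_cohort(n_cases = 25, n_controls = 25,
                             background_rate = 3, seed = 31)
  res <- region_association(sim$case_calls, sim$control_calls,
                            n_cases = 25, n_controls = 25, max_p = 1)
  all_regions <- attr(res, "all_regions")
  expect_gt(nrow(all_regions), 0)
  # no two regions on a chromosome overlap
  by_chrom <- split(all_regions, all_regions$chrom)
  for (d in by_chrom) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  # post hoc: within each reported region, every atom has the same
  # carrier sets as the region's counts
  pool <- rbind(sim$case_calls[sim$case_calls$state == "loss", ],
                sim$control_calls[sim$control_calls$state == "loss", ])
  for (r in sample(seq_len(nrow(all_regions)), min(20, nrow(all_regions)))) {
    reg <- all_regions[r, ]
    sub <- pool[pool$chrom == reg$chrom & pool$start < reg$end &
                  pool$end > reg$start, ]
    bps <- sort(unique(c(reg$start, reg$end,
                         pmax(sub$start, reg$start),
                         pmin(sub$end, reg$end))))
    for (k in seq_len(length(bps) - 1)) {
      ov <- sub[sub$start < bps[k + 1] & sub$end > bps[k], ]
      expect_equal(length(unique(ov$sample_id[ov$group == "case"])), reg$a)
      expect_equal(length(unique(ov$sample_id[ov$group == "control"])),
                   reg$c)
    }
  }
  # BH q-values satisfy the step-up definition exactly
  ord <- order(all_regions$p)
  p <- all_regions$p[ord]; m <- length(p)
  q_manual <- rev(cummin(rev(m * p / seq_len(m))))
  expect_equal(all_regions$q[ord], pmin(1, q_manual))
})

test_that("gene association carrier rule is exact at the flank boundary", {
  genes <- data.frame(symbol = "G1", chrom = "chr1", start = 20000,
                      end = 30000)
  # call ending exactly at gene.start - flank: zero overlap
  at_edge <- make_calls(data.frame(chrom = "chr1", start = 5000,
                                   end = 10000, sample_id = "ca1"), "case")
  past_edge <- make_calls(data.frame(chrom = "chr1", start = 5000,
                                     end = 10001, sample_id = "ca1"), "case")
  ctl <- make_calls(data.frame(chrom = "chr9", start = 1, end = 2,
                               sample_id = "co1"), "control")
  res0 <- gene_association(rbind(at_edge, ctl), genes, flank = 10000,
                           n_cases = 1, n_controls = 1)
  expect_equal(nrow(res0), 0)
  res1 <- gene_association(rbind(past_edge, ctl), genes, flank = 10000,
                           n_cases = 1, n_controls = 1)
  expect_equal(nrow(res1), 1)
  expect_equal(res1$a, 1)
})

test_that("gene association matches a brute-force double loop at flank zero", {
  set.seed(21)
  genes <- data.frame(symbol = sprintf("G%02d", 1:10),
                      chrom = "chr1",
                      start = seq(10000, 100000, by = 10000),
                      end = seq(10000, 100000, by = 10000) + 4000)
  roster <- paste0("s", 1:12)
  sgroup <- setNames(sample(c("case", "control"), 12, TRUE), roster)
  calls <- make_calls(data.frame(
    chrom = "chr1",
    start = sample.int(110000, 40),
    end = NA, sample_id = sample(roster, 40, TRUE)),
    group = "case")
  calls$end <- calls$start + sample(1000:20000, 40, TRUE)
  calls$group <- unname(sgroup[calls$sample_id])
  n_cases <- sum(sgroup == "case")
  n_controls <- sum(sgroup == "control")
  res <- gene_association(calls, genes, flank = 0, min_overlap = 1,
                          n_cases = n_cases, n_controls = n_controls)
  # brute force per gene, per sample
  for (g in seq_len(nrow(genes))) {
    carr <- unique(calls$sample_id[calls$start < genes$end[g] &
                                     calls$end > genes$start[g]])
    a <- sum(sgroup[carr] == "case")
    cc <- sum(sgroup[carr] == "control")
    row <- res[res$unit == genes$symbol[g], ]
    if (a + cc == 0) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(c(row$a, row$c), c(a, cc))
    }
  }
})

test_that("swapping case and control labels inverts every odds ratio", {
  sim <- simulate_cnv_cohort(n_cases = 30, n_controls = 30,
                             background_rate = 2, seed = 55)
  genes <- data.frame(symbol = c("PL", "X1", "X2"),
                      chrom = c("chr16", "chr1", "chr2"),
                      start = c(14960000, 50e6, 50e6),
                      end = c(15020000, 50.1e6, 50.1e6))
  calls <- rbind(sim$case_calls, sim$control_calls)
  res <- gene_association(calls, genes, n_cases = 30, n_controls = 30)
  flipped <- calls
  flipped$group <- ifelse(flipped$group == "case", "control", "case")
  res2 <- gene_association(flipped, genes, n_cases = 30, n_controls = 30)
  shared <- intersect(res$unit, res2$unit)
  for (u in shared) {
    o1 <- res$or[res$unit == u]; o2 <- res2$or[res2$unit == u]
    if (!is.na(o1) && !is.na(o2) && all(res[res$unit == u, c("a","b","c","d")] > 0))
      expect_equal(o1 * o2, 1)
  }
  expect_gt(length(shared), 0)
})

test_that("pathway association counts a sample once per pathway via any member gene", {
  genes <- data.frame(symbol = c("GJB2", "GJB6", "FARAWAY"),
                      chrom = c("chr13", "chr13", "chr4"),
                      start = c(20000, 60000, 100000),
                      end = c(25000, 65000, 105000))
  pathways <- list(hearing = c("GJB2", "GJB6"), other = "FARAWAY",
                   orphan = "NOT_A_GENE")
  calls <- make_calls(data.frame(
    chrom = c("chr13", "chr13", "chr4"),
    start = c(21000, 61000, 101000), end = c(22000, 62000, 102000),
    sample_id = c("ca1", "ca1", "co1")))
  calls$group <- c("case", "case", "control")
  expect_warning(
    res <- pathway_association(calls, genes, pathways,
                               flank = 0, n_cases = 2, n_controls = 2),
    "orphan")
  hearing <- res[res$unit == "hearing", ]
  # ca1 hits both member genes but counts once
  expect_equal(c(hearing$a, hearing$c), c(1, 0))
  other <- res[res$unit == "other", ]
  expect_equal(c(other$a, other$c), c(0, 1))
  # hand-computed Fisher for the 2x2 tables (n = 2 vs 2)
  expect_equal(hearing$p, fisher_oracle(1, 1, 0, 2))
  expect_equal(other$p, fisher_oracle(0, 2, 1, 1))
})

test_that("CNV load: degenerate ties give p = 1 and counts match a recount", {
  cases <- make_calls(data.frame(chrom = "chr1",
                                 start = c(10, 30, 100, 130),
                                 end = c(20, 40, 110, 140),
                                 sample_id = c("a", "a", "b", "b")), "case")
  controls <- make_calls(data.frame(chrom = "chr1",
                                    start = c(10, 50, 100, 150),
                                    end = c(20, 60, 110, 160),
                                    sample_id = c("x", "x", "y", "y")),
                         "control")
  rep <- cnv_load_test(cases, controls)
  expect_equal(rep$p, 1)
  expect_equal(rep$per_sample$n_calls, rep(2L, 4))
  # counts equal an independent recount from the raw lists
  for (s in c("a", "b")) {
    expect_equal(rep$per_sample$n_calls[rep$per_sample$sample_id == s],
                 sum(cases$sample_id == s))
  }
  expect_equal(rep$per_sample$total_bp[rep$per_sample$sample_id == "a"],
               sum((cases$end - cases$start)[cases$sample_id == "a"]))
})

test_that("CNV load detects a threefold call-rate shift (20 seeds)", {
  sig <- logical(20)
  for (s in 1:20) {
    set.seed(400 + s)
    mk <- function(n, rate, prefix, group) {
      counts <- rpois(n, rate)
      rows <- data.frame(
        chrom = "chr1",
        start = seq_len(sum(counts)) * 1000,
        end = seq_len(sum(counts)) * 1000 + 500,
        sample_id = rep(sprintf("%s%02d", prefix, 1:n), counts))
      list(calls = make_calls(rows, group),
           samples = sprintf("%s%02d", prefix, 1:n))
    }
    ca <- mk(50, 3, "ca", "case")
    co <- mk(50, 1, "co", "control")
    rep <- cnv_load_test(ca$calls, co$calls, case_samples = ca$samples,
                         control_samples = co$samples)
    sig[s] <- rep$p < 0.01
  }
  expect_gte(mean(sig), 0.95)
})

test_that("gene-set load counting reports affected set genes per sample", {
  genes <- data.frame(symbol = c("STRC", "OTOA"), chrom = c("chr15", "chr16"),
                      start = c(41639152, 21600000),
                      end = c(41709787, 21700000))
  cases <- make_calls(data.frame(chrom = "chr15", start = 41650000,
                                 end = 41660000, sample_id = "ca1"), "case")
  controls <- make_calls(data.frame(chrom = "chr3", start = 1000,
                                    end = 2000, sample_id = "co1"),
                         "control")
  rep <- cnv_load_test(cases, controls, gene_set = c("STRC", "OTOA"),
                       gene_models = genes)
  expect_equal(rep$per_sample$n_set_genes[rep$per_sample$sample_id == "ca1"], 1L)
  expect_equal(rep$per_sample$n_set_genes[rep$per_sample$sample_id == "co1"], 0L)
})
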