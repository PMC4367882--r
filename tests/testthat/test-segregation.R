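test_that("recessive model: hom in all affected, non-hom in all unaffected", {
  ped <- quintet_ped()
  # textbook: carrier parents, three homozygous affected children
  gt <- rbind(c(1L, 1L, 2L, 2L, 2L),   # hit
              c(1L, 1L, 2L, 1L, 2L),   # one child het -> no hit
              c(2L, 1L, 2L, 2L, 2L))   # hom unaffected father -> no hit
  colnames(gt) <- ped$sample_id
  hits <- recessive_hits(make_vs(gt), ped)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$model, "recessive")
  expect_error(recessive_hits(make_vs(gt),
                              pedigree(data.frame(
                                sample_id = "X", father_id = NA,
                                mother_id = NA, sex = "male",
                                affected = FALSE))),
               "member|affected")
})

test_that("planted recessive and de novo variants are recovered exactly (manifest oracle)", {
  for (model in c("recessive", "de_novo")) {
    for (seed in 1:5) {
      sim <- simulate_pedigree_vcf(model, n_background = 300, seed = seed)
      hits <- switch(model,
                     recessive = recessive_hits(sim$variants, sim$pedigree),
                     de_novo = de_novo_hits(sim$variants, sim$pedigree))
      expect_true(all(sim$manifest$planted_ids %in% hits$variants),
                  label = sprintf("%s seed %d planted recovered", model, seed))
    }
  }
})

test_that("compound het: one allele per parent, both in every affected child", {
  fx <- snhl_fixtures()
  hits <- compound_het_hits(fx$family1$variants, fx$family1$pedigree)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene, "MYH7B")
  expect_equal(hits$n_variants, 2)
  expect_setequal(strsplit(hits$variants, ",")[[1]],
                  c("MYH7B_v1_paternal", "MYH7B_v2_maternal"))
  # break one child's second allele -> no hit
  broken <- fx$family1$variants
  broken$gt["MYH7B_v2_maternal", "F1.3"] <- 0L
  expect_equal(nrow(compound_het_hits(broken, fx$family1$pedigree)), 0)
})

test_that("compound het agrees with a brute-force predicate over enumerated genotypes", {
  ped <- quintet_ped()
  members <- ped$sample_id
  aff <- c("C1", "C2", "C3"); una <- c("FA", "MO")
  brute <- function(g1, g2) {
    # independent re-statement of the rule
    p1 <- g1["FA"] == 1 && g1["MO"] == 0
    m1 <- g1["MO"] == 1 && g1["FA"] == 0
    p2 <- g2["FA"] == 1 && g2["MO"] == 0
    m2 <- g2["MO"] == 1 && g2["FA"] == 0
    trans <- (p1 && m2) || (m1 && p2)
    kids_both <- all(g1[aff] == 1) && all(g2[aff] == 1)
    una_both <- any(g1[una] > 0 & g2[una] > 0)
    trans && kids_both && !una_both
  }
  grid <- as.matrix(expand.grid(rep(list(0:2), 5)))
  colnames(grid) <- members
  v1_pat <- setNames(c(1L, 0L, 1L, 1L, 1L), members)
  for (r in seq_len(nrow(grid))) {
    g2 <- setNames(as.integer(grid[r, ]), members)
    gt <- rbind(v1_pat, g2)
    colnames(gt) <- members
    got <- nrow(compound_het_hits(make_vs(gt, genes = "GENE"), ped)) == 1
    expect_equal(got, brute(v1_pat, g2),
                 label = paste("v2 =", paste(g2, collapse = "")))
  }
  # swapping parental labels together with their genotype columns is
  # symmetric
  swapped_ped <- pedigree(data.frame(
    sample_id = c("MO", "FA", "C1", "C2", "C3"),
    father_id = c(NA, NA, "MO", "MO", "MO"),
    mother_id = c(NA, NA, "FA", "FA", "FA"),
    sex = c("male", "female", "male", "male", "female"),
    affected = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))
  gt <- rbind(v1_pat, setNames(c(0L, 1L, 1L, 1L, 1L), members))
  colnames(gt) <- members
  vs <- make_vs(gt, genes = "GENE")
  expect_equal(nrow(compound_het_hits(vs, ped)),
               nrow(compound_het_hits(vs, swapped_ped)))
})

test_that("compound het pairs require the two variants to share a gene", {
  ped <- quintet_ped()
  gt <- rbind(c(1L, 0L, 1L, 1L, 1L), c(0L, 1L, 1L, 1L, 1L))
  colnames(gt) <- ped$sample_id
  expect_equal(nrow(compound_het_hits(make_vs(gt, genes = c("A", "B")), ped)), 0)
  expect_equal(nrow(compound_het_hits(make_vs(gt, genes = c("A", "A")), ped)), 1)
})

test_that("dominant model on the printed worked example retains 14 of 20 variants", {
  fx <- snhl_fixtures()
  vs <- fx$table3$variants
  ped <- fx$table3$pedigree
  expect_equal(n_variants(vs), 20)
  expect_equal(sum(!grepl("^SYN_DECOY", variant_ids(vs))), 14)
  hits <- dominant_hits(vs, ped, allow_homozygous_affected = TRUE)
  expect_equal(nrow(hits), 14)
  expect_false(any(grepl("^SYN_DECOY", hits$variants)))
  # seven of the retained variants are missense
  imp <- vs$info$impact[match(hits$variants, variant_ids(vs))]
  expect_equal(sum(imp == "missense"), 7)
  # two show the mother-homozygous / children-heterozygous pattern
  gt <- vs$gt[match(hits$variants, variant_ids(vs)), , drop = FALSE]
  expect_equal(sum(gt[, "F3.2"] == 2 & gt[, "F3.3"] == 1 &
                     gt[, "F3.4"] == 1), 2)
  # disallowing homozygous affected drops exactly those two
  strict <- dominant_hits(vs, ped, allow_homozygous_affected = FALSE)
  expect_equal(nrow(strict), 12)
})

test_that("dominant model excludes carriers among the unaffected", {
  ped <- quartet_ped()
  ped$affected <- c(FALSE, TRUE, TRUE, TRUE)  # mother + twins affected
  gt <- rbind(c(1L, 1L, 1L, 1L),   # het in unaffected father -> excluded
              c(0L, 1L, 1L, 1L))   # father ref -> hit
  colnames(gt) <- ped$sample_id
  hits <- dominant_hits(make_vs(gt), ped)
  expect_equal(nrow(hits), 1)
})

test_that("de novo model requires ref parents and het in every required member", {
  ped <- quartet_ped()
  gt <- rbind(c(0L, 0L, 1L, 1L),   # hit in both twins
              c(0L, 0L, 1L, 0L),   # one twin ref -> no hit
              c(1L, 0L, 1L, 1L))   # inherited -> no hit
  colnames(gt) <- ped$sample_id
  hits <- de_novo_hits(make_vs(gt), ped, required_affected = c("T1", "T2"))
  expect_equal(nrow(hits), 1)
  expect_error(de_novo_hits(make_vs(gt), ped, required_affected = "ghost"),
               "not in the pedigree")
})

test_that("homozygous-rare hits partition by known-gene membership", {
  gt <- matrix(c(2L, 1L, 2L), 3, 1, dimnames = list(NULL, "P1"))
  vs <- make_vs(gt, genes = c("MYO7A", "MYO7A", "NOVEL1"))
  hits <- homozygous_rare_hits(vs, known_genes = c("MYO7A", "GJB2"))
  expect_equal(nrow(hits), 2)          # the het variant is not returned
  expect_equal(sum(hits$in_known_gene), 1)
  expect_error(homozygous_rare_hits(make_vs(matrix(2L, 1, 2,
    dimnames = list(NULL, c("A", "B")))), "X"), "single-sample")
})

test_that("every model returns nothing when a required genotype is missing", {
  ped <- quintet_ped()
  gt <- matrix(c(1L, 1L, 2L, NA, 2L), 1, 5,
               dimnames = list(NULL, ped$sample_id))
  vs <- make_vs(gt)
  expect_equal(nrow(recessive_hits(vs, ped)), 0)
  expect_equal(nrow(dominant_hits(vs, ped)), 0)
  expect_equal(nrow(de_novo_hits(vs, ped)), 0)
  gt2 <- rbind(c(1L, 0L, 1L, 1L, NA), c(0L, 1L, 1L, 1L, 1L))
  colnames(gt2) <- ped$sample_id
  expect_equal(nrow(compound_het_hits(make_vs(gt2, genes = "G"), ped)), 0)
})

test_that("network proximity filter matches a breadth-first-search oracle", {
  # forced cases: an anchor at distance 0, a chain A-B-C
  chain <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                        anchors = "A")
  hit <- function(gene) {
    structure(data.frame(model = "dominant", gene = gene, variants = "v",
                         n_variants = 1L, carriers = "",
                         stringsAsFactors = FALSE),
              class = c("segregation_hits", "data.frame"))
  }
  expect_equal(nrow(network_proximity_filter(hit("A"), chain, 0)), 1)
  expect_equal(nrow(network_proximity_filter(hit("C"), chain, 2)), 1)
  expect_equal(nrow(network_proximity_filter(hit("C"), chain, 1)), 0)
  # gene absent from the network is unreachable
  expect_equal(nrow(suppressMessages(
    network_proximity_filter(hit("ZZ"), chain, 5))), 0)

  # random graphs against an independent BFS implementation
  bfs_dist <- function(edges, from_set, target) {
    adj <- list()
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
    dist <- 0; frontier <- intersect(from_set, c(edges[, 1], edges[, 2], from_set))
    seen <- frontier
    while (length(frontier)) {
      if (target %in% frontier) return(dist)
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- union(seen, frontier)
      dist <- dist + 1
    }
    Inf
  }
  set.seed(77)
  for (rep_i in 1:50) {
    genes <- sprintf("g%02d", 1:12)
    edges <- data.frame(from = sample(genes, 14, TRUE),
                        to = sample(genes, 14, TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, ]
    anchors <- sample(genes, 2)
    net <- gene_network(edges, anchors)
    maxd <- sample(0:3, 1)
    probe <- sample(genes, 4)
    hits <- do.call(rbind, lapply(probe, hit))
    class(hits) <- c("segregation_hits", "data.frame")
    got <- suppressMessages(network_proximity_filter(hits, net, maxd))$gene
    want <- probe[vapply(probe, function(g)
      min(vapply(anchors, function(a)
        bfs_dist(as.matrix(edges), a, g), numeric(1))) <= maxd, logical(1))]
    expect_setequal(got, want)
  }
})
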