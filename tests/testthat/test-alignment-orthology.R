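# alignment engine, BBH orthology, synteny and rearrangement mapping

test_that("align_local: self-alignment and point mutants behave", {
  s <- strrep("ACGT", 25)
  h <- align_local(s, s, type = "dna")
  expect_equal(h$identity, 1)
  expect_equal(h$query_coverage, 1)
  expect_equal(h$subject_coverage, 1)

  mut <- paste0(substr(s, 1, 49), "T", substr(s, 51, 100))
  h2 <- align_local(s, mut, type = "dna")
  expect_equal(h2$identity, 0.99, tolerance = 1e-6)

  expect_error(align_local("ACGU", "ACGT", type = "dna"), "alphabet")
  expect_error(align_local("MABZ", "MA", type = "protein"), "alphabet")
})

test_that("seeded path equals exhaustive DP on 2-kb pairs", {
  for (seed in 1:10) {
    g <- random_dna(2000, seed = seed)
    q <- mutate_sequence(substr(g, 501, 1500), 0.05,
                         seed = seed + 100)$sequence
    dp <- align_local(q, g, type = "dna", method = "dp")
    sd_ <- align_local(q, g, type = "dna", method = "seed")
    expect_equal(sd_$raw_score, dp$raw_score)
    expect_equal(sd_$identity, dp$identity)
    expect_equal(sd_$s_start, dp$s_start)
  }
})

test_that("e-values are monotone in score and search space", {
  s <- random_dna(300, seed = 1)
  h <- align_local(s, s, type = "dna")
  h_small <- align_local(s, s, type = "dna", n_total = 100L)
  expect_equal(h_small$evalue / h$evalue, 100 / 300)
  expect_lt(align_local(s, s, type = "dna")$evalue,
            align_local(substr(s, 1, 50), substr(s, 1, 50),
                        type = "dna")$evalue)
})

test_that("BBH maps identical proteomes onto themselves", {
  prots <- setNames(vapply(1:20, function(i) random_protein(250, i),
                           character(1)), sprintf("p%02d", 1:20))
  bbh <- bidirectional_best_hits(prots, prots)
  expect_identical(nrow(bbh), 20L)
  expect_identical(bbh$gene_a, bbh$gene_b)
  expect_true(all(bbh$identity == 1))

  plus <- c(prots, orphan = random_protein(250, 999))
  bbh2 <- bidirectional_best_hits(plus, prots)
  expect_false("orphan" %in% bbh2$gene_a)
})

test_that("BBH recovers simulated orthologs and is symmetric", {
  sim <- simulate_pangenome(pangenome_spec(1, 1, n_core = 100,
                                           n_A_specific = 0,
                                           n_B_specific = 0,
                                           aa_divergence_within = 0.05),
                            seed = 13)
  pa <- sim$proteomes$A01; pb <- sim$proteomes$B01
  bbh <- bidirectional_best_hits(pa, pb)
  expect_identical(nrow(bbh), 100L)
  truth <- sim$membership
  key <- setNames(truth$cluster_id, truth$gene_id)
  expect_true(all(key[bbh$gene_a] == key[bbh$gene_b]))

  rev <- bidirectional_best_hits(pb, pa)
  expect_setequal(paste(bbh$gene_a, bbh$gene_b),
                  paste(rev$gene_b, rev$gene_a))
})

test_that("BBH gates are monotone", {
  sim <- simulate_pangenome(pangenome_spec(1, 1, n_core = 30,
                                           n_A_specific = 0,
                                           n_B_specific = 0,
                                           aa_divergence_within = 0.25),
                            seed = 17)
  pa <- sim$proteomes$A01; pb <- sim$proteomes$B01
  base <- bidirectional_best_hits(pa, pb, evalue_max = 1e-20,
                                  min_coverage = 0.5)
  for (args in list(list(evalue_max = 1e-60, min_coverage = 0.5),
                    list(evalue_max = 1e-20, min_coverage = 0.9))) {
    sub <- bidirectional_best_hits(pa, pb, evalue_max = args$evalue_max,
                                   min_coverage = args$min_coverage)
    expect_true(all(paste(sub$gene_a, sub$gene_b) %in%
                      paste(base$gene_a, base$gene_b)))
  }
})

test_that("synteny links carry coordinates and write circos TSV", {
  sp <- simulate_strain_pair(genes_per_replicon = c(10),
                             aa_divergence = 0.02, seed = 31)
  bbh <- bidirectional_best_hits(sp$a$proteome, sp$b$proteome)
  p <- withr::local_tempfile(fileext = ".tsv")
  links <- synteny_links(bbh, sp$a$genes, sp$b$genes, path = p)
  expect_identical(nrow(links), 10L)
  expect_identical(length(readLines(p)), 11L)
  ia <- match(bbh$gene_a, sp$a$genes$gene_id)
  expect_identical(links$start_a, sp$a$genes$start[ia])

  empty <- bbh[0, ]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  l0 <- synteny_links(empty, sp$a$genes, sp$b$genes, path = p2)
  expect_identical(nrow(l0), 0L)
  expect_identical(length(readLines(p2)), 1L)   # header only

  bad <- bbh; bad$gene_a[1] <- "missing_gene"
  expect_error(synteny_links(bad, sp$a$genes, sp$b$genes),
               "missing_gene")
})

test_that("cointegration map recovers the fused sources", {
  sp <- simulate_strain_pair(genes_per_replicon = c(40, 30, 25),
                             aa_divergence = 0.05, cointegrate = TRUE,
                             seed = 4)
  bbh <- bidirectional_best_hits(sp$b$proteome, sp$a$proteome)
  cm <- cointegration_map("B_cointegrant", sp$b$genes, sp$a$genes, bbh)
  expect_identical(nrow(cm$segments), 3L)
  expect_setequal(cm$segments$source, c("A_rep1", "A_rep2", "A_rep3"))
  # >= 95% of genes assigned to the correct ancestral replicon
  src_truth <- sp$genes_b_source$source_replicon[
    match(cm$genes$gene_id, sp$genes_b_source$gene_id)]
  want <- sub("^B_", "A_", src_truth)
  ok <- !is.na(cm$genes$source) & cm$genes$source == want
  expect_gte(mean(ok), 0.95)
})

test_that("a one-to-one replicon ortholog maps as one dominant segment", {
  sp <- simulate_strain_pair(genes_per_replicon = c(40),
                             aa_divergence = 0.05, seed = 6)
  bbh <- bidirectional_best_hits(sp$b$proteome, sp$a$proteome)
  cm <- cointegration_map("B_rep1", sp$b$genes, sp$a$genes, bbh)
  expect_identical(nrow(cm$segments), 1L)
  expect_gte(cm$segments$n_genes[1] / 40, 0.9)

  # disjoint proteomes: empty map with a warning
  other <- setNames(vapply(1:10, function(i) random_protein(200, i + 500),
                           character(1)), sprintf("x%02d", 1:10))
  bbh0 <- bidirectional_best_hits(sp$b$proteome, other)
  expect_warning(cm0 <- cointegration_map("B_rep1", sp$b$genes,
    data.frame(gene_id = names(other), replicon_id = "z", start = 1,
               end = 600, strand = "+"), bbh0), "no BBH")
  expect_identical(nrow(cm0$counts), 0L)
})

test_that("translocated blocks are recovered with exact sizes", {
  sp <- simulate_strain_pair(genes_per_replicon = c(80, 60, 50),
    aa_divergence = 0.05,
    translocations = list(list(from = 1, to = 2, n = 41),
                          list(from = 3, to = 1, n = 25)), seed = 9)
  bbh <- bidirectional_best_hits(sp$a$proteome, sp$b$proteome)
  blocks <- detect_translocated_blocks(bbh, sp$a$genes, sp$b$genes,
                                       sp$partner_map)
  expect_identical(nrow(blocks), 2L)
  expect_setequal(blocks$n_genes, c(41L, 25L))
  expect_identical(
    blocks$replicon_b[match(41L, blocks$n_genes)], "B_rep2")

  none <- simulate_strain_pair(genes_per_replicon = c(30, 20),
                               aa_divergence = 0.05, seed = 10)
  bbh0 <- bidirectional_best_hits(none$a$proteome, none$b$proteome)
  expect_identical(nrow(detect_translocated_blocks(
    bbh0, none$a$genes, none$b$genes, none$partner_map)), 0L)
})

test_that("count_snps counts substitutions and gates non-homologs", {
  s <- random_dna(1500, seed = 12)
  expect_identical(count_snps(s, s), 0L)
  x <- strsplit(s, "")[[1]]
  for (i in c(100, 700, 1200))
    x[i] <- setdiff(c("A", "C", "G", "T"), x[i])[1]
  expect_identical(count_snps(s, paste(x, collapse = "")), 3L)
  expect_error(count_snps(s, random_dna(1500, seed = 99)), "homology gate")
})
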