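# synthetic-genome generators: determinism, composition control, fusion
# and pan-genome ground truth

test_that("generator is deterministic and hits its GC target", {
  spec <- replicon_spec("r", 1e5, 50, signature = "iid",
                        role_truth = "chromosome")
  r1 <- generate_replicon(spec, 42)
  r2 <- generate_replicon(spec, 42)
  expect_identical(r1$sequence, r2$sequence)
  expect_gte(gc_content(r1), 49.7)
  expect_lte(gc_content(r1), 50.3)

  spec2 <- replicon_spec("r", 2e5, 60.9,
                         signature = random_signature(1, 0.1),
                         role_truth = "chromosome")
  expect_lt(abs(gc_content(generate_replicon(spec2, 3)) - 60.9), 0.3)
})

test_that("invalid replicon specs are rejected", {
  expect_error(replicon_spec("r", 0, 50), ">= 1,000")
  expect_error(replicon_spec("r", 1e5, 10), "GC")
  bad_sig <- setNames(rep(0, 16), names(random_signature(1)))
  expect_error(generate_replicon(
    replicon_spec("r", 1e4, 50, signature = bad_sig,
                  role_truth = "chromid"), 1),
    "not normalizable")
})

test_that("mutate_sequence realizes its stated substitution rate", {
  g <- random_dna(1e6, seed = 2)
  expect_identical(mutate_sequence(g, 0, seed = 1)$sequence, g)
  mu <- mutate_sequence(g, 0.05, seed = 3)
  obs <- mu$truth$n_substitutions / 1e6
  expect_lt(abs(obs - 0.05), 0.001)
  expect_identical(mu$truth$identity, 0.95)
  expect_error(mutate_sequence(g, 0.5), "\\[0, 0.5\\)")
})

test_that("cointegrants conserve length and record junction truth", {
  reps <- lapply(1:3, function(i)
    replicon(paste0("r", i), random_dna(c(10000, 20000, 30000)[i],
                                        seed = i)))
  co <- simulate_cointegrant(reps, seed = 5)
  expect_identical(co$replicon$length, 60000L)
  expect_identical(length(co$junctions), 3L)
  expect_identical(nrow(co$segments), 3L)
  expect_setequal(co$segments$source_id, c("r1", "r2", "r3"))

  one <- simulate_cointegrant(reps[1], seed = 1)
  expect_identical(one$replicon$length, 10000L)
  expect_identical(length(one$junctions), 1L)   # circular closure
  expect_error(simulate_cointegrant(list()), "at least one")
})

test_that("cointegration lifts gene coordinates consistently", {
  reps <- lapply(1:2, function(i)
    replicon(paste0("r", i), random_dna(5000, seed = i)))
  genes <- data.frame(gene_id = c("g1", "g2"),
                      replicon_id = c("r1", "r2"),
                      start = c(11L, 101L), end = c(310L, 400L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  co <- simulate_cointegrant(reps, seed = 2, genes = genes)
  lifted <- co$genes
  expect_true(all(lifted$start >= 1 & lifted$end <= co$replicon$length))
  # lifted gene sequences equal the originals (up to strand)
  for (i in seq_len(nrow(lifted))) {
    orig <- genes[genes$gene_id == lifted$gene_id[i], ]
    src <- reps[[match(orig$replicon_id, c("r1", "r2"))]]$sequence
    want <- substr(src, orig$start, orig$end)
    got <- substr(co$replicon$sequence, lifted$start[i], lifted$end[i])
    if (lifted$strand[i] != orig$strand) got <- revcomp(got)
    expect_identical(got, want)
  }
})

test_that("pan-genome simulation honours its truth table", {
  spec <- pangenome_spec(3, 2, n_core = 20, n_A_specific = 5,
                         n_B_specific = 4, n_cloud = 6,
                         aa_divergence_within = 0.05)
  sim <- simulate_pangenome(spec, seed = 7)
  expect_identical(length(sim$proteomes), 5L)
  pres <- sim$presence
  expect_true(all(rowSums(pres[sim$truth$category == "core", ]) == 5))
  a_cols <- names(sim$groups)[sim$groups == "A"]
  b_cols <- names(sim$groups)[sim$groups == "B"]
  asp <- pres[sim$truth$category == "A_specific", , drop = FALSE]
  expect_true(all(asp[, a_cols]) && !any(asp[, b_cols]))
  cl <- pres[sim$truth$category == "cloud", , drop = FALSE]
  expect_true(all(rowSums(cl) >= 1 & rowSums(cl) < 5))
  # realized ortholog divergence matches the requested pairwise value
  core_ids <- sim$truth$cluster_id[sim$truth$category == "core"]
  divs <- vapply(core_ids, function(cid) {
    g <- sim$membership[sim$membership$cluster_id == cid, ]
    s1 <- sim$proteomes[[g$strain[1]]][[g$gene_id[1]]]
    s2 <- sim$proteomes[[g$strain[2]]][[g$gene_id[2]]]
    mean(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(divs) - 0.05), 0.01)

  empty <- simulate_pangenome(pangenome_spec(2, 2, 0, 0, 0, 0), seed = 1)
  expect_true(all(lengths(empty$proteomes) == 0))
})

test_that("same-signature replicons are as close as sampling noise allows", {
  # The DRA distance between two replicons generated from one signature is
  # pure sampling noise; on the x100 scale its floor is ~0.43 at 500 kb
  # (analytic noise model in the vignette), far below genuinely different
  # signatures. Bound: below 1.0 (noise mean + >5 sd), and at least 5x
  # smaller than an independent-signature pair at equal length.
  sig <- random_signature(3, 0.1)
  make <- function(sg, seed) dinucleotide_signature(generate_replicon(
    replicon_spec("r", 5e5, 60, signature = sg, role_truth = "chromid"),
    seed))
  for (seed in 1:3) {
    d_same <- dra_distance(make(sig, seed * 2), make(sig, seed * 2 + 1))
    d_diff <- dra_distance(make(sig, seed * 2),
                           make(random_signature(seed + 50, 0.1), seed))
    expect_lt(d_same, 1.0)
    expect_gt(d_diff, 5 * d_same)
  }
})

test_that("marker sets realize the requested between-group divergence", {
  mk <- simulate_marker_set(20, list(G1 = "s1", G2 = "s2"),
                            aa_divergence_between = 0.14, seed = 9)
  ident <- vapply(mk, function(m)
    mean(strsplit(m[["s1"]], "")[[1]] == strsplit(m[["s2"]], "")[[1]]),
    numeric(1))
  expect_lt(abs(mean(ident) - 0.86), 0.01)
})

test_that("the clade preset emits the stated architecture", {
  sims <- simulate_clade_preset(seed = 2)
  expect_identical(length(sims), 3L)
  expect_identical(nrow(sims$rho_like$truth), 4L)
  expect_identical(nrow(sims$tum1_like$truth), 6L)
  expect_identical(sum(sims$tum1_like$truth$role == "chromid"), 3L)
  expect_identical(replicon_lengths(sims$rho_like$assembly)[[1]], 370969L)
})
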