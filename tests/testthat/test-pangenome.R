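# ortholog clustering, specific-gene logic, compensation, CD-HIT-style
# clustering, demarcation

test_that("identical proteomes cluster one-to-one", {
  prots <- setNames(vapply(1:20, function(i) random_protein(250, i),
                           character(1)), sprintf("p%02d", 1:20))
  cl <- cluster_orthologs(list(s1 = prots, s2 = prots, s3 = prots))
  expect_identical(length(unique(cl$cluster_id)), 20L)
  expect_true(all(table(cl$cluster_id) == 3))
})

test_that("clustering recovers the simulated pan-genome exactly", {
  sim <- simulate_pangenome(pangenome_spec(3, 2, n_core = 30,
                                           n_A_specific = 8,
                                           n_B_specific = 6,
                                           aa_divergence_within = 0.05),
                            seed = 19)
  cl <- cluster_orthologs(sim$proteomes)
  expect_identical(length(unique(cl$cluster_id)), 44L)
  # cluster membership matches the generating truth table
  key <- setNames(sim$membership$cluster_id, sim$membership$gene_id)
  for (cid in unique(cl$cluster_id)) {
    members <- cl$gene_id[cl$cluster_id == cid]
    expect_identical(length(unique(key[members])), 1L)
  }
  # singleton gene forms a singleton cluster
  pro2 <- sim$proteomes
  pro2$A01 <- c(pro2$A01, lone = random_protein(260, 777))
  cl2 <- cluster_orthologs(pro2)
  lone_cid <- cl2$cluster_id[cl2$gene_id == "lone"]
  expect_identical(sum(cl2$cluster_id == lone_cid), 1L)
})

test_that("specific-gene logic uses strict quantifiers", {
  sim <- simulate_pangenome(pangenome_spec(3, 2, n_core = 20,
                                           n_A_specific = 10,
                                           n_B_specific = 10,
                                           aa_divergence_within = 0.05),
                            seed = 23)
  cl <- cluster_orthologs(sim$proteomes)
  rep_ <- core_and_specific(cl, sim$groups)
  expect_identical(length(rep_$core), 20L)
  expect_identical(nrow(rep_$specific$A), 10L)
  expect_identical(nrow(rep_$specific$B), 10L)

  # remove one A-specific gene from one A strain: that cluster drops out
  key <- sim$membership
  drop_gene <- key$gene_id[key$strain == "A01" &
                             key$category == "A_specific"][1]
  cl_drop <- cl[!(cl$strain == "A01" & cl$gene_id == drop_gene), ]
  rep2 <- core_and_specific(cl_drop, sim$groups)
  expect_identical(nrow(rep2$specific$A), 9L)

  expect_error(core_and_specific(cl, sim$groups[-1]),
               "without group assignment")
})

test_that("all-shared simulations yield zero specific clusters", {
  sim <- simulate_pangenome(pangenome_spec(2, 2, n_core = 15,
                                           n_A_specific = 0,
                                           n_B_specific = 0,
                                           aa_divergence_within = 0.03),
                            seed = 29)
  rep_ <- core_and_specific(cluster_orthologs(sim$proteomes), sim$groups)
  expect_identical(nrow(rep_$specific$A), 0L)
  expect_identical(nrow(rep_$specific$B), 0L)
})

test_that("specificity is anti-monotone in group size", {
  sim <- simulate_pangenome(pangenome_spec(3, 2, n_core = 10,
                                           n_A_specific = 6,
                                           n_B_specific = 0, n_cloud = 10,
                                           aa_divergence_within = 0.05),
                            seed = 31)
  cl <- cluster_orthologs(sim$proteomes)
  rep_small <- core_and_specific(cl[cl$strain != "A03", ],
                                 sim$groups[names(sim$groups) != "A03"])
  rep_full <- core_and_specific(cl, sim$groups)
  expect_true(all(rep_full$specific$A$cluster_id %in%
                    rep_small$specific$A$cluster_id))
})

test_that("compensation check flags planted divergent homologs", {
  sim <- simulate_pangenome(pangenome_spec(2, 2, n_core = 5,
                                           n_A_specific = 3,
                                           n_B_specific = 0,
                                           aa_divergence_between = 0.55,
                                           n_compensated = 2), seed = 8)
  memb <- sim$membership
  rep_of <- function(i) {
    gid <- memb$gene_id[memb$strain == "A01" &
                          memb$category == "A_specific"][i]
    sim$proteomes$A01[[gid]]
  }
  others <- sim$proteomes[c("B01", "B02")]
  cc1 <- compensation_check(rep_of(1), others)
  expect_identical(cc1$status, "compensated")
  expect_gt(cc1$best_hit$identity, 0.3)
  cc3 <- compensation_check(rep_of(3), others)   # not compensated
  expect_identical(cc3$status, "not_found")
  # monotone gates: raising min_identity never flips not_found
  cc1_hi <- compensation_check(rep_of(1), others, min_identity = 0.9)
  expect_identical(cc1_hi$status, "not_found")
})

test_that("greedy identity clustering behaves like CD-HIT at 90%", {
  p1 <- random_protein(200, 1)
  fam1 <- c(a = p1, b = mutate_protein(p1, 0.05, 2),
            c = mutate_protein(p1, 0.08, 3))
  p2 <- mutate_protein(p1, 0.5, 4)   # ~50% cross-identity family
  fam2 <- c(d = p2, e = mutate_protein(p2, 0.05, 5))
  cl <- greedy_identity_clustering(c(fam1, fam2), 0.9)
  expect_identical(length(cl), 2L)
  expect_setequal(unlist(cl), c("a", "b", "c", "d", "e"))

  same <- c(x = p1, y = p1, z = p1)
  expect_identical(length(greedy_identity_clustering(same, 0.9)), 1L)
  distinct <- c(u = random_protein(150, 7), v = random_protein(150, 8))
  expect_identical(length(greedy_identity_clustering(distinct, 1.0)), 2L)
})

test_that("demarcation applies the ANI and cpAAI thresholds", {
  labs <- c("A", "B", "C")
  ani <- matrix(c(100, 97, 93, 97, 100, 93, 93, 93, 100), 3, 3,
                dimnames = list(labs, labs))
  rep_ <- demarcate(ani)
  expect_setequal(lapply(rep_$species, sort), list(c("A", "B"), "C"))

  # 96.8 is above the species threshold: same species
  ani2 <- ani; ani2["A", "B"] <- ani2["B", "A"] <- 96.8
  expect_setequal(lapply(demarcate(ani2)$species, sort),
                  list(c("A", "B"), "C"))

  # a pair in the 95-96 window is flagged ambiguous, not merged
  ani3 <- ani; ani3["A", "B"] <- ani3["B", "A"] <- 95.5
  rep3 <- demarcate(ani3)
  expect_identical(length(rep3$species), 3L)
  expect_identical(nrow(rep3$species_ambiguous_pairs), 1L)
})

test_that("a taxon bridging two genus components is flagged", {
  labs <- c("t1", "t2", "r1", "r2", "bridge")
  cp <- matrix(80, 5, 5, dimnames = list(labs, labs))
  diag(cp) <- 100
  cp["t1", "t2"] <- cp["t2", "t1"] <- 95
  cp["r1", "r2"] <- cp["r2", "r1"] <- 95
  cp["bridge", "t1"] <- cp["t1", "bridge"] <- 86.9
  cp["bridge", "r1"] <- cp["r1", "bridge"] <- 86.8
  ani <- matrix(80, 5, 5, dimnames = list(labs, labs)); diag(ani) <- 100
  rep_ <- demarcate(ani, cp)
  expect_identical(rep_$genus_ambiguous_taxa, "bridge")
  expect_identical(length(rep_$genus), 1L)   # single linkage merges via bridge

  # species spanning two genera is an error
  ani_bad <- ani; ani_bad["t1", "r1"] <- ani_bad["r1", "t1"] <- 99
  cp2 <- cp; cp2["bridge", "t1"] <- cp2["t1", "bridge"] <- 80
  cp2["bridge", "r1"] <- cp2["r1", "bridge"] <- 80
  expect_error(demarcate(ani_bad, cp2), "spans multiple genus")
})
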