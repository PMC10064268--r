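# Synthetic multipartite genomes with known ground truth. Sequence-level
# generators use a first-order Markov chain (dinucleotide-level control is
# all the DRA signature needs); protein-level generators control pairwise
# amino-acid divergence exactly (single-branch mutation, no reversions).

# Evaluate expr under a local RNG seed, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.BASES <- c("A", "C", "G", "T")
.DINUCS <- as.vector(outer(.BASES, .BASES, paste0))
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of a dinucleotide name
.rc_dinuc <- function(d) {
  paste0(.COMP[substr(d, 2, 2)], .COMP[substr(d, 1, 1)])
}

#' Draw a strand-symmetry-consistent dinucleotide signature
#'
#' Samples relative abundances `rho*_XY` for the 10 free dinucleotide cells
#' (the other 6 are fixed by `rho*_XY = rho*_comp(Y)comp(X)`), as
#' `1 + N(0, sd)` with the CG and TA cells biased low, the way bacterial
#' genomes tend to be. Used for "independent" (megaplasmid-like) signatures
#' and as a realistic chromosome signature.
#'
#' @param seed Integer seed.
#' @param sd Spread of the deviations from 1 (default 0.12).
#' @return A `dinuc_signature` 16-vector.
#' @export
random_signature <- function(seed, sd = 0.12) {
  .with_seed(seed, {
    rho <- setNames(rep(NA_real_, 16), .DINUCS)
    for (d in .DINUCS) {
      if (!is.na(rho[d])) next
      base_mean <- if (d %in% c("CG", "TA")) 0.8 else 1
      val <- max(0.15, base_mean + stats::rnorm(1, 0, sd))
      rho[d] <- val
      rho[.rc_dinuc(d)] <- val
    }
    structure(as.numeric(rho), names = .DINUCS, class = "dinuc_signature")
  })
}

# Stationary distribution of a 4x4 stochastic matrix (power iteration).
.stationary <- function(P, iter = 200L) {
  v <- rep(0.25, 4)
  for (i in seq_len(iter)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# Build a Markov transition matrix whose stationary dinucleotide frequencies
# approximate the requested signature at the requested GC. Base frequencies
# are strand-symmetric (fA = fT, fC = fG) and iterated so the realized
# stationary GC matches the target.
.signature_to_transition <- function(rho, target_gc) {
  rho <- setNames(as.numeric(rho), .DINUCS)
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("infeasible signature: negative or non-finite relative abundance")
  gc <- target_gc / 100
  fC <- gc / 2
  for (it in 1:40) {
    f <- c(A = (1 - 2 * fC) / 2, C = fC, G = fC, T = (1 - 2 * fC) / 2)
    q <- rho * f[substr(.DINUCS, 1, 1)] * f[substr(.DINUCS, 2, 2)]
    M <- matrix(q, 4, 4, dimnames = list(.BASES, .BASES))
    rs <- rowSums(M)
    if (any(rs == 0)) {
      bad <- .DINUCS[substr(.DINUCS, 1, 1) == .BASES[which(rs == 0)[1]]]
      stop("infeasible signature: transition row for dinucleotides ",
           paste(bad, collapse = ","), " is not normalizable")
    }
    P <- M / rs
    pi_ <- .stationary(P)
    gc_real <- pi_[2] + pi_[3]
    if (abs(gc_real - gc) < 1e-6) break
    fC <- max(1e-4, min(0.4999, fC * gc / gc_real))
  }
  list(P = P, init = pi_)
}

#' Specify a synthetic replicon
#'
#' @param id Replicon id.
#' @param length Length in bp (>= 1000).
#' @param target_gc Target GC percent (20-80).
#' @param signature `"random"` (an independent signature drawn from the
#'   seed), `"iid"` (all relative abundances 1), or an explicit 16-vector
#'   (e.g. the chromosome's, for a shared chromid-like signature).
#' @param role_truth Ground-truth role: `"chromosome"`, `"chromid"` or
#'   `"megaplasmid"`.
#' @return A `replicon_spec` list.
#' @export
replicon_spec <- function(id, length, target_gc, signature = "random",
                          role_truth = c("chromosome", "chromid",
                                         "megaplasmid")) {
  role_truth <- match.arg(role_truth)
  if (length < 1000) stop("replicon length must be >= 1,000 bp")
  if (target_gc < 20 || target_gc > 80)
    stop("target GC must be within [20, 80]")
  structure(list(id = id, length = as.integer(length),
                 target_gc = target_gc, signature = signature,
                 role_truth = role_truth),
            class = "replicon_spec")
}

#' Generate a replicon from a spec
#'
#' The sequence is sampled from a first-order Markov chain whose stationary
#' dinucleotide frequencies match the requested signature and GC; realized
#' GC is within about +/-0.3 percentage points of target for lengths
#' >= 100 kb.
#'
#' @param spec A [replicon_spec()].
#' @param seed Integer seed.
#' @return A [replicon()], with the spec attached as attribute `"spec"`.
#' @export
generate_replicon <- function(spec, seed) {
  stopifnot(inherits(spec, "replicon_spec"))
  sig <- spec$signature
  if (identical(sig, "random")) sig <- random_signature(seed * 131L %% .Machine$integer.max)
  if (identical(sig, "iid")) sig <- setNames(rep(1, 16), .DINUCS)
  if (length(sig) != 16) stop("signature must be 'random', 'iid' or a 16-vector")
  tm <- .signature_to_transition(sig, spec$target_gc)
  seq <- .with_seed(seed, .markov_chain_cpp(spec$length, tm$init, tm$P))
  r <- replicon(spec$id, seq)
  attr(r, "spec") <- spec
  r
}

#' Mutate a DNA sequence with known ground truth
#'
#' Each site is substituted, independently, to a uniformly chosen different
#' base with probability `substitution_rate`; single-base insertions and
#' deletions occur at `indel_rate` (default 0 so the ground-truth identity
#' `1 - substitution_rate` is exact).
#'
#' @param seq DNA string or `replicon`.
#' @param substitution_rate Per-site substitution probability in `[0, 0.5)`.
#' @param indel_rate Per-site single-base indel probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `sequence` and a `truth` list (`substitution_rate`,
#'   `identity`, `n_substitutions`, `n_insertions`, `n_deletions`).
#' @export
mutate_sequence <- function(seq, substitution_rate, indel_rate = 0, seed = 1L) {
  seq <- .as_dna_string(seq)
  for (r in c(substitution_rate, indel_rate))
    if (r < 0 || r >= 0.5) stop("rates must lie in [0, 0.5)")
  .with_seed(seed, {
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(x)
    hit <- which(stats::runif(n) < substitution_rate)
    if (length(hit)) {
      cur <- match(x[hit], .BASES)
      off <- sample.int(3L, length(hit), replace = TRUE)
      x[hit] <- .BASES[((cur - 1L + off) %% 4L) + 1L]
    }
    n_ins <- 0L; n_del <- 0L
    if (indel_rate > 0) {
      del <- stats::runif(length(x)) < indel_rate / 2
      n_del <- sum(del)
      x <- x[!del]
      ins_at <- which(stats::runif(length(x)) < indel_rate / 2)
      n_ins <- length(ins_at)
      if (n_ins) {
        pieces <- sample(.BASES, n_ins, replace = TRUE)
        out <- character(length(x) + n_ins)
        idx <- sort(c(seq_along(x), ins_at + 0.5))
        out <- x
        for (k in rev(seq_along(ins_at)))
          out <- append(out, pieces[k], after = ins_at[k])
        x <- out
      }
    }
    list(sequence = paste(x, collapse = ""),
         truth = list(substitution_rate = substitution_rate,
                      identity = 1 - substitution_rate,
                      n_substitutions = length(hit),
                      n_insertions = n_ins, n_deletions = n_del))
  })
}

#' Fuse replicons into a cointegrant with junction ground truth
#'
#' Concatenates the replicons in randomized order and orientation into one
#' circular replicon, recording segment boundaries and junction coordinates,
#' and lifting gene coordinates over when a gene table is supplied.
#'
#' @param replicons List of [replicon()] (length >= 1).
#' @param seed Integer seed (controls order and orientation).
#' @param genes Optional gene table on the input replicons.
#' @param id Id of the fused replicon.
#' @return List with `replicon`, `segments` (source_id, start, end,
#'   orientation), `junctions` (positions, bp), and `genes` (lifted, with a
#'   `source_replicon` column) when supplied.
#' @export
simulate_cointegrant <- function(replicons, seed = 1L, genes = NULL,
                                 id = "cointegrant") {
  if (!length(replicons)) stop("need at least one replicon to fuse")
  ord_flip <- .with_seed(seed, list(
    ord = sample(length(replicons)),
    flip = stats::runif(length(replicons)) < 0.5))
  reps <- replicons[ord_flip$ord]
  flip <- ord_flip$flip
  lens <- vapply(reps, `[[`, integer(1), "length")
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  have_seq <- all(!vapply(reps, function(r) is.null(r$sequence), logical(1)))
  seqs <- NULL
  if (have_seq) {
    seqs <- vapply(seq_along(reps), function(i) {
      s <- reps[[i]]$sequence
      if (flip[i])
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    }, character(1))
  }
  segments <- data.frame(
    source_id = vapply(reps, `[[`, character(1), "id"),
    start = starts, end = ends,
    orientation = ifelse(flip, "-", "+"), stringsAsFactors = FALSE)
  junctions <- sort(unique(c(1L, starts)))   # includes the circular closure
  fused <- if (have_seq) replicon(id, paste(seqs, collapse = "")) else
    replicon(id, length = sum(lens))

  lifted <- NULL
  if (!is.null(genes)) {
    genes <- gene_table(genes)
    lifted <- do.call(rbind, lapply(seq_along(reps), function(i) {
      g <- genes[genes$replicon_id == reps[[i]]$id, , drop = FALSE]
      if (!nrow(g)) return(NULL)
      L <- lens[i]; off <- starts[i] - 1L
      if (flip[i]) {
        new_start <- off + L - g$end + 1L
        new_end <- off + L - g$start + 1L
        g$strand <- ifelse(g$strand == "+", "-", "+")
        g$start <- new_start; g$end <- new_end
      } else {
        g$start <- g$start + off; g$end <- g$end + off
      }
      g$source_replicon <- g$replicon_id
      g$replicon_id <- id
      g
    }))
    lifted <- lifted[order(lifted$start), , drop = FALSE]
    rownames(lifted) <- NULL
  }
  list(replicon = fused, segments = segments, junctions = junctions,
       genes = lifted)
}

# ---- protein-level simulation ------------------------------------------

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random protein sequence
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Amino-acid string starting with M.
#' @export
random_protein <- function(length = 300L, seed = 1L) {
  .with_seed(seed, paste0("M", paste(sample(.AA20, length - 1L, replace = TRUE),
                                     collapse = "")))
}

#' Mutate a protein to an exact target divergence rate
#'
#' Each site is replaced with probability `divergence` by a uniformly chosen
#' *different* residue, so the realized identity to the input is
#' `1 - divergence` in expectation with no back-substitutions.
#'
#' @param aa Amino-acid string.
#' @param divergence Per-site replacement probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(aa, divergence, seed = 1L) {
  if (divergence < 0 || divergence >= 1) stop("divergence must lie in [0, 1)")
  if (divergence == 0) return(aa)
  .with_seed(seed, {
    x <- strsplit(aa, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(x)) < divergence)
    if (length(hit)) {
      repl <- vapply(x[hit], function(cur)
        sample(setdiff(.AA20, cur), 1L), character(1))
      x[hit] <- repl
    }
    paste(x, collapse = "")
  })
}

#' Specify a two-species pan-genome simulation
#'
#' @param n_strains_A,n_strains_B Strains per group.
#' @param n_core Clusters present in every strain.
#' @param n_A_specific,n_B_specific Clusters present in all strains of one
#'   group and absent from all strains of the other.
#' @param n_cloud Clusters present in a random proper subset of strains.
#' @param aa_divergence_within Pairwise amino-acid divergence between
#'   orthologs within a cluster (default 0.02).
#' @param aa_divergence_between Divergence of planted cross-group
#'   compensation homologs (default 0.5).
#' @param n_compensated Number of A-specific clusters that get a divergent
#'   homolog planted in every B strain (outside the cluster truth).
#' @param protein_length Residues per protein (default 300).
#' @return A `pangenome_spec` list.
#' @export
pangenome_spec <- function(n_strains_A, n_strains_B, n_core = 50L,
                           n_A_specific = 10L, n_B_specific = 10L,
                           n_cloud = 0L, aa_divergence_within = 0.02,
                           aa_divergence_between = 0.5,
                           n_compensated = 0L, protein_length = 300L) {
  stopifnot(n_strains_A >= 1, n_strains_B >= 1,
            n_core >= 0, n_A_specific >= 0, n_B_specific >= 0, n_cloud >= 0,
            aa_divergence_within >= 0, aa_divergence_within < 1,
            aa_divergence_between >= 0, aa_divergence_between < 1,
            n_compensated <= n_A_specific)
  structure(as.list(environment()), class = "pangenome_spec")
}

# per-branch rate q such that two independent branches at q give expected
# pairwise divergence d (replacement to a uniform different residue, 19
# alternatives: P(match) = (1-q)^2 + q^2/19)
.branch_rate <- function(d) {
  if (d == 0) return(0)
  a <- 1 + 1 / 19
  (1 - sqrt(1 - a * d)) / a
}

#' Simulate a two-species pan-genome with a truth table
#'
#' Every core cluster is present in all strains; group-specific clusters are
#' present in all strains of their group and absent from the other; cloud
#' clusters land in random proper subsets. Orthologs within a cluster are
#' pairwise diverged by `aa_divergence_within`. Optionally, divergent
#' homologs of the first `n_compensated` A-specific clusters are planted in
#' all B strains (at `aa_divergence_between`), emulating functional
#' compensation by a divergent gene.
#'
#' @param spec A [pangenome_spec()].
#' @param seed Integer seed.
#' @return List: `proteomes` (named list of named character vectors),
#'   `membership` (strain, gene_id, cluster_id, category), `truth`
#'   (cluster_id, category, presence count), `strains`, `groups` (named
#'   vector strain -> "A"/"B").
#' @export
simulate_pangenome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pangenome_spec"))
  strains_A <- sprintf("A%02d", seq_len(spec$n_strains_A))
  strains_B <- sprintf("B%02d", seq_len(spec$n_strains_B))
  strains <- c(strains_A, strains_B)
  groups <- setNames(rep(c("A", "B"), c(length(strains_A), length(strains_B))),
                     strains)
  n_clusters <- spec$n_core + spec$n_A_specific + spec$n_B_specific +
    spec$n_cloud
  category <- rep(c("core", "A_specific", "B_specific", "cloud"),
                  c(spec$n_core, spec$n_A_specific, spec$n_B_specific,
                    spec$n_cloud))
  cluster_id <- sprintf("C%04d", seq_len(n_clusters))
  q <- .branch_rate(spec$aa_divergence_within)

  .with_seed(seed, {
    roots <- vapply(seq_len(n_clusters), function(i)
      random_protein(spec$protein_length,
                     seed = sample.int(.Machine$integer.max, 1)),
      character(1))
    presence <- matrix(FALSE, n_clusters, length(strains),
                       dimnames = list(cluster_id, strains))
    presence[category == "core", ] <- TRUE
    presence[category == "A_specific", strains_A] <- TRUE
    presence[category == "B_specific", strains_B] <- TRUE
    for (i in which(category == "cloud")) {
      k <- sample(seq_len(length(strains) - 1L), 1L)
      presence[i, sample(strains, k)] <- TRUE
    }
    proteomes <- setNames(vector("list", length(strains)), strains)
    membership <- list()
    for (s in strains) {
      idx <- which(presence[, s])
      if (!length(idx)) {
        proteomes[[s]] <- setNames(character(0), character(0))
        membership[[s]] <- data.frame(strain = character(0),
                                      gene_id = character(0),
                                      cluster_id = character(0),
                                      category = character(0),
                                      stringsAsFactors = FALSE)
        next
      }
      gid <- sprintf("%s_g%04d", s, idx)
      aa <- vapply(idx, function(i)
        mutate_protein(roots[i], q, seed = sample.int(.Machine$integer.max, 1)),
        character(1))
      proteomes[[s]] <- setNames(aa, gid)
      membership[[s]] <- data.frame(strain = s, gene_id = gid,
                                    cluster_id = cluster_id[idx],
                                    category = category[idx],
                                    stringsAsFactors = FALSE)
    }
    # planted compensation homologs (divergent, outside the cluster truth)
    if (spec$n_compensated > 0) {
      comp_idx <- which(category == "A_specific")[seq_len(spec$n_compensated)]
      for (s in strains_B) {
        gid <- sprintf("%s_comp%04d", s, comp_idx)
        aa <- vapply(comp_idx, function(i)
          mutate_protein(roots[i], spec$aa_divergence_between,
                         seed = sample.int(.Machine$integer.max, 1)),
          character(1))
        proteomes[[s]] <- c(proteomes[[s]], setNames(aa, gid))
        membership[[s]] <- rbind(membership[[s]],
          data.frame(strain = s, gene_id = gid,
                     cluster_id = paste0(cluster_id[comp_idx], "_homolog"),
                     category = "compensation_homolog",
                     stringsAsFactors = FALSE))
      }
    }
    membership <- do.call(rbind, membership)
    rownames(membership) <- NULL
    truth <- data.frame(cluster_id = cluster_id, category = category,
                        n_present = rowSums(presence),
                        stringsAsFactors = FALSE)
    list(proteomes = proteomes, membership = membership, truth = truth,
         presence = presence, strains = strains, groups = groups)
  })
}

#' Simulate a marker-protein set for cpAAI tests
#'
#' One protein per strain per marker. Strains within a group carry identical
#' copies (plus optional within-group divergence); group B's copies are
#' diverged from group A's by exactly `aa_divergence_between` per site, so
#' the expected between-group identity is `1 - aa_divergence_between`.
#'
#' @param n_markers Number of markers.
#' @param groups Named list: group label -> character vector of strain ids.
#' @param aa_divergence_between Between-group per-site divergence.
#' @param aa_divergence_within Pairwise within-group divergence (default 0).
#' @param protein_length Residues per marker (default 350).
#' @param seed Integer seed.
#' @return Named list marker_id -> named character vector (strain -> aa).
#' @export
simulate_marker_set <- function(n_markers, groups, aa_divergence_between,
                                aa_divergence_within = 0,
                                protein_length = 350L, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1)
  qw <- .branch_rate(aa_divergence_within)
  .with_seed(seed, {
    out <- setNames(vector("list", n_markers),
                    sprintf("M%03d", seq_len(n_markers)))
    for (m in names(out)) {
      root <- random_protein(protein_length,
                             seed = sample.int(.Machine$integer.max, 1))
      anc <- list()
      anc[[names(groups)[1]]] <- root
      for (g in names(groups)[-1])
        anc[[g]] <- mutate_protein(root, aa_divergence_between,
                                   seed = sample.int(.Machine$integer.max, 1))
      per_strain <- character(0)
      for (g in names(groups)) for (s in groups[[g]]) {
        aa <- if (qw > 0)
          mutate_protein(anc[[g]], qw,
                         seed = sample.int(.Machine$integer.max, 1))
        else anc[[g]]
        per_strain[s] <- aa
      }
      out[[m]] <- per_strain
    }
    out
  })
}

# ---- multipartite genome / strain-pair simulation -----------------------

#' Simulate one multipartite genome with role ground truth
#'
#' Defaults mirror the architecture of the sequenced genomes (a ~3-Mb
#' chromosome at GC 60.9, Mb-scale chromids sharing the chromosome's
#' dinucleotide signature with GC within +/-0.6 points, and megaplasmids
#' with independent signatures at GC 3-4.5 points below the chromosome).
#' Chromid sizes default to >= 1 Mb because below ~500 kb the sampling-noise
#' floor of the DRA distance approaches the 0.4 classification threshold
#' (see the methods vignette).
#'
#' @param seed Integer seed.
#' @param sizes Named vector of replicon sizes (names are roles:
#'   `chromosome`, `chromid`, `megaplasmid`; roles may repeat).
#' @param chromosome_gc Chromosome GC percent (default 60.9).
#' @return List: `assembly` (a `genome_assembly`), `truth` (data frame
#'   replicon_id, role).
#' @export
simulate_multipartite_genome <- function(seed = 1L,
    sizes = c(chromosome = 3e6, chromid = 1.5e6, chromid = 1e6,
              megaplasmid = 5e5),
    chromosome_gc = 60.9) {
  roles <- names(sizes)
  stopifnot(sum(roles == "chromosome") == 1)
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max,
                                       length(sizes) + 1L))
  chrom_sig <- random_signature(seeds[length(seeds)], sd = 0.10)
  gc_off <- .with_seed(seed + 7L, stats::runif(length(sizes), -0.6, 0.6))
  mp_off <- .with_seed(seed + 11L, stats::runif(length(sizes), -4.5, -2.5))
  reps <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    role <- roles[i]
    id <- sprintf("%s_%d", role, i)
    spec <- switch(role,
      chromosome = replicon_spec(id, sizes[i], chromosome_gc,
                                 signature = chrom_sig,
                                 role_truth = "chromosome"),
      chromid = replicon_spec(id, sizes[i], chromosome_gc + gc_off[i],
                              signature = chrom_sig, role_truth = "chromid"),
      megaplasmid = replicon_spec(id, sizes[i], chromosome_gc + mp_off[i],
                                  signature = random_signature(seeds[i], sd = 0.12),
                                  role_truth = "megaplasmid"),
      stop("unknown role: ", role))
    reps[[i]] <- generate_replicon(spec, seeds[i])
  }
  asm <- genome_assembly(sprintf("sim%d", seed), reps)
  truth <- data.frame(
    replicon_id = vapply(reps, `[[`, character(1), "id"),
    role = roles, stringsAsFactors = FALSE)
  list(assembly = asm, truth = truth)
}

#' Simulate an orthologous strain pair with rearrangement ground truth
#'
#' Strain A carries `genes_per_replicon` genes on each of several replicons
#' (sequence-free stubs; protein sequences are authoritative). Strain B
#' carries one ortholog per gene at exact pairwise amino-acid divergence
#' `aa_divergence`, on the corresponding partner replicon, except for
#' requested translocated blocks (runs of consecutive genes moved to a
#' different partner replicon); optionally B's replicons are fused into a
#' single cointegrant.
#'
#' @param genes_per_replicon Integer vector; one entry per replicon.
#' @param aa_divergence Pairwise ortholog divergence (default 0.05).
#' @param translocations List of `list(from=i, to=j, n=k)` blocks: the last
#'   `k` genes of B's replicon `i` are moved to B's replicon `j`.
#' @param cointegrate Fuse all of strain B's replicons into one (default
#'   FALSE).
#' @param protein_length Residues per protein.
#' @param gene_spacing Gene footprint in bp (start-to-start).
#' @param seed Integer seed.
#' @return List: `a`, `b` (genome assemblies with genes + proteomes),
#'   `ortholog_truth` (gene_a, gene_b), `translocation_truth`,
#'   `cointegrant` (output of [simulate_cointegrant()] or NULL).
#' @export
simulate_strain_pair <- function(genes_per_replicon = c(60, 40, 30),
                                 aa_divergence = 0.05,
                                 translocations = list(),
                                 cointegrate = FALSE,
                                 protein_length = 300L,
                                 gene_spacing = 1200L, seed = 1L) {
  nrep <- length(genes_per_replicon)
  rep_a <- sprintf("A_rep%d", seq_len(nrep))
  rep_b <- sprintf("B_rep%d", seq_len(nrep))

  make_genes <- function(rep_ids, counts, prefix) {
    do.call(rbind, lapply(seq_along(rep_ids), function(i) {
      n <- counts[i]
      if (!n) return(NULL)
      start <- (seq_len(n) - 1L) * gene_spacing + 1L
      data.frame(gene_id = sprintf("%s_r%d_g%03d", prefix, i, seq_len(n)),
                 replicon_id = rep_ids[i], start = start,
                 end = start + 3L * protein_length - 1L,
                 strand = "+", product = "", stringsAsFactors = FALSE)
    }))
  }
  genes_a <- make_genes(rep_a, genes_per_replicon, "a")

  seeds <- .with_seed(seed, sample.int(.Machine$integer.max,
                                       2L * nrow(genes_a)))
  prot_a <- setNames(vapply(seq_len(nrow(genes_a)), function(i)
    random_protein(protein_length, seeds[i]), character(1)), genes_a$gene_id)
  prot_b_seq <- vapply(seq_len(nrow(genes_a)), function(i)
    mutate_protein(prot_a[[i]], aa_divergence, seeds[nrow(genes_a) + i]),
    character(1))

  # B gene layout: same order as A on partner replicons, then translocations
  genes_b <- genes_a
  genes_b$gene_id <- sub("^a_", "b_", genes_a$gene_id)
  genes_b$replicon_id <- rep_b[match(genes_a$replicon_id, rep_a)]
  names(prot_b_seq) <- genes_b$gene_id

  transloc_truth <- NULL
  for (tr in translocations) {
    src <- rep_b[tr$from]; dst <- rep_b[tr$to]
    on_src <- which(genes_b$replicon_id == src)
    if (length(on_src) < tr$n) stop("translocation block larger than source")
    block <- tail(on_src, tr$n)
    genes_b$replicon_id[block] <- dst
    transloc_truth <- rbind(transloc_truth, data.frame(
      from = src, to = dst, n = tr$n,
      gene_ids = I(list(genes_b$gene_id[block])), stringsAsFactors = FALSE))
  }
  # re-assign coordinates per B replicon in current row order
  for (rb in rep_b) {
    idx <- which(genes_b$replicon_id == rb)
    st <- (seq_along(idx) - 1L) * gene_spacing + 1L
    genes_b$start[idx] <- st
    genes_b$end[idx] <- st + 3L * protein_length - 1L
  }

  stub_len <- function(genes, rid)
    max(gene_spacing, max(c(0L, genes$end[genes$replicon_id == rid])) + 100L)
  reps_a <- lapply(rep_a, function(r) replicon(r, length = stub_len(genes_a, r)))
  reps_b <- lapply(rep_b, function(r) replicon(r, length = stub_len(genes_b, r)))

  coint <- NULL
  if (cointegrate) {
    coint <- simulate_cointegrant(reps_b, seed = seed + 13L, genes = genes_b,
                                  id = "B_cointegrant")
    genes_b <- coint$genes[, c("gene_id", "replicon_id", "start", "end",
                               "strand", "product", "source_replicon")]
    reps_b <- list(coint$replicon)
  }

  a <- genome_assembly("strainA", reps_a,
                       genes_a, prot_a)
  b <- genome_assembly("strainB", reps_b,
                       genes_b[, c("gene_id", "replicon_id", "start", "end",
                                   "strand", "product")],
                       prot_b_seq)
  list(a = a, b = b,
       ortholog_truth = data.frame(gene_a = genes_a$gene_id,
                                   gene_b = genes_b$gene_id,
                                   stringsAsFactors = FALSE),
       translocation_truth = transloc_truth,
       cointegrant = coint,
       partner_map = setNames(if (cointegrate)
         rep("B_cointegrant", nrep) else rep_b, rep_a),
       genes_b_source = if (cointegrate) coint$genes else NULL)
}

#' Three-strain toy preset mirroring the sequenced clade's architecture
#'
#' Emits genomes with the replicon inventory of the study's Table-2-like
#' architecture scaled down 10x (one 4-replicon strain with a large
#' cointegrant-like chromid, two 6-replicon strains). At this scale the DRA
#' criterion is dominated by sampling noise (see the methods vignette);
#' the preset exists as a fast end-to-end demo, not as the recovery
#' benchmark.
#'
#' @param seed Integer seed.
#' @param scale Size scale factor (default 0.1).
#' @return Named list of `simulate_multipartite_genome()` results.
#' @export
simulate_clade_preset <- function(seed = 1L, scale = 0.1) {
  arch <- list(
    rho_like = c(chromosome = 3709686, chromid = 1530638,
                 megaplasmid = 381845, chromid = 336962),
    tum1_like = c(chromosome = 3664408, megaplasmid = 834411,
                  megaplasmid = 439071, chromid = 432998,
                  chromid = 304572, chromid = 302267),
    tum2_like = c(chromosome = 3816680, megaplasmid = 756443,
                  megaplasmid = 430508, chromid = 339618,
                  chromid = 319653, chromid = 304177))
  out <- list()
  for (i in seq_along(arch)) {
    sizes <- pmax(round(arch[[i]] * scale), 1000)
    out[[names(arch)[i]]] <-
      simulate_multipartite_genome(seed = seed + i, sizes = sizes)
  }
  out
}
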