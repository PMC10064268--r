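# Pan-genome clustering, species-specific gene reporting, compensation
# checks, CD-HIT-style clustering, and species/genus demarcation.

#' Cluster orthologs across strains via BBH graph components
#'
#' BBH edges are computed for every strain pair; clusters are the connected
#' components of the resulting graph. A component that chains together two
#' or more genes of one strain is split greedily: edges are removed from
#' weakest to strongest until every component carries at most one gene per
#' strain (each gene effectively keeps only its strongest link per partner
#' strain).
#'
#' @param proteomes Named list (strain -> named character vector).
#' @param evalue_max,min_coverage BBH gates (defaults 1e-100 and 0.75).
#' @return Data frame: `cluster_id, strain, gene_id`.
#' @export
cluster_orthologs <- function(proteomes, evalue_max = 1e-100,
                              min_coverage = 0.75) {
  stopifnot(is.list(proteomes), length(proteomes) >= 2,
            !is.null(names(proteomes)))
  strains <- names(proteomes)
  edges <- list()
  for (i in seq_len(length(strains) - 1)) for (j in (i + 1):length(strains)) {
    bbh <- bidirectional_best_hits(proteomes[[i]], proteomes[[j]],
                                   evalue_max = evalue_max,
                                   min_coverage = min_coverage)
    if (nrow(bbh))
      edges[[length(edges) + 1L]] <- data.frame(
        from = paste0(strains[i], "|", bbh$gene_a),
        to = paste0(strains[j], "|", bbh$gene_b),
        weight = bbh$raw_score, stringsAsFactors = FALSE)
  }
  all_genes <- unlist(lapply(strains, function(s)
    paste0(s, "|", names(proteomes[[s]]))))
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0)),
    directed = FALSE, vertices = data.frame(name = all_genes))

  strain_of <- function(v) sub("\\|.*$", "", v)
  repeat {
    comp <- igraph::components(g)
    memb <- comp$membership
    dup <- FALSE
    for (ci in seq_len(comp$no)) {
      vs <- names(memb)[memb == ci]
      if (anyDuplicated(strain_of(vs))) { dup <- TRUE; break }
    }
    if (!dup) break
    sub <- igraph::induced_subgraph(g, vs)
    w <- igraph::E(sub)$weight
    weakest <- igraph::E(sub)[which.min(w)]
    ends <- igraph::ends(sub, weakest)
    g <- igraph::delete_edges(g, igraph::get_edge_ids(g, as.vector(t(ends))))
  }
  comp <- igraph::components(g)
  memb <- comp$membership
  ord <- order(memb, names(memb))
  v <- names(memb)[ord]
  cid <- memb[ord]
  # stable ids: number components by their first (sorted) member
  first_member <- tapply(v, cid, min)
  rank <- rank(first_member, ties.method = "first")
  data.frame(cluster_id = sprintf("OC%05d", rank[as.character(cid)]),
             strain = sub("\\|.*$", "", v),
             gene_id = sub("^[^|]*\\|", "", v),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Presence/absence (and copy-number) matrix from a cluster table
#' @param clusters Output of [cluster_orthologs()].
#' @param strains Optional strain universe (columns), defaults to those seen.
#' @param copy_number Return counts instead of 0/1 (default FALSE).
#' @return Integer matrix clusters x strains.
#' @export
presence_matrix <- function(clusters, strains = NULL, copy_number = FALSE) {
  if (is.null(strains)) strains <- sort(unique(clusters$strain))
  tab <- table(factor(clusters$cluster_id),
               factor(clusters$strain, levels = strains))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), strains))
  if (!copy_number) m <- (m > 0) + 0L
  m
}

#' Core and species-specific gene clusters
#'
#' Core = present in every strain. Group-specific = present in *all*
#' strains of that group and absent from *all* strains of the other
#' group(s) (strict quantifiers). Per-cluster replicon locations and
#' per-strain copy numbers are reported when gene tables are supplied.
#'
#' @param clusters Cluster table from [cluster_orthologs()].
#' @param groups Named character vector: strain -> group label.
#' @param genes Optional named list: strain -> gene table, for replicon
#'   locations.
#' @return List of class `specific_gene_report`: `core` (cluster ids),
#'   `specific` (named list group -> data frame with cluster_id, and
#'   location/copy-number columns when available), `presence` matrix.
#' @export
core_and_specific <- function(clusters, groups, genes = NULL) {
  strains <- names(groups)
  missing_group <- setdiff(unique(clusters$strain), strains)
  if (length(missing_group))
    stop("strains without group assignment: ",
         paste(missing_group, collapse = ", "))
  if (!length(strains) || any(!nzchar(groups)))
    stop("every strain must be assigned to exactly one non-empty group")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  for (gl in unique(groups)) if (!sum(groups == gl))
    stop("empty group: ", gl)
  pm <- presence_matrix(clusters, strains = strains)
  core <- rownames(pm)[rowSums(pm > 0) == length(strains)]
  specific <- list()
  for (gl in unique(groups)) {
    own <- strains[groups == gl]; other <- strains[groups != gl]
    sel <- rowSums(pm[, own, drop = FALSE] > 0) == length(own) &
      rowSums(pm[, other, drop = FALSE] > 0) == 0
    ids <- rownames(pm)[sel]
    df <- data.frame(cluster_id = ids, stringsAsFactors = FALSE)
    if (!is.null(genes) && length(ids)) {
      loc <- vapply(ids, function(cid) {
        rows <- clusters[clusters$cluster_id == cid, , drop = FALSE]
        locs <- vapply(seq_len(nrow(rows)), function(k) {
          gt <- genes[[rows$strain[k]]]
          if (is.null(gt)) return(NA_character_)
          gt$replicon_id[match(rows$gene_id[k], gt$gene_id)]
        }, character(1))
        paste(unique(stats::na.omit(locs)), collapse = ",")
      }, character(1))
      df$replicon_location <- loc
      cn <- presence_matrix(clusters, strains = strains, copy_number = TRUE)
      df <- cbind(df, as.data.frame(cn[ids, own, drop = FALSE]))
    }
    specific[[gl]] <- df
  }
  structure(list(core = core, specific = specific, presence = pm,
                 groups = groups),
            class = "specific_gene_report")
}

#' Check whether a specific gene's function may be compensated
#'
#' Relaxed local-alignment search of a cluster representative against the
#' other group's proteomes: any hit with at least `min_identity` identity
#' and `min_coverage` coverage of the representative marks the cluster
#' `compensated` (a divergent homolog or isoenzyme candidate); otherwise
#' `not_found`. Gates are monotone: raising them never turns `not_found`
#' into `compensated`.
#'
#' @param representative Protein sequence representing the cluster.
#' @param other_proteomes Named list (strain -> named character vector) or a
#'   single named character vector.
#' @param min_identity,min_coverage Relaxed gates (defaults 0.3 and 0.5).
#' @return List: `status` ("compensated"/"not_found"), `best_hit`
#'   (gene id, identity, coverage) when found.
#' @export
compensation_check <- function(representative, other_proteomes,
                               min_identity = 0.3, min_coverage = 0.5) {
  stopifnot(nzchar(representative))
  if (!is.list(other_proteomes)) other_proteomes <- list(other_proteomes)
  pool <- unlist(unname(other_proteomes))
  if (!length(pool)) return(list(status = "not_found", best_hit = NULL))
  cand <- .protein_candidates(setNames(list(representative), "rep"),
                              as.list(pool), k = 4L)
  best <- NULL
  if (!is.null(cand) && nrow(cand)) {
    for (gb in unique(cand$b)) {
      h <- align_local(representative, pool[[gb]], type = "protein",
                       method = "dp")
      if (h$identity >= min_identity && h$query_coverage >= min_coverage &&
          (is.null(best) || h$raw_score > best$raw_score))
        best <- list(gene_id = gb, identity = h$identity,
                     coverage = h$query_coverage, raw_score = h$raw_score)
    }
  }
  if (is.null(best)) list(status = "not_found", best_hit = NULL)
  else list(status = "compensated", best_hit = best)
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Sequences are sorted by decreasing length; each joins the first existing
#' cluster whose representative it matches at `threshold` identity or
#' better (identical residues over the length of the shorter sequence),
#' else founds a new cluster.
#'
#' @param proteins Named character vector.
#' @param threshold Identity threshold in `[0, 1]` (default 0.9).
#' @return Named list: representative id -> member ids.
#' @export
greedy_identity_clustering <- function(proteins, threshold = 0.9) {
  stopifnot(length(proteins) > 0, !is.null(names(proteins)))
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)
  clusters <- list()
  for (g in names(proteins)) {
    placed <- FALSE
    for (r in reps) {
      h <- align_local(proteins[[g]], proteins[[r]], type = "protein",
                       method = "dp")
      ident_short <- h$n_ident / min(nchar(proteins[[g]]),
                                     nchar(proteins[[r]]))
      if (ident_short >= threshold) {
        clusters[[r]] <- c(clusters[[r]], g)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, g)
      clusters[[g]] <- g
    }
  }
  clusters
}

# single-linkage components of a thresholded similarity matrix
.sl_components <- function(m, threshold) {
  adj <- m >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Species and genus demarcation from relatedness matrices
#'
#' Species are single-linkage components at ANI >= `ani_species[2]`; pairs
#' in the `[ani_species[1], ani_species[2])` window are flagged ambiguous.
#' Genera are single-linkage components at cpAAI >= `cpaai_genus`. Taxa
#' whose above-threshold cpAAI neighbors fall into two or more distinct
#' components once the taxon itself is removed are flagged (the
#' borderline-genus situation). A species spanning two genera is an error.
#'
#' @param ani Symmetric percent ANI matrix.
#' @param cpaai_m Symmetric percent cpAAI matrix (same labels); optional.
#' @param ani_species Species window `(lower, upper)`, default `c(95, 96)`.
#' @param cpaai_genus Genus threshold, default 86.
#' @return List of class `demarcation_report`: `species` (list of label
#'   vectors), `species_ambiguous_pairs` (data frame), `genus`,
#'   `genus_ambiguous_taxa`.
#' @export
demarcate <- function(ani, cpaai_m = NULL, ani_species = c(95, 96),
                      cpaai_genus = 86) {
  stopifnot(is.matrix(ani), identical(rownames(ani), colnames(ani)))
  labs <- rownames(ani)
  species <- .sl_components(ani, ani_species[2])
  amb <- which(ani >= ani_species[1] & ani < ani_species[2] &
                 upper.tri(ani), arr.ind = TRUE)
  species_amb <- data.frame(a = labs[amb[, 1]], b = labs[amb[, 2]],
                            ani = ani[amb], stringsAsFactors = FALSE)
  genus <- NULL; genus_amb <- character(0)
  if (!is.null(cpaai_m)) {
    stopifnot(identical(rownames(cpaai_m), labs))
    genus <- .sl_components(cpaai_m, cpaai_genus)
    for (t in labs) {
      others <- setdiff(labs, t)
      sub <- cpaai_m[others, others, drop = FALSE]
      comps <- .sl_components(sub, cpaai_genus)
      nb <- others[cpaai_m[t, others] >= cpaai_genus]
      if (length(nb) < 2) next
      # only components of >= 2 taxa count as genuine foreign clades;
      # a singleton stranded by removing its own hub is not one
      in_comp <- vapply(comps, function(cc)
        length(cc) >= 2 && any(nb %in% cc), logical(1))
      if (sum(in_comp) >= 2) genus_amb <- c(genus_amb, t)
    }
    # species must refine genus
    gid <- setNames(rep(seq_along(genus), lengths(genus)), unlist(genus))
    for (sp in species) {
      if (length(unique(gid[sp])) > 1)
        stop("species spans multiple genus components: ",
             paste(sp, collapse = ", "))
    }
  }
  structure(list(species = unname(species),
                 species_ambiguous_pairs = species_amb,
                 genus = if (is.null(genus)) NULL else unname(genus),
                 genus_ambiguous_taxa = genus_amb,
                 thresholds = list(ani_species = ani_species,
                                   cpaai_genus = cpaai_genus)),
            class = "demarcation_report")
}

#' @export
print.demarcation_report <- function(x, ...) {
  cat("Species (ANI >=", x$thresholds$ani_species[2], "):\n")
  for (sp in x$species) cat("  {", paste(sp, collapse = ", "), "}\n")
  if (nrow(x$species_ambiguous_pairs))
    cat("  ambiguous pairs:",
        paste(sprintf("%s-%s (%.2f)", x$species_ambiguous_pairs$a,
                      x$species_ambiguous_pairs$b,
                      x$species_ambiguous_pairs$ani), collapse = "; "), "\n")
  if (!is.null(x$genus)) {
    cat("Genera (cpAAI >=", x$thresholds$cpaai_genus, "):\n")
    for (ge in x$genus) cat("  {", paste(ge, collapse = ", "), "}\n")
    if (length(x$genus_ambiguous_taxa))
      cat("  borderline taxa:", paste(x$genus_ambiguous_taxa,
                                      collapse = ", "), "\n")
  }
  invisible(x)
}
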