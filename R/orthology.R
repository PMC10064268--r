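# BBH orthology and synteny / rearrangement mapping.

# k-mer (amino acid) candidate pair prefilter: pairs of proteins sharing at
# least `min_shared` exact k-mers. Keeps the all-vs-all DP affordable, the
# same way BLAST's word seeding does; gates below decide what survives.
.protein_candidates <- function(pa, pb, k = 5L, min_shared = 1L) {
  kmers <- function(x) {
    n <- nchar(x)
    if (n < k) return(character(0))
    unique(substring(x, 1:(n - k + 1L), k:n))
  }
  ta <- data.table::rbindlist(lapply(names(pa), function(g)
    data.table::data.table(kmer = kmers(pa[[g]]), a = g)))
  tb <- data.table::rbindlist(lapply(names(pb), function(g)
    data.table::data.table(kmer = kmers(pb[[g]]), b = g)))
  if (!nrow(ta) || !nrow(tb)) return(NULL)
  m <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(m)) return(NULL)
  cnt <- m[, .N, by = .(a, b)]
  as.data.frame(cnt[N >= min_shared, .(a, b)])
}

# align all candidate pairs (one vectorized local-DP call); returns one
# row per pair with alignment statistics
.pair_hits <- function(pa, pb, cand) {
  if (is.null(cand) || !nrow(cand)) return(NULL)
  n_a <- sum(nchar(pa)); n_b <- sum(nchar(pb))
  la <- nchar(pa[cand$a]); lb <- nchar(pb[cand$b])
  gp <- .gap_params("protein")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(pa[cand$a])),
    Biostrings::AAStringSet(unname(pb[cand$b])), type = "local",
    substitutionMatrix = .protein_submat(),
    gapOpening = gp["open"], gapExtension = gp["ext"])
  n_ident <- Biostrings::nmatch(aln)
  ni <- Biostrings::nindel(aln)
  # alignment length including (internal) gap columns, BLAST-style
  aln_len <- Biostrings::nchar(aln) + ni@insertion[, "WidthSum"] +
    ni@deletion[, "WidthSum"]
  raw <- Biostrings::score(aln)
  data.frame(
    gene_a = cand$a, gene_b = cand$b,
    identity = n_ident / aln_len,
    coverage_a = BiocGenerics::width(aln@pattern@range) / la,
    coverage_b = BiocGenerics::width(aln@subject@range) / lb,
    raw_score = raw, bits = .bits(raw, "protein"),
    evalue_ab = .evalue(raw, la, n_b, "protein"),
    evalue_ba = .evalue(raw, lb, n_a, "protein"),
    stringsAsFactors = FALSE)
}

#' Bidirectional best hits between two proteomes
#'
#' Reciprocal best hits by raw alignment score, with BLAST-style gates
#' applied in both directions: e-value at most `evalue_max` and at least
#' `min_coverage` of *each* protein aligned. Ties on score are broken by
#' higher identity, then lexicographic gene id. Candidate pairs are
#' prefiltered by shared amino-acid 5-mers (word seeding).
#'
#' @param proteome_a,proteome_b Named character vectors of protein
#'   sequences.
#' @param evalue_max E-value gate (default 1e-100).
#' @param min_coverage Aligned fraction required of each protein
#'   (default 0.5).
#' @param min_identity Optional identity gate (default 0, i.e. off).
#' @return Data frame of BBH pairs with alignment statistics; zero rows if
#'   none.
#' @export
bidirectional_best_hits <- function(proteome_a, proteome_b,
                                    evalue_max = 1e-100,
                                    min_coverage = 0.5,
                                    min_identity = 0) {
  stopifnot(length(proteome_a) > 0, length(proteome_b) > 0)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0), raw_score = numeric(0),
                      bits = numeric(0), evalue_ab = numeric(0),
                      evalue_ba = numeric(0))
  cand <- .protein_candidates(proteome_a, proteome_b)
  hits <- .pair_hits(proteome_a, proteome_b, cand)
  if (is.null(hits)) return(empty)
  ok <- hits$evalue_ab <= evalue_max & hits$evalue_ba <= evalue_max &
    hits$coverage_a >= min_coverage & hits$coverage_b >= min_coverage &
    hits$identity >= min_identity
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  ord <- order(hits$gene_a, -hits$raw_score, -hits$identity, hits$gene_b)
  hits <- hits[ord, , drop = FALSE]
  best_ab <- hits[!duplicated(hits$gene_a), , drop = FALSE]
  ord2 <- order(hits$gene_b, -hits$raw_score, -hits$identity, hits$gene_a)
  h2 <- hits[ord2, , drop = FALSE]
  best_ba <- h2[!duplicated(h2$gene_b), , drop = FALSE]
  key_ab <- paste(best_ab$gene_a, best_ab$gene_b)
  key_ba <- paste(best_ba$gene_a, best_ba$gene_b)
  out <- best_ab[key_ab %in% key_ba, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synteny links between two annotated genomes
#'
#' One link per BBH pair, carrying the replicon and coordinates of each
#' partner; a circos-style links TSV is written when `path` is given, with
#' the color keyed by the source replicon.
#'
#' @param bbh BBH table from [bidirectional_best_hits()].
#' @param genes_a,genes_b Gene tables ([gene_table()]) with coordinates for
#'   every gene in `bbh`.
#' @param path Optional output TSV path.
#' @return Data frame: `replicon_a, start_a, end_a, replicon_b, start_b,
#'   end_b, identity, color`.
#' @export
synteny_links <- function(bbh, genes_a, genes_b, path = NULL) {
  genes_a <- gene_table(genes_a); genes_b <- gene_table(genes_b)
  ia <- match(bbh$gene_a, genes_a$gene_id)
  ib <- match(bbh$gene_b, genes_b$gene_id)
  miss <- c(bbh$gene_a[is.na(ia)], bbh$gene_b[is.na(ib)])
  if (length(miss))
    stop("genes without coordinates: ", paste(head(miss, 10), collapse = ", "))
  reps <- unique(genes_a$replicon_id)
  palette <- grDevices::hcl.colors(max(3L, length(reps)), "Dark 3")
  links <- data.frame(
    replicon_a = genes_a$replicon_id[ia],
    start_a = genes_a$start[ia], end_a = genes_a$end[ia],
    replicon_b = genes_b$replicon_id[ib],
    start_b = genes_b$start[ib], end_b = genes_b$end[ib],
    identity = bbh$identity,
    color = palette[match(genes_a$replicon_id[ia], reps)],
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    out <- links[, c("replicon_a", "start_a", "end_a",
                     "replicon_b", "start_b", "end_b")]
    names(out)[c(1, 4)] <- c("chr_a", "chr_b")
    out$options <- sprintf("color=%s,identity=%.3f", links$color,
                           links$identity)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  links
}

# partner replicon of every gene on `replicon_id` of the focal strain,
# ordered by coordinate; NA for genes without a BBH partner
.partner_sources <- function(replicon_id, genes_t, genes_r, bbh,
                             target_is_a = TRUE) {
  gt <- genes_t[genes_t$replicon_id == replicon_id, , drop = FALSE]
  gt <- gt[order(gt$start), , drop = FALSE]
  if (target_is_a) {
    partner <- bbh$gene_b[match(gt$gene_id, bbh$gene_a)]
  } else {
    partner <- bbh$gene_a[match(gt$gene_id, bbh$gene_b)]
  }
  src <- genes_r$replicon_id[match(partner, genes_r$gene_id)]
  data.frame(gene_id = gt$gene_id, start = gt$start, partner = partner,
             source = src, stringsAsFactors = FALSE)
}

# maximal runs of consecutive non-NA entries sharing a value, tolerating
# gaps of <= max_gap NA entries inside a run
.source_runs <- function(source, max_gap = 2L) {
  runs <- list()
  cur_val <- NA; cur_start <- NA; cur_end <- NA; gap <- 0L; n_in <- 0L
  flush <- function() {
    if (!is.na(cur_val))
      runs[[length(runs) + 1L]] <<- list(value = cur_val, start = cur_start,
                                         end = cur_end, n = n_in)
  }
  for (i in seq_along(source)) {
    v <- source[i]
    if (is.na(v)) {
      gap <- gap + 1L
      if (gap > max_gap) { flush(); cur_val <- NA; gap <- 0L }
      next
    }
    if (!is.na(cur_val) && v == cur_val) {
      cur_end <- i; n_in <- n_in + 1L; gap <- 0L
    } else {
      flush()
      cur_val <- v; cur_start <- i; cur_end <- i; n_in <- 1L; gap <- 0L
    }
  }
  flush()
  runs
}

#' Map a (putative) cointegrant replicon onto a reference strain
#'
#' For each reference replicon, counts the genes of the target replicon
#' whose BBH partner lies on it; dominant-source segments are maximal runs
#' of at least `min_run` consecutive target genes (coordinate order, up to
#' `max_gap` partnerless genes tolerated inside a run) sharing one source
#' replicon. Three dominant segments mapping to a megaplasmid and two
#' chromids is the signature of a chromid cointegrant.
#'
#' @param target_replicon Id of the target replicon.
#' @param genes_target Gene table of the target strain.
#' @param genes_reference Gene table of the reference strain.
#' @param bbh BBH table (target genes in column `gene_a`, reference genes in
#'   `gene_b`; set `target_is_a = FALSE` for the transpose).
#' @param min_run Minimum genes per dominant segment (default 10).
#' @param max_gap Partnerless genes tolerated inside a run (default 2).
#' @param target_is_a Orientation of `bbh` (default TRUE).
#' @return List: `counts` (reference replicon, n_genes, fraction),
#'   `segments` (source, first/last gene index, n_genes), `genes`
#'   (per-gene source calls). Empty map (with a warning) when no target
#'   gene has a partner.
#' @export
cointegration_map <- function(target_replicon, genes_target, genes_reference,
                              bbh, min_run = 10L, max_gap = 2L,
                              target_is_a = TRUE) {
  genes_target <- gene_table(genes_target)
  genes_reference <- gene_table(genes_reference)
  ps <- .partner_sources(target_replicon, genes_target, genes_reference,
                         bbh, target_is_a)
  if (!nrow(ps) || all(is.na(ps$source))) {
    warning("no BBH pairs on target replicon '", target_replicon, "'")
    return(list(counts = data.frame(reference_replicon = character(0),
                                    n_genes = integer(0),
                                    fraction = numeric(0)),
                segments = data.frame(source = character(0),
                                      from_gene = integer(0),
                                      to_gene = integer(0),
                                      n_genes = integer(0)),
                genes = ps))
  }
  tab <- table(ps$source)
  counts <- data.frame(reference_replicon = names(tab),
                       n_genes = as.integer(tab),
                       fraction = as.numeric(tab) / sum(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_genes), , drop = FALSE]
  rownames(counts) <- NULL
  runs <- .source_runs(ps$source, max_gap = max_gap)
  runs <- Filter(function(r) r$n >= min_run, runs)
  segments <- if (length(runs)) data.frame(
    source = vapply(runs, `[[`, character(1), "value"),
    from_gene = vapply(runs, `[[`, numeric(1), "start"),
    to_gene = vapply(runs, `[[`, numeric(1), "end"),
    n_genes = vapply(runs, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE)
  else data.frame(source = character(0), from_gene = integer(0),
                  to_gene = integer(0), n_genes = integer(0))
  list(counts = counts, segments = segments, genes = ps)
}

#' Detect translocated gene blocks between two strains
#'
#' Given which replicon pairs are expected partners, finds maximal runs of
#' at least `min_run` consecutive genes (coordinate order on the focal
#' strain's replicon, up to `max_gap` partnerless genes tolerated) whose
#' BBH partners all sit on one *non-expected* replicon of the other strain.
#'
#' @param bbh BBH table (focal strain = `gene_a`).
#' @param genes_a,genes_b Gene tables.
#' @param expected_partners Named character vector: focal replicon id ->
#'   expected partner replicon id.
#' @param min_run Minimum block length in genes (default 10).
#' @param max_gap Partnerless genes tolerated inside a block (default 2).
#' @return Data frame: `replicon_a, replicon_b, n_genes, gene_ids` (list
#'   column); zero rows when nothing is translocated.
#' @export
detect_translocated_blocks <- function(bbh, genes_a, genes_b,
                                       expected_partners, min_run = 10L,
                                       max_gap = 2L) {
  genes_a <- gene_table(genes_a); genes_b <- gene_table(genes_b)
  out <- list()
  for (ra in unique(genes_a$replicon_id)) {
    ps <- .partner_sources(ra, genes_a, genes_b, bbh, target_is_a = TRUE)
    expected <- expected_partners[[ra]]
    marked <- ps$source
    marked[!is.na(marked) & marked == expected] <- NA   # expected = break
    # runs share one foreign replicon; genes on the expected partner break
    # runs, which .source_runs does not know about, so split manually:
    on_expected <- !is.na(ps$source) & ps$source == expected
    seg_id <- cumsum(on_expected)
    for (sid in unique(seg_id[!on_expected])) {
      idx <- which(seg_id == sid & !on_expected)
      runs <- .source_runs(ps$source[idx], max_gap = max_gap)
      for (r in Filter(function(r) r$n >= min_run, runs)) {
        sel <- idx[r$start:r$end]
        sel <- sel[!is.na(ps$source[sel]) & ps$source[sel] == r$value]
        out[[length(out) + 1L]] <- data.frame(
          replicon_a = ra, replicon_b = r$value, n_genes = r$n,
          gene_ids = I(list(ps$gene_id[sel])), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(replicon_a = character(0), replicon_b = character(0),
                      n_genes = integer(0), gene_ids = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
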