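# Pairwise alignment engine: Biostrings dynamic programming underneath,
# with a k-mer seeded window finder for long subjects and Karlin-Altschul
# e-values so BLAST-style gates (e-value, coverage) are reproducible.

# Karlin-Altschul parameters. Proteins: gapped BLOSUM62, gap open 11 /
# extend 1 (standard published table). DNA: match +1 / mismatch -2, gap
# open 5 / extend 2.
.KA <- list(protein = c(lambda = 0.267, K = 0.041),
            dna = c(lambda = 1.28, K = 0.46))

.protein_submat <- function() {
  # BLOSUM62 extended with X (0 against everything)
  data(BLOSUM62, package = "Biostrings", envir = environment())
  m <- BLOSUM62
  if (!"X" %in% rownames(m)) stop("BLOSUM62 without X")
  m
}

.dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

.gap_params <- function(type) {
  if (type == "protein") c(open = 11, ext = 1) else c(open = 5, ext = 2)
}

.check_alphabet <- function(x, type) {
  bad <- if (type == "protein") grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", x)
  else grepl("[^ACGTN]", x)
  if (any(bad)) stop("alphabet violation for ", type, " sequence")
  invisible(TRUE)
}

# e-value from a raw DP score; search space = m * n_total residues
.evalue <- function(raw_score, m, n_total, type) {
  p <- .KA[[type]]
  unname(p["K"] * m * n_total * exp(-p["lambda"] * raw_score))
}

.bits <- function(raw_score, type) {
  p <- .KA[[type]]
  unname((p["lambda"] * raw_score - log(p["K"])) / log(2))
}

# summarize one Biostrings PairwiseAlignments object (single pair)
.hit_from_pa <- function(pa, qlen, slen, type, n_total,
                         s_offset = 0L) {
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(ap, "")[[1]]; sc <- strsplit(as_, "")[[1]]
  aln_len <- length(pc)
  n_ident <- sum(pc == sc & pc != "-")
  qr <- pa@pattern@range
  sr <- pa@subject@range
  raw <- Biostrings::score(pa)
  list(identity = n_ident / aln_len,
       n_ident = n_ident, aln_len = aln_len,
       query_coverage = BiocGenerics::width(qr) / qlen,
       subject_coverage = BiocGenerics::width(sr) / slen,
       raw_score = raw,
       score = .bits(raw, type),
       evalue = .evalue(raw, qlen, n_total, type),
       q_start = BiocGenerics::start(qr), q_end = BiocGenerics::end(qr),
       s_start = BiocGenerics::start(sr) + s_offset,
       s_end = BiocGenerics::end(sr) + s_offset)
}

# 2-bit encode all k-mers of a DNA string as doubles (exact for k <= 15)
.dna_kmers <- function(seq, k = 15L) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES) - 1
  n <- length(code)
  if (n < k || anyNA(code)) return(numeric(0))
  v <- numeric(n - k + 1L)
  for (j in seq_len(k)) v <- v + code[j:(n - k + j)] * 4^(k - j)
  v
}

# find, for each query fragment, the best-supported subject window by
# k-mer diagonal voting; returns data.frame(frag, rep_idx, d_lo, d_hi)
.seed_windows <- function(frags, subjects, k = 15L, step = 48L,
                          bucket = 24L) {
  st <- data.table::rbindlist(lapply(seq_along(subjects), function(i) {
    km <- .dna_kmers(subjects[[i]], k)
    if (!length(km)) return(NULL)
    data.table::data.table(kmer = km, rep_idx = i, spos = seq_along(km))
  }))
  if (is.null(st) || !nrow(st)) return(NULL)
  data.table::setkey(st, kmer)
  qt <- data.table::rbindlist(lapply(seq_along(frags), function(f) {
    km <- .dna_kmers(frags[[f]], k)
    if (!length(km)) return(NULL)
    pos <- unique(c(seq(1L, length(km), by = step), length(km)))
    data.table::data.table(kmer = km[pos], frag = f, qpos = pos)
  }))
  if (is.null(qt) || !nrow(qt)) return(NULL)
  hits <- st[qt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (!nrow(hits)) return(NULL)
  hits[, diag := spos - qpos]
  hits[, dbucket := round(diag / bucket)]
  votes <- hits[, .N, by = .(frag, rep_idx, dbucket)]
  best <- votes[order(-N), .SD[1], by = frag]
  merged <- hits[best, on = .(frag, rep_idx, dbucket)]
  out <- merged[, .(d_lo = min(diag), d_hi = max(diag)),
                by = .(frag, rep_idx)]
  as.data.frame(out)
}

#' Local pairwise alignment with BLAST-style statistics
#'
#' Optimal Smith-Waterman (Biostrings dynamic programming) for sequence
#' pairs up to `dp_limit` bases; above that, a k-mer seeded window is
#' located first (k = 15 for DNA, diagonal voting) and the DP is run
#' against that window only. E-values use Karlin-Altschul statistics with
#' gapped BLOSUM62 constants for proteins and +1/-2 (gap 5/2) constants for
#' DNA.
#'
#' @param a,b Sequences (character). `a` is the query.
#' @param type `"protein"` or `"dna"`.
#' @param method `"auto"` (default), `"dp"` (force full DP), or `"seed"`
#'   (force the seeded path).
#' @param dp_limit Maximum subject length for full DP under `"auto"`
#'   (default 50000).
#' @param n_total Total subject search-space size in residues (defaults to
#'   `nchar(b)`); used for the e-value.
#' @return List of class `alignment_hit`: identity, query/subject coverage,
#'   bit score, raw score, e-value, and aligned coordinates; `NULL` if the
#'   seeded path finds no seed support.
#' @export
align_local <- function(a, b, type = c("protein", "dna"),
                        method = c("auto", "dp", "seed"),
                        dp_limit = 50000L, n_total = NULL) {
  type <- match.arg(type); method <- match.arg(method)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  .check_alphabet(a, type); .check_alphabet(b, type)
  if (is.null(n_total)) n_total <- nchar(b)
  use_dp <- method == "dp" ||
    (method == "auto" && max(nchar(a), nchar(b)) <= dp_limit)
  submat <- if (type == "protein") .protein_submat() else .dna_submat()
  gp <- .gap_params(type)
  if (use_dp) {
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
      substitutionMatrix = submat, gapOpening = gp["open"],
      gapExtension = gp["ext"])
    hit <- .hit_from_pa(pa, nchar(a), nchar(b), type, n_total)
  } else {
    if (type != "dna")
      stop("seeded path implemented for DNA; protein pairs use full DP")
    win <- .seed_windows(list(a), list(b))
    if (is.null(win) || !nrow(win)) return(NULL)
    margin <- 200L
    lo <- max(1L, win$d_lo[1] + 1L - margin)
    hi <- min(nchar(b), win$d_hi[1] + nchar(a) + margin)
    pa <- Biostrings::pairwiseAlignment(a, substr(b, lo, hi), type = "local",
      substitutionMatrix = submat, gapOpening = gp["open"],
      gapExtension = gp["ext"])
    hit <- .hit_from_pa(pa, nchar(a), nchar(b), type, n_total,
                        s_offset = lo - 1L)
    hit$subject_coverage <- (hit$s_end - hit$s_start + 1) / nchar(b)
  }
  structure(hit, class = "alignment_hit")
}

#' Global pairwise alignment summary
#'
#' Needleman-Wunsch global alignment; reports identical, mismatching and
#' gap columns. Identity here is over non-gap (aligned-in-both) columns,
#' the convention used for concatenated-marker AAI and SNP counting.
#'
#' @param a,b Sequences.
#' @param type `"protein"` or `"dna"`.
#' @return List: `n_ident`, `n_mismatch`, `n_gapcols`, `aln_len`,
#'   `identity` (over non-gap columns).
#' @export
align_global <- function(a, b, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  .check_alphabet(a, type); .check_alphabet(b, type)
  submat <- if (type == "protein") .protein_submat() else .dna_submat()
  gp <- .gap_params(type)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
    substitutionMatrix = submat, gapOpening = gp["open"],
    gapExtension = gp["ext"])
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- pc == "-" | sc == "-"
  n_ident <- sum(!gap & pc == sc)
  n_mis <- sum(!gap & pc != sc)
  list(n_ident = n_ident, n_mismatch = n_mis, n_gapcols = sum(gap),
       aln_len = length(pc),
       identity = if (n_ident + n_mis > 0) n_ident / (n_ident + n_mis)
       else NA_real_)
}

#' Count substitutions between two homologous sequences
#'
#' Global alignment; mismatch columns are counted and indel columns
#' excluded. Refuses sequence pairs below a 70% identity sanity gate
#' (likely non-homologous).
#'
#' @param a,b DNA strings (e.g. two 16S rRNA genes).
#' @param min_identity Sanity gate on non-gap-column identity (default 0.7).
#' @return Integer substitution (SNP) count.
#' @export
count_snps <- function(a, b, min_identity = 0.7) {
  g <- align_global(a, b, type = "dna")
  if (is.na(g$identity) || g$identity < min_identity)
    stop(sprintf(
      "alignment identity %.2f below the %.2f homology gate; refusing SNP count",
      g$identity, min_identity))
  g$n_mismatch
}
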