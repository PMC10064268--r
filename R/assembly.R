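#' Construct a replicon
#'
#' A replicon is one circular (or linear) DNA molecule of a bacterial
#' genome: the chromosome, a chromid, or a (mega)plasmid.
#'
#' @param id Replicon identifier, unique within an assembly.
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive), or `NULL`
#'   for a sequence-free stub used by protein-level simulations. Stubs carry
#'   a declared `length` instead.
#' @param length Length in bp; required when `sequence` is `NULL`, otherwise
#'   it must equal `nchar(sequence)`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `replicon`.
#' @export
replicon <- function(id, sequence = NULL, length = NULL,
                     topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), base::length(sequence) == 1L)
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
      stop("replicon '", id, "': sequence contains characters outside {A,C,G,T,N}")
    if (!nzchar(sequence)) stop("replicon '", id, "': empty sequence")
    if (is.null(length)) length <- nchar(sequence)
    if (length != nchar(sequence))
      stop("replicon '", id, "': declared length ", length,
           " != sequence length ", nchar(sequence))
  } else {
    if (is.null(length) || length < 1)
      stop("replicon '", id, "': sequence-free replicon needs a positive length")
  }
  structure(list(id = id, sequence = sequence, length = as.integer(length),
                 topology = topology),
            class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp (%s)%s\n", x$id,
              format(x$length, big.mark = ","), x$topology,
              if (is.null(x$sequence)) " [no sequence]" else ""))
  invisible(x)
}

#' Construct a gene table
#'
#' Validates and normalizes a data frame of gene records
#' (`gene_id, replicon_id, start, end, strand[, product]`). Coordinates are
#' 1-based inclusive (GFF convention).
#'
#' @param df Data frame of gene records.
#' @return The normalized data frame.
#' @export
gene_table <- function(df) {
  need <- c("gene_id", "replicon_id", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) {
    bad <- df$gene_id[df$start > df$end]
    stop("gene records with start > end: ", paste(head(bad, 5), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene ids: ",
         paste(head(unique(df$gene_id[duplicated(df$gene_id)]), 5), collapse = ", "))
  if (is.null(df$product)) df$product <- ""
  df[, c(need, "product")]
}

#' Construct a genome assembly
#'
#' @param strain Strain identifier.
#' @param replicons List of [replicon()] objects, in input order.
#' @param genes Optional gene table (see [gene_table()]).
#' @param proteome Optional named character vector of amino-acid sequences;
#'   names are gene ids.
#' @return An object of class `genome_assembly`.
#' @export
genome_assembly <- function(strain, replicons, genes = NULL, proteome = NULL) {
  stopifnot(is.character(strain), length(strain) == 1L)
  if (!length(replicons)) stop("assembly needs at least one replicon")
  if (!all(vapply(replicons, inherits, logical(1), "replicon")))
    stop("replicons must be a list of replicon objects")
  ids <- vapply(replicons, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate replicon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(replicons) <- ids
  if (!is.null(genes)) {
    genes <- gene_table(genes)
    dangle <- setdiff(unique(genes$replicon_id), ids)
    if (length(dangle))
      stop("gene records reference unknown replicons: ",
           paste(dangle, collapse = ", "))
    lens <- setNames(vapply(replicons, `[[`, integer(1), "length"), ids)
    over <- genes$end > lens[genes$replicon_id] | genes$start < 1L
    if (any(over))
      stop("gene coordinates outside replicon length: ",
           paste(head(genes$gene_id[over], 5), collapse = ", "))
  }
  if (!is.null(proteome)) {
    stopifnot(is.character(proteome), !is.null(names(proteome)))
    proteome <- toupper(proteome)
    if (any(!nzchar(proteome))) stop("empty protein sequences in proteome")
    if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", proteome)))
      stop("proteome contains non amino-acid characters")
  }
  structure(list(strain = strain, replicons = replicons, genes = genes,
                 proteome = proteome),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d replicon(s), %s bp total\n",
              x$strain, length(x$replicons),
              format(sum(replicon_lengths(x)), big.mark = ",")))
  for (r in x$replicons) print(r)
  if (!is.null(x$genes)) cat(sprintf("  %d gene record(s)\n", nrow(x$genes)))
  if (!is.null(x$proteome)) cat(sprintf("  %d protein(s)\n", length(x$proteome)))
  invisible(x)
}

#' Replicon lengths of an assembly
#' @param assembly A `genome_assembly`.
#' @return Named integer vector of lengths (bp), in input order.
#' @export
replicon_lengths <- function(assembly) {
  vapply(assembly$replicons, `[[`, integer(1), "length")
}

# 1-based inclusive (GFF) <-> 0-based half-open conversions; both directions
# are exercised in the tests.
to_zero_based <- function(start, end) list(start = start - 1L, end = end)
to_one_based  <- function(start, end) list(start = start + 1L, end = end)

.validate_fasta_lines <- function(path, alphabet = "ACGTNacgtn") {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("FASTA parse error in ", path, ": file is empty")
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("FASTA parse error in ", path, " at line ", nonblank[1],
         ": expected '>' header")
  pat <- sprintf("^[%s]+$", alphabet)
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    if (!grepl(pat, ln))
      stop("FASTA parse error in ", path, " at line ", i,
           ": invalid characters in sequence line")
  }
  invisible(TRUE)
}

#' Read a genome assembly from FASTA (+ optional feature table)
#'
#' One FASTA record per replicon. Features may be a 5-column TSV
#' (`gene_id, replicon_id, start, end, strand`, with header) or GFF3
#' (CDS features; `ID=` attribute used as gene id). When coordinates are
#' given and no protein FASTA is supplied, proteins are translated from the
#' CDS coordinates with the bacterial genetic code (table 11).
#'
#' @param fasta_path Path to a multi-record DNA FASTA.
#' @param features_path Optional path to the feature table.
#' @param proteins_path Optional path to a protein FASTA (record ids must be
#'   gene ids).
#' @param strain Strain label; defaults to the FASTA file stem.
#' @param translate Translate CDS coordinates into a proteome when no protein
#'   FASTA is given (default `TRUE` when features are present).
#' @return A [genome_assembly()].
#' @export
read_assembly <- function(fasta_path, features_path = NULL,
                          proteins_path = NULL, strain = NULL,
                          translate = TRUE) {
  .validate_fasta_lines(fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate replicon ids in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  reps <- lapply(seq_along(seqs), function(i)
    replicon(ids[i], as.character(seqs[[i]])))
  if (is.null(strain))
    strain <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))

  genes <- NULL
  if (!is.null(features_path)) genes <- read_features(features_path)

  proteome <- NULL
  if (!is.null(proteins_path)) {
    .validate_fasta_lines(proteins_path, alphabet = "A-Za-z*")
    aa <- Biostrings::readAAStringSet(proteins_path)
    proteome <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  } else if (!is.null(genes) && translate) {
    asm0 <- genome_assembly(strain, reps, genes)
    proteome <- translate_genes(asm0)
  }
  genome_assembly(strain, reps, genes, proteome)
}

#' Read a gene feature table (GFF3 or 5-column TSV)
#' @param path File path.
#' @return A normalized gene table.
#' @export
read_features <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  is_gff <- any(startsWith(first, "##gff")) ||
    length(strsplit(first[!startsWith(first, "#")][1], "\t", fixed = TRUE)[[1]]) == 9L
  if (is_gff) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) != 9L)
    if (length(bad)) stop("GFF3 parse error: line ", bad[1], " has ",
                          lengths(f)[bad[1]], " fields (expected 9)")
    m <- do.call(rbind, f)
    keep <- m[, 3] %in% c("CDS", "gene")
    m <- m[keep, , drop = FALSE]
    gid <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
    df <- data.frame(gene_id = gid, replicon_id = m[, 1],
                     start = as.integer(m[, 4]), end = as.integer(m[, 5]),
                     strand = m[, 7], product = "", stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
  }
  gene_table(df)
}

#' Translate CDS coordinates into a proteome (genetic code table 11)
#'
#' Minus-strand genes are reverse-complemented before translation; a single
#' trailing stop is trimmed. Translating a CDS and translating its
#' reverse-complement annotated on the opposite strand give identical
#' proteins.
#'
#' @param assembly A `genome_assembly` with sequences and a gene table.
#' @return Named character vector of protein sequences.
#' @export
translate_genes <- function(assembly) {
  stopifnot(!is.null(assembly$genes))
  g <- assembly$genes
  code <- Biostrings::getGeneticCode("11")
  out <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    rep <- assembly$replicons[[g$replicon_id[i]]]
    if (is.null(rep$sequence))
      stop("replicon '", rep$id, "' has no sequence; cannot translate")
    cds <- substr(rep$sequence, g$start[i], g$end[i])
    d <- Biostrings::DNAString(cds)
    if (g$strand[i] == "-") d <- Biostrings::reverseComplement(d)
    aa <- as.character(Biostrings::translate(d, genetic.code = code,
                                             if.fuzzy.codon = "X"))
    out[i] <- sub("\\*$", "", aa)
  }
  setNames(out, g$gene_id)
}

#' Write an assembly as normalized FASTA
#' @param assembly A `genome_assembly`.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (r in assembly$replicons) {
    if (is.null(r$sequence)) stop("replicon '", r$id, "' has no sequence")
    writeLines(paste0(">", r$id), con)
    starts <- seq(1L, r$length, by = width)
    writeLines(substring(r$sequence, starts, pmin(starts + width - 1L, r$length)),
               con)
  }
  invisible(path)
}

#' Read a plain-text key=value configuration file
#'
#' Blank lines and `#` comments are ignored. Every CLI flag has a config
#' twin; CLI values override config values.
#'
#' @param path Config file path.
#' @return Named character vector.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("config parse error: line '", lines[bad][1], "'")
  setNames(trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                         character(1))),
           trimws(vapply(kv, `[[`, character(1), 1)))
}

# One log line per pipeline stage: stage name, input digest, parameters,
# elapsed seconds.
.stage_log <- function(stage, digest, params = "", t0 = NULL) {
  elapsed <- if (is.null(t0)) NA_real_ else
    round(as.numeric(proc.time()["elapsed"]) - t0, 2)
  message(sprintf("[replitax] %s | input=%s | %s | %ss",
                  stage, digest, params, elapsed))
}
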