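# shared fixture builders; everything is generated in code, no stored data

random_dna <- function(n, seed = 1L, probs = c(0.25, 0.25, 0.25, 0.25)) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, TRUE, probs), collapse = ""))
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# tiny annotated assembly: `n` genes of `aa_len` residues back-translated
# onto one replicon, so translation-based tests have a consistent genome
tiny_assembly <- function(n = 3L, aa_len = 20L, seed = 1L,
                          strain = "toy") {
  withr::with_seed(seed, {
    code <- Biostrings::getGeneticCode("11")
    aa2codon <- split(names(code), code)
    genes <- list(); seqs <- character(0); pos <- 1L
    prot <- character(n)
    for (i in seq_len(n)) {
      aa <- c("M", sample(setdiff(unique(code), c("*", "M")), aa_len - 1L,
                          TRUE))
      cds <- paste(vapply(aa, function(x) sample(aa2codon[[x]], 1L),
                          character(1)), collapse = "")
      cds <- paste0(cds, sample(names(code)[code == "*"], 1L))
      spacer <- paste(sample(c("A", "C", "G", "T"), 30L, TRUE),
                      collapse = "")
      seqs <- c(seqs, spacer, cds)
      start <- pos + 30L
      genes[[i]] <- data.frame(gene_id = sprintf("g%02d", i),
                               replicon_id = "r1", start = start,
                               end = start + nchar(cds) - 1L, strand = "+",
                               stringsAsFactors = FALSE)
      pos <- start + nchar(cds)
      prot[i] <- paste(aa, collapse = "")
    }
    seq <- paste(c(seqs, "ACGT"), collapse = "")
    asm <- genome_assembly(strain, list(replicon("r1", seq)),
                           do.call(rbind, genes))
    asm$proteome <- translate_genes(asm)
    attr(asm, "expected_proteins") <- prot
    asm
  })
}
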