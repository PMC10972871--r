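# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; nothing is read from disk except files the tests
# themselves write.

# reverse-translate a peptide into one (arbitrary, deterministic) codon
# choice so reads that are exact back-translations of protein segments can
# be constructed
CODON_OF <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), code)
})

back_translate <- function(peptide) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  paste(vapply(aas, function(a) CODON_OF[[a]][1], character(1)),
        collapse = "")
}

# a tiny deterministic protein set derived from random sense codons
tiny_proteins <- function(n = 3L, len_aa = 120L, seed = 101L) {
  g <- make_genome(50000, n, exon_len_bp = c(len_aa * 3L, len_aa * 3L),
                   seed = seed)
  g$proteins
}

# Exhaustive six-frame Smith-Waterman search without seeding: the oracle
# the seeded search is compared against. Independent double loop over
# frames and proteins.
brute_force_search <- function(batch, proteins, scheme = scoring_scheme(),
                               evalue_max = 1e-5) {
  space <- (sum(as.numeric(Biostrings::width(batch))) / 3) *
    sum(as.numeric(Biostrings::width(proteins)))
  out <- list()
  for (r in seq_along(batch)) {
    frames <- sixframe_translate(as.character(batch[[r]]))
    best <- list()
    for (p in seq_along(proteins)) {
      best_raw <- -Inf
      for (f in frames) {
        if (nchar(f) == 0) next
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(f), proteins[[p]], type = "local",
          substitutionMatrix = scheme$matrix,
          gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
        s <- Biostrings::score(aln)
        if (s > best_raw) best_raw <- s
      }
      bit <- (scheme$karlin_lambda * best_raw - log(scheme$karlin_k)) / log(2)
      ev <- space * 2^(-bit)
      if (is.finite(bit) && ev <= evalue_max)
        best[[length(best) + 1L]] <- data.frame(
          read_id = names(batch)[r], protein_id = names(proteins)[p],
          bitscore = bit, evalue = ev, stringsAsFactors = FALSE)
    }
    out <- c(out, best)
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(), protein_id = character(),
                      bitscore = numeric(), evalue = numeric()))
  do.call(rbind, out)
}

# brute-force recomputation of the Z-score filter decision, written as an
# explicit per-protein loop
brute_force_zfilter <- function(depths, z_max = 1.96) {
  n <- length(depths)
  m <- sum(depths) / n
  if (n < 3L) return(rep(TRUE, n))
  v <- sum((depths - m)^2) / (n - 1)
  if (v == 0) return(rep(TRUE, n))
  keep <- logical(n)
  for (i in seq_len(n))
    keep[i] <- abs((depths[i] - m) / sqrt(v)) <= z_max
  keep
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
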