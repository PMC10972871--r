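# Synthetic-data generator: genomes with embedded single-copy multi-exon
# genes, whole-genome duplication to higher ploidies, and uniform read
# sampling, so every pipeline stage (mapping depth, outlier filter, slope
# calibration, ploidy inference, depth titration) can be exercised offline
# against known truth.

SENSE_CODONS <- local({
  nt <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(cod, c("TAA", "TAG", "TGA"))
})

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with single-copy genes
#'
#' Places `n_genes` non-overlapping genes uniformly on a random background
#' of the requested GC content. Each gene has a configurable number of
#' exons; exon lengths are multiples of 3 and coding sequence is drawn from
#' the 61 sense codons, so the truth proteins (translations of the
#' concatenated exons) are exact and stop-free while intron junctions still
#' cause the read loss that the calibration slope models. Strands are
#' random. Coordinates are 0-based half-open.
#'
#' @param genome_size_bp Total genome length.
#' @param n_genes Number of single-copy genes (0 allowed).
#' @param exons_per_gene Integer, or length-2 range to sample from
#'   (default 1).
#' @param exon_len_bp Length-2 range of exon lengths in bp; values are
#'   rounded to multiples of 3 (default c(900, 1500), a typical single-exon
#'   plant CDS of 300-500 residues).
#' @param intron_len_bp Length-2 range of intron lengths (default
#'   c(90, 300)).
#' @param gc GC fraction of non-coding sequence (default 0.37).
#' @param paralog_fraction Fraction of genes additionally inserted a second
#'   time (default 0), to exercise the Z-score filter's removal of
#'   duplicated genes.
#' @param seed Optional integer seed; the same seed reproduces the genome
#'   byte for byte.
#' @return An object of class `synthetic_genome`: list with `sequence`
#'   (character), `genes` (data.frame with `gene_id`, `strand`, `exon_start`
#'   / `exon_end` list-columns), `proteins` ([Biostrings::AAStringSet]) and
#'   `truth` (list with `monoploid_size_bp`, `ploidy`, `exons_per_gene`,
#'   `cds_len`).
#' @export
make_genome <- function(genome_size_bp, n_genes, exons_per_gene = 1L,
                        exon_len_bp = c(900L, 1500L),
                        intron_len_bp = c(90L, 300L), gc = 0.37,
                        paralog_fraction = 0, seed = NULL) {
  with_seed(seed, {
    sample_range <- function(rng, n, step = 1L) {
      rng <- as.integer(rng)
      if (length(rng) == 1L) rng <- c(rng, rng)
      vals <- seq(rng[1], rng[2], by = step)
      vals[sample.int(length(vals), n, replace = TRUE)]
    }
    n_genes <- as.integer(n_genes)
    if (n_genes == 0L) {
      return(structure(list(
        sequence = random_dna(genome_size_bp, gc),
        genes = data.frame(gene_id = character(), strand = character()),
        proteins = Biostrings::AAStringSet(),
        truth = list(monoploid_size_bp = genome_size_bp, ploidy = 2L,
                     exons_per_gene = integer(), cds_len = integer())),
        class = "synthetic_genome"))
    }
    n_exons <- sample_range(exons_per_gene, n_genes)
    gene_parts <- vector("list", n_genes)
    cds <- character(n_genes)
    footprints <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      ex_len <- sample_range(exon_len_bp, n_exons[i], step = 3L)
      in_len <- if (n_exons[i] > 1L)
        sample_range(intron_len_bp, n_exons[i] - 1L) else integer()
      exons <- vapply(ex_len, function(l)
        paste(SENSE_CODONS[sample.int(61L, l / 3L, replace = TRUE)],
              collapse = ""), character(1))
      introns <- vapply(in_len, function(l) random_dna(l, gc), character(1))
      parts <- character(2L * n_exons[i] - 1L)
      parts[seq(1L, length(parts), by = 2L)] <- exons
      if (n_exons[i] > 1L) parts[seq(2L, length(parts), by = 2L)] <- introns
      gene_parts[[i]] <- list(ex_len = ex_len, in_len = in_len,
                              seq = paste(parts, collapse = ""))
      cds[i] <- paste(exons, collapse = "")
      footprints[i] <- nchar(gene_parts[[i]]$seq)
    }
    n_paralog <- as.integer(round(paralog_fraction * n_genes))
    paralog_of <- if (n_paralog > 0L) sample.int(n_genes, n_paralog)
                  else integer()
    blocks <- c(seq_len(n_genes), paralog_of)      # gene index per block
    block_len <- footprints[blocks]
    free <- genome_size_bp - sum(block_len)
    if (free < 0)
      stop("infeasible packing: gene footprint exceeds genome size")
    ord <- sample(seq_along(blocks))               # placement order
    gaps <- diff(c(0, sort(runif(length(blocks), 0, free)), free))
    gaps <- floor(gaps)
    strand <- sample(c("+", "-"), length(blocks), replace = TRUE)
    pieces <- character(2L * length(blocks) + 1L)
    exon_start <- vector("list", n_genes)
    exon_end <- vector("list", n_genes)
    pos <- 0L
    for (j in seq_along(blocks)) {
      pieces[2L * j - 1L] <- random_dna(gaps[j], gc)
      pos <- pos + gaps[j]
      gi <- blocks[ord[j]]
      gseq <- gene_parts[[gi]]$seq
      if (strand[j] == "-")
        gseq <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gseq)))
      pieces[2L * j] <- gseq
      if (ord[j] <= n_genes) {
        # primary copy: record exon coordinates (0-based half-open)
        offs <- cumsum(c(0L, head(
          as.vector(rbind(gene_parts[[gi]]$ex_len,
                          c(gene_parts[[gi]]$in_len, 0L))), -1L)))
        rel_s <- offs[seq(1L, length(offs), by = 2L)]
        rel_e <- rel_s + gene_parts[[gi]]$ex_len
        if (strand[j] == "-") {              # mirror onto the genome strand
          fp <- footprints[gi]
          tmp <- rev(fp - rel_e)
          rel_e <- rev(fp - rel_s)
          rel_s <- tmp
        }
        exon_start[[gi]] <- as.integer(pos + rel_s)
        exon_end[[gi]] <- as.integer(pos + rel_e)
      }
      pos <- pos + nchar(pieces[2L * j])
    }
    pieces[length(pieces)] <- random_dna(genome_size_bp - pos, gc)
    sequence <- paste(pieces, collapse = "")
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    prot <- Biostrings::translate(Biostrings::DNAStringSet(cds))
    names(prot) <- gene_id
    genes <- data.frame(gene_id = gene_id,
                        strand = strand[match(seq_len(n_genes), ord)],
                        stringsAsFactors = FALSE)
    genes$exon_start <- exon_start
    genes$exon_end <- exon_end
    structure(list(
      sequence = sequence, genes = genes, proteins = prot,
      truth = list(monoploid_size_bp = genome_size_bp, ploidy = 2L,
                   exons_per_gene = n_exons,
                   cds_len = nchar(cds))),
      class = "synthetic_genome")
  })
}

#' Whole-genome duplication of a synthetic genome
#'
#' Concatenates the sequence so the total content corresponds to the target
#' ploidy (a recent autopolyploid), optionally substituting sites of the
#' extra copies at the given divergence rate. The monoploid truth size is
#' unchanged; the single-copy protein set stays that of the base genome, so
#' reads from every copy map onto the same proteins.
#'
#' @param g A `synthetic_genome`.
#' @param ploidy Target ploidy; must be a multiple of the current one.
#' @param divergence Per-site substitution rate of the extra copies
#'   (default 0, an exact duplication).
#' @param seed Optional seed for the divergence substitutions.
#' @return A `synthetic_genome` with updated `sequence` and `truth$ploidy`.
#' @export
duplicate_genome <- function(g, ploidy, divergence = 0, seed = NULL) {
  stopifnot(inherits(g, "synthetic_genome"))
  fac <- ploidy / g$truth$ploidy
  if (fac != round(fac) || fac < 1)
    stop("ploidy must be a multiple of the current ploidy (",
         g$truth$ploidy, ")")
  fac <- as.integer(fac)
  if (fac == 1L) return(g)
  with_seed(seed, {
    copies <- c(g$sequence, vapply(seq_len(fac - 1L), function(i)
      mutate_sequence(g$sequence, divergence), character(1)))
    g$sequence <- paste(copies, collapse = "")
    g$truth$ploidy <- as.integer(ploidy)
    g
  })
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  nt <- c("A", "C", "G", "T")
  for (p in pos) {
    alt <- setdiff(nt, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Sample uniform error-free (or noisy) reads from a synthetic genome
#'
#' Read count is round(depth x genome length / read length); start
#' positions and strands are uniform. Deterministic under `seed`.
#'
#' @param g A `synthetic_genome`.
#' @param depth Target fold-coverage (> 0).
#' @param read_len Read length (default 100 nt, the calibration length).
#' @param error_rate Per-base substitution rate (default 0).
#' @param seed Optional integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
sample_reads <- function(g, depth, read_len = 100L, error_rate = 0,
                         seed = NULL) {
  stopifnot(inherits(g, "synthetic_genome"), depth > 0)
  glen <- nchar(g$sequence)
  stopifnot(glen >= read_len)
  n <- round(depth * glen / read_len)
  with_seed(seed, {
    starts <- sample.int(glen - read_len + 1L, n, replace = TRUE)
    seqs <- substring(g$sequence, starts, starts + read_len - 1L)
    reads <- Biostrings::DNAStringSet(seqs)
    minus <- runif(n) < 0.5
    reads[minus] <- Biostrings::reverseComplement(reads[minus])
    if (error_rate > 0) {
      ner <- rbinom(n, read_len, error_rate)
      for (i in which(ner > 0L)) {
        reads[[i]] <- Biostrings::DNAString(
          mutate_sequence(as.character(reads[[i]]), ner[i] / read_len))
      }
    }
    names(reads) <- sprintf("read%07d", seq_len(n))
    reads
  })
}

#' Bernoulli subsampling of a read batch
#'
#' Each read is kept independently with probability `fraction`, emulating
#' depth titration by random read selection from a sequencing run.
#'
#' @param batch A [Biostrings::DNAStringSet].
#' @param fraction Keep probability in (0, 1].
#' @param seed Optional integer seed.
#' @return The subsampled batch.
#' @export
subsample_reads <- function(batch, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(batch)
  with_seed(seed, batch[runif(length(batch)) < fraction])
}

#' Write a synthetic genome to disk
#'
#' Emits `<prefix>.genome.fasta`, `<prefix>.proteins.faa` and
#' `<prefix>.truth.json`.
#'
#' @param g A `synthetic_genome`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(g, prefix) {
  gf <- paste0(prefix, ".genome.fasta")
  pf <- paste0(prefix, ".proteins.faa")
  tf <- paste0(prefix, ".truth.json")
  gs <- Biostrings::DNAStringSet(g$sequence)
  names(gs) <- "genome"
  Biostrings::writeXStringSet(gs, gf)
  Biostrings::writeXStringSet(g$proteins, pf)
  jsonlite::write_json(g$truth, tf, auto_unbox = TRUE, digits = NA)
  invisible(c(gf, pf, tf))
}
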