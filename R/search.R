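# Built-in translated search: six-frame translation of the reads, exact
# amino-acid k-mer seeding against the protein set, Smith-Waterman extension
# under BLOSUM62, and Karlin-Altschul bitscores/e-values, so the pipeline is
# fully testable with zero external binaries. An adapter runs any external
# blastx-style tool instead and parses its tabular output into the same hit
# records.

#' Scoring scheme of the built-in translated aligner
#'
#' BLOSUM62 with affine gaps (open 11, extend 1) and the conventional gapped
#' Karlin-Altschul parameters for that matrix (lambda = 0.267, K = 0.041),
#' so bitscores and the 1e-5 e-value cutoff are comparable with external
#' blastx-style backends.
#'
#' @param gap_open,gap_extend Positive gap penalties.
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters.
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           karlin_lambda = 0.267, karlin_k = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_k > 0)
  structure(list(matrix = blosum62(), gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Six-frame translation of a nucleotide sequence
#'
#' Frames +1..+3 read the sequence itself, -1..-3 its reverse complement;
#' the standard genetic code is used, stop codons become `*` and codons
#' containing ambiguity letters become `X`. Sequences shorter than 3 nt
#' yield six empty peptides.
#'
#' @param sequence A nucleotide string or [Biostrings::DNAString].
#' @return A named character vector of 6 peptides
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
sixframe_translate <- function(sequence) {
  b <- Biostrings::DNAStringSet(as.character(sequence))
  fr <- translate_frames(b)
  setNames(vapply(fr, `[`, character(1), 1L), names(fr))
}

# vectorised frame translation of a whole batch; returns a list of six
# character vectors named +1..+3, -1..-3
translate_frames <- function(batch) {
  w <- Biostrings::width(batch)
  rc <- Biostrings::reverseComplement(batch)
  one <- function(set, off) {
    wid <- pmax(0L, ((Biostrings::width(set) - off) %/% 3L) * 3L)
    sub <- XVector::subseq(set, start = off + 1L, width = wid)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  out <- list(
    `+1` = one(batch, 0L), `+2` = one(batch, 1L), `+3` = one(batch, 2L),
    `-1` = one(rc, 0L), `-2` = one(rc, 1L), `-3` = one(rc, 2L))
  out
}

FRAME_CODES <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Search a read batch against a protein set
#'
#' For every read, exact amino-acid seeds of length `seed_len_aa` shared
#' between any translation frame and any protein trigger a local
#' (Smith-Waterman) extension under the scoring scheme. A seeded diagonal is
#' extended in gapped mode only when its best ungapped segment reaches
#' `min_ungapped_score`; because every gap costs at least
#' `gap_open + gap_extend`, any alignment able to pass the e-value cutoff at
#' realistic search-space sizes contains such a segment, so the gate prunes
#' random seed matches without changing the reported hit set. Bitscores are
#' (lambda*S - ln K)/ln 2 and e-values use the effective search space
#' (total read nt / 3) x (total protein residues). At most one hit (the
#' best-scoring frame) is kept per (read, protein) pair.
#'
#' @param batch Named [Biostrings::DNAStringSet] of (trimmed) reads.
#' @param proteins Named [Biostrings::AAStringSet].
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Hits with larger e-value are discarded (default 1e-5).
#' @param seed_len_aa Exact seed length in residues (default 5). Frames
#'   shorter than this are skipped.
#' @param min_ungapped_score Raw-score gate of the ungapped pre-extension.
#' @return A hits `data.frame` (see [parse_tabular_hits()] for columns).
#' @export
search_reads <- function(batch, proteins, scheme = scoring_scheme(),
                         evalue_max = 1e-5, seed_len_aa = 5L,
                         min_ungapped_score = 40) {
  stopifnot(length(proteins) > 0L)
  if (length(batch) == 0L) return(empty_hits())
  if (is.null(names(batch))) names(batch) <- as.character(seq_along(batch))
  n <- length(batch)
  frames <- translate_frames(batch)
  peptides <- unlist(frames, use.names = FALSE)   # 6n, frame-major blocks
  prot_seqs <- as.character(proteins)
  pairs <- seed_scan_cpp(peptides, prot_seqs, as.integer(seed_len_aa),
                         scheme$matrix, min_ungapped_score)
  if (length(pairs$pep) == 0L) return(empty_hits())

  read_idx <- ((pairs$pep - 1L) %% n) + 1L
  frame_slot <- ((pairs$pep - 1L) %/% n) + 1L
  total_read_nt <- cumulative_length(batch)
  total_prot_res <- sum(as.numeric(Biostrings::width(proteins)))
  space <- (total_read_nt / 3) * total_prot_res

  res <- vector("list", length(prot_seqs))
  for (p in sort(unique(pairs$prot))) {
    sel <- which(pairs$prot == p)
    pep <- Biostrings::AAStringSet(peptides[pairs$pep[sel]])
    aln <- Biostrings::pairwiseAlignment(
      pep, Biostrings::AAString(prot_seqs[p]), type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    raw <- Biostrings::score(aln)
    bit <- (scheme$karlin_lambda * raw - log(scheme$karlin_k)) / log(2)
    ev <- space * 2^(-bit)
    keep <- which(ev <= evalue_max)
    if (length(keep) == 0L) next
    aln <- aln[keep]
    ind <- indel_counts(aln)
    aa_s <- IRanges::start(Biostrings::pattern(aln))
    aa_e <- IRanges::end(Biostrings::pattern(aln))
    qc <- frame_to_read_coords(frame_slot[sel][keep],
                               Biostrings::width(batch)[read_idx[sel][keep]],
                               aa_s, aa_e)
    res[[p]] <- data.frame(
      read_id = names(batch)[read_idx[sel][keep]],
      protein_id = names(proteins)[p],
      pident = 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln),
      align_len_aa = Biostrings::nchar(aln),
      mismatch = Biostrings::nmismatch(aln),
      gapopen = ind,
      qstart = qc$qstart, qend = qc$qend,
      sstart = IRanges::start(Biostrings::subject(aln)),
      send = IRanges::end(Biostrings::subject(aln)),
      evalue = ev[keep], bitscore = bit[keep],
      frame = FRAME_CODES[frame_slot[sel][keep]],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(hits)) return(empty_hits())
  rownames(hits) <- NULL
  # best frame per (read, protein)
  o <- order(hits$read_id, hits$protein_id, -hits$bitscore, hits$evalue)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits[c("read_id", "protein_id")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# number of gap openings (insertion runs + deletion runs) per alignment
indel_counts <- function(aln) {
  ni <- Biostrings::nindel(aln)
  Biostrings::insertion(ni)[, "Length"] + Biostrings::deletion(ni)[, "Length"]
}

# map residue positions on a frame peptide back to 1-based nucleotide
# coordinates on the original read (qstart > qend on the reverse strand)
frame_to_read_coords <- function(frame_slot, read_width, aa_start, aa_end) {
  f <- ((frame_slot - 1L) %% 3L) + 1L       # frame offset 1..3
  fwd <- frame_slot <= 3L
  nt_s <- f + 3L * (aa_start - 1L)          # on read (fwd) or revcomp (rev)
  nt_e <- f + 3L * aa_end - 1L
  list(qstart = ifelse(fwd, nt_s, read_width + 1L - nt_s),
       qend   = ifelse(fwd, nt_e, read_width + 1L - nt_e))
}

#' Select one best hit per read
#'
#' Highest bitscore wins; ties are broken by lowest e-value, then by
#' lexicographically smallest protein id so results are deterministic.
#'
#' @param hits A hits `data.frame`.
#' @return A hits `data.frame` with at most one row per `read_id`.
#' @export
best_hit_per_read <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$read_id, -hits$bitscore, hits$evalue, hits$protein_id)
  hits <- hits[o, , drop = FALSE]
  hits <- hits[!duplicated(hits$read_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Recompute e-values for a different search space and refilter
#'
#' E-values depend on the cumulative input length; when a hit set obtained
#' on a full read set is restricted to a subsample (depth titration), this
#' recomputes each e-value from the bitscore under the subsample's search
#' space and applies the cutoff, reproducing what an independent search of
#' the subsample reports.
#'
#' @param hits A hits `data.frame` with a `bitscore` column.
#' @param total_read_nt Cumulative read length of the (sub)sample.
#' @param total_protein_res Total residues in the protein set.
#' @param evalue_max Cutoff (default 1e-5).
#' @return The refiltered hits with updated `evalue`.
#' @export
refilter_hits <- function(hits, total_read_nt, total_protein_res,
                          evalue_max = 1e-5) {
  if (nrow(hits) == 0L) return(hits)
  space <- (total_read_nt / 3) * total_protein_res
  hits$evalue <- space * 2^(-hits$bitscore)
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Run an external blastx-style aligner
#'
#' Executes a user-supplied shell command template containing the
#' placeholders `{query}`, `{db}` and `{out}`, then parses the 12-column
#' tabular output with [parse_tabular_hits()], giving the same downstream
#' contract as [search_reads()]. Reads are written as FASTA for the tool.
#'
#' @param batch Named [Biostrings::DNAStringSet] of (trimmed) reads.
#' @param protein_fasta_path Path to the protein FASTA database.
#' @param command_template Shell command with `{query}`, `{db}`, `{out}`.
#' @param workdir Directory for temporary files.
#' @return A hits `data.frame`.
#' @export
run_external_search <- function(batch, protein_fasta_path, command_template,
                                workdir = tempdir()) {
  for (ph in c("{query}", "{db}", "{out}"))
    if (!grepl(ph, command_template, fixed = TRUE))
      stop("command template lacks placeholder ", ph)
  query <- file.path(workdir, "skimsize_query.fasta")
  out <- file.path(workdir, "skimsize_hits.tsv")
  Biostrings::writeXStringSet(batch, query)
  cmd <- command_template
  cmd <- gsub("{query}", query, cmd, fixed = TRUE)
  cmd <- gsub("{db}", protein_fasta_path, cmd, fixed = TRUE)
  cmd <- gsub("{out}", out, cmd, fixed = TRUE)
  errfile <- file.path(workdir, "skimsize_external.err")
  status <- system2("sh", c("-c", shQuote(cmd)), stdout = FALSE,
                    stderr = errfile)
  if (status != 0L) {
    err <- if (file.exists(errfile))
      paste(readLines(errfile, warn = FALSE), collapse = "\n") else ""
    stop("external aligner failed (exit ", status, "): ", err)
  }
  parse_tabular_hits(out)
}
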