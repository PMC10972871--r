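# Readers and writers for every external format the tool touches: protein
# FASTA, FASTQ(.gz) reads, 12-column blastx-style tabular hits, slope tables
# and reports. No science lives here.

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                "R","S","T","V","W","Y","X")

#' Read a single-copy protein FASTA file
#'
#' Headers are truncated at the first whitespace to obtain the protein id;
#' sequences are uppercased and must use the 20 amino-acid letters plus X.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return An [Biostrings::AAStringSet] named by protein id.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("sequence letters outside the amino-acid alphabet in ", path,
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L) stop("no proteins in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(aa))
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("protein(s) with letters outside the amino-acid alphabet: ",
         paste(ids[bad][seq_len(min(3L, sum(bad)))], collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read one or two FASTQ files into a read batch
#'
#' Mates of a pair are treated as independent reads and simply concatenated;
#' when the two files share read ids, "/1" and "/2" suffixes are appended so
#' best-hit selection never collapses a pair. Quality lines are discarded.
#' Gzipped input is detected from the file content.
#'
#' @param paths One or two FASTQ(.gz) paths.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(paths) {
  stopifnot(length(paths) %in% c(1L, 2L))
  one <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    lines <- readLines(p, warn = FALSE)
    while (length(lines) > 0L && !nzchar(lines[length(lines)]))
      lines <- lines[-length(lines)]
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ in ", p, ": truncated record ",
           length(lines) %/% 4L + 1L, call. = FALSE)
    x <- tryCatch(
      Biostrings::readDNAStringSet(p, format = "fastq"),
      error = function(e)
        stop("malformed FASTQ in ", p, ": ", conditionMessage(e),
             call. = FALSE))
    names(x) <- sub("\\s.*$", "", names(x))
    x
  }
  if (length(paths) == 1L) return(one(paths))
  a <- one(paths[[1]]); b <- one(paths[[2]])
  if (any(names(a) %in% names(b))) {
    names(a) <- paste0(names(a), "/1")
    names(b) <- paste0(names(b), "/2")
  }
  c(a, b)
}

#' Write a read batch as FASTQ
#'
#' @param batch A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fastq <- function(batch, path) {
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(batch),
           function(w) paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(batch, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Total read length of a batch
#'
#' L, the cumulative length in nucleotides of the reads used as input for
#' mapping; the numerator of the Lander-Waterman relation.
#'
#' @param batch A [Biostrings::DNAStringSet].
#' @return A non-negative number.
#' @export
cumulative_length <- function(batch) {
  if (length(batch) == 0L) return(0)
  sum(as.numeric(Biostrings::width(batch)))
}

HIT_COLUMNS <- c("read_id", "protein_id", "pident", "align_len_aa",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore", "frame")

empty_hits <- function() {
  data.frame(read_id = character(), protein_id = character(),
             pident = numeric(), align_len_aa = integer(),
             mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(), frame = integer(),
             stringsAsFactors = FALSE)
}

#' Parse a 12-column blastx-style tabular alignment file
#'
#' Columns follow the standard tabular convention: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore, with
#' 1-based inclusive coordinates. Reverse-strand hits are recognised by
#' qstart > qend; the tabular format does not record the frame index, so
#' reverse hits get frame -1 and forward hits ((qstart - 1) mod 3) + 1.
#'
#' @param path Path to a tab-separated file without header.
#' @return A hits `data.frame` (one row per alignment).
#' @export
parse_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1],
         " at line ", which(nf != 12L)[1])
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("non-numeric ", what, " at line ", which(is.na(v))[1])
    v
  }
  qstart <- as.integer(num(7, "qstart")); qend <- as.integer(num(8, "qend"))
  data.frame(
    read_id = m[, 1], protein_id = m[, 2],
    pident = num(3, "pident"),
    align_len_aa = as.integer(num(4, "length")),
    mismatch = as.integer(num(5, "mismatch")),
    gapopen = as.integer(num(6, "gapopen")),
    qstart = qstart, qend = qend,
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    frame = ifelse(qstart <= qend, ((qstart - 1L) %% 3L) + 1L, -1L),
    stringsAsFactors = FALSE)
}

#' Write hits in the 12-column tabular dialect
#'
#' Numeric fields are written with full precision so that
#' [parse_tabular_hits()] reproduces them exactly.
#'
#' @param hits A hits `data.frame`.
#' @param path Output path.
#' @export
write_tabular_hits <- function(hits, path) {
  g17 <- function(x) sprintf("%.17g", x)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   hits$read_id, hits$protein_id, g17(hits$pident),
                   hits$align_len_aa, hits$mismatch, hits$gapopen,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   g17(hits$evalue), g17(hits$bitscore))
  writeLines(lines, path)
  invisible(path)
}

#' Read a slope (calibration coefficient) table
#'
#' A two-or-more-column TSV with a header containing `group` and `slope`.
#' Group lookup is case-insensitive; a `default` entry with slope 1 is added
#' when absent, matching the behaviour of estimation without calibration.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `slope_table` with columns `group`,
#'   `slope` (and any extra columns present in the file).
#' @export
read_slope_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("group", "slope") %in% names(tab)))
    stop("slope table needs 'group' and 'slope' columns")
  as_slope_table(tab)
}

#' Build a slope table from a data frame
#' @param tab `data.frame` with columns `group` and `slope`.
#' @return A `slope_table`.
#' @export
as_slope_table <- function(tab) {
  tab$slope <- as.numeric(tab$slope)
  if (any(!is.finite(tab$slope) | tab$slope <= 0))
    stop("slope(s) must be positive: ",
         paste(tab$group[!is.finite(tab$slope) | tab$slope <= 0],
               collapse = ", "))
  dup <- unique(tab$group[duplicated(tolower(tab$group))])
  if (length(dup) > 0L)
    stop("duplicate group(s) in slope table: ", paste(dup, collapse = ", "))
  if (!"default" %in% tolower(tab$group))
    tab <- rbind(tab[, c("group", "slope")],
                 data.frame(group = "default", slope = 1))
  class(tab) <- c("slope_table", "data.frame")
  tab
}

#' Look up a slope by group name
#'
#' Case-insensitive. Unknown groups fall back to the `default` slope of 1
#' with a warning, so estimation proceeds uncalibrated rather than failing.
#'
#' @param table A `slope_table`.
#' @param group Group (lineage or family) name.
#' @return A single positive slope.
#' @export
slope_lookup <- function(table, group) {
  i <- match(tolower(group), tolower(table$group))
  if (is.na(i)) {
    warning("group '", group, "' not in slope table; using default slope ",
            "of the uncalibrated estimator", call. = FALSE)
    i <- match("default", tolower(table$group))
  }
  table$slope[i]
}

#' Write a slope table as TSV
#' @param table A `slope_table`.
#' @param path Output path.
#' @export
write_slope_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a genome size report as TSV and JSON
#'
#' Emits `<prefix>.tsv` and `<prefix>.json` with the cumulative read length,
#' SCP depth, slope, group, retained/removed protein counts and the 1Cx
#' estimate in bp and Mb; when the estimate carries a per-protein depth
#' profile, `<prefix>.depth.tsv` is written as well.
#'
#' @param estimate A `size_estimate` (see [estimate_size()]).
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(estimate, prefix) {
  stopifnot(inherits(estimate, "size_estimate"))
  fields <- list(
    L = estimate$L, scp_depth = estimate$scp_depth, beta = estimate$beta,
    group = estimate$group, n_retained = estimate$n_retained,
    n_removed = estimate$n_removed, one_cx_bp = estimate$one_cx_bp,
    one_cx_mb = estimate$one_cx_mb)
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  df <- data.frame(field = names(fields),
                   value = vapply(fields, function(x)
                     if (is.numeric(x)) sprintf("%.17g", x) else as.character(x),
                     character(1)))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fields, json, auto_unbox = TRUE, digits = NA)
  paths <- c(tsv, json)
  profile <- attr(estimate, "profile")
  if (!is.null(profile)) {
    dtsv <- paste0(prefix, ".depth.tsv")
    write.table(profile, dtsv, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, dtsv)
  }
  invisible(paths)
}
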