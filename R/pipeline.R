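# Orchestration: trim -> translated search -> best hit -> per-protein depth
# -> Z-score filter -> size equation, with slope selection by lineage group.

#' Estimate monoploid genome size from reads and a single-copy protein set
#'
#' Runs the four pipeline steps: reads are trimmed to the calibration
#' length, aligned in translated space on the protein set (built-in aligner,
#' or a precomputed tabular hit file), one best hit per read is kept, the
#' per-protein depths are outlier-filtered by Z-score, and the monoploid
#' size is computed as G = L / (beta * SCP depth).
#'
#' @param reads FASTQ path(s) (one or two files) or a named
#'   [Biostrings::DNAStringSet]. Optional when `hits` and `total_read_nt`
#'   are supplied.
#' @param proteins Protein FASTA path or a named [Biostrings::AAStringSet].
#' @param hits Optional precomputed 12-column tabular hit file (path) or
#'   hits `data.frame`; skips the built-in alignment.
#' @param group Lineage/family label looked up in `slope_table`; `NULL`
#'   (with no `slope`) means the uncalibrated default slope 1.
#' @param slope Explicit slope value; overrides `group`.
#' @param slope_table A `slope_table`, a TSV path, or `NULL` to use the
#'   table shipped with the package (pooled Angiosperm slope `all` = 1.56
#'   and `default` = 1).
#' @param trim_len,no_trim See [trim_reads()].
#' @param evalue_max,seed_len_aa,scheme See [search_reads()].
#' @param z_max See [zscore_filter()].
#' @param use_full_read_length See [per_protein_depth()].
#' @param total_read_nt Cumulative post-trim read length; required when
#'   `hits` is given without `reads`.
#' @param report Optional output path prefix; when given,
#'   [write_report()] is called.
#' @param verbose Log progress with [message()].
#' @return A `size_estimate` with the filtered `depth_profile` attached as
#'   attribute `profile` and the best hits as attribute `best_hits`.
#' @export
estimate_genome_size <- function(reads = NULL, proteins, hits = NULL,
                                 group = NULL, slope = NULL,
                                 slope_table = NULL,
                                 trim_len = 100L, no_trim = FALSE,
                                 evalue_max = 1e-5, seed_len_aa = 5L,
                                 scheme = scoring_scheme(), z_max = 1.96,
                                 use_full_read_length = TRUE,
                                 total_read_nt = NULL, report = NULL,
                                 verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(proteins)) proteins <- read_protein_fasta(proteins)
  batch <- NULL
  if (!is.null(reads)) {
    batch <- if (is.character(reads)) read_fastq(reads) else reads
    batch <- trim_reads(batch, target_len = trim_len, no_trim = no_trim)
  }
  if (is.null(hits)) {
    if (is.null(batch)) stop("either reads or hits must be supplied")
    L <- cumulative_length(batch)
    say("searching ", length(batch), " reads (L = ", L, " nt) against ",
        length(proteins), " proteins")
    hits <- search_reads(batch, proteins, scheme = scheme,
                         evalue_max = evalue_max,
                         seed_len_aa = seed_len_aa)
  } else {
    if (is.character(hits)) hits <- parse_tabular_hits(hits)
    L <- if (!is.null(total_read_nt)) total_read_nt
         else if (!is.null(batch)) cumulative_length(batch)
         else stop("total_read_nt is required when hits are supplied ",
                   "without reads")
  }
  best <- best_hit_per_read(hits)
  say(nrow(best), " reads with a best hit")
  read_lengths <- if (!is.null(batch))
    setNames(Biostrings::width(batch), names(batch)) else trim_len
  profile <- per_protein_depth(best, proteins,
                               use_full_read_length = use_full_read_length,
                               read_lengths = read_lengths)
  profile <- zscore_filter(profile, z_max = z_max)
  n_ret <- sum(profile$retained); n_rem <- sum(!profile$retained)
  say(n_ret, " proteins retained, ", n_rem, " removed by the Z-score filter")
  scp <- overall_scp_depth(profile)
  beta_group <- resolve_slope(group, slope, slope_table)
  est <- estimate_size(L, scp, beta = beta_group$slope,
                       group = beta_group$group,
                       n_retained = n_ret, n_removed = n_rem)
  attr(est, "profile") <- profile
  attr(est, "best_hits") <- best
  say(sprintf("1Cx = %.3f Mb (beta = %.3f, SCP depth = %.4f)",
              est$one_cx_mb, est$beta, est$scp_depth))
  if (!is.null(report)) write_report(est, report)
  est
}

resolve_slope <- function(group, slope, slope_table) {
  if (!is.null(slope)) {
    if (slope <= 0) stop("slope must be positive")
    return(list(slope = slope, group = if (is.null(group)) "manual" else group))
  }
  if (is.null(group)) return(list(slope = 1, group = "default"))
  tab <- load_slope_table(slope_table)
  list(slope = slope_lookup(tab, group), group = group)
}

load_slope_table <- function(slope_table) {
  if (is.null(slope_table))
    read_slope_table(system.file("extdata", "slopes.tsv",
                                 package = "skimsize", mustWork = TRUE))
  else if (is.character(slope_table)) read_slope_table(slope_table)
  else as_slope_table(slope_table)
}

#' List the groups available in a slope table
#'
#' @param slope_table A `slope_table`, a TSV path, or `NULL` for the table
#'   shipped with the package.
#' @return Sorted unique group names, invisibly; also printed.
#' @export
list_groups <- function(slope_table = NULL) {
  tab <- load_slope_table(slope_table)
  groups <- sort(unique(tab$group))
  cat(groups, sep = "\n")
  invisible(groups)
}
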