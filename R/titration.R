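# Depth titration: size estimates on nested subsamples of one simulated
# sequencing run, emulating the evaluation of the depth of coverage a
# genome skim needs before the estimate plateaus.

#' Genome size estimates across a ladder of sequencing depths
#'
#' Samples one read set from a synthetic genome at the largest requested
#' depth, aligns it once, and then estimates the genome size on nested
#' Bernoulli subsamples corresponding to each depth. Because reads are
#' processed independently, restricting the hit set to a subsample and
#' recomputing e-values under the subsample's search space (see
#' [refilter_hits()]) reproduces what an independent run on that subsample
#' reports, at a fraction of the alignment cost. The initial search runs at
#' a relaxed e-value cutoff so that hits which only pass under the smaller
#' search space of a shallow subsample are not lost.
#'
#' @param g A `synthetic_genome`.
#' @param depths Fold-coverages to evaluate.
#' @param seed Integer seed driving read sampling and subsampling.
#' @param beta Slope used for the estimates (default 1).
#' @param evalue_max Per-depth e-value cutoff (default 1e-5).
#' @param search_evalue Relaxed cutoff of the shared search (default 1e-3).
#' @return A `data.frame` with one row per depth: `depth`, `n_reads`, `L`,
#'   `scp_depth`, `one_cx_bp`, `percent_error` (vs the truth monoploid
#'   size).
#' @export
titrate_depths <- function(g, depths, seed = NULL, beta = 1,
                           evalue_max = 1e-5, search_evalue = 1e-3) {
  stopifnot(inherits(g, "synthetic_genome"), all(depths > 0))
  dmax <- max(depths)
  reads <- sample_reads(g, depth = dmax, seed = seed)
  hits <- search_reads(reads, g$proteins, evalue_max = search_evalue)
  total_prot_res <- sum(as.numeric(Biostrings::width(g$proteins)))
  rows <- lapply(seq_along(depths), function(i) {
    d <- depths[i]
    sub <- if (d == dmax) reads
           else subsample_reads(reads, d / dmax,
                                seed = if (is.null(seed)) NULL
                                       else seed + i)
    L <- cumulative_length(sub)
    h <- hits[hits$read_id %in% names(sub), , drop = FALSE]
    h <- refilter_hits(h, L, total_prot_res, evalue_max = evalue_max)
    best <- best_hit_per_read(h)
    prof <- zscore_filter(per_protein_depth(
      best, g$proteins,
      read_lengths = setNames(Biostrings::width(sub), names(sub))))
    est <- estimate_size(L, overall_scp_depth(prof), beta = beta)
    data.frame(depth = d, n_reads = length(sub), L = L,
               scp_depth = est$scp_depth, one_cx_bp = est$one_cx_bp,
               percent_error = percent_error(est$one_cx_bp,
                                             g$truth$monoploid_size_bp))
  })
  do.call(rbind, rows)
}
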