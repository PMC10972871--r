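# From best hits to a genome size: per-protein mapping depth, Z-score
# outlier removal, overall single-copy-protein (SCP) depth, and the modified
# Lander-Waterman conversion G = L / (beta * SCP depth).

#' Per-protein mapping depth
#'
#' Depth is computed in nucleotide space: for each protein, the mapped
#' nucleotides (by default the full post-trim length of every read whose
#' best hit lands on it, matching "total length of reads mapped"; optionally
#' 3 x the aligned residue span) divided by 3 x the protein length. Every
#' protein of the set appears exactly once; proteins with no hits get
#' depth 0.
#'
#' @param best_hits A hits `data.frame` with at most one row per read
#'   (see [best_hit_per_read()]).
#' @param proteins Named [Biostrings::AAStringSet].
#' @param use_full_read_length If `TRUE` (default) count the full post-trim
#'   read length per mapped read; if `FALSE` count 3 x `align_len_aa`
#'   (aligned-span convention, for sensitivity analysis).
#' @param read_lengths Either a single post-trim read length (default 100)
#'   or a vector of lengths named by read id.
#' @return A `data.frame` of class `depth_profile` with columns
#'   `protein_id`, `length_aa`, `n_reads`, `mapped_nt`, `depth`.
#' @export
per_protein_depth <- function(best_hits, proteins,
                              use_full_read_length = TRUE,
                              read_lengths = 100L) {
  stopifnot(!anyDuplicated(best_hits$read_id))
  ids <- names(proteins)
  unknown <- setdiff(unique(best_hits$protein_id), ids)
  if (length(unknown) > 0L)
    stop("hit(s) reference unknown protein id(s): ",
         paste(unknown[seq_len(min(3L, length(unknown)))], collapse = ", "))
  if (use_full_read_length) {
    if (!is.null(names(read_lengths))) {
      nt <- unname(read_lengths[best_hits$read_id])
      if (anyNA(nt))
        stop("read length missing for read(s): ",
             best_hits$read_id[is.na(nt)][1])
    } else {
      nt <- rep(as.numeric(read_lengths[1]), nrow(best_hits))
    }
  } else {
    nt <- 3 * as.numeric(best_hits$align_len_aa)
  }
  f <- factor(best_hits$protein_id, levels = ids)
  mapped_nt <- as.numeric(tapply(nt, f, sum, default = 0))
  n_reads <- as.integer(tapply(rep(1L, nrow(best_hits)), f, sum, default = 0))
  length_aa <- Biostrings::width(proteins)
  out <- data.frame(protein_id = ids, length_aa = length_aa,
                    n_reads = n_reads, mapped_nt = mapped_nt,
                    depth = mapped_nt / (3 * length_aa),
                    stringsAsFactors = FALSE)
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Z-score outlier filtering of the depth profile
#'
#' Proteins whose depth deviates from the set mean by more than `z_max`
#' sample standard deviations are flagged as removed: these typically
#' correspond to genes lost or duplicated in the sample, or to proteins with
#' unspecific domains. The default cutoff 1.96 is the two-sided standard
#' normal critical value for P < 0.05. Mean and (n-1) standard deviation are
#' computed once over all proteins (single pass, no re-iteration). With
#' fewer than 3 proteins or zero spread, no protein is removed and Z-scores
#' are undefined.
#'
#' @param profile A `depth_profile` from [per_protein_depth()].
#' @param z_max Two-sided Z cutoff (default 1.96).
#' @return The profile with `zscore` and `retained` columns and attributes
#'   `mean_depth` / `sd_depth`.
#' @export
zscore_filter <- function(profile, z_max = 1.96) {
  stopifnot(nrow(profile) > 0L)
  m <- mean(profile$depth)
  s <- sd(profile$depth)
  if (nrow(profile) < 3L || is.na(s) || s == 0) {
    profile$zscore <- NA_real_
    profile$retained <- TRUE
  } else {
    profile$zscore <- (profile$depth - m) / s
    profile$retained <- abs(profile$zscore) <= z_max
  }
  attr(profile, "mean_depth") <- m
  attr(profile, "sd_depth") <- s
  profile
}

#' Overall single-copy-protein depth
#'
#' Total mapped nucleotides on all retained proteins divided by the
#' cumulative nucleotide-equivalent length (3 x residues) of the retained
#' proteins.
#'
#' @param profile A filtered `depth_profile` (with a `retained` column; a
#'   profile without one is taken as all-retained).
#' @return A single fold-coverage value.
#' @export
overall_scp_depth <- function(profile) {
  keep <- if ("retained" %in% names(profile)) profile$retained
          else rep(TRUE, nrow(profile))
  tot_nt <- sum(profile$mapped_nt[keep])
  tot_len <- sum(3 * as.numeric(profile$length_aa[keep]))
  if (sum(keep) == 0L || tot_len == 0 || tot_nt == 0)
    stop("no usable signal: no retained protein with mapped reads")
  tot_nt / tot_len
}

#' Monoploid genome size from cumulative length, depth and slope
#'
#' G(1Cx) = L / (beta * SCP depth): the Lander-Waterman relation G = L/C
#' with the true depth C estimated as beta times the observed single-copy
#' protein depth. beta > 1 compensates reads lost at exon junctions during
#' protein-space mapping.
#'
#' @param L Cumulative post-trim read length (nt).
#' @param scp_depth Outlier-filtered SCP depth (> 0).
#' @param beta Calibration slope (> 0; default 1, the uncalibrated case).
#' @param group Label of the slope used (for the report).
#' @param n_retained,n_removed Retained/removed protein counts (optional).
#' @return An object of class `size_estimate` with fields `L`, `scp_depth`,
#'   `beta`, `group`, `one_cx_bp`, `one_cx_mb`, `n_retained`, `n_removed`.
#' @export
estimate_size <- function(L, scp_depth, beta = 1, group = "default",
                          n_retained = NA_integer_,
                          n_removed = NA_integer_) {
  if (!is.finite(scp_depth) || scp_depth <= 0)
    stop("scp_depth must be positive")
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  one_cx_bp <- L / (beta * scp_depth)
  structure(list(L = L, scp_depth = scp_depth, beta = beta, group = group,
                 one_cx_bp = one_cx_bp, one_cx_mb = one_cx_bp / 1e6,
                 n_retained = n_retained, n_removed = n_removed),
            class = "size_estimate")
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf("Monoploid genome size estimate\n"))
  cat(sprintf("  L (cumulative read nt): %.0f\n", x$L))
  cat(sprintf("  SCP depth:              %.4f\n", x$scp_depth))
  cat(sprintf("  slope (beta), group:    %.3f, %s\n", x$beta, x$group))
  if (!is.na(x$n_retained))
    cat(sprintf("  proteins retained/removed: %d / %d\n",
                x$n_retained, x$n_removed))
  cat(sprintf("  1Cx: %.3f Mb (%.0f bp)\n", x$one_cx_mb, x$one_cx_bp))
  invisible(x)
}

#' Signed percent error of a prediction
#'
#' (predicted - expected) x 100 / expected.
#'
#' @param predicted,expected Numeric vectors; `expected` must be positive.
#' @return Signed percentage(s).
#' @export
percent_error <- function(predicted, expected) {
  if (any(expected <= 0)) stop("expected size must be positive")
  (predicted - expected) * 100 / expected
}
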