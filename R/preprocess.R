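# Read length normalisation. The slope calibration is performed on 100-nt
# reads and mapping efficiency depends strongly on read length (longer reads
# overlap exon junctions more often), so estimation input is trimmed to the
# calibration length first.

#' Trim reads to the calibration length
#'
#' Each read is truncated to its first `target_len` nucleotides; shorter
#' reads pass unchanged (truncation only, never removal, so the cumulative
#' length is not biased downward relative to the calibration).
#'
#' @param batch A [Biostrings::DNAStringSet].
#' @param target_len Target read length in nt (default 100, the length the
#'   shipped calibration was performed on). Must be at least 30: below that,
#'   translated alignment of the read is meaningless.
#' @param no_trim If `TRUE` the batch is returned unchanged (for input that
#'   is already exactly the calibration length).
#' @return The trimmed [Biostrings::DNAStringSet].
#' @export
trim_reads <- function(batch, target_len = 100L, no_trim = FALSE) {
  if (no_trim) return(batch)
  if (target_len < 30L)
    stop("target_len must be >= 30 nt (got ", target_len, ")")
  if (length(batch) == 0L) return(batch)
  w <- Biostrings::width(batch)
  XVector::subseq(batch, start = 1L, width = pmin(w, as.integer(target_len)))
}
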