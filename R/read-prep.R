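#' Per-read statistics from a FASTQ file
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return data.frame with columns `read_id`, `length`, `mean_quality`
#'   (arithmetic mean of per-base Phred scores).
#' @export
fastq_read_stats <- function(path) {
  qs <- Biostrings::readQualityScaledDNAStringSet(path)
  q <- as(Biostrings::quality(qs), "IntegerList")
  data.frame(read_id = names(qs),
             length = Biostrings::width(qs),
             mean_quality = vapply(q, function(x) mean(as.numeric(x)), numeric(1)))
}

#' Filter long reads by length and drop the lowest-quality fraction
#'
#' Applies a strict length cutoff (`length > min_length_exclusive`, matching
#' the convention of keeping "reads > 5 kb" / "> 20 kb"), then removes the
#' `floor(drop_worst_fraction * n)` reads with the lowest mean Phred quality
#' among the length-passing reads. Input order of the retained reads is
#' preserved.
#'
#' @param reads data.frame with columns `read_id`, `length`, `mean_quality`.
#' @param min_length_exclusive Length threshold in bases; retained reads are
#'   strictly longer.
#' @param drop_worst_fraction Fraction of length-passing reads to discard by
#'   lowest mean quality, in \[0, 1).
#' @return The retained subset of `reads`, original order preserved.
#' @export
filter_reads <- function(reads, min_length_exclusive = 0,
                         drop_worst_fraction = 0) {
  stopifnot(all(c("length", "mean_quality") %in% names(reads)))
  if (min_length_exclusive < 0) stop("min_length_exclusive must be >= 0")
  if (drop_worst_fraction < 0 || drop_worst_fraction >= 1) {
    stop("drop_worst_fraction must be in [0, 1)")
  }
  kept <- reads[reads$length > min_length_exclusive, , drop = FALSE]
  n_drop <- floor(drop_worst_fraction * nrow(kept))
  if (n_drop > 0) {
    # ties broken by position so the filter is deterministic
    drop_idx <- order(kept$mean_quality, seq_len(nrow(kept)))[seq_len(n_drop)]
    kept <- kept[-drop_idx, , drop = FALSE]
  }
  kept
}

#' Cumulative read-output curve
#'
#' For each length threshold L, the total number of bases contained in reads
#' of length >= L. Used to judge whether enough long reads are available to
#' span the longest repeats of a metagenome.
#'
#' @param reads data.frame with a `length` column.
#' @return data.frame with columns `threshold` (bases, starting at 0 and then
#'   every distinct read length) and `cumulative_bases` (non-increasing; the
#'   value at threshold 0 equals the total base count).
#' @export
cumulative_output_curve <- function(reads) {
  len <- as.numeric(reads$length)
  thresholds <- sort(unique(c(0, len)))
  cum <- vapply(thresholds, function(L) sum(len[len >= L]), numeric(1))
  data.frame(threshold = thresholds, cumulative_bases = cum)
}

#' Check whether reads can span the longest repeat
#'
#' A read can anchor an assembly across a repeat if it is at least as long as
#' the repeat plus an anchor of unique sequence on each side.
#'
#' @param reads data.frame with a `length` column.
#' @param longest_repeat Longest repeat length in bases.
#' @param anchor Required unique anchor on each side, in bases (>= 0).
#' @return A list with `spanning_capable_count` and `feasible` (TRUE when at
#'   least one read is long enough).
#' @export
repeat_spanning_check <- function(reads, longest_repeat, anchor = 1000) {
  if (anchor < 0) stop("anchor must be >= 0")
  n <- sum(reads$length >= longest_repeat + 2 * anchor)
  list(spanning_capable_count = n, feasible = n >= 1)
}
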