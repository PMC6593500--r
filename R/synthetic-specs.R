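#' Specification of a replicon to simulate
#'
#' Describes one replicon (chromosome, plasmid or phage) of a synthetic
#' community: its length, target GC content, topology and any exact repeat
#' blocks to plant (emulating multicopy elements such as rRNA operons and
#' transposases, the main cause of assembly breaks in low-complexity dairy
#' metagenomes).
#'
#' @param id Replicon identifier.
#' @param kind One of `"chromosome"`, `"plasmid"`, `"phage"`.
#' @param length Replicon length in bases (> 0).
#' @param gc_target Target GC fraction, strictly between 0 and 1.
#' @param circular Logical; circular topology (reads may wrap the origin).
#' @param repeat_blocks `data.frame` with columns `block_length` and
#'   `copy_number` (one row per repeat family), or `NULL` for none.
#' @return An object of class `replicon_spec`.
#' @export
replicon_spec <- function(id, kind = c("chromosome", "plasmid", "phage"),
                          length, gc_target = 0.5, circular = TRUE,
                          repeat_blocks = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length <= 0L) stop("replicon length must be > 0")
  if (!(gc_target > 0 && gc_target < 1)) stop("gc_target must be in (0, 1)")
  if (is.null(repeat_blocks)) {
    repeat_blocks <- data.frame(block_length = integer(0), copy_number = integer(0))
  }
  stopifnot(is.data.frame(repeat_blocks),
            all(c("block_length", "copy_number") %in% names(repeat_blocks)))
  if (nrow(repeat_blocks)) {
    if (any(repeat_blocks$copy_number < 1)) stop("repeat copy_number must be >= 1")
    if (sum(repeat_blocks$block_length * repeat_blocks$copy_number) > length) {
      stop("repeat blocks exceed replicon length (",
           sum(repeat_blocks$block_length * repeat_blocks$copy_number),
           " repeat bases > ", length, ")")
    }
  }
  structure(list(id = id, kind = kind, length = length, gc_target = gc_target,
                 circular = circular, repeat_blocks = repeat_blocks),
            class = "replicon_spec")
}

#' Specification of a sibling-strain pair
#'
#' Parameters of the second strain derived from a base chromosome: the
#' fraction of the base genome shared between the two strains, the SNV rate on
#' shared segments, the number of large-scale rearrangements, and the
#' sequencing coverage ratio of strain B over strain A.
#'
#' @param shared_fraction Fraction of base positions present in both strains,
#'   in \[0, 1\].
#' @param snv_rate Substitutions per base planted on shared segments (>= 0).
#' @param n_rearrangements Number of shared-block order swaps in the sibling.
#' @param coverage_ratio Coverage of strain B relative to strain A (> 0).
#' @param n_unique_blocks Number of strain-unique blocks the non-shared
#'   sequence is split into (per strain).
#' @return An object of class `strain_pair_spec`.
#' @export
strain_pair_spec <- function(shared_fraction = 0.94, snv_rate = 0,
                             n_rearrangements = 0, coverage_ratio = 2,
                             n_unique_blocks = 4) {
  if (shared_fraction < 0 || shared_fraction > 1) stop("shared_fraction must be in [0, 1]")
  if (snv_rate < 0) stop("snv_rate must be >= 0")
  if (coverage_ratio <= 0) stop("coverage_ratio must be > 0")
  structure(list(shared_fraction = shared_fraction, snv_rate = snv_rate,
                 n_rearrangements = as.integer(n_rearrangements),
                 coverage_ratio = coverage_ratio,
                 n_unique_blocks = as.integer(n_unique_blocks)),
            class = "strain_pair_spec")
}

#' Specification of a planted CRISPR array and its phage protospacers
#'
#' @param repeat_sequence The direct-repeat sequence (23--55 bases).
#' @param spacer_length Spacer length in bases (>= 20; typical arrays carry
#'   roughly 30 bp spacers).
#' @param mismatch_schedule Integer vector, one entry per spacer: the number
#'   of substitutions introduced into the phage-side protospacer copy.
#' @return An object of class `crispr_plant_spec`.
#' @export
crispr_plant_spec <- function(repeat_sequence, spacer_length = 30L,
                              mismatch_schedule = integer(0)) {
  repeat_sequence <- toupper(repeat_sequence)
  rl <- nchar(repeat_sequence)
  if (rl < 23 || rl > 55) stop("repeat_sequence must be 23-55 bases, got ", rl)
  spacer_length <- as.integer(spacer_length)
  if (spacer_length < 20L) stop("spacer_length must be >= 20")
  mismatch_schedule <- as.integer(mismatch_schedule)
  if (any(mismatch_schedule < 0)) stop("mismatch counts must be >= 0")
  if (any(mismatch_schedule > spacer_length)) {
    stop("mismatch count exceeds spacer length (", spacer_length, ")")
  }
  structure(list(repeat_sequence = repeat_sequence, spacer_length = spacer_length,
                 mismatch_schedule = mismatch_schedule),
            class = "crispr_plant_spec")
}

#' Specification of a prophage molecule-state mixture
#'
#' Proportions of the three molecule states coexisting at a prophage locus:
#' host chromosome with the prophage integrated, host chromosome without it,
#' and free circular phage genome.
#'
#' @param integrated,absent,circular Non-negative fractions summing to 1.
#' @param insertion_site 0-based host coordinate of the insertion.
#' @return An object of class `prophage_mixture_spec`.
#' @export
prophage_mixture_spec <- function(integrated, absent, circular, insertion_site) {
  fr <- c(integrated = integrated, absent = absent, circular = circular)
  if (any(fr < 0)) stop("mixture fractions must be >= 0")
  if (abs(sum(fr) - 1) > 1e-9) stop("mixture fractions must sum to 1, got ", sum(fr))
  structure(list(integrated = integrated, absent = absent, circular = circular,
                 insertion_site = as.integer(insertion_site)),
            class = "prophage_mixture_spec")
}

#' Specification of the long-read simulator
#'
#' @param coverage Named numeric vector of per-replicon target fold coverage,
#'   or a single value applied to all replicons.
#' @param length_family `"lognormal"` or `"fixed"` read-length distribution.
#' @param mean_length,sd_length Mean and standard deviation of read length in
#'   bases (sd ignored for `"fixed"`).
#' @param min_length Minimum read length; shorter draws are rejected.
#' @param sub_rate,ins_rate,del_rate Independent per-base error probabilities
#'   in \[0, 1).
#' @param quality_mean,quality_sd Mean/sd of the per-read mean Phred quality;
#'   each read gets a constant quality drawn from this normal, clamped to
#'   \[2, 40\].
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(coverage = 30, length_family = c("lognormal", "fixed"),
                          mean_length = 8000, sd_length = 6000, min_length = 500,
                          sub_rate = 0, ins_rate = 0, del_rate = 0,
                          quality_mean = 12, quality_sd = 3) {
  length_family <- match.arg(length_family)
  if (any(coverage <= 0)) stop("coverage must be > 0")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates >= 1)) stop("error rates must be in [0, 1)")
  if (min_length < 1) stop("min_length must be >= 1")
  structure(list(coverage = coverage, length_family = length_family,
                 mean_length = mean_length, sd_length = sd_length,
                 min_length = min_length, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "read_sim_spec")
}
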