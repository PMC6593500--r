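#' @importFrom stats rnorm runif rlnorm rbinom rpois pbinom p.adjust prcomp
#'   quantile optim dnorm sd qnorm setNames var aggregate
#' @importFrom utils read.table write.table modifyList head
#' @importFrom methods as
NULL

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC complement map (covers degenerate codes used in methylation motifs)
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Generate a random DNA sequence at a target GC fraction
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2.
#'
#' @param n Sequence length in bases.
#' @param gc Target GC fraction in (0, 1).
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x A character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr(IUPAC_FROM, IUPAC_TO, toupper(s)))))
  }, character(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#'
#' Computed over A/C/G/T symbols only; other symbols are ignored.
#'
#' @param x A single DNA string.
#' @return GC fraction in \[0, 1\]; `NA` if no ACGT base is present.
#' @export
gc_fraction <- function(x) {
  b <- charToRaw(toupper(x))
  acgt <- b %in% charToRaw("ACGT")
  if (!any(acgt)) return(NA_real_)
  sum(b %in% charToRaw("GC")) / sum(acgt)
}

# Substring with circular wrap-around. start is 0-based; len may exceed the
# distance to the end of the sequence only when circular = TRUE.
extract_interval <- function(seq, start, len, circular = FALSE) {
  L <- nchar(seq)
  stopifnot(start >= 0, start < L, len >= 0)
  if (start + len <= L) return(substr(seq, start + 1, start + len))
  if (!circular) stop("interval [", start, ", ", start + len, ") exceeds linear sequence of length ", L)
  n_wrap <- (start + len) - L
  paste0(substr(seq, start + 1, L), substr(strrep(seq, ceiling(n_wrap / L)), 1, n_wrap))
}

# Overwrite seq at 0-based position start with replacement (no length change).
overwrite_at <- function(seq, start, replacement) {
  w <- nchar(replacement)
  stopifnot(start >= 0, start + w <= nchar(seq))
  paste0(substr(seq, 1, start), replacement, substr(seq, start + w + 1, nchar(seq)))
}

# Insert a string at 0-based position site (length grows).
insert_at <- function(seq, site, insert) {
  stopifnot(site >= 0, site <= nchar(seq))
  paste0(substr(seq, 1, site), insert, substr(seq, site + 1, nchar(seq)))
}

# Delete 0-based half-open interval [start, end).
delete_interval <- function(seq, start, end) {
  stopifnot(start >= 0, end >= start, end <= nchar(seq))
  paste0(substr(seq, 1, start), substr(seq, end + 1, nchar(seq)))
}

#' Mismatch counts of a pattern at every ungapped offset of a subject
#'
#' Slides `pattern` along `subject` and returns the Hamming distance at each
#' 0-based start offset (no gaps, case-sensitive on upper-cased input).
#'
#' @param pattern Short DNA string (e.g. a CRISPR spacer).
#' @param subject Longer DNA string.
#' @return Integer vector of length `nchar(subject) - nchar(pattern) + 1`
#'   (length 0 if the pattern is longer than the subject); element `i` is the
#'   number of mismatching positions when the pattern starts at offset `i - 1`.
#' @export
sliding_mismatch_counts <- function(pattern, subject) {
  p <- charToRaw(toupper(pattern))
  s <- charToRaw(toupper(subject))
  L <- length(p); N <- length(s)
  if (L == 0L || N < L) return(integer(0))
  n_off <- N - L + 1L
  mm <- integer(n_off)
  for (j in seq_len(L)) {
    mm <- mm + (s[j:(j + n_off - 1L)] != p[j])
  }
  mm
}

# Convert an IUPAC motif to a regular expression character-class pattern.
iupac_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) stop("invalid IUPAC symbol(s) in motif '", motif, "': ", paste(bad, collapse = ","))
  paste(map[chars], collapse = "")
}

# 0-based start positions of an IUPAC motif on the forward strand of seq.
# Circular sequences are scanned across the origin; positions are reported
# modulo the sequence length and deduplicated.
motif_positions <- function(seq, motif, circular = FALSE) {
  L <- nchar(seq)
  k <- nchar(motif)
  if (L < k) return(integer(0))
  scan_seq <- if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq
  # zero-width lookahead finds overlapping occurrences too
  rx <- paste0("(?=", iupac_regex(motif), ")")
  m <- gregexpr(rx, scan_seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  pos <- as.integer(m) - 1L
  pos <- pos[pos <= (if (circular) L - 1L else L - k)]
  sort(unique(pos %% L))
}

# Apply a function under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a bounded sub-seed from a master seed and a stream index; keeps all
# seeds well inside 32-bit integer range.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483L + 1L
}
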