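#' Default CRISPR array detection parameters
#'
#' Repeat length bounds 23--55, spacer length 0.6--2.5 times the repeat
#' length, at least 3 repeats per array, seed k-mer size 8.
#'
#' @return Named list of parameters.
#' @export
crispr_params <- function() {
  list(repeat_len_min = 23L, repeat_len_max = 55L,
       spacer_frac_min = 0.6, spacer_frac_max = 2.5,
       min_repeats = 3L, seed_k = 8L, spacer_max_identity = 0.8)
}

# all 0-based start positions of each seed k-mer in seq, as a named list
seed_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(list())
  kmers <- substring(seq, 1:(L - k + 1L), k:L)
  split(0:(L - k), kmers)
}

# fraction of identical positions between two strings (compared over the
# shorter length); crude but sufficient to reject tandem-repeat "spacers"
string_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  mean(charToRaw(substr(a, 1, n)) == charToRaw(substr(b, 1, n)))
}

# Extend the common flank of anchor copies. positions: 0-based starts of the
# seed in each copy; dir = -1 extends left of the seed, +1 right of the end.
# Returns the number of columns over which all copies agree, capped by
# max_ext and the sequence boundaries.
extend_common_flank <- function(raw_seq, positions, seed_k, dir, max_ext) {
  e <- 0L
  L <- length(raw_seq)
  while (e < max_ext) {
    # 0-based column under test: one past the current flank on either side
    idx0 <- if (dir < 0) positions - e - 1L else positions + seed_k + e
    idx <- idx0 + 1L # 1-based
    if (any(idx < 1L | idx > L)) break
    if (length(unique(raw_seq[idx])) != 1L) break
    e <- e + 1L
  }
  e
}

#' Detect CRISPR repeat-spacer arrays in a replicon
#'
#' Seed-and-extend detection: exact seed k-mers recurring at tandem spacings
#' compatible with a repeat-spacer period anchor candidate arrays; repeat
#' boundaries are refined as the maximal flank on which all copies agree.
#' Candidates are kept when they show at least `min_repeats` repeat copies
#' within the repeat-length bounds, spacer lengths within the configured
#' multiple of the repeat length, and mutually dissimilar spacers (rejecting
#' plain tandem repeats). Both strands are scanned and overlapping calls
#' deduplicated.
#'
#' @param seq Replicon sequence.
#' @param params Parameter list, see [crispr_params()].
#' @return List of arrays; each is a list with `start`, `end` (0-based
#'   half-open on the input sequence), `strand`, `repeat_consensus` and
#'   `spacers` (data.frame: `sequence`, `start`, `end`, forward-strand
#'   coordinates).
#' @export
detect_crispr_arrays <- function(seq, params = crispr_params()) {
  if (nchar(seq) == 0L) stop("empty sequence")
  fwd <- detect_arrays_one_strand(toupper(seq), params)
  for (a in seq_along(fwd)) fwd[[a]]$strand <- "+"
  rc <- detect_arrays_one_strand(revcomp(seq), params)
  L <- nchar(seq)
  rc <- lapply(rc, function(a) {
    sp <- a$spacers
    new_sp <- data.frame(sequence = revcomp(sp$sequence),
                         start = L - sp$end, end = L - sp$start)
    new_sp <- new_sp[order(new_sp$start), , drop = FALSE]
    rownames(new_sp) <- NULL
    list(start = L - a$end, end = L - a$start, strand = "-",
         repeat_consensus = a$repeat_consensus, spacers = new_sp)
  })
  dedupe_arrays(c(fwd, rc))
}

detect_arrays_one_strand <- function(seq, params) {
  k <- params$seed_k
  L <- nchar(seq)
  period_min <- params$repeat_len_min +
    max(1L, floor(params$spacer_frac_min * params$repeat_len_min))
  period_max <- params$repeat_len_max +
    ceiling(params$spacer_frac_max * params$repeat_len_max)
  pos_by_kmer <- seed_positions(seq, k)
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= params$min_repeats]
  raw_seq <- charToRaw(seq)
  arrays <- list()
  for (positions in pos_by_kmer) {
    gaps <- diff(positions)
    in_range <- gaps >= period_min & gaps <= period_max
    if (!any(in_range)) next
    runs <- rle(in_range)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values & runs$lengths >= params$min_repeats - 1L)) {
      chain <- positions[starts[r]:(ends[r] + 1L)]
      cand <- refine_array(raw_seq, seq, chain, k, params)
      if (!is.null(cand)) arrays[[length(arrays) + 1L]] <- cand
    }
  }
  dedupe_arrays(arrays)
}

refine_array <- function(raw_seq, seq, chain, seed_k, params) {
  left <- extend_common_flank(raw_seq, chain, seed_k, -1L,
                              max_ext = params$repeat_len_max - seed_k)
  right <- extend_common_flank(raw_seq, chain, seed_k, +1L,
                               max_ext = params$repeat_len_max - seed_k - left)
  rep_len <- left + seed_k + right
  if (rep_len < params$repeat_len_min || rep_len > params$repeat_len_max) return(NULL)
  rep_start <- chain - left
  rep_end <- rep_start + rep_len
  n <- length(chain)
  # spacers between consecutive repeat copies
  sp_start <- rep_end[-n]; sp_end <- rep_start[-1L]
  sp_len <- sp_end - sp_start
  lo <- params$spacer_frac_min * rep_len; hi <- params$spacer_frac_max * rep_len
  if (any(sp_len < lo | sp_len > hi)) return(NULL)
  spacers <- substring(seq, sp_start + 1L, sp_end)
  if (length(spacers) >= 2L) {
    for (i in 1:(length(spacers) - 1L)) {
      for (j in (i + 1L):length(spacers)) {
        if (string_identity(spacers[i], spacers[j]) > params$spacer_max_identity) {
          return(NULL)
        }
      }
    }
  }
  consensus <- substring(seq, rep_start[1] + 1L, rep_end[1])
  list(start = rep_start[1], end = rep_end[n],
       repeat_consensus = consensus,
       spacers = data.frame(sequence = spacers, start = sp_start, end = sp_end))
}

# keep non-overlapping arrays, preferring more repeats then wider span
dedupe_arrays <- function(arrays) {
  if (length(arrays) <= 1L) return(arrays)
  n_rep <- vapply(arrays, function(a) nrow(a$spacers) + 1L, integer(1))
  span <- vapply(arrays, function(a) a$end - a$start, numeric(1))
  ord <- order(-n_rep, -span)
  kept <- list()
  for (i in ord) {
    a <- arrays[[i]]
    overlaps <- any(vapply(kept, function(b) a$start < b$end && b$start < a$end,
                           logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, `[[`, numeric(1), "start"))]
}

#' Match CRISPR spacers against phage genomes under a mismatch budget
#'
#' Exhaustive ungapped (Hamming) comparison of every spacer against every
#' position of every phage on both strands; circular phages are scanned
#' across the origin. Substitutions only -- no indels.
#'
#' @param spacers Named character vector of spacer sequences (names are
#'   spacer ids).
#' @param phages Named character vector of phage sequences.
#' @param max_mismatches Report positions with at most this many mismatches.
#'   The default 2 reflects the "fewer than three mismatches in a ~30 bp
#'   spacer" convention for calling a protospacer hit; raise it (e.g. to 6)
#'   to scan for weak matches.
#' @param circular Named logical vector (or single value) per phage.
#' @return data.frame with columns `spacer_id`, `phage_id`, `position`
#'   (0-based forward-strand start of the matched window), `strand`,
#'   `mismatches`, `spacer_length`.
#' @export
match_protospacers <- function(spacers, phages, max_mismatches = 2L,
                               circular = FALSE) {
  if (length(spacers) == 0L) stop("no spacers given")
  if (is.null(names(spacers))) names(spacers) <- paste0("spacer", seq_along(spacers))
  if (is.null(names(phages))) names(phages) <- paste0("phage", seq_along(phages))
  if (length(circular) == 1L) circular <- setNames(rep(circular, length(phages)),
                                                   names(phages))
  out <- list()
  for (ph in names(phages)) {
    plen <- nchar(phages[[ph]])
    for (sp in names(spacers)) {
      slen <- nchar(spacers[[sp]])
      if (slen > plen) {
        warning("spacer ", sp, " (", slen, " nt) longer than phage ", ph,
                " (", plen, " nt); skipped")
        next
      }
      scan_seq <- if (isTRUE(circular[[ph]])) {
        paste0(phages[[ph]], substr(phages[[ph]], 1L, slen - 1L))
      } else phages[[ph]]
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") spacers[[sp]] else revcomp(spacers[[sp]])
        mm <- sliding_mismatch_counts(probe, scan_seq)
        hit <- which(mm <= max_mismatches) - 1L
        hit <- hit[hit < plen] # wrap-scan duplicates
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            spacer_id = sp, phage_id = ph, position = hit, strand = strand,
            mismatches = mm[hit + 1L], spacer_length = slen)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(spacer_id = character(0), phage_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatches = integer(0), spacer_length = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$spacer_id, res$phage_id, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Summarize host-phage encounter evidence from spacer matches
#'
#' Per host-phage pair: close matches (<= 2 mismatches) indicate a previous
#' encounter and acquired resistance; when only poor matches (>= 5
#' mismatches) exist, protection is likely diminished; no match means no
#' evidence of an encounter.
#'
#' @param matches data.frame from [match_protospacers()].
#' @param spacer_hosts Named character vector spacer id -> host replicon id.
#' @return data.frame with one row per host-phage pair observed (plus pairs
#'   without matches if `all_pairs` is given): `host`, `phage`, `n_close`
#'   (matches with <= 2 mismatches), `n_total`, `min_mismatches`, `verdict`.
#' @param all_pairs Optional data.frame with columns `host`, `phage` forcing
#'   rows (verdict `"no evidence"`) for pairs without any match.
#' @export
interaction_report <- function(matches, spacer_hosts, all_pairs = NULL) {
  if (nrow(matches)) {
    matches$host <- unname(spacer_hosts[matches$spacer_id])
    if (anyNA(matches$host)) stop("match references spacer with unknown host")
    pairs <- unique(matches[, c("host", "phage_id")])
  } else {
    matches$host <- character(0)
    pairs <- data.frame(host = character(0), phage_id = character(0))
  }
  if (!is.null(all_pairs)) {
    extra <- all_pairs[!paste(all_pairs$host, all_pairs$phage) %in%
                         paste(pairs$host, pairs$phage_id), , drop = FALSE]
    if (nrow(extra)) {
      pairs <- rbind(pairs, data.frame(host = extra$host, phage_id = extra$phage))
    }
  }
  if (!nrow(pairs)) {
    return(data.frame(host = character(0), phage = character(0),
                      n_close = integer(0), n_total = integer(0),
                      min_mismatches = integer(0), verdict = character(0)))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    m <- matches[matches$host == pairs$host[i] &
                   matches$phage_id == pairs$phage_id[i], , drop = FALSE]
    n_close <- sum(m$mismatches <= 2L)
    verdict <- if (nrow(m) == 0L) {
      "no evidence"
    } else if (n_close > 0L) {
      "previous encounter / acquired resistance"
    } else if (min(m$mismatches) >= 5L) {
      "poor match / diminished protection"
    } else {
      "intermediate match"
    }
    data.frame(host = pairs$host[i], phage = pairs$phage_id[i],
               n_close = n_close, n_total = nrow(m),
               min_mismatches = if (nrow(m)) min(m$mismatches) else NA_integer_,
               verdict = verdict)
  }))
  rownames(out) <- NULL
  out
}
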