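#' Configuration of a prophage junction locus
#'
#' @param replicon Id of the integrated-host reference replicon.
#' @param start,end 0-based half-open prophage interval on that reference.
#' @param min_anchor Minimum aligned bases required on each side of a
#'   junction for a read to be informative (long reads make a generous
#'   anchor cheap; default 500).
#' @param tol Coordinate tolerance in bases when matching alignment
#'   breakpoints to the junctions.
#' @return An object of class `junction_config`.
#' @export
junction_config <- function(replicon, start, end, min_anchor = 500L, tol = 20L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("prophage interval must satisfy start < end")
  if (min_anchor <= 0L) stop("min_anchor must be > 0")
  structure(list(replicon = replicon, start = start, end = end,
                 min_anchor = as.integer(min_anchor), tol = as.integer(tol)),
            class = "junction_config")
}

#' Classify reads at a prophage locus into molecule-state classes
#'
#' Works on alignment records against the integrated-host reference. A read
#' is `integrated` when one alignment segment runs contiguously across a
#' prophage boundary with at least `min_anchor` bases on each side;
#' `absent` when its segments jump from the host flank at the prophage start
#' directly to the host flank at the prophage end (deletion-type junction,
#' the prophage missing from the molecule); `circular` when its segments
#' jump from the prophage end back to the prophage start (origin of a free
#' circular phage genome); otherwise `uninformative`. Reads whose segments
#' support more than one class (chimeras) are classed uninformative with a
#' warning.
#'
#' @param alignments data.frame of alignment segments with columns
#'   `read_id`, `target`, `tstart`, `tend` (0-based half-open reference
#'   interval); additional columns are ignored. Split reads occupy several
#'   rows.
#' @param config A [junction_config()].
#' @return data.frame with columns `read_id` and `label` (one row per
#'   distinct read in `alignments`).
#' @export
classify_junction_reads <- function(alignments, config) {
  stopifnot(inherits(config, "junction_config"))
  if (nrow(alignments) == 0L) {
    return(data.frame(read_id = character(0), label = character(0)))
  }
  aln <- alignments[alignments$target == config$replicon, , drop = FALSE]
  reads <- unique(alignments$read_id)
  ps <- config$start; pe <- config$end
  a <- config$min_anchor; tol <- config$tol
  labels <- vapply(reads, function(id) {
    seg <- aln[aln$read_id == id, , drop = FALSE]
    if (nrow(seg) == 0L) return("uninformative")
    hits <- character(0)
    # one segment contiguous across a boundary
    for (j in c(ps, pe)) {
      if (any(seg$tstart <= j - a & seg$tend >= j + a)) {
        hits <- c(hits, "integrated")
        break
      }
    }
    if (nrow(seg) >= 2L) {
      for (i in seq_len(nrow(seg))) {
        for (k in seq_len(nrow(seg))) {
          if (i == k) next
          si <- seg[i, ]; sk <- seg[k, ]
          # host flank -> host flank, prophage deleted
          if (abs(si$tend - ps) <= tol && abs(sk$tstart - pe) <= tol &&
              ps - si$tstart >= a && sk$tend - pe >= a) {
            hits <- c(hits, "absent")
          }
          # prophage end -> prophage start, circular molecule
          if (abs(si$tend - pe) <= tol && abs(sk$tstart - ps) <= tol &&
              si$tstart >= ps - tol && sk$tend <= pe + tol &&
              pe - si$tstart >= a && sk$tend - ps >= a) {
            hits <- c(hits, "circular")
          }
        }
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) return(hits)
    if (length(hits) > 1L) {
      warning("read ", id, " supports several states (",
              paste(hits, collapse = ","), "); classed uninformative")
    }
    "uninformative"
  }, character(1))
  data.frame(read_id = reads, label = unname(labels))
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Molecule-state fractions at a prophage locus
#'
#' @param labels data.frame from [classify_junction_reads()].
#' @return A list of class `prophage_state_counts` with `counts` (named:
#'   integrated, absent, circular, uninformative), `fractions` (over
#'   informative reads, summing to 1) and `ci` (2-column matrix of Wilson
#'   95% intervals per state).
#' @export
variant_fractions <- function(labels) {
  states <- c("integrated", "absent", "circular")
  counts <- vapply(c(states, "uninformative"),
                   function(s) sum(labels$label == s), integer(1))
  n_inf <- sum(counts[states])
  if (n_inf == 0L) stop("no junction-informative reads")
  fractions <- counts[states] / n_inf
  ci <- t(vapply(states, function(s) wilson_ci(counts[[s]], n_inf), numeric(2)))
  colnames(ci) <- c("lower", "upper")
  structure(list(counts = counts, n_informative = n_inf,
                 fractions = fractions, ci = ci),
            class = "prophage_state_counts")
}

#' Call the activity state of a prophage locus
#'
#' `active_mixed` when both a circular (lytic) and an integrated (lysogenic)
#' signal exceed their thresholds -- the signature of an active phage system
#' in which integrated, prophage-free and circularized molecules coexist.
#'
#' @param counts A [variant_fractions()] result.
#' @param min_lytic_fraction Minimum circular fraction for a lytic signal.
#' @param min_lysogenic_fraction Minimum integrated fraction for a
#'   lysogenic signal.
#' @return A list with `state` (one of `lysogenic_only`, `lytic_only`,
#'   `active_mixed`, `undetermined`) and `rationale` (text).
#' @export
activity_call <- function(counts, min_lytic_fraction = 0.02,
                          min_lysogenic_fraction = 0.05) {
  stopifnot(inherits(counts, "prophage_state_counts"))
  fr <- counts$fractions
  lytic <- fr[["circular"]] >= min_lytic_fraction
  lysogenic <- fr[["integrated"]] >= min_lysogenic_fraction
  state <- if (lytic && lysogenic) "active_mixed"
  else if (lysogenic) "lysogenic_only"
  else if (lytic) "lytic_only"
  else "undetermined"
  rationale <- sprintf(
    "integrated %.1f%% (threshold %.1f%%), circular %.1f%% (threshold %.1f%%), absent %.1f%%; n = %d informative reads",
    100 * fr[["integrated"]], 100 * min_lysogenic_fraction,
    100 * fr[["circular"]], 100 * min_lytic_fraction,
    100 * fr[["absent"]], counts$n_informative)
  list(state = state, rationale = rationale)
}
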