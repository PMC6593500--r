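# Occurrences of an IUPAC motif on both strands, in the coordinate/strand
# convention of the site-call tables: forward occurrences are reported at the
# 0-based position of their first base; minus-strand occurrences at the
# forward-strand coordinate of the motif's first base on the minus strand.
motif_occurrences <- function(seq, motif, circular = FALSE) {
  L <- nchar(seq)
  k <- nchar(motif)
  fwd <- motif_positions(seq, motif, circular = circular)
  rev_on_rc <- motif_positions(revcomp(seq), motif, circular = circular)
  rev_pos <- (L - 1L - rev_on_rc) %% L
  data.frame(position = c(fwd, rev_pos),
             strand = c(rep("+", length(fwd)), rep("-", length(rev_pos))))
}

#' Methylation motif profile of a replicon from site-level calls
#'
#' For each motif, counts its occurrences on both strands (circular
#' replicons scanned across the origin) and the fraction of occurrences
#' supported by a methylation call at the motif's first base. Calls with a
#' score below `score_cutoff` are ignored. The profile is flagged
#' `low_coverage` when the mean per-strand coverage of the calls is below
#' `min_strand_coverage` (motif detection from kinetic data is unreliable
#' below roughly 250-fold per strand).
#'
#' @param seq Replicon sequence.
#' @param site_calls data.frame for this replicon with columns `position`,
#'   `strand`, `coverage_fwd`, `coverage_rev`, `methylated`, `score`.
#' @param motifs Character vector of IUPAC motifs to profile.
#' @param circular Logical topology flag.
#' @param min_strand_coverage Per-strand coverage below which confidence is
#'   `"low_coverage"`.
#' @param score_cutoff Minimum call score; lower-scoring calls are dropped.
#' @return data.frame with columns `motif`, `n_sites`, `n_methylated`,
#'   `methylated_fraction`, `mean_strand_coverage`, `confidence`.
#' @export
motif_profile <- function(seq, site_calls, motifs, circular = FALSE,
                          min_strand_coverage = 250, score_cutoff = 50) {
  calls <- site_calls[site_calls$methylated & site_calls$score >= score_cutoff, ,
                      drop = FALSE]
  if (nrow(calls) && any(calls$position >= nchar(seq) | calls$position < 0)) {
    stop("site call position outside the sequence")
  }
  called <- paste(calls$position, calls$strand)
  mean_cov <- if (nrow(calls)) mean(c(calls$coverage_fwd, calls$coverage_rev)) else 0
  out <- do.call(rbind, lapply(motifs, function(m) {
    occ <- motif_occurrences(seq, m, circular = circular)
    n <- nrow(occ)
    n_meth <- if (n) sum(paste(occ$position, occ$strand) %in% called) else 0L
    data.frame(motif = m, n_sites = n, n_methylated = n_meth,
               methylated_fraction = if (n) n_meth / n else NA_real_,
               mean_strand_coverage = mean_cov,
               confidence = if (mean_cov >= min_strand_coverage) "ok" else "low_coverage")
  }))
  rownames(out) <- NULL
  out
}

#' Motifs detected in a profile
#'
#' A motif counts as detected when it has at least `min_sites` methylated
#' occurrences and a methylated fraction of at least `min_fraction`.
#'
#' @param profile data.frame from [motif_profile()].
#' @param min_sites,min_fraction Detection thresholds.
#' @return Character vector of detected motifs.
#' @export
detected_motifs <- function(profile, min_sites = 3L, min_fraction = 0.5) {
  ok <- profile$n_sites > 0 & profile$n_methylated >= min_sites &
    profile$methylated_fraction >= min_fraction
  profile$motif[ok]
}

# sequence context of length k whose first base is the call site, read on the
# call's strand; NA where the context runs off a linear sequence end
site_contexts <- function(seq, positions, strands, k, circular = FALSE) {
  L <- nchar(seq)
  vapply(seq_along(positions), function(i) {
    p <- positions[i]
    if (strands[i] == "+") {
      if (p + k <= L) substr(seq, p + 1L, p + k)
      else if (circular) extract_interval(seq, p, k, circular = TRUE)
      else NA_character_
    } else {
      s <- p - k + 1L
      if (s >= 0L) revcomp(substr(seq, s + 1L, p + 1L))
      else if (circular) revcomp(extract_interval(seq, (s %% L), k, circular = TRUE))
      else NA_character_
    }
  }, character(1))
}

#' Discover methylation motifs by k-mer enrichment
#'
#' For every non-degenerate k-mer in `k_range` (anchored so that the
#' methylated base is the k-mer's first position), tests whether the k-mer is
#' over-represented among the contexts of methylated sites relative to its
#' genomic background frequency (one-sided binomial test), then applies
#' Benjamini-Hochberg correction across all tested k-mers. k-mers of the
#' same length that pass the threshold and differ at a single position are
#' merged into a degenerate IUPAC motif (reported in `merged_motif`).
#'
#' @param seq Replicon sequence.
#' @param site_calls data.frame with `position`, `strand`, `methylated`,
#'   `score` (as in [motif_profile()]); only methylated calls with
#'   `score >= score_cutoff` are used.
#' @param k_range Integer vector of k-mer sizes, each in 2--8.
#' @param alpha BH-corrected significance threshold.
#' @param circular Logical topology flag.
#' @param score_cutoff Minimum call score.
#' @return data.frame with columns `motif`, `k`, `n_observed`,
#'   `n_background`, `expected`, `p_value`, `p_adj`, `merged_motif`, sorted
#'   by `p_adj`; zero rows when nothing passes.
#' @export
discover_motifs <- function(seq, site_calls, k_range = 4:6, alpha = 0.05,
                            circular = FALSE, score_cutoff = 50) {
  if (any(k_range < 2 | k_range > 8)) stop("k_range values must be in 2..8")
  calls <- site_calls[site_calls$methylated & site_calls$score >= score_cutoff, ,
                      drop = FALSE]
  empty <- data.frame(motif = character(0), k = integer(0),
                      n_observed = integer(0), n_background = integer(0),
                      expected = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), merged_motif = character(0))
  if (nrow(calls) == 0L) return(empty)
  L <- nchar(seq)
  rows <- list()
  n_tests <- sum(4^k_range)
  for (k in sort(unique(k_range))) {
    ctx <- site_contexts(seq, calls$position, calls$strand, k, circular = circular)
    ctx <- ctx[!is.na(ctx)]
    m <- length(ctx)
    if (m == 0L) next
    obs <- table(ctx)
    # genomic background: occurrences per strand-position
    counts <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq), k)
    n_pos <- if (circular) L else L - k + 1L
    for (w in names(obs)) {
      bg <- counts[[w]] + counts[[revcomp(w)]] # both strands
      p0 <- bg / (2 * n_pos)
      x <- as.integer(obs[[w]])
      pv <- pbinom(x - 1L, m, p0, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = w, k = k, n_observed = x, n_background = bg,
        expected = m * p0, p_value = pv)
    }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  # BH over all tested k-mers: unobserved k-mers have p = 1, so the observed
  # p-values occupy the lowest ranks and the full test count is the BH m
  ord <- order(res$p_value)
  p_sorted <- res$p_value[ord]
  padj_sorted <- pmin(1, rev(cummin(rev(p_sorted * n_tests / seq_along(p_sorted)))))
  res$p_adj <- NA_real_
  res$p_adj[ord] <- padj_sorted
  res <- res[res$p_adj <= alpha, , drop = FALSE]
  if (!nrow(res)) {
    return(empty)
  }
  res <- res[order(res$p_adj, -res$n_observed), , drop = FALSE]
  res$merged_motif <- merge_one_off_kmers(res$motif)
  rownames(res) <- NULL
  res
}

# merge k-mers differing at exactly one position into IUPAC motifs;
# returns the merged motif for each input k-mer
merge_one_off_kmers <- function(kmers) {
  iupac_union <- c(A = "A", C = "C", G = "G", T = "T",
                   AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                   ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  merged <- kmers
  for (k in unique(nchar(kmers))) {
    idx <- which(nchar(kmers) == k)
    if (length(idx) < 2L) next
    mat <- do.call(rbind, strsplit(kmers[idx], ""))
    groups <- seq_along(idx)
    for (i in 1:(length(idx) - 1L)) {
      for (j in (i + 1L):length(idx)) {
        if (sum(mat[i, ] != mat[j, ]) == 1L) groups[groups == groups[j]] <- groups[i]
      }
    }
    for (g in unique(groups)) {
      members <- which(groups == g)
      if (length(members) < 2L) next
      motif <- vapply(seq_len(k), function(p) {
        key <- paste(sort(unique(mat[members, p])), collapse = "")
        iupac_union[[key]]
      }, character(1))
      merged[idx[members]] <- paste(motif, collapse = "")
    }
  }
  merged
}

#' Reduce discovered motifs to their most specific forms
#'
#' Motif discovery over a k-range reports a true motif at several sizes: a
#' 5-mer motif also surfaces truncated at k = 4 and extended (merged into
#' `<motif>N`) at k = 6. Truncated forms dilute the methylated fraction of a
#' profile (most occurrences of the truncation are not methylation sites),
#' so only motifs that are not a prefix of a longer discovered motif are
#' kept.
#'
#' @param discovered data.frame from [discover_motifs()].
#' @return Character vector of merged motifs (unique, sorted) with prefixes
#'   of longer discoveries removed.
#' @export
canonical_motifs <- function(discovered) {
  motifs <- sort(unique(discovered$merged_motif))
  if (!length(motifs)) return(character(0))
  keep <- vapply(motifs, function(m) {
    longer <- motifs[nchar(motifs) > nchar(m)]
    if (!length(longer)) return(TRUE)
    !any(substr(longer, 1, nchar(m)) == m)
  }, logical(1))
  motifs[keep]
}

#' Assign plasmids to host genomes by methylation motif matching
#'
#' A plasmid is methylated by its host's restriction-modification systems,
#' so its motif set must be a subset of the host's. A plasmid is assigned to
#' a single host when every plasmid motif occurs in that host's profile and
#' at least one of those motifs is unique to that host among all candidate
#' hosts (`basis = "unique_motif"`). When all matched motifs are shared by
#' several hosts, every compatible host is listed (`basis = "shared_motif"`).
#' A plasmid with no detected motif is `"unassigned"`.
#'
#' @param plasmid_motifs Named list: plasmid id -> character vector of
#'   detected motifs (see [detected_motifs()]).
#' @param host_motifs Named list: host id -> character vector of detected
#'   motifs.
#' @return data.frame with columns `plasmid`, `hosts` (comma-separated ids,
#'   `""` if none) and `basis`.
#' @export
assign_plasmid_hosts <- function(plasmid_motifs, host_motifs) {
  if (!length(host_motifs)) stop("need motif profiles for at least one host")
  host_ids <- names(host_motifs)
  motif_host_count <- table(unlist(lapply(host_motifs, unique)))
  out <- do.call(rbind, lapply(names(plasmid_motifs), function(pl) {
    pm <- unique(plasmid_motifs[[pl]])
    if (!length(pm)) {
      return(data.frame(plasmid = pl, hosts = "", basis = "unassigned"))
    }
    compatible <- host_ids[vapply(host_ids, function(h)
      all(pm %in% host_motifs[[h]]), logical(1))]
    if (!length(compatible)) {
      return(data.frame(plasmid = pl, hosts = "", basis = "shared_motif"))
    }
    unique_motifs <- pm[motif_host_count[pm] == 1L]
    if (length(unique_motifs) && length(compatible) == 1L) {
      data.frame(plasmid = pl, hosts = compatible, basis = "unique_motif")
    } else {
      data.frame(plasmid = pl, hosts = paste(compatible, collapse = ","),
                 basis = "shared_motif")
    }
  }))
  rownames(out) <- NULL
  out
}
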