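#' Simulate the default benchmark community with full ground truth
#'
#' Builds a low-complexity dairy-style community: two sibling strains of one
#' species sharing most of their genome at a 2:1 coverage ratio, a third
#' chromosome at divergent GC carrying a CRISPR array and an integrated
#' prophage segregating as a mixture of integrated / prophage-free /
#' circular molecules, two small circular plasmids whose methylation motif
#' sets are inherited from their hosts, and a lytic phage carrying
#' protospacers derived from the CRISPR spacers. Long reads are simulated
#' for every replicon.
#'
#' @param cfg The `simulate` block of [default_config()].
#' @param seed Integer master seed; all generator calls derive sub-seeds
#'   from it.
#' @return A [truth_bundle()].
#' @export
simulate_community <- function(cfg = default_config()$simulate, seed = 1L) {
  # strain pair
  base <- generate_base_genome(
    replicon_spec("strain_a", "chromosome", cfg$strain_length, cfg$strain_gc),
    seed = sub_seed(seed, 1L))
  pair <- strain_pair_spec(shared_fraction = cfg$shared_fraction,
                           snv_rate = cfg$snv_rate,
                           n_rearrangements = cfg$n_rearrangements,
                           coverage_ratio = cfg$coverage_b / cfg$coverage_a,
                           n_unique_blocks = cfg$n_unique_blocks)
  sib <- derive_sibling_strain(base$seq, pair, seed = sub_seed(seed, 2L))

  # CRISPR-carrying chromosome + lytic phage with planted protospacers
  host0 <- generate_base_genome(
    replicon_spec("host_c", "chromosome", cfg$host_length, cfg$host_gc),
    seed = sub_seed(seed, 3L))
  phage0 <- generate_base_genome(
    replicon_spec("phage_a", "phage", cfg$phage_length, cfg$phage_gc,
                  circular = FALSE),
    seed = sub_seed(seed, 4L))
  rep_seq <- with_seed(sub_seed(seed, 5L), random_dna(32L, cfg$host_gc))
  cr <- plant_crispr_and_protospacers(
    host0$seq, phage0$seq,
    crispr_plant_spec(rep_seq, cfg$spacer_length, cfg$mismatch_schedule),
    seed = sub_seed(seed, 6L))

  # prophage integration, avoiding the CRISPR array
  pro <- generate_base_genome(
    replicon_spec("prophage", "phage", cfg$prophage_length, cfg$phage_gc),
    seed = sub_seed(seed, 7L))
  site <- as.integer(floor(nchar(cr$host) / 2))
  if (!is.null(cr$array) && site >= cr$array$start - 1000L &&
      site <= cr$array$end + 1000L) {
    site <- cr$array$end + 2000L
  }
  integ <- integrate_prophage(cr$host, pro$seq, site)
  crispr_truth <- cr
  if (!is.null(cr$array) && cr$array$start >= site) {
    # array lies downstream of the insertion: shift truth coordinates
    shift <- nchar(pro$seq)
    crispr_truth$array$start <- cr$array$start + shift
    crispr_truth$array$end <- cr$array$end + shift
    crispr_truth$array$spacers$start <- cr$array$spacers$start + shift
    crispr_truth$array$spacers$end <- cr$array$spacers$end + shift
  }

  plasmids <- lapply(names(cfg$plasmid_lengths), function(pl) {
    generate_base_genome(
      replicon_spec(pl, "plasmid", cfg$plasmid_lengths[[pl]], cfg$strain_gc),
      seed = sub_seed(seed, 10L + match(pl, names(cfg$plasmid_lengths))))
  })
  names(plasmids) <- names(cfg$plasmid_lengths)

  community <- c(
    list(community_replicon("strain_a", base$seq, circular = TRUE, kind = "chromosome"),
         community_replicon("strain_b", sib$seq, circular = TRUE, kind = "chromosome"),
         community_replicon("host_c", integ$seq, circular = TRUE, kind = "chromosome")),
    lapply(names(plasmids), function(pl)
      community_replicon(pl, plasmids[[pl]]$seq, circular = TRUE, kind = "plasmid")),
    list(community_replicon("phage_a", cr$phage, circular = FALSE, kind = "phage")))
  names(community) <- vapply(community, `[[`, character(1), "id")

  meth <- assign_methylation_truth(community, cfg$motif_sets,
                                   plasmid_hosts = cfg$plasmid_hosts,
                                   seed = sub_seed(seed, 20L))
  coverage <- c(strain_a = cfg$coverage_a, strain_b = cfg$coverage_b,
                host_c = cfg$host_coverage,
                setNames(as.numeric(cfg$plasmid_coverages), names(cfg$plasmid_coverages)),
                phage_a = cfg$phage_coverage)
  calls <- simulate_site_calls(meth, community, coverage = coverage,
                               n_noise = 20L, seed = sub_seed(seed, 21L))

  sim <- read_sim_spec(coverage = coverage,
                       mean_length = cfg$read$mean_length,
                       sd_length = cfg$read$sd_length,
                       min_length = cfg$read$min_length,
                       sub_rate = cfg$read$sub_rate,
                       ins_rate = cfg$read$ins_rate,
                       del_rate = cfg$read$del_rate,
                       quality_mean = cfg$read$quality_mean,
                       quality_sd = cfg$read$quality_sd)
  mixture <- prophage_mixture_spec(cfg$prophage_mixture[["integrated"]],
                                   cfg$prophage_mixture[["absent"]],
                                   cfg$prophage_mixture[["circular"]],
                                   insertion_site = site)
  reads <- simulate_reads(community, sim, mixture = mixture,
                          prophage = list(replicon = "host_c", start = site,
                                          end = site + nchar(pro$seq),
                                          phage_id = "prophage"),
                          seed = sub_seed(seed, 30L))

  truth_bundle(
    community, sim_reads = reads,
    strains = list(strain_a = "strain_a", strain_b = "strain_b",
                   segments = sib$segments, snv = sib$snv,
                   coverage_ratio = pair$coverage_ratio),
    crispr = list(host = "host_c", phage = "phage_a",
                  array = crispr_truth$array,
                  protospacers = crispr_truth$protospacers),
    plasmid_hosts = cfg$plasmid_hosts,
    prophage = list(replicon = "host_c", start = site,
                    end = site + nchar(pro$seq), phage_id = "prophage",
                    mixture = cfg$prophage_mixture),
    methylation = meth, motif_sets = cfg$motif_sets, site_calls = calls)
}

# split a read interval [start, start+len) on a molecule of length L into
# at most two linear pieces (wrap across the origin)
read_pieces <- function(start, len, L) {
  if (start + len <= L) {
    cbind(start = start, end = start + len)
  } else {
    rbind(c(start = start, end = L), c(start = 0L, end = start + len - L))
  }
}

overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

#' Synthesize reference alignments from simulation truth
#'
#' Turns per-read truth intervals into PAF-like alignment records against
#' the community reference replicons: reads from prophage-state molecules
#' become single or split alignments on the integrated host reference, reads
#' wrapping a circular origin are split in two, and reads from strain-shared
#' segments gain a secondary near-tied alignment to the sibling strain.
#' This plays the role an external long-read mapper would play on real data,
#' with exactly known coordinates.
#'
#' @param bundle A [truth_bundle()] with simulated reads.
#' @param read_ids Optional subset of read ids.
#' @return data.frame with columns `read_id`, `target`, `tstart`, `tend`,
#'   `qstart`, `qend`, `strand`, `score` (aligned bases).
#' @export
alignments_from_truth <- function(bundle, read_ids = NULL) {
  stopifnot(inherits(bundle, "truth_bundle"))
  reads <- bundle$sim_reads$reads
  if (!is.null(read_ids)) reads <- reads[reads$read_id %in% read_ids, , drop = FALSE]
  lens <- vapply(bundle$community, function(r) nchar(r$seq), integer(1))
  pp <- bundle$prophage
  seg <- if (!is.null(bundle$strains)) bundle$strains$segments
  sh <- if (!is.null(seg)) seg[seg$type == "shared", , drop = FALSE]
  sa <- if (!is.null(bundle$strains)) bundle$strains$strain_a
  sb <- if (!is.null(bundle$strains)) bundle$strains$strain_b

  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    mol <- r$replicon
    recs <- NULL
    if (!is.null(pp) && mol == paste0(pp$replicon, "_delta")) {
      # host molecule without the prophage: deletion-type junction
      plen <- pp$end - pp$start
      pcs <- read_pieces(r$start, r$length, lens[[pp$replicon]] - plen)
      segs <- list()
      for (p in seq_len(nrow(pcs))) {
        s <- pcs[p, 1]; e <- pcs[p, 2]
        if (e <= pp$start || s >= pp$start) {
          off <- if (s >= pp$start) plen else 0L
          segs[[length(segs) + 1L]] <- c(s + off, e + off)
        } else {
          segs[[length(segs) + 1L]] <- c(s, pp$start)
          segs[[length(segs) + 1L]] <- c(pp$end, pp$end + (e - pp$start))
        }
      }
      recs <- do.call(rbind, segs)
      recs <- data.frame(target = pp$replicon, tstart = recs[, 1], tend = recs[, 2])
    } else if (!is.null(pp) && mol == paste0(pp$phage_id, "_circ")) {
      # free circular phage molecule: coordinates inside the prophage interval
      P <- pp$end - pp$start
      pcs <- read_pieces(r$start, r$length, P)
      recs <- data.frame(target = pp$replicon,
                         tstart = pp$start + pcs[, 1],
                         tend = pp$start + pcs[, 2])
    } else {
      L <- lens[[mol]]
      pcs <- read_pieces(r$start, r$length, L)
      recs <- data.frame(target = mol, tstart = pcs[, 1], tend = pcs[, 2])
    }
    recs$read_id <- r$read_id
    recs$strand <- r$strand
    recs$score <- recs$tend - recs$tstart
    # query coordinates in segment order
    qlen <- cumsum(c(0, recs$score))
    recs$qstart <- qlen[-length(qlen)]
    recs$qend <- qlen[-1]

    # secondary near-tied hit on the sibling strain for shared-segment reads
    if (!is.null(sh) && nrow(sh) && mol %in% c(sa, sb)) {
      from_a <- mol == sa
      ss <- if (from_a) sh$base_start else sh$sib_start
      se <- if (from_a) sh$base_end else sh$sib_end
      os <- if (from_a) sh$sib_start else sh$base_start
      shared_bases <- 0; m_start <- NA; m_end <- NA
      for (p in seq_len(nrow(recs))) {
        ov <- pmin(recs$tend[p], se) - pmax(recs$tstart[p], ss)
        ov[ov < 0] <- 0
        shared_bases <- shared_bases + sum(ov)
        j <- which.max(ov)
        if (ov[j] > 0 && is.na(m_start)) {
          m_start <- os[j] + (max(recs$tstart[p], ss[j]) - ss[j])
          m_end <- m_start + ov[j]
        }
      }
      if (shared_bases > 0) {
        recs <- rbind(recs, data.frame(
          target = if (from_a) sb else sa, tstart = m_start, tend = m_end,
          read_id = r$read_id, strand = r$strand, score = shared_bases,
          qstart = 0, qend = shared_bases))
      }
    }
    out[[i]] <- recs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("read_id", "target", "tstart", "tend", "qstart", "qend", "strand", "score")]
}

#' Contig set of the strain pair derived from truth segments
#'
#' Mimics the contigs an assembler would produce for a two-strain species:
#' strain-unique segments become strain-specific contigs, shared segments
#' become single contigs carrying reads of both strains. Long segments are
#' split into pieces of at most `max_len`.
#'
#' @param bundle A [truth_bundle()] with strain truth.
#' @param max_len Maximum contig length in bases.
#' @return data.frame with columns `contig`, `truth` (A/B/shared),
#'   `a_start`, `a_end`, `b_start`, `b_end` (NA where absent), `length`.
#' @export
strain_contigs_from_truth <- function(bundle, max_len = 30000L) {
  seg <- bundle$strains$segments
  rows <- list()
  add <- function(truth, a_s, a_e, b_s, b_e) {
    len <- if (!is.na(a_s)) a_e - a_s else b_e - b_s
    n_chunk <- max(1L, ceiling(len / max_len))
    bnd <- round(seq(0L, len, length.out = n_chunk + 1L))
    for (c in seq_len(n_chunk)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        truth = truth,
        a_start = if (!is.na(a_s)) a_s + bnd[c] else NA_integer_,
        a_end = if (!is.na(a_s)) a_s + bnd[c + 1L] else NA_integer_,
        b_start = if (!is.na(b_s)) b_s + bnd[c] else NA_integer_,
        b_end = if (!is.na(b_s)) b_s + bnd[c + 1L] else NA_integer_,
        length = bnd[c + 1L] - bnd[c])
    }
  }
  for (i in seq_len(nrow(seg))) {
    if (seg$type[i] == "shared") {
      add("shared", seg$base_start[i], seg$base_end[i],
          seg$sib_start[i], seg$sib_end[i])
    } else {
      add("A", seg$base_start[i], seg$base_end[i], NA, NA)
      add("B", NA, NA, seg$sib_start[i], seg$sib_end[i])
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$length > 0, , drop = FALSE]
  out$contig <- sprintf("ctg_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("contig", "truth", "a_start", "a_end", "b_start", "b_end", "length")]
}

#' Mean coverage of strain contigs from read truth intervals
#'
#' Shared contigs accumulate aligned bases from both strains; unique contigs
#' only from their own strain. Origin-wrapping reads are handled.
#'
#' @param bundle A [truth_bundle()].
#' @param contigs data.frame from [strain_contigs_from_truth()].
#' @param read_ids Optional subset of read ids (e.g. after filtering).
#' @return Named numeric vector of mean fold coverage per contig.
#' @export
strain_contig_coverage <- function(bundle, contigs, read_ids = NULL) {
  reads <- bundle$sim_reads$reads
  if (!is.null(read_ids)) reads <- reads[reads$read_id %in% read_ids, , drop = FALSE]
  sa <- bundle$strains$strain_a; sb <- bundle$strains$strain_b
  lens <- vapply(bundle$community, function(r) nchar(r$seq), integer(1))
  pieces_for <- function(strain) {
    rr <- reads[reads$replicon == strain, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(rr)), function(i)
      read_pieces(rr$start[i], rr$length[i], lens[[strain]])))
  }
  pa <- pieces_for(sa); pb <- pieces_for(sb)
  total_overlap <- function(p, s, e) {
    if (is.null(p) || nrow(p) == 0L) return(0)
    sum(pmax(0, pmin(p[, 2], e) - pmax(p[, 1], s)))
  }
  cov <- vapply(seq_len(nrow(contigs)), function(i) {
    b <- 0
    if (!is.na(contigs$a_start[i])) {
      b <- b + total_overlap(pa, contigs$a_start[i], contigs$a_end[i])
    }
    if (!is.na(contigs$b_start[i])) {
      b <- b + total_overlap(pb, contigs$b_start[i], contigs$b_end[i])
    }
    b / contigs$length[i]
  }, numeric(1))
  setNames(cov, contigs$contig)
}
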