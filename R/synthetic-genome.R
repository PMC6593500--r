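#' Generate a base replicon sequence with planted repeat blocks
#'
#' Draws a random sequence at the spec's target GC and overwrites it with
#' exact repeat-block copies at recorded, non-overlapping coordinates. All
#' coordinates are 0-based half-open.
#'
#' @param spec A [replicon_spec()].
#' @param seed Integer RNG seed; identical spec + seed give identical output.
#' @return A list with `seq` (character), `repeats` (data.frame with columns
#'   `family`, `copy`, `start`, `end`), and the `spec`.
#' @export
generate_base_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "replicon_spec"))
  with_seed(seed, {
    seq <- random_dna(spec$length, spec$gc_target)
    repeats <- data.frame(family = integer(0), copy = integer(0),
                          start = integer(0), end = integer(0))
    if (nrow(spec$repeat_blocks)) {
      placed <- matrix(integer(0), ncol = 2) # occupied [start, end) intervals
      for (f in seq_len(nrow(spec$repeat_blocks))) {
        blen <- as.integer(spec$repeat_blocks$block_length[f])
        ncopy <- as.integer(spec$repeat_blocks$copy_number[f])
        block <- random_dna(blen, spec$gc_target)
        for (cp in seq_len(ncopy)) {
          start <- place_nonoverlapping(spec$length, blen, placed)
          placed <- rbind(placed, c(start, start + blen))
          seq <- overwrite_at(seq, start, block)
          repeats <- rbind(repeats, data.frame(family = f, copy = cp,
                                               start = start, end = start + blen))
        }
      }
    }
    list(seq = seq, repeats = repeats, spec = spec)
  })
}

# Rejection-sample a 0-based start for an interval of width w in [0, L) that
# does not overlap previously placed intervals.
place_nonoverlapping <- function(L, w, placed, max_tries = 10000L) {
  if (w > L) stop("block longer than replicon")
  for (i in seq_len(max_tries)) {
    start <- sample.int(L - w + 1L, 1L) - 1L
    if (nrow(placed) == 0L ||
        all(start + w <= placed[, 1] | start >= placed[, 2])) {
      return(start)
    }
  }
  stop("could not place block of ", w, " bases without overlap after ",
       max_tries, " tries")
}

#' Derive a sibling strain from a base chromosome
#'
#' Emulates two distantly related strains of one species: a configurable
#' fraction of the base genome is shared verbatim (up to planted SNVs), the
#' remainder is replaced by strain-unique novel sequence, and optionally some
#' shared blocks are reordered in the sibling (large-scale rearrangements).
#'
#' @param base Base strain sequence (character).
#' @param pair A [strain_pair_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `seq` (the sibling), `segments` (data.frame mapping
#'   base to sibling coordinates with a `type` of `"shared"` or `"unique"`;
#'   unique rows describe base-only segments and the novel sibling segment
#'   replacing them), `snv` (data.frame of planted substitutions with base and
#'   sibling 0-based positions, `ref`, `alt`), and `shared_fraction_realized`.
#' @export
derive_sibling_strain <- function(base, pair, seed = 1L) {
  stopifnot(inherits(pair, "strain_pair_spec"), nchar(base) > 0)
  L <- nchar(base)
  with_seed(seed, {
    unique_bases <- round(L * (1 - pair$shared_fraction))
    nb <- if (unique_bases > 0) max(1L, pair$n_unique_blocks) else 0L
    # split unique bases into nb near-equal blocks (random remainder)
    if (nb > 0L) {
      base_size <- unique_bases %/% nb
      block_sizes <- rep(base_size, nb)
      rem <- unique_bases - base_size * nb
      if (rem > 0L) {
        bump <- sample.int(nb, rem)
        block_sizes[bump] <- block_sizes[bump] + 1L
      }
      placed <- matrix(integer(0), ncol = 2)
      starts <- integer(nb)
      for (i in seq_len(nb)) {
        starts[i] <- place_nonoverlapping(L, block_sizes[i], placed)
        placed <- rbind(placed, c(starts[i], starts[i] + block_sizes[i]))
      }
      ord <- order(starts)
      u_start <- starts[ord]; u_end <- starts[ord] + block_sizes[ord]
    } else {
      u_start <- integer(0); u_end <- integer(0)
    }
    # alternating segment walk over the base genome
    bounds <- sort(unique(c(0L, u_start, u_end, L)))
    seg <- data.frame(base_start = head(bounds, -1L), base_end = bounds[-1L])
    seg$type <- ifelse(vapply(seg$base_start, function(s)
      any(s >= u_start & s < u_end), logical(1)), "unique", "shared")
    seg <- seg[seg$base_end > seg$base_start, , drop = FALSE]

    # sibling segment order: shared segments may be swapped (rearrangements)
    seg$piece <- seq_len(nrow(seg))
    order_vec <- seg$piece
    sh_idx <- which(seg$type == "shared")
    n_swaps <- min(pair$n_rearrangements, floor(length(sh_idx) / 2))
    if (n_swaps > 0) {
      for (i in seq_len(n_swaps)) {
        sw <- sample(sh_idx, 2L)
        order_vec[match(sw, order_vec)] <- rev(sw)
      }
    }

    gc <- gc_fraction(base)
    pieces <- character(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      if (seg$type[i] == "shared") {
        pieces[i] <- substr(base, seg$base_start[i] + 1L, seg$base_end[i])
      } else {
        # novel strain-B sequence of the same length replaces the base block
        pieces[i] <- random_dna(seg$base_end[i] - seg$base_start[i], gc)
      }
    }
    sib_pieces <- pieces[order_vec]
    sib_len <- cumsum(c(0L, nchar(sib_pieces)))
    seg$sib_start <- NA_integer_; seg$sib_end <- NA_integer_
    for (k in seq_along(order_vec)) {
      i <- order_vec[k]
      seg$sib_start[i] <- sib_len[k]
      seg$sib_end[i] <- sib_len[k + 1L]
    }
    sibling <- paste(sib_pieces, collapse = "")

    # plant SNVs on shared segments
    snv <- data.frame(base_pos = integer(0), sib_pos = integer(0),
                      ref = character(0), alt = character(0))
    if (pair$snv_rate > 0) {
      sib_raw <- charToRaw(sibling)
      for (i in which(seg$type == "shared")) {
        w <- seg$base_end[i] - seg$base_start[i]
        n_mut <- rbinom(1L, w, pair$snv_rate)
        if (n_mut == 0L) next
        off <- sort(sample.int(w, n_mut)) - 1L
        for (o in off) {
          bpos <- seg$base_start[i] + o
          spos <- seg$sib_start[i] + o
          ref <- rawToChar(sib_raw[spos + 1L])
          alt <- sample(setdiff(DNA_BASES, ref), 1L)
          sib_raw[spos + 1L] <- charToRaw(alt)
          snv <- rbind(snv, data.frame(base_pos = bpos, sib_pos = spos,
                                       ref = ref, alt = alt))
        }
      }
      sibling <- rawToChar(sib_raw)
    }

    shared_realized <- sum(seg$base_end[seg$type == "shared"] -
                             seg$base_start[seg$type == "shared"]) / L
    seg <- seg[, c("piece", "type", "base_start", "base_end",
                   "sib_start", "sib_end")]
    for (col in c("piece", "base_start", "base_end", "sib_start", "sib_end")) {
      seg[[col]] <- as.integer(seg[[col]])
    }
    snv$base_pos <- as.integer(snv$base_pos)
    snv$sib_pos <- as.integer(snv$sib_pos)
    list(seq = sibling, segments = seg,
         snv = snv, shared_fraction_realized = shared_realized)
  })
}

#' Plant a CRISPR array in a host and matching protospacers in a phage
#'
#' Inserts a repeat-spacer array (n spacers flanked by n+1 direct repeats)
#' into the host sequence and overwrites phage positions with protospacer
#' copies of each spacer, each carrying the scheduled number of substitutions
#' on a random strand. Emulates a host that has acquired immunity against the
#' phage through past encounters.
#'
#' @param host Host replicon sequence.
#' @param phage Phage genome sequence.
#' @param spec A [crispr_plant_spec()].
#' @param seed Integer RNG seed.
#' @return A list with `host` and `phage` (modified sequences), `array`
#'   (list: `start`, `end` on the modified host, `repeat_sequence`, `spacers`
#'   data.frame with columns `spacer_id`, `sequence`, `start`, `end`), and
#'   `protospacers` (data.frame: `spacer_id`, `start`, `end`, `strand`,
#'   `mismatches`, `planted_sequence`).
#' @export
plant_crispr_and_protospacers <- function(host, phage, spec, seed = 1L) {
  stopifnot(inherits(spec, "crispr_plant_spec"))
  n <- length(spec$mismatch_schedule)
  if (n == 0L) {
    return(list(host = host, phage = phage, array = NULL,
                protospacers = data.frame(spacer_id = integer(0),
                                          start = integer(0), end = integer(0),
                                          strand = character(0),
                                          mismatches = integer(0),
                                          planted_sequence = character(0))))
  }
  rep_seq <- spec$repeat_sequence
  slen <- spec$spacer_length
  array_len <- (n + 1L) * nchar(rep_seq) + n * slen
  if (nchar(host) < array_len) stop("host too short to hold the CRISPR array")
  if (nchar(phage) < n * slen) stop("phage too short to hold all protospacers")
  with_seed(seed, {
    gc <- gc_fraction(host)
    # mutually dissimilar spacers: random draws, re-drawn on high identity
    spacers <- character(n)
    for (i in seq_len(n)) {
      repeat {
        cand <- random_dna(slen, gc)
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (mean(strsplit(cand, "")[[1]] == strsplit(spacers[j], "")[[1]]) > 0.7) ok <- FALSE
          }
        }
        if (ok) break
      }
      spacers[i] <- cand
    }
    site <- sample.int(nchar(host) - 1L, 1L)
    # guarantee well-defined repeat boundaries: the columns flanking the
    # repeat copies (spacer edges and host bases at the insertion point) must
    # not all agree, otherwise the repeat would legitimately extend into them
    left_nb <- c(substr(host, site, site),
                 vapply(spacers, function(s) substr(s, slen, slen), character(1)))
    if (length(unique(left_nb)) == 1L) {
      substr(spacers[1], slen, slen) <- sample(setdiff(DNA_BASES, left_nb[1]), 1L)
    }
    right_nb <- c(vapply(spacers, function(s) substr(s, 1L, 1L), character(1)),
                  substr(host, site + 1L, site + 1L))
    if (length(unique(right_nb)) == 1L) {
      substr(spacers[1], 1L, 1L) <- sample(setdiff(DNA_BASES, right_nb[1]), 1L)
    }
    array_seq <- paste0(rep_seq, paste(vapply(spacers, function(s)
      paste0(s, rep_seq), character(1)), collapse = ""))
    host2 <- insert_at(host, site, array_seq)
    sp_start <- site + nchar(rep_seq) +
      (seq_len(n) - 1L) * (slen + nchar(rep_seq))
    array <- list(start = site, end = site + nchar(array_seq),
                  repeat_sequence = rep_seq,
                  spacers = data.frame(spacer_id = seq_len(n),
                                       sequence = spacers,
                                       start = sp_start, end = sp_start + slen))

    # protospacers: scheduled substitutions, random strand, non-overlapping
    placed <- matrix(integer(0), ncol = 2)
    proto <- data.frame(spacer_id = integer(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        mismatches = integer(0), planted_sequence = character(0))
    phage2 <- phage
    for (i in seq_len(n)) {
      m <- spec$mismatch_schedule[i]
      ps <- strsplit(spacers[i], "")[[1]]
      if (m > 0L) {
        at <- sample.int(slen, m)
        for (a in at) ps[a] <- sample(setdiff(DNA_BASES, ps[a]), 1L)
      }
      ps <- paste(ps, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") ps else revcomp(ps)
      start <- place_nonoverlapping(nchar(phage2), slen, placed)
      placed <- rbind(placed, c(start, start + slen))
      phage2 <- overwrite_at(phage2, start, planted)
      proto <- rbind(proto, data.frame(spacer_id = i, start = start,
                                       end = start + slen, strand = strand,
                                       mismatches = m, planted_sequence = planted))
    }
    list(host = host2, phage = phage2, array = array, protospacers = proto)
  })
}

#' Integrate a phage genome into a host chromosome
#'
#' Clean splice of the phage sequence at a 0-based host coordinate (no
#' attachment-site duplication).
#'
#' @param host Host sequence.
#' @param phage Phage sequence.
#' @param site 0-based insertion coordinate, `0 <= site <= nchar(host)`.
#' @return A list with `seq` (integrated host), `left_junction` (= site) and
#'   `right_junction` (= site + phage length), 0-based coordinates on the
#'   integrated sequence.
#' @export
integrate_prophage <- function(host, phage, site) {
  site <- as.integer(site)
  if (site < 0L || site > nchar(host)) {
    stop("insertion site ", site, " outside host [0, ", nchar(host), "]")
  }
  list(seq = insert_at(host, site, phage),
       left_junction = site,
       right_junction = site + nchar(phage))
}
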