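#' Assemble a community replicon list
#'
#' @param id Replicon identifier.
#' @param seq Sequence (character).
#' @param circular Logical topology flag.
#' @param kind One of `"chromosome"`, `"plasmid"`, `"phage"`.
#' @return A list of class `community_replicon`.
#' @export
community_replicon <- function(id, seq, circular = TRUE,
                               kind = c("chromosome", "plasmid", "phage")) {
  kind <- match.arg(kind)
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  structure(list(id = id, seq = seq, circular = circular, kind = kind),
            class = "community_replicon")
}

BASE_RAW <- charToRaw("ACGT")

# Apply independent per-base substitution / insertion / deletion errors to a
# read sequence. Returns the mutated character string.
apply_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  b <- charToRaw(seq)
  n <- length(b)
  if (sub_rate > 0) {
    idx <- which(runif(n) < sub_rate)
    if (length(idx)) {
      old <- match(b[idx], BASE_RAW)
      new <- ((old - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
      b[idx] <- BASE_RAW[new]
    }
  }
  keep <- if (del_rate > 0) runif(n) >= del_rate else rep(TRUE, n)
  ins_pos <- if (ins_rate > 0) which(runif(n) < ins_rate) else integer(0)
  if (any(!keep) || length(ins_pos)) {
    ins_bytes <- BASE_RAW[sample.int(4L, length(ins_pos), replace = TRUE)]
    keys <- c(which(keep), ins_pos + 0.5)
    b <- c(b[keep], ins_bytes)[order(keys)]
  }
  rawToChar(b)
}

draw_read_length <- function(sim, n) {
  if (sim$length_family == "fixed") return(rep(as.integer(sim$mean_length), n))
  m <- sim$mean_length; s <- sim$sd_length
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  len <- as.integer(round(rlnorm(n, meanlog, sdlog)))
  pmax(len, as.integer(sim$min_length))
}

#' Simulate long reads from a synthetic community with full ground truth
#'
#' Reads are drawn replicon by replicon until the total simulated bases reach
#' the target fold coverage. Circular replicons yield origin-wrapping reads.
#' When a prophage locus is declared, reads overlapping either prophage
#' junction are re-sourced from one of three molecule states (host with the
#' prophage integrated, host without it, free circular phage) drawn with the
#' mixture proportions, so the state labels of junction reads follow the
#' configured mixture directly.
#'
#' @param community List of [community_replicon()] objects. When a prophage
#'   locus is given, the host entry must carry the *integrated* sequence.
#' @param sim A [read_sim_spec()]; `sim$coverage` may be a single value or a
#'   named vector keyed by replicon id.
#' @param mixture A [prophage_mixture_spec()] or `NULL`.
#' @param prophage `NULL`, or a list with `replicon` (host id), `start`,
#'   `end` (0-based half-open prophage interval on the integrated host) and
#'   optionally `phage_id` (id used for the free circular molecule).
#' @param seed Integer RNG seed.
#' @return A list with `reads` (data.frame: `read_id`, `replicon` = source
#'   molecule, `start`, `length`, `strand`, `state`, `mean_quality`),
#'   `sequences` and `qualities` (named character vectors), and `molecules`
#'   (named character vector of the molecule sequences reads were drawn from,
#'   including prophage-state variants).
#' @export
simulate_reads <- function(community, sim, mixture = NULL, prophage = NULL,
                           seed = 1L) {
  stopifnot(inherits(sim, "read_sim_spec"))
  ids <- vapply(community, `[[`, character(1), "id")
  names(community) <- ids
  if (!is.null(prophage)) {
    stopifnot(inherits(mixture, "prophage_mixture_spec"),
              prophage$replicon %in% ids)
    if (mixture$integrated == 0 && mixture$absent == 0 && mixture$circular == 0) {
      stop("all prophage mixture fractions are zero")
    }
  }
  cov <- sim$coverage
  if (is.null(names(cov))) cov <- setNames(rep(cov[1], length(ids)), ids)
  missing_cov <- setdiff(ids, names(cov))
  if (length(missing_cov)) stop("no coverage given for replicon(s): ",
                                paste(missing_cov, collapse = ", "))

  molecules <- setNames(lapply(community, `[[`, "seq"), ids)
  mol_circ <- setNames(vapply(community, `[[`, logical(1), "circular"), ids)
  if (!is.null(prophage)) {
    host_id <- prophage$replicon
    ph_id <- if (!is.null(prophage$phage_id)) prophage$phage_id else paste0(host_id, "_phage")
    pstart <- as.integer(prophage$start); pend <- as.integer(prophage$end)
    host_seq <- molecules[[host_id]]
    molecules[[paste0(host_id, "_delta")]] <- delete_interval(host_seq, pstart, pend)
    molecules[[paste0(ph_id, "_circ")]] <- substr(host_seq, pstart + 1L, pend)
    mol_circ[paste0(host_id, "_delta")] <- mol_circ[[host_id]]
    mol_circ[paste0(ph_id, "_circ")] <- TRUE
  }

  with_seed(seed, {
    all_reads <- list(); all_seq <- list(); all_qual <- list()
    for (rid in ids) {
      rseq <- molecules[[rid]]
      L <- nchar(rseq)
      circ <- mol_circ[[rid]]
      target <- cov[[rid]] * L
      total <- 0; k <- 0L
      v_id <- list(); v_src <- list(); v_start <- list(); v_len <- list()
      v_strand <- list(); v_state <- list(); v_q <- list()
      while (total < target) {
        k <- k + 1L
        # a sequenced fragment cannot exceed the (linearized) molecule length
        len <- min(draw_read_length(sim, 1L), L)
        start <- if (circ) sample.int(L, 1L) - 1L else sample.int(L - len + 1L, 1L) - 1L
        src_id <- rid; src_seq <- rseq; src_circ <- circ; state <- "na"
        if (!is.null(prophage) && rid == prophage$replicon) {
          # modular distance from the read start to each junction; the read
          # crosses a junction when that distance falls strictly inside it
          # (wrap-aware on circular hosts, where start + len may exceed L)
          off <- c((pstart - start) %% L, (pend - start) %% L)
          hit <- off[off > 0 & off < len]
          if (length(hit)) {
            off_j <- min(hit) # first junction the read reaches
            state <- sample(c("integrated", "absent", "circular"), 1L,
                            prob = c(mixture$integrated, mixture$absent,
                                     mixture$circular))
            if (state == "absent") {
              src_id <- paste0(rid, "_delta")
              src_seq <- molecules[[src_id]]
              src_circ <- mol_circ[[src_id]]
              # both integrated junctions collapse onto the deletion junction
              Ld <- nchar(src_seq)
              len <- min(len, Ld)
              start <- if (src_circ) (pstart - off_j) %% Ld else
                max(0L, min(pstart - off_j, Ld - len))
            } else if (state == "circular") {
              src_id <- paste0(ph_id, "_circ")
              src_seq <- molecules[[src_id]]
              src_circ <- TRUE
              P <- nchar(src_seq)
              len <- min(len, P)
              start <- (P - min(off_j, len - 1L)) %% P
            }
          }
        }
        raw_seq <- extract_interval(src_seq, start, len, circular = src_circ)
        strand <- sample(c("+", "-"), 1L)
        out_seq <- if (strand == "-") revcomp(raw_seq) else raw_seq
        out_seq <- apply_read_errors(out_seq, sim$sub_rate, sim$ins_rate,
                                     sim$del_rate)
        q <- as.integer(round(max(2, min(40, rnorm(1, sim$quality_mean,
                                                   sim$quality_sd)))))
        read_id <- sprintf("%s_r%05d", rid, k)
        v_id[[k]] <- read_id; v_src[[k]] <- src_id; v_start[[k]] <- start
        v_len[[k]] <- len; v_strand[[k]] <- strand; v_state[[k]] <- state
        v_q[[k]] <- q
        all_seq[[read_id]] <- out_seq
        all_qual[[read_id]] <- strrep(rawToChar(as.raw(q + 33L)), nchar(out_seq))
        total <- total + len
      }
      all_reads[[rid]] <- data.frame(
        read_id = unlist(v_id), replicon = unlist(v_src),
        start = unlist(v_start), length = unlist(v_len),
        strand = unlist(v_strand), state = unlist(v_state),
        mean_quality = unlist(v_q))
    }
    reads <- do.call(rbind, all_reads)
    rownames(reads) <- NULL
    list(reads = reads,
         sequences = unlist(all_seq),
         qualities = unlist(all_qual),
         molecules = unlist(molecules))
  })
}

#' Assign methylation motif sets and enumerate motif sites
#'
#' Each host chromosome receives a motif set (its restriction-modification
#' recognition sequences); plasmids inherit the motif set of their assigned
#' host, reflecting that plasmid DNA is methylated by host methyltransferases.
#' All motif occurrences on both strands are enumerated (circular replicons
#' scanned across the origin) and each is methylated with probability
#' `methylated_fraction`.
#'
#' @param community List of [community_replicon()] objects.
#' @param motif_sets Named list: host replicon id -> character vector of
#'   IUPAC motifs.
#' @param plasmid_hosts Named character vector: plasmid id -> host id.
#' @param methylated_fraction Per-site methylation probability.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `replicon`, `motif`, `position` (0-based
#'   forward-strand coordinate of the first motif base on its strand),
#'   `strand`, `methylated`.
#' @export
assign_methylation_truth <- function(community, motif_sets,
                                     plasmid_hosts = character(0),
                                     methylated_fraction = 0.98, seed = 1L) {
  ids <- vapply(community, `[[`, character(1), "id")
  names(community) <- ids
  sets <- motif_sets
  for (pl in names(plasmid_hosts)) {
    if (!plasmid_hosts[[pl]] %in% names(motif_sets)) {
      stop("plasmid ", pl, " assigned to unknown host ", plasmid_hosts[[pl]])
    }
    sets[[pl]] <- motif_sets[[plasmid_hosts[[pl]]]]
  }
  with_seed(seed, {
    rows <- list()
    for (rid in intersect(ids, names(sets))) {
      seq <- community[[rid]]$seq
      circ <- community[[rid]]$circular
      L <- nchar(seq)
      for (motif in sets[[rid]]) {
        k <- nchar(motif)
        fwd <- motif_positions(seq, motif, circular = circ)
        rev_on_rc <- motif_positions(revcomp(seq), motif, circular = circ)
        # first motif base on the minus strand, in forward coordinates
        rev_pos <- (L - 1L - rev_on_rc) %% L
        pos <- c(fwd, rev_pos)
        strand <- c(rep("+", length(fwd)), rep("-", length(rev_pos)))
        if (!length(pos)) next
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = rid, motif = motif, position = pos, strand = strand,
          methylated = runif(length(pos)) < methylated_fraction)
      }
    }
    if (!length(rows)) {
      return(data.frame(replicon = character(0), motif = character(0),
                        position = integer(0), strand = character(0),
                        methylated = logical(0)))
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$replicon, out$position, out$strand), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-site methylation calls from methylation truth
#'
#' Produces the site-call table the methylation stage consumes: one row per
#' called site with per-strand coverage (Poisson around half the replicon
#' fold coverage) and a call score. True methylated sites receive high
#' scores; optional spurious calls at random positions receive low scores so
#' the downstream score cutoff has something to remove.
#'
#' @param meth_truth Output of [assign_methylation_truth()].
#' @param community List of [community_replicon()] objects.
#' @param coverage Named per-replicon fold coverage (single value recycled).
#' @param score_mean,score_sd Score distribution of true calls.
#' @param n_noise Number of spurious low-score calls per replicon.
#' @param noise_score_mean,noise_score_sd Score distribution of spurious calls.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `replicon`, `position`, `strand`,
#'   `coverage_fwd`, `coverage_rev`, `methylated`, `score`.
#' @export
simulate_site_calls <- function(meth_truth, community, coverage = 30,
                                score_mean = 150, score_sd = 25,
                                n_noise = 0, noise_score_mean = 30,
                                noise_score_sd = 8, seed = 1L) {
  ids <- vapply(community, `[[`, character(1), "id")
  names(community) <- ids
  if (is.null(names(coverage))) coverage <- setNames(rep(coverage[1], length(ids)), ids)
  with_seed(seed, {
    tr <- meth_truth[meth_truth$methylated, , drop = FALSE]
    per_strand <- coverage[tr$replicon] / 2
    calls <- data.frame(replicon = tr$replicon, position = tr$position,
                        strand = tr$strand,
                        coverage_fwd = rpois(nrow(tr), per_strand),
                        coverage_rev = rpois(nrow(tr), per_strand),
                        methylated = TRUE,
                        score = as.integer(round(pmax(0, rnorm(nrow(tr), score_mean,
                                                               score_sd)))))
    if (n_noise > 0) {
      noise <- do.call(rbind, lapply(intersect(unique(tr$replicon), ids),
        function(rid) {
          L <- nchar(community[[rid]]$seq)
          data.frame(replicon = rid,
                     position = sample.int(L, n_noise) - 1L,
                     strand = sample(c("+", "-"), n_noise, replace = TRUE),
                     coverage_fwd = rpois(n_noise, coverage[[rid]] / 2),
                     coverage_rev = rpois(n_noise, coverage[[rid]] / 2),
                     methylated = TRUE,
                     score = as.integer(round(pmax(0, rnorm(n_noise, noise_score_mean,
                                                            noise_score_sd)))))
        }))
      calls <- rbind(calls, noise)
    }
    calls <- calls[order(calls$replicon, calls$position, calls$strand), ]
    rownames(calls) <- NULL
    calls
  })
}
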