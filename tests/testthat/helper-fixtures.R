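# Shared fixture builders; all randomness goes through explicit seeds.

rand_seq <- function(n, gc = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
          collapse = "")
  })
}

# Independent brute-force protospacer oracle: naive per-offset Hamming count
# on both strands (no shared code with the package matcher).
brute_force_matches <- function(spacer, phage, max_mm, circular = FALSE) {
  L <- nchar(phage)
  k <- nchar(spacer)
  scan <- if (circular) paste0(phage, substr(phage, 1, k - 1)) else phage
  out <- list()
  for (strand in c("+", "-")) {
    probe <- if (strand == "+") spacer else {
      paste(rev(strsplit(chartr("ACGT", "TGCA", spacer), "")[[1]]), collapse = "")
    }
    pc <- strsplit(probe, "")[[1]]
    n_off <- nchar(scan) - k + 1
    for (off in seq_len(max(n_off, 0))) {
      win <- strsplit(substr(scan, off, off + k - 1), "")[[1]]
      mm <- sum(win != pc)
      if (mm <= max_mm && off - 1 < L) {
        out[[length(out) + 1]] <- data.frame(position = off - 1L,
                                             strand = strand,
                                             mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand), , drop = FALSE]
}

# host sequence with a planted repeat-spacer array; returns planted truth
plant_test_array <- function(host_len = 20000, repeat_len = 32,
                             spacer_len = 34, n_spacers = 3, seed = 1L,
                             gc = 0.5) {
  withr::with_seed(seed, {
    host <- rand_seq(host_len, gc, seed = seed + 1000L)
    rep_seq <- rand_seq(repeat_len, gc, seed = seed + 2000L)
    spacers <- vapply(seq_len(n_spacers), function(i)
      rand_seq(spacer_len, gc, seed = seed + 3000L + i), character(1))
    site <- sample(host_len - 1L, 1L)
    # keep the boundary columns divergent so the planted repeat is maximal
    left_nb <- c(substr(host, site, site),
                 vapply(spacers, function(s) substr(s, spacer_len, spacer_len),
                        character(1)))
    if (length(unique(left_nb)) == 1L) {
      substr(spacers[1], spacer_len, spacer_len) <-
        setdiff(c("A", "C", "G", "T"), left_nb[1])[1]
    }
    right_nb <- c(vapply(spacers, function(s) substr(s, 1, 1), character(1)),
                  substr(host, site + 1L, site + 1L))
    if (length(unique(right_nb)) == 1L) {
      substr(spacers[1], 1, 1) <- setdiff(c("A", "C", "G", "T"), right_nb[1])[1]
    }
    arr <- paste0(rep_seq, paste(vapply(spacers, function(s) paste0(s, rep_seq),
                                        character(1)), collapse = ""))
    host2 <- paste0(substr(host, 1, site), arr,
                    substr(host, site + 1, host_len))
    list(seq = host2, start = site, end = site + nchar(arr),
         repeat_sequence = rep_seq, spacers = spacers)
  })
}

# minimal two-replicon community for read-simulation tests
tiny_community <- function(seed = 1L) {
  list(community_replicon("chr", rand_seq(60000, 0.45, seed), circular = TRUE),
       community_replicon("pl", rand_seq(9000, 0.40, seed + 1L),
                          circular = TRUE, kind = "plasmid"))
}
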