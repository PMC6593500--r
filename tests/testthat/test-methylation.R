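mk_calls <- function(pos, strand, score = 150, cov = 300, methylated = TRUE) {
  n <- length(pos)
  data.frame(position = pos, strand = strand,
             coverage_fwd = rep_len(cov, n), coverage_rev = rep_len(cov, n),
             methylated = rep_len(methylated, n), score = rep_len(score, n))
}

test_that("motif profile counts occurrences and methylated fractions exactly", {
  # sequence with GATC planted 10 times on the forward strand, far apart;
  # GATC is palindromic so each occurrence also appears on the minus strand
  spacer <- strrep("CCA", 20) # GATC-free filler
  seq <- paste0(paste(rep(paste0(spacer, "GATC"), 10), collapse = ""), spacer)
  occ <- magweave:::motif_occurrences(seq, "GATC")
  expect_equal(nrow(occ), 20L) # 10 per strand
  fwd_pos <- occ$position[occ$strand == "+"]
  # 9 of 10 forward occurrences called methylated (plus all minus-strand ones)
  calls <- rbind(mk_calls(fwd_pos[1:9], "+"),
                 mk_calls(occ$position[occ$strand == "-"], "-"))
  prof <- motif_profile(seq, calls, "GATC", min_strand_coverage = 250)
  expect_equal(prof$n_sites, 20L)
  expect_equal(prof$n_methylated, 19L)
  expect_equal(prof$methylated_fraction, 0.95)
  expect_identical(prof$confidence, "ok")

  # low per-strand coverage flips the confidence flag
  low <- motif_profile(seq, mk_calls(fwd_pos, "+", cov = 100), "GATC",
                       min_strand_coverage = 250)
  expect_identical(low$confidence, "low_coverage")

  # calls below the score cutoff are ignored
  weak <- motif_profile(seq, mk_calls(fwd_pos, "+", score = 30), "GATC")
  expect_equal(weak$n_methylated, 0L)

  # motif absent from the sequence: zero sites, downstream unassigned
  none <- motif_profile(seq, calls, "GCCGGC")
  expect_equal(none$n_sites, 0L)
  expect_true(is.na(none$methylated_fraction))
  expect_length(detected_motifs(none), 0L)
})

test_that("circular scanning finds motif occurrences across the origin", {
  # GATC split across the origin: ...GA | TC...
  seq <- paste0("TC", strrep("A", 50), "GA")
  expect_length(magweave:::motif_positions(seq, "GATC", circular = FALSE), 0L)
  expect_identical(magweave:::motif_positions(seq, "GATC", circular = TRUE),
                   52L)
})

test_that("motif discovery recovers a planted GATC context with BH control", {
  seq <- rand_seq(40000, 0.4, seed = 401)
  sites <- magweave:::motif_occurrences(seq, "GATC")
  expect_gt(nrow(sites), 100)
  calls <- mk_calls(sites$position, sites$strand)
  disc <- discover_motifs(seq, calls, k_range = 4, alpha = 0.05)
  expect_true("GATC" %in% disc$motif)
  expect_lte(disc$p_adj[disc$motif == "GATC"], 0.05)
  # oracle: the binomial p-value for GATC recomputed independently
  m <- nrow(sites)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), 4)
  p0 <- (counts[["GATC"]] + counts[["GATC"]]) / (2 * (nchar(seq) - 3))
  p_oracle <- pbinom(m - 1, m, p0, lower.tail = FALSE)
  expect_equal(disc$p_value[disc$motif == "GATC"], unname(p_oracle),
               tolerance = 1e-12)
})

test_that("a planted 6-mer motif is recovered at k = 6", {
  seq <- rand_seq(60000, 0.45, seed = 402)
  sites <- magweave:::motif_occurrences(seq, "CTGCAG")
  calls <- mk_calls(sites$position, sites$strand)
  disc <- discover_motifs(seq, calls, k_range = 4:6, alpha = 0.05)
  expect_true("CTGCAG" %in% disc$motif[disc$k == 6])
  # canonical reduction keeps the most specific form
  expect_true("CTGCAG" %in% canonical_motifs(disc))
  expect_false("CTGC" %in% canonical_motifs(disc))
})

test_that("degenerate-position merging unites one-off k-mers", {
  seq <- rand_seq(60000, 0.45, seed = 403)
  sites <- rbind(magweave:::motif_occurrences(seq, "CCAGG"),
                 magweave:::motif_occurrences(seq, "CCTGG"))
  calls <- mk_calls(sites$position, sites$strand)
  disc <- discover_motifs(seq, calls, k_range = 5, alpha = 0.05)
  expect_true(all(c("CCAGG", "CCTGG") %in% disc$motif))
  expect_identical(unique(disc$merged_motif[disc$motif %in% c("CCAGG", "CCTGG")]),
                   "CCWGG")
})

test_that("uniform-random sites rarely yield discoveries (type-I control)", {
  seq <- rand_seq(20000, 0.45, seed = 404)
  n_disc <- 0L
  n_sim <- 60L
  for (i in seq_len(n_sim)) {
    set.seed(500 + i)
    pos <- sample.int(19000, 80) - 1L
    strand <- sample(c("+", "-"), 80, replace = TRUE)
    calls <- mk_calls(pos, strand)
    disc <- discover_motifs(seq, calls, k_range = 4, alpha = 0.05)
    if (nrow(disc)) n_disc <- n_disc + 1L
    }
  expect_lte(n_disc / n_sim, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("no methylated sites gives an empty discovery result", {
  seq <- rand_seq(5000, 0.5, seed = 405)
  empty <- discover_motifs(seq, mk_calls(integer(0), character(0)), 4)
  expect_equal(nrow(empty), 0L)
  expect_error(discover_motifs(seq, mk_calls(1, "+"), k_range = 9), "2..8")
})

test_that("plasmid-host assignment follows the unique-motif rule", {
  hostm <- list(A = c("GATC", "CCWGG"), B = c("GCGC"))
  asg <- assign_plasmid_hosts(list(p1 = "GATC"), hostm)
  expect_identical(asg$hosts, "A")
  expect_identical(asg$basis, "unique_motif")

  # motifs shared by two sibling hosts: both listed
  sib <- list(A = c("GATC", "CCWGG"), B = c("GATC", "CCWGG", "GCGC"))
  asg2 <- assign_plasmid_hosts(list(p = c("GATC", "CCWGG")), sib)
  expect_identical(asg2$basis, "shared_motif")
  expect_setequal(strsplit(asg2$hosts, ",")[[1]], c("A", "B"))

  # no motif detected on the plasmid
  asg3 <- assign_plasmid_hosts(list(p = character(0)), hostm)
  expect_identical(asg3$basis, "unassigned")
  expect_identical(asg3$hosts, "")

  expect_error(assign_plasmid_hosts(list(p = "GATC"), list()), "at least one")
})

test_that("generator-truth plasmids are assigned to their hosts across seeds", {
  for (seed in 1:5) {
    comm <- list(
      community_replicon("hA", rand_seq(60000, 0.4, seed = 600 + seed)),
      community_replicon("hB", rand_seq(60000, 0.4, seed = 700 + seed)),
      community_replicon("p1", rand_seq(12000, 0.4, seed = 800 + seed),
                         kind = "plasmid"),
      community_replicon("p2", rand_seq(12000, 0.4, seed = 900 + seed),
                         kind = "plasmid"))
    motif_sets <- list(hA = c("GATC", "CCWGG"), hB = c("GATC", "GCGC"))
    ph <- c(p1 = "hA", p2 = "hB")
    truth <- assign_methylation_truth(comm, motif_sets, plasmid_hosts = ph,
                                      methylated_fraction = 0.98,
                                      seed = seed)
    calls <- simulate_site_calls(truth, comm, coverage = 600, seed = seed)
    names(comm) <- vapply(comm, `[[`, character(1), "id")
    det <- lapply(setNames(names(comm), names(comm)), function(rid) {
      detected_motifs(motif_profile(comm[[rid]]$seq,
                                    calls[calls$replicon == rid, ],
                                    c("GATC", "CCWGG", "GCGC"),
                                    circular = TRUE))
    })
    asg <- assign_plasmid_hosts(det[c("p1", "p2")], det[c("hA", "hB")])
    expect_identical(asg$hosts[asg$plasmid == "p1"], "hA")
    expect_identical(asg$hosts[asg$plasmid == "p2"], "hB")
    expect_true(all(asg$basis == "unique_motif"))
  }
})
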