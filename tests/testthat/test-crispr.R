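test_that("planted arrays are detected with correct structure and consensus", {
  tr <- plant_test_array(host_len = 20000, repeat_len = 32, spacer_len = 34,
                         n_spacers = 3, seed = 101)
  arrays <- detect_crispr_arrays(tr$seq)
  expect_length(arrays, 1L)
  a <- arrays[[1]]
  expect_equal(nrow(a$spacers), 3L)
  expect_identical(a$repeat_consensus, tr$repeat_sequence)
  expect_equal(a$start, tr$start)
  expect_equal(a$end, tr$end)
  expect_identical(a$spacers$sequence, unname(tr$spacers))
})

test_that("two tandem repeat copies do not qualify as an array", {
  host <- rand_seq(10000, 0.5, seed = 7)
  rep_seq <- rand_seq(32, 0.5, seed = 8)
  spacer <- rand_seq(34, 0.5, seed = 9)
  two <- paste0(substr(host, 1, 4000), rep_seq, spacer, rep_seq,
                substr(host, 4001, 10000))
  expect_length(detect_crispr_arrays(two), 0L)
})

test_that("planted arrays are recalled across seeds; random sequence yields none", {
  hits <- 0L
  for (seed in 1:20) {
    tr <- plant_test_array(host_len = 15000, seed = 200 + seed)
    arrays <- detect_crispr_arrays(tr$seq)
    found <- any(vapply(arrays, function(a)
      a$start <= tr$start + 5 && a$end >= tr$end - 5 &&
        nrow(a$spacers) == 3L, logical(1)))
    hits <- hits + found
  }
  expect_equal(hits, 20L)

  for (seed in 1:5) {
    expect_length(detect_crispr_arrays(rand_seq(100000, 0.45, seed = 300 + seed)),
                  0L)
  }
})

test_that("protospacer matcher equals the brute-force oracle", {
  set.seed(77)
  for (case in 1:40) {
    slen <- sample(25:35, 1)
    plen <- sample(500:3000, 1)
    circ <- sample(c(TRUE, FALSE), 1)
    phage <- rand_seq(plen, runif(1, 0.3, 0.6), seed = 1000 + case)
    # half the cases carry a planted near-match so hits actually occur
    spacer <- if (case %% 2 == 0) {
      rand_seq(slen, 0.5, seed = 2000 + case)
    } else {
      pos <- sample(plen - slen, 1)
      s <- substr(phage, pos, pos + slen - 1)
      ch <- strsplit(s, "")[[1]]
      at <- sample(slen, sample(0:3, 1))
      for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1)
      if (runif(1) < 0.5) paste(ch, collapse = "") else
        revcomp(paste(ch, collapse = ""))
    }
    maxmm <- sample(0:3, 1)
    got <- match_protospacers(c(sp = spacer), c(ph = phage),
                              max_mismatches = maxmm, circular = circ)
    want <- brute_force_matches(spacer, phage, maxmm, circular = circ)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$position, want$position)
      expect_identical(got$strand, want$strand)
      expect_identical(as.integer(got$mismatches), as.integer(want$mismatches))
    }
  }
})

test_that("matcher finds reverse-strand hits and respects the mismatch budget", {
  phage <- rand_seq(4000, 0.5, seed = 55)
  spacer <- substr(phage, 1001, 1030)
  # exact forward occurrence
  m0 <- match_protospacers(c(s = spacer), c(p = phage), 0)
  expect_true(any(m0$position == 1000 & m0$strand == "+" & m0$mismatches == 0))

  # reverse-complement occurrence with 2 substitutions, max 2 -> strand "-"
  ch <- strsplit(spacer, "")[[1]]
  ch[c(5, 20)] <- vapply(ch[c(5, 20)], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  probe <- revcomp(paste(ch, collapse = ""))
  m2 <- match_protospacers(c(s = probe), c(p = phage), 2)
  expect_true(any(m2$position == 1000 & m2$strand == "-" & m2$mismatches == 2))

  # three substitutions exceed the default budget of two
  ch3 <- strsplit(spacer, "")[[1]]
  ch3[c(3, 15, 27)] <- vapply(ch3[c(3, 15, 27)], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  m3 <- match_protospacers(c(s = paste(ch3, collapse = "")), c(p = phage), 2)
  expect_false(any(m3$position == 1000))
  # but a weak-match rescan with budget 6 reports it
  m6 <- match_protospacers(c(s = paste(ch3, collapse = "")), c(p = phage), 6)
  expect_true(any(m6$position == 1000 & m6$mismatches == 3))

  expect_warning(match_protospacers(c(s = strrep("A", 50)),
                                    c(p = strrep("C", 30)), 2), "longer")
})

test_that("strand symmetry: matching a reverse-complemented phage flips strands", {
  phage <- rand_seq(3000, 0.5, seed = 66)
  spacer <- substr(phage, 501, 530)
  fwd <- match_protospacers(c(s = spacer), c(p = phage), 2)
  rev <- match_protospacers(c(s = spacer), c(p = revcomp(phage)), 2)
  expect_equal(nrow(fwd), nrow(rev))
  ford <- fwd[order(fwd$position), ]
  rord <- rev[order(3000L - rev$position - 30L), ]
  expect_identical(ford$position, 3000L - rord$position - 30L)
  expect_identical(as.integer(ford$mismatches), as.integer(rord$mismatches))
  expect_true(all(ford$strand != rord$strand))
})

test_that("interaction report applies the encounter evidence rules", {
  matches <- data.frame(
    spacer_id = c(paste0("s", 1:6), "w1"),
    phage_id = c(rep("phA", 6), "phB"),
    position = 1:7, strand = "+",
    mismatches = c(0, 0, 1, 1, 2, 2, 6), spacer_length = 30)
  hosts <- setNames(rep("hostX", 7), c(paste0("s", 1:6), "w1"))
  rep <- interaction_report(matches, hosts,
                            all_pairs = data.frame(host = "hostX",
                                                   phage = c("phA", "phB", "phC")))
  rA <- rep[rep$phage == "phA", ]
  expect_equal(rA$n_close, 6L)
  expect_match(rA$verdict, "previous encounter")
  rB <- rep[rep$phage == "phB", ]
  expect_equal(rB$min_mismatches, 6L)
  expect_match(rB$verdict, "poor match")
  rC <- rep[rep$phage == "phC", ]
  expect_identical(rC$verdict, "no evidence")

  empty <- interaction_report(matches[0, ], hosts)
  expect_equal(nrow(empty), 0L)
})
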