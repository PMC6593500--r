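test_that("base genome generation honors length, GC, repeats and determinism", {
  spec <- replicon_spec("c1", "chromosome", 50000, gc_target = 0.40)
  g <- generate_base_genome(spec, seed = 1)
  expect_equal(nchar(g$seq), 50000L)
  expect_gte(gc_fraction(g$seq), 0.38)
  expect_lte(gc_fraction(g$seq), 0.42)
  expect_identical(g$seq, generate_base_genome(spec, seed = 1)$seq)
  expect_false(identical(g$seq, generate_base_genome(spec, seed = 2)$seq))

  spec2 <- replicon_spec("c2", "chromosome", 20000, gc_target = 0.5,
                         repeat_blocks = data.frame(block_length = 5000,
                                                    copy_number = 2))
  g2 <- generate_base_genome(spec2, seed = 3)
  r <- g2$repeats
  expect_equal(nrow(r), 2L)
  expect_identical(substr(g2$seq, r$start[1] + 1, r$end[1]),
                   substr(g2$seq, r$start[2] + 1, r$end[2]))
  # planted copies must not overlap
  expect_true(r$end[1] <= r$start[2] || r$end[2] <= r$start[1])

  expect_error(replicon_spec("bad", "chromosome", 10000,
                             repeat_blocks = data.frame(block_length = 6000,
                                                        copy_number = 2)),
               "exceed")
  expect_error(replicon_spec("bad", "chromosome", 0), "length")
  expect_error(replicon_spec("bad", "chromosome", 100, gc_target = 1.2),
               "gc_target")
})

test_that("sibling strain derivation plants verifiable shared/unique/SNV truth", {
  base <- generate_base_genome(replicon_spec("a", "chromosome", 200000,
                                             gc_target = 0.40), seed = 1)$seq

  # identity case: full sharing, no SNVs, no rearrangements
  same <- derive_sibling_strain(base, strain_pair_spec(1, 0, 0), seed = 2)
  expect_identical(same$seq, base)
  expect_equal(same$shared_fraction_realized, 1)

  sib <- derive_sibling_strain(base, strain_pair_spec(0.94, snv_rate = 1e-3,
                                                      n_rearrangements = 1),
                               seed = 3)
  expect_lte(abs(sib$shared_fraction_realized - 0.94), 0.01)
  expect_equal(nchar(sib$seq), nchar(base))

  # oracle: recount differences on every shared segment by direct comparison
  seg <- sib$segments
  for (i in which(seg$type == "shared")) {
    a <- substr(base, seg$base_start[i] + 1, seg$base_end[i])
    b <- substr(sib$seq, seg$sib_start[i] + 1, seg$sib_end[i])
    diffs <- which(charToRaw(a) != charToRaw(b)) - 1L
    planted <- sib$snv$base_pos[sib$snv$base_pos >= seg$base_start[i] &
                                  sib$snv$base_pos < seg$base_end[i]] -
      seg$base_start[i]
    expect_identical(sort(diffs), sort(as.integer(planted)))
  }
  # unique segments carry novel sequence, not the base block
  for (i in which(seg$type == "unique")) {
    a <- substr(base, seg$base_start[i] + 1, seg$base_end[i])
    b <- substr(sib$seq, seg$sib_start[i] + 1, seg$sib_end[i])
    expect_lt(mean(charToRaw(a) == charToRaw(b)), 0.5)
  }
  expect_error(derive_sibling_strain(base, strain_pair_spec(1.2)), "shared")
})

test_that("CRISPR planting builds n+1 repeats and exact scheduled mismatches", {
  host <- generate_base_genome(replicon_spec("h", "chromosome", 60000,
                                             gc_target = 0.42), seed = 1)$seq
  phage <- generate_base_genome(replicon_spec("p", "phage", 40000,
                                              gc_target = 0.44,
                                              circular = FALSE), seed = 2)$seq
  rep_seq <- withr::with_seed(9, paste(sample(c("A", "C", "G", "T"), 32,
                                              replace = TRUE), collapse = ""))
  sched <- c(0L, 0L, 1L, 1L, 2L, 2L)
  cr <- plant_crispr_and_protospacers(host, phage,
                                      crispr_plant_spec(rep_seq, 30, sched),
                                      seed = 3)
  arr <- cr$array
  expect_equal(nrow(arr$spacers), 6L)
  expect_equal(nchar(cr$host), nchar(host) + 7 * 32 + 6 * 30)
  # repeats flank every spacer
  arr_seq <- substr(cr$host, arr$start + 1, arr$end)
  expect_identical(substr(arr_seq, 1, 32), rep_seq)
  for (i in seq_len(6)) {
    sp <- arr$spacers
    expect_identical(substr(cr$host, sp$start[i] + 1, sp$end[i]),
                     sp$sequence[i])
    expect_identical(substr(cr$host, sp$end[i] + 1, sp$end[i] + 32), rep_seq)
  }
  # oracle: recount planted protospacer mismatches by direct comparison
  for (i in seq_len(6)) {
    pr <- cr$protospacers[i, ]
    planted <- substr(cr$phage, pr$start + 1, pr$end)
    if (pr$strand == "-") planted <- revcomp(planted)
    mm <- sum(charToRaw(planted) != charToRaw(arr$spacers$sequence[i]))
    expect_identical(mm, as.integer(sched[i]))
  }

  # zero spacers: sequences unchanged
  none <- plant_crispr_and_protospacers(host, phage,
                                        crispr_plant_spec(rep_seq, 30,
                                                          integer(0)),
                                        seed = 4)
  expect_identical(none$host, host)
  expect_identical(none$phage, phage)
  expect_null(none$array)

  expect_error(crispr_plant_spec(rep_seq, 30, c(0, 31)), "exceeds")
  expect_error(crispr_plant_spec("ACGT", 30, 0), "23-55")
})

test_that("prophage integration is a clean splice with recorded junctions", {
  host <- strrep("ACGTTGCA", 1250) # 10 kb
  phage <- strrep("TTGGCCAA", 250) # 2 kb
  ig <- integrate_prophage(host, phage, 5000)
  expect_equal(nchar(ig$seq), 12000L)
  expect_identical(substr(ig$seq, 1, 5000), substr(host, 1, 5000))
  expect_identical(substr(ig$seq, 7001, 12000), substr(host, 5001, 10000))
  expect_identical(substr(ig$seq, 5001, 7000), phage)
  expect_equal(ig$left_junction, 5000L)
  expect_equal(ig$right_junction, 7000L)

  expect_identical(integrate_prophage(host, phage, 0)$seq, paste0(phage, host))
  expect_identical(integrate_prophage(host, phage, nchar(host))$seq,
                   paste0(host, phage))
  expect_error(integrate_prophage(host, phage, nchar(host) + 1), "outside")
  expect_error(integrate_prophage(host, phage, -1), "outside")
})
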