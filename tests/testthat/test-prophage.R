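# junction locus used throughout: prophage at [50000, 70000) on the
# integrated reference
jc <- junction_config("hc", 50000, 70000, min_anchor = 500, tol = 20)

seg <- function(read_id, tstart, tend, target = "hc") {
  data.frame(read_id = read_id, target = target, tstart = tstart, tend = tend)
}

test_that("junction reads are classified into the three molecule states", {
  aln <- rbind(
    seg("int_left", 48000, 52000),            # host flank across prophage start
    seg("int_right", 68000, 72000),           # prophage across right junction
    seg("abs", 48000, 50000), seg("abs", 70000, 72000), # deletion junction
    seg("circ", 68000, 70000), seg("circ", 50000, 52000), # phage end -> start
    seg("inside", 55000, 60000),              # entirely inside the prophage
    seg("short_anchor", 49900, 52000),        # only 100 bases on the host side
    seg("elsewhere", 10000, 18000))
  labels <- classify_junction_reads(aln, jc)
  lab <- setNames(labels$label, labels$read_id)
  expect_identical(lab[["int_left"]], "integrated")
  expect_identical(lab[["int_right"]], "integrated")
  expect_identical(lab[["abs"]], "absent")
  expect_identical(lab[["circ"]], "circular")
  expect_identical(lab[["inside"]], "uninformative")
  expect_identical(lab[["short_anchor"]], "uninformative")
  expect_identical(lab[["elsewhere"]], "uninformative")

  # partition: one label per read, counts conserve input
  expect_equal(nrow(labels), length(unique(aln$read_id)))

  # chimera supporting two states is uninformative with a warning
  chim <- rbind(seg("x", 48000, 52000), seg("x", 68000, 70000),
                seg("x", 50000, 52000))
  expect_warning(lc <- classify_junction_reads(chim, jc), "several states")
  expect_identical(lc$label, "uninformative")

  empty <- classify_junction_reads(seg("a", 1, 2)[0, ], jc)
  expect_equal(nrow(empty), 0L)
})

test_that("raising min_anchor never increases the informative count", {
  set.seed(21)
  alns <- do.call(rbind, lapply(1:200, function(i) {
    s <- sample(40000:78000, 1)
    seg(paste0("r", i), s, s + sample(1000:8000, 1))
  }))
  prev <- Inf
  for (a in c(100, 500, 1000, 2000)) {
    cfg <- junction_config("hc", 50000, 70000, min_anchor = a)
    lab <- classify_junction_reads(alns, cfg)
    n_inf <- sum(lab$label != "uninformative")
    expect_lte(n_inf, prev)
    prev <- n_inf
  }
})

test_that("variant fractions reproduce the 22/71/7 split with Wilson CIs", {
  labels <- data.frame(
    read_id = sprintf("r%03d", 1:700),
    label = rep(c("integrated", "absent", "circular", "uninformative"),
                c(148, 476, 47, 29)))
  fr <- variant_fractions(labels)
  expect_equal(fr$n_informative, 671L)
  expect_equal(unname(fr$fractions),
               c(148 / 671, 476 / 671, 47 / 671), tolerance = 1e-12)
  expect_equal(round(unname(fr$fractions), 3), c(0.221, 0.709, 0.070))
  expect_equal(sum(fr$fractions), 1)
  # Wilson interval brackets the point estimate and stays inside [0, 1]
  expect_true(all(fr$ci[, "lower"] <= fr$fractions &
                    fr$fractions <= fr$ci[, "upper"]))
  expect_true(all(fr$ci >= 0 & fr$ci <= 1))

  trivial <- variant_fractions(data.frame(read_id = 1:10, label = "absent"))
  expect_equal(unname(trivial$fractions), c(0, 1, 0))

  expect_error(variant_fractions(data.frame(read_id = 1, label = "uninformative")),
               "no junction-informative")
})

test_that("confidence intervals cover simulated mixtures near the nominal rate", {
  p <- c(integrated = 0.22, absent = 0.71, circular = 0.07)
  n <- 150
  covered <- matrix(FALSE, 100, 3, dimnames = list(NULL, names(p)))
  set.seed(31)
  for (i in 1:100) {
    draws <- sample(names(p), n, replace = TRUE, prob = p)
    fr <- variant_fractions(data.frame(read_id = seq_len(n), label = draws))
    for (s in names(p)) {
      covered[i, s] <- p[[s]] >= fr$ci[s, "lower"] & p[[s]] <= fr$ci[s, "upper"]
    }
  }
  expect_gte(mean(covered), 0.92)
})

test_that("activity call thresholds distinguish phage states", {
  mk_counts <- function(int, abs, circ) {
    variant_fractions(data.frame(
      read_id = seq_len(int + abs + circ),
      label = rep(c("integrated", "absent", "circular"), c(int, abs, circ))))
  }
  expect_identical(activity_call(mk_counts(22, 71, 7))$state, "active_mixed")
  expect_identical(activity_call(mk_counts(30, 70, 0))$state, "lysogenic_only")
  expect_identical(activity_call(mk_counts(0, 50, 50))$state, "lytic_only")
  expect_identical(activity_call(mk_counts(1, 98, 1),
                                 min_lytic_fraction = 0.05,
                                 min_lysogenic_fraction = 0.05)$state,
                   "undetermined")
  act <- activity_call(mk_counts(22, 71, 7))
  expect_match(act$rationale, "informative reads")
})

test_that("end-to-end: simulated mixture is recovered through alignment classification", {
  host <- rand_seq(120000, 0.45, seed = 41)
  phage <- rand_seq(20000, 0.45, seed = 42)
  ig <- integrate_prophage(host, phage, 60000)
  comm <- list(community_replicon("hc", ig$seq, circular = TRUE))
  mix <- prophage_mixture_spec(0.22, 0.71, 0.07, insertion_site = 60000)
  rr <- simulate_reads(comm, read_sim_spec(coverage = 250, mean_length = 5000,
                                           sd_length = 2500, min_length = 1500),
                       mixture = mix,
                       prophage = list(replicon = "hc", start = 60000,
                                       end = 80000, phage_id = "ph"),
                       seed = 43)
  bundle <- truth_bundle(comm, sim_reads = rr,
                         prophage = list(replicon = "hc", start = 60000,
                                         end = 80000, phage_id = "ph",
                                         mixture = c(integrated = 0.22,
                                                     absent = 0.71,
                                                     circular = 0.07)))
  aln <- alignments_from_truth(bundle)
  cfg <- junction_config("hc", 60000, 80000, min_anchor = 500)
  labels <- classify_junction_reads(aln, cfg)
  # classification agrees with per-read truth state on informative reads
  st <- setNames(rr$reads$state, rr$reads$read_id)
  inf <- labels[labels$label != "uninformative", ]
  expect_gte(nrow(inf), 300L)
  expect_true(all(inf$label == st[inf$read_id]))
  fr <- variant_fractions(labels)
  for (s in c("integrated", "absent", "circular")) {
    expect_gte(c(integrated = 0.22, absent = 0.71, circular = 0.07)[[s]],
               fr$ci[s, "lower"] - 0.03)
    expect_lte(c(integrated = 0.22, absent = 0.71, circular = 0.07)[[s]],
               fr$ci[s, "upper"] + 0.03)
  }
  expect_identical(activity_call(fr)$state, "active_mixed")
})
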