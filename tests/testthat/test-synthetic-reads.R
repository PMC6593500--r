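test_that("simulated reads hit target coverage and are exact substrings without errors", {
  comm <- tiny_community(seed = 1)
  sim <- read_sim_spec(coverage = c(chr = 30, pl = 40), mean_length = 8000,
                       sd_length = 6000, min_length = 500)
  rr <- simulate_reads(comm, sim, seed = 7)
  bases <- tapply(rr$reads$length, rr$reads$replicon, sum)
  expect_lte(abs(bases[["chr"]] / 60000 - 30) / 30, 0.10)
  expect_lte(abs(bases[["pl"]] / 9000 - 40) / 40, 0.10)

  # error-free reads are exact (possibly wrapped, possibly reverse-complemented)
  # substrings of their source
  seqs <- setNames(vapply(comm, `[[`, character(1), "seq"),
                   vapply(comm, `[[`, character(1), "id"))
  n_wrapped <- 0L
  for (i in seq_len(nrow(rr$reads))) {
    r <- rr$reads[i, ]
    src <- seqs[[r$replicon]]
    L <- nchar(src)
    if (r$start + r$length > L) n_wrapped <- n_wrapped + 1L
    ext <- if (r$start + r$length <= L) {
      substr(src, r$start + 1, r$start + r$length)
    } else {
      paste0(substr(src, r$start + 1, L),
             substr(strrep(src, 2), 1, r$start + r$length - L))
    }
    obs <- rr$sequences[[r$read_id]]
    if (r$strand == "-") obs <- revcomp(obs)
    expect_identical(obs, ext)
  }
  expect_gt(n_wrapped, 0L) # circular replicons must produce wrap-around reads

  # determinism: same community + spec + seed, byte-identical output
  expect_identical(rr, simulate_reads(comm, sim, seed = 7))
})

test_that("error rates mutate reads at roughly the configured rates", {
  comm <- tiny_community(seed = 2)[1]
  sim <- read_sim_spec(coverage = 10, mean_length = 5000, sd_length = 2000,
                       min_length = 1000, sub_rate = 0.02, ins_rate = 0.01,
                       del_rate = 0.01)
  rr <- simulate_reads(comm, sim, seed = 3)
  # indel balance: observed length vs truth interval length
  dlen <- nchar(rr$sequences[rr$reads$read_id]) - rr$reads$length
  expect_lt(abs(mean(dlen / rr$reads$length)), 0.005)
  # substitutions: compare one long read against its source interval
  r <- rr$reads[which.max(rr$reads$length), ]
  ext <- substr(comm[[1]]$seq, r$start + 1, r$start + r$length)
  obs <- rr$sequences[[r$read_id]]
  if (r$strand == "-") obs <- revcomp(obs)
  n <- min(nchar(obs), nchar(ext))
  frac_diff <- mean(charToRaw(substr(obs, 1, n)) != charToRaw(substr(ext, 1, n)))
  expect_gt(frac_diff, 0.005) # errors present
})

test_that("prophage-state labels follow the configured mixture", {
  host <- rand_seq(150000, 0.45, seed = 5)
  phage <- rand_seq(20000, 0.45, seed = 6)
  ig <- integrate_prophage(host, phage, 70000)
  comm <- list(community_replicon("hc", ig$seq, circular = TRUE))
  sim <- read_sim_spec(coverage = 400, mean_length = 5000, sd_length = 2500,
                       min_length = 1500)
  mix <- prophage_mixture_spec(0.22, 0.71, 0.07, insertion_site = 70000)
  rr <- simulate_reads(comm, sim, mixture = mix,
                       prophage = list(replicon = "hc", start = 70000,
                                       end = 90000, phage_id = "ph"),
                       seed = 8)
  st <- rr$reads$state
  labeled <- st[st != "na"]
  n <- length(labeled)
  expect_gte(n, 600L)
  truth <- c(integrated = 0.22, absent = 0.71, circular = 0.07)
  for (cls in names(truth)) {
    p_hat <- mean(labeled == cls)
    half <- 1.96 * sqrt(truth[[cls]] * (1 - truth[[cls]]) / n)
    expect_lte(abs(p_hat - truth[[cls]]), half + 1e-9)
  }
  # all-zero mixture is rejected
  expect_error(prophage_mixture_spec(0, 0, 0, 1), "sum to 1")
})

test_that("methylation truth sites all sit on motif occurrences; plasmids inherit host motifs", {
  comm <- list(community_replicon("hostA", rand_seq(40000, 0.4, seed = 11)),
               community_replicon("p1", rand_seq(8000, 0.4, seed = 12),
                                  kind = "plasmid"))
  truth <- assign_methylation_truth(comm,
                                    motif_sets = list(hostA = c("GATC", "CCWGG")),
                                    plasmid_hosts = c(p1 = "hostA"),
                                    methylated_fraction = 1, seed = 13)
  expect_setequal(unique(truth$replicon), c("hostA", "p1"))
  expect_setequal(unique(truth$motif[truth$replicon == "p1"]),
                  c("GATC", "CCWGG"))
  # every site is the first base of a motif occurrence on its strand
  seqs <- list(hostA = comm[[1]]$seq, p1 = comm[[2]]$seq)
  for (i in seq_len(nrow(truth))) {
    s <- seqs[[truth$replicon[i]]]
    k <- nchar(truth$motif[i])
    ctx <- if (truth$strand[i] == "+") {
      substr(paste0(s, substr(s, 1, k)), truth$position[i] + 1,
             truth$position[i] + k)
    } else {
      start <- truth$position[i] - k + 1
      piece <- if (start >= 0) substr(s, start + 1, truth$position[i] + 1) else
        paste0(substr(s, nchar(s) + start + 1, nchar(s)),
               substr(s, 1, truth$position[i] + 1))
      revcomp(piece)
    }
    expect_true(grepl(paste0("^(?:", gsub("W", "[AT]", truth$motif[i]), ")$"),
                      ctx, perl = TRUE),
                info = paste("row", i, ctx, truth$motif[i]))
  }
  expect_error(assign_methylation_truth(comm, list(hostA = "GATC"),
                                        plasmid_hosts = c(p1 = "nope")),
               "unknown host")
})

test_that("truth bundle round trips exactly and writes deterministically", {
  comm <- tiny_community(seed = 20)
  sim <- read_sim_spec(coverage = 8, mean_length = 4000, sd_length = 2000,
                       min_length = 500, sub_rate = 0.002)
  rr <- simulate_reads(comm, sim, seed = 21)
  meth <- assign_methylation_truth(comm, list(chr = "GATC"),
                                   plasmid_hosts = c(pl = "chr"), seed = 22)
  calls <- simulate_site_calls(meth, comm, coverage = 30, n_noise = 5, seed = 23)
  bundle <- truth_bundle(comm, sim_reads = rr, plasmid_hosts = c(pl = "chr"),
                         methylation = meth, motif_sets = list(chr = "GATC"),
                         site_calls = calls)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_truth_bundle(bundle, file.path(d1, "t"))
  back <- read_truth_bundle(file.path(d1, "t"))
  expect_identical(back$sim_reads$reads, bundle$sim_reads$reads)
  expect_identical(back$sim_reads$sequences[bundle$sim_reads$reads$read_id],
                   bundle$sim_reads$sequences[bundle$sim_reads$reads$read_id])
  expect_identical(back$methylation, bundle$methylation)
  expect_identical(back$site_calls, bundle$site_calls)
  expect_identical(lapply(back$community, `[[`, "seq"),
                   lapply(bundle$community, `[[`, "seq"))
  expect_identical(back$plasmid_hosts, bundle$plasmid_hosts)

  write_truth_bundle(bundle, file.path(d2, "t"))
  f1 <- sort(list.files(file.path(d1, "t"), full.names = TRUE))
  f2 <- sort(list.files(file.path(d2, "t"), full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # truth referencing an unknown replicon is rejected
  expect_error(truth_bundle(comm, plasmid_hosts = c(ghost = "chr")),
               "unknown replicon")
})
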