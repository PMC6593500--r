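#' Default pipeline configuration
#'
#' One block per stage. Analysis defaults follow the conventions of
#' long-read, low-complexity metagenome studies: a strict 5 kb read-length
#' cutoff with the worst 10% of reads by mean Phred quality dropped, a <= 2
#' mismatch budget for calling a protospacer hit (with a weak-match rescan
#' up to 6), BH alpha 0.05 and a score cutoff of 50 for methylation calls
#' with a 250-fold per-strand coverage confidence threshold, and a 500 bp
#' junction anchor for prophage read classification. The `simulate` block
#' defines the benchmark community (see [simulate_community()]); replicon
#' sizes are scaled to desk size while preserving the structure the analyses
#' rely on.
#'
#' @return Nested named list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    simulate = list(
      strain_length = 1000000L, strain_gc = 0.37, shared_fraction = 0.94,
      snv_rate = 2e-4, n_rearrangements = 1L, n_unique_blocks = 2L,
      coverage_a = 30, coverage_b = 60,
      host_length = 250000L, host_gc = 0.50, host_coverage = 80,
      plasmid_lengths = c(plasmid_a = 15000L, plasmid_b = 20000L),
      plasmid_coverages = c(plasmid_a = 120, plasmid_b = 100),
      plasmid_hosts = c(plasmid_a = "strain_a", plasmid_b = "strain_b"),
      phage_length = 40000L, phage_gc = 0.44, phage_coverage = 50,
      spacer_length = 30L, mismatch_schedule = c(0L, 0L, 1L, 1L, 2L, 2L),
      prophage_length = 35000L,
      prophage_mixture = c(integrated = 0.22, absent = 0.71, circular = 0.07),
      motif_sets = list(strain_a = c("GATC", "CCWGG"),
                        strain_b = c("GATC", "GCGC"),
                        host_c = c("CTGCAG")),
      read = list(mean_length = 8000, sd_length = 6000, min_length = 500,
                  sub_rate = 0.002, ins_rate = 0.001, del_rate = 0.001,
                  quality_mean = 12, quality_sd = 3)),
    filter = list(min_length = 5000, drop_worst_fraction = 0.10,
                  longest_repeat = 10000, anchor = 1000),
    binning = list(k = 4L, tie_margin = 0.05, window = 10000L),
    strains = list(ambiguity_margin = 0.2, max_contig = 30000L),
    crispr = list(max_mismatches = 2L, weak_max_mismatches = 6L),
    methylation = list(alpha = 0.05, score_cutoff = 50,
                       min_strand_coverage = 250, min_sites = 3L,
                       min_fraction = 0.5, k_range = c(4L, 5L, 6L)),
    prophage = list(min_anchor = 500L, tol = 20L,
                    min_lytic_fraction = 0.02, min_lysogenic_fraction = 0.05))
}

# recursive merge of a user config over defaults; unknown keys are an error
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], defaults[[k]], paste0(path, ".", k))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (pure defaults), a nested list of overrides, or a
#'   path to a YAML file of overrides.
#' @return The merged configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(config)
}

stage_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full simulate-analyze-compare workflow
#'
#' Stages run in dependency order: simulate, read filtering, binning
#' diagnostics, strain deconvolution, CRISPR linking, methylation linking,
#' prophage state classification, truth comparison. All outputs are written
#' as plain-text tables under `outdir` together with a JSON run report
#' containing a checksummed file manifest. Identical config + seed give
#' byte-identical outputs.
#'
#' @param config See [load_config()].
#' @param seed Integer master seed.
#' @param outdir Output directory.
#' @return Invisibly, a list with all stage results (`bundle`, `read_prep`,
#'   `binning`, `strains`, `crispr`, `methylation`, `prophage`, `metrics`,
#'   `report`).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, outdir = tempfile("magweave_run_")) {
  cfg <- load_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    written <<- c(written, path)
  }

  stage_msg("simulate", "building synthetic community (seed ", seed, ")")
  bundle <- simulate_community(cfg$simulate, seed = seed)
  written <- c(written, write_truth_bundle(bundle, file.path(outdir, "truth")))

  stage_msg("read_prep", "filtering reads")
  stats <- data.frame(read_id = bundle$sim_reads$reads$read_id,
                      length = nchar(bundle$sim_reads$sequences[
                        bundle$sim_reads$reads$read_id]),
                      mean_quality = bundle$sim_reads$reads$mean_quality)
  filtered <- filter_reads(stats, cfg$filter$min_length,
                           cfg$filter$drop_worst_fraction)
  curve <- cumulative_output_curve(stats)
  spanning <- repeat_spanning_check(filtered, cfg$filter$longest_repeat,
                                    cfg$filter$anchor)
  stage_msg("read_prep", nrow(filtered), "/", nrow(stats), " reads retained; ",
            "repeat-spanning reads: ", spanning$spanning_capable_count)
  emit(filtered, "reads_filtered.tsv")
  emit(curve, "cumulative_curve.tsv")
  read_prep <- list(stats = stats, filtered = filtered, curve = curve,
                    spanning = spanning)

  aln <- alignments_from_truth(bundle, read_ids = filtered$read_id)

  stage_msg("binning", "composition features and best-hit bins")
  chroms <- names(bundle$community)[vapply(bundle$community, `[[`, character(1),
                                           "kind") == "chromosome"]
  windows <- do.call(rbind, lapply(names(bundle$community), function(rid) {
    seq <- bundle$community[[rid]]$seq
    starts <- seq.int(0L, max(nchar(seq) - cfg$binning$window, 0L),
                      by = cfg$binning$window)
    do.call(rbind, lapply(starts, function(s) {
      w <- substr(seq, s + 1L, min(s + cfg$binning$window, nchar(seq)))
      feat <- composition_features(w, cfg$binning$k)
      data.frame(replicon = rid, start = s, gc = feat$gc,
                 t(feat$kmer_vector))
    }))
  }))
  kmat <- as.matrix(windows[, -(1:3)])
  emb <- pca_embed(kmat, 2L)
  blob <- data.frame(windows[, 1:3], PC1 = emb$coordinates[, 1],
                     PC2 = emb$coordinates[, 2])
  mol2bin <- function(m) {
    m <- sub("_delta$", "", m)
    if (!is.null(bundle$prophage) &&
        any(m == paste0(bundle$prophage$phage_id, "_circ"))) {
      m[m == paste0(bundle$prophage$phage_id, "_circ")] <- bundle$prophage$replicon
    }
    m
  }
  read_truth_bin <- setNames(
    vapply(bundle$sim_reads$reads$replicon, function(m) mol2bin(m), character(1)),
    bundle$sim_reads$reads$read_id)
  bins <- assign_bins_and_evaluate(aln, items = filtered$read_id,
                                   truth = read_truth_bin,
                                   tie_margin = cfg$binning$tie_margin)
  emit(blob, "binning_windows.tsv")
  emit(bins$labels, "binning_labels.tsv")
  emit(bins$evaluation, "binning_evaluation.tsv")
  binning <- list(windows = blob, pca = emb, labels = bins$labels,
                  evaluation = bins$evaluation)

  stage_msg("strains", "coverage mixture deconvolution")
  contigs <- strain_contigs_from_truth(bundle, cfg$strains$max_contig)
  cov <- strain_contig_coverage(bundle, contigs, read_ids = filtered$read_id)
  fit <- assign_strain_contigs(cov, cfg$strains$ambiguity_margin,
                               lengths = setNames(contigs$length, contigs$contig))
  abundance <- strain_abundance(fit$model)
  strain_out <- merge(contigs, fit$assignment, by = "contig")
  strain_out$coverage <- cov[strain_out$contig]
  emit(strain_out[, c("contig", "length", "coverage", "truth", "label",
                      "w_A", "w_B", "w_shared")], "strain_assignment.tsv")
  stage_msg("strains", sprintf("mu_A=%.1f mu_B=%.1f; abundance A=%.1f%% B=%.1f%%",
                               fit$model$mu_A, fit$model$mu_B,
                               100 * abundance[["A"]], 100 * abundance[["B"]]))
  strains <- list(contigs = contigs, coverage = cov, fit = fit,
                  abundance = abundance)

  stage_msg("crispr", "array detection and protospacer matching")
  arrays <- lapply(setNames(chroms, chroms), function(rid)
    detect_crispr_arrays(bundle$community[[rid]]$seq))
  spacers <- character(0); spacer_hosts <- character(0)
  for (rid in chroms) {
    for (a in seq_along(arrays[[rid]])) {
      sp <- arrays[[rid]][[a]]$spacers
      nm <- sprintf("%s.arr%d.sp%d", rid, a, seq_len(nrow(sp)))
      spacers <- c(spacers, setNames(sp$sequence, nm))
      spacer_hosts <- c(spacer_hosts, setNames(rep(rid, nrow(sp)), nm))
    }
  }
  phage_ids <- names(bundle$community)[vapply(bundle$community, `[[`,
                                              character(1), "kind") == "phage"]
  phage_seqs <- vapply(bundle$community[phage_ids], `[[`, character(1), "seq")
  phage_circ <- vapply(bundle$community[phage_ids], `[[`, logical(1), "circular")
  matches <- if (length(spacers)) {
    match_protospacers(spacers, phage_seqs, cfg$crispr$max_mismatches,
                       circular = phage_circ)
  } else {
    match_protospacers(c(dummy = "A"), phage_seqs, -1L)[0, ]
  }
  weak <- if (length(spacers)) {
    match_protospacers(spacers, phage_seqs, cfg$crispr$weak_max_mismatches,
                       circular = phage_circ)
  } else matches
  report <- interaction_report(weak, spacer_hosts,
                               all_pairs = expand.grid(host = chroms,
                                                       phage = phage_ids,
                                                       stringsAsFactors = FALSE))
  emit(matches, "crispr_matches.tsv")
  emit(report, "crispr_report.tsv")
  stage_msg("crispr", length(spacers), " spacers detected, ",
            nrow(matches), " matches at <= ", cfg$crispr$max_mismatches,
            " mismatches")
  crispr <- list(arrays = arrays, spacers = spacers,
                 spacer_hosts = spacer_hosts, matches = matches,
                 weak_matches = weak, report = report)

  stage_msg("methylation", "motif discovery, profiling, host assignment")
  calls <- bundle$site_calls
  mcfg <- cfg$methylation
  prof_ids <- names(bundle$community)[vapply(bundle$community, `[[`,
                                             character(1), "kind") != "phage"]
  discovered <- lapply(setNames(prof_ids, prof_ids), function(rid) {
    discover_motifs(bundle$community[[rid]]$seq,
                    calls[calls$replicon == rid, , drop = FALSE],
                    k_range = mcfg$k_range, alpha = mcfg$alpha,
                    circular = bundle$community[[rid]]$circular,
                    score_cutoff = mcfg$score_cutoff)
  })
  candidate_motifs <- sort(unique(unlist(lapply(discovered, canonical_motifs))))
  profiles <- lapply(setNames(prof_ids, prof_ids), function(rid) {
    motif_profile(bundle$community[[rid]]$seq,
                  calls[calls$replicon == rid, , drop = FALSE],
                  candidate_motifs,
                  circular = bundle$community[[rid]]$circular,
                  min_strand_coverage = mcfg$min_strand_coverage,
                  score_cutoff = mcfg$score_cutoff)
  })
  det <- lapply(profiles, detected_motifs, min_sites = mcfg$min_sites,
                min_fraction = mcfg$min_fraction)
  plasmid_ids <- names(bundle$community)[vapply(bundle$community, `[[`,
                                                character(1), "kind") == "plasmid"]
  assignment <- assign_plasmid_hosts(det[plasmid_ids], det[chroms])
  prof_tab <- do.call(rbind, lapply(prof_ids, function(rid)
    data.frame(replicon = rid, profiles[[rid]])))
  emit(prof_tab, "methylation_profiles.tsv")
  emit(assignment, "plasmid_host_assignment.tsv")
  stage_msg("methylation", "candidate motifs: ",
            paste(candidate_motifs, collapse = ","))
  methylation <- list(discovered = discovered, profiles = profiles,
                      detected = det, assignment = assignment)

  stage_msg("prophage", "junction read classification")
  pp <- bundle$prophage
  jcfg <- junction_config(pp$replicon, pp$start, pp$end,
                          min_anchor = cfg$prophage$min_anchor,
                          tol = cfg$prophage$tol)
  labels <- classify_junction_reads(
    aln[aln$target == pp$replicon, , drop = FALSE], jcfg)
  fractions <- variant_fractions(labels)
  activity <- activity_call(fractions, cfg$prophage$min_lytic_fraction,
                            cfg$prophage$min_lysogenic_fraction)
  emit(labels, "prophage_read_labels.tsv")
  stage_msg("prophage", activity$rationale, " -> ", activity$state)
  prophage <- list(labels = labels, fractions = fractions, activity = activity)

  outputs <- list(read_prep = read_prep, binning = binning, strains = strains,
                  crispr = crispr, methylation = methylation,
                  prophage = prophage)
  metrics <- compare_to_truth(outputs, bundle)
  emit(metrics, "metrics.tsv")

  report_obj <- list(
    seed = seed,
    stages = c("simulate", "read_prep", "binning", "strains", "crispr",
               "methylation", "prophage", "compare"),
    status = "complete",
    activity_state = activity$state,
    manifest = data.frame(file = basename(written),
                          md5 = unname(tools::md5sum(written))))
  report_path <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report_obj, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(list(bundle = bundle, metrics = metrics,
                   report = report_obj, outdir = outdir), outputs))
}

#' Compare stage outputs against the simulation ground truth
#'
#' @param outputs List of stage results as assembled by [run_pipeline()];
#'   stages may be missing, in which case their metrics are omitted (absent,
#'   not zero).
#' @param bundle The [truth_bundle()] the outputs were computed from.
#' @param position_tol Tolerance in bases when matching protospacer
#'   positions against planted truth.
#' @return data.frame with columns `metric` and `value`.
#' @export
compare_to_truth <- function(outputs, bundle, position_tol = 3L) {
  rows <- list()
  add <- function(metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = as.numeric(value))
  }

  if (!is.null(outputs$strains) && !is.null(bundle$strains)) {
    st <- outputs$strains
    orphans <- setdiff(st$fit$assignment$contig, st$contigs$contig)
    if (length(orphans)) {
      stop("assignment contains contigs absent from truth: ",
           paste(orphans, collapse = ", "))
    }
    truth <- setNames(st$contigs$truth, st$contigs$contig)
    acc <- mean(st$fit$assignment$label == truth[st$fit$assignment$contig])
    add("strain_assignment_accuracy", acc)
    ratio <- bundle$strains$coverage_ratio
    add("strain_abundance_b_pct", 100 * st$abundance[["B"]])
    add("strain_abundance_b_truth_pct", 100 * ratio / (1 + ratio))
    add("strain_abundance_abs_error_pct",
        abs(100 * st$abundance[["B"]] - 100 * ratio / (1 + ratio)))
    if (!st$fit$model$single_strain) {
      add("strain_mu_a", st$fit$model$mu_A)
      add("strain_mu_b", st$fit$model$mu_B)
    }
  }

  if (!is.null(outputs$crispr) && !is.null(bundle$crispr)) {
    truth_ps <- bundle$crispr$protospacers
    matches <- outputs$crispr$matches
    ph <- bundle$crispr$phage
    m_ph <- matches[matches$phage_id == ph, , drop = FALSE]
    recoverable <- truth_ps[truth_ps$mismatches <= 2L, , drop = FALSE]
    hit <- vapply(seq_len(nrow(recoverable)), function(i)
      any(abs(m_ph$position - recoverable$start[i]) <= position_tol),
      logical(1))
    add("spacer_matches_recovered", sum(hit))
    add("spacer_matches_plantable", nrow(recoverable))
    false_hit <- vapply(seq_len(nrow(m_ph)), function(i)
      !any(abs(m_ph$position[i] - truth_ps$start) <= position_tol),
      logical(1))
    add("spacer_false_matches", if (nrow(m_ph)) sum(false_hit) else 0)
    n_arrays <- sum(vapply(outputs$crispr$arrays, length, integer(1)))
    add("crispr_arrays_detected", n_arrays)
  }

  if (!is.null(outputs$methylation) && length(bundle$plasmid_hosts)) {
    asg <- outputs$methylation$assignment
    correct <- vapply(names(bundle$plasmid_hosts), function(pl) {
      row <- asg[asg$plasmid == pl, , drop = FALSE]
      nrow(row) == 1L && row$hosts == bundle$plasmid_hosts[[pl]] &&
        row$basis == "unique_motif"
    }, logical(1))
    add("plasmid_hosts_correct", sum(correct))
    add("plasmid_hosts_total", length(correct))
  }

  if (!is.null(outputs$prophage) && !is.null(bundle$prophage)) {
    fr <- outputs$prophage$fractions
    truth_mix <- bundle$prophage$mixture
    for (s in c("integrated", "absent", "circular")) {
      add(paste0("prophage_", s, "_pct"), 100 * fr$fractions[[s]])
      add(paste0("prophage_", s, "_abs_error_pct"),
          100 * abs(fr$fractions[[s]] - truth_mix[[s]]))
      add(paste0("prophage_", s, "_ci_covers_truth"),
          as.numeric(truth_mix[[s]] >= fr$ci[s, "lower"] &
                       truth_mix[[s]] <= fr$ci[s, "upper"]))
    }
    add("prophage_informative_reads", fr$n_informative)
  }

  if (!is.null(outputs$binning) && !is.null(outputs$binning$evaluation)) {
    ev <- outputs$binning$evaluation
    add("binning_min_purity", min(ev$purity, na.rm = TRUE))
    add("binning_ambiguous_fraction",
        mean(outputs$binning$labels$bin == "ambiguous"))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
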