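#' Bundle a simulated community with its complete ground truth
#'
#' Collects the replicon sequences, simulated reads and all planted truth
#' (strain segments and SNVs, spacer/protospacer pairs, plasmid-host map,
#' prophage locus and mixture, methylation sites) into one validated object
#' that can be written to plain-text files and re-read without loss.
#'
#' @param community List of [community_replicon()] objects.
#' @param sim_reads Output of [simulate_reads()], or `NULL`.
#' @param strains `NULL`, or a list with `strain_a`, `strain_b` (replicon
#'   ids), `segments`, `snv` (from [derive_sibling_strain()]) and
#'   `coverage_ratio`.
#' @param crispr `NULL`, or a list with `host`, `phage` (replicon ids),
#'   `array` and `protospacers` (from [plant_crispr_and_protospacers()]).
#' @param plasmid_hosts Named character vector plasmid id -> host id.
#' @param prophage `NULL`, or a list with `replicon`, `start`, `end`,
#'   `phage_id` and `mixture` (named numeric: integrated, absent, circular).
#' @param methylation `NULL`, or output of [assign_methylation_truth()].
#' @param motif_sets Named list host id -> IUPAC motif vector.
#' @param site_calls `NULL`, or output of [simulate_site_calls()].
#' @return An object of class `truth_bundle`.
#' @export
truth_bundle <- function(community, sim_reads = NULL, strains = NULL,
                         crispr = NULL, plasmid_hosts = NULL, prophage = NULL,
                         methylation = NULL, motif_sets = NULL,
                         site_calls = NULL) {
  ids <- vapply(community, `[[`, character(1), "id")
  names(community) <- ids
  check_id <- function(id, what) {
    if (!id %in% ids) stop(what, " refers to unknown replicon '", id, "'")
  }
  if (!is.null(strains)) {
    check_id(strains$strain_a, "strain truth"); check_id(strains$strain_b, "strain truth")
  }
  if (!is.null(crispr)) {
    check_id(crispr$host, "CRISPR truth"); check_id(crispr$phage, "CRISPR truth")
  }
  for (pl in names(plasmid_hosts)) {
    check_id(pl, "plasmid map"); check_id(plasmid_hosts[[pl]], "plasmid map")
  }
  if (!is.null(prophage)) check_id(prophage$replicon, "prophage truth")
  if (!is.null(methylation) && nrow(methylation)) {
    orphan <- setdiff(unique(methylation$replicon), ids)
    if (length(orphan)) stop("methylation truth refers to unknown replicon(s): ",
                             paste(orphan, collapse = ", "))
  }
  if (!is.null(sim_reads)) {
    stopifnot(identical(sort(names(sim_reads$sequences)),
                        sort(sim_reads$reads$read_id)))
  }
  structure(list(community = community, sim_reads = sim_reads,
                 strains = strains, crispr = crispr,
                 plasmid_hosts = plasmid_hosts, prophage = prophage,
                 methylation = methylation, motif_sets = motif_sets,
                 site_calls = site_calls),
            class = "truth_bundle")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, colClasses = NA) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = colClasses, comment.char = "")
}

#' Write reads to a FASTQ file
#'
#' Plain four-line Sanger-scaled FASTQ records (one line per sequence, no
#' wrapping), robust to arbitrarily long reads.
#'
#' @param ids,sequences,qualities Parallel character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(ids, sequences, qualities, path) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(qualities),
            all(nchar(sequences) == nchar(qualities)))
  con <- file(path, "wb") # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), unname(sequences),
                             "+", unname(qualities))),
             con, sep = "\n")
  invisible(path)
}

#' Write a truth bundle to a directory of plain-text files
#'
#' Emits `replicons.fasta`, `reads.fastq`, and TSV truth tables
#' (`truth_replicons.tsv`, `truth_reads.tsv`, `truth_strains.tsv`,
#' `truth_snv.tsv`, `truth_spacers.tsv`, `truth_plasmids.tsv`,
#' `truth_prophage.tsv`, `truth_methylation.tsv`, `truth_motif_sets.tsv`,
#' `site_calls.tsv`). Output is byte-identical for identical bundles.
#'
#' @param bundle A [truth_bundle()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a character vector of the files written.
#' @export
write_truth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "truth_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    write_tsv(df, path)
    written <<- c(written, path)
  }

  seqs <- Biostrings::DNAStringSet(unname(vapply(bundle$community, `[[`,
                                                 character(1), "seq")))
  names(seqs) <- names(bundle$community)
  fa <- file.path(dir, "replicons.fasta")
  suppressWarnings(Biostrings::writeXStringSet(seqs, fa, width = 80L))
  written <- c(written, fa)
  emit(data.frame(id = names(bundle$community),
                  kind = vapply(bundle$community, `[[`, character(1), "kind"),
                  circular = vapply(bundle$community, `[[`, logical(1), "circular"),
                  length = vapply(bundle$community, function(r) nchar(r$seq), integer(1))),
       "truth_replicons.tsv")

  if (!is.null(bundle$sim_reads)) {
    sr <- bundle$sim_reads
    fq <- file.path(dir, "reads.fastq")
    write_fastq(sr$reads$read_id, sr$sequences[sr$reads$read_id],
                sr$qualities[sr$reads$read_id], fq)
    written <- c(written, fq)
    emit(sr$reads, "truth_reads.tsv")
  }
  if (!is.null(bundle$strains)) {
    seg <- bundle$strains$segments
    seg$strain_a <- bundle$strains$strain_a
    seg$strain_b <- bundle$strains$strain_b
    seg$coverage_ratio <- bundle$strains$coverage_ratio
    emit(seg, "truth_strains.tsv")
    emit(bundle$strains$snv, "truth_snv.tsv")
  }
  if (!is.null(bundle$crispr)) {
    arr <- bundle$crispr$array
    sp <- arr$spacers
    proto <- bundle$crispr$protospacers
    tab <- data.frame(host = bundle$crispr$host, phage = bundle$crispr$phage,
                      array_start = arr$start, array_end = arr$end,
                      repeat_sequence = arr$repeat_sequence,
                      spacer_id = sp$spacer_id, spacer_sequence = sp$sequence,
                      spacer_start = sp$start, spacer_end = sp$end,
                      proto_start = proto$start[match(sp$spacer_id, proto$spacer_id)],
                      proto_end = proto$end[match(sp$spacer_id, proto$spacer_id)],
                      proto_strand = proto$strand[match(sp$spacer_id, proto$spacer_id)],
                      mismatches = proto$mismatches[match(sp$spacer_id, proto$spacer_id)])
    emit(tab, "truth_spacers.tsv")
  }
  if (length(bundle$plasmid_hosts)) {
    emit(data.frame(plasmid = names(bundle$plasmid_hosts),
                    host = unname(bundle$plasmid_hosts)),
         "truth_plasmids.tsv")
  }
  if (!is.null(bundle$prophage)) {
    pp <- bundle$prophage
    emit(data.frame(replicon = pp$replicon, start = pp$start, end = pp$end,
                    phage_id = pp$phage_id,
                    integrated = pp$mixture[["integrated"]],
                    absent = pp$mixture[["absent"]],
                    circular = pp$mixture[["circular"]]),
         "truth_prophage.tsv")
  }
  if (!is.null(bundle$methylation)) emit(bundle$methylation, "truth_methylation.tsv")
  if (!is.null(bundle$motif_sets)) {
    emit(data.frame(replicon = rep(names(bundle$motif_sets),
                                   lengths(bundle$motif_sets)),
                    motif = unlist(bundle$motif_sets, use.names = FALSE)),
         "truth_motif_sets.tsv")
  }
  if (!is.null(bundle$site_calls)) emit(bundle$site_calls, "site_calls.tsv")
  invisible(written)
}

#' Read a truth bundle back from a directory
#'
#' Inverse of [write_truth_bundle()].
#'
#' @param dir Directory written by [write_truth_bundle()].
#' @return A [truth_bundle()].
#' @export
read_truth_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("truth bundle directory not found: ", dir)
  rep_tab <- read_tsv(file.path(dir, "truth_replicons.tsv"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "replicons.fasta"))
  community <- lapply(seq_len(nrow(rep_tab)), function(i) {
    community_replicon(rep_tab$id[i], as.character(seqs[[rep_tab$id[i]]]),
                       circular = rep_tab$circular[i], kind = rep_tab$kind[i])
  })
  names(community) <- rep_tab$id

  sim_reads <- NULL
  if (file.exists(file.path(dir, "reads.fastq"))) {
    # the mcols carried by the FASTQ parser are irrelevant here
    qs <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(file.path(dir, "reads.fastq")))
    reads <- read_tsv(file.path(dir, "truth_reads.tsv"))
    sim_reads <- list(reads = reads,
                      sequences = setNames(as.character(qs), names(qs)),
                      qualities = setNames(as.character(Biostrings::quality(qs)),
                                           names(qs)),
                      molecules = NULL)
  }
  strains <- NULL
  if (file.exists(file.path(dir, "truth_strains.tsv"))) {
    seg <- read_tsv(file.path(dir, "truth_strains.tsv"))
    snv <- if (file.exists(file.path(dir, "truth_snv.tsv"))) {
      # ref/alt columns can be all-T and must not be parsed as logical
      read_tsv(file.path(dir, "truth_snv.tsv"),
               colClasses = c(base_pos = "integer", sib_pos = "integer",
                              ref = "character", alt = "character"))
    }
    strains <- list(strain_a = seg$strain_a[1], strain_b = seg$strain_b[1],
                    coverage_ratio = seg$coverage_ratio[1],
                    segments = seg[, c("piece", "type", "base_start", "base_end",
                                       "sib_start", "sib_end")],
                    snv = snv)
  }
  crispr <- NULL
  if (file.exists(file.path(dir, "truth_spacers.tsv"))) {
    tab <- read_tsv(file.path(dir, "truth_spacers.tsv"))
    crispr <- list(host = tab$host[1], phage = tab$phage[1],
                   array = list(start = tab$array_start[1], end = tab$array_end[1],
                                repeat_sequence = tab$repeat_sequence[1],
                                spacers = data.frame(spacer_id = tab$spacer_id,
                                                     sequence = tab$spacer_sequence,
                                                     start = tab$spacer_start,
                                                     end = tab$spacer_end)),
                   protospacers = data.frame(spacer_id = tab$spacer_id,
                                             start = tab$proto_start,
                                             end = tab$proto_end,
                                             strand = tab$proto_strand,
                                             mismatches = tab$mismatches,
                                             planted_sequence = NA_character_))
  }
  plasmid_hosts <- NULL
  if (file.exists(file.path(dir, "truth_plasmids.tsv"))) {
    tab <- read_tsv(file.path(dir, "truth_plasmids.tsv"))
    plasmid_hosts <- setNames(tab$host, tab$plasmid)
  }
  prophage <- NULL
  if (file.exists(file.path(dir, "truth_prophage.tsv"))) {
    tab <- read_tsv(file.path(dir, "truth_prophage.tsv"))
    prophage <- list(replicon = tab$replicon, start = tab$start, end = tab$end,
                     phage_id = tab$phage_id,
                     mixture = c(integrated = tab$integrated,
                                 absent = tab$absent, circular = tab$circular))
  }
  methylation <- if (file.exists(file.path(dir, "truth_methylation.tsv"))) {
    read_tsv(file.path(dir, "truth_methylation.tsv"))
  }
  motif_sets <- NULL
  if (file.exists(file.path(dir, "truth_motif_sets.tsv"))) {
    tab <- read_tsv(file.path(dir, "truth_motif_sets.tsv"))
    motif_sets <- split(tab$motif, tab$replicon)
  }
  site_calls <- if (file.exists(file.path(dir, "site_calls.tsv"))) {
    read_tsv(file.path(dir, "site_calls.tsv"))
  }
  truth_bundle(community, sim_reads = sim_reads, strains = strains,
               crispr = crispr, plasmid_hosts = plasmid_hosts,
               prophage = prophage, methylation = methylation,
               motif_sets = motif_sets, site_calls = site_calls)
}
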