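#' Composition features of a sequence: GC and canonical k-mer frequencies
#'
#' Counts k-mers canonically (each k-mer pooled with its reverse complement
#' under the lexicographically smaller representative) so a sequence and its
#' reverse complement yield identical vectors. Windows containing non-ACGT
#' symbols are skipped.
#'
#' @param seq DNA string.
#' @param k k-mer size, 1--6 (default 4, tetranucleotide frequency).
#' @return A list with `gc` (fraction) and `kmer_vector` (named numeric
#'   vector over canonical k-mers, summing to 1; length 0 with attribute
#'   `empty = TRUE` when the sequence contains no valid k-mer).
#' @export
composition_features <- function(seq, k = 4L) {
  k <- as.integer(k)
  if (k < 1L || k > 6L) stop("k must be between 1 and 6")
  gc <- gc_fraction(seq)
  if (nchar(seq) < k) {
    v <- numeric(0); attr(v, "empty") <- TRUE
    return(list(gc = gc, kmer_vector = v))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), k)
  canon <- canonical_kmer_map(k)
  v <- tapply(counts[names(canon)], canon, sum)
  v <- v[sort(unique(unname(canon)))]
  tot <- sum(v)
  if (tot == 0) {
    v <- numeric(0); attr(v, "empty") <- TRUE
    return(list(gc = gc, kmer_vector = v))
  }
  list(gc = gc, kmer_vector = v / tot)
}

# named vector: k-mer -> canonical representative (lexicographic min of the
# k-mer and its reverse complement); cached per k
canonical_kmer_map <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    kmers <- Biostrings::mkAllStrings(DNA_BASES, k)
    rc <- revcomp(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    names(canon) <- kmers
    cache[[key]] <<- canon
    canon
  }
})

#' Principal-component embedding of composition profiles
#'
#' @param x Numeric matrix, one row per contig/read, columns = k-mer
#'   frequencies (e.g. stacked `kmer_vector`s from [composition_features()]).
#' @param n_components Number of components to return.
#' @return A list with `coordinates` (matrix, rows as in `x`),
#'   `explained_variance` (fractions, non-increasing, summing to <= 1) and
#'   `rotation` (orthonormal loadings).
#' @export
pca_embed <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 profiles")
  n_components <- min(as.integer(n_components), ncol(x), nrow(x) - 1L)
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var == 0) {
    return(list(coordinates = matrix(0, nrow(x), n_components,
                                     dimnames = list(rownames(x), paste0("PC", seq_len(n_components)))),
                explained_variance = rep(0, n_components),
                rotation = NULL))
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE])
}

#' Label reads/contigs by best reference hit and evaluate bins against truth
#'
#' Each item is assigned to the species of its highest-scoring alignment
#' (score = number of matching bases). Items whose best hits to two different
#' species are within a relative score margin are labeled `"ambiguous"`
#' (typically reads from inter-genomic repeats or strain-shared regions);
#' items without alignments are `"unassigned"`. When truth labels are given,
#' per-bin purity, completeness and contamination are computed. Ambiguous
#' items are excluded from purity but count against completeness;
#' contamination counts only items assigned to a wrong bin.
#'
#' @param alignments data.frame with columns `read_id`, `target` (reference
#'   replicon) and `score` (matching bases); multiple rows per read allowed.
#' @param items Character vector of all item ids (so unaligned items appear).
#' @param target_species Named character vector mapping reference replicon to
#'   species/bin label; defaults to the replicon ids themselves.
#' @param truth Optional named character vector item id -> true bin label.
#' @param tie_margin Relative score margin under which two species tie.
#' @return A list with `labels` (data.frame `read_id`, `bin`) and
#'   `evaluation` (data.frame `bin`, `n_assigned`, `purity`, `completeness`,
#'   `contamination_reads`; `NULL` without truth).
#' @export
assign_bins_and_evaluate <- function(alignments, items = NULL,
                                     target_species = NULL, truth = NULL,
                                     tie_margin = 0.05) {
  if (is.null(items)) items <- unique(alignments$read_id)
  if (nrow(alignments) == 0L) {
    labels <- data.frame(read_id = items, bin = "unassigned")
    return(list(labels = labels, evaluation = NULL))
  }
  if (is.null(target_species)) {
    tg <- unique(alignments$target)
    target_species <- setNames(tg, tg)
  }
  aln <- alignments
  aln$species <- unname(target_species[aln$target])
  if (anyNA(aln$species)) stop("alignments reference replicons with no species label")
  # sum split-alignment scores per read x target, then best target per species
  agg <- stats::aggregate(score ~ read_id + target + species, data = aln,
                          FUN = sum)
  agg <- stats::aggregate(score ~ read_id + species, data = agg, FUN = max)
  bins <- vapply(items, function(id) {
    rows <- agg[agg$read_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) return("unassigned")
    rows <- rows[order(-rows$score), , drop = FALSE]
    if (nrow(rows) >= 2L && rows$score[2] >= rows$score[1] * (1 - tie_margin)) {
      return("ambiguous")
    }
    rows$species[1]
  }, character(1))
  labels <- data.frame(read_id = items, bin = unname(bins))
  evaluation <- NULL
  if (!is.null(truth)) {
    orphans <- setdiff(items, names(truth))
    if (length(orphans)) stop("no truth label for item(s): ",
                              paste(utils::head(orphans, 5), collapse = ", "))
    tr <- truth[labels$read_id]
    species <- sort(unique(tr))
    evaluation <- do.call(rbind, lapply(species, function(s) {
      assigned <- labels$bin == s
      data.frame(bin = s,
                 n_assigned = sum(assigned),
                 purity = if (any(assigned)) mean(tr[assigned] == s) else NA_real_,
                 completeness = mean(labels$bin[tr == s] == s),
                 contamination_reads = sum(assigned & tr != s))
    }))
  }
  list(labels = labels, evaluation = evaluation)
}
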