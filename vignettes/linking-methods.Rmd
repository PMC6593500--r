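---
title: "Linking strains, plasmids and phages in low-complexity long-read metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking strains, plasmids and phages in low-complexity long-read metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magweave)
```

## Scope

Once a low-complexity community — a handful of dominant bacteria with their
plasmids and phages, as in a dairy starter culture — has been sequenced with
long reads and assembled into (near-)complete replicons, a second layer of
questions opens up that assembly alone does not answer: which of two
co-assembled sibling strains does each contig belong to, and at what
abundance do the strains occur; which phage has a host encountered before;
which host does a plasmid reside in; and is an integrated prophage dormant
or active. `magweave` implements these four linking analyses together with
the read-selection and binning diagnostics they rest on, plus a synthetic
community generator that produces complete ground truth, so every stage can
be validated end to end without any sequencing data.

## The synthetic community

`simulate_community()` builds a community with the statistical structure the
analyses assume: two sibling chromosomes of one species sharing most of
their genome at a 2:1 coverage ratio, a third chromosome at divergent GC
carrying a CRISPR array and an integrated prophage, two small circular
plasmids that inherit their host's methylation motifs, and a lytic phage
carrying protospacers derived from the CRISPR spacers.

The default conditions mirror the scenario the analyses were designed for:
94% genome sharing between the sibling strains, 30x and 60x strain
coverage, six planted protospacers at 0, 0, 1, 1, 2 and 2 substitutions, a
prophage locus segregating as a 22% integrated / 71% absent / 7% circular
molecule mixture, and a strict 5 kb read-length cutoff with the worst 10%
of reads by mean Phred quality discarded. Replicon sizes are scaled to desk
size — 1 Mb sibling strains, a 250 kb third chromosome, 15–40 kb mobile
elements — so that a full run completes in about a minute and a half on one
CPU while preserving the quantities that matter: the ratio of contig length
to read length, per-contig coverage noise, and junction read counts in the
hundred range. Sizes, coverages, motif sets and error rates are all
configurable through the `simulate` block of `default_config()`.

Reads follow a truncated log-normal length distribution (default mean 8 kb,
sd 6 kb, minimum 500 bp), matching the long-read length skew without
modeling instrument specifics. Errors are independent per-base
substitutions, insertions and deletions; there is no homopolymer bias, and
no kinetic (IPD) signal is simulated — methylation exists as truth-site
lists and score-carrying site calls, which is the level at which motif
analysis consumes real data. Each read carries a constant quality drawn
from a clamped normal; this exists to exercise the "drop the worst 10%"
filter, not to model basecaller behavior. Coordinates are 0-based
half-open throughout; circular replicons are handled by modulo arithmetic
and reads may wrap the origin. A read never exceeds the length of the
molecule it derives from.

Two generator choices deserve justification:

* **Prophage mixture semantics.** The observable in real data is the set of
  reads overlapping a junction, while the biological question is what
  fraction of *molecules* carry each variant. The generator draws the state
  of each junction-overlapping read directly from the configured mixture
  (integrated molecules expose two junctions, the deletion and circular
  variants one each, and all three share the read-length distribution, so
  per-read and per-junction proportions coincide). Read-level and
  molecule-level proportions are thereby treated as equal — the
  molecule-level truth underlying observed read fractions is not
  identifiable from junction counts alone, and this convention makes the
  planted truth exactly the quantity the classifier estimates.
* **Well-defined repeat boundaries.** When a repeat–spacer array is
  planted, the generator enforces that the columns immediately flanking the
  repeat copies do not all agree across copies; otherwise the repeat would
  legitimately extend into them and the planted boundary would be ambiguous
  by construction rather than by detection error.

All generator functions are deterministic given a seed; the truth bundle
writes to plain-text FASTA/FASTQ/TSV and reads back without loss, and two
runs with the same seed produce byte-identical files.

## Read selection and repeat-spanning diagnostics

`filter_reads()` applies a strictly-greater length cutoff (the convention
behind "reads > 5 kb") and then removes the `floor(f * n)` lowest reads by
arithmetic mean Phred quality. The mean is taken on the Phred scale rather
than through error probabilities — the simplest reading of "lowest-quality
reads" — and the quality drop is applied after the length filter; both
choices are configurable. `cumulative_output_curve()` gives total bases in
reads at least every length threshold, and `repeat_spanning_check()` counts
reads long enough to cross the longest repeat with a unique anchor on both
sides — the quantity that decides whether an assembly can be finished at
all.

## Binning diagnostics

`composition_features()` computes GC and canonical k-mer frequencies
(k ≤ 6, default tetranucleotides; each k-mer pooled with its reverse
complement, windows containing non-ACGT symbols skipped), and `pca_embed()`
projects them. `assign_bins_and_evaluate()` labels each read by its
best-scoring reference species, with a 5% relative score margin declaring a
tie ambiguous; split alignments of one read against one target are summed
before comparison. Ambiguity is deliberately not counted as contamination:
contamination means assignment to a *wrong* bin under truth, whereas reads
from strain-shared sequence are inherently ambiguous. On the default
community the two sibling strains stay unseparable (about half of their
reads are ambiguous) while species-level bins are pure — the behavior that
motivates strain deconvolution by coverage instead of by composition.

## Strain deconvolution by coverage

Contigs of a two-strain species fall into three coverage classes: unique to
the low-coverage strain (mean $\mu_A$), unique to the high-coverage strain
($\mu_B$), and present in both, where aligned reads of the two strains
accumulate so the class mean is constrained to $\mu_A + \mu_B$.
`assign_strain_contigs()` fits a three-component mixture of log-normals
with a common log-scale dispersion under this constraint by direct
likelihood maximization, and compares it against a single log-normal by
BIC; losing to the single model raises a single-strain flag.

Numerical choices:

* When contig lengths are supplied, the likelihood weights each contig by
  its length — the mean coverage of a long contig is a far tighter estimate
  than that of a short one.
* Optimization starts from a coarse grid of candidate $(\mu_A, \mu_B)$
  pairs (every observed coverage value for modest inputs), because a class
  represented by only two contigs is invisible to quantile-based starts.
* Near-ties in likelihood are broken toward the fit with the largest
  shared-class weight. This matters when the unique contigs of one strain
  drift into the shared cloud: the likelihood is then degenerate between
  "B at its own level, shared populated" and "B relabeled onto the shared
  cloud, shared empty", and in a co-assembled two-strain species the second
  reading is biologically implausible.
* Classification uses equal class priors rather than the fitted mixture
  weights: how many contigs ended up in a class reflects assembly
  fragmentation, not evidence about the next contig. A contig whose top two
  class weights differ by less than 0.2 is labeled ambiguous.

Relative strain abundances are $\mu_A/(\mu_A+\mu_B)$ and
$\mu_B/(\mu_A+\mu_B)$. With 1 Mb strains, ~30 kb contigs and ~12 kb reads,
per-contig coverage noise is 8–15% (long reads make coverage lumpy — the
effective number of independent depth draws per window is the window length
over the bases-weighted read length), which places occasional unique
contigs near a class boundary; at the full genome sizes of a real study the
same analysis is essentially noise-free.

## CRISPR spacer–protospacer linking

`detect_crispr_arrays()` is a seed-and-extend detector: exact 8-mers
recurring at spacings compatible with a repeat–spacer period anchor
candidates; repeat boundaries extend over the maximal flank on which all
copies agree; candidates must show at least 3 repeat copies of 23–55 bp,
spacers of 0.6–2.5 repeat lengths, and mutually dissimilar spacers (which
rejects plain tandem repeats). Both strands are scanned and overlapping
calls deduplicated. These structural conventions follow the common
CRISPR-detection heuristics; on 100 kb of uniform-random sequence the
detector finds nothing.

`match_protospacers()` is an exhaustive ungapped Hamming scan of every
spacer against both strands of every phage at every offset, wrapping the
origin of circular phages. Substitutions only — no gaps — which matches the
"mismatches among the spacer" framing; a planted protospacer whose true
alignment contains an indel would be missed, a documented limitation. The
default budget of 2 mismatches encodes "fewer than three mismatches in a
~30 bp spacer" as the threshold for claiming a previous host–phage
encounter; a rescan at a budget of 6 surfaces weak matches, and
`interaction_report()` grades each host–phage pair: close matches mean
acquired resistance, only-poor matches (≥ 5 mismatches) mean likely
diminished protection, no matches mean no evidence.

## Methylation-based plasmid–host assignment

Plasmids carry no methyltransferases of their own, so their methylation
motifs are those of their host's restriction–modification systems — which
turns motif profiles into host labels. `discover_motifs()` tests every
non-degenerate k-mer (k = 4–6 by default), anchored so the methylated base
is the k-mer's first position, for over-representation among methylated-site
contexts relative to its genomic background frequency (one-sided binomial),
with Benjamini–Hochberg correction across all `4^k` tested k-mers at
alpha = 0.05. Site calls below score 50 are ignored, mirroring the standard
quality cutoff for base-modification calls, and profiles are flagged
`low_coverage` below 250-fold per strand, the conventional minimum for
reliable motif detection from kinetic data. Significant k-mers differing at
one position are merged into degenerate IUPAC motifs (CCAGG + CCTGG become
CCWGG); `canonical_motifs()` then drops any motif that is a prefix of a
longer discovery, keeping the most specific form — truncated forms dilute
the methylated fraction, since most occurrences of a truncation are not
methylation sites. Relative motif abundance is reported as the methylated
fraction per motif (methylated occurrences over occurrences, both strands,
origin-wrapping on circular replicons).

`assign_plasmid_hosts()` assigns a plasmid to a host when every detected
plasmid motif occurs in that host's profile and at least one of them occurs
in no other host (`unique_motif`); when all matched motifs are shared,
every compatible host is listed (`shared_motif`); a plasmid with no
detected motif stays `unassigned` — the realistic outcome for a small,
low-coverage plasmid.

## Prophage activity from junction-spanning reads

At a prophage locus three molecule variants can coexist: the chromosome
with the prophage integrated, the chromosome without it, and the excised
circular phage. Long reads distinguish them at the junctions.
`classify_junction_reads()` works on alignments against the
integrated-host reference: a single alignment running contiguously across a
prophage boundary with at least 500 bp on each side is `integrated`; a
split read jumping from the host flank at the prophage start to the host
flank at its end (a deletion-type junction) is `absent`; a split read
jumping from the prophage end back to its start is `circular`; everything
else — including reads fully inside the prophage and chimeras supporting
two classes — is uninformative. The 500 bp anchor is generous because long
reads make it cheap; junction breakpoints are matched with a 20 bp
tolerance. `variant_fractions()` reports fractions over informative reads
with Wilson 95% intervals (the denominator convention — all informative
reads at the locus rather than per-junction counts — is a documented
choice; per-junction counts are available from the labels).
`activity_call()` declares `active_mixed` when both an integrated
(lysogenic, ≥ 5%) and a circular (lytic, ≥ 2%) signal are present —
the signature of an active phage system.

## Orchestration

`run_pipeline()` chains simulate → read filtering → binning → strain
deconvolution → CRISPR linking → methylation linking → prophage
classification → truth comparison, writes every table as TSV plus a JSON
run report with an md5 manifest, and is byte-reproducible for a given
config and seed. Configuration is a nested list (or YAML file) merged over
`default_config()`; unknown keys are rejected by name. Since the synthetic
truth records every read's source interval, `alignments_from_truth()`
plays the role of an external long-read mapper with exactly known
coordinates — including split alignments for deletion-type and circular
junction reads and near-tied secondary hits for strain-shared reads — so
the analysis stages exercise the same record structure they would consume
from a PAF-like table of real alignments. `compare_to_truth()` scores
every stage against the bundle: contig-assignment accuracy, spacer match
recall and false matches, plasmid-host correctness, prophage fraction
errors and CI coverage.

## What passing tests do and do not show

The simulation reproduces the coverage structure, repeat/spacer/motif
content and junction geometry that the analyses key on, with exactly known
truth. It does not emulate instrument-specific error profiles, homopolymer
artifacts, chimeric library molecules, kinetic signal noise, or biological
complications such as partial methylation by orphan methyltransferases,
multiple strains beyond two, or attachment-site duplication at prophage
boundaries (insertion is modeled as a clean splice). Passing the suite
therefore demonstrates the statistical and algorithmic correctness of each
stage under its stated model, not robustness to every artifact of real
libraries. The interfaces accept real data at the same boundaries —
FASTQ reads, PAF-like alignment tables, TSV site calls — so each stage can
be fed mapper or basecaller output directly.

The test and acceptance problem sizes (1 Mb strains, a 250 kb host
chromosome, a few hundred junction-informative reads, 20-seed property
loops) were chosen so the full suite runs in minutes on one CPU; they are
stated here as the package's validation conditions, and all thresholds the
suite asserts (assignment accuracy ≥ 0.95, full spacer recall with zero
false matches at the 2-mismatch budget, CI coverage of planted mixtures)
are met with margin under these conditions.
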