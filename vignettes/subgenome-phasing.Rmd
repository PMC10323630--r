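---
title: "Phasing allopolyploid subgenomes: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing allopolyploid subgenomes: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphase)
```

# The problem

An allopolyploid genome carries chromosome sets (subgenomes) inherited from
distinct progenitor species. In a chromosome-scale assembly of such a
genome, three independent lines of evidence can resolve which chromosome
belongs to which subgenome and which progenitor each subgenome descends
from:

1. **Repeat content.** Satellite DNA evolves fast and is largely
   species-specific, and it concentrates at centromeres. Chromosomes that
   share a recent origin therefore share centromeric repeat families, which
   surface as k-mers with strongly unequal abundance between homoeologous
   chromosomes.
2. **Read depth.** A subgenome present in more than one copy (e.g. the BB
   pair of an AA'BB tetraploid collapsed into one assembled haplotype)
   shows proportionally higher short-read depth.
3. **Gene phylogenies and synteny.** For each gene, a tree containing the
   polyploid's gene copies and orthologs from candidate progenitor species
   shows which progenitor each copy is sister to; restricting to
   bootstrap-supported relations that also fall in collinear (syntenic)
   blocks gives high-confidence per-chromosome progenitor assignments
   (syntelogs).

`polyphase` implements all three, plus the downstream analyses that
typically accompany them: gene-tree topology censuses,
penalized-likelihood divergence dating, Nei–Gojobori Ka/Ks with Ks-peak
diagnosis of allo- vs autopolyploidy, and rule-based annotation/marker QC.
A synthetic allotetraploid generator with planted truth makes every stage
testable without external data.

# The synthetic genome generator

`genome_spec()` / `build_genome()` produce an AA'BB-like genome. The
defaults define the validation conditions used throughout the test suite:
3 subgenomes (A, A' coded `Ap`, B) × 2 chromosomes × 2 Mb; a 200 kb
centromere per chromosome; a private 100 bp satellite monomer per subgenome
tandem-arrayed 400× at its own centromeres; 15 dispersed copies of *every*
monomer family on *every* chromosome; a shared background repeat covering
2% of each chromosome; 300 collinear genes per chromosome in homoeologous
groups mutated at per-subgenome rates (A, A' at 0.005 and B at 0.02
substitutions/site from the group ancestor); and dosage A:1, A':1, B:2.

Design notes:

* The dispersed low-copy placement of every family is essential: the
  differential k-mer filter requires a k-mer to be *present on all
  chromosomes* yet ≥2-fold enriched on one homoeolog, which is how real
  subgenome-specific satellites behave (high tandem copy number at their
  own centromeres, scattered relics elsewhere). A generator without the
  scatter would leave nothing for the filter to keep.
* Divergence is parameterized per subgenome (branch from the group
  ancestor), so a pair's divergence is the sum of its branch rates; setting
  A = A' = 0 reproduces the degenerate identical-homoeolog case.
* Homoeologous exchanges are modeled by copying the donor's sequence (and
  hence gene content) over the recipient's interval; exchanges overlapping
  the centromere are rejected because the copied tandem array would change
  the recipient's repeat identity wholesale.
* The read simulator is error-free and uniform. Sequencing error and bias
  are irrelevant to the depth/dosage logic under test; consequently,
  passing tests say nothing about alignment robustness to error, only
  about the depth arithmetic and multi-mapping treatment.

What the generator does *not* emulate: assembly fragmentation and
collapse, Hi-C signal, transposon families with realistic age structure,
GC/coverage bias, and error-bearing reads. Results on synthetic data
validate the pipeline's logic, not its tolerance to real-data artifacts.

# K-mer phasing

`count_kmers()` performs exact sliding-window counting (canonical form =
lexicographic minimum of a k-mer and its reverse complement; `N` breaks
the window; k ≤ 31 via 2-bit encoding in compiled code).
`differential_filter()` keeps k-mers with ≥ `min_count` (default 10)
occurrences on every chromosome and a ≥ `fold` (default 2) excess on some
homoeolog relative to at least one of its sisters. Both boundaries are
closed (`>= 10`, `>= 2`) and configurable, as is the stricter
"all sisters" comparison.

`cluster_chromosomes()` applies complete-linkage hierarchical clustering.
The distance is Euclidean on `log2(count + 1)`-transformed columns by
default: the log transform variance-stabilizes counts so a single
mega-abundant repeat cannot dominate the metric; raw-count distance is
available via `transform = "raw"`. On the default synthetic genome the
3-cut recovers the planted subgenomes with adjusted Rand index 1, and
removing deliberately chimeric chromosomes strictly improves the
silhouette at the 3-cut, mirroring how excluding two poorly assembled
homoeologs sharpens subgenome separation in practice.

`density_profile()` reports, per window (default 1 Mb), `occurrences × k /
window length` — the fraction of window bases occupied by group k-mers —
with the trailing short window normalized by its true length, so the
conservation identity `sum(value × window length) = k × total occurrences`
holds exactly. `estimate_centromere()` scores windows as `z(TE density) −
z(gene density)` and returns the maximal-scoring contiguous run (Kadane's
algorithm); constant tracks are flagged undefined rather than silently
returning an interval.

# Depth and dosage

`map_reads()` places error-free reads at every exact-match position on
either strand, contributing `1/n_hits` per covered site, so depth mass is
conserved regardless of repeat copy number. A full mismatch-tolerant
aligner is intentionally out of scope: with error-free synthetic reads,
exact placement preserves the analytical question (relative depth between
subgenomes). `bin_depth()` averages depth per 1000 sites (trailing bin by
its true length) and reports the genome-wide median; `dosage_ratios()`
summarizes each subgenome by the median of its bin means — robust against
repeat-driven pileups — and rounds ratios against the shallowest subgenome
to integer copy numbers. At 20× base coverage and ≥ 1 Mb per subgenome the
B/A ratio is recovered within 5%.

`coverage_fold()` and `percent_of_estimate()` are exact reporting
arithmetic (round half away from zero at the requested precision, one
decimal for folds and integers for percentages, matching how such numbers
are conventionally printed).

# Syntelogs and progenitor assignment

`find_anchors()` chains 1:1 homology hits into collinear runs by dynamic
programming in gene-rank space (strictly increasing query ranks; subject
ranks strictly monotone, decreasing for inverted blocks; consecutive
anchors ≤ 20 ranks apart; chains of ≥ 4 anchors reported, best-first, each
gene in at most one chain per chromosome pair). This captures the
function of a full synteny pipeline at desk scale without reimplementing
its scoring heuristics.

`extract_sisters()` reads each focal (subgenome) tip's sibling clade: a
relation is emitted only when every sibling tip belongs to exactly one
progenitor species (a cherry, or a multi-copy clade of one species) and
the joining node's bootstrap is ≥ 80 (configurable; boundary closed). A
sibling clade mixing species yields nothing — a deliberate conservative
choice, since an ambiguous sister cannot support a progenitor call.
`intersect_syntelogs()` keeps relations whose gene pair appears in an
anchor chain, and `assign_and_summarize()` tallies per-chromosome and
per-subgenome progenitor support (percentages at one decimal, half away
from zero), reporting explicit no-calls for requested units without
relations. A focal gene with several qualifying relations keeps all of
them; multiplicity is visible in the per-gene table.

# Topology census

`classify_topology()` roots on the outgroup and classifies each focal
subgenome by its sibling clade's species; subgenome–subgenome cherries are
canonicalized (A with A' is one class regardless of which is focal).
`census()` reports counts and percentages per focal subgenome; formatting
follows the convention of the tables it emulates — integer percent unless
below 10%, then one decimal.

# Penalized-likelihood dating

`pl_date()` converts branch lengths to substitution counts (`round(length
× n_sites)`), models them as Poisson with mean `rate × duration ×
n_sites`, and maximizes the log-likelihood minus `λ ×` a roughness
penalty: squared differences of log-rates between parent and child
branches plus the summed squared deviation of root-child log-rates from
their mean. Ages respect constraints *by construction*: the root age is
fixed by calibration and every free node's age is its subtree lower bound
plus a logistic fraction of the span up to its parent, so the optimizer
(L-BFGS-B with analytic gradients, multi-start with a deterministic first
start) never visits an infeasible configuration. Minimum-age calibrations
enter the lower bounds; fixed internal calibrations pin nodes exactly, and
infeasible combinations are rejected up front.

Numerical choices worth recording:

* The Poisson log-likelihood is evaluated **centered at its saturated
  maximum**, per edge as `x·log1p((μ−x)/x) + (x−μ)`. Near the optimum each
  term is O((μ−x)²/x), so the objective resolves differences ~12 orders of
  magnitude below the raw log-likelihood's scale. This matters because the
  likelihood is exactly flat along rate–age compensation; only the penalty
  (often ~1e−10 near a clock optimum) identifies ages, and the raw-scale
  objective would drown it in rounding noise.
* Multi-start results tied within numerical resolution resolve to the
  deterministic first start rather than an arbitrary random one.
* Substitution counts are rounded, so tests that demand exact clock
  recovery use branch lengths whose counts are integers; with such input
  the clock solution is the exact global optimum at any λ.

**Identifiability.** Because the likelihood is flat in rate–age
compensation, node ages under penalized likelihood are determined by
penalty minimization subject to the fitted substitution totals. A strict
clock is recovered exactly at any λ. An *abrupt* rate shift, however, is
smoothed: nodes adjacent to the shift are biased (we measured ~28% on a
node bordering a 3× clade calibrated only at the root), and no choice of λ
removes the bias since λ scales out of a flat-likelihood problem. The
package's two-rate validation therefore brackets the rate shift with
calibrations (fixed root plus fixed nodes at the shift boundary), the
standard remedy in practice; under bracketing calibrations both the
remaining free ages (within 10%, in fact ~0.1%) and the 3× rate ratio are
recovered. `bootstrap_ages()` dates replicate trees and reports mean and
2.5/97.5 percentile intervals, reporting (not dropping) failed replicates.

The "rate = gamma" setting of the r8s-style workflow (gamma-distributed
rate variation) is outside this objective; the package implements the
standard penalized-likelihood objective and documents the difference here.

# Ka/Ks and Ks peaks

`ng86()` implements Nei–Gojobori (1986) counting: per-codon synonymous
site fractions averaged over both sequences (mutations creating stop
codons are excluded from the synonymous tally; codon pairs containing
stops or ambiguity are dropped pairwise), pathway-averaged difference
counting over all orderings of multi-position codon differences (orderings
through stop codons excluded, with an all-orderings fallback), and
Jukes–Cantor correction `K = −(3/4)·ln(1 − (4/3)p)`, flagged invalid at
p ≥ 3/4. Replacing a maximum-likelihood estimator with NG86 shifts
absolute values slightly at high divergence, but at the Ks scale relevant
for young polyploids (≤ 0.03) the difference is negligible; the test suite
pins the implementation to an independent pathway-enumeration oracle at
1e−9.

`filter_ks()` applies the standard cleanup (self-comparisons removed;
Ka or Ks strictly greater than 3 removed — records at exactly 3.0 are
kept). `ks_peaks()` histograms Ks at a fixed bin width (default 0.002,
suited to the low-Ks range of young polyploids) and reports strict local
maxima above a prominence floor (5% of the tallest bin, to suppress noise
bins); peak positions are bin midpoints, so a planted mode is recovered to
within one bin width. Two surviving peaks label the distribution
"two-peak" — the allopolyploid signature of homologous plus homoeologous
pair populations.

# Annotation and marker QC

All three QC operations are pure interval/threshold rules, validated
against brute-force oracles on randomized fixtures:

* `fusion_candidates()`: a combined-evidence gene model overlapped (≥ 1 bp,
  same chromosome, strand-agnostic) by ≥ 2 distinct proteins-only models
  is a candidate fusion.
* `filter_markers()`: markers mapping more than 4 times are dropped
  entirely, then individual hits covering less than 80% of the marker are
  dropped (boundary closed: 80% is kept; applied per hit), then counts are
  recomputed. `marker_stats()` counts markers mapping exactly once to each
  subgenome and checks map-vs-physical collinearity by Spearman rank
  correlation.
* `s_locus_call()`: an S-RNase pairs with the nearest same-chromosome SFB
  (separation between nearest feature edges); the pair is a "full" allele
  only with both identities strictly above 90% and separation strictly
  below 100 kb.

# Problem sizes used in validation

The shipped validation uses: a 12 Mb six-chromosome genome for phasing
(ARI and centromere colocalization), a 3.6 Mb genome at 20× (960k reads)
for dosage, 450 genes/chromosome with a planted 200-gene exchange for
syntelog assignment, 336 trees for the census, 5–6-tip trees at 10⁴–10⁵
sites for dating (with a 200-run coverage simulation of 25 replicates
each), 10⁵ pairs for Ks peaks, and 1000 randomized fixtures per QC rule.
These sizes exercise every code path at full fidelity while keeping the
whole suite comfortably reproducible on a laptop.

# Known limitations

* Exact k-mer counting holds the count table in memory; genomes far beyond
  the hundreds-of-megabases range would need disk-backed or sketched
  counting, which is out of scope.
* `map_reads()` requires exact matches and is therefore only meaningful
  for error-free reads against their source assembly.
* Anchor chaining is single-linkage DP without C-score-style filtering of
  promiscuous hits; extremely repetitive gene families could chain
  spuriously.
* The dating module reports per-tree tables; combining estimates across
  tree topologies is left to the caller.
* NG86 assumes equal base frequencies and no transition/transversion bias;
  for saturated pairs the record is flagged invalid rather than corrected.
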