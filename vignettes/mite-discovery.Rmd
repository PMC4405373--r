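---
title: "Structural discovery of MITEs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural discovery of MITEs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitescope)
```

Miniature inverted-repeat transposable elements (MITEs) are short
(< 1.5 kb) non-autonomous DNA transposons defined purely by structure:
a terminal inverted repeat (TIR) at each end, an identical target site
duplication (TSD) flanking both ends, high AT content and high copy
number.  Because they carry no coding sequence, they are found
structurally and characterised comparatively: candidate loci are
grouped into families by sequence identity, a consensus per family is
used to mine decayed remnant copies, TSD/TIR attributes assign
superfamilies (Stowaway-like, Tourist-like, hAT-like, Merlin-like,
Mutator-like), and the distribution of pairwise divergences within a
family records its amplification history.  `mitescope` implements this
workflow end to end for small AT-rich genomes (microsporidia-sized,
roughly 1-16 Mb), together with the downstream analyses that usually
accompany it: insertion-bias statistics against a Monte-Carlo
placement null, candidate MITE insertion polymorphisms (MIPs) between
related genomes, and small-RNA profiles along family consensi.

This vignette records the models and the design decisions, with the
rationale for every place where the method is under-determined by
convention.

# The structural scanner

A candidate is an element body $[b, e)$ (0-based half-open, TSD
excluded) such that

* some $t \in [2, 20]$ gives identical flanking direct repeats
  $s[b-t,b) = s[e,e+t)$; the recorded TSD is the longest such $t$;
* the body termini form an inverted repeat of length
  $L \in [5, \min(60, \lfloor(e-b)/2\rfloor)]$ with at most one
  mismatch (Hamming distance between the 5' terminus and the reverse
  complement of the 3' terminus); the recorded TIR is the longest
  such $L$;
* $e - b < 1500$ (the length bound applies to the body; whether it
  includes the TSDs is not fixed by convention — we exclude them).

`N` is a legal residue but never matches anything, in TSD equality or
TIR complementarity.

**Matched-end TIRs.**  One refinement proved necessary: the recorded
TIR must *begin and end on a matching base pair*, i.e. it is a maximal
approximate inverted repeat rather than one padded with terminal
mismatches.  Without this rule, any body shifted one or two bases off
a real element claims a "longer" TIR by spending its mismatch budget
on the outermost position, and overlap resolution then systematically
displaces element boundaries: on synthetic genomes 42% of planted
copies were reported with 1-3 bp coordinate shifts.  With the rule, a
shifted reading must be supported by genuine chance complementarity,
and planted coordinates are recovered exactly (see the acceptance
suite).

**Overlap resolution.**  The raw candidate definition is extremely
permissive on AT-rich sequence (thousands of chance TSD+TIR loci per
100 kb).  Overlapping candidates are therefore reduced: candidates are
ranked by longer TIR, then fewer TIR mismatches, then longer TSD, then
leftmost position, and a candidate is dropped when it shares more than
half of the shorter span with a better-ranked survivor.  Rankings that
put the TSD first, or a TSD+TIR sum first, were tried and rejected:
both are dominated either by chance long direct repeats or by inward
boundary-shift artifacts.

**Two independent implementations.**  The production scanner finds
direct repeats first (one run-length pass per repeat distance) and
then tests the enclosed termini; the reference enumerator
(`scan_genome_bruteforce()`) loops over every body interval and
applies the definitions directly, on the raw character sequence with
no shared helper code.  The test suite asserts exact equality of the
two outputs on dozens of 50 kb random sequences; this validates the
scanner against the definition rather than against any third-party
tool's internals.

**Known ambiguity: the TA duplication.**  A TSD whose ends complement
each other lets the TIR chain outward *through* the duplication, so
the locus admits several nested structural readings; the palindromic
`TA` duplication of Stowaway-like elements is the irreducible case.
For such families the reported body may absorb up to one TSD copy per
side.  Family recovery is unaffected; coordinate-exact recovery is
asserted only for families whose TSDs do not have complementary ends,
and a dedicated test covers the TA case with the corresponding
tolerance.

# Candidate filters, families, consensus, remnants

Candidates with three or more `N`s in the body, or with TSD copies
that do not match exactly, are removed (`filter_candidates()`), with
per-rule attrition logged.

**Clustering.**  Families are single-linkage components of the graph
whose edges join candidate pairs with alignment identity ≥ 0.90,
mirroring transitive family assignment by all-vs-all homology search;
components with fewer than three members are discarded.  Edges
additionally require that the shorter sequence participate in at
least 60% of its length (guarding against spurious short-overlap
links) and that the two loci not overlap on the genome — overlapping
loci cannot be two distinct copies, and such pairs (junk candidates
sharing genome sequence) otherwise dominate the alignment workload.
Above 300 candidates an all-vs-all megablast prefilter proposes the
pairs worth aligning; every retained edge is still decided by the
package's own aligner.

**Alignment.**  Identity and divergence statistics use a batched
free-end-gap global aligner (Gotoh dynamic programming, written for
this package): match +1, mismatch −1, linear gap −2 for
identity/clustering; gap open −4 / extend −1 (affine) for distance
estimation.  Identity is matches over aligned columns with terminal
overhangs excluded; coverage is the aligned span of the shorter
sequence over its length.  The test suite cross-checks alignment
scores exactly against `Biostrings::pairwiseAlignment` under both
scoring schemes, and against a small independent DP oracle.  Distance
alignments are banded by default (50 columns around the
length-difference diagonal) — exact for copies diverged by
substitutions and short indels, and an order of magnitude faster;
`band = 0` restores the unrestricted program.

**Consensus.**  Center-star multiple alignment: the star is the
member with the highest summed alignment score against the rest (a
length-weighted criterion — mean identity would let a junk candidate
embedding a copy *fragment* win the star role, because free-end-gap
identity ignores coverage).  Members are projected onto star
coordinates, insertions relative to the star are ignored, and each
column takes the majority base with ties broken alphabetically;
majority-gap columns are dropped.  The procedure is deterministic.

**Remnant mining and membership.**  The consensus is searched against
both genome strands (BLAST+ nominates loci; the package recomputes
identity and coverage and makes all accept/reject decisions).  Hits
are kept when identity ≥ 0.90 *and* consensus coverage ≥ 0.80 — the
conventional mining filters — and each kept locus is flagged intact
when TIR+TSD structure is re-detected there.  The same two filters
are applied uniformly to structural members when a family is
assembled, and structural members are vetted *before* mined hits are
merged, so a rejected structural candidate cannot shadow a genuine
remnant at the same locus.

**Superfamily key and naming.**  TSD `TA` → Stowaway-like; 3 bp TSD →
Tourist-like; 8 bp TSD with TIR 24-34 bp → Merlin-like, other 8 bp
TSDs → hAT-like; 10 bp TSD → Mutator-like; otherwise Unknown, with a
flag for the recurrent novel configuration (5-6 bp TSD, TIR starting
`TGT`).  Families are named `N<species letter><code><number>` with
numbers assigned within superfamily by decreasing copy count, ties by
discovery order.

# Divergence, bursts and trees

Pairwise distances use the Kimura two-parameter model,
$d = -\tfrac12 \ln\big((1-2P-Q)\sqrt{1-2Q}\big)$, with transition and
transversion proportions computed over comparable sites (pairwise
deletion of gap and `N` columns).  Saturated pairs (log domain
violated) are excluded from matrices and reported, never silently
clamped.

Divergence histograms use a 0.02 bin.  A *burst peak* is a local
maximum of the histogram whose topographic prominence is at least 10%
of the total pair count; prominence (height above the key saddle
toward higher terrain) suppresses the bin-to-bin jitter of a sampled
mode while keeping genuinely separate modes apart.  Peak count is
read as the number of amplification episodes.

Trees are canonical Saitou-Nei neighbor joining with deterministic
tie-breaking (lowest index pair); negative branch lengths are clamped
to zero with the deficit moved to the sister edge.  No bootstrap is
computed; the two-episode separation claim is tested as monophyly of
the planted episodes instead.  Exact topology recovery on additive
matrices, agreement with `ape::nj`, and the closed-form three-taxon
solution are asserted in the tests.

# Gene association and its null

An element is associated with genes when its span intersects any CDS
extended by a flank (300/200/100/0 bp) on both sides.  The null model
places elements of the observed lengths uniformly at random without
overlap and records the associated fraction per replicate.  Observed
counts are compared to null-expected counts with a Pearson chi-square
test, without continuity correction: the two-way form
(df $=(r-1)(c-1)$) for contingency tables, and a goodness-of-fit form
(df $=$ cells $-1$) when a single observed sample is compared against
Monte-Carlo expected counts — forcing that comparison into a 2×2
margins table halves the variance and makes the test severely
conservative.

The calibration experiment in the acceptance suite runs the test on
data generated by the null itself and checks the rejection rate at
$\alpha = 0.05$.  It uses equal-length elements at about 1% genome
occupancy, which is the validity regime of the binomial sampling
model behind the chi-square: at high occupancy the non-overlap
constraint induces negative dependence between placements (measured
variance ratio ≈ 0.86 at 19% occupancy) and the test becomes
conservative.  This is a real property of the statistic worth knowing
when interpreting its p-values on dense genomes, not an artifact of
the implementation.

# TIS re-annotation, orthologs, MIP candidates

Start-codon re-annotation operationalises "CCC-like or GGG-like
motifs" as any `CC` or `GG` dinucleotide (the degenerate-triplet
reading `CCN|NCC|GGN|NGG`) within the 10 nt upstream of a candidate
ATG, with the additional criterion that the 30 nt upstream be more
than 80% AT; both the motif and the windows are configurable because
the motif definition is loose in the literature.  A gene whose
annotated ATG already satisfies both criteria is left unchanged;
otherwise in-frame ATGs within 30 nt are examined downstream first
(the procedure exists to shrink over-predicted genes), and the first
qualifying one becomes the revised start.  Because a revised start
satisfies the acceptance criteria, the operation is idempotent, which
the tests assert.

Orthologs are reciprocal best hits under local protein alignment
(BLOSUM62, gap open 10 / extend 0.5, via Biostrings); ties yield no
pair.  Syntenic blocks are maximal runs of at least three ortholog
pairs collinear in order and direction on both genomes; a MIP
candidate is an ortholog pair whose species-A 5' flank contains a
MITE while the homologous species-B flank contains none.

# Small-RNA profiles

Reads (16-30 nt) are mapped ungapped, end-to-end, at every offset of
every consensus on both strands, with up to two mismatches — the
conventional short-read budget — and each read reports all of its
equal-best loci.  Ungapped alignment is adequate at these lengths and
makes the brute-force oracle in the tests exact.  Length histograms
count each read once regardless of multi-mapping; positional density
increments every covered position per strand, with multi-mapped reads
contributing fractionally ($1/$loci), so total density equals total
mapped read length exactly — an invariant the tests check, along with
exact sense/antisense exchange under reverse complementation of the
read set.

# The synthetic-genome generator

The generator exists so that every stage can be validated against
ground truth.  It emulates: small AT-rich genomes (background i.i.d.
at a requested AT fraction, 0.4-0.85); element families with defined
TSD (2-20 bp, literal `TA` or per-copy random), TIR (5-60 bp) and
internal length, with total length < 1500 bp; copy bursts at one or
more divergence levels; truncated remnant copies (one terminus lost,
40-95% of the body retained, no TSD); non-overlapping CDS
annotations; and small-RNA reads with lengths peaked at 24-25 nt and
a configurable fraction starting in the outer 20% of the consensus.

**Burst model.**  Each divergence level $\ell_k$ is one amplification
episode on a master lineage: the episode ancestor sits at distance
$\ell_k/2$ from the founder, and each copy accumulates its own
$\ell_k/2$ (plus a small within-burst term, default 0.005) after
insertion.  A copy's distance to the founder is then $\ell_k$ in
expectation, and the distance between copies from episodes $k$ and
$l$ is $\max(\ell_k, \ell_l)$ — all pairs involving an episode
collapse onto that episode's level, so $k$ episodes give exactly $k$
histogram modes located at the levels themselves.  (A chained model
in which each copy carries the full level distance was implemented
first and discarded: its cross-episode pair distances resolve into
separate modes, producing $\binom{k}{2}+1$ peaks rather than the $k$
amplification episodes the analysis is supposed to count.)

**Mutations** are substitutions only, at a 2:1
transition:transversion ratio, so a target K2P distance maps to a
per-site substitution probability analytically (solved numerically
from the K2P closed form); indels are excluded because the burst
analysis is substitution-distance based.  Substitutions are confined
to the internal region — TIRs and TSDs stay intact on non-remnant
copies — with the internal rate scaled up so the distance over the
whole body hits the target.

**TSD draws.**  Length-specified TSDs are drawn rejecting draws whose
terminal bases complement each other, because such duplications make
the element boundary structurally ambiguous (the TA case above);
literal motifs like `TA` are planted verbatim.  This is an
identifiability condition of the simulation, stated openly: it makes
"the planted coordinates" a well-defined quantity for recall
measurement.

**What the generator does not emulate** — and hence what passing
tests do *not* establish about real data: segmental duplications,
nested or tandem element insertions (the recovery experiment plants
copies more than one element length apart, because two same-family
copies within 1.5 kb create a genuine scanner artifact, a
pseudo-candidate spanning between them whose termini are the
flanking copies' TIRs), transposase ORFs, indel decay of old copies,
GC-content heterogeneity along the genome, and sequencing error in
small-RNA reads.

# Study sizes used by the tests

Chosen as the package's own validation conditions: scanner/oracle
equality on twenty 50 kb sequences; planted-family recovery on a 1 Mb
genome with five families × 20 copies (half undiverged, half at
distance 0.05, 10% remnants); burst detection over 50 seeds per
condition with families of ~1 kb elements; chi-square calibration
over 1000 null simulations on a 2 Mb genome; small-RNA invariants on
10,000 reads.

# Limitations

* Boundary coordinates of TA-TSD elements are ambiguous by one TSD
  copy per side (intrinsic to the structure, not the implementation).
* The permissive structural definition means raw candidate lists are
  dominated by chance loci; downstream identity clustering and the
  three-member family floor carry the specificity burden, as in the
  underlying methodology.
* The chi-square association test is conservative on densely occupied
  genomes (see above).
* Remnant mining depends on the BLAST+ executables being on the
  `PATH`; all decisions, but not the initial hit search, are
  recomputed internally.
* Superfamily assignment uses TSD/TIR attributes only; no repeat
  database lookup is attempted, so "Unknown" conflates genuinely novel
  superfamilies with known ones whose structural attributes fall
  outside the key.
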