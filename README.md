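# mitescope

Genome-wide discovery and characterization of **miniature
inverted-repeat transposable elements (MITEs)** in small AT-rich
genomes — the scale of microsporidian parasites (1–16 Mb), where MITEs
can make up several percent of the genome and record its recent
history of transposon amplification.

MITEs are short (< 1.5 kb) non-autonomous DNA transposons defined
purely by structure: a terminal inverted repeat (TIR, 5–60 bp) at each
end and an identical target site duplication (TSD, 2–20 bp) flanking
both ends. `mitescope` implements the full comparative workflow around
that definition:

* **Structural scanning** — every locus where an identical direct
  repeat flanks a body whose termini form an inverted repeat (≤ 1
  mismatch), with deterministic resolution of overlapping readings and
  an independent brute-force enumerator used to validate the scanner
  exactly.
* **Family building** — candidate filtering (< 3 Ns, exact TSD match),
  single-linkage clustering at ≥ 90% identity (families under three
  members discarded), center-star consensus, genome-wide remnant
  mining (identity ≥ 90%, consensus coverage ≥ 80%; BLAST+ nominates
  loci, the package decides), TSD/TIR superfamily classification
  (Stowaway-like, Tourist-like, hAT-like, Merlin-like, Mutator-like)
  and `NxY#` family naming.
* **Amplification history** — pairwise Kimura two-parameter distances
  (`d = -1/2 ln((1-2P-Q)√(1-2Q))`), divergence histograms with
  prominence-based burst-peak detection, 100%-identity copy groups,
  and Saitou–Nei neighbor-joining trees.
* **Genomic context** — gene-association fractions at 300/200/100/0 bp
  CDS flanks against a Monte-Carlo random-placement null with a
  Pearson chi-square bias test; start-codon re-annotation from
  CC/GG-motif, AT-rich initiation contexts; reciprocal-best-hit
  orthologs; and MITE insertion polymorphism (MIP) candidates in
  syntenic blocks.
* **Small-RNA profiling** — exhaustive ungapped mapping of 16–30 nt
  reads to family consensi (≤ 2 mismatches, all equal-best loci),
  length distributions and per-position sense/antisense density.
* **A synthetic-genome generator** with complete ground truth (planted
  families with defined TSD/TIR, divergence episodes, remnants, gene
  models, terminal-biased small-RNA reads), so every stage is testable
  without any external data.

## Worked example

Simulate a 200 kb genome with one planted hAT-like family (12 copies,
8 bp TSD, 20 bp TIR; half the copies undiverged, half at distance
0.08; one truncated remnant), then run the pipeline:

```r
library(mitescope)

spec <- family_spec("demo", tsd = 8L, tir = 20L, internal_length = 500L,
                    copy_number = 12L,
                    divergence_levels = list(c(0, 0.5), c(0.08, 0.5)),
                    remnant_fraction = 0.1)
sim    <- generate_genome(2e5, at_content = 0.65, list(spec), seed = 42,
                          min_gap = 1600L)
genes  <- generate_gene_annotations(sim$genome, 60L, seed = 1)
report <- run_pipeline(sim$genome, genes, species_letter = "b",
                       divergence_min_copies = 8L)
report
```

```
MITE discovery run
  candidates 617 -> filtered 617 -> families 1 (12 copies, 11 intact)
  genome fraction occupied: 0.0321
  superfamily families elements total_bp
1    hAT-like        1       12     6414
2       Total        1       12     6414
  gene association:
 flank_bp n_elements n_associated  fraction null_mean_fraction null_replicates
      300         12            7 0.5833333          0.4316667             200
      200         12            6 0.5000000          0.3816667             200
      100         12            5 0.4166667          0.3266667             200
        0         12            4 0.3333333          0.2937500             200
 chi_square   p_value
 1.12514861 0.2888125
 0.71201403 0.3987760
 0.44190746 0.5062032
 0.09062951 0.7633784
```

The scanner reports 617 raw structural candidates on this AT-rich
sequence — chance TSD+TIR loci are abundant by construction — but
identity clustering with the three-member floor keeps exactly the one
planted family: 12 copies, 11 structurally intact plus the truncated
remnant recovered by consensus mining, correctly typed hAT-like from
its 8 bp TSD. MITEs occupy 3.2% of the simulated genome. At every
flank size the observed gene-association fraction is statistically
indistinguishable from the random-placement null (all p > 0.05, as it
should be: copies were planted uniformly).

The family's divergence profile recovers the two planted amplification
episodes:

```r
report$profiles$Nbh1$histogram
```

```
divergence histogram: 55 pairs in 6 bins of 0.02; 2 peak(s)
  peak at 0.010 (prominence 10)
  peak at 0.090 (prominence 24)
```

— one recent burst (pairwise distances near 0) and one older burst at
divergence ≈ 0.08, matching the simulated levels.

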