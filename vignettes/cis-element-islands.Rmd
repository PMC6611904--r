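---
title: "From promoter element to chromatin mark: the cismark methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From promoter element to chromatin mark: the cismark methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismark)
```

`cismark` asks a composite question of a genome: do the genes whose
promoters carry a short cis-element, and which respond when the
element's reader is knocked down, preferentially carry a broad gene-body
chromatin mark (H3K36me3)? This vignette explains each method, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open. Nothing here reports an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates

Internally every interval is 0-based, half-open — the convention of BED
and bedGraph. User-facing promoter coordinates follow the convention
molecular biologists print: position +1 is the TSS base, the base
immediately 5′ of it is −1, and there is no position 0. For a 7-bp
element whose 5′-most base lies 989 bp upstream of the TSS, the reported
span is −989 to −983. The conversion happens only at the reporting
boundary (`scan_pattern`); all arithmetic below it stays half-open.

For a plus-strand gene the TSS is `start` and the TES is `end − 1`; a
minus-strand gene mirrors this. Promoters (`extract_promoter`, default
2000 bp) are returned 5′→3′ in gene orientation, reverse-complemented
for minus-strand genes, truncated at chromosome edges with the actual
length reported.

## Element scanning

`scan_pattern` reports every occurrence — overlapping ones included — of
the pattern and, by default, of its reverse complement
(`both_strands = TRUE`). Strandedness of the original genome screen for
the CGGAAAT element is not decidable from published numbers alone, so
the flag is explicit and recorded in outputs; the default scans both
orientations because a double-stranded binding site has no preferred
strand a priori. IUPAC ambiguity codes in the *pattern* match their
expansion sets; ambiguity letters in the *subject* never match — the
conservative reading, since an N in an assembly is absence of evidence.
Matching is delegated to `Biostrings::matchPattern`; the test suite
checks it against a naive all-positions substring scan. A gene belongs
to the element set iff its promoter has ≥ 1 hit.

## Island calling

H3K36me3 forms broad domains, so the caller is SICER-like rather than a
narrow-peak model: fixed `W = 200` bp windows, gaps up to `G = 200` bp
bridged, island FDR < 10⁻³ and ChIP/input fold ≥ 2 — the standard broad
H3K36me3 parameter set, kept as defaults. The original SICER background
model (the random-reads island-score distribution) is replaced by a
fully specified deterministic scheme, labelled `sicer-like` in output
metadata:

1. integer read counts per window for ChIP and input (coverage mass /
   read length);
2. scale factor `s` = ChIP library size / input library size;
3. window `i` eligible iff `P(Pois(λᵢ) ≥ chipᵢ) < p_window` with
   `λᵢ = s · max(inputᵢ, m̄)`, `m̄` the genome-wide mean input count per
   window (`p_window` defaults to 0.1; it only gates candidacy, the
   island-level FDR does the inference);
4. maximal eligible runs merged, bridging ineligible runs ≤ `G`;
5. per island, `fold = (chip/chip_lib) / ((input + 1)/input_lib)` (the
   +1 pseudocount prevents division by zero and is recorded in output)
   and `p = P(Pois(s · max(input, m̄ · n_win)) ≥ chip)`;
6. Benjamini–Hochberg across islands; significant iff `q < fdr` and
   `fold ≥ min_fold`.

The genome-wide floor `m̄` appears **twice**, and the island-level use
is load-bearing: without it, a window where the input happens to be low
while the ChIP happens to be high receives a vanishing Poisson p from
its own sparse input, and the null (ChIP ≡ input in distribution) emits
confidently significant islands. With the floor, null simulations at
depth 20 on 2 Mb produce significant islands in at most a run or two in
twenty (checked in the test suite). The input normalisation constant
for the fold filter is not published; scaling by library sizes is our
substitute and is stated in the output metadata.

A gene is *H3K36me3-enriched* when ≥ 1 significant island overlaps, by
at least 1 bp, the strand-aware union of its 1-kb upstream region and
gene body — `[TSS − 1000, TES]` in gene orientation.

## Metagene profiles

Each gene is mapped onto 900 bins: a 3-kb upstream flank in 300 fixed
10-bp bins, the gene body scaled to 300 equal-fraction bins, and a 3-kb
downstream flank in 300 bins, always oriented so bin 1 is 3 kb upstream
of the TSS. Body bins use a cumulative-rounding partition (base *j* of
an *L*-bp body lands in bin ⌊300·j/L⌋), so every base belongs to exactly
one bin; bodies shorter than 300 bp leave some bins empty, which become
missing values and are excluded from aggregates. Flank bins truncated
by a chromosome edge are missing, not zero-padded, so truncation cannot
masquerade as signal. One published description anchors both flanks at
the TTS while the accompanying axis runs TSS→TTS; we anchor the upstream
flank at the TSS and the downstream flank at the TES, matching the axis.

"Calibrated to the input" is implemented as a per-bin ratio
`(RPKM_chip + c) / (RPKM_input + c)` with pseudocount `c = 1`
(configurable). A ratio keeps the no-enrichment expectation near 1 and
tolerates sparse bins; subtraction or ChIP-only RPKM are plausible
alternative readings, which is why `pseudocount` and the ratio operation
sit behind one function (`gene_profile`) rather than being scattered.
Note one honest wrinkle the worked example shows: RPKM uses the total
library size, so a large enriched fraction inflates the ChIP library
and pushes the *background* ratio below 1 (a composition effect); the
island caller is unaffected because its scale factor `s` is shared
genome-wide.

Group contrasts reduce each gene to the mean over its 300 body bins
(`tss_downstream_signal`) and compare groups with the two-sample
Kolmogorov–Smirnov test (`stats::ks.test`, asymptotic two-sided p). The
test suite checks D against a brute ECDF scan and the p-value against a
10,000-replicate permutation reference.

## DEG filtering and the resampling null

Down-regulated means log₂FC < −log₂(1.5) **and** adjusted p < 0.05,
both strict, matching the published "more than 1.5 fold-change"
wording; a gene at exactly 1.5-fold is excluded.

Candidates are element ∩ down-regulated genes; the observed statistic
is how many are enriched. The null draws `n_sets` (default 1000) sets
of |candidates| genes, each uniformly *without* replacement from the
down-regulated genes lacking the element, independently across sets.
Two summaries are reported side by side: the raw empirical exceedance
percentage 100 · #{sets ≥ observed}/B (the convention under which 26
qualifying sets of 1000 print as 2.6%), and the never-zero estimator
(b + 1)/(B + 1) used for testing. The tail direction defaults to ≥
("the gene number over 100" is ambiguous between > and ≥; the flag is
explicit). The analytic comparator `hypergeom_tail` —
P(X ≥ observed), X ~ Hypergeom(N, K, k) via `stats::phyper` — is always
reported next to the Monte-Carlo percentage without asserting the two
are the same quantity.

**A calibration caveat.** The observed count has binomial-like variance
k·p(1−p), while the resampled null is hypergeometric with variance
smaller by (N − k)/(N − 1). When the candidate set is a sizable fraction
of the pool, the test is therefore anti-conservative. The published
geometry is safely sparse (132 candidates against a pool of 1731,
k/N ≈ 0.08); the calibration study in the test suite (200 null
replicates, 300 genes, B = 500) uses a comparable sparsity and confirms
a type-I error statistically compatible with α = 0.05. Users with
candidate sets approaching their pool size should rely on the
hypergeometric tail only as a descriptive, not inferential, quantity.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
standard study conditions used throughout the tests and the acceptance
script:

| parameter | default | why |
|---|---|---|
| `n_genes`, `chrom_len` | 500 on 2 Mb | a desk-scale genome the full pipeline traverses in seconds |
| `gene_len_range` | 500–3000 bp | typical plant gene-body lengths |
| `intergenic_len_range` | 1500–2700 bp | min gap > 1-kb gene extension + worst-case island overhang (one partial window + one bridged chance window ≈ 600 bp), so a true island cannot legitimately reach a neighbour's annotation region; still well below real rice intergenic spacing |
| `element_rate` | 0.2 | elements in a minority of promoters, enough genes in every downstream set |
| `enrich_fold`, `depth` | 8, 20 | a clear but not caricatural ChIP signal over Poisson noise |
| `enrich_len`, `enrich_anchor` | 1000 bp at the TSS | the 5′ bias of plant H3K36me3; `"tes"` plants the animal-style 3′ bias for contrast |
| `p_down_element`, `p_down_no_element` | 0.4, 0.15 | an association the integration stage should detect, while keeping the non-element down-regulated pool larger than the candidate set — as in real knockdown data, where indirect targets dominate |
| `read_length` | 50 bp | bookkeeping constant for library sizes |

Sequences are uniform-random ACGT. Spontaneous occurrences of the
element inside promoter windows are mutated away
(`reject_spontaneous = TRUE`), and planted copies are placed at uniform
TSS-relative starts in [−2000, −8] at positions disjoint from every
*other* gene's promoter window — together these make the element truth
set exact, so `genes_with_element` can be scored for identity rather
than mere similarity. Disabling rejection restores spontaneous hits for
realism studies. ChIP and input counts are Poisson per 200-bp window
(enriched windows at `fold × depth`, partial overlaps interpolated),
emitted as bedGraph-style coverage whose per-window mass recovers the
counts exactly.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: mappability and GC bias, fragment-length
effects (reads enter as midpoint-style coverage mass), replicate
structure, promoter sequence composition (real promoters are not
uniform-random), and expression-level confounding between H3K36me3 and
DEG status. The genome-scale published counts (3809 element genes, 1863
down-regulated, 16,046 enriched) require the rice genome and the
deposited sequencing data and are deliberately out of desk-scale scope;
the pipeline reproduces the *procedures* and their worked arithmetic
(100/132 → 75.8%; 26/1000 → 2.6%), not those counts.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed; `run_pipeline` derives
per-stage seeds from one master seed with a stage-name-keyed hash
(`derive_seed`), so stages are independently reproducible and a repeated
run is byte-identical (manifest timestamp aside). The test suite runs
the recovery study at the full default scale (500 genes, 2 Mb), the
null-calibration study at 300 genes with B = 500 over 200 replicates,
and oracle-equivalence checks at the sizes named above — sizes chosen
so the whole suite stays in the minutes range on one core while leaving
the statistical assertions enough resolution to fail when the code is
wrong.

## Known limitations

- The island caller's Poisson/BH scheme is a deterministic stand-in for
  SICER's island-score background model; W/G/FDR/fold semantics match,
  score arithmetic does not.
- Coverage input is bedGraph only (BAM/bigWig are out of scope); read
  BED files should be reduced to midpoint coverage upstream.
- The resampling test's calibration degrades as |candidates| approaches
  the pool size (see above).
- One element pattern per invocation; no PWM scoring or motif
  discovery.
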