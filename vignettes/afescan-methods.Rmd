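---
title: "Predicting quorum-sensing regulator binding sites from palindromic operator models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting quorum-sensing regulator binding sites from palindromic operator models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afescan)
```

## The problem

LuxR-family transcription factors of acyl-homoserine-lactone quorum sensing
bind short palindromic operators ("lux-boxes") upstream of their target
genes. In *Acidithiobacillus ferrooxidans* the known operator upstream of the
AHL synthase gene — the afe-box — is unusually modular: an 18–20 bp lux-box-
like core sits at the centre of a 30 bp palindrome whose two halves are
themselves palindromic and inverted repeats of each other. `afescan`
exploits that modularity to predict candidate binding sites genome-wide:
rather than aligning poorly conserved known lux-boxes, it derives training
alignments *combinatorially* from the operator itself, holding the
palindromic arms fixed and enumerating every possible sequence at the
non-palindromic positions.

## Palindrome templates and profile models

Five fixed-length templates cover the modular structure:

| id   | model | set | pattern |
|------|-------|-----|---------|
| SP13 | A | SP | `TGACANNNTGTCA` |
| SP15 | B | SP | `YTGACANNNTGTCAR` |
| MP18 | C | MP | `GCTGTCAANNTTGACAGC` |
| MP20 | D | MP | `AGCTGTCAANNTTGACAGCT` |
| LP30 | E | LP | `TGACAAGCTGTCANNNNTGACAGCTTGTCA` |

`enumerate_variants()` expands `N` to the four bases and `Y`/`R` to the
pyrimidines/purines, giving 64, 256, 16, 16 and 256 training sequences
respectively. For SP15 we enumerate all 64 central trinucleotides (times the
`Y`/`R` flanks, 256 sequences): restricting the centre to homopolymer 3-mers
would give only 16 alignments, which is inconsistent with the 256-sequence
alignment size the design calls for, so the full enumeration is used. The
assignment of letters within the pairs (A vs B, C vs D) is arbitrary: A/B
and C/D are pooled into the SP and MP sets downstream, so nothing depends on
it.

Because these alignments are fixed-length and ungapped, a hidden Markov
model over them has degenerate insert/delete states. `build_profile()`
therefore builds an ungapped position-wise profile: emission
$e_{i}(b) = (c_{i}(b) + \alpha)/(n + 4\alpha)$ with pseudocount $\alpha = 1$
per base, and a window score in bits

$$S(w) = \sum_i \log_2 \frac{e_i(w_i)}{b(w_i)},$$

with the background $b$ estimated from the scanned genome's mononucleotide
frequencies, strand-symmetrised (A with T, C with G). This is a
re-implementation of the scanning idea, not an emulation of any particular
HMM package's bit scores. Ambiguous genome bases (`N`) contribute 0 bits.

## Genome scanning

`scan_genome()` scores every window on both strands and keeps a maximal set
of hits with score at or above the threshold, chosen greedily by descending
score; a window overlapping an already-accepted hit of the same model is
discarded regardless of strand. Ties are broken by position and then by
strand, with scores quantised to $10^{-6}$ bits for the ordering so that the
two strands of a perfect palindrome — which tie mathematically but not
bit-for-bit in floating point — collapse deterministically to a single
forward-strand hit.

The original analysis' scanning threshold is not recoverable, so the default
is 0 bits (a window must look more like the model than like background) and
is configurable; `calibrate_threshold()` optionally sets it to the
$(1-q)$-quantile ($q = 10^{-5}$ by default) of window scores on a surrogate
sequence simulated from a first-order Markov fit of the genome's
dinucleotide transition frequencies. Consequently, absolute hit counts are
not comparable with any particular published run; the package's accuracy
claims are made on synthetic chromosomes with known ground truth.

## From hits to a candidate regulon

* **PBSs** (`group_hits()`): hits overlapping by at least 1 bp on either
  strand are merged single-linkage; each merged fragment is one predicted
  binding site carrying the union of its members' set labels (A/B → SP,
  C/D → MP, E → LP). Adjacent-but-not-overlapping hits stay separate.
* **Context** (`compute_intergenic()`, `classify_pbs()`): intergenic (IG)
  regions are the complement of the CDS union; an IG region is *sense* when
  at least one flanking gene reads away from it, i.e. its start codon abuts
  the region — the gap between converging stop codons is not sense. Because
  IG regions are by construction adjacent to their flanking CDS, "start
  codon in proximity" reduces to a strand test on the flanks. Type I PBSs
  overlap a sense IG region by ≥ 1 bp; Type II PBSs have their *centre*
  within the strand-aware window −200…+50 bp around some start codon
  without being Type I; Type III is everything else. The interval rule for
  Type I and the centre rule for Type II reflect the two idioms the
  classification combines (region membership vs distance-to-start), and the
  window is configurable.
* **Density**: PBSs per megabase divide each type's count by the bases
  available to it — total IG bases for Type I, unioned start-codon-zone
  bases minus IG bases for Type II, and the remainder of the genome for
  Type III; the three denominators always sum to the genome length. On
  gene-sparse toy genomes the Type II denominator can be non-positive; it is
  then reported as `NA` rather than a misleading number.
* **Promoter gate** (`predict_sigma70()`, `select_candidates()`): every
  Type I PBS is kept. A Type II PBS is kept only if a σ70-like promoter is
  predicted within the PBS ± 100 bp window. The predictor is this package's
  own consensus-PWM substitute for closed-source promoter tools: literature
  consensus-frequency PWMs anchored on TTGACA/TATAAT, spacer 15–19 bp,
  combined log-odds threshold defaulting to 60% of the maximum achievable
  score. Its output is labelled "σ70-like predictions". Type III PBSs are
  always discarded.

## Motif refinement

`discover_motif()` re-implements ZOOPS (zero-or-one occurrence per sequence)
EM motif discovery over both strands on the selected PBSs plus 80 bp flanks.
Starting points are drawn deterministically from the sorted pool of distinct
subsequence windows (the whole pool up to 5000 words, a seed-controlled
subsample beyond that), ranked by a one-pass ZOOPS likelihood, and the best
is run to convergence (relative change < $10^{-6}$, at most 500 iterations). The M-step smooths counts with
a 0.25 pseudocount, so the quantity EM keeps monotone is the MAP objective
(data LLR plus the Dirichlet smoothing term); the model records that
objective trace alongside the final data LLR. With a width range, each
width is fitted and a BIC-style penalty ($\mathrm{LLR} - \tfrac{3}{2} w
\log_2 n$) selects the winner; the default candidate widths are the
palindrome-module widths 13, 15, 18, 20, 30.

`mast_scan()` rescans a database of all intergenic regions with the
discovered PSSM: the per-position p-value comes from the exact distribution
of the discretised score under the background
(`exact_score_distribution()`, dynamic-programming convolution at 0.01-bit
granularity), the sequence p-value uses the independence approximation
$1-(1-p)^m$ over the $m$ scored windows of both strands, and the e-value
multiplies by the database size; occurrences with e-value below 10 are
reported. `consensus_and_logo()` summarises aligned sites by plurality
consensus (ties become IUPAC codes) and per-column information content
$2 + \sum_b f_b \log_2 f_b$ bits.

## The synthetic benchmark

`simulate_genome()` emulates the kind of chromosome the method targets: one
contig (default 100 kb — large enough for ~90 genes and stable statistics,
small enough to keep a full multi-seed benchmark in seconds), i.i.d.
background at 58% GC, non-overlapping CDS of 650–1400 bp packed at
bacterial density (60–160 bp gaps) with strands drawn to realise a
diverging/converging/tandem arrangement mix, and operator instances sampled
from the template emission models planted at recorded positions in three
contexts: sense IG regions, deep coding sequence (≥ 280 bp from the start,
so that planted coding instances are unambiguously Type III), and
convergent IG regions. A 40 bp clearance between planted instances prevents
chance hit chains from bridging two plants. The `sharpness` parameter
interpolates between the template profile (1, "consensus-sharp") and the
background (0) to create easy and hard recovery regimes; the standard
benchmark plants 30 consensus-sharp instances.

What the simulator does *not* emulate: codon usage and reading-frame
structure (genes are background sequence with terminal start/stop codons),
operons, RNA genes, repeats, and compositional heterogeneity (an optional
first-order Markov background exists for robustness tests). Passing the
benchmark therefore demonstrates correctness of the scanning, merging and
classification machinery under the stated noise model — not performance on
a real chromosome, where the unknown scan threshold and genome composition
dominate.

`benchmark_recovery()` scores a run against the truth table: an instance is
recovered when a PBS overlaps at least half of it; a false merge is a PBS
that swallows two disjoint plants; classification accuracy compares the
recovering PBS's context type with the instance's expected type (itself
derived by applying the classification rules to the planted interval, which
keeps the two rule implementations consistent by construction).

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere in the R API and reports;
  BED exports are converted to 0-based half-open.
* Scan-score ties: quantised ordering as above; deterministic radix sort.
* Zero-width or short contigs yield empty hit lists, not errors; database
  sequences shorter than the motif are skipped with a notice.
* `density_by_type()` reports `NA` for non-positive denominators.
* All-identical motif-discovery input converges to a (pseudocount-bounded)
  one-hot motif.
* Every stochastic step (simulation, EM starts, calibration surrogate) is
  seeded explicitly; identical configurations reproduce byte-identical
  artifacts.

## Problem sizes used in the shipped checks

The test-suite and acceptance benchmarks use 2 kb sequences for the
scanner/oracle comparison (20 replicates, all five models), the 100-kb
standard benchmark over 5 seeds for recovery, 20 × 200 bp planted sets over
3 seeds for motif discovery, and widths ≤ 5 for the exhaustive score-
distribution check — sizes chosen so the full suite exercises every stage
end-to-end in a few minutes on one core.

## Known limitations

* The scanner is ungapped by design; operators with indels relative to the
  templates are not modelled.
* The σ70 predictor is a consensus-PWM heuristic, not a trained promoter
  model; its role is the positional gate and annotation, not promoter
  discovery.
* The MAST-like sequence p-value uses the independence approximation and a
  discretised score distribution; e-values are comparable within a run, not
  calibrated against any external tool.
* Absolute hit/PBS counts depend strongly on the configurable scan
  threshold and are not meaningful reproduction targets.
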