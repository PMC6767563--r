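---
title: "Methods: inferring an ECF sigma-factor regulon with ecfmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring an ECF sigma-factor regulon with ecfmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecfmap)
```

## The problem

Extracytoplasmic-function (ECF) sigma factors redirect RNA polymerase to a
dedicated promoter class, typically as part of a stress response. In
*Streptomyces coelicolor*, the ECF factor sigma-E coordinates the
cell-envelope stress response: its promoters carry a conserved −35 tetramer
(AAC-like) and a −10 pentamer (TC-bearing) separated by a weakly constrained
16–17 bp spacer. `ecfmap` implements the computational arc of a regulon
study for such a factor:

1. **Peak calling** — windowed enrichment of ChIP coverage over an input
   control identifies binding regions.
2. **Motif discovery** — a two-block Gibbs sampler finds the gapped
   promoter motif in the peak regions.
3. **PWM scanning** — position weight matrices built from validated
   promoters locate sites in upstream windows genome-wide.
4. **Dependence classification** — WT versus deletion-mutant induction
   time courses sort targets into Class I/II/III promoter dependence.
5. **Conservation** — reciprocal-best-hit orthologs plus upstream scanning
   across a genome panel yield a targets × species conservation matrix.

A seeded synthetic-data module generates inputs with the statistical
structure each stage assumes, so the whole pipeline is exercised and
benchmarked without downloads.

## Peak calling

Coverage is tiled in 25 bp windows. Each window's ChIP count is compared
with the control count by the exact conditional test for the ratio of two
Poisson rates: conditional on the window total $n = k_{chip} + k_{ctrl}$,
$k_{chip} \sim \mathrm{Binomial}(n, r/(1+r))$ under the null, with $r$ the
ChIP/control library-size ratio. We use this conditional form rather than
plugging the raw control count in as a Poisson mean because the plug-in
version ignores the control's own sampling noise and inflates the type I
error roughly tenfold at these depths; the conditional test is exact and
calibrated (its realised rate is at or slightly below nominal, from
discreteness). Defaults: window 25 bp, raw $P < 10^{-4}$ (no
multiple-testing correction, matching the original screen; Benjamini–
Hochberg is available behind `fdr = TRUE`), minimum 2-fold
library-normalised enrichment, significant windows merged when ≤ 25 bp
apart. Summit ties break by lower p-value, higher enrichment, then leftmost
coordinate. An all-zero control is refused with instructions to supply a
pseudo-flat control rather than silently inventing one.

## Two-block motif discovery

`gibbs_two_block()` is a one-occurrence-per-sequence (OOPS) Gibbs sampler
for a W-mer and w-mer separated by a gap in $[g_{min}, g_{max}]$, searched
on the forward strand only (defaults W = 4, w = 5, gap 16–17, 40
reinitialisations — the configuration under which the sigma-E promoter
motif was originally recovered). Each update withholds one sequence,
rebuilds pseudocounted count matrices (0.5 per cell) from the rest, and
samples that sequence's (start, gap) from the posterior proportional to the
product of position-specific odds versus the background times the gap-length
frequencies of the remaining sequences. The background defaults to the
empirical mononucleotide composition of the input: at ~72% GC a uniform
background would reward any GC-rich pattern.

Numerical choices worth knowing:

* **Scoring.** Motifs are ranked by total relative entropy (sum of
  per-column Kullback–Leibler divergences from the background, in bits);
  gap columns contribute nothing.
* **Convergence.** The stochastic phase stops after 10 sweeps without
  score improvement; a deterministic argmax sweep then runs to an
  assignment fixed point, so the reported optimum is reproducible
  bit-for-bit under a fixed seed.
* **Phase shifts.** Single-sequence moves cannot leave a "shift-locked"
  optimum in which every site is displaced by the same offset (e.g. all
  gaps one too long, the −10 column frame shifted by one). After the
  polish, a global move slides all sites (start ± 2, gap ± 1) together and
  keeps any improvement, iterating with the polish until neither helps.
* **Restarts.** The best of `restarts` random reinitialisations is
  returned; the score is monotone in the restart count by construction
  (later restarts reuse nothing from earlier ones, and the running
  maximum is kept).

When the pipeline extracts peak-flank sequences for the sampler it orients
each flank to the sense strand of the nearest gene for which the summit
lies upstream. A single forward-strand search then covers targets on both
genomic strands; the sampler itself never scans the reverse strand.

## Promoter PWMs and scanning

`build_pwm()` accumulates −35 and −10 count matrices over the supplied
promoters and converts them to probabilities with a 0.5 pseudocount.
**Spacer columns are score-neutral**: only the nine block columns carry
probabilities, so promoters with 16- and 17-bp spacers contribute
identically and the 16- and 17-spacer models (`PWM_19_16`, `PWM_19_17`
when built from the 19 validated sigma-E promoters) differ only in the gap
the scanner applies. This makes the published spacer normalization — one
base removed from, or added to, the non-conserved region — exact, with no
arbitrary choice of which spacer base to drop. A raw score is the summed
log2 odds of the block bases against the background (N scores at
background, i.e. contributes 0); the normalized score rescales it between
the worst and best possible sequences under the model. The six columns of
highest information content form the core (ties break 5′-first); for the
validated sigma-E set these are the three −35 positions A-A-C and the −10
positions T-C-T.

**Detection thresholds.** The tool the original conservation analysis used
is closed-source and its "sensitivity" parameters are not published, so the
package defines them operationally: `sensitivity` and `core_sensitivity`
are guaranteed recall levels on the PWM's *source* promoters. The
detection threshold is the empirical $(1-s)$ quantile of the source-site
scores — at the default $s = 1$, the weakest source promoter — applied to
both the full score and the core score. Two consequences follow by
construction rather than by tuning: every promoter the PWM was built from
is detectable (all 19 validated promoters self-detect), and specificity is
set by how tightly the training envelope excludes background. Exhaustive
enumeration over all $4^9$ block pairs at 72% GC gives a per-position
false-hit probability of $1.5 \times 10^{-4}$, i.e. ~95% of random 190-bp
upstream windows scan clean. An alternative definition in which
`core_sensitivity = 1` demands an exact consensus match at the six core
columns was considered and rejected: only three of the nine block columns
are perfectly conserved in the validated set, so that rule can recover at
most 15 of the 19 promoters the model was built from, contradicting the
observed behaviour of the original analysis.

**Candidate screening.** The original candidate list was assembled by a
manual screen for conservation of AAC (−35) and TC (−10) within 400 bp of
a start codon. `candidate_rule()` formalises it: the −35 must match AAC at
block positions 1–3 with ≤ 1 mismatch, and the −10 must contain TC
starting at position 3 or 4 with ≤ 1 mismatch. A stricter variant
requiring position 4 of the −35 to be C was rejected because many
published target promoters (e.g. the *mreB* promoter's AACG) violate it —
the published target table, not the regex, is the ground truth. The
screened window extends one full site span beyond the 400-bp distance
bound so a −10 element at exactly 400 bp is still found intact; retained
candidates always satisfy the distance bound, measured from the base 3′ of
the −10 pentamer to the first base of the start codon (the published
table's "distance to start codon" never states its measurement point; this
convention is applied consistently and is configurable). When a discovered
motif is supplied, stage-1 pattern matches are rescored with it and only
the best per peak–gene pair is kept.

## Dependence classification

Expression input is a per-gene log2 matrix over (strain ∈ {WT, ΔsigE}) ×
(0/30/60/90 min after induction), normalized by subtracting each gene's own
median (idempotent, and removes gene-wise constants so classification is
shift-invariant). Induction is the maximal rise over the time-zero value.
The qualitative published scheme — Class I: one promoter, completely
sigma-E-dependent; Class II: one promoter, partially dependent; Class III:
multiple promoters, at least one (partially) dependent — is made
operational with explicit thresholds, all exposed in
`class_thresholds()`:

* induced: WT induction ≥ 1 log2 (two-fold);
* complete dependence: mutant induction ≤ 0.5 log2;
* no dependence: mutant induction within 0.1 log2 of the WT induction
  (the 0.1 band keeps a mutant rise of 1.8 against a WT rise of 2.0 in
  the "partial" band, which is where the subtlest real Class III targets
  sit);
* partial: everything between.

The number of promoters per gene is experimental evidence (transcript
mapping), supplied as an annotation table, never inferred. Agreement with
the published labels on real data is not asserted anywhere — only recovery
of planted labels on synthetic data. At noise σ = 0.3 log2 the max-based
induction statistic flips roughly a fifth of Class I genes to Class II
(their mutant's noise maximum crosses the 0.5 bound) and sends a similar
share of borderline Class III genes to "unclassified"; overall per-gene
label accuracy across a realistic matrix (≈ 19% targets) is ~95%. These
confusions are inherent to the estimator-plus-threshold combination, not
to the noise level alone, and they only cross adjacent class boundaries.

## Conservation across a genome panel

Orthologs are mapped by reciprocal best hit: Smith–Waterman local
alignment (BLOSUM62, affine gaps 11/1 — BLAST-style constants) in both
directions, a pair kept iff mutual-best with identity ≥ 30% over the
alignment and coverage ≥ 50% of the shorter sequence. These thresholds are
conventional, not published values, and are config-exposed; a precomputed
ortholog table can be supplied instead for large proteomes. The alignment
engine is `Biostrings::pairwiseAlignment` behind the module surface; tests
verify it against an independently written affine-gap dynamic program.

For each (target, species) cell: no ortholog → `no_ortholog` (black in the
published rendering); else the ortholog's 10–200 bp upstream window is
scanned on its sense strand with both spacer PWMs, recording the best
normalized score (`site`, the colour gradient) or `no_site` (grey).
`conserved_targets()` applies the ≥ 9-of-19 genome rule (both numbers
configurable). Conservation counts are monotone non-increasing in the
identity/coverage thresholds.

## The synthetic-data generators

`sim_config()` fixes the study conditions the generators emulate; all
randomness derives from its seed (plus a fixed offset per generator), so
every output is byte-reproducible.

* **Genome** — one contig of i.i.d. background at 72% GC (Streptomyces-
  like); genes alternate strands, each with its own 600-bp upstream
  intergenic region; no codon structure inside genes (motif discovery does
  not depend on it). Target genes receive a site sampled column-wise from
  the validated-promoter matrix (pseudocount-free frequencies), spacer
  drawn from the background, planted at a uniform distance 10–400 bp.
  Column-independent sampling occasionally emits block combinations weaker
  than every real validated promoter (~6% of draws); since planted sites
  stand for *functional* promoters, emission is rejection-conditioned on
  the detection envelope (score at least the weakest validated promoter's)
  by default — `functional_only = FALSE` disables this.
* **ChIP** — control Poisson(depth) everywhere; ChIP Poisson(depth ×
  enrichment) within 150 bp of each planted site; defaults depth 5,
  enrichment 10.
* **Expression** — Normal(0,1) baselines; a step rise at 30 min held
  through 90 min; Class I: WT Δ ~ U(2,4), mutant flat; Class II: mutant
  scaled by U(0.2, 0.7); Class III: mutant lower by U(0.3, 0.8) with 2–4
  promoters; Gaussian noise σ = 0.3 everywhere. Default class mix
  5% / 10% / 4% / 81% non-target — targets are a small minority on a
  genome-wide array, and the I:II:III ratio mirrors the validated set's
  5:10:4.
* **Species family** — per-base substitutions at the configured rate
  (default 0.1), sparing retained planted sites (the object under study);
  planted sites randomized with probability 0.2; genes deleted (with
  their sites, from annotation and proteome) with probability 0.1.
  Proteins are random 20-letter sequences mutated at the amino-acid
  level — translating simulated ORFs would add stop-codon bookkeeping
  without changing anything the ortholog machinery sees.

What passing on these generators does *not* show: real coverage has
non-uniform shearing and mappability structure the Poisson model lacks;
real upstream regions contain other promoters and regulatory elements, so
real-genome scans face a harder specificity problem than i.i.d.
background; real induction curves are not step functions; and real
orthology involves paralogy, synteny and domain shuffling far beyond
point-mutated sequences. The package therefore validates the machinery and
its calibration, not biological discovery performance.

## Problem sizes used by the test-suite benchmarks

The shipped benchmarks use deliberately desk-scale conditions, chosen once:
motif recovery over 20 seeded replicates of 30 × 250-bp sequences with 10
reinitialisations per replicate (the planted signal sits at consensus
strength, where extra restarts only guard against rare local optima —
restart-count monotonicity is tested separately); peak-caller calibration
on 10⁶ bp of null coverage; classifier recovery on 200-gene matrices, 20
seeds; conservation on families of 8 species × 12 targets with 120-residue
proteins, 10 seeds, with planting distances 10–160 bp so every retained
site lies inside the scanned window; and one full end-to-end run at the
default 40-gene / 20-target genome. The demo genome plants ~20 sites
because two-block discovery from only ~12 peak regions overfits: with so
few sequences an AT-rich coincidental motif can outscore the planted one
in a GC-rich background — the original screen had ~200 peaks.

## Known limitations

* The equivalence of `gibbs_two_block` with the original closed-source
  two-block sampler is not claimed; relative-entropy scoring and the OOPS
  model are this package's own stand-ins, and the "non-occurrence
  penalty" of the original scanning tool has no analogue here.
* Peak calling is a deliberately simple windowed Poisson-ratio screen: no
  fragment-size modelling, duplicate handling or local background
  estimation.
* Scanning never calls reverse-strand sites within a gene's upstream
  window, matching the forward-strand convention of the original search.
* Whether the original scan scored spacer columns is unknown; this
  package's models are spacer-neutral by design (a full-width variant was
  considered and dropped — it reintroduces the arbitrary choice the
  normalization exists to avoid).
* Reproducing the published external-genome numbers (recovery of ChIP
  targets, 21-of-91 conservation, the *mreB* promoter in all 19 regulons)
  requires the real chromosome sequences and annotations, which are not
  shipped; the corresponding acceptance check documents how to supply
  them.
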