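---
title: "Predicting aptamers and protein-aptamer interactions from sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting aptamers and protein-aptamer interactions from sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaboost)
```

# The problem

Aptamers are short single-stranded DNA or RNA oligonucleotides that fold
into three-dimensional structures binding a specific target — here,
proteins — with high affinity. Discovering them experimentally (SELEX) is
slow, so two *in silico* questions matter to practitioners: given a
nucleotide sequence, is it likely to be an aptamer at all; and given a
protein and a candidate aptamer, are they likely to interact? `aptaboost`
treats both as binary classification on sequence-derived physicochemical
features, with a boosted ensemble of random forests as the classifier.

# Feature encodings

Proteins are encoded by five composable descriptors (156 features under
the defaults):

* **AAC** — the 20 amino-acid frequencies.
* **PseAAC** (type 1) — the 20 frequencies augmented with $\lambda$
  sequence-order correlation factors. The correlation between residues
  $R_i$ and $R_{i+j}$ is the mean squared difference of their
  standardized hydrophobicity, hydrophilicity and side-chain mass;
  $\theta_j$ averages it over all pairs at separation $j$, and the full
  vector $(f_1, \dots, f_{20}, w\theta_1, \dots, w\theta_\lambda)$ is
  normalized to sum to one. Defaults $\lambda = 30$, $w = 0.05$ — the
  conventional reference values; both matter mainly through the feature
  count and the relative weight of order information. Property scales are
  standardized to mean 0 and (population) variance 1 over the 20 letters
  before use.
* **GAAC** — frequencies of five physicochemical groups (aliphatic,
  aromatic, positively/negatively charged, uncharged).
* **CTD composition** — for seven attributes (hydrophobicity, van der
  Waals volume, polarity, polarizability, charge, secondary structure,
  solvent accessibility), the frequencies of three attribute classes.
  The paper-facing descriptor family also defines Transition and
  Distribution parts; they are implemented (`encodeCTDT()`,
  `encodeCTDD()`) but kept out of the default feature set, since only the
  Composition part is defined by the model's equations. "Solubility" is
  mapped to the conventional seventh CTD attribute, solvent
  accessibility.
* **SOCN** — sequence-order-coupling numbers
  $f_d = \sum_i d(R_i, R_{i+d})^2$, $d = 1 \dots \lambda$ (default 30),
  over two 20×20 distance matrices. The first is a composite
  physicochemical matrix built by this package (Euclidean distance on the
  standardized hydrophobicity/hydrophilicity/side-chain-mass triple,
  scaled to a maximum of 1); the second is the Grantham chemical
  distance matrix, computed from Grantham's published
  composition/polarity/volume values and formula, with the scale factor
  chosen so the mean off-diagonal distance is 100 (spot-checked against
  published entries: S–R 110, L–I 5, W–C 215).

Nucleotide sequences are encoded by three descriptors (140 features under
the defaults): **NAC** (four base frequencies, U sharing the T slot),
**PseKNC** ($4^k$ k-tuple frequencies plus $\lambda$ correlation factors
from dinucleotide properties; defaults $k = 2$, $\lambda = 10$,
$w = 0.05$), and **NMBAC**, the normalized Moreau–Broto autocorrelation
$AC(p, d) = \frac{1}{L-1-d} \sum_i \tilde P_p(i) \tilde P_p(i+d)$ of each
standardized dinucleotide property profile at lags $1 \dots 10$.

The eleven dinucleotide properties (shift, slide, rise, tilt, roll,
twist, stacking energy, entropy, enthalpy, free energy, hydrophilicity)
ship as separate DNA and RNA tables; that the two tables differ is the
reason DNA and RNA inputs are never mixed in one run. One published list
of these properties prints "twist" twice; the eleventh property here is
enthalpy, the standard companion of entropy and free energy in
nearest-neighbor thermodynamics. The thermodynamic rows follow published
nearest-neighbor parameter sets (the unified DNA set; the Watson–Crick
RNA set, with entropy derived from enthalpy and free energy); the
geometric, stacking and hydrophilicity rows are representative values
compiled for this package, and the resource files are marked `synthetic`
accordingly. Every property is standardized across the 16 dinucleotides
before any encoder touches it, so features depend only on the relative
ordering of the table values — which is why representative values are
acceptable there.

Sequences with letters outside the strict alphabets are rejected rather
than skipped: silently dropping residues would change the length $N$ and
corrupt every frequency. Records containing `B`, `N`, or a mixture of `U`
and `T` are removed up front by `filterProblematic()`, the same rule the
interaction dataset is cleaned with. The filter targets nucleotide
records; whether it should also apply to proteins (where `B` is the
ambiguous Asx code) is not settled by the sources, so protein filtering
is available behind `includeProtein = TRUE` but off by default.

# Class imbalance: SMOTE on the training partition only

Interaction datasets are heavily imbalanced (three negatives per
positive). `smote()` raises the minority class to the majority count by
interpolating between each minority sample and one of its $k = 5$
nearest minority neighbors: $x_\text{new} = x + u (x_{nn} - x)$,
$u \sim U(0,1)$. Every synthetic row is therefore a convex combination of
two real minority rows and stays inside the minority bounding box.
Synthetic rows carry a provenance flag, and `evaluateModel()` refuses any
dataset containing one — making train-only balancing a structural
property of the pipeline, not a convention. Balancing 561 positives
against 1682 negatives adds 1121 synthetic rows for a fully balanced
1682/1682; the source experiment reports 1681/1682, one short of full
balance, a discrepancy we do not reproduce. Distances are Euclidean on
the raw feature scale; the encoders already produce comparable-magnitude
values except for SOCN (which is scale-free within itself), and no
internal re-standardization is applied.

# The classifier

`fitBoostedForest()` is discrete AdaBoost with random forests as weak
learners. Sample weights start uniform; round $t$ fits a forest, computes
the weighted training error $\varepsilon_t$, sets
$\alpha_t = \eta \cdot \tfrac12 \ln\frac{1-\varepsilon_t}{\varepsilon_t}$
(the learning rate $\eta$ multiplies outside the log), multiplies the
weights of misclassified samples by $e^{\alpha_t}$ and renormalizes.
Defaults follow the published operating point: forests of 10 trees with
maximum depth 150, $T = 300$ rounds, $\eta = 0.75$.

Design points that were genuinely open:

* **Weight-aware base learners.** Forests are trained on bootstrap draws
  sampled proportionally to the boosting weights, which keeps the
  contract independent of any particular forest library's support for
  case weights.
* **Early stopping.** $\varepsilon_t = 0$ caps $\alpha_t$ at $\ln 10^{10}$
  instead of $\infty$; $\varepsilon_t \ge 0.5$ retains the round with
  $\alpha_t$ clamped at 0 (exactly 0 at $\varepsilon_t = 0.5$) and stops,
  so a useless round is recorded but never harmful.
* **Score aggregation.** The reported score is the $\alpha$-weighted mean
  of the base forests' positive-class probabilities, bounded in $[0,1]$
  and monotone in each of them; the classical hard-vote sign rule is
  available as `type = "vote"` and agrees with thresholding the vote
  score at one half.

Decisions use an inclusive threshold — "yes" iff score ≥ threshold —
with defaults 0.44 for pair prediction and 0.48 for aptamer prediction,
both configurable. A grid search over a validation split can be used to
re-tune the threshold for other data; no automatic tuning is built in
because the underlying simulation protocol for the published values is
not specified.

# Secondary-structure screening and the negative aptamer set

Aptamer prediction needs negatives. Following the construction in which
random sequences that do not conform to the structural pattern of
aptamers become the negative class, `generateNegatives()` draws target
lengths from the positive set's empirical length distribution, generates
candidates with bases i.i.d. from the positives' mononucleotide
frequencies, folds each candidate, and keeps those that are *not*
aptamer-like. Stratifying by length first (rather than rejecting over a
pooled candidate stream) is essential: the probability of failing the
screen varies strongly with length, and pooled rejection would skew the
negative lengths away from the positives'.

Folding uses a pluggable engine. RNAfold-style text output (dot-bracket
plus energy) can be read with `readViennaStructures()`; the built-in
engine `nussinovFold()` is a base-pair-maximization dynamic program
(minimum hairpin size 3; pairs A–U/T, G–C and the G–U/T wobble, so DNA
folds under the T≡U rules) whose pseudo-energy is simply `-pairCount` —
a structural score, **not** a thermodynamic minimum free energy.
Pseudoknots are out of scope: crossing brackets are rejected, and all
statistics operate on nested structures, a known limitation shared with
the thermodynamic engines this format comes from.

`parseDotBracket()` derives the screening statistics: pair count, stems
(maximal runs of stacked pairs), hairpin loops, bulges (one-sided gaps),
internal loops (two-sided), unpaired fraction and energy density
(energy/length). `aptamerLikeness()` then calls a structure aptamer-like
iff energy density ≤ −0.30 per nt, unpaired fraction ≤ 0.38, at least one
hairpin, and a longest stem of ≥ 4 pairs. These defaults are calibrated
to the pseudo-energy scale of the built-in folder, not taken from the
source text (which gives only qualitative criteria): under base-pair
maximization, random sequences concentrate near density −0.35/nt with
~28% unpaired at lengths ≥ 60 nt, so thresholds must sit inside that bulk
for both outcomes — aptamer-like and not — to be reachable at every
aptamer-typical length. With a thermodynamic engine the energy-density
cut-off should be rescaled to kcal/mol. All four values are configurable
and surfaced in `screeningThresholds()`.

# The synthetic data generator

Fixtures are generated in code, seeded, at the scales the tests need.

* **Lengths.** `sampleAptamerLengths()` fixes the aptamer length
  distribution: 80% of mass in 30–80 nt, modal length 40 nt with
  secondary peaks at 30, 50 and 80 nt, and the remaining 20% spread over
  the SELEX-typical flanks 20–29 and 81–100 nt.
* **Positive aptamers.** `makeAptamerBenchmark()` constructs stem-loops:
  a random sequence with an embedded inverted repeat (stem fraction
  25–40% of the length, loop 3–8 nt), screened to pass
  `aptamerLikeness()`. This emulates the one property of real aptamers
  the screen can see — robust folding — while preserving the length
  distribution exactly (the target length is fixed before construction).
* **Pairs.** `plantedPairDataset()` plants a compositional signal:
  sequences of positive pairs are drawn from letter distributions
  proportional to $e^{\text{shift} \cdot t}$ for a fixed alternating tilt
  vector $t$, negatives from the untilted distributions. `shift = 0` is
  an exact null; the default `shift = 0.5` produces clear separation
  through any composition-sensitive encoder.
* **Benchmark tables.** `makeInteractionBenchmark()` emulates the shape
  of the published interaction benchmark: a train partition that holds
  exactly 561 positive and 1682 negative clean pairs and a test partition
  with 143/421, plus 24 planted defective rows per partition (letters
  `N`, `B`, and mixed U/T) that the problematic-sequence filter must
  remove before the counts come out right.

What passing tests on these fixtures shows — and what it does not: the
pipeline recovers planted compositional signal essentially perfectly
(held-out AUC ≥ 0.95 at 400 training pairs) and is exactly calibrated at
the null; the dataset plumbing reproduces the published partition counts;
every encoder, the folder, SMOTE, the boosting loop, the AUC and the
DeLong test match independent oracles. None of this certifies
performance on real aptamer data, whose signal is weaker, motif-driven
and not compositional. On the aptamer task specifically, the synthetic
construction bounds what is learnable: negatives share the positives'
mononucleotide frequencies by design, so the classes differ mainly
through the screen's conditioning, and the measured ceiling with this
feature set is an AUC around 0.8 (a 500-tree forest at 400 samples
reaches ~0.81 out-of-bag; the default pipeline ~0.76–0.84 held out at
fixture scale). The end-to-end aptamer test therefore asserts AUC ≥ 0.70,
not the ~0.9 that real, non-random positives support.

# Evaluation

`confusionMetrics()` evaluates Sn, Sp, Acc, MCC, Precision and F1
exactly, with zero-denominator conventions MCC → 0, Precision → 0,
F1 → 0. `rocCurve()` sweeps every distinct score plus infinite endpoints
and integrates by the trapezoid rule, which equals the Mann–Whitney rank
statistic under ties. `delongTest()` implements the paired AUC comparison
via placement values with a two-sided normal reference; identical score
vectors return p = 1 by convention. It agrees with the pROC reference
implementation to machine precision, and its null rejection rate at
$\alpha = 0.05$ is ~0.05 (tests use 4000 Monte-Carlo replicates so the
check's own error is well inside the acceptance band).

# Numerical and degenerate-input choices

* Property standardization uses the population (1/n) variance so a table
  "has variance 1" in the stated sense.
* SMOTE neighbor ties break by row index; `k` is capped at minority
  size − 1.
* Homopolymers give zero correlation factors (PseAAC/PseKNC) and zero
  SOCN; both are exact, not special-cased.
* Sequences too short for a lag/separation parameter raise per-sequence
  errors naming the minimum length; padding would fabricate signal.
* The Nussinov traceback resolves co-optimal structures deterministically
  (first admissible branch), so folding is reproducible.
* Model archives embed a format version and the training feature
  signature; prediction refuses inputs whose column names or order
  differ.

# Problem sizes used by the checks

The test-suite and acceptance-script experiments run at desk scale,
chosen as the package's own verification sizes: 30 boosting rounds on
400–2 243 training pairs for the end-to-end checks (the 2 243-pair run is
the benchmark-shaped retraining), 150 + 150 training sequences for the
aptamer-mode check, 704 positives / 350–500 negatives for the
construction statistics, and 4000 replicates for the DeLong calibration.
The published operating point (300 rounds) is the package default for
real use.

# Known limitations

* The built-in folder maximizes pairs; its pseudo-energy is not
  comparable across engines, and screening thresholds are
  engine-relative.
* Pseudoknots — common in real aptamers — are invisible to the nested
  dot-bracket representation.
* The synthetic fixtures plant compositional signal; they do not emulate
  binding motifs, modified bases, or the selection biases of real SELEX
  data.
* CTD Transition/Distribution descriptors are implemented but excluded
  from the default feature set (see above).
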