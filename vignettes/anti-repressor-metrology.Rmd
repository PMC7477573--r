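---
title: "Anti-repressor unit operations: metrology, logic composition, and screen design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-repressor unit operations: metrology, logic composition, and screen design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buometry)
```

## The system being modeled

Allosteric transcription factors in the LacI/GalR family regulate a reporter
gene by binding a DNA operator near a bacterial promoter. Four phenotypes
span the allosteric possibilities, and each one implements a one-input
Boolean gate on its ligand:

* **repressor** (`X_plus`, a BUFFER gate): binds DNA until its ligand
  induces release, so output follows the ligand;
* **anti-repressor** (`X_anti`, a NOT gate): DNA affinity *increases* on
  ligand binding, so the ligand silences the gene;
* **super-repressor** (`X_super`): allosteric communication is blocked and
  the protein binds constitutively — output is always low;
* **nonfunctional** (`X_null`): never binds — output is always high.

A *biological unit operation* (BUO) is one TF paired with one operator at
one position. The operator position matters mechanistically: a **core**
operator is intercalated between the −35 and −10 promoter hexamers, so a
bound TF competes directly with RNA polymerase; a **proximal** operator sits
downstream of the −10 box, where TF and polymerase bind without direct
competition. Unit operations compose into multi-input gates through three
architectures: **series** (core + proximal operators on one gene, a
conjunction of unit operations), **parallel** (two channels with a coupled
output, a disjunction), and **series-parallel** (several TFs sharing one
operator through a common DNA-binding domain, exchanging independently on
the same site).

`buometry` implements this system end to end: a plate-reader and cytometry
simulator that reproduces the assay design; cassette builders for the
promoter/operator layouts; the statistical phenotype classifier; a
performance-card metrology with traceability scoring; the Boolean and
quantitative composition model with ANOVA/Tukey gate evaluation; and the
library-design calculators used when screening for new anti-repressors.

## The composition model

Under a ligand condition (a subset of the circuit's input ligands), each TF
either binds DNA or not, following its phenotype semantics (`binds()`). An
operator node is **occupied** when *any* cognate, effective TF binds — the
series-parallel disjunction. A channel **permits** transcription when *all*
of its nodes are unoccupied — the series conjunction. A coupled output is
high when *any* channel permits — the parallel disjunction. Enumerating the
2^k ligand subsets gives the predicted truth table, and `classify_gate()`
names the resulting pattern (AND, NOR, NAND, XNOR, single-input reductions,
constants).

Core-position competition with RNA polymerase is handled as a
per-(TF, operator, position) *effectiveness* entry rather than a
thermodynamic occupancy model, because the phenomenon is reported
qualitatively: the wild-type-affinity LacI-core repressor loses its grip on
its natural operator at the core position (polymerase acts as an
antagonist), and function is restored either by a higher-affinity symmetric
operator or by ~10-fold higher TF expression. The default effectiveness rule
encodes exactly those three observations and nothing else; every other
cognate interaction defaults to effective, and `effectiveness_overrides`
can force any entry. We deliberately restrict the default nullification to
the IPTG-sensing (LacI-core) repressor: other regulatory cores adapted with
the same DNA-binding domain retained function at the same core operator, so
keying the rule on the DBD alone would be wrong.

The quantitative model assigns each node a transmission: the ON level
(default 0.9 of maximum) when free, or the bound TF's leak when occupied;
channels multiply node transmissions and the coupled output takes the
channel maximum. Max (not sum) keeps outputs in [0, 1] and matches the gate
assay's normalization, which anchors the highest condition at 1. The
Boolean and quantitative routes are independent implementations; a test
checks they agree at the 0.5 threshold on every study circuit, and the
Boolean route is additionally checked against a brute-force enumerator
over random circuits.

## What the simulator emulates — and what it does not

The generator reproduces the study's assay design: 6 biological replicates
per condition for single-TF characterization and 12 for gates; one
condition block per element of the ligand power set; media-only blank
wells; and a TF-free `lac_null` control in every (operator, position)
stratum, defining that stratum's maximum output. Ligands are binary
(present at a fixed 10 mM working concentration or absent); there is no
dose–response model. Defaults for the well-level means are invented
plumbing, chosen once: unregulated ON at 0.9 of maximum, fold change 10 at
the proximal position and 30 at the core (core mechanisms give larger
dynamic ranges), super-repressed leak 0.03, nonfunctional level 0.95, and a
maximum output of 75,000 r.f.u. The source data never print per-BUO
fluorescence values, so these cannot be calibrated to the measured heatmap
magnitudes — only their qualitative ordering is meaningful, and all of them
are overridable through `profile_defaults()`.

Noise is multiplicative log-normal on fluorescence and OD600 (reader error
scales with signal), mean-one so replicate-mean fold changes are unbiased;
the default CV is 0.05 on both channels. Culture density is drawn around a
fixed mean (0.5 OD above blank) independent of genotype — metabolic burden
is ignored. Single-cell FITC is log-normal around a geometric mean that
interpolates between an autofluorescence floor (200 a.u.) and the
maximum-output brightness (50,000 a.u.), with σ(log) = 0.4; scatter
channels come from a 90/5/5 singlet/debris/doublet mixture so the standard
gates (side-scatter threshold 5,000; area/height ratio cutoff 1.5 for
doublets) have work to do. None of this models real-instrument artifacts —
compensation, drift, autofluorescence spectra — so passing tests show the
*analysis* is correct under its stated assumptions, not that those
assumptions exhaust real data.

## Statistical rules and numerical choices

Phenotype calls follow the study's decision procedure: Welch's two-tailed
t-test between ligand states at α = 0.001; significant calls are
directional (`X_plus` vs `X_anti`), non-significant calls split on whether
the pooled mean exceeds 50% of the stratum maximum (`X_null` above,
`X_super` below). Three points were genuinely open and resolved as follows:

* the 50% rule does not specify which state's fluorescence to use; we use
  the pooled mean of both states (for a non-significant call the two states
  are interchangeable anyway);
* a tie at exactly 50% is called `X_null` — conservative, since claiming
  super-repression is the stronger claim;
* the test runs on standardized replicate vectors; standardization is a
  per-stratum constant rescaling, so the t statistic is identical to the
  raw-scale test.

No multiple-testing correction is applied across response-matrix cells;
the per-cell α = 0.001 mirrors the source analysis and is documented as
such. Degenerate inputs are handled explicitly: both-groups-zero-variance
Welch tests return p = 1 (equal means) or 0 (separated); a zero pooled SD
with unequal means reports Cohen's d as `Inf`.

Gate evaluation normalizes condition means to the maximum condition
(normalized output units), then uses one-way ANOVA and Tukey HSD at
α = 0.01: conditions in the max condition's Tukey group binarize to 1,
those in the min group to 0, anything separated from both is indeterminate.
Tukey group membership, rather than a fixed threshold, mirrors the source
analysis's reliance on post-hoc grouping for state separation. When
replicate variance is numerically zero (noise-free simulation), binarization
falls back to direct mean comparison, since an F statistic is undefined.

Performance cards report fraction-of-maximum ON/OFF levels, the dynamic
range (fold anti-induction for `X_anti`, fold induction for `X_plus`), and
two raw units: AIU/IU, defined as the dynamic range itself, and RU
(repression units), defined as 1 / (no-ligand level). The exact formulas
behind these units live in supplementary material not available to this
implementation; the definitions used here are a reconstruction chosen so
that the published compatibility rules are meaningful — RU approaches AIU
exactly when a NOT unit's ON state is attenuated toward super-repression,
which is the failure mode the proximity rule (|AIU − RU| < 1.5 with dynamic
range ≥ 5) flags. Traceability is the ratio of a card's metric to the
reference card's (wild-type LacI repressor, natural operator, proximal), so
the reference scores exactly 1.0 against itself; ratio-ness is inferred
from that published anchor. Fold-change denominators are floored at 0.005
fraction-of-maximum (≈ detection limit) and the card records when the floor
was applied. The cytometry summary used for plate/cytometry concordance is
the geometric mean of gated FITC (log-normal assumption); the source does
not state its summary statistic.

## Library-design calculators

NNS site saturation uses 32 codons (4 × 4 × 2) covering all 20 amino acids
with one stop (TAG). The familiar "96 picks give 95% coverage" is the
*per-codon* probability 1 − (31/32)^96 ≈ 0.952; the probability that *all*
32 codons appear among 96 picks (inclusion–exclusion, `all_codons_coverage()`)
is far lower (≈ 0.18). Both are exposed so the distinction stays visible.
Codons are treated as equiprobable — synthesis bias is ignored. The
error-prone PCR model is substitution-only Binomial (815 bp at 0.7% per
base gives a mean of ~5.7 substitutions, i.e. 5–7 bp touching 3–5 codons);
indels and the transition/transversion spectrum are out of scope.

The sort simulator applies the two-step anti-repressor plan: sort with
ligand collecting low-FITC events (keeping anti- and super-repressors),
then without ligand collecting high-FITC events (separating anti- from
super-repressors), each step run twice, with the 10^4 FITC bin boundary.
Between sorts the surviving composition is regrown, i.e. the next sample is
drawn fresh from the renormalized genotype fractions. Enrichment of the
anti-repressor fraction is monotone at step granularity; within a step's
repeated passes the fraction can fluctuate by sampling noise once the
competing phenotypes are already depleted, which is why the monotonicity
property (and its test) is stated over steps.

## Construct builders

Cassette records use 0-based half-open feature coordinates. The core
builder enforces the 17-bp operator intercalation between TTGACA and the
scaffold's −10 hexamer (TATAAT for trc, GATACT for pL, GACTAT for the
weakened pL variant); the proximal builder places the operator 15 bp
downstream of the −10 box by default. Engineered operator sequences are not
public, so symbolic operator IDs are authoritative and sequences are
config-supplied placeholders validated by length; insulator (RiboJ /
RiboJ10), gene and terminator features carry correct labels with
placeholder sequences, replaceable via the `parts` argument. The original
single-operator proximal reporter's unstated spacer is treated identically
to the 15-bp series rule. `validate_layout()` is the builders' inverse and
reports violations rather than raising.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is bit-reproducible.
The test suite exercises the recovery properties at the sizes the analysis
is designed for: phenotype recovery over 500 simulated plates (≥ 99%
correct calls at fold ≥ 5 and default noise), gate-name round trips over
200 seeds per gate (≥ 95% recovery for NAND, NOR, XNOR at 12 replicates),
sort enrichment over 100 seeds (final anti-repressor fraction > 0.9 from an
equal 4-way mix at 20,000 events per sort), and kernel-level agreement with
independent oracles (permutation test, surjection recurrence, Monte-Carlo
coverage, binomial simulation). These sizes were chosen to make the
property estimates stable; all of them complete on a single CPU in well
under a minute each.

This package is a library, not a shell tool: its users drive analyses from
R scripts, so the exported functions (plus `scripts/acceptance.R` for the
benchmark recomputation) are the interface, and no separate command-line
wrapper is shipped.

## A worked example

```{r example}
# characterize an anti-repressor unit operation
tf <- tf_spec("R_anti_HQN", "d-ribose", "HQN", "X_anti")
pr <- profile_from_phenotype(tf, "Ottg", "proximal")
plate <- simulate_buo_plate(list(pr), noise_model(), n_reps = 6, seed = 1)
classify_plate(plate)

# compose and evaluate a NAND gate
nand <- circuit(
  list(channel("trc", operator_node("Ottg", "core")),
       channel("pL", operator_node("Oagg", "core"))),
  list(tf_spec("I_anti_HQN", "IPTG", "HQN", "X_anti"),
       tf_spec("R_anti_KSL", "d-ribose", "KSL", "X_anti")),
  id = "NAND")
classify_gate(predict_truth_table(nand))
evaluate_gate(simulate_gate_plate(nand, noise_model(), seed = 7))
```

## Known limitations

No growth kinetics, resource competition, or dose–response; strictly binary
ligand inputs. Non-cognate interactions are treated as non-binding (one
weak non-cognate interaction is reported in the source data; modeling it is
left to `effectiveness_overrides` and custom profiles). Multi-layer
inverter architectures are documented history, not modeled. The synthetic
defaults cannot be calibrated to unpublished per-unit fluorescence values,
so quantitative agreement with any particular measured unit operation is
out of scope — the package's claims are about the analysis pipeline and the
composition semantics.
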