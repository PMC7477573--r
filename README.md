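# buometry

Metrology and logic composition for engineered anti-repressor gene circuits.

## The problem

Synthetic gene circuits are mostly built from transcriptional *repressors*:
proteins that silence a gene until a ligand induces their release
(biological BUFFER gates). *Anti-repressors* invert that allostery — ligand
binding **increases** DNA affinity, so the ligand silences the gene — which
makes a single protein on a single promoter a complete NOT gate. Composing
engineered repressors and anti-repressors across promoter/operator
architectures (core vs proximal operator positions; series, parallel, and
series-parallel layouts) yields every NOT-oriented combinatorial gate —
NOT, NOR, NAND, XNOR — with far fewer parts than inverter-based designs.

`buometry` is an R toolkit for the quantitative side of that program, aimed
at synthetic biologists characterizing allosteric transcription-factor
parts and composing them into logic:

* **Simulation** — plate-reader assays with the real replicate structure
  (6 replicates for unit operations, 12 for gates, blank and TF-free
  `lac_null` maximum-output controls, multiplicative log-normal noise) and
  single-cell cytometry (log-normal FITC, debris/doublet scatter mixture).
* **Constructs** — promoter cassette builders enforcing the layout rules
  (17-bp operator intercalated between the −35/−10 hexamers at the core
  position; operator 15 bp downstream of the −10 box at the proximal
  position; series and two-channel parallel records with distinct ribozyme
  insulators), with FASTA/GenBank/JSON export and a layout validator.
* **Phenotyping** — blank subtraction, OD normalization, standardization to
  the stratum maximum, then classification of each TF/operator/position
  unit into repressor (X⁺), anti-repressor (Xᴬ), super-repressor (Xˢ) or
  nonfunctional (X⁻) by a Welch two-tailed t-test (α = 0.001) plus the 50%
  rule, and assembly of DBD × operator response matrices.
* **Metrology** — performance cards (fraction of maximum output, dynamic
  range, anti-induction/induction units, repression units), traceability
  scores against the reference unit operation (the wild-type LacI
  repressor–operator pair, which scores exactly 1.0 against itself),
  pairing-compatibility rules, reference rankings, and plate-vs-cytometry
  concordance.
* **Logic** — an architecture-based composition model (`binds` →
  occupancy → series conjunction → parallel disjunction) that predicts
  truth tables, names gates, reproduces the core-position nullification of
  the wild-type LacI BUFFER and both of its rescues, and evaluates measured
  gate plates with one-way ANOVA + Tukey HSD binarization (α = 0.01).
* **Screen design** — NNS site-saturation coverage (per-codon and strict
  all-codon), error-prone PCR mutation statistics, and a two-step FACS
  sort-plan simulator for anti-repressor discovery.

## A worked example

Characterize a simulated anti-repressor unit operation and compose a NAND
gate:

```r
library(buometry)

tf <- tf_spec("R_anti_HQN", "d-ribose", "HQN", "X_anti")
pr <- profile_from_phenotype(tf, "Ottg", "proximal")
plate <- simulate_buo_plate(list(pr), noise_model(), n_reps = 6, seed = 1)
classify_plate(plate)
#>        tf_id operator position phenotype      p_value  cohen_d mean_no_ligand mean_with_ligand significant
#> 1 R_anti_HQN     Ottg proximal    X_anti 3.206896e-09 42.69355      0.9269327       0.09106793        TRUE

buo <- collect_buos(standardize_to_max(normalize_plate(plate)))[[1]]
performance_card(buo)
#> <performance_card> R_anti_HQN|Ottg|proximal [X_anti]
#>   ON 0.927 +/- 0.027 | OFF 0.091 +/- 0.005 (F.M.O.)
#>   dynamic range 10.18 AIU | RU 1.08
```

The call is significant at α = 0.001 with a huge effect size; the unit
silences its reporter ~10-fold on ligand addition (10.18 anti-induction
units) while keeping a strong ON state (RU 1.08, i.e. near-maximal output
without ligand) — a healthy NOT gate.

```r
nand <- circuit(
  list(channel("trc", operator_node("Ottg", "core")),
       channel("pL",  operator_node("Oagg", "core"))),
  list(tf_spec("I_anti_HQN", "IPTG", "HQN", "X_anti"),
       tf_spec("R_anti_KSL", "d-ribose", "KSL", "X_anti")),
  id = "NAND")
classify_gate(predict_truth_table(nand))
#> [1] "NAND"

evaluate_gate(simulate_gate_plate(nand, noise_model(), seed = 7))
#> <gate_eval> matched gate: NAND (ANOVA p = 5.92e-47, alpha = 0.01)
#>      condition       mean          sd state
#>                1.00000000 0.053335101  TRUE
#>       d-ribose 0.97459736 0.043184259  TRUE
#>  d-ribose;IPTG 0.03229208 0.001465344 FALSE
#>           IPTG 0.99946929 0.029243290  TRUE
```

Only the both-ligands condition is anti-induced on both parallel channels
(normalized output 0.03, in the minimum Tukey group); every other condition
sits at the ON plateau — the NAND truth table.

See `vignettes/anti-repressor-metrology.Rmd` for the full account of the
model, the statistical rules, the simulator's assumptions, and the design
decisions.

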