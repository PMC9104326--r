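# disbench

Benchmarking residue-wise intrinsic-disorder prediction from predicted
protein structures.

## The problem

Structure predictors now produce models for essentially any sequence, and
each model carries a per-residue confidence score (pLDDT, 0–100, stored
in the B-factor field). For intrinsically disordered proteins and regions
(IDPs/IDRs) — which have no fixed native structure — two very different
disorder predictors can be read off the same model:

* **tpLD**, the continuous transform `tpLDDT = 1 − pLDDT/100`, so 1 is
  fully disordered;
* **pLDn**, the binary rule calling a residue ordered iff `pLDDT ≥ n`,
  with the threshold *n* selected by maximising the Matthews correlation
  coefficient (MCC) against a reference set; thresholds from two
  reference sets are combined by their rounded mean (e.g. 76 and 68
  combine to pLD72);
* **DSSPp**, the naive structure rule: residues assigned by the
  Kabsch–Sander algorithm to helices, strands, or H-bond-stabilised turns
  are ordered, bends and coil are disordered.

`disbench` implements all three (including a from-scratch Kabsch–Sander
secondary-structure assignment), constructs the two standard reference
variants from interval annotations — the DisProt-style set (unannotated =
ordered) and the DisProt-PDB-style set (only annotated-or-covered
residues evaluated, annotation/structure conflicts resolved to disorder,
the rest masked) — and scores everything with pooled-residue ROC/AUC,
precision–recall/Fmax, MCC, per-protein RMSD
`sqrt(mean((v − w)^2))`, disorder content, protein-class breakdowns, and
bootstrap summaries (10,000 resamples of size 60 at the protein level,
size 500 at the residue level). A synthetic cohort generator produces
labelled proteins, confidence profiles, secondary-structure strings,
ideal backbone coordinates, coverage intervals and emulated external
predictor files, so the full pipeline runs and is tested without any
downloads. External per-residue predictions are ingested in the CAID
text format.

## Worked example

```r
library(disbench)
cfg <- run_config(generator = generator_config(n_proteins = 60, seed = 7), seed = 7)
run <- run_benchmark(cfg)
print(run)
```

```
<benchmark_run>
  thresholds: 65 (disprot), 67 (disprot_pdb), combined 66
<evaluation_report> disprot_pdb (60 proteins, 10915 evaluated residues)
       predictor   auc  fmax      mcc mean_rmsd rmsd_boot_mean rmsd_boot_stderr
            tpLD 0.999 0.986       NA    0.3090         0.3090          0.00903
           pLD67    NA    NA  0.97633    0.0879         0.0879          0.00705
  pLD66_combined    NA    NA  0.97588    0.0886         0.0885          0.00684
           DSSPp    NA    NA  0.72669    0.3577         0.3577          0.00546
 emulated_strong 0.923 0.807  0.67773    0.3938         0.3937          0.00419
    emulated_mid 0.756 0.636  0.35840    0.5614         0.5614          0.00430
 emulated_random 0.495 0.550 -0.00719    0.7092         0.7092          0.00356
```

Reading the table: the MCC-optimal thresholds of the two reference sets
(65 and 67 on this cohort) combine to pLD66. The confidence-based rules
dominate — pLD67 reaches MCC 0.976 and the lowest per-protein RMSD
(0.088) — while the naive structure rule DSSPp trails badly (RMSD 0.358)
because the generator plants transient helices in disordered segments and
confident coils in ordered ones, exactly the discordance seen in real
predicted structures. An emulated external predictor built to have AUC
0.92 measures 0.923; a random one sits at AUC ≈ 0.5 and the
random-predictor RMSD level ≈ 0.71.

The numbered scripts under `analysis/` run the same pipeline as a
narrative — cohort generation, geometry + secondary-structure assignment,
reference construction, prediction, benchmarking, and the
codon-level confidence analysis — writing tables under `results/`.

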