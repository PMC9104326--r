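#!/usr/bin/env Rscript
# Generate the synthetic benchmark cohort and write every input the later
# stages consume: disorder/coverage interval tables, emulated external
# predictor files (CAID format), and the generator manifest.

suppressMessages(library(disbench))

out <- "results/cohort"
cfg <- generator_config(seed = 1L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, out)

lens <- lengths(cohort$labels)
contents <- vapply(cohort$labels, mean, numeric(1))
cat(sprintf("cohort: %d proteins, %d-%d residues (total %d)\n",
            cfg$n_proteins, min(lens), max(lens), sum(lens)))
cat(sprintf("pooled disorder fraction: %.3f (target %.2f)\n",
            mean(unlist(cohort$labels)), cfg$disorder_fraction))
cat(sprintf("per-protein disorder content: mean %.3f, range %.2f-%.2f\n",
            mean(contents), min(contents), max(contents)))
cat("wrote", out, "\n")
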