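#!/usr/bin/env Rscript
# Build the two reference label sets from the interval tables written by
# 01_generate_cohort.R: the DisProt-style set (unannotated = ordered) and
# the DisProt-PDB-style set (annotation-or-coverage only, conflicts ->
# disorder, the rest masked).

suppressMessages(library(disbench))

disorder <- read_intervals("results/cohort/disorder.tsv", kind = "disorder")
coverage <- read_intervals("results/cohort/coverage.tsv", kind = "pdb_coverage")
manifest <- jsonlite::read_json("results/cohort/manifest.json")

# protein lengths come from the regenerated cohort (the manifest pins it)
cohort <- generate_cohort(do.call(generator_config, manifest))
accs <- names(cohort$labels)

disprot <- list(); disprot_pdb <- list()
for (acc in accs) {
  len <- length(cohort$labels[[acc]])
  disprot[[acc]] <- build_disprot_reference(disorder[[acc]], len,
                                            accession = acc)
  disprot_pdb[[acc]] <- build_disprot_pdb_reference(disorder[[acc]],
                                                    coverage[[acc]], len,
                                                    accession = acc)
}
write_reference_table(disprot, "results/reference_disprot.tsv")
write_reference_table(disprot_pdb, "results/reference_disprot_pdb.tsv")

mf <- masked_fraction(disprot_pdb)
cat(sprintf("proteins: %d\n", length(accs)))
cat(sprintf("masked fraction (disprot_pdb): overall %.4f, per-protein %.4f-%.4f\n",
            mf$overall, min(mf$per_protein), max(mf$per_protein)))
cat("disprot references mask nothing:",
    !any(vapply(disprot, function(r) any(r$mask), logical(1))), "\n")
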