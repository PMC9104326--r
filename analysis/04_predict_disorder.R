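#!/usr/bin/env Rscript
# Derive the three structure-based disorder predictors for the cohort:
# the continuous confidence transform tpLD, the thresholded pLDn at the
# MCC-optimal threshold of each reference set, and the naive structure
# rule DSSPp. Predictions are written in CAID text format.

suppressMessages(library(disbench))

manifest <- jsonlite::read_json("results/cohort/manifest.json")
cohort <- generate_cohort(do.call(generator_config, manifest))
refs <- disbench:::cohort_references(cohort)

ts_dis <- select_threshold_mcc(cohort$plddt, refs$disprot, dataset = "disprot")
ts_pdb <- select_threshold_mcc(cohort$plddt, refs$disprot_pdb,
                               dataset = "disprot_pdb")
n_comb <- combine_thresholds(c(ts_dis$best_n, ts_pdb$best_n))
print(ts_dis); print(ts_pdb)
cat(sprintf("combined threshold: pLD%d\n", n_comb))

as_caid <- function(score_list, label_list = NULL) {
  out <- lapply(names(score_list), function(acc) {
    list(accession = acc, score = score_list[[acc]],
         label = if (is.null(label_list)) NULL else label_list[[acc]])
  })
  names(out) <- names(score_list)
  out
}
tpld <- lapply(cohort$plddt, tpld_predict)
pldn <- lapply(cohort$plddt, pldn_predict, n = n_comb)
dsspp <- lapply(cohort$ss, function(s) dsspp_predict(s$ss8))

write_caid_predictions(as_caid(tpld), "results/pred_tpld.caid")
write_caid_predictions(as_caid(lapply(pldn, as.numeric), pldn),
                       "results/pred_pldn.caid")
write_caid_predictions(as_caid(lapply(dsspp, as.numeric), dsspp),
                       "results/pred_dsspp.caid")
cat(sprintf("wrote tpLD / pLD%d / DSSPp predictions for %d proteins\n",
            n_comb, length(tpld)))
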