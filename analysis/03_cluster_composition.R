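#!/usr/bin/env Rscript
# Pairwise differential proportion analysis of mesenchymal cluster
# composition across the four conditions (study settings n_perm = 100,000,
# p_mix = 0.1; asterisks at p < 0.01).

suppressPackageStartupMessages(library(limbscape))

cells <- read_cell_table("results/cells_classified.tsv")
conds <- split(cells$cluster, paste(cells$genotype, cells$tissue, sep = "-"))
sets <- lapply(names(conds), function(nm) label_set(nm, conds[[nm]]))

res <- pairwise_dpa(sets, n_perm = 1e5, p_mix = 0.1, seed = 20260924)
for (nm in names(res)) {
  path <- file.path("results", paste0("dpa_", gsub("[^A-Za-z0-9_]", "", nm),
                                      ".tsv"))
  write_dpa_result(res[[nm]], path)
}

wt_vs_mut <- res[[grep("PenDel-HL_vs_WT-HL|WT-HL_vs_PenDel-HL", names(res))]]
cat("wildtype vs enhancer-deleted hindlimb cluster composition:\n")
tab <- wt_vs_mut[order(wt_vs_mut$p_value), ]
tab$sig <- ifelse(tab$p_value < 0.01, "*", "")
print(tab[, c("cluster", "prop_a", "prop_b", "statistic", "p_value", "sig")],
      row.names = FALSE, digits = 3)
cat("clusters shifting at p < 0.01:",
    paste(tab$cluster[tab$p_value < 0.01], collapse = ", "), "\n")
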