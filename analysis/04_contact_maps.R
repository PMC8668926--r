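#!/usr/bin/env Rscript
# Contact-map post-processing: bin the simulated pairs, KR-balance, scale
# the two conditions together across their subdiagonals, subtract,
# truncate for display, and extract virtual 4C profiles from the promoter
# viewpoint (bedGraph output).

suppressPackageStartupMessages(library(limbscape))

region <- genomic_interval("chr13", 55500001, 56100000)
vp <- genomic_interval("chr13", 55920001, 55940000)
anc <- genomic_interval("chr13", 55770001, 55790000)

active <- read_contact_pairs("results/pairs_active.tsv", region)
inactive <- read_contact_pairs("results/pairs_inactive.tsv", region)

ma <- kr_balance(bin_pairs(active, 10000))
mb <- kr_balance(bin_pairs(inactive, 10000))
cat(sprintf("KR balancing: %d/%d iterations, residuals %.1e / %.1e\n",
            attr(ma, "iterations"), attr(mb, "iterations"),
            attr(ma, "residual"), attr(mb, "residual")))

sc <- subdiagonal_scale(ma, mb)
d <- subtract_maps(sc$a, sc$b)
write_matrix_triplet(truncate_percentile(ma, 99), "results/map_active_kr.tsv")
write_matrix_triplet(truncate_percentile(mb, 99),
                     "results/map_inactive_kr.tsv")
write_matrix_triplet(d, "results/map_subtraction.tsv")

valid <- outer(d$mask, d$mask, "&")
top <- which(d$M == max(d$M[valid]) & valid, arr.ind = TRUE)[1, ]
cat("strongest active-specific contact:",
    format(bin_to_interval(top[1] - 1L, region, 10000)), "x",
    format(bin_to_interval(top[2] - 1L, region, 10000)),
    "(configured loop:", format(vp), "x", format(anc), ")\n")

p_act <- virtual_4c(active, vp, raw_bin = 1000, interval_size = 5000)
p_ina <- virtual_4c(inactive, vp, raw_bin = 1000, interval_size = 5000)
write_bedgraph(p_act, "results/v4c_active.bedgraph", "v4c_active")
write_bedgraph(p_ina, "results/v4c_inactive.bedgraph", "v4c_inactive")
write_bedgraph(profile_subtract(p_act, p_ina),
               "results/v4c_subtraction.bedgraph", "v4c_subtraction")
starts <- region$start + (seq_along(p_act$values) - 1) * 5000
at_anchor <- starts >= anc$start & starts < anc$end
cat(sprintf("virtual 4C: %d / %d qualifying pairs; anchor signal %.1f vs %.1f\n",
            p_act$n_qualifying, p_ina$n_qualifying,
            mean(p_act$values[at_anchor]), mean(p_ina$values[at_anchor])))
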