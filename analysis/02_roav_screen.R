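#!/usr/bin/env Rscript
# ROAV screen of the 30 aroma-active volatiles: recompute scores from the
# content and threshold tables, tier the compounds, and select the key set
# used for curve fitting.

library(roavcurves)

dir.create("results", showWarnings = FALSE)

contents <- mrp_content()
compounds <- mrp_compounds()
roav <- compute_roav(contents, compounds)
print(roav)

tal <- tally_classes(compounds)
message("class tallies: ", paste(names(tal), tal, sep = "=", collapse = ", "))

fdq <- max_fd_query(mrp_fd(), setNames(compounds$retention_index,
                                       compounds$name))
message(sprintf("most dilution-robust odorant: %s (FD %d-%d in all samples)",
                fdq$compound, fdq$min_fd, fdq$max_fd))

printed <- mrp_roav_printed()[roav$sample_ids, roav$compounds]
dev <- abs(roav$roav - printed) / pmax(printed, .Machine$double.eps)
message(sprintf(paste("recomputed ROAVs agree with the published table to",
                      "%.1f%% (worst cell; inputs are printed to 2 decimals)"),
                100 * max(dev[printed >= 0.1])))

keys <- select_key_compounds(roav, "MRPs A")
message(sprintf("key compounds for curve fitting (baseline MRPs A, reference excluded): %s",
                paste(keys, collapse = ", ")))

write.table(data.frame(compound = roav$compounds, t(round(roav$roav, 3)),
                       check.names = FALSE),
            "results/roav_computed.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
tiers <- classify_roav(roav)
write.table(tiers, "results/roav_tiers.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
writeLines(keys, "results/key_compounds.txt")
message("wrote results/roav_computed.tsv, results/roav_tiers.tsv, results/key_compounds.txt")
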