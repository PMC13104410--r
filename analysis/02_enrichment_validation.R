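#!/usr/bin/env Rscript
# Stage 2: enrichment screening of docking/scoring combinations against a
# seeded decoy database.
#
# Emulates the validation screen: 3 active ligands seeded into a decoy
# library, ranked by each combination, then judged by the enrichment
# factor at the top 10%, the database EF ceiling, and ROC-AUC with
# Hanley-McNeil standard errors, significance against AUC = 0.5 and the
# conventional quality bands. Score separations are chosen to span the
# whole quality range, from perfectly discriminating combinations (the
# regime in which EF hits its ceiling of NC_tot/Hits_tot) down to
# worse-than-random ones. Writes results/enrichment.csv.

suppressMessages(library(screenperm))
dir.create("results", showWarnings = FALSE)

seed <- 1
# one synthetic combination per separation regime
deltas <- c(PLP1 = 10, PLP2 = 8, PMF = 6, Jain = 2.5,
            PMF4 = 2.2, Native = 10, LigScore1 = -0.6, LigScore2 = -0.4)
tb <- gen_seeded_database(300, 3, delta = deltas[[1]], seed = seed,
                          combination = names(deltas)[1])
for (i in 2:length(deltas)) {
  extra <- gen_seeded_database(300, 3, delta = deltas[[i]], seed = seed + i,
                               combination = names(deltas)[i])
  tb[[names(deltas)[i]]] <- extra[[names(deltas)[i]]]
}

report <- enrichment_report(tb, fraction = 0.10)
write.csv(report, "results/enrichment.csv", row.names = FALSE)
print(report, row.names = FALSE)
cat("\nEF ceiling for this database:",
    max_enrichment_factor(303, 3)$reported, "(303 compounds / 3 actives)\n")
cat("wrote results/enrichment.csv\n")
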