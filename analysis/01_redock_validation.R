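#!/usr/bin/env Rscript
# Stage 1: redocking accuracy of the docking/scoring combinations.
#
# For each receptor crystal structure (6PT0, 6KPC, 5ZTY) and each docking
# algorithm (LibDock, LigandFit), synthetic pose ensembles for the three
# co-crystallised ligands (9JU, E3R, 5IW) are generated at the tabulated
# per-pose RMSDs, then scored, ranked and summarised: best-pose RMSD,
# per-scoring-function top-pose RMSD, success rate under the strict
# < 2 A rule, and column-mean RMSD. Writes one long-form table per
# structure under results/.

suppressMessages(library(screenperm))
dir.create("results", showWarnings = FALSE)

for (structure in c("6PT0", "6KPC", "5ZTY")) {
  summaries <- lapply(c("LibDock", "LigandFit"), function(alg) {
    fx <- gen_redock_fixture(structure, alg, seed = 1)
    redock_summary(fx$pose_sets, cutoff = 2, algorithm = alg)
  })
  tab <- redock_table(summaries)
  out <- sprintf("results/redock_%s.csv", structure)
  write.csv(tab, out, row.names = FALSE)
  cat("==", structure, "==\n")
  print(tab[tab$row %in% c("Success rate", "Average RMSD",
                           "Overall success rate"), ], row.names = FALSE)
  cat("wrote", out, "\n\n")
}

cat("Best-pose success is 100% for 6PT0/6KPC and 67% for 5ZTY under\n")
cat("LibDock; scoring functions differ widely, so enrichment screening\n")
cat("(stage 2) is needed before any combination is trusted.\n")
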