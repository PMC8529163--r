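#!/usr/bin/env Rscript
# Pharmacokinetic screen: bioactivity-score classification, ADMET rule
# findings and docking-table analytics over the transcribed study tables.

suppressPackageStartupMessages(library(cdftscreen))
dir.create("results", showWarnings = FALSE)

fx <- function(f) system.file("extdata", f, package = "cdftscreen")
report <- run_profile(pipeline_config(bioactivity = fx("table2_bioactivity.csv"),
                                      admet = fx("table3_admet.csv"),
                                      docking = fx("table1_docking.csv")))

write.csv(report$bioactivity, "results/bioactivity_classes.csv", row.names = FALSE)
cat("Bioactivity verdicts per ligand/target class:\n")
print(with(report$bioactivity, table(ligand_id, verdict)))
enz <- subset(report$bioactivity, target_class == "enzyme inhibitor")
cat("\nEnzyme-inhibitor scores are positive for every ligand:",
    all(enz$verdict == "active"), "\n")

write.csv(report$admet_findings, "results/admet_findings.csv", row.names = FALSE)
poor <- subset(report$admet_findings,
               rule == "human intestinal absorption" & verdict == "poorly absorbed")
cat("\nLigands predicted poorly absorbed (<30% intestinal absorption):\n")
print(poor$ligand_id)

s <- report$docking
cat(sprintf("\nDocking: %d complexes; affinities span %.1f to %.1f kcal/mol.\n",
            s$n_complexes, s$global_best$affinity, s$global_worst$affinity))
cat(sprintf("Strongest binder overall: %s on %s (%.1f kcal/mol).\n",
            s$global_best$ligand_id, s$global_best$protein_id,
            s$global_best$affinity))
cat("Best ligand per protein target:\n")
print(s$best_per_protein, row.names = FALSE)
write.csv(s$best_per_protein, "results/docking_best_per_protein.csv",
          row.names = FALSE)
writeLines(render_report(report, "markdown"), "results/pharma_report.md")
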