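#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs with known ground truth:
# a proteome with planted copper-gene homologs among decoys, an annotated
# two-replicon genome carrying full and partial merR-copA clusters (some on
# genomic islands), and a copper-induction qPCR CT table with planted
# log2 fold changes. Everything downstream reads from results/inputs/.

suppressPackageStartupMessages(library(copperscan))
seed <- 42
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Proteome: 100 decoys + 5 planted homologs at 10% divergence")
prot <- simulate_proteome(proteome_spec(), seed = seed)
write_proteome_fasta(prot$proteome, file.path(out, "proteome.faa"))
write.csv(prot$truth, file.path(out, "proteome_truth.csv"), row.names = FALSE)

message("Profile HMMs for the five planted families (calibrated)")
accs <- vapply(default_planted_homologs(), `[[`, "", "model")
models <- simulate_model_set(accs, seed = seed)
write_hmm_file(models, file.path(out, "models.hmm"))

message("Annotated genome: chromosome + plasmid, 2 full + 3 partial clusters")
gen <- simulate_annotated_genome(genome_spec(), seed = seed)
write_genome_fixture(gen, out)
write.csv(gen$truth, file.path(out, "cluster_truth.csv"), row.names = FALSE)

message("CT table: plasmid copA variants induced, chromosomal copy flat")
cts <- simulate_ct_table(ct_spec(), seed = seed)
write_ct_table(cts$records, file.path(out, "ct_table.csv"))
write.csv(cts$truth, file.path(out, "ct_truth.csv"), row.names = FALSE)

message("Model catalog (17 accessions, four copper-system categories)")
write_model_catalog(default_model_catalog(), file.path(out, "catalog.tsv"))

message("Inputs written under ", out)
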