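#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Builds a 16,569 bp circular reference (one placeholder position, rCRS-style),
# a five-gene coding model (one light-strand ND6 analogue), and a 4,000-person
# cohort with 150 sibling pairs under the two-step mechanism: cryptic
# replication-error mutations accrue with age at low cell fraction, and
# clonal hematopoiesis (CH) carries a subset up to detectable bulk
# heteroplasmy. Outputs feed every later step.

library(mthet)

seed <- 20260927
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reference <- generate_reference(16569, placeholder_positions = 3107, seed = seed)
gene_model <- generate_gene_model(reference, 5, c(heavy = 4, light = 1),
                                  seed = seed + 1)
config <- cohort_config(n_samples = 4000, n_sibling_pairs = 150,
                        ch_intercept = -7)
sim <- simulate_cohort(reference, gene_model, config, seed = seed + 2)

write_reference_fasta(reference, file.path(out, "reference.fa"))
write_gene_model(gene_model, file.path(out, "genes.tsv"))
write_sample_table(sim$samples, file.path(out, "samples.tsv"))
write_callset_tsv(sim$callset, file.path(out, "callset.tsv"))
# one example per-sample VCF, for interoperability checks
write_callset_vcf(sim$callset, sim$samples$sample_id[1],
                  file.path(out, "example_sample.vcf"))

cat(sprintf("cohort: %d samples (%d CH carriers, %.1f%%), %d sibling pairs\n",
            nrow(sim$samples), sum(sim$samples$ch),
            100 * mean(sim$samples$ch), config$n_sibling_pairs))
cat(sprintf("callset: %d detected heteroplasmy records across %d samples\n",
            nrow(sim$callset), length(unique(sim$callset$sample_id))))
cat(sprintf("median detected HL %.4f; %.1f%% of records below HL 0.05\n",
            median(sim$callset$HL), 100 * mean(sim$callset$HL < 0.05)))
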