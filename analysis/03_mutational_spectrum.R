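#!/usr/bin/env Rscript
# Step 3: strand/region-aware mutational spectrum.
#
# Computes possible-variant-normalized mean counts per person by strand,
# substitution class and region; repeats within 5-year age strata; collapses
# the strand-resolved context spectrum to COSMIC 96 categories and regresses
# it on a panel of synthetic SBS-style signatures (Bonferroni over the panel
# size, 86 in the published catalogue).

library(mthet)

out <- "results/spectrum"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

reference <- read_reference_fasta("results/cohort/reference.fa",
                                  ori = c(16172, 210))
samples <- read_sample_table("results/cohort/samples.tsv")
samples <- filter_samples(samples, "variants")$kept
callset <- read_callset_tsv("results/qc/callset_burden_qc.tsv")

spec <- normalized_mean_counts(callset, samples, reference,
                               by = c("strand", "substitution", "region"))
write.table(spec, file.path(out, "normalized_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

other <- spec[spec$region == "Other", ]
hm <- other[other$strand == "heavy" & other$substitution == "C>T", ]
lm_ <- other[other$strand == "light" & other$substitution == "C>T", ]
cat(sprintf("C>T normalized rate, Other region: heavy %.2e vs light %.2e (ratio %.1f)\n",
            hm$normalized_mean, lm_$normalized_mean,
            hm$normalized_mean / lm_$normalized_mean))

by_age <- normalized_mean_counts(callset, samples, reference,
                                 by = c("strand", "substitution", "region"),
                                 age_breaks = seq(20, 90, 5))
write.table(by_age, file.path(out, "normalized_counts_by_age.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
aa <- by_age[by_age$region == "Other" & by_age$substitution == "A>G" &
             by_age$strand == "heavy" & by_age$n_samples > 0, ]
cat(sprintf("A>G heavy (Other) normalized mean, youngest vs oldest stratum: %.2e vs %.2e\n",
            aa$normalized_mean[1], aa$normalized_mean[nrow(aa)]))

# context-level spectrum on the COSMIC 96 axis, light strand
ctx <- normalized_mean_counts(callset, samples, reference,
                              by = c("strand", "substitution", "context"))
light <- ctx[ctx$strand == "light" & !is.na(ctx$context), ]
obs96 <- cosmic96_spectrum(light$substitution, light$context,
                           weights = light$normalized_mean)

# synthetic signature panel: one signature concentrated on the cohort's
# dominant categories plus flat/random ones
set.seed(1)
lab <- cosmic96_labels()
panel <- cbind(
  SBS_like = obs96 / sum(obs96),
  SBS_flat = rep(1 / 96, 96),
  replicate(4, { x <- rexp(96); x / sum(x) })
)
colnames(panel)[3:6] <- paste0("SBS_rand", 1:4)
rownames(panel) <- lab
res <- sbs_correlation(obs96, panel)
write.table(res, file.path(out, "sbs_correlation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("top signature by slope p-value:", res$signature[which.min(res$p)], "\n")
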