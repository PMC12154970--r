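# reference with hand-set bases at the positions used in the examples
example_reference <- function() {
  seq <- rep("A", 16569)
  seq[5000] <- "G"; seq[16300] <- "C"; seq[150] <- "T"; seq[3107] <- "N"
  mt_reference(seq, ori = c(16172, 210))
}

test_that("strand resolution, region and age-accumulating flag", {
  ref <- example_reference()
  cls <- classify_variants(c(5000, 16300, 150),
                           c("G", "C", "T"), c("A", "T", "C"), ref)
  # G>A at 5000: complement to heavy strand C>T, Other region -> age-accumulating
  expect_equal(cls$strand[1], "heavy")
  expect_equal(cls$substitution[1], "C>T")
  expect_equal(cls$region[1], "Other")
  expect_true(cls$age_accumulating[1])
  # C>T at 16300: light strand as-is, inside Ori -> not age-accumulating
  expect_equal(cls$strand[2], "light")
  expect_equal(cls$substitution[2], "C>T")
  expect_equal(cls$region[2], "Ori")
  expect_false(cls$age_accumulating[2])
  # T>C at 150: heavy strand A>G, but Ori excludes it
  expect_equal(cls$strand[3], "heavy")
  expect_equal(cls$substitution[3], "A>G")
  expect_equal(cls$region[3], "Ori")
  expect_false(cls$age_accumulating[3])
  # Ori bounds are inclusive on both sides
  seq2 <- rep("C", 16569)
  ref2 <- mt_reference(seq2, ori = c(16172, 210))
  b <- classify_variants(c(16171, 16172, 210, 211), "C", "T", ref2)
  expect_equal(b$region, c("Other", "Ori", "Ori", "Other"))

  expect_error(classify_variants(5000, "C", "T", ref), "mismatch")
  expect_error(classify_variants(3107, "N", "A", ref), "placeholder")
})

test_that("trinucleotide context wraps circularly and is strand-specific", {
  ref <- mt_reference(c("A", "C", "G", "T", "A"), ori = c(4, 1))
  expect_equal(trinucleotide_context(1, ref, "light"), "AAC")  # 5' is pos 5
  expect_equal(trinucleotide_context(3, ref, "heavy"), revcomp("CGT"))
  expect_equal(revcomp("CGT"), "ACG")
  # placeholder neighbour makes the context unusable
  refN <- mt_reference(c("A", "N", "G", "T", "A", rep("C", 95)), ori = c(97, 1))
  expect_true(is.na(trinucleotide_context(3, refN, "light")))
  expect_false(is.na(trinucleotide_context(5, refN, "light")))
})

test_that("classification is involution-consistent across strands", {
  ref <- tiny_reference(200, seed = 7)
  pos <- setdiff(1:200, ref$placeholder_positions)
  alts <- vapply(ref$seq[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                 character(1))
  cls <- classify_variants(pos, ref$seq[pos], alts, ref)
  # strand-resolved reference base is always C or A, and equals the centre
  # of the context 3-mer
  expect_true(all(substr(cls$substitution, 1, 1) %in% c("C", "A")))
  ok <- !is.na(cls$context)
  expect_equal(substr(cls$context[ok], 2, 2), substr(cls$substitution[ok], 1, 1))
  # complementing the allele pair is the identity in strand-resolved space:
  # a G>A variant classifies exactly as C>T would on the complement strand
  gpos <- pos[ref$seq[pos] == "G"]
  if (length(gpos)) {
    a <- classify_variants(gpos, "G", "A", ref)
    expect_true(all(a$strand == "heavy" & a$substitution == "C>T"))
  }
})

test_that("the strand-resolved category system has 192 categories", {
  expect_equal(length(context_categories(TRUE)), 192)
  expect_equal(length(context_categories(FALSE)), 96)
  expect_false(any(duplicated(context_categories(TRUE))))
})

test_that("possible-variant counts partition the genome", {
  ref <- mt_reference(rep("C", 100), ori = c(96, 2))
  expect_equal(count_possible(ref, "all", "light", "C>T"), 100)
  expect_equal(count_possible(ref, "all", "heavy", "C>T"), 0)

  ref2 <- tiny_reference(300, seed = 3, placeholder = 17)
  informative <- 299
  combos <- expand.grid(strand = c("light", "heavy"),
                        sub = c("C>A", "C>G", "C>T", "A>C", "A>G", "A>T"),
                        stringsAsFactors = FALSE)
  tot <- sum(mapply(function(s, b) count_possible(ref2, "all", s, b),
                    combos$strand, combos$sub))
  # every informative position supports exactly 3 substitutions
  expect_equal(tot, 3 * informative)
  # positions partition across the 4 (strand, reference base) groups
  pos_groups <- mapply(function(s, b) count_possible(ref2, "all", s, b),
                       c("light", "light", "heavy", "heavy"),
                       c("C>T", "A>G", "C>T", "A>G"))
  expect_equal(sum(pos_groups), informative)
  # region counts split the total
  expect_equal(count_possible(ref2, "Ori", "light", "C>T") +
               count_possible(ref2, "Other", "light", "C>T"),
               count_possible(ref2, "all", "light", "C>T"))
})

test_that("normalized mean counts divide by denominators over all samples", {
  seq <- rep("A", 16569); seq[3107] <- "N"; seq[5000] <- "G"
  ref <- mt_reference(seq, ori = c(16172, 210))
  samples <- make_samples(c("S1", "S2"))
  cs <- make_callset("S1", 5000, "G", "A")   # one heavy C>T, Other
  tab <- normalized_mean_counts(cs, samples, ref,
                                by = c("strand", "substitution", "region"))
  row <- tab[tab$strand == "heavy" & tab$substitution == "C>T" &
             tab$region == "Other", ]
  expect_equal(row$possible, 1)       # single G in the Other region
  expect_equal(row$mean_count, 0.5)   # 1 variant over 2 QC-pass samples
  expect_equal(row$normalized_mean, 0.5)
  # a category with a denominator but no observations is reported as 0
  rowA <- tab[tab$strand == "light" & tab$substitution == "A>G" &
              tab$region == "Other", ]
  # informative A positions outside Ori: 16568 total - 608 Ori - the one G
  expect_equal(rowA$possible, 16568 - 608 - 1)
  expect_equal(rowA$mean_count, 0)
  # permuting sample order leaves the table unchanged
  tab2 <- normalized_mean_counts(cs, samples[2:1, ], ref,
                                 by = c("strand", "substitution", "region"))
  expect_equal(tab, tab2)
})

test_that("normalized rates recover configured class-rate ratios", {
  ref <- generate_reference(2000, integer(0), seed = 55)
  cfg <- detect_all_config(n_samples = 3000, age_range = c(60, 60),
                           rates_per_year = c("C>T:heavy" = 0.06, "C>T:light" = 0.02),
                           baseline_rates = c("C>A:light" = 0))
  sim <- simulate_cohort(ref, NULL, cfg, seed = 9)
  tab <- normalized_mean_counts(sim$callset, sim$samples, ref,
                                by = c("strand", "substitution", "region"))
  h <- tab[tab$strand == "heavy" & tab$substitution == "C>T" & tab$region == "Other", ]
  l <- tab[tab$strand == "light" & tab$substitution == "C>T" & tab$region == "Other", ]
  # the generator spreads each class's per-person rate uniformly over its
  # position pool, so the normalized (per-position) rate ratio has
  # closed-form expectation (0.06/0.02) * possible_light / possible_heavy
  ratio <- h$normalized_mean / l$normalized_mean
  expected <- 3 * l$possible / h$possible
  se_ratio <- ratio * sqrt((h$normalized_se / h$normalized_mean)^2 +
                           (l$normalized_se / l$normalized_mean)^2)
  expect_lt(abs(ratio - expected), 3 * se_ratio)
})

test_that("age stratification restricts samples and reports empty strata", {
  seq <- rep("A", 16569); seq[3107] <- "N"
  ref <- mt_reference(seq, ori = c(16172, 210))
  samples <- make_samples(c("S1", "S2", "S3"), age = c(45, 52, 95))
  cs <- make_callset("S1", 100, "A", "G")
  tab <- normalized_mean_counts(cs, samples, ref, by = "strand",
                                age_breaks = c(40, 50, 60, 70))
  expect_false(any(grepl("95", tab$age_stratum)))   # age 95 outside range
  light_4050 <- tab[tab$strand == "light" & tab$age_stratum == "[40,50)", ]
  expect_equal(light_4050$n_samples, 1)
  light_6070 <- tab[tab$strand == "light" & tab$age_stratum == "[60,70]", ]
  expect_equal(light_6070$n_samples, 0)
  expect_true(is.na(light_6070$mean_count))
})

test_that("COSMIC 96 mapping re-references A-class variants to pyrimidines", {
  v <- cosmic96_spectrum(c("C>T", "A>G"), c("ACA", "TAG"), weights = c(2, 3))
  expect_equal(unname(v["A[C>T]A"]), 2)
  expect_equal(unname(v["C[T>C]A"]), 3)   # revcomp(TAG) = CTA, A>G -> T>C
  expect_equal(sum(v), 5)
  expect_equal(length(v), 96)
})

test_that("SBS correlation recovers exact and orthogonal spectra", {
  lab <- cosmic96_labels()
  set.seed(5)
  sig <- matrix(rexp(96 * 5), nrow = 96, dimnames = list(lab, paste0("SBS", 1:5)))
  sig <- sweep(sig, 2, colSums(sig), "/")
  # observed equal to signature 3 exactly (perfect-fit lm warning expected)
  res <- suppressWarnings(sbs_correlation(stats::setNames(sig[, 3], lab), sig))
  expect_equal(res$slope[3], 1)
  expect_lt(res$p[3], 1e-20)
  expect_equal(res$p_adj, pmin(1, res$p * 5))
  # observed residualized against signature 2 gives slope ~ 0
  y <- rexp(96)
  y_orth <- stats::setNames(resid(lm(y ~ sig[, 2])), lab)
  res2 <- sbs_correlation(y_orth, sig)
  expect_lt(abs(res2$slope[2]), 1e-10)
  # Bonferroni factor equals the number of signatures supplied (86 published)
  sig86 <- matrix(rexp(96 * 86), nrow = 96,
                  dimnames = list(lab, paste0("SBS", 1:86)))
  res86 <- sbs_correlation(stats::setNames(rexp(96), lab), sig86)
  expect_equal(res86$p_adj, pmin(1, res86$p * 86))
  expect_error(sbs_correlation(setNames(rexp(96), paste0("x", 1:96)), sig),
               "96 COSMIC")
})
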