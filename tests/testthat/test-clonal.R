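test_that("matched control sets reproduce the CH (age, sex) multiset exactly", {
  set.seed(1)
  n <- 400
  s <- make_samples(sprintf("M%04d", 1:n),
                    age = sample(60:70, n, replace = TRUE),
                    sex = sample(c("F", "M"), n, replace = TRUE))
  s$ch <- FALSE
  s$ch[sample.int(n, 40)] <- TRUE
  m <- match_controls(s, R = 20, seed = 5)
  key <- function(ids) sort(paste(floor(s$age), s$sex)[match(ids, s$sample_id)])
  ch_key <- key(m$ch_ids)
  for (set in m$control_sets) {
    expect_identical(key(set), ch_key)
    expect_false(any(s$ch[match(set, s$sample_id)]))
    expect_false(any(duplicated(set)))
  }
  # deterministic under seed
  expect_identical(m$control_sets, match_controls(s, R = 20, seed = 5)$control_sets)
  # a stratum with no eligible controls errors, naming the stratum
  s2 <- make_samples(c("A1", "A2"), age = c(99, 50), sex = "F", ch = c(TRUE, FALSE))
  expect_error(match_controls(s2, R = 2, seed = 1), "99 F")
})

test_that("matched difference test calibrates under the null and finds real shifts", {
  set.seed(2)
  n <- 1200
  s <- make_samples(sprintf("M%04d", 1:n),
                    age = sample(60:64, n, replace = TRUE),
                    sex = sample(c("F", "M"), n, replace = TRUE))
  s$ch <- seq_len(n) <= 150
  burden_null <- rpois(n, 1)
  burden_alt <- burden_null + ifelse(s$ch, rpois(n, 1), 0)  # CH doubled rate
  m <- match_controls(s, R = 100, seed = 9)
  stat_fun <- function(burden) {
    function(ids) c(mean_burden = mean(burden[match(ids, s$sample_id)]))
  }
  res_null <- matched_difference_test(m, stat_fun(burden_null))
  expect_equal(res_null$p_adj, res_null$p)  # single category: factor 1
  expect_gt(res_null$p, 0.001)
  res_alt <- matched_difference_test(m, stat_fun(burden_alt))
  expect_lt(res_alt$p, 1e-6)
  expect_gt(res_alt$diff, 0)
  # control point estimate is the mean over sets, SE the SD over sets
  ctrl_means <- vapply(m$control_sets, function(ids)
    mean(burden_alt[match(ids, s$sample_id)]), numeric(1))
  expect_equal(res_alt$control_mean, mean(ctrl_means))
  expect_equal(res_alt$control_se, sd(ctrl_means))
  # degenerate zero-SE case
  const_stat <- function(ids) c(x = if (any(s$ch[match(ids, s$sample_id)])) 1 else 0)
  expect_warning(res0 <- matched_difference_test(m, const_stat), "zero resampling SE")
  expect_equal(res0$p, 0)
})

test_that("multi-category Bonferroni singles out the perturbed class", {
  n <- 2000
  hits <- matrix(0, nrow = 20, ncol = 3,
                 dimnames = list(NULL, c("classA", "classB", "classC")))
  for (i in seq_len(20)) {
    set.seed(100 + i)
    s <- make_samples(sprintf("M%04d", 1:n),
                      age = sample(50:54, n, replace = TRUE),
                      sex = sample(c("F", "M"), n, replace = TRUE))
    s$ch <- seq_len(n) <= 100
    counts <- cbind(classA = rpois(n, 1 + s$ch * 1.5), classB = rpois(n, 1),
                    classC = rpois(n, 0.5))
    m <- match_controls(s, R = 100, seed = 100 + i)
    stat <- function(ids) colMeans(counts[match(ids, s$sample_id), , drop = FALSE])
    res <- matched_difference_test(m, stat)
    expect_equal(res$p_adj, pmin(1, res$p * 3))
    hits[i, ] <- res$p_adj < 0.05
  }
  # the doubled-rate class is detected essentially always; the two null
  # classes reject at no more than a small multiple of the nominal rate
  expect_gte(sum(hits[, "classA"]), 19)
  expect_lte(sum(hits[, c("classB", "classC")]), 4)
})

test_that("sibling sharing counts shared variants at any heteroplasmy", {
  # variant v1 carried by 6 individuals incl. both siblings (HL 0.6 / 0.1);
  # variant v2 carried by 3 individuals only -> excluded by the carrier rule;
  # variant v3 private to sibling 1, carried by 5 individuals cohort-wide
  cs <- rbind(
    make_callset(c("P1a", "P1b", "X1", "X2", "X3", "X4"), 100, "A", "G",
                 HL = c(0.6, 0.1, 0.2, 0.2, 0.2, 0.2)),
    make_callset(c("P1a", "X1", "X2"), 200, "A", "G", HL = 0.6),
    make_callset(c("P1a", "X1", "X2", "X3", "X4"), 300, "A", "G", HL = 0.6)
  )
  pairs <- data.frame(sib1 = "P1a", sib2 = "P1b")
  res <- sibling_sharing(cs, pairs, hl_bins = c(0, 0.95), min_carriers = 5)
  expect_equal(res$n, 2)          # v1 and v3 (v2 excluded)
  expect_equal(res$shared, 1)     # v1 found in both at any HL
  expect_equal(res$proportion, 0.5)
  # orientation defaults to the lexically smaller id as sibling 1
  res_rev <- sibling_sharing(cs, data.frame(sib1 = "P1b", sib2 = "P1a"),
                             hl_bins = c(0, 0.95), min_carriers = 5)
  expect_equal(res_rev$proportion, 0.5)
  expect_error(sibling_sharing(cs, data.frame(sib1 = c("P1a", "P1a"),
                                              sib2 = c("P1b", "X1"))),
               "duplicated")
})

test_that("transmitted variants in simulated siblings are recovered as shared", {
  ref <- generate_reference(2000, integer(0), seed = 61)
  cfg <- cohort_config(n_samples = 10, n_sibling_pairs = 40,
                       transmitted_mean = 2,
                       transmitted_hl_shape1 = 8, transmitted_hl_shape2 = 4,
                       rates_per_year = c("A>G:light" = 0),
                       baseline_rates = c("C>A:light" = 0))
  sim <- simulate_cohort(ref, NULL, cfg, seed = 15)
  sam <- sim$samples[!is.na(sim$samples$sibling_pair), ]
  pairs <- do.call(rbind, lapply(split(sam$sample_id, sam$sibling_pair),
                                 function(x) data.frame(sib1 = x[1], sib2 = x[2])))
  # transmitted true HL ~ Beta(8,4) is high, so detection in both siblings is
  # near-certain at these coverages; sharing should be (almost) complete
  res <- sibling_sharing(sim$callset, pairs, hl_bins = c(0, 1),
                         min_carriers = 1)
  expect_gt(res$n, 20)
  expect_gte(res$proportion, 0.95)
})

test_that("locus clumping merges overlapping 100kb windows", {
  assoc <- data.frame(pos = c(1e6, 1.15e6, 1.5e6, 2e6),
                      p = c(1e-8, 1e-6, 0.5, 1e-7))
  res <- clump_loci(assoc)
  expect_equal(nrow(res$loci), 2)           # 1.0M+1.15M merge; 2.0M separate
  expect_equal(res$loci$lead_pos, c(1e6, 2e6))
  expect_equal(res$loci$n_variants, c(2, 1))
  # disjoint partition of significant variants
  expect_equal(sum(res$loci$n_variants), sum(assoc$p < 5e-5))
  # leads attain the locus-minimal p
  expect_equal(res$loci$lead_p, c(1e-8, 1e-7))
  res2 <- clump_loci(data.frame(pos = c(1e6, 1.3e6), p = c(1e-8, 1e-8)))
  expect_equal(nrow(res2$loci), 2)          # 300kb apart: windows disjoint
  expect_equal(nrow(clump_loci(data.frame(pos = 1e6, p = 0.1))$loci), 0)
  # chromosomes never merge
  res3 <- clump_loci(data.frame(chrom = c("1", "2"), pos = c(1e6, 1.05e6),
                                p = c(1e-8, 1e-8)))
  expect_equal(nrow(res3$loci), 2)
})

test_that("IVW regression weights by both standard errors", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  res <- ivw_effect_correlation(bx, rep(0.05, 4), 2 * bx, rep(0.05, 4))
  expect_equal(res$slope, 2)
  expect_lt(res$p, 1e-10)
  # a wild outlier with huge SEs barely moves the slope
  res_out <- ivw_effect_correlation(c(bx, 0.4), c(rep(0.05, 4), 5),
                                    c(2 * bx, -30), c(rep(0.05, 4), 5))
  expect_lt(abs(res_out$slope - 2), 0.01)
  expect_error(ivw_effect_correlation(1:2, c(0.1, 0.1), 1:2, c(0.1, 0.1)),
               "at least 3")
  # null: slope CI covers 0 at ~95% over repetitions
  set.seed(8)
  covered <- replicate(200, {
    bx <- abs(rnorm(30, 0.2, 0.05)); sx <- rep(0.05, 30)
    sy <- runif(30, 0.02, 0.1)
    by <- rnorm(30, 0, sy)
    r <- ivw_effect_correlation(bx, sx, by, sy)
    abs(r$slope) < 1.96 * r$se
  })
  expect_gt(mean(covered), 0.90)
})

test_that("disease association applies the exclusion rules and recovers nulls", {
  set.seed(10)
  n <- 4000
  d <- data.frame(
    phenotype = rbinom(n, 1, 0.3),
    burden = rpois(n, 1),
    age = runif(n, 40, 70),
    sex = sample(c("F", "M"), n, replace = TRUE),
    ancestry = sample(c("EUR", "AFR", "EAS"), n, replace = TRUE,
                      prob = c(0.9, 0.08, 0.02)),
    haplogroup = sample(c("H", "U", "J"), n, replace = TRUE),
    smoker = runif(n) < 0.3
  )
  # an ancestry group with < 3 individuals in a phenotype class is excluded
  d$ancestry[d$ancestry == "EAS"] <- "EUR"
  d <- rbind(d, data.frame(phenotype = c(1, 1, 0), burden = 0, age = 50,
                           sex = "F", ancestry = "RARE", haplogroup = "H",
                           smoker = FALSE))
  res <- disease_association(d)
  expect_false(res$separation)
  expect_lte(res$n, sum(!d$smoker) - 3)      # smokers and RARE excluded
  expect_true(res$ci[1] < 1 & res$ci[2] > 1) # null burden: CI covers OR 1
  # inverse-rank-normalised burden also runs
  res_irn <- disease_association(d, inverse_rank_normalize = TRUE)
  expect_false(res_irn$separation)
  # complete separation is flagged, no estimate
  d2 <- data.frame(phenotype = rep(c(0, 1), each = 30),
                   burden = rep(c(0, 10), each = 30),
                   age = runif(60, 40, 70), sex = rep(c("F", "M"), 30))
  res2 <- disease_association(d2)
  expect_true(res2$separation)
  expect_true(is.na(res2$or))
})

test_that("positional score means respond as expected", {
  scores <- data.frame(pos = 1:100, score = 0.5)
  cs <- make_callset(rep(c("A1", "B1"), each = 3), c(1, 2, 3, 1, 2, 3), "A", "G")
  groups <- list(g1 = "A1", g2 = "B1")
  res <- mean_positional_score(cs, scores, groups)
  expect_equal(res$mean, c(0.5, 0.5))  # constant table
  # identical variant sets give identical means under a non-constant table
  scores2 <- data.frame(pos = 1:100, score = seq(0, 1, length.out = 100))
  res2 <- mean_positional_score(cs, scores2, groups)
  expect_equal(res2$mean[1], res2$mean[2])
  # affine transform of scores transforms means affinely
  scores3 <- transform(scores2, score = 3 * score + 1)
  res3 <- mean_positional_score(cs, scores3, groups)
  expect_equal(res3$mean, 3 * res2$mean + 1)
  # variants without scores are dropped with a message
  expect_message(res4 <- mean_positional_score(make_callset("A1", c(1, 101), "A", "G"),
                                               scores, list(g = "A1")),
                 "dropped")
  expect_equal(res4$n, 1)
})
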