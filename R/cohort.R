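#' Cohort generator configuration
#'
#' Encodes a two-step generative model of blood mtDNA heteroplasmy: cryptic
#' mutations accrue at low cell fraction from mtDNA replication errors, and
#' clonal expansion of a hematopoietic clone (clonal hematopoiesis, CH)
#' carries a subset of them up to detectable bulk heteroplasmy. Observed
#' calls are produced by binomial read sampling against Poisson site depth,
#' so the detection threshold interacts with coverage exactly as in real
#' callsets.
#'
#' Rates are expressed per class label "substitution:strand" in
#' strand-resolved space. \code{rates_per_year} classes accrue in the Other
#' (non-Ori) region proportionally to age (or, with
#' \code{timing = "embryogenesis"}, as a single early burst whose expected
#' count still scales with the configured rate times age at draw — the data
#' cannot distinguish the two, see the methods vignette); \code{baseline_rates}
#' classes have age-independent expected counts and arise genome-wide.
#'
#' @param n_samples cohort size.
#' @param age_range uniform age bounds in years.
#' @param rates_per_year named numeric: expected cryptic mutations per year
#'   for the age-accumulating process.
#' @param baseline_rates named numeric: age-flat expected cryptic counts.
#' @param cf_shape1,cf_shape2 Beta parameters of the per-mutation cell
#'   fraction for mutations outside the expanded clone (concentrated near 0).
#' @param ch_intercept,ch_slope logistic model of CH prevalence vs age.
#' @param clone_frac_shape1,clone_frac_shape2 Beta parameters of a CH
#'   carrier's clonal fraction.
#' @param clone_carry_prob probability that a given cryptic mutation of a CH
#'   carrier sits on the expanded clone (its bulk HL then equals the clonal
#'   fraction).
#' @param mt_coverage_meanlog,mt_coverage_sdlog lognormal mean mtDNA coverage.
#' @param nuc_coverage_mean,nuc_coverage_sd normal mean nuclear coverage
#'   (truncated below at 5).
#' @param n_sibling_pairs number of sibling pairs (appended as paired
#'   samples sharing transmitted variants at identical true HL).
#' @param transmitted_mean expected transmitted variants per pair.
#' @param transmitted_hl_shape1,transmitted_hl_shape2 Beta parameters of
#'   transmitted-variant heteroplasmy.
#' @param contamination_outlier_prob probability a sample carries a
#'   contamination estimate above the 2% QC cutoff.
#' @param timing "aging" (cryptic mutations accumulate through life) or
#'   "embryogenesis" (generated early); both give counts proportional to
#'   age x rate by construction.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(
    n_samples = 1000,
    age_range = c(18, 90),
    rates_per_year = c("C>T:heavy" = 0.04, "A>G:heavy" = 0.05, "A>G:light" = 0.015),
    baseline_rates = c("C>A:light" = 0.2, "C>G:light" = 0.1, "C>T:light" = 0.4,
                       "A>C:light" = 0.1, "A>T:light" = 0.1,
                       "C>A:heavy" = 0.2, "C>G:heavy" = 0.1,
                       "A>C:heavy" = 0.1, "A>G:heavy" = 0, "A>T:heavy" = 0.1),
    cf_shape1 = 0.3, cf_shape2 = 30,
    ch_intercept = -8, ch_slope = 0.08,
    clone_frac_shape1 = 2, clone_frac_shape2 = 6,
    clone_carry_prob = 0.25,
    mt_coverage_meanlog = log(2000), mt_coverage_sdlog = 0.3,
    nuc_coverage_mean = 30, nuc_coverage_sd = 3,
    n_sibling_pairs = 0,
    transmitted_mean = 1,
    transmitted_hl_shape1 = 2, transmitted_hl_shape2 = 5,
    contamination_outlier_prob = 0.01,
    timing = c("aging", "embryogenesis")) {
  timing <- match.arg(timing)
  cfg <- as.list(environment())
  stopifnot(all(rates_per_year >= 0), all(baseline_rates >= 0),
            cf_shape1 > 0, cf_shape2 > 0,
            clone_frac_shape1 > 0, clone_frac_shape2 > 0,
            clone_carry_prob >= 0, clone_carry_prob <= 1,
            n_samples >= 1, age_range[1] <= age_range[2])
  class(cfg) <- "cohort_config"
  cfg
}

# position pools per "substitution:strand" class, optionally Other-region only
class_position_pools <- function(reference, other_only) {
  tab <- position_classes(reference)
  if (other_only) tab <- tab[tab$region == "Other", , drop = FALSE]
  pools <- list()
  for (b in c("C", "A")) {
    alts <- setdiff(c("A", "C", "G", "T"), b)
    for (s in c("light", "heavy")) {
      pos <- tab$pos[tab$base == b & tab$strand == s]
      for (a in alts) pools[[paste0(b, ">", a, ":", s)]] <- pos
    }
  }
  pools
}

#' Simulate a cohort of heteroplasmy callsets
#'
#' Draws per-sample demographics, CH status and coverages; generates cryptic
#' mutations per class (age-proportional for the configured age-accumulating
#' process, age-flat baselines elsewhere); assigns cell fractions (small
#' Beta draws, or the clonal fraction for clone-borne mutations in CH
#' carriers); and emits observed calls via alt depth ~ Binomial(site depth,
#' true HL) with site depth ~ Poisson(mean mtDNA coverage), keeping calls
#' with alt depth >= 1. Observed HL is alt depth / site depth. Sibling pairs
#' share transmitted variants at identical true HL; somatic variants are
#' private. Deterministic under \code{seed}.
#'
#' @param reference an [mt_reference].
#' @param gene_model gene model data.frame (unused by the generator itself
#'   but carried for provenance; may be NULL).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list: samples (sample table with demographics, QC fields, raw
#'   mtCN, sibling_pair), callset (sample_id, pos, ref, alt, HL, AD, DP,
#'   filter, plus truth columns true_hl, class, on_clone, transmitted).
#' @export
simulate_cohort <- function(reference, gene_model = NULL, config = cohort_config(),
                            seed = 1) {
  set.seed(seed)
  n <- config$n_samples + 2L * config$n_sibling_pairs
  ids <- sprintf("S%05d", seq_len(n))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ch <- stats::rbinom(n, 1, stats::plogis(config$ch_intercept + config$ch_slope * age)) == 1
  clone_frac <- ifelse(ch, stats::rbeta(n, config$clone_frac_shape1, config$clone_frac_shape2), NA)
  mt_cov <- stats::rlnorm(n, config$mt_coverage_meanlog, config$mt_coverage_sdlog)
  nuc_cov <- pmax(5, stats::rnorm(n, config$nuc_coverage_mean, config$nuc_coverage_sd))
  contam_out <- stats::runif(n) < config$contamination_outlier_prob
  mt_contam <- ifelse(contam_out, 0.05, stats::rbeta(n, 1, 200))

  sibling_pair <- rep(NA_integer_, n)
  if (config$n_sibling_pairs > 0) {
    sib_idx <- config$n_samples + seq_len(2L * config$n_sibling_pairs)
    sibling_pair[sib_idx] <- rep(seq_len(config$n_sibling_pairs), each = 2L)
  }

  samples <- data.frame(
    sample_id = ids, age = age, sex = sex, ch = ch,
    clone_fraction = clone_frac,
    mt_contamination = mt_contam,
    nuc_contamination = stats::rbeta(n, 1, 300),
    overlapping_homoplasmies = FALSE,
    haplogroup_conflict = FALSE,
    pilot = FALSE,
    haplogroup = sample(c("H", "U", "J", "T", "K"), n, replace = TRUE,
                        prob = c(0.45, 0.2, 0.15, 0.1, 0.1)),
    smoker = stats::runif(n) < 0.3,
    mean_mt_coverage = mt_cov,
    mean_nuc_coverage = nuc_cov,
    sibling_pair = sibling_pair,
    stringsAsFactors = FALSE
  )
  samples$mtcn_raw <- raw_mtcn(samples$mean_mt_coverage, samples$mean_nuc_coverage)

  pools_other <- class_position_pools(reference, other_only = TRUE)
  pools_all <- class_position_pools(reference, other_only = FALSE)

  draw_class <- function(class_label, lam_per_sample, pools, cryptic) {
    pool <- pools[[class_label]]
    if (is.null(pool) || !length(pool)) return(NULL)
    k <- stats::rpois(n, lam_per_sample)
    tot <- sum(k)
    if (tot == 0) return(NULL)
    data.frame(
      sample_idx = rep(seq_len(n), k),
      pos = pool[sample.int(length(pool), tot, replace = TRUE)],
      class = class_label,
      cryptic = cryptic,
      stringsAsFactors = FALSE
    )
  }

  muts <- list()
  for (cl in names(config$rates_per_year)) {
    if (config$rates_per_year[[cl]] > 0) {
      muts[[length(muts) + 1L]] <-
        draw_class(cl, age * config$rates_per_year[[cl]], pools_other,
                   cryptic = TRUE)
    }
  }
  for (cl in names(config$baseline_rates)) {
    if (config$baseline_rates[[cl]] > 0) {
      muts[[length(muts) + 1L]] <-
        draw_class(cl, rep(config$baseline_rates[[cl]], n), pools_all,
                   cryptic = FALSE)
    }
  }
  muts <- if (length(muts)) do.call(rbind, muts) else
    data.frame(sample_idx = integer(0), pos = integer(0), class = character(0),
               cryptic = logical(0))

  if (nrow(muts)) {
    # one latent mutation per (sample, position)
    muts <- muts[!duplicated(muts[c("sample_idx", "pos")]), , drop = FALSE]
    m <- nrow(muts)
    cf <- stats::rbeta(m, config$cf_shape1, config$cf_shape2)
    # only cell-private cryptic replication-error mutations ride the expanded
    # clone; baseline-process variants are carried uniformly across cells, so
    # clonal expansion leaves their bulk heteroplasmy unchanged
    on_clone <- ch[muts$sample_idx] & muts$cryptic &
      stats::runif(m) < config$clone_carry_prob
    cf[on_clone] <- clone_frac[muts$sample_idx[on_clone]]
    muts$true_hl <- pmin(cf, 1)
    muts$on_clone <- on_clone
    muts$transmitted <- FALSE
  }

  if (config$n_sibling_pairs > 0) {
    trans <- list()
    pool_any <- setdiff(seq_len(reference$length), reference$placeholder_positions)
    for (p in seq_len(config$n_sibling_pairs)) {
      k <- stats::rpois(1, config$transmitted_mean)
      if (k == 0) next
      pos <- sample(pool_any, k)
      hl <- stats::rbeta(k, config$transmitted_hl_shape1, config$transmitted_hl_shape2)
      # the transmitted allele is one variant shared by the pair
      alt <- vapply(reference$seq[pos], function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1))
      pair_idx <- config$n_samples + 2L * (p - 1L) + c(1L, 2L)
      trans[[length(trans) + 1L]] <- data.frame(
        sample_idx = rep(pair_idx, each = k),
        pos = rep(pos, 2L), class = NA_character_, cryptic = FALSE,
        alt = rep(alt, 2L),
        true_hl = rep(hl, 2L), on_clone = FALSE, transmitted = TRUE,
        stringsAsFactors = FALSE
      )
    }
    if (length(trans)) {
      somatic <- if (nrow(muts)) transform(muts, alt = NA_character_) else NULL
      muts <- rbind(somatic, do.call(rbind, trans))
      muts <- muts[!duplicated(muts[c("sample_idx", "pos")]), , drop = FALSE]
    }
  }

  if (!nrow(muts)) {
    callset <- data.frame(sample_id = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          HL = numeric(0), AD = integer(0), DP = integer(0),
                          filter = character(0), true_hl = numeric(0),
                          class = character(0), on_clone = logical(0),
                          transmitted = logical(0), stringsAsFactors = FALSE)
    return(list(samples = samples, callset = callset))
  }

  # alleles: ref from genome; somatic alts follow the class (strand-resolved),
  # transmitted alts were fixed per shared variant above
  muts$ref <- reference$seq[muts$pos]
  if (is.null(muts$alt)) muts$alt <- NA_character_
  has_class <- !is.na(muts$class)
  sub_alt <- substr(muts$class[has_class], 3, 3)
  strand <- sub("^.*:", "", muts$class[has_class])
  muts$alt[has_class] <- ifelse(strand == "light", sub_alt, complement_bases(sub_alt))

  dp <- stats::rpois(nrow(muts), mt_cov[muts$sample_idx])
  ad <- stats::rbinom(nrow(muts), dp, muts$true_hl)
  emitted <- ad >= 1L
  callset <- data.frame(
    sample_id = ids[muts$sample_idx[emitted]],
    pos = muts$pos[emitted],
    ref = muts$ref[emitted],
    alt = muts$alt[emitted],
    HL = ad[emitted] / dp[emitted],
    AD = ad[emitted],
    DP = dp[emitted],
    filter = "PASS",
    true_hl = muts$true_hl[emitted],
    class = muts$class[emitted],
    on_clone = muts$on_clone[emitted],
    transmitted = muts$transmitted[emitted],
    stringsAsFactors = FALSE
  )
  callset <- callset[order(callset$sample_id, callset$pos, callset$alt), , drop = FALSE]
  rownames(callset) <- NULL
  list(samples = samples, callset = callset)
}

#' Simulate binary disease phenotypes from a burden
#'
#' phenotype ~ Bernoulli(logistic(intercept + beta * burden + age_beta * age)).
#'
#' @param samples sample table (needs age when \code{age_beta != 0}).
#' @param burden numeric vector aligned to \code{samples} rows.
#' @param beta log odds ratio per unit burden.
#' @param intercept log odds at zero burden (and age 0 if age_beta != 0).
#' @param age_beta optional log odds per year of age.
#' @param seed integer seed.
#' @return integer 0/1 phenotype vector.
#' @export
simulate_phenotypes <- function(samples, burden, beta = log(1.5),
                                intercept = stats::qlogis(0.1),
                                age_beta = 0, seed = 1) {
  stopifnot(length(burden) == nrow(samples))
  set.seed(seed)
  eta <- intercept + beta * burden +
    if (age_beta != 0) age_beta * samples$age else 0
  stats::rbinom(nrow(samples), 1, stats::plogis(eta))
}
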