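# Shared fixtures, built in code.

# brute-force Poisson threshold oracle: smallest t with P(X < t) >= q,
# by direct pmf summation (independent of qpois)
oracle_poisson_threshold <- function(lambda, q) {
  t <- 0L
  cum <- 0  # P(X < t) with t = 0 is 0
  repeat {
    if (cum >= q) return(t)
    cum <- cum + exp(-lambda + t * log(lambda) - lgamma(t + 1))
    t <- t + 1L
  }
}

# a small circular reference with a hand-chosen sequence; no placeholder
# unless asked. Ori wraps the origin.
tiny_reference <- function(n = 120, seed = 42, placeholder = integer(0)) {
  set.seed(seed)
  seq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  seq[placeholder] <- "N"
  mt_reference(seq, ori = default_ori_bounds(n))
}

# two-gene toy genome with hand-designed codons for consequence oracles:
#   gene L (light strand): CDS = bases 11..22 read forward
#   gene H (heavy strand): CDS = reverse complement of bases 31..42
toy_coding_genome <- function() {
  seq <- rep("A", 120)
  # light gene: ATG GCA TTA CAA at 11..22
  seq[11:22] <- strsplit("ATGGCATTACAA", "")[[1]]
  # heavy gene: we want CDS (read on heavy strand) = ATG CCT TGG TAA;
  # the light-strand span 31..42 is its reverse complement
  cds_h <- "ATGCCTTGGTAA"
  seq[31:42] <- strsplit(paste(rev(strsplit(chartr("ACGT", "TGCA", cds_h), "")[[1]]), collapse = ""), "")[[1]]
  ref <- mt_reference(seq, ori = c(110, 5))
  gm <- data.frame(
    gene = c("L1", "H1"),
    start = c(11L, 31L),
    end = c(22L, 42L),
    strand = c("light", "heavy"),
    coding = TRUE, frame = 0L,
    stringsAsFactors = FALSE
  )
  list(reference = ref, gene_model = gm)
}

# minimal long-format callset constructor
make_callset <- function(sample_id, pos, ref, alt, HL = 0.1, AD = 10L,
                         DP = 100L, filter = "PASS") {
  data.frame(sample_id = sample_id, pos = as.integer(pos), ref = ref,
             alt = alt, HL = HL, AD = as.integer(AD), DP = as.integer(DP),
             filter = filter, stringsAsFactors = FALSE)
}

# sample table with clean QC fields
make_samples <- function(ids, age = 50, sex = "F", ch = FALSE, mtcn = 100) {
  n <- length(ids)
  data.frame(
    sample_id = ids,
    age = rep_len(age, n), sex = rep_len(sex, n), ch = rep_len(ch, n),
    mt_contamination = 0, nuc_contamination = 0,
    overlapping_homoplasmies = FALSE, haplogroup_conflict = FALSE,
    pilot = FALSE, mtcn_raw = rep_len(mtcn, n),
    stringsAsFactors = FALSE
  )
}

# cohort configuration with (near-)certain detection: cell fractions
# concentrated at 1 and high coverage, so emitted counts equal latent counts
detect_all_config <- function(...) {
  cohort_config(cf_shape1 = 200, cf_shape2 = 0.5,
                mt_coverage_meanlog = log(3000), mt_coverage_sdlog = 0.05,
                ch_intercept = -30, contamination_outlier_prob = 0, ...)
}
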