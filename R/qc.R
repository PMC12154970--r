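#' Per-individual Poisson read-depth detection threshold
#'
#' The burden callset keeps a heteroplasmic SNV only if its alternate-allele
#' depth reaches a per-person threshold: the smallest integer t such that a
#' Poisson(lambda) site — lambda being the person's mean nuclear coverage —
#' has probability at least q of showing *less* coverage than t,
#' i.e. t = min\{k : P(X < k) >= q\}. At q = 0.95 this is the depth exceeded
#' by at most 5% of nuclear genomic sites, guarding against reads
#' misassigned from nuclear segments of mitochondrial origin (NUMTs).
#'
#' @param lambda mean nuclear coverage (reads/base), > 0; vectorized.
#' @param q Poisson quantile, in (0,1); default 0.95.
#' @param basis kept for configuration transparency: "nuclear" (default,
#'   the Methods definition) or "mito" if callers supply mean mtDNA coverage
#'   as lambda instead. The arithmetic is identical.
#' @return integer threshold(s) t, nondecreasing in lambda and q.
#' @export
poisson_detection_threshold <- function(lambda, q = 0.95,
                                        basis = c("nuclear", "mito")) {
  basis <- match.arg(basis)
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (q <= 0 || q >= 1) stop("q must be in (0,1)")
  # min{k : P(X <= k-1) >= q}  ==  qpois(q, lambda) + 1
  as.integer(stats::qpois(q, lambda)) + 1L
}

#' Sample-level quality control
#'
#' Removes samples flagged for abnormally overlapping homoplasmies, with
#' mtDNA or nuclear contamination estimates above 2%, with multiple
#' haplogroup-defining variants at relatively low heteroplasmy, or collected
#' in the pilot phase. In \code{variants} mode, samples with raw mtDNA copy
#' number below 50 are additionally removed (low mtCN inflates NUMT
#' contamination risk); copy-number analyses keep them. Each removed sample
#' is logged with exactly one primary reason (first matching rule in the
#' order above).
#'
#' @param samples sample table; required columns: sample_id,
#'   overlapping_homoplasmies, mt_contamination, nuc_contamination,
#'   haplogroup_conflict, pilot (and mtcn_raw in variants mode).
#' @param analysis_mode "copy_number" or "variants".
#' @param max_contamination contamination cutoff (default 0.02).
#' @param min_mtcn mtCN cutoff in variants mode (default 50).
#' @return list: kept (sample table subset), report (data.frame sample_id,
#'   reason), counts (named vector: input, kept, per-reason removals).
#' @export
filter_samples <- function(samples, analysis_mode = c("variants", "copy_number"),
                           max_contamination = 0.02, min_mtcn = 50) {
  analysis_mode <- match.arg(analysis_mode)
  required <- c("sample_id", "overlapping_homoplasmies", "mt_contamination",
                "nuc_contamination", "haplogroup_conflict", "pilot")
  if (analysis_mode == "variants") required <- c(required, "mtcn_raw")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("missing required sample column(s): ", paste(missing_cols, collapse = ", "))
  }
  reason <- rep(NA_character_, nrow(samples))
  rule <- function(cond, label) ifelse(is.na(reason) & cond, label, reason)
  reason <- rule(samples$overlapping_homoplasmies, "overlapping_homoplasmies")
  reason <- rule(samples$mt_contamination > max_contamination |
                 samples$nuc_contamination > max_contamination, "contamination")
  reason <- rule(samples$haplogroup_conflict, "haplogroup_conflict")
  reason <- rule(samples$pilot, "pilot")
  if (analysis_mode == "variants") {
    reason <- rule(samples$mtcn_raw < min_mtcn, "low_mtcn")
  }
  removed <- !is.na(reason)
  report <- data.frame(sample_id = samples$sample_id[removed],
                       reason = reason[removed], stringsAsFactors = FALSE)
  counts <- c(input = nrow(samples), kept = sum(!removed),
              table(factor(report$reason)))
  list(kept = samples[!removed, , drop = FALSE], report = report, counts = counts)
}

#' Genotype recoding
#'
#' Drops any genotype carrying a caller QC filter flag; recodes genotypes
#' with HL < 0.01 as homoplasmic for the reference allele (the variant is
#' treated as absent downstream); recodes missing genotypes (HL is NA) as
#' homoplasmic reference when site coverage is at least
#' \code{min_missing_coverage} (100), otherwise leaves them missing.
#'
#' @param callset callset with columns HL, DP, filter ("PASS" or "" = clean).
#' @param min_missing_coverage coverage needed to call a missing genotype
#'   homoplasmic reference.
#' @return callset with a \code{genotype} column in \{heteroplasmic,
#'   homoplasmic_alt, homoplasmic_ref, missing\}; flagged rows removed.
#' @export
recode_genotypes <- function(callset, min_missing_coverage = 100) {
  clean <- is.na(callset$filter) | callset$filter %in% c("", "PASS", ".")
  callset <- callset[clean, , drop = FALSE]
  gt <- ifelse(is.na(callset$HL),
               ifelse(callset$DP >= min_missing_coverage, "homoplasmic_ref", "missing"),
        ifelse(callset$HL < 0.01, "homoplasmic_ref",
        ifelse(callset$HL > 0.95, "homoplasmic_alt", "heteroplasmic")))
  callset$genotype <- gt
  callset
}

#' Heteroplasmy-level variant filters
#'
#' \code{common} mode (individual common heteroplasmies): keeps variants
#' with 0.05 <= HL <= 0.95 (both bounds inclusive). \code{burden} mode
#' (SNV burden): keeps SNVs with HL <= 0.95 whose alternate allele depth
#' reaches the per-sample Poisson detection threshold; indels are excluded
#' by construction. Rows recoded away from heteroplasmic by
#' [recode_genotypes()] are dropped in both modes.
#'
#' @param callset callset (after [recode_genotypes()] if a genotype column
#'   is wanted; otherwise raw HL/AD are used).
#' @param mode "common" or "burden".
#' @param thresholds burden mode: named integer vector of per-sample
#'   read-depth thresholds (names = sample_id), from
#'   [poisson_detection_threshold()].
#' @return filtered callset.
#' @export
apply_hl_filter <- function(callset, mode = c("burden", "common"),
                            thresholds = NULL) {
  mode <- match.arg(mode)
  if ("genotype" %in% names(callset)) {
    callset <- callset[callset$genotype == "heteroplasmic", , drop = FALSE]
  }
  if (mode == "common") {
    keep <- !is.na(callset$HL) & callset$HL >= 0.05 & callset$HL <= 0.95
    return(callset[keep, , drop = FALSE])
  }
  if (is.null(thresholds)) {
    stop("burden mode requires per-sample detection thresholds")
  }
  t_i <- thresholds[as.character(callset$sample_id)]
  if (any(is.na(t_i))) {
    stop("no detection threshold for sample(s): ",
         paste(unique(callset$sample_id[is.na(t_i)]), collapse = ", "))
  }
  is_snv <- nchar(callset$ref) == 1 & nchar(callset$alt) == 1 &
    callset$ref %in% c("A", "C", "G", "T") & callset$alt %in% c("A", "C", "G", "T")
  keep <- is_snv & !is.na(callset$HL) & callset$HL <= 0.95 & callset$AD >= t_i
  callset[keep, , drop = FALSE]
}

#' The published burden-QC variant blacklist
#'
#' Five recurrent variants whose detections rose by more than 500% under the
#' lenient allele-depth filter relative to the HL > 0.05 filter while being
#' detected more than 30 times, in either of two large cohorts — a signature
#' of NUMT artefacts rather than true low-level heteroplasmy.
#'
#' @return data.frame: pos, ref, alt.
#' @export
default_blacklist <- function() {
  data.frame(
    pos = c(11467L, 12684L, 12705L, 13052L, 13095L),
    ref = c("A", "G", "C", "A", "T"),
    alt = c("G", "A", "T", "G", "C"),
    stringsAsFactors = FALSE
  )
}

#' Remove blacklisted variants from a callset
#'
#' Exact (pos, ref, alt) matches are removed across all samples; row order
#' is otherwise preserved.
#'
#' @param callset callset with pos, ref, alt.
#' @param blacklist data.frame with pos, ref, alt (default: the packaged
#'   published list, see [default_blacklist()]).
#' @return list: callset (filtered), removed (number of rows removed).
#' @export
apply_blacklist <- function(callset, blacklist = default_blacklist()) {
  if (!all(c("pos", "ref", "alt") %in% names(blacklist)) ||
      any(is.na(blacklist$pos)) ||
      (nrow(blacklist) > 0 && !all(nchar(blacklist$ref) >= 1 & nchar(blacklist$alt) >= 1))) {
    stop("malformed blacklist: need complete pos, ref, alt columns")
  }
  key <- function(df) paste(df$pos, df$ref, df$alt, sep = ":")
  hit <- key(callset) %in% key(blacklist)
  list(callset = callset[!hit, , drop = FALSE], removed = sum(hit))
}

#' Derive a blacklist from lenient vs strict callsets
#'
#' The published list was derived by comparing, in each of two cohorts, the
#' per-variant detection count under the lenient allele-depth burden filter
#' against the HL > 0.05 filter: variants whose count increased by more than
#' \code{min_increase} x 100% and that were detected more than
#' \code{min_detections} times in either cohort are flagged. Provided as a
#' testable rule on any such pair(s) of callsets; the published 5-entry list
#' ships as the packaged default.
#'
#' @param lenient,strict callsets (or lists of callsets, one per cohort)
#'   with pos, ref, alt; one row per detection.
#' @param min_increase minimum fractional increase (5 = 500%).
#' @param min_detections minimum detections under the lenient filter.
#' @return data.frame: pos, ref, alt of flagged variants.
#' @export
derive_blacklist <- function(lenient, strict, min_increase = 5,
                             min_detections = 30) {
  if (is.data.frame(lenient)) lenient <- list(lenient)
  if (is.data.frame(strict)) strict <- list(strict)
  stopifnot(length(lenient) == length(strict))
  flagged <- character(0)
  for (i in seq_along(lenient)) {
    key_l <- paste(lenient[[i]]$pos, lenient[[i]]$ref, lenient[[i]]$alt, sep = ":")
    key_s <- paste(strict[[i]]$pos, strict[[i]]$ref, strict[[i]]$alt, sep = ":")
    nl <- table(key_l)
    ns <- table(key_s)[names(nl)]
    ns[is.na(ns)] <- 0L
    inc <- (as.numeric(nl) - as.numeric(ns)) / pmax(as.numeric(ns), 1)
    hit <- names(nl)[inc > min_increase & as.numeric(nl) > min_detections]
    flagged <- union(flagged, hit)
  }
  if (!length(flagged)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0)))
  }
  parts <- do.call(rbind, strsplit(flagged, ":", fixed = TRUE))
  out <- data.frame(pos = as.integer(parts[, 1]), ref = parts[, 2],
                    alt = parts[, 3], stringsAsFactors = FALSE)
  out[order(out$pos, out$alt), , drop = FALSE]
}

#' Per-sample heteroplasmic SNV burden
#'
#' Counts QC-pass heteroplasmic SNVs per person; every QC-pass sample
#' appears in the output, with people carrying no retained variants kept as
#' zeros. The age-accumulating burden counts only variants in the
#' age-accumulating classes (the phenotype used for the bulk of genetic
#' association analyses).
#'
#' @param callset burden-QC'd callset; needs an \code{age_accumulating}
#'   column when \code{class_filter = "age_accumulating"}.
#' @param samples QC-pass sample table (sample_id).
#' @param class_filter "all" or "age_accumulating".
#' @return data.frame: sample_id, burden (integer).
#' @export
compute_snv_burden <- function(callset, samples,
                               class_filter = c("all", "age_accumulating")) {
  class_filter <- match.arg(class_filter)
  absent <- setdiff(unique(callset$sample_id), samples$sample_id)
  if (length(absent)) {
    stop("callset sample(s) absent from sample table: ",
         paste(absent, collapse = ", "))
  }
  if (class_filter == "age_accumulating") {
    if (!"age_accumulating" %in% names(callset)) {
      stop("callset lacks an age_accumulating classification column")
    }
    callset <- callset[callset$age_accumulating, , drop = FALSE]
  }
  counts <- tabulate(match(callset$sample_id, samples$sample_id),
                     nbins = nrow(samples))
  data.frame(sample_id = samples$sample_id, burden = as.integer(counts),
             stringsAsFactors = FALSE)
}
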