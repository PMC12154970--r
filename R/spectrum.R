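#' Strand-resolved variant classification
#'
#' The mtDNA reference sequence represents the light strand. Variants whose
#' reference allele is C or A are reported on the light strand as-is; those
#' with reference G or T are complemented and reported on the heavy strand.
#' Every SNV therefore falls into one of six substitution classes
#' (C>A, C>G, C>T, A>C, A>G, A>T) on one of two strands. Positions between
#' the Ori bounds (wrapping the origin) are region "Ori", all others
#' "Other". The age-accumulating classes are the Other-region variants that
#' are A>G on either strand or C>T on the heavy strand.
#'
#' @param pos,ref,alt parallel vectors describing SNVs (single bases).
#' @param reference an [mt_reference]; \code{ref} must match its base at
#'   \code{pos}.
#' @return data.frame with columns strand, substitution, region, context
#'   (strand-resolved trinucleotide, NA when a flank is a placeholder),
#'   age_accumulating.
#' @export
classify_variants <- function(pos, ref, alt, reference) {
  pos <- as.integer(pos)
  ref <- rep_len(toupper(ref), length(pos))
  alt <- rep_len(toupper(alt), length(pos))
  if (any(pos %in% reference$placeholder_positions)) {
    stop("cannot classify variants at placeholder positions")
  }
  genome_ref <- ref_base(reference, pos)
  if (any(ref != genome_ref)) {
    bad <- which(ref != genome_ref)[1]
    stop(sprintf("ref allele mismatch at position %d: given %s, reference %s",
                 pos[bad], ref[bad], genome_ref[bad]))
  }
  light <- ref %in% c("C", "A")
  strand <- ifelse(light, "light", "heavy")
  sub_ref <- ifelse(light, ref, complement_bases(ref))
  sub_alt <- ifelse(light, alt, complement_bases(alt))
  substitution <- paste0(sub_ref, ">", sub_alt)
  region <- ifelse(in_ori(reference, pos), "Ori", "Other")
  context <- trinucleotide_context(pos, reference, strand)
  age_acc <- region == "Other" &
    (substitution == "A>G" | (substitution == "C>T" & strand == "heavy"))
  data.frame(
    strand = strand, substitution = substitution, region = region,
    context = context, age_accumulating = age_acc,
    stringsAsFactors = FALSE
  )
}

#' Strand-specific trinucleotide context
#'
#' Light strand: the bases at (pos-1, pos, pos+1) with circular wrap. Heavy
#' strand: the reverse complement of that window, so the centre base is the
#' strand-resolved reference allele. Windows touching a placeholder are
#' returned as NA (unusable).
#'
#' @param pos integer positions.
#' @param reference an [mt_reference].
#' @param strand "light" or "heavy", recycled.
#' @return character vector of 3-mers (NA where unusable).
#' @export
trinucleotide_context <- function(pos, reference, strand) {
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  up <- ref_base(reference, pos - 1L)
  ce <- ref_base(reference, pos)
  dn <- ref_base(reference, pos + 1L)
  ctx <- paste0(up, ce, dn)
  ctx[strand == "heavy"] <- revcomp(ctx[strand == "heavy"])
  ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
  ctx
}

#' The strand-resolved category system
#'
#' Six substitution classes x 16 flank pairs x 2 strands = 192 context
#' categories; collapsing strands yields the standard 96.
#'
#' @param by_strand keep strands separate (192 labels) or collapse (96).
#' @return character vector of labels "strand:X[R>A]Y" (or "X[R>A]Y").
#' @export
context_categories <- function(by_strand = TRUE) {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "A>C", "A>G", "A>T")
  grid <- expand.grid(up = bases, sub = subs, dn = bases,
                      stringsAsFactors = FALSE)
  lab <- sprintf("%s[%s]%s", grid$up, grid$sub, grid$dn)
  lab <- sort(lab)
  if (!by_strand) return(lab)
  sort(c(paste0("light:", lab), paste0("heavy:", lab)))
}

#' Count possible variants in a category (normalisation denominator)
#'
#' Counts non-placeholder positions whose strand-resolved reference base
#' matches the substitution's reference base (and whose strand-resolved
#' trinucleotide context matches, when given), one count per specific
#' alternate allele. Since a substitution class names a single alternate,
#' the denominator equals the number of qualifying positions.
#'
#' @param reference an [mt_reference].
#' @param region "Ori", "Other" or "all".
#' @param strand "light" or "heavy".
#' @param substitution class label like "C>T" (strand-resolved).
#' @param context optional strand-resolved 3-mer to restrict to.
#' @return integer count.
#' @export
count_possible <- function(reference, region = "all", strand, substitution,
                           context = NULL) {
  tab <- position_classes(reference)
  keep <- tab$strand == strand &
    tab$base == substr(substitution, 1, 1)
  if (region != "all") keep <- keep & tab$region == region
  if (!is.null(context)) keep <- keep & !is.na(tab$context) & tab$context == context
  sum(keep)
}

# per-position strand-resolved base, region, context (cached per call)
position_classes <- function(reference) {
  pos <- setdiff(seq_len(reference$length), reference$placeholder_positions)
  b <- reference$seq[pos]
  light <- b %in% c("C", "A")
  strand <- ifelse(light, "light", "heavy")
  base <- ifelse(light, b, complement_bases(b))
  data.frame(
    pos = pos, strand = strand, base = base,
    region = ifelse(in_ori(reference, pos), "Ori", "Other"),
    context = trinucleotide_context(pos, reference, strand),
    stringsAsFactors = FALSE
  )
}

#' Per-person normalized mean variant counts
#'
#' For each variant category (grouping columns of the classified callset,
#' optionally crossed with age strata), counts QC-pass SNVs per person
#' (samples with no retained variants count as zeros), and reports the mean
#' per person, its standard error (SD/sqrt(n)), the number of possible
#' variants in the category, and the normalized mean (mean / possible).
#'
#' @param callset QC-pass callset with columns sample_id, pos, ref, alt (and
#'   classification columns if already annotated).
#' @param samples sample table with sample_id (and age when stratifying);
#'   defines the QC-pass denominator population.
#' @param reference an [mt_reference] (for classification/denominators).
#' @param by character vector of classification columns to group by; any of
#'   "strand", "substitution", "region", "context", "age_accumulating".
#' @param age_breaks optional numeric vector of age-bin breaks; when given,
#'   samples outside range(age_breaks) are dropped and categories are
#'   crossed with age strata.
#' @return data.frame: one row per category (x stratum) with n_samples,
#'   mean_count, se, possible, normalized_mean, normalized_se.
#' @export
normalized_mean_counts <- function(callset, samples, reference,
                                   by = c("strand", "substitution", "region"),
                                   age_breaks = NULL) {
  callset <- annotate_classes(callset, reference)
  if (!is.null(age_breaks)) {
    samples <- samples[samples$age >= min(age_breaks) & samples$age <= max(age_breaks), ]
    stratum_f <- cut(samples$age, age_breaks, include.lowest = TRUE, right = FALSE)
    samples$age_stratum <- as.character(stratum_f)
  }
  callset <- callset[callset$sample_id %in% samples$sample_id, , drop = FALSE]
  if (!is.null(age_breaks)) {
    callset$age_stratum <- samples$age_stratum[match(callset$sample_id, samples$sample_id)]
  }
  # enumerate category levels from denominators so empty categories appear
  cats <- category_table(reference, by)
  strata <- if (is.null(age_breaks)) data.frame(age_stratum = NA_character_) else
    data.frame(age_stratum = levels(stratum_f), stringsAsFactors = FALSE)
  out <- merge(cats, strata, by = NULL)
  key_of <- function(df) do.call(paste, c(df[by], list(sep = "|")))
  out_key <- key_of(out)
  cs_key <- key_of(callset)
  rows <- lapply(seq_len(nrow(out)), function(i) {
    st <- out$age_stratum[i]
    in_cat <- cs_key == out_key[i]
    if (!is.na(st)) in_cat <- in_cat & callset$age_stratum == st
    ids <- if (is.na(st)) samples$sample_id else samples$sample_id[samples$age_stratum == st]
    n <- length(ids)
    if (n == 0) {
      return(data.frame(n_samples = 0L, mean_count = NA_real_, se = NA_real_))
    }
    counts <- tabulate(match(callset$sample_id[in_cat], ids), nbins = n)
    data.frame(n_samples = n, mean_count = mean(counts),
               se = stats::sd(counts) / sqrt(n))
  })
  res <- cbind(out, do.call(rbind, rows))
  res$normalized_mean <- res$mean_count / res$possible
  res$normalized_se <- res$se / res$possible
  if (is.null(age_breaks)) res$age_stratum <- NULL
  res
}

#' All possible SNVs with their strand-resolved classification
#'
#' Expands every informative (non-placeholder) position into its three
#' possible substitutions (in strand-resolved space) and classifies each.
#'
#' @param reference an [mt_reference].
#' @return data.frame: pos, ref, alt (genome/light-strand alleles), strand,
#'   substitution, region, context, age_accumulating; 3 rows per
#'   informative position, ordered by (pos, alt).
#' @export
possible_variant_classes <- function(reference) {
  tab <- position_classes(reference)
  bases <- c("A", "C", "G", "T")
  rows <- do.call(rbind, lapply(bases, function(a) {
    keep <- tab$pos[reference$seq[tab$pos] != a]
    data.frame(pos = keep, alt = rep_len(a, length(keep)),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$pos, rows$alt), , drop = FALSE]
  rows$ref <- reference$seq[rows$pos]
  cls <- classify_variants(rows$pos, rows$ref, rows$alt, reference)
  out <- cbind(rows[c("pos", "ref", "alt")], cls)
  rownames(out) <- NULL
  out
}

# category level table with possible-variant denominators, aggregated from
# the full possible-SNV expansion
category_table <- function(reference, by) {
  known <- c("strand", "substitution", "region", "context", "age_accumulating")
  unknown <- setdiff(by, known)
  if (length(unknown)) stop("unknown grouping columns: ", paste(unknown, collapse = ", "))
  pv <- possible_variant_classes(reference)
  if ("context" %in% by) pv <- pv[!is.na(pv$context), , drop = FALSE]
  agg <- stats::aggregate(list(possible = rep(1L, nrow(pv))), pv[by], sum)
  agg
}

# attach classification columns to a callset if not already present
annotate_classes <- function(callset, reference) {
  need <- c("strand", "substitution", "region", "context", "age_accumulating")
  if (all(need %in% names(callset))) return(callset)
  cls <- classify_variants(callset$pos, callset$ref, callset$alt, reference)
  cbind(callset[setdiff(names(callset), need)], cls)
}

#' Collapse a strand-resolved class/context spectrum to COSMIC 96 categories
#'
#' COSMIC SBS signatures are pyrimidine-referenced (C or T). Our
#' strand-resolved categories are C/A-referenced: C>* categories map
#' directly; A>* categories are re-expressed as their pyrimidine complement
#' (T>*) with the reverse-complemented context.
#'
#' @param substitution,context strand-resolved class and 3-mer vectors.
#' @param weights numeric vector (e.g. counts or normalized means).
#' @return named 96-vector in COSMIC labels "X[C>A]Y", zero-filled.
#' @export
cosmic96_spectrum <- function(substitution, context, weights = rep(1, length(substitution))) {
  keep <- !is.na(context)
  substitution <- substitution[keep]; context <- context[keep]
  weights <- weights[keep]
  is_a <- substr(substitution, 1, 1) == "A"
  sub96 <- ifelse(is_a,
                  paste0("T>", complement_bases(substr(substitution, 3, 3))),
                  substitution)
  ctx96 <- ifelse(is_a, revcomp(context), context)
  lab <- sprintf("%s[%s]%s", substr(ctx96, 1, 1), sub96, substr(ctx96, 3, 3))
  all_lab <- cosmic96_labels()
  out <- stats::setNames(numeric(96), all_lab)
  agg <- tapply(weights, lab, sum)
  out[names(agg)] <- agg
  out
}

#' COSMIC 96 category labels (pyrimidine-referenced)
#' @return character vector of 96 labels.
#' @export
cosmic96_labels <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(up = bases, sub = subs, dn = bases, stringsAsFactors = FALSE)
  sort(sprintf("%s[%s]%s", grid$up, grid$sub, grid$dn))
}

#' Correlate an observed 96-spectrum with SBS signatures
#'
#' Fits one simple linear regression per signature, predicting the observed
#' spectrum from the signature's 96 category loadings, and reports the slope,
#' its two-sided p-value and the Bonferroni-adjusted p (factor = number of
#' signatures supplied; COSMIC v3.4 has 86).
#'
#' @param observed named numeric 96-vector (COSMIC labels).
#' @param signatures numeric matrix, 96 rows (rownames = COSMIC labels), one
#'   column per signature.
#' @return data.frame: signature, slope, p, p_adj.
#' @export
sbs_correlation <- function(observed, signatures) {
  lab <- cosmic96_labels()
  if (is.null(names(observed)) || !setequal(names(observed), lab)) {
    stop("observed spectrum must be named with the 96 COSMIC categories")
  }
  if (is.null(rownames(signatures)) || !setequal(rownames(signatures), lab)) {
    stop("signature matrix rownames must be the 96 COSMIC categories")
  }
  y <- observed[lab]
  sig <- signatures[lab, , drop = FALSE]
  n_sig <- ncol(sig)
  res <- lapply(seq_len(n_sig), function(j) {
    fit <- summary(stats::lm(y ~ sig[, j]))
    co <- fit$coefficients
    # a constant signature is aliased with the intercept: no slope estimate
    if (nrow(co) < 2) {
      return(data.frame(signature = colnames(sig)[j],
                        slope = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(signature = colnames(sig)[j],
               slope = co[2, 1], p = co[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p * n_sig)
  out
}
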