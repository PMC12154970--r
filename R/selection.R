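#' Enumerate all possible mtDNA SNVs
#'
#' Three alternate alleles per informative (non-placeholder) position, in
#' deterministic (position, alt) order. For the canonical 16,569 bp genome
#' with one placeholder this yields 49,704 rows.
#'
#' @param reference an [mt_reference].
#' @return data.frame: pos, ref, alt (light-strand alleles).
#' @export
enumerate_possible_snvs <- function(reference) {
  possible_variant_classes(reference)[c("pos", "ref", "alt")]
}

#' Annotate SNVs with coding consequence under the vertebrate mitochondrial code
#'
#' For each SNV inside a coding gene, the codon containing the position is
#' translated before and after the substitution on the gene's strand
#' (heavy-strand genes read the reverse complement of the reference span).
#' Identical amino acid (including stop-retained) is synonymous; a change to
#' stop is predicted loss of function (pLoF); any other change (missense,
#' stop-lost, start-lost) is nonsynonymous. Positions outside genes are
#' noncoding. Strand-resolved variant classes are attached as well.
#'
#' @param snvs data.frame with pos, ref, alt (e.g. from
#'   [enumerate_possible_snvs()] or an observed callset).
#' @param gene_model gene model data.frame (gene, start, end, strand,
#'   coding, frame).
#' @param reference an [mt_reference].
#' @return the input with columns gene, consequence
#'   (synonymous|nonsynonymous|pLoF|noncoding) and classification columns
#'   appended.
#' @export
annotate_consequence <- function(snvs, gene_model, reference) {
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  n <- nrow(snvs)
  gene <- rep(NA_character_, n)
  consequence <- rep("noncoding", n)
  for (g in seq_len(nrow(gene_model))) {
    if (!isTRUE(gene_model$coding[g])) next
    gp <- gene_positions(gene_model$start[g], gene_model$end[g], reference$length)
    span <- length(gp) - gene_model$frame[g]
    if (span %% 3 != 0) {
      stop(sprintf("gene %s: span %d not a multiple of 3 after frame offset",
                   gene_model$gene[g], span))
    }
    cds_pos <- gp[(gene_model$frame[g] + 1L):length(gp)]
    cds <- reference$seq[cds_pos]
    if (gene_model$strand[g] == "heavy") {
      cds_pos <- rev(cds_pos)
      cds <- complement_bases(rev(cds))
    }
    hit <- which(snvs$pos %in% cds_pos)
    if (!length(hit)) next
    idx <- match(snvs$pos[hit], cds_pos)        # 1-based index in CDS
    codon_i <- (idx - 1L) %/% 3L                # 0-based codon index
    off <- (idx - 1L) %% 3L + 1L                # position within codon
    c1 <- codon_i * 3L + 1L
    codon_ref <- paste0(cds[c1], cds[c1 + 1L], cds[c1 + 2L])
    alt_cds <- if (gene_model$strand[g] == "heavy") {
      complement_bases(snvs$alt[hit])
    } else snvs$alt[hit]
    codon_alt <- codon_ref
    substr(codon_alt, off, off) <- alt_cds
    aa_ref <- unname(code[codon_ref])
    aa_alt <- unname(code[codon_alt])
    cons <- ifelse(aa_ref == aa_alt, "synonymous",
            ifelse(aa_alt == "*", "pLoF", "nonsynonymous"))
    gene[hit] <- gene_model$gene[g]
    consequence[hit] <- cons
  }
  out <- snvs
  out$gene <- gene
  out$consequence <- consequence
  annotate_classes(out, reference)
}

# dN/dS value from observed and possible syn/nonsyn counts; dS = 0 -> NA
dnds_value <- function(obs_n, obs_s, poss_n, poss_s) {
  if (poss_n == 0 || poss_s == 0) return(NA_real_)
  dn <- obs_n / poss_n
  ds <- obs_s / poss_s
  if (ds == 0) return(NA_real_)
  dn / ds
}

#' Nonparametric observed/possible dN/dS
#'
#' dN is the number of observed nonsynonymous variant records divided by the
#' number of possible nonsynonymous variants in the gene; dS likewise for
#' synonymous; dN/dS is their ratio. Observed records are (sample, variant)
#' pairs: a variant recurring in several individuals counts once per
#' individual, matching the per-individual sampling null. Both numerator and
#' denominator are restricted to the same variant-class subset
#' (age-accumulating classes by default, the mutational process under
#' study). pLoF variants are excluded from both sides by default; set
#' \code{include_plof} to fold them into nonsynonymous.
#'
#' @param callset annotated observed callset (columns sample_id, pos, ref,
#'   alt, HL, gene, consequence, age_accumulating, substitution, strand).
#' @param possible annotated possible-SNV table from
#'   [annotate_consequence()].
#' @param gene gene name.
#' @param hl_bin numeric length-2, heteroplasmy bin [lo, hi) (final bin
#'   closed at the top via \code{hl_closed = TRUE}).
#' @param classes "age_accumulating", "all", or a character vector of
#'   "substitution:strand" labels (e.g. "A>G:light") to restrict to.
#' @param include_plof count pLoF as nonsynonymous.
#' @param hl_closed treat the upper bin edge as inclusive.
#' @return list with observed/possible counts, dn, ds, dnds (NA with
#'   \code{undefined = TRUE} when dS is zero).
#' @export
compute_dnds <- function(callset, possible, gene, hl_bin = c(0, 0.95),
                         classes = "age_accumulating", include_plof = FALSE,
                         hl_closed = TRUE) {
  poss <- restrict_class(possible[!is.na(possible$gene) & possible$gene == gene, ], classes)
  obs <- restrict_class(callset[!is.na(callset$gene) & callset$gene == gene, ], classes)
  hi_ok <- if (hl_closed) obs$HL <= hl_bin[2] else obs$HL < hl_bin[2]
  obs <- obs[obs$HL >= hl_bin[1] & hi_ok, , drop = FALSE]
  nonsyn <- if (include_plof) c("nonsynonymous", "pLoF") else "nonsynonymous"
  poss_n <- sum(poss$consequence %in% nonsyn)
  poss_s <- sum(poss$consequence == "synonymous")
  obs_n <- sum(obs$consequence %in% nonsyn)
  obs_s <- sum(obs$consequence == "synonymous")
  ratio <- dnds_value(obs_n, obs_s, poss_n, poss_s)
  list(
    gene = gene, hl_bin = hl_bin, classes = classes,
    obs_nonsyn = obs_n, obs_syn = obs_s,
    poss_nonsyn = poss_n, poss_syn = poss_s,
    dn = if (poss_n > 0) obs_n / poss_n else NA_real_,
    ds = if (poss_s > 0) obs_s / poss_s else NA_real_,
    dnds = ratio, undefined = is.na(ratio)
  )
}

# restrict a classified table to a variant-class subset
restrict_class <- function(df, classes) {
  if (identical(classes, "all") || nrow(df) == 0) return(df)
  if (identical(classes, "age_accumulating")) {
    return(df[df$age_accumulating, , drop = FALSE])
  }
  key <- paste0(df$substitution, ":", df$strand)
  df[key %in% classes, , drop = FALSE]
}

#' Per-individual sampling null for dN/dS
#'
#' For each individual i and mutation class c, draws N_ic variants without
#' replacement from the possible variants of class c in the gene, where N_ic
#' is the individual's observed count in the gene/heteroplasmy bin; dN/dS is
#' computed on each such null callset exactly as for the observed data. The
#' procedure is repeated \code{n_reps} times (1000 in the reference
#' analysis) to yield a null distribution, its median and 2.5/97.5
#' percentile envelope, and the observed value's percentile within it.
#'
#' @inheritParams compute_dnds
#' @param n_reps number of null replicates.
#' @param seed integer seed (reproducible draws).
#' @return list: observed (from [compute_dnds()]), draws (numeric vector,
#'   NA where a replicate's dS was zero), median, lower, upper (2.5/97.5
#'   percentiles), percentile (fraction of non-NA draws <= observed).
#' @export
sampling_null_dnds <- function(callset, possible, gene, hl_bin = c(0, 0.95),
                               classes = "age_accumulating", n_reps = 1000,
                               seed = 1, include_plof = FALSE,
                               hl_closed = TRUE) {
  observed <- compute_dnds(callset, possible, gene, hl_bin, classes,
                           include_plof, hl_closed)
  poss <- restrict_class(possible[!is.na(possible$gene) & possible$gene == gene, ], classes)
  obs <- restrict_class(callset[!is.na(callset$gene) & callset$gene == gene, ], classes)
  hi_ok <- if (hl_closed) obs$HL <= hl_bin[2] else obs$HL < hl_bin[2]
  obs <- obs[obs$HL >= hl_bin[1] & hi_ok, , drop = FALSE]

  nonsyn <- if (include_plof) c("nonsynonymous", "pLoF") else "nonsynonymous"
  class_key <- function(df) {
    if (nrow(df) == 0) return(character(0))
    paste0(df$substitution, ":", df$strand)
  }
  pools <- split(seq_len(nrow(poss)), class_key(poss))
  is_n <- poss$consequence %in% nonsyn
  is_s <- poss$consequence == "synonymous"

  counts <- table(obs$sample_id, class_key(obs))
  # validate pool sizes
  for (cc in colnames(counts)) {
    pool_size <- length(pools[[cc]])
    over <- rownames(counts)[counts[, cc] > pool_size]
    if (length(over)) {
      stop(sprintf("individual %s: observed %d class-%s variants but only %d possible in gene %s",
                   over[1], counts[over[1], cc], cc, pool_size, gene))
    }
  }
  set.seed(seed)
  draws <- vapply(seq_len(n_reps), function(r) {
    obs_n <- 0L; obs_s <- 0L
    for (cc in colnames(counts)) {
      pool <- pools[[cc]]
      for (k in counts[, cc]) {
        if (k == 0L) next
        take <- pool[sample.int(length(pool), k)]
        obs_n <- obs_n + sum(is_n[take])
        obs_s <- obs_s + sum(is_s[take])
      }
    }
    v <- dnds_value(obs_n, obs_s, observed$poss_nonsyn, observed$poss_syn)
    if (is.na(v)) NA_real_ else v
  }, numeric(1))
  ok <- !is.na(draws)
  pct <- if (any(ok) && !is.na(observed$dnds)) mean(draws[ok] <= observed$dnds) else NA_real_
  list(
    observed = observed,
    draws = draws,
    median = stats::median(draws, na.rm = TRUE),
    lower = unname(stats::quantile(draws, 0.025, na.rm = TRUE, type = 7)),
    upper = unname(stats::quantile(draws, 0.975, na.rm = TRUE, type = 7)),
    percentile = pct,
    n_reps = n_reps
  )
}

#' Heteroplasmy-distribution shift between consequence groups
#'
#' Compares the heteroplasmy fractions of two consequence arms within a gene
#' (missense/nonsynonymous vs synonymous by default) with a two-sided
#' Wilcoxon rank-sum test, and reports a rank-biserial location statistic
#' (2*AUC - 1): negative means the first arm is left-shifted (lower HL).
#'
#' @param callset annotated callset.
#' @param gene gene name.
#' @param arms length-2 character, consequence labels (first vs second).
#' @return list: statistic (rank-biserial), p, n (per arm), ecdf_a, ecdf_b;
#'   or NULL (with a message) if either arm is empty.
#' @export
heteroplasmy_shift <- function(callset, gene,
                               arms = c("nonsynonymous", "synonymous")) {
  sub <- callset[!is.na(callset$gene) & callset$gene == gene, , drop = FALSE]
  a <- sub$HL[sub$consequence == arms[1]]
  b <- sub$HL[sub$consequence == arms[2]]
  if (!length(a) || !length(b)) {
    message(sprintf("gene %s: empty arm, no estimate", gene))
    return(NULL)
  }
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  u <- unname(wt$statistic)  # number of (a > b) pairs (+ half ties)
  rb <- 2 * u / (length(a) * length(b)) - 1
  list(statistic = rb, p = wt$p.value, n = c(length(a), length(b)),
       ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b))
}
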