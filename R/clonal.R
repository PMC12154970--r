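#' Age- and sex-matched control resampling
#'
#' Constructs R random control sets of non-CH individuals, each with exactly
#' the same multiset of (integer age, sex) as the CH group. Sampling is
#' without replacement within a set and independent (with replacement)
#' across sets. Matching exactness is asserted on every generated set.
#'
#' @param samples sample table with sample_id, age, sex, ch (logical).
#' @param R number of control sets (500 in the reference analysis).
#' @param seed integer seed.
#' @return list of class \code{matched_sample_set}: ch_ids, control_sets
#'   (list of R character vectors), R, seed.
#' @export
match_controls <- function(samples, R = 500, seed = 1) {
  stopifnot(all(c("sample_id", "age", "sex", "ch") %in% names(samples)))
  key <- paste(floor(samples$age), samples$sex)
  ch_ids <- samples$sample_id[samples$ch]
  ch_key <- key[samples$ch]
  need <- table(ch_key)
  pool <- split(samples$sample_id[!samples$ch], key[!samples$ch])
  short <- names(need)[vapply(names(need), function(k) {
    length(pool[[k]]) < need[[k]]
  }, logical(1))]
  if (length(short)) {
    stop("insufficient non-CH controls in stratum (age sex): ",
         paste(short, collapse = "; "))
  }
  set.seed(seed)
  control_sets <- lapply(seq_len(R), function(r) {
    unlist(lapply(names(need), function(k) {
      p <- pool[[k]]
      p[sample.int(length(p), need[[k]])]
    }), use.names = FALSE)
  })
  # invariant: exact (age, sex) multiset match, no CH carriers
  key_by_id <- stats::setNames(key, samples$sample_id)
  ch_by_id <- stats::setNames(samples$ch, samples$sample_id)
  for (s in control_sets) {
    stopifnot(!any(ch_by_id[s]), identical(sort(unname(key_by_id[s])), sort(unname(ch_key))))
  }
  structure(list(ch_ids = ch_ids, control_sets = control_sets, R = R, seed = seed),
            class = "matched_sample_set")
}

#' Matched-resampling difference test
#'
#' Evaluates a per-category statistic (e.g. normalized mean variant count
#' per trinucleotide context) on the CH group and on each matched control
#' set. The control point estimate is the mean over sets and its SE the SD
#' over sets; the difference statistic (CH minus control) is summarised the
#' same way, tested against zero with a two-sided z test, and
#' Bonferroni-corrected over the number of categories (192 for the
#' strand-resolved context tables).
#'
#' @param matched a [match_controls()] result.
#' @param stat function(sample_ids) -> named numeric vector of per-category
#'   statistics.
#' @param bonferroni correction factor; default = number of categories
#'   returned by \code{stat}.
#' @param method "normal" (z test on the resampling SE, the reference
#'   analysis) or "permutation" (two-sided rank of the CH statistic among
#'   the control-set statistics, p = 2 * min tail rank / (R + 1); exactly
#'   calibrated under exchangeability, preferable in small cohorts where the
#'   normal z is mildly anti-conservative).
#' @return data.frame per category: ch, control_mean, control_se, diff,
#'   diff_se, z, p, p_adj.
#' @export
matched_difference_test <- function(matched, stat, bonferroni = NULL,
                                    method = c("normal", "permutation")) {
  method <- match.arg(method)
  ch_stat <- stat(matched$ch_ids)
  ctrl <- vapply(matched$control_sets, stat, ch_stat)
  if (is.null(dim(ctrl))) ctrl <- matrix(ctrl, nrow = 1, dimnames = list(names(ch_stat)))
  diffs <- ch_stat - ctrl
  est <- rowMeans(diffs)
  se <- apply(diffs, 1, stats::sd)
  if (is.null(bonferroni)) bonferroni <- length(ch_stat)
  z <- est / se
  if (method == "permutation") {
    R <- ncol(ctrl)
    p <- vapply(seq_along(ch_stat), function(k) {
      lo <- 1 + sum(ctrl[k, ] <= ch_stat[k])
      hi <- 1 + sum(ctrl[k, ] >= ch_stat[k])
      min(1, 2 * min(lo, hi) / (R + 1))
    }, numeric(1))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    zero_se <- se == 0 & est != 0
    if (any(zero_se)) {
      warning("zero resampling SE with nonzero difference; p reported as 0")
      p[zero_se] <- 0
    }
    p[se == 0 & est == 0] <- 1
  }
  data.frame(
    category = names(ch_stat),
    ch = unname(ch_stat),
    control_mean = rowMeans(ctrl),
    control_se = apply(ctrl, 1, stats::sd),
    diff = unname(est),
    diff_se = unname(se),
    z = unname(z),
    p = unname(p),
    p_adj = pmin(1, unname(p) * bonferroni),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Heteroplasmic variant sharing between siblings
#'
#' Restricts to variants seen in at least \code{min_carriers} individuals
#' cohort-wide (guarding against artefactual calls), then, per pair, asks
#' for each variant of sibling 1 (the lexically smaller sample id by
#' default) whether it is also found in sibling 2 at any heteroplasmy.
#' Results are binned by the sibling-1 heteroplasmy.
#'
#' @param callset callset with sample_id, pos, ref, alt, HL.
#' @param pairs data.frame with columns sib1, sib2 (sample ids); orientation
#'   is normalised unless \code{randomize_sib1 = TRUE}.
#' @param hl_bins numeric breaks for sibling-1 HL bins.
#' @param min_carriers minimum cohort-wide carrier count (default 5,
#'   i.e. variants seen in at least 5 individuals).
#' @param randomize_sib1 pick sibling 1 at random per pair instead of by id.
#' @param seed used only when \code{randomize_sib1}.
#' @return data.frame per bin: bin, n, shared, proportion, ci_lo, ci_hi
#'   (exact binomial CI).
#' @export
sibling_sharing <- function(callset, pairs, hl_bins = c(0, 0.05, 0.2, 0.5, 0.95, 1),
                            min_carriers = 5, randomize_sib1 = FALSE, seed = 1) {
  stopifnot(!any(duplicated(c(pairs$sib1, pairs$sib2))))
  key <- paste(callset$pos, callset$ref, callset$alt, sep = ":")
  carriers <- tapply(callset$sample_id, key, function(x) length(unique(x)))
  keep_key <- names(carriers)[carriers >= min_carriers]
  cs <- callset[key %in% keep_key, , drop = FALSE]
  cs$key <- paste(cs$pos, cs$ref, cs$alt, sep = ":")

  if (randomize_sib1) {
    set.seed(seed)
    flip <- stats::runif(nrow(pairs)) < 0.5
  } else {
    flip <- pairs$sib1 > pairs$sib2
  }
  s1 <- ifelse(flip, pairs$sib2, pairs$sib1)
  s2 <- ifelse(flip, pairs$sib1, pairs$sib2)

  rows <- lapply(seq_along(s1), function(i) {
    v1 <- cs[cs$sample_id == s1[i], , drop = FALSE]
    if (!nrow(v1)) return(NULL)
    k2 <- cs$key[cs$sample_id == s2[i]]
    data.frame(HL = v1$HL, shared = v1$key %in% k2)
  })
  rows <- do.call(rbind, rows)
  bins <- cut(rows$HL, hl_bins, include.lowest = TRUE, right = FALSE)
  out <- lapply(levels(bins), function(b) {
    sel <- !is.na(bins) & bins == b
    n <- sum(sel); sh <- sum(rows$shared[sel])
    ci <- if (n > 0) stats::binom.test(sh, n)$conf.int else c(NA, NA)
    data.frame(bin = b, n = n, shared = sh,
               proportion = if (n > 0) sh / n else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Proximity-based locus clumping
#'
#' Takes association results, keeps variants below the p-value threshold,
#' draws a window of \code{half_window} bases up- and downstream of each,
#' and merges variants with overlapping windows (per chromosome) into loci.
#' The lead variant of a locus is its most significant variant (smallest
#' position on ties).
#'
#' @param assoc data.frame with pos, p and optionally chrom.
#' @param p_threshold significance threshold (default 5e-5).
#' @param half_window window half-width in bases (default 100 kb).
#' @return list: loci (data.frame locus, chrom, start, end, n_variants,
#'   lead_pos, lead_p), assignments (significant variants with locus ids).
#' @export
clump_loci <- function(assoc, p_threshold = 5e-5, half_window = 1e5) {
  if (!"chrom" %in% names(assoc)) assoc$chrom <- "1"
  sig <- assoc[assoc$p < p_threshold, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(loci = data.frame(), assignments = sig))
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  locus <- integer(nrow(sig))
  cur <- 0L
  for (i in seq_len(nrow(sig))) {
    new_locus <- i == 1 ||
      sig$chrom[i] != sig$chrom[i - 1] ||
      sig$pos[i] - sig$pos[i - 1] > 2 * half_window
    if (new_locus) cur <- cur + 1L
    locus[i] <- cur
  }
  sig$locus <- locus
  loci <- do.call(rbind, lapply(split(sig, sig$locus), function(d) {
    lead <- d[order(d$p, d$pos), ][1, ]
    data.frame(locus = d$locus[1], chrom = d$chrom[1],
               start = min(d$pos) - half_window, end = max(d$pos) + half_window,
               n_variants = nrow(d), lead_pos = lead$pos, lead_p = lead$p,
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- NULL
  list(loci = loci, assignments = sig)
}

#' Inverse-variance-weighted effect-size regression
#'
#' Regresses outcome effect sizes on exposure effect sizes with weights
#' w_i = (1/SEx_i^2)(1/SEy_i^2); exposure alleles are assumed pre-oriented
#' so all x effects are risk-increasing (>= 0). Through the origin by
#' default (the MR-IVW convention).
#'
#' @param bx,sx exposure effects and standard errors.
#' @param by,sy outcome effects and standard errors.
#' @param intercept include an intercept term.
#' @return list: slope, se, p (two-sided), n, fit.
#' @export
ivw_effect_correlation <- function(bx, sx, by, sy, intercept = FALSE) {
  stopifnot(length(bx) == length(sx), length(bx) == length(by),
            length(bx) == length(sy))
  ok <- is.finite(bx) & is.finite(by) & is.finite(sx) & is.finite(sy) &
    sx > 0 & sy > 0
  if (sum(ok) < 3) stop("need at least 3 variant pairs with finite SEs")
  bx <- bx[ok]; by <- by[ok]
  w <- 1 / (sx[ok]^2 * sy[ok]^2)
  fit <- if (intercept) stats::lm(by ~ bx, weights = w) else
    stats::lm(by ~ 0 + bx, weights = w)
  co <- summary(fit)$coefficients
  row <- if (intercept) 2 else 1
  list(slope = co[row, 1], se = co[row, 2], p = co[row, 4], n = sum(ok),
       fit = fit)
}

#' Logistic disease association for an mtDNA trait
#'
#' Fits phenotype ~ burden + age + sex + age:sex + age^2 + age^2:sex +
#' ancestry + haplogroup indicators by maximum-likelihood logistic
#' regression. Ever-smokers are excluded when a \code{smoker} column is
#' present; ancestry groups with fewer than 3 individuals in either
#' phenotype class are excluded; constant factors are dropped from the
#' design. Complete separation is flagged and no estimate returned.
#'
#' @param data data.frame with columns phenotype (0/1), burden, age, sex,
#'   and optionally ancestry, haplogroup, smoker.
#' @param inverse_rank_normalize transform the burden to normal scores
#'   before fitting.
#' @return list: or (odds ratio per burden unit), ci (95%), beta, se, p,
#'   n, separation (logical).
#' @export
disease_association <- function(data, inverse_rank_normalize = FALSE) {
  if ("smoker" %in% names(data)) data <- data[!data$smoker, , drop = FALSE]
  if ("ancestry" %in% names(data)) {
    tab <- table(data$ancestry, data$phenotype)
    keep_groups <- rownames(tab)[apply(tab, 1, min) >= 3]
    data <- data[data$ancestry %in% keep_groups, , drop = FALSE]
  }
  if (inverse_rank_normalize) {
    r <- rank(data$burden, ties.method = "average")
    data$burden <- stats::qnorm((r - 0.5) / length(r))
  }
  data$sex <- factor(data$sex)
  terms <- c("burden", "age", "sex", "age:sex", "I(age^2)", "I(age^2):sex")
  for (v in c("ancestry", "haplogroup")) {
    if (v %in% names(data)) {
      data[[v]] <- factor(data[[v]])
      if (nlevels(droplevels(data[[v]])) > 1) terms <- c(terms, v)
    }
  }
  if (nlevels(droplevels(data$sex)) < 2) {
    terms <- setdiff(terms, c("sex", "age:sex", "I(age^2):sex"))
  }
  form <- stats::as.formula(paste("phenotype ~", paste(terms, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # (quasi-)separation can slip past glm without a warning: detect it from
  # 0/1 fitted probabilities combined with an absurd burden standard error
  probs <- stats::fitted(fit)
  burden_se <- summary(fit)$coefficients["burden", 2]
  if ((any(probs > 1 - 1e-8) || any(probs < 1e-8)) &&
      (burden_se > 100 || abs(stats::coef(fit)["burden"]) > 10)) {
    separation <- TRUE
  }
  if (separation || !fit$converged) {
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_), beta = NA_real_,
                se = NA_real_, p = NA_real_, n = nrow(data), separation = TRUE))
  }
  co <- summary(fit)$coefficients["burden", ]
  list(or = exp(co[1]), ci = exp(co[1] + c(-1, 1) * 1.96 * co[2]),
       beta = unname(co[1]), se = unname(co[2]), p = unname(co[4]),
       n = nrow(data), separation = FALSE)
}

#' Mean positional constraint score per group
#'
#' Joins a per-position score table (e.g. an mtDNA local-constraint score)
#' onto a callset and reports each group's mean per-variant score with its
#' standard error. Variants at positions missing from the score table are
#' dropped with a message.
#'
#' @param callset callset with sample_id and pos.
#' @param scores data.frame with pos, score.
#' @param groups named list of sample-id vectors defining the groups.
#' @return data.frame per group: group, n, mean, se (NA when empty).
#' @export
mean_positional_score <- function(callset, scores, groups) {
  sc <- scores$score[match(callset$pos, scores$pos)]
  if (anyNA(sc)) {
    message(sum(is.na(sc)), " variant(s) at positions without a score dropped")
  }
  callset <- callset[!is.na(sc), , drop = FALSE]
  sc <- sc[!is.na(sc)]
  out <- lapply(names(groups), function(g) {
    v <- sc[callset$sample_id %in% groups[[g]]]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
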