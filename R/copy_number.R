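#' Mean nuclear coverage from alignment metrics
#'
#' lambda = (total mapped reads - singletons - mate-different-chromosome
#' reads - duplicates) * read length / nuclear genome length.
#'
#' @param total_mapped,singletons,mate_diff_chr,duplicates read counts.
#' @param read_length read length in bases.
#' @param genome_length nuclear genome length in bases.
#' @return mean nuclear coverage (reads/base).
#' @export
mean_nuclear_coverage <- function(total_mapped, singletons, mate_diff_chr,
                                  duplicates, read_length, genome_length) {
  if (any(genome_length <= 0)) stop("genome length must be > 0")
  if (any(read_length <= 0)) stop("read length must be > 0")
  num <- total_mapped - singletons - mate_diff_chr - duplicates
  if (any(num < 0)) stop("inconsistent metrics: negative usable read count")
  num * read_length / genome_length
}

#' Raw mtDNA copy number
#'
#' mtCN_raw = 2 * mean mtDNA coverage / mean nuclear coverage (the factor 2
#' reflects the diploid nuclear genome).
#'
#' @param mean_mt_coverage mean mtDNA coverage (reads/base).
#' @param lambda mean nuclear coverage (reads/base), > 0.
#' @return raw copy number.
#' @export
raw_mtcn <- function(mean_mt_coverage, lambda) {
  if (any(lambda <= 0)) stop("mean nuclear coverage must be > 0")
  2 * mean_mt_coverage / lambda
}

#' Residualize log mtCN against technical and blood-composition covariates
#'
#' Fits, by ordinary least squares,
#' \code{log(mtcn_raw) ~ ns(draw_time, 5) + center + fasting indicators +
#' ns(date, seasonal knots) + month + blood variables} and returns the
#' residuals (adjusted mtCN). Blood measurements more than 4 standard
#' deviations from their mean are blanked per variable, and rows with any
#' missing covariate are dropped from the fit (adjusted value NA). Fasting
#' times are clamped to [1, 18] hours (0 relabelled 1, >18 relabelled 18)
#' and entered as indicators. Draw time enters via a natural cubic spline
#' with 5 df; assessment date via a natural spline with knots every 3 months
#' anchored at the earliest date. A display-scale variant adds back the
#' pre-adjustment mean of log mtCN and exponentiates.
#'
#' @param samples data.frame with sample_id and mtcn_raw (> 0).
#' @param covariates data.frame aligned to \code{samples} rows with columns
#'   draw_time (hours), fasting_time (hours), assessment_date (Date or
#'   numeric days), assessment_month, assessment_center, plus the blood
#'   variables named in \code{blood_vars}.
#' @param blood_vars character vector naming blood-composition columns.
#' @param draw_df spline df for draw time (default 5).
#' @return data.frame: sample_id, mtcn_adj (residual, mean 0 over fitted
#'   rows), mtcn_adj_display (positive, absolute scale); attribute
#'   \code{fit} holds the lm object.
#' @export
adjust_mtcn <- function(samples, covariates, blood_vars, draw_df = 5) {
  stopifnot(nrow(samples) == nrow(covariates), all(samples$mtcn_raw > 0, na.rm = TRUE))
  cov <- covariates
  for (v in blood_vars) {
    x <- cov[[v]]
    out <- abs(x - mean(x, na.rm = TRUE)) > 4 * stats::sd(x, na.rm = TRUE)
    x[out] <- NA
    cov[[v]] <- x
  }
  fast <- pmin(pmax(round(cov$fasting_time), 1), 18)
  date_num <- as.numeric(cov$assessment_date)
  knots <- seq(min(date_num, na.rm = TRUE) + 91, max(date_num, na.rm = TRUE) - 1,
               by = 91)
  knots <- knots[knots > min(date_num, na.rm = TRUE) & knots < max(date_num, na.rm = TRUE)]

  df <- data.frame(
    y = log(samples$mtcn_raw),
    draw_time = cov$draw_time,
    date_num = date_num,
    fasting = factor(fast),
    month = factor(cov$assessment_month),
    center = factor(cov$assessment_center)
  )
  df <- cbind(df, cov[blood_vars])
  complete <- stats::complete.cases(df)

  terms <- c(sprintf("splines::ns(draw_time, df = %d)", draw_df),
             if (nlevels(droplevels(df$center[complete])) > 1) "center",
             if (nlevels(droplevels(df$fasting[complete])) > 1) "fasting",
             if (length(knots)) "splines::ns(date_num, knots = knots)" else "date_num",
             if (nlevels(droplevels(df$month[complete])) > 1) "month",
             blood_vars)
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = df[complete, , drop = FALSE])
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient covariate design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  resid <- rep(NA_real_, nrow(samples))
  resid[complete] <- stats::residuals(fit)
  mean_log <- mean(df$y[complete])
  out <- data.frame(sample_id = samples$sample_id,
                    mtcn_adj = resid,
                    mtcn_adj_display = exp(resid + mean_log),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}
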