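#' Construct an allelic-expression-imbalance sample
#'
#' One heterozygous sample measured for both alleles in cDNA and in
#' genomic DNA. Signals may be fluorescence intensities, quantities from
#' a standard curve, or pyrosequencing peak areas, as long as the same
#' read-out is used within a material. The per-sample normalized ratio is
#' `(a_cdna / b_cdna) / (a_gdna / b_gdna)`; the gDNA ratio of a
#' heterozygote plays the role of the expected 1:1 calibration.
#'
#' @param sample_id Identifier.
#' @param signal_a_cdna,signal_b_cdna,signal_a_gdna,signal_b_gdna
#'   Non-negative allele signals; all denominators and gDNA signals must
#'   be positive for a valid sample.
#' @return Object of class `aei_sample` with the four signals plus
#'   `ratio_cdna`, `ratio_gdna`, `normalized_ratio`.
#' @export
aei_sample <- function(sample_id, signal_a_cdna, signal_b_cdna,
                       signal_a_gdna, signal_b_gdna) {
  sig <- c(signal_a_cdna, signal_b_cdna, signal_a_gdna, signal_b_gdna)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("invalid sample: all four allele signals must be positive", call. = FALSE)
  s <- list(sample_id = as.character(sample_id),
            signal_a_cdna = signal_a_cdna, signal_b_cdna = signal_b_cdna,
            signal_a_gdna = signal_a_gdna, signal_b_gdna = signal_b_gdna)
  s$ratio_cdna <- signal_a_cdna / signal_b_cdna
  s$ratio_gdna <- signal_a_gdna / signal_b_gdna
  s$normalized_ratio <- s$ratio_cdna / s$ratio_gdna
  structure(s, class = "aei_sample")
}

#' Normalized allelic ratio of a sample
#'
#' cDNA allelic ratio divided by the same sample's gDNA allelic ratio;
#' 1.0 means no allelic imbalance. Swapping the allele labels inverts
#' the ratio exactly.
#'
#' @param s An [aei_sample()].
#' @return The normalized ratio.
#' @export
normalized_allelic_ratio <- function(s) {
  stopifnot(inherits(s, "aei_sample"))
  s$normalized_ratio
}

#' Allelic ratio from pyrosequencing peak areas
#'
#' @param peak_area_a,peak_area_b Non-negative areas under the curve for
#'   the two alleles; both zero is an error.
#' @return List with `ratio` (a/b; `Inf` with `undefined = TRUE` when
#'   b = 0) and `percent_a` = 100 a/(a+b).
#' @export
pyro_allelic_ratio <- function(peak_area_a, peak_area_b) {
  if (peak_area_a < 0 || peak_area_b < 0)
    stop("peak areas must be non-negative", call. = FALSE)
  if (peak_area_a == 0 && peak_area_b == 0)
    stop("both peak areas are zero", call. = FALSE)
  list(ratio = if (peak_area_b > 0) peak_area_a / peak_area_b else Inf,
       undefined = peak_area_b == 0,
       percent_a = 100 * peak_area_a / (peak_area_a + peak_area_b))
}

#' Cohort test for allelic expression imbalance
#'
#' Works on log2 ratios (allelic ratios are multiplicative). Two tests
#' are reported: a paired t-test of log2 cDNA ratios against log2 gDNA
#' ratios across samples, and a one-sample t-test of the log2 normalized
#' ratios against 0 (i.e. normalized ratio against the expected 1.0).
#' Both two-sided.
#'
#' @param samples List of [aei_sample()] objects, >= 3.
#' @param conf_level Confidence level for the mean log2 ratio CI.
#' @return List with `n`, `mean_log2_ratio`, `mean_ratio` (geometric
#'   mean of normalized ratios), `ci` (on the ratio scale), `p_paired`,
#'   `p_vs_one`.
#' @export
aei_cohort_test <- function(samples, conf_level = 0.95) {
  if (length(samples) < 3L)
    stop("insufficient data: need at least 3 heterozygous samples", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "aei_sample")))
  lc <- log2(vapply(samples, function(s) s$ratio_cdna, numeric(1)))
  lg <- log2(vapply(samples, function(s) s$ratio_gdna, numeric(1)))
  lnr <- lc - lg
  if (all(lnr == lnr[1])) {
    # degenerate: identical normalized ratios in every sample (zero paired
    # variance); the t statistic is 0/0 at ratio 1 and +-Inf otherwise
    p <- if (lnr[1] == 0) 1 else 0
    return(list(n = length(samples), mean_log2_ratio = lnr[1],
                mean_ratio = 2^lnr[1], ci = 2^c(lnr[1], lnr[1]),
                p_paired = p, p_vs_one = p))
  }
  paired <- t.test(lc, lg, paired = TRUE)
  one <- t.test(lnr, mu = 0, conf.level = conf_level)
  list(n = length(samples),
       mean_log2_ratio = mean(lnr),
       mean_ratio = 2^mean(lnr),
       ci = 2^one$conf.int,
       p_paired = paired$p.value,
       p_vs_one = one$p.value)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a dilution
#' series. A valid curve has negative slope (about -3.32 for a perfectly
#' efficient assay); a non-negative slope triggers a degenerate-curve
#' warning.
#'
#' @param quantity Known input quantities (> 0), length >= 3.
#' @param ct Measured Ct values.
#' @return Object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency` (`10^(-1/slope)`).
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(length(quantity) == length(ct))
  if (length(ct) < 3L)
    stop("need at least 3 dilution points", call. = FALSE)
  if (any(quantity <= 0)) stop("quantities must be positive", call. = FALSE)
  fit <- lm(ct ~ log10(quantity))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope >= -1e-8)
    warning("degenerate standard curve: non-negative slope", call. = FALSE)
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 r2 = r2,
                 efficiency = if (is.finite(slope) && slope < 0)
                   10^(-1 / slope) else NA_real_),
            class = "standard_curve")
}

#' Quantity from a Ct value via a fitted standard curve
#' @param ct Ct value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Estimated quantity (inverts the regression line).
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Convert Ct values to relative quantities
#'
#' `efficiency^(-ct)`: each cycle multiplies template by the assay
#' efficiency (2 for a perfect doubling).
#'
#' @param ct Ct value(s).
#' @param efficiency Amplification efficiency per cycle.
#' @return Relative quantity.
#' @export
ct_to_quantity <- function(ct, efficiency = 2) {
  stopifnot(efficiency > 1)
  efficiency^(-ct)
}

#' Pearson correlation with a two-sided p-value
#'
#' Standard Pearson r; the p-value comes from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom (for |r| = 1
#' the p-value is 0).
#'
#' @param x,y Finite numeric vectors, length >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) return(list(r = r, p = 0, n = length(x)))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Read an AEI sample table
#'
#' TSV columns: `sample_id`, `signal_a_cdna`, `signal_b_cdna`,
#' `signal_a_gdna`, `signal_b_gdna`.
#'
#' @param path TSV path with header.
#' @return List of [aei_sample()] objects.
#' @export
read_aei_table <- function(path) {
  df <- read_table_schema(path, c(sample_id = "character",
                                  signal_a_cdna = "numeric",
                                  signal_b_cdna = "numeric",
                                  signal_a_gdna = "numeric",
                                  signal_b_gdna = "numeric"))
  lapply(seq_len(nrow(df)), function(i)
    aei_sample(df$sample_id[i], df$signal_a_cdna[i], df$signal_b_cdna[i],
               df$signal_a_gdna[i], df$signal_b_gdna[i]))
}
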