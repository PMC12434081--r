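# Agreement statistics between predictive BSA estimates and the mesh-derived
# criterion: RMSE, relative bias +/- SD of the percentage differences,
# Bland-Altman mean difference / limits of agreement / proportional bias,
# Pearson correlation, and the omnibus comparison across methods gated on
# normality (repeated-measures ANOVA vs Friedman).

#' Root mean square error
#'
#' @param pred,ref Equal-length numeric vectors (m^2).
#' @return sqrt(mean((pred - ref)^2)).
#' @export
rmse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (!length(pred)) stop("empty vectors", call. = FALSE)
  sqrt(mean((pred - ref)^2))
}

#' Relative bias and SD of the percentage differences
#'
#' Per-subject difference d_i = 100 * (pred_i - ref_i) / ref_i, i.e. the
#' equation-derived estimate minus the criterion, expressed as a percentage
#' of the criterion. Returns the mean and the sample (n-1) SD of the d_i.
#'
#' @param pred,ref Equal-length numeric vectors, `ref` strictly positive.
#' @return Named numeric vector `c(bias_pct = , sd_pct = )`.
#' @export
relative_bias_sd <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(ref <= 0)) stop("reference values must be > 0", call. = FALSE)
  d <- 100 * (pred - ref) / ref
  c(bias_pct = mean(d), sd_pct = stats::sd(d))
}

#' Bland-Altman agreement analysis
#'
#' Mean difference, 1.96-SD limits of agreement, and proportional bias
#' assessed as the Pearson correlation of the differences against the
#' pairwise means, with its two-sided p-value. With zero-variance
#' differences the proportional-bias test is undefined and reported as NA.
#'
#' @param pred,ref Equal-length numeric vectors, length >= 3.
#' @return A list: `mean_diff`, `loa` (length-2 `c(low, high)`), `sd_diff`,
#'   `prop_bias_r`, `prop_bias_p`.
#' @export
bland_altman <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- pred - ref
  m <- (pred + ref) / 2
  sd_d <- stats::sd(d)
  # a numerically constant difference (e.g. pred = ref + c) leaves the
  # proportional-bias correlation undefined
  if (sd_d < 1e-10 * (abs(mean(d)) + max(abs(d)))) sd_d <- 0
  out <- list(mean_diff = mean(d),
              loa = c(low = mean(d) - 1.96 * sd_d, high = mean(d) + 1.96 * sd_d),
              sd_diff = sd_d, prop_bias_r = NA_real_, prop_bias_p = NA_real_)
  if (sd_d > 0 && stats::sd(m) > 0) {
    ct <- stats::cor.test(d, m, method = "pearson")
    out$prop_bias_r <- unname(ct$estimate)
    out$prop_bias_p <- ct$p.value
  }
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with positive
#'   variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Friedman rank test across methods
#'
#' Within-subject mid-rank Friedman chi-square with asymptotic p-value, for a
#' subjects x methods matrix of paired measurements.
#'
#' @param mat Numeric matrix, rows = subjects (>= 2), columns = methods (>= 2).
#' @return A list with `statistic` (chi-square), `df`, and `p_value`.
#' @export
friedman_methods <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 subjects and 2 methods", call. = FALSE)
  # fully tied rows (all columns identical) degenerate: no evidence of any
  # method ordering, statistic 0 by convention
  rk <- t(apply(mat, 1, rank))
  if (all(apply(rk, 1, stats::sd) == 0))
    return(list(statistic = 0, df = ncol(mat) - 1, p_value = 1))
  ft <- stats::friedman.test(mat)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

# Omnibus branch: Shapiro-Wilk on each method's paired differences from the
# criterion; all p > alpha -> one-way repeated-measures ANOVA, otherwise
# Friedman. shapiro.test caps at n = 5000; larger samples use a fixed-seed
# subsample, which only affects the branch choice, never the statistics.
.omnibus_gate <- function(diff_mat, alpha = 0.05) {
  ps <- apply(diff_mat, 2, function(d) {
    if (length(d) > 5000) {
      d <- d[round(seq(1, length(d), length.out = 5000))]
    }
    if (stats::sd(d) == 0) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(d)$p.value
  })
  list(normal = all(ps > alpha), shapiro_p = ps)
}

#' Compare the ten predictive equations against criterion BSA
#'
#' Reproduces the per-sex accuracy table: for each equation, the median and
#' interquartile range of the estimate distribution, Pearson correlation with
#' the criterion, RMSE, relative bias +/- SD of the percentage differences,
#' and Bland-Altman summary statistics. The omnibus comparison across the
#' eleven paired distributions (criterion + ten equations) is a one-way
#' repeated-measures ANOVA when all per-method paired differences pass a
#' Shapiro-Wilk normality gate (alpha 0.05), and Friedman's rank ANOVA
#' otherwise. Each equation is additionally compared to the criterion with a
#' paired post-hoc test (t-test on the parametric branch, Wilcoxon signed-rank
#' otherwise), Bonferroni-corrected across the ten comparisons.
#'
#' @param cohort Data frame with `id`, `sex`, `weight_kg`, `height_cm`,
#'   `criterion_bsa_m2`.
#' @param sex_filter Optional `"male"`/`"female"` to restrict the cohort.
#' @param alpha Significance level for the normality gate.
#' @return A list per sex present: `table` (tibble, one row per method),
#'   `criterion_summary`, `omnibus` (branch, statistic, p), `post_hoc`
#'   (tibble of per-method corrected p-values).
#' @export
compare_equations <- function(cohort, sex_filter = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  need <- c("id", "sex", "weight_kg", "height_cm", "criterion_bsa_m2")
  if (!all(need %in% names(cohort)))
    stop("cohort is missing columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "), call. = FALSE)
  if (any(is.na(cohort$criterion_bsa_m2)))
    stop("missing criterion BSA values", call. = FALSE)
  if (!is.null(sex_filter)) cohort <- cohort[cohort$sex %in% sex_filter, , drop = FALSE]
  sexes <- intersect(c("male", "female"), unique(cohort$sex))
  out <- lapply(sexes, function(sx) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    if (nrow(sub) < 3L)
      stop("need at least 3 ", sx, " subjects with criterion BSA", call. = FALSE)
    est <- predict_all(sub)
    est_wide <- tidyr::pivot_wider(est, names_from = "method_id",
                                   values_from = "bsa_m2")
    est_wide <- est_wide[match(sub$id, est_wide$id), ]
    ref <- sub$criterion_bsa_m2
    per_method <- lapply(bsa_methods(), function(m) {
      p <- est_wide[[m]]
      rb <- relative_bias_sd(p, ref)
      ba <- bland_altman(p, ref)
      tibble::tibble(
        method_id = m, sex = sx, n = length(p),
        median_m2 = stats::median(p),
        q1_m2 = unname(stats::quantile(p, 0.25)),
        q3_m2 = unname(stats::quantile(p, 0.75)),
        pcc = pearson_r(p, ref),
        rmse_m2 = rmse(p, ref),
        bias_pct = unname(rb["bias_pct"]),
        sd_diff_pct = unname(rb["sd_pct"]),
        ba_mean_diff_m2 = ba$mean_diff,
        ba_loa_low_m2 = unname(ba$loa["low"]),
        ba_loa_high_m2 = unname(ba$loa["high"]),
        prop_bias_r = ba$prop_bias_r,
        prop_bias_p = ba$prop_bias_p
      )
    })
    tab <- dplyr::bind_rows(per_method)
    tab <- dplyr::mutate(tab, rmse_rank = rank(.data$rmse_m2, ties.method = "min"))

    meth_mat <- as.matrix(est_wide[, bsa_methods()])
    diff_mat <- meth_mat - ref
    gate <- .omnibus_gate(diff_mat, alpha)
    full_mat <- cbind(criterion = ref, meth_mat)
    if (gate$normal) {
      long <- data.frame(
        y = as.vector(full_mat),
        method = factor(rep(colnames(full_mat), each = nrow(full_mat)),
                        levels = colnames(full_mat)),
        subject = factor(rep(sub$id, times = ncol(full_mat))))
      fit <- stats::aov(y ~ method + Error(subject), data = long)
      smry <- summary(fit)[["Error: Within"]][[1]]
      omnibus <- list(branch = "repeated_measures_anova",
                      statistic = smry[["F value"]][1],
                      df = unname(smry[["Df"]][1:2]),
                      p_value = smry[["Pr(>F)"]][1],
                      shapiro_p = gate$shapiro_p)
      ph_p <- apply(meth_mat, 2, function(p) {
        if (stats::sd(p - ref) == 0) return(if (all(p == ref)) 1 else 0)
        stats::t.test(p, ref, paired = TRUE)$p.value
      })
    } else {
      fr <- friedman_methods(full_mat)
      omnibus <- list(branch = "friedman", statistic = fr$statistic,
                      df = fr$df, p_value = fr$p_value, shapiro_p = gate$shapiro_p)
      ph_p <- apply(meth_mat, 2, function(p) {
        if (stats::sd(p - ref) == 0) return(if (all(p == ref)) 1 else 0)
        stats::wilcox.test(p, ref, paired = TRUE, exact = FALSE)$p.value
      })
    }
    post_hoc <- tibble::tibble(
      method_id = bsa_methods(),
      p_raw = unname(ph_p),
      p_bonferroni = pmin(1, unname(ph_p) * length(ph_p)))
    list(sex = sx,
         criterion_summary = tibble::tibble(
           sex = sx, n = length(ref),
           median_m2 = stats::median(ref),
           q1_m2 = unname(stats::quantile(ref, 0.25)),
           q3_m2 = unname(stats::quantile(ref, 0.75))),
         table = tab, omnibus = omnibus, post_hoc = post_hoc)
  })
  names(out) <- sexes
  out
}
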