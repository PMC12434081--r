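# BSA normalization of echocardiographic size measures, sex-specific
# ventricular-dilatation classification, the athlete's-heart exclusion rule,
# and paired comparison of dilatation prevalence across BSA normalizations.

#' Default dilatation cut-points
#'
#' Sex-specific thresholds on the BSA-normalized measures: left ventricular
#' dilatation if indexed LVEDD exceeds 30 (males) / 31 (females) mm/m^2 or
#' indexed LVEDV exceeds 74 (males) / 61 (females) ml/m^2; right ventricular
#' dilatation if indexed RVBD exceeds 22 mm/m^2 in both sexes. All
#' comparisons are strict ("above the cut-point"); exact equality is
#' non-dilated.
#'
#' @param lvedd_male,lvedd_female LVEDD cut-points (mm/m^2).
#' @param lvedv_male,lvedv_female LVEDV cut-points (ml/m^2).
#' @param rvbd RVBD cut-point (mm/m^2), common to both sexes.
#' @return A named list of cut-points.
#' @export
dilatation_cutpoints <- function(lvedd_male = 30, lvedd_female = 31,
                                 lvedv_male = 74, lvedv_female = 61,
                                 rvbd = 22) {
  cp <- list(lvedd = c(male = lvedd_male, female = lvedd_female),
             lvedv = c(male = lvedv_male, female = lvedv_female),
             rvbd = c(male = rvbd, female = rvbd))
  if (any(unlist(cp) <= 0)) stop("cut-points must be positive", call. = FALSE)
  cp
}

#' Normalize an echocardiographic measure by BSA
#'
#' @param value Absolute measurement (mm or ml), > 0. Vectorized.
#' @param bsa Body surface area (m^2), > 0. Vectorized.
#' @return Relative index (mm/m^2 or ml/m^2), full precision; conventional
#'   reporting precision is 1 decimal.
#' @export
#' @examples
#' normalize_echo(147, 1.933)  # 76.0 ml/m^2
#' normalize_echo(147, 2.004)  # 73.4 ml/m^2
normalize_echo <- function(value, bsa) {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("`value` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(bsa)) || any(bsa <= 0))
    stop("`bsa` must be finite and > 0", call. = FALSE)
  value / bsa
}

#' Classify ventricular dilatation for one subject under one BSA value
#'
#' Left ventricular dilatation: indexed LVEDD or indexed LVEDV strictly above
#' its sex-specific cut-point. Right ventricular dilatation: indexed RVBD
#' strictly above 22 mm/m^2. A subject flagged on both sides is treated as
#' possible athlete's heart (balanced biventricular enlargement) and is not
#' counted in the prevalence numerator: `counted = left XOR right`.
#' Classification always uses unrounded relative indexes.
#'
#' @param lvedd,lvedv,rvbd Absolute measurements (mm, ml, mm), > 0.
#' @param bsa Normalizing BSA (m^2), > 0.
#' @param sex `"male"` or `"female"`.
#' @param cutpoints A [dilatation_cutpoints()] list.
#' @return A list: `left`, `right`, `counted` (logicals) and `indexes`
#'   (named vector of the three relative values).
#' @export
classify_subject <- function(lvedd, lvedv, rvbd, bsa, sex,
                             cutpoints = dilatation_cutpoints()) {
  .check_sex(sex)
  idx <- c(lvedd = normalize_echo(lvedd, bsa),
           lvedv = normalize_echo(lvedv, bsa),
           rvbd = normalize_echo(rvbd, bsa))
  left <- idx[["lvedd"]] > cutpoints$lvedd[[sex]] ||
    idx[["lvedv"]] > cutpoints$lvedv[[sex]]
  right <- idx[["rvbd"]] > cutpoints$rvbd[[sex]]
  list(left = left, right = right, counted = xor(left, right), indexes = idx)
}

#' Dilatation prevalence from a set of per-subject calls
#'
#' The numerator counts subjects dilated on exactly one side (the
#' athlete's-heart exclusion removes both-sided subjects from the numerator
#' but not the denominator); it always equals `left_count + right_count`.
#'
#' @param calls Data frame with columns `id`, `left`, `right` (logicals),
#'   one row per subject.
#' @return A list: `fraction`, `numerator`, `denominator`, `left_count`
#'   (left-only), `right_count` (right-only), `both_count`.
#' @export
prevalence <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("id", "left", "right") %in% names(calls)))
  if (!nrow(calls)) stop("empty call list", call. = FALSE)
  if (anyDuplicated(calls$id)) stop("duplicate subject ids", call. = FALSE)
  left_only <- sum(calls$left & !calls$right)
  right_only <- sum(calls$right & !calls$left)
  both <- sum(calls$left & calls$right)
  num <- left_only + right_only
  list(fraction = num / nrow(calls), numerator = num, denominator = nrow(calls),
       left_count = left_only, right_count = right_only, both_count = both)
}

#' McNemar comparison of paired dilatation classifications
#'
#' Compares the counted-dilatation flags of the same subjects under two BSA
#' normalizations via the discordant pairs b = A+/B- and c = A-/B+. The
#' p-value is the exact two-sided binomial test on (b, b + c) at p = 1/2 when
#' b + c < 25, and the continuity-corrected chi-square approximation
#' otherwise.
#'
#' @param flags_a,flags_b Equal-length logical vectors, aligned by subject.
#' @return A list: `b`, `c`, `p_value`, `method` ("exact" or "chisq").
#' @export
mcnemar_paired <- function(flags_a, flags_b) {
  if (length(flags_a) != length(flags_b))
    stop("call sets are misaligned", call. = FALSE)
  b <- sum(flags_a & !flags_b)
  cc <- sum(!flags_a & flags_b)
  n_disc <- b + cc
  if (n_disc == 0) {
    return(list(b = b, c = cc, p_value = 1, method = "exact"))
  }
  if (n_disc < 25) {
    p <- stats::binom.test(b, n_disc, p = 0.5)$p.value
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n_disc
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(b = b, c = cc, p_value = p, method = method)
}

#' Dilatation prevalence under each BSA normalization
#'
#' For each of the ten predictive equations: per-sex medians and
#' interquartile ranges of the three relative indexes, counted-dilatation
#' prevalence with the left-only/right-only split, and a pairwise McNemar
#' p-value matrix across normalizations. Also reports Mann-Whitney
#' male-vs-female comparisons of the absolute and relative values.
#'
#' @param cohort Data frame with `id`, `sex`, `weight_kg`, `height_cm`,
#'   `lvedd_mm`, `lvedv_ml`, `rvbd_mm`.
#' @param cutpoints A [dilatation_cutpoints()] list.
#' @return A list: `index_summary` (tibble: method x sex x variable medians
#'   and IQRs), `prevalence` (tibble: per-method counts and fraction),
#'   `calls` (tibble of per-subject per-method flags), `mcnemar` (named
#'   p-value matrix), `sex_comparison` (tibble of Mann-Whitney p-values).
#' @export
prevalence_by_method <- function(cohort, cutpoints = dilatation_cutpoints()) {
  need <- c("id", "sex", "weight_kg", "height_cm", "lvedd_mm", "lvedv_ml", "rvbd_mm")
  if (!all(need %in% names(cohort)))
    stop("cohort is missing columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "), call. = FALSE)
  if (any(is.na(cohort[need])))
    stop("missing echo measurements or anthropometry", call. = FALSE)
  est <- predict_all(cohort)
  est <- dplyr::left_join(est,
                          cohort[, c("id", "sex", "lvedd_mm", "lvedv_ml", "rvbd_mm")],
                          by = "id")
  est <- dplyr::mutate(est,
                       lvedd_rel = .data$lvedd_mm / .data$bsa_m2,
                       lvedv_rel = .data$lvedv_ml / .data$bsa_m2,
                       rvbd_rel = .data$rvbd_mm / .data$bsa_m2)
  cut_lvedd <- cutpoints$lvedd[est$sex]
  cut_lvedv <- cutpoints$lvedv[est$sex]
  cut_rvbd <- cutpoints$rvbd[est$sex]
  calls <- dplyr::mutate(est,
                         left = .data$lvedd_rel > cut_lvedd | .data$lvedv_rel > cut_lvedv,
                         right = .data$rvbd_rel > cut_rvbd,
                         counted = xor(.data$left, .data$right))

  index_summary <- calls |>
    tidyr::pivot_longer(cols = c("lvedd_rel", "lvedv_rel", "rvbd_rel"),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(.data$method_id, .data$sex, .data$variable) |>
    dplyr::summarise(median = stats::median(.data$value),
                     q1 = unname(stats::quantile(.data$value, 0.25)),
                     q3 = unname(stats::quantile(.data$value, 0.75)),
                     .groups = "drop")

  prev_tab <- dplyr::bind_rows(lapply(bsa_methods(), function(m) {
    pv <- prevalence(calls[calls$method_id == m, c("id", "left", "right")])
    tibble::tibble(method_id = m, numerator = pv$numerator,
                   denominator = pv$denominator, fraction = pv$fraction,
                   pct = 100 * pv$fraction, left_count = pv$left_count,
                   right_count = pv$right_count, both_count = pv$both_count)
  }))

  ids <- cohort$id
  flag_mat <- vapply(bsa_methods(), function(m) {
    sub <- calls[calls$method_id == m, ]
    sub$counted[match(ids, sub$id)]
  }, logical(length(ids)))
  flag_mat <- matrix(flag_mat, nrow = length(ids),
                     dimnames = list(NULL, bsa_methods()))
  k <- length(bsa_methods())
  mcn <- matrix(NA_real_, k, k, dimnames = list(bsa_methods(), bsa_methods()))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- mcnemar_paired(flag_mat[, i], flag_mat[, j])$p_value
    mcn[i, j] <- p; mcn[j, i] <- p
  }
  diag(mcn) <- 1

  sex_comparison <- NULL
  if (all(c("male", "female") %in% cohort$sex)) {
    abs_p <- vapply(c("lvedd_mm", "lvedv_ml", "rvbd_mm"), function(v)
      stats::wilcox.test(cohort[[v]][cohort$sex == "male"],
                         cohort[[v]][cohort$sex == "female"],
                         exact = FALSE)$p.value, 0)
    rel <- calls |>
      tidyr::pivot_longer(cols = c("lvedd_rel", "lvedv_rel", "rvbd_rel"),
                          names_to = "variable", values_to = "value") |>
      dplyr::group_by(.data$method_id, .data$variable) |>
      dplyr::summarise(p_mann_whitney = stats::wilcox.test(
        .data$value[.data$sex == "male"], .data$value[.data$sex == "female"],
        exact = FALSE)$p.value, .groups = "drop")
    sex_comparison <- list(
      absolute = tibble::tibble(variable = names(abs_p), p_mann_whitney = unname(abs_p)),
      relative = rel)
  }

  list(index_summary = index_summary, prevalence = prev_tab,
       calls = tibble::as_tibble(calls[, c("id", "method_id", "sex", "lvedd_rel",
                                           "lvedv_rel", "rvbd_rel", "left",
                                           "right", "counted")]),
       mcnemar = mcn, sex_comparison = sex_comparison)
}
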