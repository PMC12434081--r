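# End-to-end orchestration: cohort I/O, the accuracy study (Grubbs QC ->
# equation evaluation -> per-sex agreement table) and the dilatation study
# (normalization -> classification -> prevalence and paired comparisons),
# with JSON report writers. Numbers are rounded only at render time;
# machine-readable output keeps full precision.

#' Read a cohort CSV
#'
#' Expected columns: `id`, `sex`, `weight_kg`, `height_cm`, and optionally
#' `criterion_bsa_m2`, scan replicates (`scan1_bsa_m2`, `scan2_bsa_m2`) and
#' the echo block (`lvedd_mm`, `lvedv_ml`, `rvbd_mm`).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "weight_kg", "height_cm")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$id <- as.character(df$id)
  df$sex <- tolower(df$sex)
  .check_sex(df$sex)
  tibble::as_tibble(df)
}

#' Write a cohort CSV
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Run the BSA-equation accuracy study
#'
#' Pipeline: resolve the criterion BSA (an existing `criterion_bsa_m2`
#' column, or replicate-scan averaging via [criterion_from_scans()]), run
#' Grubbs outlier QC on the cohort criterion distribution, then compute the
#' per-sex agreement table with [compare_equations()].
#'
#' @param cohort Cohort tibble (see [read_cohort()]).
#' @param grubbs_alpha Significance level for the outlier QC.
#' @param alpha Significance level for the normality gate.
#' @param drop_outliers Remove Grubbs-flagged subjects before comparison
#'   (default TRUE; flagged ids are always reported).
#' @return A list of class `bsa_accuracy_study`: `qc`, `comparison` (per-sex
#'   output of [compare_equations()]), `n_input`, `n_analyzed`.
#' @export
run_accuracy_study <- function(cohort, grubbs_alpha = 0.05, alpha = 0.05,
                               drop_outliers = TRUE) {
  if (!"criterion_bsa_m2" %in% names(cohort)) {
    if ("scan1_bsa_m2" %in% names(cohort)) {
      cfs <- criterion_from_scans(cohort, alpha = grubbs_alpha)
      cohort <- dplyr::left_join(cohort, cfs$criterion, by = "id")
      qc <- cfs$qc
    } else {
      stop("no criterion BSA source: need criterion_bsa_m2 or scan columns",
           call. = FALSE)
    }
  } else {
    qc <- grubbs_outliers(cohort$criterion_bsa_m2, alpha = grubbs_alpha)
    qc$flagged_ids <- cohort$id[qc$outliers]
  }
  n_input <- nrow(cohort)
  if (drop_outliers && length(qc$flagged_ids))
    cohort <- cohort[!cohort$id %in% qc$flagged_ids, , drop = FALSE]
  comparison <- compare_equations(cohort, alpha = alpha)
  structure(list(qc = qc, comparison = comparison,
                 n_input = n_input, n_analyzed = nrow(cohort)),
            class = "bsa_accuracy_study")
}

#' @export
print.bsa_accuracy_study <- function(x, digits = 3, ...) {
  cat("BSA accuracy study:", x$n_analyzed, "of", x$n_input,
      "subjects analyzed;", length(x$qc$outliers), "Grubbs outlier(s)\n")
  for (sx in names(x$comparison)) {
    cmp <- x$comparison[[sx]]
    cat("\n--", sx, "(n =", cmp$criterion_summary$n, ") omnibus:",
        cmp$omnibus$branch, sprintf("statistic = %.1f, p = %.3g\n",
                                    cmp$omnibus$statistic, cmp$omnibus$p_value))
    tab <- cmp$table
    out <- data.frame(
      method = tab$method_id,
      `median (IQR) m2` = sprintf("%.*f (%.*f-%.*f)", digits, tab$median_m2,
                                  digits, tab$q1_m2, digits, tab$q3_m2),
      PCC = sprintf("%.3f", tab$pcc),
      `RMSE m2` = sprintf("%.*f", digits, tab$rmse_m2),
      `bias +/- SD (%)` = sprintf("%.1f +/- %.1f", tab$bias_pct, tab$sd_diff_pct),
      rank = tab$rmse_rank, check.names = FALSE)
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Run the ventricular-dilatation study
#'
#' Pipeline: evaluate all ten BSA equations, normalize the echo block,
#' classify left/right dilatation with the athlete's-heart exclusion, and
#' compare prevalences across normalizations (McNemar matrix). Per-sex
#' Friedman tests compare each relative index across the ten normalizations.
#' A single-subject cohort acts as a worked-example mode: the per-method
#' relative indexes and calls are the report.
#'
#' @param cohort Cohort tibble with the echo block (`lvedd_mm`, `lvedv_ml`,
#'   `rvbd_mm`).
#' @param cutpoints A [dilatation_cutpoints()] list.
#' @return A list of class `dilatation_study`: the [prevalence_by_method()]
#'   output plus `friedman` (per sex x variable).
#' @export
run_dilatation_study <- function(cohort, cutpoints = dilatation_cutpoints()) {
  res <- prevalence_by_method(cohort, cutpoints)
  friedman <- NULL
  for (sx in intersect(c("male", "female"), unique(cohort$sex))) {
    sub <- res$calls[res$calls$sex == sx, ]
    if (length(unique(sub$id)) < 2) next
    for (v in c("lvedd_rel", "lvedv_rel", "rvbd_rel")) {
      wide <- tidyr::pivot_wider(sub[, c("id", "method_id", v)],
                                 names_from = "method_id",
                                 values_from = dplyr::all_of(v))
      fr <- friedman_methods(as.matrix(wide[, -1]))
      friedman <- dplyr::bind_rows(friedman, tibble::tibble(
        sex = sx, variable = sub("_rel", "", v),
        statistic = fr$statistic, df = fr$df, p_value = fr$p_value))
    }
  }
  structure(c(res, list(friedman = friedman)), class = "dilatation_study")
}

#' @export
print.dilatation_study <- function(x, ...) {
  n <- x$prevalence$denominator[1]
  cat("Ventricular dilatation study:", n, "subject(s)\n\n")
  tab <- data.frame(
    method = x$prevalence$method_id,
    `prevalence cases/total (%)` = sprintf("%d/%d (%.1f%%)", x$prevalence$numerator,
                                           x$prevalence$denominator, x$prevalence$pct),
    `left (right) cases` = sprintf("%d (%d)", x$prevalence$left_count,
                                   x$prevalence$right_count),
    both = x$prevalence$both_count, check.names = FALSE)
  print(tab, row.names = FALSE)
  if (n == 1) {
    cat("\nWorked example - per-method relative indexes (1 decimal):\n")
    ex <- x$calls
    tab1 <- data.frame(method = ex$method_id,
                       `LVEDD mm/m2` = sprintf("%.1f", ex$lvedd_rel),
                       `LVEDV ml/m2` = sprintf("%.1f", ex$lvedv_rel),
                       `RVBD mm/m2` = sprintf("%.1f", ex$rvbd_rel),
                       left = ex$left, right = ex$right, counted = ex$counted,
                       check.names = FALSE)
    print(tab1, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report as JSON
#'
#' Full-precision machine-readable rendering of an accuracy or dilatation
#' study result.
#'
#' @param study Output of [run_accuracy_study()] or [run_dilatation_study()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(study, path) {
  x <- unclass(study)
  if (!is.null(x$mcnemar)) {
    x$mcnemar <- list(methods = rownames(x$mcnemar),
                      p_values = unname(as.data.frame(x$mcnemar)))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
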