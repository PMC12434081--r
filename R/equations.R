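# Registry of the ten literature BSA predictive equations.
#
# All equations take weight in kg and height in cm and return body surface
# area in m^2. Coefficients are stored exactly as printed in the source
# registry; no re-derivation from the original publications is attempted.
# Three methods (tikuisis, schlich, ashby_thompson) carry distinct male and
# female parameter sets; livingston is weight-only; sendroy is affine in
# (weight + height) and applies identically to both sexes.

.bsa_registry <- list(
  dubois = list(
    label = "DuBois", form = "power", sex_specific = FALSE, requires_height = TRUE,
    both = c(coefficient = 0.007184, weight_exponent = 0.425, height_exponent = 0.725),
    reference = "DuBois & DuBois (1916)"
  ),
  sendroy = list(
    label = "Sendroy", form = "linear", sex_specific = FALSE, requires_height = TRUE,
    both = c(slope = 0.0097, intercept = -0.545),
    reference = "Sendroy & Cecchini (1954)"
  ),
  gehan = list(
    label = "Gehan", form = "power", sex_specific = FALSE, requires_height = TRUE,
    both = c(coefficient = 0.0235, weight_exponent = 0.51456, height_exponent = 0.42246),
    reference = "Gehan & George (1970)"
  ),
  mosteller = list(
    label = "Mosteller", form = "power", sex_specific = FALSE, requires_height = TRUE,
    both = c(coefficient = 0.016667, weight_exponent = 0.5, height_exponent = 0.5),
    reference = "Mosteller (1987)"
  ),
  shuter = list(
    label = "Shuter", form = "power", sex_specific = FALSE, requires_height = TRUE,
    both = c(coefficient = 0.00949, weight_exponent = 0.441, height_exponent = 0.655),
    reference = "Shuter & Aslani (2000)"
  ),
  tikuisis = list(
    label = "Tikuisis", form = "power", sex_specific = TRUE, requires_height = TRUE,
    male = c(coefficient = 0.01281, weight_exponent = 0.44, height_exponent = 0.60),
    female = c(coefficient = 0.01474, weight_exponent = 0.47, height_exponent = 0.55),
    reference = "Tikuisis et al. (2001)"
  ),
  livingston = list(
    label = "Livingston", form = "power", sex_specific = FALSE, requires_height = FALSE,
    both = c(coefficient = 0.1173, weight_exponent = 0.6466, height_exponent = 0),
    reference = "Livingston & Lee (2001)"
  ),
  schlich = list(
    label = "Schlich", form = "power", sex_specific = TRUE, requires_height = TRUE,
    male = c(coefficient = 0.000579479, weight_exponent = 0.38, height_exponent = 1.24),
    female = c(coefficient = 0.000975482, weight_exponent = 0.46, height_exponent = 1.08),
    reference = "Schlich et al. (2010)"
  ),
  kuehnapfel = list(
    label = "Kuehnapfel", form = "power", sex_specific = FALSE, requires_height = TRUE,
    both = c(coefficient = 0.015, weight_exponent = 0.4259, height_exponent = 0.5751),
    reference = "Kuehnapfel et al. (2017)"
  ),
  ashby_thompson = list(
    label = "Ashby-Thompson", form = "power", sex_specific = TRUE, requires_height = TRUE,
    male = c(coefficient = 0.01624, weight_exponent = 0.4725, height_exponent = 0.5231),
    female = c(coefficient = 0.01522, weight_exponent = 0.4921, height_exponent = 0.5231),
    reference = "Ashby-Thompson et al. (2020)"
  )
)

#' Names of the registered BSA predictive equations
#'
#' @return Character vector of the ten method identifiers, in registry order.
#' @export
bsa_methods <- function() names(.bsa_registry)

#' Machine-readable table of the BSA equation registry
#'
#' One row per (method, sex variant): power-law methods report coefficient and
#' exponents, the affine Sendroy equation reports slope/intercept in the
#' coefficient/weight-exponent columns with `form = "linear"`.
#'
#' @return A tibble with columns `method_id`, `label`, `sex`, `form`,
#'   `coefficient`, `weight_exponent`, `height_exponent`, `requires_height`,
#'   `reference`.
#' @export
#' @examples
#' bsa_registry_table()
bsa_registry_table <- function() {
  rows <- lapply(names(.bsa_registry), function(id) {
    eq <- .bsa_registry[[id]]
    sexes <- if (eq$sex_specific) c("male", "female") else "both"
    do.call(rbind, lapply(sexes, function(sx) {
      p <- if (eq$sex_specific) eq[[sx]] else eq$both
      if (eq$form == "linear") {
        data.frame(method_id = id, label = eq$label, sex = sx, form = eq$form,
                   coefficient = unname(p["slope"]),
                   weight_exponent = unname(p["intercept"]),
                   height_exponent = NA_real_,
                   requires_height = eq$requires_height,
                   reference = eq$reference, stringsAsFactors = FALSE)
      } else {
        data.frame(method_id = id, label = eq$label, sex = sx, form = eq$form,
                   coefficient = unname(p["coefficient"]),
                   weight_exponent = unname(p["weight_exponent"]),
                   height_exponent = if (eq$requires_height) unname(p["height_exponent"]) else NA_real_,
                   requires_height = eq$requires_height,
                   reference = eq$reference, stringsAsFactors = FALSE)
      }
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Export the equation registry as JSON
#'
#' @param path File path to write to.
#' @return The path, invisibly.
#' @export
write_bsa_registry <- function(path) {
  jsonlite::write_json(bsa_registry_table(), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.check_sex <- function(sex, n = NULL) {
  if (is.null(sex) || any(is.na(sex)) || !all(sex %in% c("male", "female")))
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  if (!is.null(n) && !(length(sex) %in% c(1L, n)))
    stop("`sex` must have length 1 or match weight/height", call. = FALSE)
  sex
}

# Human-plausibility guard: the equations are algebraically defined on all
# positive inputs but validated only on human ranges; values far outside them
# usually indicate a unit mistake (grams, meters), so warn rather than fail.
.check_anthropometry <- function(weight, height, need_height = TRUE) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("`weight` must be finite and > 0 (kg)", call. = FALSE)
  if (need_height && (any(!is.finite(height)) || any(height <= 0)))
    stop("`height` must be finite and > 0 (cm)", call. = FALSE)
  if (any(weight < 20 | weight > 150))
    warning("weight outside the validated 20-150 kg range; check units (kg expected)",
            call. = FALSE)
  if (need_height && any(height < 120 | height > 220))
    warning("height outside the validated 120-220 cm range; check units (cm expected)",
            call. = FALSE)
  invisible(NULL)
}

#' Predict body surface area from weight and height
#'
#' Evaluates one of the ten registered predictive equations. Weight is in kg
#' and height in cm; the result is in m^2 at full floating precision
#' (rounding to 3 decimals is a reporting concern only). Inputs outside the
#' validated human ranges (weight 20-150 kg, height 120-220 cm) trigger a
#' warning, as they usually indicate a unit mistake.
#'
#' @param method_id One of [bsa_methods()].
#' @param sex `"male"` or `"female"`; required for the sex-specific methods
#'   (`tikuisis`, `schlich`, `ashby_thompson`) and ignored by the others.
#' @param weight Body weight in kg, strictly positive. Vectorized.
#' @param height Standing height in cm, strictly positive. Vectorized;
#'   ignored by the weight-only `livingston` equation.
#' @return Numeric vector of BSA values in m^2.
#' @export
#' @examples
#' predict_bsa("dubois", "male", weight = 77, height = 185)   # 2.004 m^2
#' predict_bsa("livingston", "female", weight = 60, height = 165)
predict_bsa <- function(method_id, sex = NULL, weight, height = NULL) {
  if (length(method_id) != 1L || !method_id %in% names(.bsa_registry))
    stop("unknown method_id: ", paste(method_id, collapse = ", "),
         " (see bsa_methods())", call. = FALSE)
  eq <- .bsa_registry[[method_id]]
  if (eq$requires_height && is.null(height))
    stop("method '", method_id, "' requires height", call. = FALSE)
  .check_anthropometry(weight, height, need_height = eq$requires_height)
  if (eq$sex_specific) {
    .check_sex(sex, n = length(weight))
    sex <- rep(sex, length.out = length(weight))
    pm <- eq$male; pf <- eq$female
    if (eq$form != "power") stop("internal: unexpected form") # registry invariant
    male <- sex == "male"
    coefficient <- ifelse(male, pm["coefficient"], pf["coefficient"])
    we <- ifelse(male, pm["weight_exponent"], pf["weight_exponent"])
    he <- ifelse(male, pm["height_exponent"], pf["height_exponent"])
    return(unname(coefficient * weight^we * height^he))
  }
  p <- eq$both
  if (eq$form == "linear") {
    unname(p["slope"] * (weight + height) + p["intercept"])
  } else if (eq$requires_height) {
    unname(p["coefficient"] * weight^p["weight_exponent"] * height^p["height_exponent"])
  } else {
    unname(p["coefficient"] * weight^p["weight_exponent"])
  }
}

#' Evaluate all ten registered equations for one or more subjects
#'
#' @param subjects A data frame with columns `id`, `sex`, `weight_kg`,
#'   `height_cm` (the cohort CSV schema).
#' @return A tibble in long format: `id`, `method_id`, `bsa_m2`, one row per
#'   subject x method, deterministic registry order.
#' @export
#' @examples
#' predict_all(data.frame(id = "s1", sex = "male", weight_kg = 77, height_cm = 185))
predict_all <- function(subjects) {
  stopifnot(is.data.frame(subjects))
  need <- c("id", "sex", "weight_kg", "height_cm")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols))
    stop("subjects is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(subjects$id))
    stop("duplicate subject ids", call. = FALSE)
  out <- lapply(bsa_methods(), function(m) {
    bsa <- tryCatch(
      predict_bsa(m, sex = subjects$sex, weight = subjects$weight_kg,
                  height = subjects$height_cm),
      error = function(e) stop("method '", m, "': ", conditionMessage(e), call. = FALSE)
    )
    tibble::tibble(id = subjects$id, method_id = m, bsa_m2 = bsa)
  })
  dplyr::bind_rows(out)
}
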