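# Shared fixtures: tiny deterministic cohorts and geometry helpers.

tiny_cohort <- function() {
  data.frame(
    id = c("m1", "m2", "m3", "m4", "f1", "f2", "f3"),
    sex = c(rep("male", 4), rep("female", 3)),
    weight_kg = c(77, 70, 82, 65, 60, 55, 63),
    height_cm = c(185, 176, 181, 170, 168, 160, 171),
    stringsAsFactors = FALSE
  )
}

# cohort where the criterion equals one chosen equation exactly
cohort_with_criterion <- function(method = "kuehnapfel") {
  co <- tiny_cohort()
  co$criterion_bsa_m2 <- predict_bsa(method, sex = co$sex,
                                     weight = co$weight_kg, height = co$height_cm)
  co
}

rotation_matrix <- function(ax, ay, az) {
  rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# exact two-sided binomial tail at p = 1/2, by enumeration
binom_two_sided_oracle <- function(b, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[b + 1] + 1e-12])
}

# Friedman chi-square from first principles (no ties assumed handled by
# mid-ranks); rows = subjects, cols = methods
friedman_statistic_oracle <- function(mat) {
  r <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}
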