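test_that("normalization reproduces the worked-example relative indexes", {
  expect_equal(round(normalize_echo(147, 1.933), 1), 76.0)
  expect_equal(normalize_echo(147, 2.004), 73.35, tolerance = 1e-3)
  expect_lt(abs(normalize_echo(147, 2.004) - 73.3), 0.1)
  expect_equal(normalize_echo(42.7, 1), 42.7)
  expect_error(normalize_echo(-1, 2), "> 0")
  expect_error(normalize_echo(147, 0), "> 0")
})

test_that("classification uses strict sex-specific cut-points and the XOR rule", {
  cp <- dilatation_cutpoints()
  # worked example: LVEDV 147 ml, male; Kuehnapfel BSA flags, DuBois does not
  pos <- classify_subject(lvedd = 52, lvedv = 147, rvbd = 38, bsa = 1.933,
                          sex = "male", cp)
  neg <- classify_subject(lvedd = 52, lvedv = 147, rvbd = 38, bsa = 2.004,
                          sex = "male", cp)
  expect_true(pos$left); expect_true(pos$counted)
  expect_false(neg$left); expect_false(neg$counted)
  expect_false(pos$right); expect_false(neg$right)
  # exact equality at a cut-point is non-dilated ("above" is strict)
  at <- classify_subject(lvedd = 29 * 2, lvedv = 60 * 2, rvbd = 22 * 2,
                         bsa = 2, sex = "male", cp)
  expect_false(at$right)
  # female LVEDV cut-point is lower at 61 ml/m^2
  f <- classify_subject(lvedd = 50, lvedv = 62 * 1.8, rvbd = 30, bsa = 1.8,
                        sex = "female", cp)
  expect_true(f$left)
  # both-sided dilatation is excluded from the numerator
  both <- classify_subject(lvedd = 80, lvedv = 200, rvbd = 60, bsa = 1.8,
                           sex = "male", cp)
  expect_true(both$left && both$right)
  expect_false(both$counted)
  expect_equal(both$counted, xor(both$left, both$right))
})

test_that("prevalence bookkeeping: numerator = left-only + right-only", {
  calls <- data.frame(
    id = sprintf("s%03d", 1:111),
    left = c(rep(TRUE, 24), rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 80)),
    right = c(rep(FALSE, 24), rep(TRUE, 5), rep(TRUE, 2), rep(FALSE, 80)))
  pv <- prevalence(calls)
  expect_equal(pv$numerator, 29)
  expect_equal(pv$left_count, 24)
  expect_equal(pv$right_count, 5)
  expect_equal(pv$both_count, 2)
  expect_equal(round(100 * pv$fraction, 1), 26.1)
  expect_equal(pv$left_count + pv$right_count, pv$numerator)
  # no positives and all-both cohorts both give zero prevalence
  none <- data.frame(id = 1:10, left = FALSE, right = FALSE)
  expect_equal(prevalence(none)$fraction, 0)
  allboth <- data.frame(id = 1:10, left = TRUE, right = TRUE)
  expect_equal(prevalence(allboth)$fraction, 0)
  expect_error(prevalence(none[0, ]), "empty")
  expect_error(prevalence(rbind(none, none)), "duplicate")
})

test_that("McNemar exact path matches a brute-force binomial-tail oracle", {
  # identical classifications
  same <- rep(c(TRUE, FALSE), 10)
  res <- mcnemar_paired(same, same)
  expect_equal(res$b + res$c, 0)
  expect_equal(res$p_value, 1)
  # one-sided discordance b = 6, c = 0: exact p = 2 * (1/2)^6
  a <- c(rep(TRUE, 6), rep(FALSE, 10))
  b <- rep(FALSE, 16)
  res6 <- mcnemar_paired(a, b)
  expect_equal(res6$b, 6); expect_equal(res6$c, 0)
  expect_equal(res6$p_value, 0.03125)
  # all (b, c) with b + c <= 12 against the enumeration oracle
  for (n in 1:12) for (bb in 0:n) {
    fa <- c(rep(TRUE, bb), rep(FALSE, n - bb), TRUE, FALSE)
    fb <- c(rep(FALSE, bb), rep(TRUE, n - bb), TRUE, FALSE)
    got <- mcnemar_paired(fa, fb)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, binom_two_sided_oracle(bb, n),
                 tolerance = 1e-12, label = sprintf("b=%d c=%d", bb, n - bb))
  }
  # symmetry: swapping the call sets swaps b and c, p unchanged
  set.seed(14)
  fa <- runif(40) < 0.3; fb <- runif(40) < 0.3
  r1 <- mcnemar_paired(fa, fb); r2 <- mcnemar_paired(fb, fa)
  expect_equal(r1$b, r2$c); expect_equal(r1$c, r2$b)
  expect_equal(r1$p_value, r2$p_value)
  expect_error(mcnemar_paired(fa, fb[-1]), "misaligned")
})

test_that("McNemar switches to continuity-corrected chi-square for large discordance", {
  fa <- c(rep(TRUE, 20), rep(FALSE, 10))
  fb <- c(rep(FALSE, 20), rep(TRUE, 10))
  res <- mcnemar_paired(fa, fb)
  expect_equal(res$method, "chisq")
  expect_equal(res$p_value,
               pchisq((abs(20 - 10) - 1)^2 / 30, 1, lower.tail = FALSE))
  # agrees with the standard implementation of the corrected test
  tab <- table(factor(fa, c(FALSE, TRUE)), factor(fb, c(FALSE, TRUE)))
  expect_equal(res$p_value, mcnemar.test(tab, correct = TRUE)$p.value)
})

test_that("per-ventricle flag sets are nested under pointwise-ordered BSA", {
  set.seed(15)
  cp <- dilatation_cutpoints()
  for (rep in 1:50) {
    n <- 25
    sex <- sample(c("male", "female"), n, replace = TRUE)
    bsa_a <- runif(n, 1.5, 2.1)
    bsa_b <- bsa_a * runif(n, 1.01, 1.12)  # B strictly larger subject-wise
    lvedd <- runif(n, 45, 62); lvedv <- runif(n, 90, 160); rvbd <- runif(n, 30, 46)
    for (i in seq_len(n)) {
      ca <- classify_subject(lvedd[i], lvedv[i], rvbd[i], bsa_a[i], sex[i], cp)
      cb <- classify_subject(lvedd[i], lvedv[i], rvbd[i], bsa_b[i], sex[i], cp)
      # flags under the larger BSA imply flags under the smaller
      expect_true(!cb$left || ca$left)
      expect_true(!cb$right || ca$right)
    }
  }
})

test_that("prevalence_by_method assembles per-method calls, counts, and McNemar matrix", {
  cfg <- cohort_config("echo")
  co <- inject_echo(simulate_cohort(cfg, seed = 21), cfg, seed = 22)
  res <- prevalence_by_method(co)
  expect_setequal(res$prevalence$method_id, bsa_methods())
  expect_true(all(res$prevalence$numerator ==
                    res$prevalence$left_count + res$prevalence$right_count))
  expect_true(all(res$prevalence$denominator == nrow(co)))
  expect_equal(dim(res$mcnemar), c(10, 10))
  expect_true(isSymmetric(res$mcnemar))
  expect_true(all(res$mcnemar >= 0 & res$mcnemar <= 1))
  # methods giving uniformly smaller BSA index more subjects as dilated
  est <- predict_all(co)
  wide <- tidyr::pivot_wider(est, names_from = method_id, values_from = bsa_m2)
  if (all(wide$kuehnapfel < wide$dubois)) {
    pk <- res$prevalence
    left_k <- res$calls$left[res$calls$method_id == "kuehnapfel"]
    left_d <- res$calls$left[res$calls$method_id == "dubois"]
    expect_true(all(left_k | !left_d))  # dubois flags are a subset
  }
  expect_true(!is.null(res$sex_comparison))
  expect_equal(nrow(res$sex_comparison$relative), 30)
})

test_that("single-subject cohort collapses to the point estimates", {
  co <- data.frame(id = "w1", sex = "male", weight_kg = 77, height_cm = 185,
                   lvedd_mm = 52, lvedv_ml = 147, rvbd_mm = 38)
  res <- prevalence_by_method(co)
  expect_true(all(res$prevalence$fraction %in% c(0, 1)))
  expect_true(all(res$index_summary$median == res$index_summary$q1))
  expect_true(all(res$index_summary$median == res$index_summary$q3))
  kue <- res$calls[res$calls$method_id == "kuehnapfel", ]
  dub <- res$calls[res$calls$method_id == "dubois", ]
  expect_true(kue$left); expect_false(dub$left)
})
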