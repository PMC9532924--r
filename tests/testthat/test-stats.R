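test_that("responder labels use inclusive 1.0/0.8/0.5 reduction thresholds", {
  lab <- label_responder(c(100, 100, 100, 100, 100, 100),
                         c(0, 20, 50, 60, 150, 49.9))
  expect_identical(as.character(lab$category),
                   c("R100", "R80", "R50", "NR50", "NR50", "R50"))
  expect_identical(lab$responder, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(lab$reduction_fraction[5], -0.5)
  expect_error(label_responder(0, 10), "baseline")
})

test_that("KS screen accepts normal and rejects exponential samples", {
  res <- sapply(1:100, function(s) {
    set.seed(s)
    c(norm = ks_normality(rnorm(1000)),
      expo = ks_normality(rexp(1000)))
  })
  expect_gte(sum(res["norm", ] > 0.05), 90)
  expect_gte(sum(res["expo", ] < 0.05), 95)
  expect_error(ks_normality(c(1, 2)), "at least 3")
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("Mann-Whitney exact path reproduces full-enumeration results", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_identical(res$method, "exact")

  # identical multisets: fully symmetric, p = 1
  same <- mann_whitney_u(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$p, 1)

  # tie-free exact path agrees with the reference exact implementation
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_identical(ours$method, "exact")
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation tracks the exact path", {
  set.seed(8)
  gap <- sapply(1:100, function(i) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    abs(mann_whitney_u(x, y, exact = TRUE)$p -
          mann_whitney_u(x, y, exact = FALSE)$p)
  })
  expect_lt(max(gap), 0.02)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("contingency tests dispatch on expected counts and match references", {
  perfect <- chi_square_or_fisher(rbind(c(10, 10), c(10, 10)))
  expect_identical(perfect$test, "chi_square")
  expect_equal(perfect$p, 1)

  # sparse 2x2 -> Fisher; matches the brute-force hypergeometric tail sum
  tab <- rbind(c(8, 2), c(1, 9))
  res <- chi_square_or_fisher(tab)
  expect_identical(res$test, "fisher")
  # enumerate all tables with the observed margins
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m, k), m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  expect_equal(res$p, sum(probs[probs <= p_obs + 1e-12]),
               tolerance = 1e-12)

  # the gender table of a 37/33 responder split: expected counts all >= 5,
  # so the dispatch rule runs chi-square; the Fisher path on the same
  # table reproduces the published-style exact value 0.4611
  gender <- rbind(c(25, 19), c(12, 14))
  disp <- chi_square_or_fisher(gender)
  expect_identical(disp$test, "chi_square")
  expect_equal(disp$p,
               unname(stats::chisq.test(gender, correct = FALSE)$p.value))
  expect_equal(stats::fisher.test(gender)$p.value, 0.4611, tolerance = 1e-3)

  expect_error(chi_square_or_fisher(matrix(0, 2, 2)), "all-zero")
  expect_warning(chi_square_or_fisher(rbind(c(2, 1, 30), c(1, 2, 30))),
                 "larger than 2x2")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdr_bh(0.37), 0.37)
  set.seed(21)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, bh_stepup(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sync group comparison is FDR-corrected per metric and order-invariant", {
  set.seed(33)
  n <- 40
  labels <- rep(c("R50", "NR50"), each = n / 2)
  cols <- paste(rep(c("plv", "pli", "wpli"), each = 5),
                rep(c("delta", "theta", "alpha", "low_beta", "high_beta"),
                    3), sep = "_")
  ft <- as.data.frame(matrix(runif(n * 15, 0.2, 0.4), n, 15,
                             dimnames = list(NULL, cols)))
  ft$pli_high_beta[labels == "R50"] <- ft$pli_high_beta[labels == "R50"] +
    0.3
  cmp <- compare_sync_by_group(ft, labels)
  expect_equal(nrow(cmp), 15)
  expect_true(all(cmp$p_adjusted >= cmp$p_raw))
  hb <- cmp[cmp$metric == "pli" & cmp$band == "high_beta", ]
  expect_true(hb$significant)
  expect_gt(hb$mean_R50, hb$mean_NR50)
  expect_false(any(cmp$significant[!(cmp$metric == "pli" &
                                       cmp$band == "high_beta")]))

  perm <- sample(n)
  cmp2 <- compare_sync_by_group(ft[perm, ], labels[perm])
  expect_equal(cmp, cmp2)

  expect_error(compare_sync_by_group(ft[1:3, ], labels[1:3]),
               "2 subjects per group")
})

test_that("clinical comparison handles continuous, categorical and multi-hot blocks", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 40, responder_fraction = 0.5, duration_s = 4, fs = 200,
    n_channels = 2, seed = 9))
  tab <- cohort_clinical_table(cohort)
  labs <- cohort_labels(cohort)
  cmp <- suppressWarnings(compare_clinical_by_group(tab, labs))
  expect_true(all(c("seizure_frequency", "bmi", "etiology", "seizure_type")
                  %in% cmp$variable))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))

  # planted shift in one continuous variable is detected
  tab2 <- tab
  tab2$bmi[labs == "R50"] <- tab2$bmi[labs == "R50"] + 8
  cmp2 <- suppressWarnings(compare_clinical_by_group(tab2, labs))
  expect_true(cmp2$significant[cmp2$variable == "bmi"])

  # single-category variable is skipped with a warning
  tab3 <- tab
  tab3$gender <- "male"
  expect_warning(cmp3 <- suppressWarnings(
    compare_clinical_by_group(tab3, labs),
    classes = "vnseeg_sparse_table"),
                 "single observed category")
  expect_false("gender" %in% cmp3$variable)
})

test_that("t-test mode is available for the sync comparison", {
  set.seed(12)
  cols <- paste(rep(c("plv", "pli", "wpli"), each = 5),
                rep(c("delta", "theta", "alpha", "low_beta", "high_beta"),
                    3), sep = "_")
  ft <- as.data.frame(matrix(runif(300, 0.2, 0.4), 20, 15,
                             dimnames = list(NULL, cols)))
  labels <- rep(c("R50", "NR50"), 10)
  cmp <- compare_sync_by_group(ft, labels, method = "t_test")
  expect_true(all(cmp$test == "t_test"))
})
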