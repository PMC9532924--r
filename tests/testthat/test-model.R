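make_clinical_row <- function(subject_id = "S001",
                              etiology = "structural",
                              types = c(FALSE, TRUE, FALSE, FALSE),
                              syndrome = "unclassified", mri = "negative") {
  data.frame(subject_id = subject_id, gender = "male", bmi = 16.5,
             diastolic_pressure = 60, pulse_pressure = 41,
             age_onset = 2.1, epilepsy_duration = 3.5,
             age_implantation = 5.6, prior_surgery = FALSE,
             seizure_frequency = 120, etiology = etiology,
             seizure_generalized = types[1], seizure_focal = types[2],
             seizure_spasms = types[3], seizure_multiple = types[4],
             syndrome = syndrome, mri = mri, n_asm_baseline = 3,
             n_asm_historical = 5, benzodiazepine = TRUE,
             stringsAsFactors = FALSE)
}

test_that("clinical encoding yields 25 columns with correct indicator blocks", {
  row <- make_clinical_row()
  X <- encode_clinical(row)
  expect_equal(dim(X), c(1L, 25L))
  expect_identical(colnames(X), vnseeg:::clinical_feature_names())
  expect_equal(unname(X[1, c("etiology_structural", "etiology_genetic",
                             "etiology_autoimmune", "etiology_unknown")]),
               c(1, 0, 0, 0))
  # seizure types are multi-hot, not one-hot
  row2 <- make_clinical_row(types = c(FALSE, TRUE, TRUE, TRUE))
  X2 <- encode_clinical(row2)
  expect_equal(unname(X2[1, c("seizure_generalized", "seizure_focal",
                              "seizure_spasms", "seizure_multiple")]),
               c(0, 1, 1, 1))
  expect_equal(sum(X2[1, paste0("mri_", c("local", "multifocal",
                                          "negative"))]), 1)

  bad <- make_clinical_row(etiology = "viral")
  expect_error(encode_clinical(bad), "unknown etiology")
  expect_error(encode_clinical(row[, -3]), "missing clinical field")
})

test_that("assembled matrices have 43/25/18 columns in the three modes", {
  cohort <- generate_cohort(cohort_spec(
    n_subjects = 16, responder_fraction = 0.5, duration_s = 4, fs = 200,
    n_channels = 2, seed = 14))
  clin <- cohort_clinical_table(cohort)
  sync <- fast_features(cohort, bands = eeg_bands())
  labs <- cohort_labels(cohort)
  m_int <- assemble_matrix(clin, sync, labs, "integrated")
  m_cli <- assemble_matrix(clin, sync, labs, "clinical")
  m_syn <- assemble_matrix(clin, sync, labs, "sync")
  expect_equal(ncol(m_int$X), 43)
  expect_equal(ncol(m_cli$X), 25)
  expect_equal(ncol(m_syn$X), 18)
  expect_equal(nrow(m_int$X), 16)
  expect_identical(m_int$feature_names[1:25],
                   vnseeg:::clinical_feature_names())
  expect_false(anyNA(m_int$X))

  dup <- rbind(clin, clin[1, ])
  expect_error(assemble_matrix(dup, sync, c(labs, labs[1])), "duplicate")
  expect_error(assemble_matrix(clin, sync[-1, ], labs), "different subjects")
})

test_that("F-score ranks separating features first and guards degeneracy", {
  set.seed(2)
  y <- rep(c(TRUE, FALSE), 35)
  X <- matrix(rnorm(70 * 3), 70, 3)
  X[y, 2] <- X[y, 2] + 3
  r <- f_score_rank(X, y)
  expect_equal(r$order[1], 2L)
  # identical-across-classes feature scores at the bottom
  X[y, 3] <- c(rep(1, 18), rep(2, 17))
  X[!y, 3] <- c(rep(1, 18), rep(2, 17))
  r2 <- f_score_rank(X, y)
  expect_equal(r2$scores[3], 0, tolerance = 1e-20)
  expect_equal(r2$order[3], 3L)
  # constant feature: defined as 0, no 0/0
  X[, 1] <- 5
  expect_identical(f_score_rank(X, y)$scores[[1]], 0)
  expect_error(f_score_rank(X, rep(TRUE, 70)), "both classes")
})

test_that("a 3-SD planted feature wins the F-score ranking in >= 95/100 cohorts", {
  wins <- sum(sapply(1:100, function(s) {
    set.seed(s)
    y <- rep(c(TRUE, FALSE), 35)
    X <- matrix(rnorm(70 * 43), 70, 43)
    X[y, 7] <- X[y, 7] + 3
    f_score_rank(X, y)$order[1] == 7L
  }))
  expect_gte(wins, 95)
})

test_that("RFE eliminates a pure-noise feature first and keeps the signal", {
  set.seed(4)
  y <- rep(c(TRUE, FALSE), each = 20)
  X <- cbind(sig1 = ifelse(y, 1, -1) + rnorm(40, 0, 0.05),
             sig2 = ifelse(y, 1, -1) + rnorm(40, 0, 0.05),
             noise = rnorm(40))
  sel <- rfe_select(X, y, 2)
  expect_identical(as.integer(sel), c(1L, 2L))
  expect_identical(attr(sel, "elimination_order"), 3L)
  expect_identical(as.integer(rfe_select(X, y, 3)), 1:3)
  expect_error(rfe_select(X, y, 4), "n_keep")

  keep1 <- sum(sapply(1:50, function(s) {
    set.seed(s)
    yy <- rep(c(TRUE, FALSE), 35)
    XX <- matrix(rnorm(70 * 10), 70, 10)
    XX[yy, 3] <- XX[yy, 3] + 3
    rfe_select(XX, yy, 1) == 3L
  }))
  expect_gte(keep1, 45)
})

test_that("nested CV is deterministic, leak-free on permuted labels, and aces separable data", {
  set.seed(6)
  y <- rep(c(TRUE, FALSE), each = 15)
  X <- cbind(matrix(rnorm(30 * 4), 30, 4),
             signal = ifelse(y, 3, -3) + rnorm(30, 0, 0.1))
  colnames(X) <- paste0("f", 1:5)
  grids <- list(C = c(0.1, 1), k = c(2, 5))
  r1 <- nested_cv(X, y, outer_k = 5, inner_k = 3, C_grid = grids$C,
                  n_features_grid = grids$k, seed = 42)
  r2 <- nested_cv(X, y, outer_k = 5, inner_k = 3, C_grid = grids$C,
                  n_features_grid = grids$k, seed = 42)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$coefficient_summary, r2$coefficient_summary)
  expect_equal(r1$accuracy, 1.0)
  expect_equal(sum(r1$confusion), 30)
  expect_true(all(c("accuracy", "precision", "auc") %in% names(r1)))
  expect_gte(r1$auc, 0.99)
  # the planted feature (column f5) dominates the coefficient summary
  expect_identical(r1$coefficient_summary$feature[1], "f5")
  expect_error(nested_cv(X[1:8, ], y[1:8], outer_k = 10), "fewer subjects")
})

test_that("rfe selector works inside nested CV", {
  set.seed(61)
  y <- rep(c(TRUE, FALSE), each = 15)
  X <- cbind(matrix(rnorm(30 * 3), 30, 3),
             signal = ifelse(y, 2, -2) + rnorm(30, 0, 0.2))
  colnames(X) <- paste0("f", 1:4)
  r <- nested_cv(X, y, selector = "rfe", outer_k = 5, inner_k = 3,
                 C_grid = 1, n_features_grid = c(1, 2), seed = 7)
  expect_gte(r$accuracy, 0.9)
})

test_that("final refit predicts externally and validates column contracts", {
  set.seed(10)
  y <- rep(c(TRUE, FALSE), each = 20)
  X <- cbind(s = ifelse(y, 2, -2) + rnorm(40, 0, 0.3),
             n1 = rnorm(40), n2 = rnorm(40))
  fin <- fit_final_and_predict(X, y, X, y, C_grid = c(0.1, 1),
                               n_features_grid = c(1, 3), seed = 1)
  # resubstitution sanity: at least as good as honest CV on the same data
  expect_gte(fin$accuracy, 0.95)
  preds <- predict_responders(fin$bundle, X)
  expect_identical(preds$predicted, ifelse(fin$predictions, "R50", "NR50"))

  Xbad <- X[, c(2, 1, 3)]
  expect_error(fit_final_and_predict(X, y, Xbad, C_grid = 1,
                                     n_features_grid = 1),
               "columns do not match")
  expect_error(predict_responders(fin$bundle, Xbad), "do not match")

  # external null data scores at chance
  set.seed(11)
  acc <- mean(sapply(1:30, function(s) {
    Xe <- cbind(s = rnorm(40), n1 = rnorm(40), n2 = rnorm(40))
    ye <- rep(c(TRUE, FALSE), 20)
    mean((predict_responders(fin$bundle, Xe)$predicted == "R50") == ye)
  }))
  expect_lt(abs(acc - 0.5), 0.1)
})
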