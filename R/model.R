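clinical_feature_names <- function() {
  c("bmi", "diastolic_pressure", "pulse_pressure", "age_implantation",
    "epilepsy_duration", "age_onset", "prior_surgery", "seizure_frequency",
    "etiology_structural", "etiology_genetic", "etiology_autoimmune",
    "etiology_unknown",
    "seizure_generalized", "seizure_focal", "seizure_spasms",
    "seizure_multiple",
    "syndrome_infantile_spasms", "syndrome_lgs", "syndrome_eoee",
    "syndrome_unclassified",
    "mri_local", "mri_multifocal", "mri_negative",
    "n_asm_historical", "n_asm_baseline")
}

#' Encode clinical records into the 25-column model input
#'
#' Eight numeric fields (BMI, diastolic pressure, pulse pressure, age at
#' implantation, epilepsy duration, age at onset, prior surgery as 0/1,
#' seizure frequency), one-hot blocks for etiology (4), epilepsy syndrome
#' (4) and MRI finding (3), the multi-hot seizure-type block (4 —
#' seizure types are not mutually exclusive), and the two ASM counts.
#' Gender and benzodiazepine use are carried in the clinical table but not
#' encoded.
#'
#' @param clinical_table data.frame of clinical records, one row per
#'   subject (see [cohort_clinical_table()]).
#' @return numeric matrix, subjects x 25, columns in the fixed documented
#'   order of `clinical_feature_names`.
#' @export
encode_clinical <- function(clinical_table) {
  required <- c("bmi", "diastolic_pressure", "pulse_pressure",
                "age_implantation", "epilepsy_duration", "age_onset",
                "prior_surgery", "seizure_frequency", "etiology",
                "seizure_generalized", "seizure_focal", "seizure_spasms",
                "seizure_multiple", "syndrome", "mri", "n_asm_historical",
                "n_asm_baseline")
  missing <- setdiff(required, names(clinical_table))
  if (length(missing) > 0) {
    stop("missing clinical field(s): ", paste(missing, collapse = ", "))
  }
  onehot <- function(values, levels, prefix) {
    bad <- setdiff(unique(as.character(values)), levels)
    if (length(bad) > 0) {
      stop("unknown ", prefix, " category: ", paste(bad, collapse = ", "))
    }
    m <- vapply(levels, function(l) as.numeric(values == l),
                numeric(nrow(clinical_table)))
    if (nrow(clinical_table) == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- paste0(prefix, "_", levels)
    m
  }
  num <- as.matrix(clinical_table[, c(
    "bmi", "diastolic_pressure", "pulse_pressure", "age_implantation",
    "epilepsy_duration", "age_onset", "prior_surgery",
    "seizure_frequency")])
  num[, "prior_surgery"] <- as.numeric(clinical_table$prior_surgery)
  types <- as.matrix(clinical_table[, c(
    "seizure_generalized", "seizure_focal", "seizure_spasms",
    "seizure_multiple")]) * 1
  X <- cbind(
    num,
    onehot(clinical_table$etiology,
           c("structural", "genetic", "autoimmune", "unknown"), "etiology"),
    types,
    onehot(clinical_table$syndrome,
           c("infantile_spasms", "lgs", "eoee", "unclassified"), "syndrome"),
    onehot(clinical_table$mri, c("local", "multifocal", "negative"), "mri"),
    as.matrix(clinical_table[, c("n_asm_historical", "n_asm_baseline")])
  )
  colnames(X) <- clinical_feature_names()
  if (anyNA(X)) stop("missing values in clinical encoding")
  rownames(X) <- clinical_table$subject_id
  X
}

#' Assemble the model feature matrix
#'
#' Stacks the 25 encoded clinical columns and the 18 synchronization
#' columns into the 43-column integrated input (or either block alone),
#' with the binary responder label (R50-level, positive class).
#'
#' @param clinical_table clinical records, one row per subject.
#' @param sync_table synchronization features with a `subject_id` column
#'   (see [cohort_sync_features()]).
#' @param labels responder labels, one per subject in `clinical_table`
#'   order.
#' @param mode `"integrated"` (43 columns), `"clinical"` (25) or
#'   `"sync"` (18).
#' @return list with `X` (numeric matrix), `y` (logical responder vector)
#'   and `feature_names`.
#' @export
assemble_matrix <- function(clinical_table, sync_table, labels,
                            mode = c("integrated", "clinical", "sync")) {
  mode <- match.arg(mode)
  ids <- clinical_table$subject_id
  if (anyDuplicated(ids)) stop("duplicate subject id")
  y <- normalize_labels(labels)
  if (length(y) != length(ids)) stop("one label per subject required")
  sync_cols <- NULL
  if (mode != "clinical") {
    if (!setequal(ids, sync_table$subject_id)) {
      stop("clinical and synchronization tables cover different subjects")
    }
    sync <- sync_table[match(ids, sync_table$subject_id), , drop = FALSE]
    sync_cols <- as.matrix(sync[, setdiff(names(sync), "subject_id"),
                                drop = FALSE])
    rownames(sync_cols) <- ids
  }
  X <- switch(mode,
              integrated = cbind(encode_clinical(clinical_table), sync_cols),
              clinical = encode_clinical(clinical_table),
              sync = sync_cols)
  if (anyNA(X)) stop("missing values in feature matrix")
  list(X = X, y = y, feature_names = colnames(X))
}

#' Fisher-criterion F-score feature ranking
#'
#' The two-class F-score of each column:
#' `((mean_pos - mean)^2 + (mean_neg - mean)^2) / (var_pos + var_neg)`,
#' a filter statistic favouring features whose class means separate
#' relative to their within-class spread. Constant features (zero
#' denominator and numerator) score 0.
#'
#' @param X feature matrix.
#' @param y logical (or R50/NR50) labels with both classes present.
#' @return list with `scores` (per column) and `order` (column indices in
#'   decreasing score, stable, ties broken by column index).
#' @export
f_score_rank <- function(X, y) {
  y <- normalize_labels(y)
  if (!any(y) || all(y)) stop("both classes must be present")
  pos <- X[y, , drop = FALSE]
  neg <- X[!y, , drop = FALSE]
  mu <- colMeans(X); mp <- colMeans(pos); mn <- colMeans(neg)
  num <- (mp - mu)^2 + (mn - mu)^2
  den <- apply(pos, 2L, stats::var) + apply(neg, 2L, stats::var)
  scores <- ifelse(den == 0 & num == 0, 0, num / den)
  ord <- order(-scores, seq_along(scores))
  list(scores = scores, order = ord)
}

# fit a linear SVM and return weights/offset oriented so that
# score = X %*% w - rho is positive for the responder class
linear_svm <- function(X, y, C) {
  yf <- factor(ifelse(y, "R50", "NR50"), levels = c("NR50", "R50"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  rho <- fit$rho
  dv <- stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE)
  dv_name <- colnames(attr(dv, "decision.values"))
  # e1071 orients decision values toward the class named first in "A/B"
  if (strsplit(dv_name, "/")[[1]][1] != "R50") {
    w <- -w; rho <- -rho
  }
  # align names with the full feature set
  names(w) <- colnames(X)
  list(w = w, rho = rho)
}

svm_scores <- function(model, X) drop(X %*% model$w) - model$rho

#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly fits the linear maximum-margin classifier and removes the
#' single feature with the smallest absolute weight until `n_keep`
#' features remain. Deterministic given the inputs.
#'
#' @param X feature matrix (already scaled).
#' @param y binary labels, both classes present.
#' @param n_keep number of features to retain.
#' @param C SVM cost parameter.
#' @return Integer indices of the selected columns (in original column
#'   order). Attribute `elimination_order` records the removal sequence.
#' @export
rfe_select <- function(X, y, n_keep, C = 1) {
  y <- normalize_labels(y)
  p <- ncol(X)
  if (n_keep < 1L || n_keep > p) stop("n_keep must be in 1..ncol(X)")
  active <- seq_len(p)
  eliminated <- integer(0)
  while (length(active) > n_keep) {
    fit <- linear_svm(X[, active, drop = FALSE], y, C)
    drop_local <- which.min(abs(fit$w))
    eliminated <- c(eliminated, active[drop_local])
    active <- active[-drop_local]
  }
  structure(sort(active), elimination_order = eliminated)
}

# selector dispatch used by the CV loops: returns column indices
select_features <- function(X, y, n_keep, selector, C) {
  n_keep <- min(n_keep, ncol(X))
  if (selector == "f_score") {
    sort(f_score_rank(X, y)$order[seq_len(n_keep)])
  } else {
    as.integer(rfe_select(X, y, n_keep, C))
  }
}

scale_fit <- function(X) {
  centre <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0] <- 1
  list(centre = centre, sd = sdev)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2L, sc$centre, "-"), 2L, sc$sd, "/")
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

default_c_grid <- function() c(0.01, 0.1, 1, 10, 100)
default_n_features_grid <- function() c(5, 10, 15, 20, 30, 43)

# inner CV: mean accuracy for each (C, n_features) combination; ties are
# broken toward fewer features, then smaller C
inner_cv_choose <- function(X, y, selector, inner_k, C_grid,
                            n_features_grid) {
  n_features_grid <- sort(unique(pmin(n_features_grid, ncol(X))))
  fold <- stratified_folds(y, inner_k)
  grid <- expand.grid(n_features = n_features_grid, C = C_grid)
  acc <- matrix(NA_real_, nrow(grid), inner_k)
  for (f in seq_len(inner_k)) {
    tr <- fold != f
    if (!any(y[tr]) || all(y[tr]) || !any(!tr)) next
    sc <- scale_fit(X[tr, , drop = FALSE])
    Xtr <- scale_apply(X[tr, , drop = FALSE], sc)
    Xte <- scale_apply(X[!tr, , drop = FALSE], sc)
    for (C in C_grid) {
      # for RFE reuse one elimination path per (fold, C); for the F-score
      # the ranking is C-free
      ranking <- if (selector == "f_score") {
        f_score_rank(Xtr, y[tr])$order
      } else {
        path <- rfe_select(Xtr, y[tr], 1L, C)
        c(path, rev(attr(path, "elimination_order")))
      }
      for (gi in which(grid$C == C)) {
        keep <- sort(ranking[seq_len(grid$n_features[gi])])
        fit <- linear_svm(Xtr[, keep, drop = FALSE], y[tr], C)
        pred <- svm_scores(fit, Xte[, keep, drop = FALSE]) > 0
        acc[gi, f] <- mean(pred == y[!tr])
      }
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  best <- order(-mean_acc, grid$n_features, grid$C)[1L]
  list(C = grid$C[best], n_features = grid$n_features[best],
       accuracy = mean_acc[best])
}

#' Nested cross-validated linear SVM
#'
#' Outer stratified k-fold CV estimates generalization; within each outer
#' training set an inner stratified CV picks the cost parameter and the
#' number of features (F-score filter or SVM-RFE wrapper) by mean
#' accuracy, with ties broken toward the simpler model. Scaling, feature
#' selection and tuning are all refit inside each outer training fold, so
#' no information leaks from the held-out subjects. Outer-fold predictions
#' are pooled for the confusion matrix, accuracy, precision and the
#' ROC/AUC of the pooled decision scores.
#'
#' @param X feature matrix (subjects x features, named columns).
#' @param y responder labels (logical or R50/NR50).
#' @param selector `"f_score"` (default) or `"rfe"`.
#' @param outer_k,inner_k fold counts (default 10 and 5).
#' @param C_grid,n_features_grid hyperparameter grids.
#' @param seed integer seed controlling the fold assignments.
#' @param min_select_frac features selected in at least this fraction of
#'   outer folds enter `coefficient_summary` (default 0.5).
#' @return `vns_model_report`: pooled predictions, confusion matrix,
#'   accuracy, precision (positive class = responder), ROC points and AUC,
#'   per-fold chosen hyperparameters and feature sets, and the mean +/- SD
#'   of the standardized linear weights of recurrently selected features.
#' @export
nested_cv <- function(X, y, selector = c("f_score", "rfe"), outer_k = 10,
                      inner_k = 5, C_grid = default_c_grid(),
                      n_features_grid = default_n_features_grid(),
                      seed = 1L, min_select_frac = 0.5) {
  selector <- match.arg(selector)
  y <- normalize_labels(y)
  if (length(y) < outer_k) stop("fewer subjects than outer folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(as.integer(seed))
  fold <- stratified_folds(y, outer_k)
  n <- length(y)
  score <- numeric(n); pred <- logical(n)
  fold_info <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- fold != f
    if (!any(y[tr]) || all(y[tr])) {
      stop("a class is missing from an outer training fold")
    }
    choice <- inner_cv_choose(X[tr, , drop = FALSE], y[tr], selector,
                              inner_k, C_grid, n_features_grid)
    sc <- scale_fit(X[tr, , drop = FALSE])
    Xtr <- scale_apply(X[tr, , drop = FALSE], sc)
    keep <- select_features(Xtr, y[tr], choice$n_features, selector,
                            choice$C)
    fit <- linear_svm(Xtr[, keep, drop = FALSE], y[tr], choice$C)
    Xte <- scale_apply(X[!tr, , drop = FALSE], sc)
    s <- svm_scores(fit, Xte[, keep, drop = FALSE])
    score[!tr] <- s
    pred[!tr] <- s > 0
    fold_info[[f]] <- list(fold = f, C = choice$C,
                           n_features = choice$n_features,
                           selected = colnames(X)[keep],
                           weights = stats::setNames(fit$w,
                                                     colnames(X)[keep]))
  }
  confusion <- table(truth = factor(y, c(FALSE, TRUE),
                                    c("NR50", "R50")),
                     predicted = factor(pred, c(FALSE, TRUE),
                                        c("NR50", "R50")))
  accuracy <- mean(pred == y)
  precision <- if (sum(pred) == 0) NA_real_ else
    sum(pred & y) / sum(pred)
  roc <- pROC::roc(response = y, predictor = score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  coef_summary <- summarize_coefficients(fold_info, min_select_frac,
                                         outer_k)
  structure(
    list(predictions = data.frame(
           subject = if (!is.null(rownames(X))) rownames(X) else
             as.character(seq_len(n)),
           fold = fold, truth = y, predicted = pred, score = score,
           stringsAsFactors = FALSE),
         confusion = confusion, accuracy = accuracy, precision = precision,
         auc = as.numeric(pROC::auc(roc)),
         roc = data.frame(fpr = 1 - roc$specificities,
                          tpr = roc$sensitivities),
         folds = fold_info, coefficient_summary = coef_summary,
         selector = selector, seed = seed,
         config = list(outer_k = outer_k, inner_k = inner_k,
                       C_grid = C_grid,
                       n_features_grid = n_features_grid,
                       min_select_frac = min_select_frac)),
    class = "vns_model_report")
}

summarize_coefficients <- function(fold_info, min_select_frac, outer_k) {
  all_w <- lapply(fold_info, `[[`, "weights")
  feats <- unique(unlist(lapply(all_w, names)))
  rows <- lapply(feats, function(fn) {
    w <- unlist(lapply(all_w, function(x) x[fn]))
    w <- w[!is.na(w)]
    data.frame(feature = fn, n_folds_selected = length(w),
               mean_weight = mean(w),
               sd_weight = if (length(w) > 1L) stats::sd(w) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_folds_selected >= min_select_frac * outer_k, ,
             drop = FALSE]
  out <- out[order(-abs(out$mean_weight)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.vns_model_report <- function(x, ...) {
  cat(sprintf(
    "<vns_model_report> %s selector, %d-fold outer CV\n  accuracy %.3f  precision %.3f  AUC %.3f\n",
    x$selector, x$config$outer_k, x$accuracy, x$precision, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Fit the final model on all discovery data and predict an external cohort
#'
#' One pipeline (scale, select, fit) refit on the full training matrix
#' with hyperparameters chosen by inner CV on that matrix; scaling
#' statistics come from the training data only.
#'
#' @param X_train,y_train discovery matrix and labels.
#' @param X_external external matrix with identical column names and
#'   order.
#' @param y_external optional external labels; when given, accuracy is
#'   reported.
#' @param selector,inner_k,C_grid,n_features_grid,seed as in
#'   [nested_cv()].
#' @return list with the fitted `bundle` (scaling, selected features,
#'   weights, offset, chosen hyperparameters), `predictions` (logical),
#'   `scores`, and `accuracy` (`NA` without external labels).
#' @export
fit_final_and_predict <- function(X_train, y_train, X_external,
                                  y_external = NULL,
                                  selector = c("f_score", "rfe"),
                                  inner_k = 5, C_grid = default_c_grid(),
                                  n_features_grid =
                                    default_n_features_grid(),
                                  seed = 1L) {
  selector <- match.arg(selector)
  y_train <- normalize_labels(y_train)
  if (!identical(colnames(X_train), colnames(X_external))) {
    stop("external matrix columns do not match the training matrix")
  }
  set.seed(as.integer(seed))
  choice <- inner_cv_choose(X_train, y_train, selector, inner_k, C_grid,
                            n_features_grid)
  sc <- scale_fit(X_train)
  Xtr <- scale_apply(X_train, sc)
  keep <- select_features(Xtr, y_train, choice$n_features, selector,
                          choice$C)
  fit <- linear_svm(Xtr[, keep, drop = FALSE], y_train, choice$C)
  bundle <- list(scaling = sc, selected = colnames(X_train)[keep],
                 selected_idx = keep, w = fit$w, rho = fit$rho,
                 C = choice$C, n_features = choice$n_features,
                 selector = selector, positive_class = "R50",
                 feature_names = colnames(X_train))
  s <- svm_scores(fit, scale_apply(X_external, sc)[, keep, drop = FALSE])
  pred <- s > 0
  acc <- if (is.null(y_external)) NA_real_ else
    mean(pred == normalize_labels(y_external))
  list(bundle = bundle, predictions = pred, scores = s, accuracy = acc)
}

#' Predict responder status with a fitted model bundle
#'
#' @param bundle fitted model as returned in
#'   [fit_final_and_predict()]`$bundle`.
#' @param X feature matrix with the bundle's column names.
#' @return data.frame with `score` and `predicted` (`"R50"`/`"NR50"`).
#' @export
predict_responders <- function(bundle, X) {
  if (!identical(colnames(X), bundle$feature_names)) {
    stop("feature columns do not match the fitted model")
  }
  Xs <- scale_apply(X, bundle$scaling)[, bundle$selected_idx, drop = FALSE]
  s <- drop(Xs %*% bundle$w) - bundle$rho
  data.frame(score = s,
             predicted = ifelse(s > 0, "R50", "NR50"),
             stringsAsFactors = FALSE)
}
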