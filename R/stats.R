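#' Responder labeling from a seizure diary
#'
#' Reduction = (baseline - followup) / baseline. Thresholds are inclusive:
#' reduction of exactly 1 is R100, >= 0.8 is R80, >= 0.5 is R50; anything
#' below 0.5 (including a worsening, i.e. negative reduction) is NR50.
#' R100 is a subset of R80 is a subset of R50; the finest category is
#' returned, and `responder` gives the R50-level binary label used by the
#' classifier.
#'
#' @param baseline_freq baseline seizure frequency, seizures/month, > 0.
#' @param followup_freq follow-up seizure frequency, seizures/month, >= 0.
#' @return data.frame with columns `category` (factor NR50/R50/R80/R100),
#'   `reduction_fraction` and `responder` (logical, category != NR50).
#' @export
label_responder <- function(baseline_freq, followup_freq) {
  if (any(baseline_freq <= 0)) stop("baseline_freq must be > 0")
  if (any(followup_freq < 0)) stop("followup_freq must be >= 0")
  reduction <- (baseline_freq - followup_freq) / baseline_freq
  category <- ifelse(reduction >= 1, "R100",
                     ifelse(reduction >= 0.8, "R80",
                            ifelse(reduction >= 0.5, "R50", "NR50")))
  data.frame(
    category = factor(category, levels = c("NR50", "R50", "R80", "R100")),
    reduction_fraction = reduction,
    responder = category != "NR50"
  )
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test against a normal with the sample mean and SD. Note
#' the Lilliefors caveat: estimating the parameters from the same sample
#' makes the nominal KS p-value conservative; here the test is used only
#' as a distribution screen before choosing nonparametric group tests.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @return The p-value.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) stop("constant input: distribution test undefined")
  suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s)$p.value
  )
}

#' Mann-Whitney U test
#'
#' U statistic with a two-sided p-value. When `n_x + n_y <= 12` (and
#' `exact` is not `FALSE`) the null distribution of U is obtained by full
#' enumeration of all group assignments of the pooled sample (ties handled
#' exactly through midranks); otherwise a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples, both non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   default `NULL` chooses by total sample size (<= 12).
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  use_exact <- if (is.null(exact)) n <= 12L else isTRUE(exact)
  if (use_exact) {
    combos <- utils::combn(n, nx)
    rs <- colSums(matrix(r[combos], nrow = nx))
    Us <- rs - nx * (nx + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  tie_counts <- table(r)
  tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-z)), method = "normal")
}

#' Chi-square or Fisher's exact test for a contingency table
#'
#' Chi-square without continuity correction by default; when any expected
#' cell count is below 5, a 2x2 table is handed to Fisher's exact test and
#' larger tables fall back to chi-square with a warning.
#'
#' @param tab matrix of non-negative counts (2 x k).
#' @return list with `test` (`"chi_square"` or `"fisher"`), `statistic`
#'   (`NA` for Fisher) and `p`.
#' @export
chi_square_or_fisher <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    if (all(dim(tab) == c(2L, 2L))) {
      return(list(test = "fisher", statistic = NA_real_,
                  p = stats::fisher.test(tab)$p.value))
    }
    warning(warningCondition(
      "expected counts < 5 in a table larger than 2x2; using chi-square anyway",
      class = "vnseeg_sparse_table"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chi_square", statistic = unname(ct$statistic),
       p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, order-preserving with respect to the input.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# accept logical responder vectors, R50/NR50 strings, or factors
normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("R50", "NR50", "R80", "R100"))) {
    stop("labels must be logical or responder categories")
  }
  lab != "NR50"
}

#' Band-wise group comparison of synchronization features
#'
#' For each metric and band, compares responders and non-responders with a
#' two-sided Mann-Whitney U test (or unpaired Welch t-test with
#' `method = "t_test"`), and applies Benjamini-Hochberg FDR correction
#' across the bands within each metric (each metric's bands form one
#' testing family). The combined beta band is extracted as a feature but
#' excluded from the default testing family.
#'
#' @param feature_table data.frame with columns `<metric>_<band>` (as from
#'   [cohort_sync_features()]).
#' @param labels responder labels (logical, or R50/NR50 strings), one per
#'   row.
#' @param metrics metrics to test.
#' @param bands bands forming the FDR family per metric.
#' @param alpha significance level applied to the adjusted p-values.
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @return data.frame with one row per metric x band: group means and SDs,
#'   test name, statistic, `p_raw`, `p_adjusted` and `significant`.
#' @export
compare_sync_by_group <- function(feature_table, labels,
                                  metrics = c("plv", "pli", "wpli"),
                                  bands = c("delta", "theta", "alpha",
                                            "low_beta", "high_beta"),
                                  alpha = 0.05,
                                  method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  resp <- normalize_labels(labels)
  if (sum(resp) < 2L || sum(!resp) < 2L) {
    stop("need at least 2 subjects per group")
  }
  rows <- list()
  for (m in metrics) {
    res_m <- lapply(bands, function(bn) {
      col <- paste0(m, "_", bn)
      if (!col %in% names(feature_table)) {
        stop("feature column missing: ", col)
      }
      v <- feature_table[[col]]
      if (method == "mann_whitney") {
        tst <- mann_whitney_u(v[resp], v[!resp])
        stat <- tst$U; p <- tst$p; tname <- "mann_whitney"
      } else {
        tt <- stats::t.test(v[resp], v[!resp])
        stat <- unname(tt$statistic); p <- tt$p.value; tname <- "t_test"
      }
      data.frame(metric = m, band = bn,
                 mean_R50 = mean(v[resp]), sd_R50 = stats::sd(v[resp]),
                 mean_NR50 = mean(v[!resp]), sd_NR50 = stats::sd(v[!resp]),
                 test = tname, statistic = stat, p_raw = p,
                 stringsAsFactors = FALSE)
    })
    res_m <- do.call(rbind, res_m)
    res_m$p_adjusted <- fdr_bh(res_m$p_raw)
    rows[[m]] <- res_m
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Group comparison of baseline clinical variables
#'
#' Continuous variables are compared with the Mann-Whitney U test,
#' categorical variables with chi-square or Fisher's exact test (expected
#' count rule). Following the convention of baseline-characteristics
#' tables, no multiplicity correction is applied. Variables with a single
#' observed category are skipped with a warning.
#'
#' @param clinical_table data.frame as from [cohort_clinical_table()].
#' @param labels responder labels, one per row.
#' @param alpha significance level.
#' @return data.frame: variable, type, test, statistic, group summaries
#'   (mean and SD for continuous variables), `p` and `significant`.
#' @export
compare_clinical_by_group <- function(clinical_table, labels, alpha = 0.05) {
  resp <- normalize_labels(labels)
  continuous <- c("seizure_frequency", "bmi", "diastolic_pressure",
                  "pulse_pressure", "age_onset", "epilepsy_duration",
                  "age_implantation", "n_asm_baseline", "n_asm_historical")
  categorical <- c("gender", "prior_surgery", "benzodiazepine",
                   "etiology", "syndrome", "mri")
  multihot <- list(seizure_type = c("seizure_generalized", "seizure_focal",
                                    "seizure_spasms", "seizure_multiple"))
  rows <- list()
  for (v in intersect(continuous, names(clinical_table))) {
    vals <- clinical_table[[v]]
    tst <- mann_whitney_u(vals[resp], vals[!resp])
    rows[[v]] <- data.frame(
      variable = v, type = "continuous", test = "mann_whitney",
      statistic = tst$U,
      mean_R50 = mean(vals[resp]), sd_R50 = stats::sd(vals[resp]),
      mean_NR50 = mean(vals[!resp]), sd_NR50 = stats::sd(vals[!resp]),
      p = tst$p, stringsAsFactors = FALSE)
  }
  for (v in intersect(categorical, names(clinical_table))) {
    f <- as.factor(clinical_table[[v]])
    if (nlevels(droplevels(f)) < 2L) {
      warning("variable '", v, "' has a single observed category; skipped")
      next
    }
    tab <- table(resp, droplevels(f))
    tst <- chi_square_or_fisher(tab)
    rows[[v]] <- data.frame(
      variable = v, type = "categorical", test = tst$test,
      statistic = tst$statistic,
      mean_R50 = NA_real_, sd_R50 = NA_real_,
      mean_NR50 = NA_real_, sd_NR50 = NA_real_,
      p = tst$p, stringsAsFactors = FALSE)
  }
  for (v in names(multihot)) {
    cols <- intersect(multihot[[v]], names(clinical_table))
    if (length(cols) < 2L) next
    # counts of each (non-exclusive) type per group
    tab <- rbind(colSums(clinical_table[resp, cols, drop = FALSE]),
                 colSums(clinical_table[!resp, cols, drop = FALSE]))
    tst <- chi_square_or_fisher(tab)
    rows[[v]] <- data.frame(
      variable = v, type = "categorical", test = tst$test,
      statistic = tst$statistic,
      mean_R50 = NA_real_, sd_R50 = NA_real_,
      mean_NR50 = NA_real_, sd_NR50 = NA_real_,
      p = tst$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
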