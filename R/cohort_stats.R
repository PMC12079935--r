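# Recurrence-prediction statistics: Spearman correlations, ROC with
# Youden cut-off, logistic regression, Cox proportional hazards,
# Kaplan-Meier with log-rank test, and table-shaped reports.

#' Spearman rank-correlation matrix with p-values
#'
#' Midrank ties; p-values from the t approximation
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. A constant
#' column yields `NA` entries with a warning.
#'
#' @param table data frame of per-patient metrics.
#' @param columns character vector of numeric columns to correlate.
#' @return List with matrices `r` and `p` (symmetric, unit/NA diagonal).
#' @export
spearman_matrix <- function(table, columns) {
  x <- as.matrix(table[, columns, drop = FALSE])
  n <- nrow(x)
  if (n < 3) stop_invalid("need >= 3 complete rows")
  if (anyNA(x)) stop_invalid("missing values in selected columns")
  k <- length(columns)
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const))
    warning("constant column(s): ", paste(columns[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  p <- r
  rk <- apply(x, 2, rank)   # midranks
  for (i in seq_len(k)) for (j in i:k) {
    if (const[i] || const[j]) next
    rij <- stats::cor(rk[, i], rk[, j])
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- NA_real_; next }
    tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' ROC curve analysis with Youden-index cut-off
#'
#' AUC is the probability that a random event case scores on the event
#' side of a random non-case, with ties counting one half (pairwise
#' concordance, computed via midranks). The orientation is chosen
#' automatically so AUC >= 0.5 and recorded: `"higher_predicts_event"`
#' classifies score >= cutoff as event, `"lower_predicts_event"`
#' classifies score <= cutoff as event. The cut-off maximizes Youden's
#' J = sensitivity + specificity - 1 over all observed score values,
#' ties resolved to the smallest cut-off. The 95% CI is a stratified
#' percentile bootstrap.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (0/1 or logical), both classes present.
#' @param n_boot bootstrap replicates for the AUC CI (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return A `roc_result`: `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity`, `specificity`, `orientation`, `youden_j`, `n_pos`,
#'   `n_neg`.
#' @export
roc_youden <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- as.integer(labels != 0)
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop_invalid("missing values")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("single-class labels: both classes must be present")

  auc_raw <- auc_concordance(scores, labels)
  orientation <- if (auc_raw >= 0.5) "higher_predicts_event" else "lower_predicts_event"
  auc <- max(auc_raw, 1 - auc_raw)

  cut <- youden_cutoff(scores, labels, orientation)

  ci <- c(NA_real_, NA_real_)
  if (n_boot >= 1) {
    ipos <- which(labels == 1); ineg <- which(labels == 0)
    boots <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        sp <- sample(ipos, n_pos, replace = TRUE)
        sn <- sample(ineg, n_neg, replace = TRUE)
        a <- auc_concordance(scores[c(sp, sn)], labels[c(sp, sn)])
        if (orientation == "higher_predicts_event") a else 1 - a
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  }

  structure(list(auc = auc,
                 ci_low = min(ci[1], auc, na.rm = TRUE),
                 ci_high = max(ci[2], auc, na.rm = TRUE),
                 cutoff = cut$cutoff,
                 sensitivity = cut$sensitivity,
                 specificity = cut$specificity,
                 youden_j = cut$j,
                 orientation = orientation,
                 n_pos = n_pos, n_neg = n_neg,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "roc_result")
}

# AUC as normalized pairwise concordance via the midrank (Mann-Whitney)
# identity; ties count 1/2.
auc_concordance <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive Youden maximization over all observed score values, smallest
# cutoff on ties; the classification rule depends on the orientation.
youden_cutoff <- function(scores, labels, orientation) {
  cands <- sort(unique(scores))
  best <- list(j = -Inf, cutoff = NA_real_,
               sensitivity = NA_real_, specificity = NA_real_)
  for (c0 in cands) {
    pred <- if (orientation == "higher_predicts_event") scores >= c0 else scores <= c0
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best$j + 1e-15) best <- list(j = j, cutoff = c0,
                                         sensitivity = sens, specificity = spec)
  }
  best
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g (%s)\n",
              x$auc, x$ci_low, x$ci_high, x$cutoff, x$orientation))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  (J = %.3f)\n",
              x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Univariate / multivariate logistic regression
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) with Wald 95%
#' confidence intervals and p-values. Univariate mode fits each predictor
#' alone; multivariate fits all jointly. Suspected complete separation
#' (|log-odds| > 15 or SE > 10) is flagged in `converged`/`flags`, not
#' silently reported.
#'
#' @param table data frame.
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of predictor columns.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return A `fit_result` data frame: one row per predictor with
#'   `term`, `estimate`, `se`, `ratio` (odds ratio), `ci_low`, `ci_high`,
#'   `p_value`; attributes `model_kind`, `mode`, `converged`, `flags`.
#' @export
logistic_fit <- function(table, outcome, predictors,
                         mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  y <- table[[outcome]]
  if (is.null(y)) stop_invalid("outcome column not found")
  y <- as.integer(y != 0)
  if (length(unique(y)) < 2) stop_invalid("outcome must have both classes")
  for (p in predictors) {
    v <- table[[p]]
    if (is.null(v)) stop_invalid("predictor column not found: ", p)
    if (is.numeric(v) && length(unique(v)) == 1L)
      stop_invalid("constant predictor: ", p)
  }
  fit_one <- function(preds) {
    fml <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + ")))
    dat <- cbind(.y = y, table[, preds, drop = FALSE])
    warns <- character(0)
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    summarize_fit(fit, preds, kind = "logistic", warns = warns)
  }
  if (mode == "univariate") {
    rows <- do.call(rbind, lapply(predictors, function(p) fit_one(p)))
  } else {
    rows <- fit_one(predictors)
  }
  finalize_fit_result(rows, "logistic", mode)
}

#' Univariate / multivariate Cox proportional hazards regression
#'
#' Partial-likelihood maximization with Efron tie handling (via
#' [survival::coxph()]); Wald 95% CIs and p-values; hazard ratio
#' HR = exp(coefficient). Monotone likelihood (infinite coefficient)
#' is flagged.
#'
#' @param table data frame.
#' @param time name of the positive survival-time column.
#' @param event name of the 0/1 event indicator column.
#' @param predictors character vector of predictor columns.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return A `fit_result` data frame (see [logistic_fit()]); `ratio` is the
#'   hazard ratio.
#' @export
cox_fit <- function(table, time, event, predictors,
                    mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  tt <- table[[time]]; ev <- as.integer(table[[event]] != 0)
  if (is.null(tt) || is.null(table[[event]])) stop_invalid("time/event column not found")
  if (any(tt <= 0)) stop_invalid("survival times must be > 0")
  if (sum(ev) == 0) stop_invalid("no events: Cox model undefined")
  fit_one <- function(preds) {
    fml <- stats::as.formula(
      paste("survival::Surv(.t, .e) ~", paste(preds, collapse = " + ")))
    dat <- cbind(.t = tt, .e = ev, table[, preds, drop = FALSE])
    warns <- character(0)
    fit <- withCallingHandlers(
      survival::coxph(fml, data = dat, ties = "efron"),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    summarize_fit(fit, preds, kind = "cox", warns = warns)
  }
  if (mode == "univariate") {
    rows <- do.call(rbind, lapply(predictors, function(p) fit_one(p)))
  } else {
    rows <- fit_one(predictors)
  }
  finalize_fit_result(rows, "cox", mode)
}

# Wald summaries for one fitted model, rows restricted to the predictors
# (intercept dropped for logistic).
summarize_fit <- function(fit, preds, kind, warns) {
  co <- stats::coef(fit)
  vc <- stats::vcov(fit)
  keep <- setdiff(names(co), "(Intercept)")
  est <- co[keep]
  se <- sqrt(diag(vc)[keep])
  zcrit <- stats::qnorm(0.975)
  sep <- any(abs(est) > 15 | se > 10) ||
    any(grepl("fitted probabilities numerically 0 or 1|infinite|did not converge",
              warns, ignore.case = TRUE))
  data.frame(term = keep,
             estimate = unname(est),
             se = unname(se),
             ratio = unname(exp(est)),
             ci_low = unname(exp(est - zcrit * se)),
             ci_high = unname(exp(est + zcrit * se)),
             p_value = unname(2 * stats::pnorm(-abs(est / se))),
             flagged = sep,
             stringsAsFactors = FALSE)
}

finalize_fit_result <- function(rows, kind, mode) {
  structure(rows,
            model_kind = kind, mode = mode,
            converged = !any(rows$flagged),
            class = c("fit_result", "data.frame"))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s regression (%s)%s\n",
              attr(x, "model_kind"), attr(x, "mode"),
              if (!attr(x, "converged")) " [FLAGGED: possible separation/monotone likelihood]" else ""))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' from observed-minus-expected event counts over the pooled risk sets,
#' with p from chi-square on (groups - 1) df.
#'
#' @param table data frame.
#' @param time,event,group column names (time > 0, event 0/1, group a
#'   factor-like label with >= 2 nonempty levels).
#' @return A `km_result`: `curves` (data frame of group/time/n_risk/
#'   n_event/survival step coordinates), `logrank_chi2`, `logrank_p`,
#'   `groups`.
#' @export
km_logrank <- function(table, time = "dfs_months", event = "event",
                       group = "group") {
  tt <- table[[time]]; ev <- as.integer(table[[event]] != 0)
  g <- factor(table[[group]])
  if (is.null(tt) || is.null(table[[event]]) || is.null(table[[group]]))
    stop_invalid("time/event/group column not found")
  if (nlevels(g) < 2) stop_invalid("need >= 2 nonempty groups")
  if (any(tabulate(g, nlevels(g)) == 0)) stop_invalid("a group has no subjects")
  sf <- survival::survfit(survival::Surv(tt, ev) ~ g)
  strata_labels <- rep(sub("^g=", "", names(sf$strata)), sf$strata)
  curves <- data.frame(group = strata_labels,
                       time = sf$time,
                       n_risk = sf$n.risk,
                       n_event = sf$n.event,
                       survival = sf$surv,
                       stringsAsFactors = FALSE)
  if (all(ev == 0) || identical_groups_all_equal(tt, ev, g)) {
    chi2 <- 0; p <- 1
  } else {
    sd0 <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    chi2 <- unname(sd0$chisq)
    p <- stats::pchisq(chi2, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chi2 = chi2, logrank_p = p,
                 groups = levels(g)),
            class = "km_result")
}

# survdiff divides 0/0 when every group's data are identical at a single
# time pattern with no variance; detect the trivial duplicated-group case.
identical_groups_all_equal <- function(tt, ev, g) {
  sp <- split(data.frame(t = tt, e = ev), g)
  keys <- vapply(sp, function(d) paste(sort(paste(d$t, d$e)), collapse = "|"),
                 character(1))
  length(unique(keys)) == 1L
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d groups; log-rank chi2 = %.4g, p = %.4g\n",
              length(x$groups), x$logrank_chi2, x$logrank_p))
  invisible(x)
}

#' Dichotomize a metric column at a cut-off
#'
#' Adds a binary group label: `"high"` for values strictly above the
#' cut-off, `"low"` otherwise (values equal to the cut-off are assigned to
#' the lower group).
#'
#' @param table data frame.
#' @param column metric column name.
#' @param cutoff finite cut-off value.
#' @param group_name name of the new label column (default `"group"`).
#' @return The table with the added factor column (levels low, high).
#' @export
dichotomize <- function(table, column, cutoff, group_name = "group") {
  v <- table[[column]]
  if (is.null(v)) stop_invalid("column not found: ", column)
  if (!is.finite(cutoff)) stop_invalid("'cutoff' must be finite")
  lab <- ifelse(v > cutoff, "high", "low")
  if (length(unique(lab)) < 2)
    warning("all rows fall on one side of the cutoff", call. = FALSE)
  table[[group_name]] <- factor(lab, levels = c("low", "high"))
  table
}

#' Assemble report tables from analysis results
#'
#' Renders results in the deterministic column orders of a clinical
#' biomarker report: ROC rows as (parameter, auc, ci_low, ci_high,
#' sensitivity, specificity, cutoff); regression rows as (parameter,
#' uni/multi p-value and ratio with CI). Empty optional entries render as
#' `NA` (blank on write), never as zero.
#'
#' @param roc named list of `roc_result` objects (optional).
#' @param fits_uni,fits_multi `fit_result` objects (optional), e.g. from
#'   [logistic_fit()] or [cox_fit()].
#' @param km a `km_result` (optional).
#' @return List of data frames: `roc`, `regression`, `km`, any of which
#'   may be `NULL`.
#' @export
build_report <- function(roc = NULL, fits_uni = NULL, fits_multi = NULL,
                         km = NULL) {
  if (is.null(roc) && is.null(fits_uni) && is.null(fits_multi) && is.null(km))
    stop_invalid("at least one result object is required")
  out <- list(roc = NULL, regression = NULL, km = NULL)
  if (!is.null(roc)) {
    out$roc <- do.call(rbind, lapply(names(roc), function(nm) {
      r <- roc[[nm]]
      data.frame(parameter = nm, auc = r$auc,
                 ci_low = r$ci_low, ci_high = r$ci_high,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 cutoff = r$cutoff, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(fits_uni) || !is.null(fits_multi)) {
    terms <- unique(c(if (!is.null(fits_uni)) fits_uni$term,
                      if (!is.null(fits_multi)) fits_multi$term))
    pick <- function(f, term, col) {
      if (is.null(f) || !term %in% f$term) NA_real_ else f[f$term == term, col]
    }
    out$regression <- do.call(rbind, lapply(terms, function(tm) {
      data.frame(parameter = tm,
                 p_uni = pick(fits_uni, tm, "p_value"),
                 ratio_uni = pick(fits_uni, tm, "ratio"),
                 ci_low_uni = pick(fits_uni, tm, "ci_low"),
                 ci_high_uni = pick(fits_uni, tm, "ci_high"),
                 p_multi = pick(fits_multi, tm, "p_value"),
                 ratio_multi = pick(fits_multi, tm, "ratio"),
                 ci_low_multi = pick(fits_multi, tm, "ci_low"),
                 ci_high_multi = pick(fits_multi, tm, "ci_high"),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(km)) {
    out$km <- km$curves
    attr(out$km, "logrank_chi2") <- km$logrank_chi2
    attr(out$km, "logrank_p") <- km$logrank_p
  }
  out
}
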