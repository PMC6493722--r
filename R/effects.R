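#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin validated wrapper
#' around `stats::p.adjust(method = "BH")`, which enforces the step-up
#' monotonicity and preserves input order).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

# Nakagawa variance-partition R2 for an lme4 fit: fixed-effect variance
# over total (marginal), plus random-intercept variance (conditional).
# For binomial-logit fits the residual variance is the logistic
# distribution-specific pi^2/3.
r2_variance_partition <- function(model) {
  vf <- stats::var(as.vector(
    lme4::getME(model, "X") %*% lme4::fixef(model)))
  vr <- sum(vapply(lme4::VarCorr(model),
                   function(v) sum(diag(v)), numeric(1L)))
  ve <- if (inherits(model, "glmerMod")) {
    fam <- stats::family(model)
    if (fam$family == "binomial" && fam$link == "logit") pi^2 / 3
    else stop("R2 partition implemented for binomial-logit GLMMs only")
  } else attr(lme4::VarCorr(model), "sc")^2
  tot <- vf + vr + ve
  list(r2m = vf / tot, r2c = (vf + vr) / tot)
}

#' Fit one mixed model of social role, severity and their interaction
#'
#' Gaussian responses are (optionally) symmetrised by the
#' [transform_scale()] policy and standardised, then fitted by REML with
#' `response ~ role * severity` as fixed effects and random intercepts
#' for caller and event. The binary support response is fitted as a
#' binomial-logit GLMM (Laplace approximation) with caller and
#' production-context random intercepts. Wald 95% CIs; p-values by
#' Satterthwaite approximation (Gaussian) or Wald z (binomial).
#' Singular fits and convergence messages are flagged in the result,
#' never hidden.
#'
#' @param data `data.frame` with the response, `role`, `severity` and
#'   the random-effect columns.
#' @param response Response column name.
#' @param family `"gaussian"` or `"binomial"` (response coerced from
#'   `"yes"`/`"no"` if needed).
#' @param random Random-intercept column names (default caller and
#'   event).
#' @param transform Apply the symmetrise-and-scale policy to a Gaussian
#'   response?
#' @return An `effect_fit`: coefficient table (`estimate`, `se`, `stat`,
#'   `ci_lo`, `ci_hi`, `p` for the three effects), `r2m`/`r2c`,
#'   `n_individuals`, `n_units`, `singular`, `messages`, `transform`,
#'   and the underlying `model`.
#' @export
fit_effect_model <- function(data, response,
                             family = c("gaussian", "binomial"),
                             random = c("caller_id", "event_id"),
                             transform = TRUE) {
  family <- match.arg(family)
  need <- c(response, "role", "severity", random)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lack column(s): ",
                         paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
            drop = FALSE]
  if (length(unique(d$caller_id)) < 2L)
    stop("need at least 2 callers")
  d$role <- factor(d$role, levels = c("aggressor", "victim"))
  d$severity <- factor(d$severity, levels = c("mild", "severe"))
  trans <- "identity"
  if (family == "gaussian") {
    if (stats::sd(d[[response]], na.rm = TRUE) == 0)
      stop("degenerate response: `", response, "` has zero variance")
    if (transform) {
      tx <- transform_scale(d[, response, drop = FALSE])
      trans <- attr(tx, "transforms")[[1L]]
      d[[response]] <- tx[[1L]]
    }
  } else {
    if (is.character(d[[response]]) || is.factor(d[[response]]))
      d[[response]] <- as.integer(as.character(d[[response]]) == "yes")
  }
  fml <- stats::as.formula(paste0(
    "`", response, "` ~ role * severity + ",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  if (family == "gaussian") {
    model <- lmerTest::lmer(fml, data = d, REML = TRUE)
    ct <- stats::coef(summary(model))
    pcol <- "Pr(>|t|)"
    scol <- "t value"
  } else {
    model <- lme4::glmer(fml, data = d, family = stats::binomial("logit"))
    ct <- stats::coef(summary(model))
    pcol <- "Pr(>|z|)"
    scol <- "z value"
  }
  eff <- c(role = "rolevictim", severity = "severitysevere",
           `role:severity` = "rolevictim:severitysevere")
  rows <- lapply(names(eff), function(nm) {
    r <- ct[eff[[nm]], ]
    data.frame(effect = nm, estimate = r[["Estimate"]],
               se = r[["Std. Error"]], stat = r[[scol]],
               ci_lo = r[["Estimate"]] - 1.96 * r[["Std. Error"]],
               ci_hi = r[["Estimate"]] + 1.96 * r[["Std. Error"]],
               p = r[[pcol]])
  })
  r2 <- r2_variance_partition(model)
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  structure(list(
    response = response, family = family,
    coefs = do.call(rbind, rows),
    r2m = r2$r2m, r2c = r2$r2c,
    n_individuals = length(unique(d$caller_id)),
    n_units = nrow(d),
    singular = lme4::isSingular(model),
    messages = if (is.null(msgs)) character(0) else msgs,
    transform = trans, model = model), class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("Mixed model (%s) for `%s` [transform: %s]\n", x$family,
              x$response, x$transform))
  cat(sprintf("  N = %d %s from %d individuals; R2m = %.2f, R2c = %.2f%s\n",
              x$n_units, if (x$family == "binomial") "bouts" else "units",
              x$n_individuals, x$r2m, x$r2c,
              if (x$singular) " (singular fit)" else ""))
  print(x$coefs, row.names = FALSE, digits = 3)
  if (length(x$messages))
    cat("  fitter messages:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

.call_responses <- c("duration", "peak_frequency", "coef_freq_modulation",
                     "transition_onset", "transition_offset", "q50",
                     "iqr", "entropy")
.bout_responses <- c("n_screams", "avg_scream_duration", "scream_rate",
                     "pct_nlp")

#' Fit the full 12-model effect ledger with joint FDR control
#'
#' Fits one mixed model per retained acoustic parameter — eight at the
#' call level (the coefficient of frequency variation is excluded as
#' collinear with Q50) and four at the bout level (bout duration and
#' scream intervals are excluded as collinear with scream count and
#' rate) — each with social role, conflict severity and their
#' interaction as fixed effects and caller/event random intercepts. The
#' resulting 36 p-values (12 models x 3 effects) are jointly
#' Benjamini-Hochberg adjusted. Model failures are recorded in the
#' ledger and do not stop the remaining fits.
#'
#' @param call_tab Call-level feature table ([extract_features()]).
#' @param bout_tab Bout-level feature table.
#' @param transform Apply the symmetrise-and-scale policy per response?
#' @return An `effect_ledger` `data.frame`: one row per (response,
#'   effect) with estimates, Wald CIs, raw and adjusted p-values,
#'   R2m/R2c and sample sizes; failed models carry `status`.
#' @export
run_all_models <- function(call_tab, bout_tab, transform = TRUE) {
  fits <- list()
  specs <- rbind(
    data.frame(response = .call_responses, level = "call"),
    data.frame(response = .bout_responses, level = "bout"))
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    resp <- specs$response[i]
    tab <- if (specs$level[i] == "call") call_tab else bout_tab
    fit <- tryCatch(
      fit_effect_model(tab, resp, family = "gaussian",
                       transform = transform),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        response = resp, level = specs$level[i],
        effect = c("role", "severity", "role:severity"),
        estimate = NA_real_, se = NA_real_, stat = NA_real_,
        ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
        r2m = NA_real_, r2c = NA_real_, n_individuals = NA_integer_,
        n_units = NA_integer_, status = conditionMessage(fit))
      next
    }
    fits[[resp]] <- fit
    rows[[i]] <- cbind(
      data.frame(response = resp, level = specs$level[i]),
      fit$coefs,
      data.frame(r2m = fit$r2m, r2c = fit$r2c,
                 n_individuals = fit$n_individuals,
                 n_units = fit$n_units,
                 status = if (fit$singular) "singular" else "ok"))
  }
  ledger <- do.call(rbind, rows)
  ledger$p_adj <- NA_real_
  ok <- !is.na(ledger$p)
  ledger$p_adj[ok] <- bh_adjust(ledger$p[ok])
  rownames(ledger) <- NULL
  structure(ledger, fits = fits, class = c("effect_ledger", "data.frame"))
}

#' @export
print.effect_ledger <- function(x, ...) {
  cat(sprintf("Effect ledger: %d models, %d p-values (BH-adjusted jointly)\n",
              length(unique(x$response)), sum(!is.na(x$p))))
  df <- as.data.frame(x)
  df$sig <- ifelse(is.na(df$p_adj), "", ifelse(df$p_adj < 0.001, "***",
                   ifelse(df$p_adj < 0.01, "**",
                          ifelse(df$p_adj < 0.05, "*", ""))))
  print(df[, c("response", "level", "effect", "estimate", "se", "p",
               "p_adj", "sig", "r2m", "r2c", "status")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit the third-party support model
#'
#' Binomial-logit GLMM of per-bout support occurrence on signaller role,
#' conflict severity and their interaction, with caller identity and the
#' four-level production context as random intercepts.
#'
#' @param bout_tab One row per bout with `support` (`"yes"`/`"no"`),
#'   `role`, `severity`, `caller_id`, `support_context`.
#' @return An `effect_fit` (binomial).
#' @export
fit_support_model <- function(bout_tab) {
  fit_effect_model(bout_tab, "support", family = "binomial",
                   random = c("caller_id", "support_context"))
}

#' Residual-outlier and influential-caller diagnostics
#'
#' Flags observations with absolute scaled residual above `sd_limit`
#' and, optionally, callers whose removal shifts any fixed-effect
#' estimate by more than one original standard error
#' (leave-one-individual-out refits). Rows are removed only under the
#' requested `policy`; every removal is logged with before/after
#' estimates.
#'
#' @param fit An `effect_fit` (Gaussian).
#' @param data The data the model was fitted to.
#' @param policy `"none"` (diagnose only), `"outliers"`, or
#'   `"outliers+influence"`.
#' @param sd_limit Scaled-residual threshold (default 3).
#' @return List with `data` (cleaned), `outliers` (row indices),
#'   `influential` (caller ids), and `log` (a `data.frame` of actions
#'   with before/after role-effect estimates).
#' @export
diagnose_and_prune <- function(fit, data,
                               policy = c("none", "outliers",
                                          "outliers+influence"),
                               sd_limit = 3) {
  policy <- match.arg(policy)
  stopifnot(inherits(fit, "effect_fit"), fit$family == "gaussian")
  res <- stats::residuals(fit$model, scaled = TRUE)
  used <- as.integer(rownames(stats::model.frame(fit$model)))
  out_rows <- used[abs(res) > sd_limit]

  infl <- character(0)
  if (policy == "outliers+influence") {
    base <- fit$coefs$estimate
    se <- fit$coefs$se
    for (cl in unique(data$caller_id)) {
      sub <- data[data$caller_id != cl, , drop = FALSE]
      ref <- tryCatch(
        fit_effect_model(sub, fit$response, transform = fit$transform !=
                           "identity"),
        error = function(e) NULL)
      if (!is.null(ref) && any(abs(ref$coefs$estimate - base) > se))
        infl <- c(infl, cl)
    }
  }
  drop_rows <- integer(0)
  if (policy %in% c("outliers", "outliers+influence"))
    drop_rows <- out_rows
  drop_callers <- if (policy == "outliers+influence") infl else character(0)
  keep <- !(seq_len(nrow(data)) %in% drop_rows) &
    !(data$caller_id %in% drop_callers)
  cleaned <- data[keep, , drop = FALSE]

  after <- NA_real_
  if ((length(drop_rows) || length(drop_callers)) && sum(keep) > 8L) {
    refit <- tryCatch(fit_effect_model(cleaned, fit$response),
                      error = function(e) NULL)
    if (!is.null(refit)) after <- refit$coefs$estimate[1L]
  }
  log <- data.frame(
    response = fit$response, policy = policy,
    n_outliers = length(out_rows),
    outlier_rows = paste(out_rows, collapse = ";"),
    n_influential = length(infl),
    influential_callers = paste(infl, collapse = ";"),
    role_estimate_before = fit$coefs$estimate[1L],
    role_estimate_after = after)
  list(data = cleaned, outliers = out_rows, influential = infl, log = log)
}

#' Cohen's kappa inter-observer agreement
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` between two coders
#' of the same categorical items. When both coders use a single
#' identical category, chance agreement is 1 and kappa is undefined
#' (returned as `NA` with a note).
#'
#' @param a,b Equal-length categorical label vectors.
#' @return A `kappa_result`: `kappa`, `n_items`, `po` (observed
#'   agreement), `pe` (expected agreement).
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  fa <- factor(as.character(a), levels = lev)
  fb <- factor(as.character(b), levels = lev)
  tab <- table(fa, fb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, n_items = n, po = po, pe = pe,
                 note = if (is.na(kappa))
                   "single category used by both coders; kappa undefined"
                 else NULL),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (is.na(x$kappa)) {
    cat("Cohen's kappa: undefined (", x$note, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Cohen's kappa = %.3f (observed agreement %.3f, expected %.3f, N = %d)\n",
      x$kappa, x$po, x$pe, x$n_items))
  }
  invisible(x)
}

#' Assemble a study report
#'
#' One deterministic, human-readable summary of a full analysis run,
#' mirroring the layout of a classification table (observed vs expected
#' discriminant success), the 36-row effect ledger, and the support
#' model. Missing components are marked absent rather than omitted
#' silently.
#'
#' @param dfa_results Named list of `pdfa` objects (may be empty).
#' @param ledger An `effect_ledger` or `NULL`.
#' @param support An `effect_fit` for support or `NULL`.
#' @param config The [study_config()] used, for seed/condition echo.
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly if `path` given.
#' @export
scream_report <- function(dfa_results = list(), ledger = NULL,
                          support = NULL, config = NULL, path = NULL) {
  fmt <- function(v, d = 1) formatC(v, format = "f", digits = d)
  lines <- c("# Agonistic scream analysis report", "")
  if (!is.null(config))
    lines <- c(lines, sprintf(
      "Simulated study: %d callers, %d events, %d bouts, %d screams (seed %d)",
      config$n_callers, config$n_events, config$n_bouts, config$n_screams,
      config$seed), "")
  lines <- c(lines, "## Discriminant analyses", "")
  if (!length(dfa_results)) {
    lines <- c(lines, "(absent)", "")
  } else {
    for (nm in names(dfa_results)) {
      r <- dfa_results[[nm]]
      lines <- c(lines, sprintf("### %s", nm),
        sprintf("- classified: observed %s%% vs expected %s%% (p = %.4g)",
                fmt(r$observed_classification),
                fmt(r$expected_classification), r$p_classification),
        sprintf("- cross-validated: observed %s%% vs expected %s%% (p = %.4g)",
                fmt(r$observed_crossvalidation),
                fmt(r$expected_crossvalidation), r$p_crossvalidation),
        sprintf("- %d classes, %d samples, %s design", r$n_classes,
                r$n_samples, r$mode), "")
    }
  }
  lines <- c(lines, "## Effect ledger (12 models x 3 effects, BH-adjusted)",
             "")
  if (is.null(ledger)) {
    lines <- c(lines, "(absent)", "")
  } else {
    lines <- c(lines, "response | level | effect | estimate | p | p_adj",
               "---|---|---|---|---|---")
    for (i in seq_len(nrow(ledger)))
      lines <- c(lines, sprintf("%s | %s | %s | %s | %s | %s",
                                ledger$response[i], ledger$level[i],
                                ledger$effect[i],
                                fmt(ledger$estimate[i], 3),
                                fmt(ledger$p[i], 4), fmt(ledger$p_adj[i], 4)))
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Support model", "")
  if (is.null(support)) {
    lines <- c(lines, "(absent)", "")
  } else {
    lines <- c(lines, sprintf(
      "- N = %d bouts, %d callers; R2m = %.2f, R2c = %.2f",
      support$n_units, support$n_individuals, support$r2m, support$r2c))
    for (i in seq_len(nrow(support$coefs)))
      lines <- c(lines, sprintf(
        "- %s: estimate %s (se %s), p = %s", support$coefs$effect[i],
        fmt(support$coefs$estimate[i], 3), fmt(support$coefs$se[i], 3),
        fmt(support$coefs$p[i], 4)))
    lines <- c(lines, "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
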