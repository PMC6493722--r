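#' Drop highly correlated features
#'
#' Greedy multicollinearity screen: while any pair of columns has
#' `|r| > threshold`, the member of the worst pair with the larger mean
#' absolute correlation to the remaining features is removed. Removals
#' are recorded (with the triggering pair and its r) in the
#' `"removals"` attribute.
#'
#' @param x Numeric `data.frame`/matrix with at least 2 columns.
#' @param threshold Absolute Pearson correlation above which one of a
#'   pair is dropped (default 0.80).
#' @return `x` with offending columns removed.
#' @export
correlation_filter <- function(x, threshold = 0.8) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2L)
  removals <- data.frame(removed = character(0), kept = character(0),
                         r = numeric(0))
  repeat {
    if (ncol(x) < 2L) break
    r <- stats::cor(x, use = "pairwise.complete.obs")
    diag(r) <- 0
    worst <- which(abs(r) == max(abs(r)), arr.ind = TRUE)[1L, ]
    if (abs(r[worst[1L], worst[2L]]) <= threshold) break
    pair <- colnames(r)[worst]
    mean_abs <- colMeans(abs(r))[pair]
    drop <- pair[which.max(mean_abs)]
    keep <- setdiff(pair, drop)
    removals <- rbind(removals,
                      data.frame(removed = drop, kept = keep,
                                 r = r[worst[1L], worst[2L]]))
    x <- x[, setdiff(colnames(x), drop), drop = FALSE]
  }
  attr(x, "removals") <- removals
  x
}

#' Symmetrise and standardise features
#'
#' Per column: if the raw skewness exceeds `skew_threshold` in absolute
#' value, the transform among identity, log and square root (with an
#' offset when non-positive values occur) that minimises `|skewness|` is
#' applied; all columns are then scaled to mean 0 and SD 1. The chosen
#' transform per column is recorded in the `"transforms"` attribute.
#'
#' @param x Numeric `data.frame`/matrix.
#' @param skew_threshold Absolute skewness below which a column is left
#'   untransformed.
#' @return Transformed, scaled `data.frame`.
#' @export
transform_scale <- function(x, skew_threshold = 0.5) {
  x <- as.data.frame(x)
  chosen <- character(ncol(x))
  names(chosen) <- colnames(x)
  for (j in seq_len(ncol(x))) {
    v <- x[[j]]
    sk <- e1071::skewness(v, na.rm = TRUE)
    chosen[j] <- "identity"
    if (is.finite(sk) && abs(sk) > skew_threshold) {
      off <- if (min(v, na.rm = TRUE) <= 0)
        -min(v, na.rm = TRUE) + 1e-3 * stats::sd(v, na.rm = TRUE) else 0
      cand <- list(identity = v, log = log(v + off), sqrt = sqrt(v + off))
      sks <- vapply(cand, function(u) abs(e1071::skewness(u, na.rm = TRUE)),
                    numeric(1L))
      sks[!is.finite(sks)] <- Inf
      best <- names(which.min(sks))
      chosen[j] <- if (best == "identity") "identity"
      else paste0(best, if (off > 0) sprintf("(+%.3g)", off) else "")
      v <- cand[[best]]
    }
    x[[j]] <- as.numeric(scale(v))
  }
  attr(x, "transforms") <- chosen
  x
}

#' Fit a Fisher linear discriminant
#'
#' Computes class centroids and the pooled within-class covariance; new
#' observations are classified to the nearest centroid in the whitened
#' (Mahalanobis) space, which with all discriminant axes is exactly the
#' Fisher rule with equal priors. A singular within-class covariance
#' triggers a logged ridge fallback.
#'
#' @param x Numeric matrix/`data.frame` (n x p), `p <= n - k`.
#' @param labels Class labels (coerced to factor); at least 2 classes
#'   with at least 2 samples each.
#' @param axes Also compute the discriminant axes (eigenvectors of the
#'   whitened between-class scatter)? Classification does not need
#'   them, so resampling loops skip this.
#' @return A `fisher_lda` object.
#' @export
fit_discriminant <- function(x, labels, axes = TRUE) {
  x <- as.matrix(x)
  f <- droplevels(as.factor(labels))
  k <- nlevels(f)
  n <- nrow(x)
  p <- ncol(x)
  nk <- tabulate(as.integer(f), k)
  if (k < 2L) stop("need at least 2 classes")
  if (min(nk) < 2L) stop("every class needs at least 2 samples")
  if (p > n - k) stop("too many features: need p <= n - k (p = ", p,
                      ", n - k = ", n - k, ")")
  means <- rowsum(x, f) / nk
  cent <- x - means[as.integer(f), , drop = FALSE]
  Sw <- crossprod(cent) / (n - k)
  ridge <- FALSE
  R <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(R) || rcond(Sw) < 1e-10) {
    ridge <- TRUE
    Sw <- Sw + diag(1e-6 * mean(diag(Sw)) + 1e-12, p)
    R <- chol(Sw)
  }
  # whitening: ||t(solve(R)) %*% (x - m)||^2 is the Mahalanobis distance
  Wh <- t(backsolve(R, diag(p)))
  scaling <- NULL
  if (axes) {
    # discriminant axes (for inspection): eigenvectors of Sw^-1 Sb
    gm <- colMeans(x)
    Sb <- crossprod(sweep(means, 2L, gm) * sqrt(nk)) / n
    ax <- eigen(backsolve(R, forwardsolve(t(R), Sb)), symmetric = FALSE)
    scaling <- Re(ax$vectors[, seq_len(min(k - 1L, p)), drop = FALSE])
  }
  structure(list(means = means, whiten = Wh, levels = levels(f),
                 scaling = scaling, ridge = ridge, n = n, p = p, k = k),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda: %d classes, %d features, n = %d%s>\n",
              x$k, x$p, x$n, if (x$ridge) ", ridge-regularised" else ""))
  invisible(x)
}

#' Classify observations with a fitted discriminant
#'
#' Nearest class centroid in the whitened space; distance ties are
#' broken towards the lowest (first) class label.
#'
#' @param object A `fisher_lda`.
#' @param newdata Numeric matrix/`data.frame` with the training columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.fisher_lda <- function(object, newdata, ...) {
  factor(object$levels[classify_idx(object, as.matrix(newdata))],
         levels = object$levels)
}

# nearest whitened centroid as an integer level index; ties go to the
# first (lowest) class label
classify_idx <- function(fit, x) {
  z <- x %*% t(fit$whiten)
  mz <- fit$means %*% t(fit$whiten)
  d2 <- outer(rowSums(z^2), rowSums(mz^2), "+") - 2 * z %*% t(mz)
  max.col(-d2, ties.method = "first")
}

#' Jack-knifed classification and cross-validation success
#'
#' Fits the discriminant on a training subset, reports the percentage of
#' training observations correctly classified (classification success)
#' and the percentage of held-out observations correctly classified
#' (cross-validation success). Holdout observations of classes absent
#' from the training set are excluded from scoring.
#'
#' @param x Feature matrix.
#' @param labels Class labels.
#' @param train Integer indices of the training subset.
#' @return List with `classification` and `crossvalidation` (percent),
#'   and the fitted model.
#' @export
jackknife_classify <- function(x, labels, train) {
  x <- as.matrix(x)
  f <- as.factor(labels)
  fit <- fit_discriminant(x[train, , drop = FALSE], f[train],
                          axes = FALSE)
  code <- match(as.character(f), fit$levels)
  cls <- 100 * mean(classify_idx(fit, x[train, , drop = FALSE]) ==
                      code[train])
  hold <- setdiff(seq_len(nrow(x)), train)
  hold <- hold[!is.na(code[hold])]
  cv <- if (length(hold))
    100 * mean(classify_idx(fit, x[hold, , drop = FALSE]) == code[hold])
  else NA_real_
  list(classification = cls, crossvalidation = cv, fit = fit)
}

# Precompute the subset-design bookkeeping for one label configuration:
# retained individuals, sampling pools and per-pool training counts.
# Drawing a training set is then a cheap sample per pool.
prep_design <- function(f, cells, mode, train_fraction, min_samples) {
  counts <- table(f = f, cell = cells)
  if (mode == "balanced_crossed") {
    ok <- rownames(counts)[apply(counts, 1L, function(r) all(r >= 2L))]
    if (length(ok) < 2L)
      stop("design infeasible: fewer than 2 individuals present in all ",
           "control cells with >= 2 samples")
    m <- min(counts[ok, , drop = FALSE])
    t_per <- max(1L, min(m - 1L, as.integer(round(train_fraction * m))))
    pools <- list(); take <- integer(0)
    for (id in ok) for (cl in colnames(counts)) {
      pools[[length(pools) + 1L]] <- which(f == id & cells == cl)
      take <- c(take, t_per)
    }
  } else if (mode == "unbalanced_crossed") {
    ok <- rownames(counts)[rowSums(counts) >= min_samples]
    if (length(ok) < 2L)
      stop("design infeasible: fewer than 2 individuals with >= ",
           min_samples, " samples")
    pools <- list(); take <- integer(0)
    for (id in ok) for (cl in colnames(counts)) {
      pool <- which(f == id & cells == cl)
      nc <- length(pool)
      if (nc < 2L) next
      pools[[length(pools) + 1L]] <- pool
      take <- c(take, max(1L, min(nc - 1L,
                                  as.integer(round(train_fraction * nc)))))
    }
  } else {  # plain
    ok <- names(which(table(f) >= pmax(2L, min_samples)))
    if (length(ok) < 2L)
      stop("design infeasible: fewer than 2 classes with enough samples")
    pools <- lapply(ok, function(id) which(f == id))
    take <- vapply(pools, function(p)
      max(1L, min(length(p) - 1L,
                  as.integer(round(train_fraction * length(p))))),
      integer(1L))
  }
  list(pools = pools, take = take, retained = ok,
       n_retained = sum(f %in% ok))
}

draw_from <- function(prep) {
  unlist(lapply(seq_along(prep$pools), function(i) {
    p <- prep$pools[[i]]
    p[sample.int(length(p), prep$take[i])]
  }), use.names = FALSE)
}

#' Balanced / stratified training subsets for a crossed design
#'
#' Draws training index sets for the jack-knifed discriminant analysis.
#' In `"balanced_crossed"` mode only individuals present in every
#' control cell (with at least 2 samples per cell) are retained, and an
#' equal number of training calls — ruled by the minimum cell count and
#' the target training fraction — is drawn from every individual-by-cell
#' cell. `"unbalanced_crossed"` retains every individual with at least
#' `min_samples` calls and stratifies draws by cell;
#' `"plain"` ignores the control factor.
#'
#' @param labels Test-factor labels (e.g. caller identity).
#' @param cells Control-factor cells (factor), or `NULL`.
#' @param mode Design mode, as in [pdfa()].
#' @param train_fraction Target training share.
#' @param min_samples Minimum calls per individual for the unbalanced
#'   and plain modes.
#' @param n_resamples Number of subsets to draw.
#' @return List of integer index vectors; attributes `retained` (the
#'   individuals kept by the balance ruling) and `share` (achieved
#'   training share).
#' @export
balanced_subsets <- function(labels, cells = NULL,
                             mode = c("balanced_crossed",
                                      "unbalanced_crossed", "plain"),
                             train_fraction = 0.5, min_samples = 4L,
                             n_resamples = 1L) {
  mode <- match.arg(mode)
  f <- as.factor(labels)
  cells <- if (is.null(cells)) factor(rep("all", length(f)))
  else as.factor(cells)
  prep <- prep_design(f, cells, mode, train_fraction, min_samples)
  out <- lapply(seq_len(n_resamples), function(i) draw_from(prep))
  attr(out, "retained") <- prep$retained
  attr(out, "share") <- length(out[[1L]]) / prep$n_retained
  out
}

#' Permuted discriminant function analysis
#'
#' Jack-knifed discriminant classification of a test factor (e.g. caller
#' identity or recording context), with a nuisance factor controlled by
#' a crossed subset design, calibrated against permuted datasets.
#' Observed classification and cross-validation success are averaged
#' over `n_resamples` random balanced training draws; expected (chance)
#' success is the average over `n_permutations` datasets in which the
#' test-factor labels are shuffled within levels of the control factor
#' (preserving the crossed design). Each permuted dataset is evaluated
#' by exactly the same procedure as the observed one — an average over
#' `n_resamples` freshly drawn training subsets — so that the observed
#' and permuted statistics are exchangeable under the null and the
#' empirical p-values are uniform when there is no signal. Empirical
#' p-values use the add-one estimator `(b + 1) / (m + 1)`.
#'
#' @param data `data.frame` holding features and factors.
#' @param test Name of the test-factor column.
#' @param features Character vector of numeric feature columns.
#' @param control Character vector of control-factor column(s) whose
#'   interaction defines the crossed cells; `NULL` for none.
#' @param mode `"balanced_crossed"` (only individuals present in every
#'   control cell, equal per-cell training counts ruled by the minimum
#'   cell count), `"unbalanced_crossed"` (all individuals with at least
#'   `min_samples` calls, cell-stratified draws), or `"plain"`.
#' @param train_fraction Target training share per cell (the achieved
#'   share is reported).
#' @param n_resamples,n_permutations Monte-Carlo sizes (paper-scale
#'   defaults 100 and 1000).
#' @param correlation_threshold Passed to [correlation_filter()].
#' @param min_samples Minimum calls per individual in unbalanced/plain
#'   modes.
#' @param seed Integer seed; the full result is deterministic given the
#'   seed.
#' @return A `pdfa` object: observed/expected classification and
#'   cross-validation percentages, empirical p-values, per-resample and
#'   per-permutation traces, retained features/transforms and design
#'   metadata.
#' @export
pdfa <- function(data, test, features, control = NULL,
                 mode = c("balanced_crossed", "unbalanced_crossed", "plain"),
                 train_fraction = 0.5, n_resamples = 100L,
                 n_permutations = 1000L, correlation_threshold = 0.8,
                 min_samples = 4L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_resamples >= 1L, n_permutations >= 1L,
            train_fraction > 0, train_fraction < 1)
  keep <- stats::complete.cases(data[, features, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  x <- transform_scale(data[, features, drop = FALSE])
  transforms <- attr(x, "transforms")
  x <- correlation_filter(x, correlation_threshold)
  removals <- attr(x, "removals")
  x <- as.matrix(x)
  f <- droplevels(as.factor(data[[test]]))
  cells <- if (is.null(control)) factor(rep("all", nrow(data)))
  else droplevels(interaction(data[, control, drop = FALSE], drop = TRUE))

  with_seed(seed, {
    one_eval <- function(labels, prep) {
      tr <- draw_from(prep)
      jk <- jackknife_classify(x, labels, tr)
      c(classification = jk$classification,
        crossvalidation = jk$crossvalidation,
        share = length(tr) / prep$n_retained,
        n_classes = length(prep$retained))
    }
    avg_eval <- function(labels) {
      prep <- prep_design(labels, cells, mode, train_fraction, min_samples)
      m <- t(vapply(seq_len(n_resamples), function(i)
        one_eval(labels, prep), numeric(4L)))
      m
    }
    obs <- avg_eval(f)
    cell_idx <- split(seq_along(cells), cells)
    perm <- t(vapply(seq_len(n_permutations), function(b) {
      fp <- f
      for (i in cell_idx) fp[i] <- f[sample(i)]
      colMeans(avg_eval(fp), na.rm = TRUE)
    }, numeric(4L)))

    obs_cls <- mean(obs[, "classification"])
    obs_cv <- mean(obs[, "crossvalidation"], na.rm = TRUE)
    structure(list(
      test = test, control = control, mode = mode,
      observed_classification = obs_cls,
      expected_classification = mean(perm[, "classification"]),
      observed_crossvalidation = obs_cv,
      expected_crossvalidation = mean(perm[, "crossvalidation"],
                                      na.rm = TRUE),
      p_classification =
        (sum(perm[, "classification"] >= obs_cls) + 1) /
        (n_permutations + 1),
      p_crossvalidation =
        (sum(perm[, "crossvalidation"] >= obs_cv) + 1) /
        (n_permutations + 1),
      n_classes = round(mean(obs[, "n_classes"])),
      n_samples = nrow(x),
      achieved_train_share = mean(obs[, "share"]),
      resample_trace = as.data.frame(obs),
      permutation_trace = as.data.frame(perm),
      features = colnames(x), transforms = transforms,
      removals = removals,
      n_resamples = n_resamples, n_permutations = n_permutations,
      seed = seed), class = "pdfa")
  })
}

#' @export
print.pdfa <- function(x, ...) {
  cat(sprintf("Permuted DFA of `%s`%s (%s design)\n", x$test,
              if (!is.null(x$control))
                sprintf(" controlling %s", paste(x$control, collapse = " x "))
              else "", x$mode))
  cat(sprintf("  %d classes, %d samples; features: %s\n", x$n_classes,
              x$n_samples, paste(x$features, collapse = ", ")))
  cat(sprintf("  classification:    observed %5.1f%%  expected %5.1f%%  p = %.4g\n",
              x$observed_classification, x$expected_classification,
              x$p_classification))
  cat(sprintf("  cross-validation:  observed %5.1f%%  expected %5.1f%%  p = %.4g\n",
              x$observed_crossvalidation, x$expected_crossvalidation,
              x$p_crossvalidation))
  cat(sprintf("  (%d resamples, %d permutations, mean training share %.1f%%)\n",
              x$n_resamples, x$n_permutations,
              100 * x$achieved_train_share))
  invisible(x)
}

#' @export
summary.pdfa <- function(object, ...) {
  out <- data.frame(
    quantity = c("classification", "cross-validation"),
    observed = c(object$observed_classification,
                 object$observed_crossvalidation),
    expected = c(object$expected_classification,
                 object$expected_crossvalidation),
    p = c(object$p_classification, object$p_crossvalidation))
  attr(out, "design") <- object[c("test", "control", "mode", "n_classes",
                                  "n_samples")]
  out
}
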