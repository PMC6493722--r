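test_that("the correlation filter removes one member of each offending pair", {
  set.seed(1)
  x <- data.frame(a = rnorm(100))
  x$b <- x$a                                   # r = 1 duplicate
  x$c <- rnorm(100)
  out <- correlation_filter(x)
  expect_identical(ncol(out), 2L)
  expect_true("c" %in% colnames(out))
  expect_identical(nrow(attr(out, "removals")), 1L)

  y <- data.frame(a = rnorm(200))
  y$b <- 0.95 * y$a + sqrt(1 - 0.95^2) * rnorm(200)   # r ~ 0.95 > 0.80
  y$c <- rnorm(200)
  out <- correlation_filter(y, threshold = 0.8)
  expect_identical(ncol(out), 2L)

  z <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  expect_identical(ncol(correlation_filter(z)), 3L)
  expect_identical(nrow(attr(correlation_filter(z), "removals")), 0L)
})

test_that("transform_scale standardises and reduces skewness where needed", {
  set.seed(2)
  x <- data.frame(sym = rnorm(400), skewed = rlnorm(400, sdlog = 1))
  out <- transform_scale(x)
  expect_equal(unname(colMeans(out)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(out, 2, sd)), c(1, 1), tolerance = 1e-10)
  tr <- attr(out, "transforms")
  expect_identical(unname(tr["sym"]), "identity")
  expect_false(tr["skewed"] == "identity")
  expect_lt(abs(e1071::skewness(out$skewed)),
            abs(e1071::skewness(x$skewed)))

  # non-positive values under log get a logged offset, not an error
  neg <- data.frame(v = rlnorm(400) - 2)
  expect_silent(out2 <- transform_scale(neg))
  expect_false(anyNA(out2$v))
})

test_that("the discriminant separates separable clouds and matches its oracle", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 8), ncol = 2))
  lab <- rep(c("a", "b"), each = 30)
  fit <- fit_discriminant(x, lab)
  expect_equal(mean(predict(fit, x) == lab), 1)

  # oracle: nearest centroid after whitening by the pooled covariance
  oracle_predict <- function(x_tr, lab_tr, x_te) {
    f <- factor(lab_tr)
    mus <- apply(x_tr, 2, tapply, f, mean)
    cent <- x_tr - mus[as.integer(f), , drop = FALSE]
    Sw <- crossprod(cent) / (nrow(x_tr) - nlevels(f))
    d2 <- sapply(seq_len(nlevels(f)), function(j) {
      dif <- sweep(x_te, 2, mus[j, ])
      rowSums((dif %*% solve(Sw)) * dif)
    })
    levels(f)[apply(d2, 1, which.min)]
  }
  set.seed(4)
  for (i in 1:100) {
    k <- sample(2:4, 1); p <- sample(2:4, 1); n_per <- sample(6:12, 1)
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      matrix(rnorm(n_per * p, mean = 1.5 * j), ncol = p)))
    lab <- rep(letters[seq_len(k)], each = n_per)
    test_x <- matrix(rnorm(20 * p), ncol = p) + 2
    fit <- fit_discriminant(x, lab)
    expect_identical(as.character(predict(fit, test_x)),
                     oracle_predict(x, lab, test_x))
  }
})

test_that("the discriminant agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  agree <- replicate(30, {
    k <- sample(2:4, 1); p <- sample(2:5, 1)
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      matrix(rnorm(15 * p, mean = j), ncol = p)))
    lab <- rep(letters[seq_len(k)], each = 15)
    newx <- matrix(rnorm(30 * p, mean = 2), ncol = p)
    mine <- predict(fit_discriminant(x, lab), newx)
    ref <- predict(MASS::lda(x, grouping = lab,
                             prior = rep(1 / k, k)), newx)$class
    mean(as.character(mine) == as.character(ref))
  })
  expect_gt(mean(agree), 0.99)
})

test_that("degenerate discriminant inputs fail loudly or fall back to ridge", {
  x <- matrix(rnorm(40), ncol = 2)
  expect_error(fit_discriminant(x, rep("a", 20)), "2 classes")
  expect_error(fit_discriminant(x, c("b", rep("a", 19))), "2 samples")
  expect_error(fit_discriminant(matrix(rnorm(60), ncol = 10),
                                rep(c("a", "b"), 3)), "p <= n - k")

  # collinear features make the within-class scatter singular
  xc <- cbind(rnorm(30), 0)
  xc[, 2] <- xc[, 1]
  fit <- fit_discriminant(xc, rep(c("a", "b"), each = 15))
  expect_true(fit$ridge)

  # exchangeable labels: held-out accuracy near chance
  set.seed(6)
  acc <- replicate(60, {
    x <- matrix(rnorm(96 * 2), ncol = 2)
    lab <- rep(letters[1:4], each = 24)
    train <- unlist(lapply(split(seq_along(lab), lab), sample, 12))
    fit <- fit_discriminant(x[train, ], lab[train])
    hold <- setdiff(seq_along(lab), train)
    mean(as.character(predict(fit, x[hold, ])) == lab[hold])
  })
  expect_lt(abs(mean(acc) - 0.25), 0.04)
})

test_that("jack-knifed rates behave at their fixed points", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
             matrix(rnorm(40, 5, 0.3), ncol = 2))
  lab <- rep(c("a", "b"), each = 20)
  jk <- jackknife_classify(x, lab, train = c(1:10, 21:30))
  expect_equal(jk$classification, 100)
  expect_equal(jk$crossvalidation, 100)

  # holdout identical to the training points: cv equals classification
  dup <- rbind(x[c(1:5, 21:25), ], x[c(1:5, 21:25), ])
  dl <- rep(c("a", "b", "a", "b"), each = 5)
  jkd <- jackknife_classify(dup, dl, train = 1:10)
  expect_equal(jkd$crossvalidation, jkd$classification)
})

test_that("balanced subsets enforce the crossed-design counting rules", {
  set.seed(8)
  lab <- rep(paste0("I", 1:4), each = 20)
  cells <- rep(rep(c("am", "as", "vm", "vs"), each = 5), 4)
  tr <- balanced_subsets(lab, cells, mode = "balanced_crossed",
                         train_fraction = 0.5, n_resamples = 3)
  expect_length(tr, 3L)
  for (t in tr) {
    expect_length(t, 4 * 4 * round(0.5 * 5))   # equal per-cell counts
    tab <- table(lab[t], cells[t])
    expect_true(all(tab == round(0.5 * 5)))
  }
  expect_setequal(attr(tr, "retained"), paste0("I", 1:4))

  # an individual missing one cell is excluded in balanced mode
  miss <- !(lab == "I4" & cells == "vs")
  tr2 <- balanced_subsets(lab[miss], cells[miss], mode = "balanced_crossed")
  expect_setequal(attr(tr2, "retained"), paste0("I", 1:3))
  # ... but kept in the unbalanced crossed mode
  tr3 <- balanced_subsets(lab[miss], cells[miss],
                          mode = "unbalanced_crossed")
  expect_setequal(attr(tr3, "retained"), paste0("I", 1:4))

  # plain mode: about half of each class
  tr4 <- balanced_subsets(lab, mode = "plain", train_fraction = 0.5)
  expect_true(all(table(lab[tr4[[1]]]) == 10))

  # infeasible design
  expect_error(balanced_subsets(rep(c("a", "b"), 2),
                                rep(c("x", "y"), each = 2),
                                mode = "balanced_crossed"),
               "infeasible")
})

test_that("the permuted DFA is deterministic given its seed", {
  cfg <- null_identity_config(61, n_callers = 4, n_events = 24,
                              n_bouts = 32, n_screams = 100)
  ft <- simulate_call_features(cfg)
  r1 <- pdfa(ft, test = "caller_id", features = call_feature_set,
             control = c("role", "severity"), mode = "balanced_crossed",
             n_resamples = 4, n_permutations = 30, seed = 9)
  r2 <- pdfa(ft, test = "caller_id", features = call_feature_set,
             control = c("role", "severity"), mode = "balanced_crossed",
             n_resamples = 4, n_permutations = 30, seed = 9)
  expect_identical(r1$resample_trace, r2$resample_trace)
  expect_identical(r1$permutation_trace, r2$permutation_trace)
  expect_identical(r1$p_crossvalidation, r2$p_crossvalidation)
  r3 <- pdfa(ft, test = "caller_id", features = call_feature_set,
             control = c("role", "severity"), mode = "balanced_crossed",
             n_resamples = 4, n_permutations = 30, seed = 10)
  expect_false(identical(r1$permutation_trace, r3$permutation_trace))
})

test_that("strong signatures give observed far above expected; shuffled labels do not", {
  cfg <- study_config(n_callers = 4, n_events = 48, n_bouts = 64,
                      n_screams = 200, between_sd = 600, within_sd = 80,
                      p_severe = 0.5, seed = 71)
  ft <- simulate_call_features(cfg)
  r <- pdfa(ft, test = "caller_id", features = call_feature_set,
            control = c("role", "severity"), mode = "balanced_crossed",
            n_resamples = 10, n_permutations = 99, seed = 11)
  expect_gt(r$observed_crossvalidation, r$expected_crossvalidation + 15)
  expect_lte(r$p_crossvalidation, 0.01)

  shuf <- ft
  set.seed(12)
  shuf$caller_id <- sample(shuf$caller_id)
  r0 <- pdfa(shuf, test = "caller_id", features = call_feature_set,
             control = c("role", "severity"), mode = "balanced_crossed",
             n_resamples = 5, n_permutations = 99, seed = 13)
  expect_gt(r0$p_crossvalidation, 0.01)
})
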