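test_that("trajectory GLM matches the normal-equations oracle", {
  # exact fit: y = age with constant sex (sex dropped)
  f <- suppressWarnings(  # exact fit: lm warns about perfect residuals
    traj_glm(c(1, 2, 3, 4), c(1, 2, 3, 4), rep(0, 4), drop_sex = TRUE))
  expect_equal(unname(coef(f)), c(0, 1), tolerance = 1e-10)
  expect_equal(unname(residuals(f)), rep(0, 4), tolerance = 1e-10)

  set.seed(11)
  n <- 30
  age <- runif(n, 4, 40); sex <- rbinom(n, 1, 0.5)
  y <- 100 - 2 * age + 30 * sex + rnorm(n, sd = 5)
  for (form in c("linear", "interaction", "quadratic")) {
    fit <- traj_glm(y, age, sex, form)
    X <- switch(form,
      linear = cbind(1, age, sex),
      interaction = cbind(1, age, sex, age * sex),
      quadratic = cbind(1, age, sex, age^2))
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(coef(fit)), c(beta), tolerance = 1e-8)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - ncol(X))
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(unname(fit$se), unname(se), tolerance = 1e-8)
    expect_equal(fit$df_residual, n - ncol(X))
  }

  # permutation invariance
  o <- sample(n)
  f1 <- traj_glm(y, age, sex)
  f2 <- traj_glm(y[o], age[o], sex[o])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)

  # singular design
  expect_error(traj_glm(y, rep(1, n), rep(1, n)), "error")
})

test_that("traj_glm methods are coherent", {
  set.seed(12)
  age <- runif(40, 4, 40); sex <- rbinom(40, 1, 0.5)
  y <- 10 - 0.5 * age + rnorm(40)
  fit <- traj_glm(y, age, sex)
  expect_equal(unname(predict(fit, data.frame(age = 20, sex = 0))),
               coef(fit)[["(Intercept)"]] + 20 * coef(fit)[["age"]],
               tolerance = 1e-10)
  expect_length(residuals(fit), 40)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(40L, 2L))
  expect_output(print(fit), "trajectory GLM")
})

test_that("nested F-test matches brute-force RSS arithmetic", {
  set.seed(13)
  n <- 40
  age <- runif(n, 4, 40); sex <- rbinom(n, 1, 0.5)
  y <- 5 + age + rnorm(n)
  small <- traj_glm(y, age, sex, "linear")
  big <- traj_glm(y, age, sex, "interaction")
  ft <- nested_f_test(small, big)
  Fb <- ((small$rss - big$rss) / 1) / (big$rss / big$df_residual)
  expect_equal(ft$F, Fb, tolerance = 1e-10)
  expect_equal(ft$p, pf(Fb, 1, big$df_residual, lower.tail = FALSE))
  # single added coefficient: F equals that coefficient's t^2
  expect_equal(ft$F, unname(big$t["age:sex"]^2), tolerance = 1e-8)
  # identical fits -> F = 0, p = 1 (compare a model against itself via
  # a zero-variance addition is not nested; use equal-RSS instead)
  y2 <- 1 + 0 * age + rnorm(n)
  s2 <- traj_glm(y2, age, sex, "linear")
  expect_error(nested_f_test(s2, s2), "nested")
})

test_that("model selection keeps planted forms and is conservative", {
  set.seed(14)
  n <- 121
  age <- runif(n, 4, 40); sex <- rbinom(n, 1, 0.5)

  # pure linear age effect: linear form chosen in >= 90% of replicates
  keep <- replicate(120, {
    y <- 1000 - 20 * age + 100 * sex + rnorm(n, sd = 100)
    fit <- select_model(y, age, sex)
    fit$form == "linear"
  })
  expect_gte(mean(keep), 0.9)

  # strong planted interaction is retained
  y_int <- 1000 - 20 * age + 100 * sex + 15 * age * sex +
    rnorm(n, sd = 100)
  expect_equal(select_model(y_int, age, sex)$form, "interaction")

  # strong quadratic age effect is retained
  y_q <- 1000 + 40 * age - 1 * age^2 + rnorm(n, sd = 30)
  expect_equal(select_model(y_q, age, sex)$form, "quadratic")

  # y independent of covariates: age term retained at ~alpha rate
  hits <- replicate(400, {
    y0 <- rnorm(n)
    "age" %in% select_model(y0, age, sex)$terms
  })
  expect_lt(mean(hits), 0.09)  # conservative triple criterion <= alpha
})

test_that("difference-score contrast equals the explicit interaction F", {
  set.seed(15)
  n <- 50
  age <- runif(n, 4, 40)
  for (r in 1:10) {
    a <- 100 - 3 * age + rnorm(n, sd = 10)
    b <- 50 - 1 * age + rnorm(n, sd = 10)
    ct <- paired_slope_difference(a, b, age)
    expect_equal(ct$df2, n - 2)
    # long-format fit with subject indicators and class-by-age interaction
    subj <- factor(rep(seq_len(n), 2))
    cls <- rep(c(1, 0), each = n)
    yy <- c(a, b)
    aa <- rep(age, 2)
    fit_big <- lm(yy ~ subj + cls + cls:aa)
    fit_small <- lm(yy ~ subj + cls)
    av <- anova(fit_small, fit_big)
    expect_equal(ct$F, av$F[2], tolerance = 1e-8)
    expect_equal(ct$p, av$`Pr(>F)`[2], tolerance = 1e-8)
  }
  # identical totals -> F = 0, p = 1
  a <- 100 - 3 * age + rnorm(n)
  ct0 <- paired_slope_difference(a, a, age)
  expect_equal(ct0$F, 0)
  expect_equal(ct0$p, 1)
  expect_error(paired_slope_difference(a, a[-1], age), "length")
})

test_that("preferential chi-squared follows the closed form", {
  ct <- preferential_chi2(90, 10, 50, 50)
  expect_equal(ct$chi2, 64)  # E = (50, 50); (40^2/50)*2
  expect_equal(ct$df, 1)
  # losses proportional to prevalence -> chi2 = 0, p = 1
  ct0 <- preferential_chi2(30, 70, 30, 70)
  expect_equal(ct0$chi2, 0)
  expect_equal(ct0$p, 1)
  expect_error(preferential_chi2(0, 0, 5, 5), "total loss")
  # slope construction: |slope| x span
  ct2 <- preferential_chi2_from_slopes(-60, -8, 100, 300, age_span = 36)
  expect_equal(ct2$chi2,
               preferential_chi2(60 * 36, 8 * 36, 100, 300)$chi2)
})

test_that("BH-FDR matches the exhaustive step-up oracle", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$rejected))
  res1 <- bh_fdr(rep(1, 5))
  expect_false(any(res1$rejected))
  expect_equal(res1$adjusted, rep(1, 5))
  set.seed(16)
  for (r in 1:50) {
    m <- sample(1:12, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    res <- bh_fdr(p, q)
    expect_equal(res$rejected, brute_bh_reject(p, q))
    expect_equal(res$adjusted, p.adjust(p, "BH"))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FCR intervals have the 1 - Rq/m level and cover selected truths", {
  # closed-form levels
  ci <- fcr_intervals(rep(0, 10), rep(1, 10),
                      c(TRUE, TRUE, rep(FALSE, 8)), q = 0.05)
  expect_equal(unique(ci$level), 0.99)
  ci_all <- fcr_intervals(rep(0, 4), rep(1, 4), rep(TRUE, 4), q = 0.05)
  expect_equal(unique(ci_all$level), 0.95)
  expect_equal(nrow(fcr_intervals(1, 1, FALSE)), 0)
  # intervals contain the point estimate
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))

  # simulation: coverage of true slopes among BH-selected parameters
  set.seed(17)
  n <- 60; m <- 20
  age <- runif(n, 4, 40)
  true_slope <- c(rep(-2, 5), rep(0, 15))
  cover <- selected <- 0
  for (r in 1:300) {
    est <- se <- p <- numeric(m)
    for (j in 1:m) {
      y <- 100 + true_slope[j] * age + rnorm(n, sd = 8)
      f <- lm(y ~ age)
      sm <- summary(f)$coefficients
      est[j] <- sm["age", 1]; se[j] <- sm["age", 2]; p[j] <- sm["age", 4]
    }
    rej <- bh_fdr(p, 0.05)$rejected
    ci <- fcr_intervals(est, se, rej, q = 0.05, df = n - 2)
    if (nrow(ci)) {
      sel <- ci$index
      cover <- cover + sum(ci$lower <= true_slope[sel] &
                             true_slope[sel] <= ci$upper)
      selected <- selected + length(sel)
    }
  }
  expect_gte(cover / selected, 0.95 - 0.02)  # FCR guarantee at q = 0.05
})

test_that("edgewise analysis recovers planted sex-specific edges", {
  tmpl <- make_template(n_nodes = 30, n_modules = 2, target_density = 0.25,
                        seed = 71, backbone_size = 30)
  p <- generator_params(n_subjects = 80, noise_sd = 40)
  coh <- simulate_cohort(tmpl, p, seed = 72)
  # plant one strong female-only declining edge on a backbone pair
  bb <- tmpl$edges[tmpl$edges$backbone, ][1, ]
  meta <- cohort_meta(coh)
  for (k in seq_along(coh)) {
    w <- if (meta$sex01[k] == 0)
      max(300 - 8 * meta$age[k] + rnorm(1, sd = 8), 1)
    else 300 + rnorm(1, sd = 8)
    w <- round(w)
    coh[[k]]$W[bb$i, bb$j] <- coh[[k]]$W[bb$j, bb$i] <- w
  }
  ew <- edgewise_age_analysis(coh, q = 0.05)
  row <- ew[ew$i == bb$i & ew$j == bb$j, ]
  expect_equal(row$sex_specific, "female")
  expect_lt(row$slope, 0)
  # all reported slopes lie inside their FCR intervals
  sel <- ew$significant & !is.na(ew$ci_lower)
  expect_true(all(ew$ci_lower[sel] <= ew$slope[sel] &
                    ew$slope[sel] <= ew$ci_upper[sel]))
  # a constant edge yields no age effect and no sex label
  const <- ew[ew$form == "constant", ]
  if (nrow(const)) expect_true(all(const$sex_specific == "none"))
})

test_that("nodal analysis emits 2 rows per ROI and controls false positives", {
  # null cohort: no planted age or sex effects, so any significant nodal
  # change is a false positive
  tmpl <- make_template(n_nodes = 20, n_modules = 2, target_density = 0.3,
                        seed = 81, backbone_size = 20)
  # presence_prob = 1: edge dropout gives the small-module z-scores
  # heavy-tailed jumps that are not the Gaussian errors the F reference
  # assumes; the calibration check needs a clean Gaussian null
  p <- generator_params(n_subjects = 24,
                        slopes_weight = c(thick = 0, thin = 0),
                        sex_offset = 0, noise_sd = 50,
                        presence_prob = 1)
  coh <- simulate_cohort(tmpl, p, seed = 82)
  nod <- nodal_metric_analysis(coh, partitions = tmpl$modules, q = 0.05)
  expect_equal(nrow(nod), 2 * 20)
  expect_setequal(unique(nod$metric),
                  c("within_module_strength_z", "participation_coefficient"))
  expect_true(all(nod$p_fdr >= nod$p))
  # age-independent metrics: false positives kept rare by FDR
  expect_lte(sum(nod$significant), 3)
})
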