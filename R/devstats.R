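## Developmental trajectory statistics. The three candidate GLMs for a
## measurement y over a cross-sectional cohort are
##   (1) linear:      y = b0 + b1*age + b2*sex + e
##   (2) interaction: y = b0 + b1*age + b2*sex + b3*age*sex + e
##   (3) quadratic:   y = b0 + b1*age + b2*sex + b3*age^2 + e
## with Gaussian iid errors; sex is coded female = 0, male = 1, so b2 is
## the male offset. Models (2) and (3) each compete against (1) by nested
## F-tests; they are never combined.

traj_form_terms <- function(form, drop_sex = FALSE, drop_age = FALSE) {
  terms <- switch(form,
    linear = c("age", "sex"),
    interaction = c("age", "sex", "age:sex"),
    quadratic = c("age", "sex", "I(age^2)"),
    stop("unknown model form: ", form))
  if (drop_sex) terms <- setdiff(terms, "sex")
  if (drop_age) terms <- setdiff(terms, "age")
  terms
}

#' Fit a developmental trajectory GLM
#'
#' Ordinary-least-squares fit of a measurement on age and sex, in one of
#' three nested forms: \code{"linear"} (age + sex), \code{"interaction"}
#' (age + sex + age:sex) or \code{"quadratic"} (age + sex + age^2). A
#' subset of terms may be dropped (e.g. an age-only fit within one sex).
#'
#' @param y Numeric response vector (one value per subject).
#' @param age Ages in years.
#' @param sex Sex indicator: 0/1 numeric (female = 0, male = 1) or a
#'   character vector of \code{"male"}/\code{"female"}.
#' @param form Model form, see above.
#' @param drop_sex,drop_age Drop that main effect (only meaningful for
#'   forms without the corresponding higher-order term).
#' @return Object of class \code{traj_glm} with components
#'   \code{coefficients}, \code{se}, \code{t}, \code{p}, \code{df_residual},
#'   \code{sigma2}, \code{aic}, \code{bic}, \code{rss}, \code{n},
#'   \code{form}, \code{fit} (the underlying \code{lm}). Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{simulate}, \code{plot}.
#' @examples
#' set.seed(1)
#' age <- runif(60, 4, 40); sex <- rbinom(60, 1, 0.5)
#' y <- 40000 - 70 * age + 800 * sex + rnorm(60, sd = 300)
#' fit <- traj_glm(y, age, sex)
#' coef(fit)
#' @export
traj_glm <- function(y, age, sex,
                     form = c("linear", "interaction", "quadratic"),
                     drop_sex = FALSE, drop_age = FALSE) {
  form <- match.arg(form)
  if (is.character(sex)) sex <- as.numeric(sex == "male")
  n <- length(y)
  if (length(age) != n || length(sex) != n)
    stop("error: y, age, sex must have equal lengths")
  terms <- traj_form_terms(form, drop_sex, drop_age)
  fml <- stats::reformulate(if (length(terms)) terms else "1",
                            response = "y")
  dat <- data.frame(y = y, age = age, sex = sex)
  fit <- stats::lm(fml, data = dat)
  p_coef <- length(stats::coef(fit))
  if (n <= p_coef)
    stop("error: need more subjects than coefficients (n = ", n, ")")
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < p_coef) stop("singular-design error: design not full rank")
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = stats::coef(fit),
    se = ct[, "Std. Error"],
    t = ct[, "t value"],
    p = ct[, "Pr(>|t|)"],
    df_residual = fit$df.residual,
    sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual,
    rss = sum(stats::residuals(fit)^2),
    aic = stats::AIC(fit),
    bic = stats::BIC(fit),
    n = n,
    form = form,
    terms = terms,
    fit = fit), class = "traj_glm")
}

#' @export
print.traj_glm <- function(x, ...) {
  cat("trajectory GLM (", x$form, "): y ~ ",
      paste(x$terms, collapse = " + "), "\n", sep = "")
  print(round(cbind(estimate = x$coefficients, se = x$se,
                    t = x$t, p = x$p), 4))
  cat(sprintf("n = %d, residual df = %d, AIC = %.1f, BIC = %.1f\n",
              x$n, x$df_residual, x$aic, x$bic))
  invisible(x)
}

#' @export
summary.traj_glm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.traj_glm <- function(object, ...) object$coefficients

#' @export
predict.traj_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.traj_glm <- function(object, ...) stats::residuals(object$fit)

#' @export
simulate.traj_glm <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)

#' Plot a fitted trajectory over age
#'
#' Scatter of the response against age, colored by sex, with the fitted
#' trajectory drawn per sex.
#'
#' @param x A \code{traj_glm}.
#' @param ... Passed to \code{plot}.
#' @export
plot.traj_glm <- function(x, ...) {
  dat <- x$fit$model
  cols <- ifelse(dat$sex %||% 0 == 1, "steelblue", "firebrick")
  graphics::plot(dat$age, dat$y, col = cols, pch = 16,
                 xlab = "age (years)", ylab = "measurement", ...)
  ag <- seq(min(dat$age), max(dat$age), length.out = 50)
  for (sx in unique(dat$sex %||% 0)) {
    nd <- data.frame(age = ag, sex = sx)
    graphics::lines(ag, stats::predict(x$fit, newdata = nd),
                    col = if (sx == 1) "steelblue" else "firebrick")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nested F-test between two trajectory fits
#'
#' \eqn{F = ((RSS_s - RSS_b)/df_1)/(RSS_b/df_2)} for a smaller model
#' nested in a bigger one, with the F reference distribution. When the big
#' model adds a single coefficient, F equals that coefficient's squared
#' t-statistic.
#'
#' @param fit_small,fit_big \code{traj_glm} fits of the same response.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
nested_f_test <- function(fit_small, fit_big) {
  stopifnot(inherits(fit_small, "traj_glm"), inherits(fit_big, "traj_glm"))
  if (fit_small$n != fit_big$n)
    stop("error: fits are not on the same response")
  if (!all(fit_small$terms %in% fit_big$terms) ||
      length(fit_big$terms) <= length(fit_small$terms))
    stop("error: models are not strictly nested")
  df1 <- fit_small$df_residual - fit_big$df_residual
  df2 <- fit_big$df_residual
  if (fit_big$rss == 0) {
    Fv <- if (fit_small$rss == 0) 0 else Inf
  } else {
    Fv <- ((fit_small$rss - fit_big$rss) / df1) / (fit_big$rss / df2)
  }
  Fv <- max(Fv, 0)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Nested model selection for developmental trajectories
#'
#' Fits the linear, interaction and quadratic forms and retains a
#' higher-order term (age:sex or age^2) only when the nested F-test
#' against the linear form rejects at \code{alpha} \emph{and} both AIC and
#' BIC prefer the bigger model; on any disagreement among the three
#' criteria the model with fewer variables wins. If both bigger models
#' survive, the one with the lower BIC is kept. When the linear form is
#' retained, the sex term (and then the age term) is dropped in the same
#' conservative fashion. All tests are two-tailed at \code{alpha}.
#'
#' @inheritParams traj_glm
#' @param alpha Significance level for the nested F-tests (default 0.05).
#' @return The selected \code{traj_glm}, with attributes
#'   \code{selection} (a data.frame of the comparisons made) and
#'   \code{age_p} (p-value for the age effect in the selected model:
#'   the age term's F-test against the model without it, or the
#'   interaction-model F when the interaction is retained).
#' @export
select_model <- function(y, age, sex, alpha = 0.05) {
  if (is.character(sex)) sex <- as.numeric(sex == "male")
  f1 <- traj_glm(y, age, sex, "linear")
  comparisons <- list()
  prefer_big <- function(small, big, label) {
    ft <- nested_f_test(small, big)
    keep <- ft$p < alpha && big$aic < small$aic && big$bic < small$bic
    comparisons[[length(comparisons) + 1L]] <<- data.frame(
      comparison = label, F = ft$F, df1 = ft$df1, df2 = ft$df2,
      p = ft$p, d_aic = big$aic - small$aic, d_bic = big$bic - small$bic,
      kept_bigger = keep)
    keep
  }
  sex_varies <- length(unique(sex)) > 1
  cand <- f1
  if (sex_varies) {
    f2 <- traj_glm(y, age, sex, "interaction")
    f3 <- traj_glm(y, age, sex, "quadratic")
    keep2 <- prefer_big(f1, f2, "interaction vs linear")
    keep3 <- prefer_big(f1, f3, "quadratic vs linear")
    if (keep2 && keep3) cand <- if (f3$bic < f2$bic) f3 else f2
    else if (keep2) cand <- f2
    else if (keep3) cand <- f3
  } else {
    f3 <- traj_glm(y, age, sex, "quadratic", drop_sex = TRUE)
    f1 <- traj_glm(y, age, sex, "linear", drop_sex = TRUE)
    cand <- if (prefer_big(f1, f3, "quadratic vs linear")) f3 else f1
  }
  # within the linear form, drop non-significant main effects
  if (cand$form == "linear" && sex_varies) {
    f_nosex <- traj_glm(y, age, sex, "linear", drop_sex = TRUE)
    if (!prefer_big(f_nosex, cand, "sex term")) cand <- f_nosex
  }
  if (cand$form == "linear") {
    f_noage <- traj_glm(y, age, sex, "linear",
                        drop_age = TRUE,
                        drop_sex = !("sex" %in% cand$terms))
    if (!prefer_big(f_noage, cand, "age term")) cand <- f_noage
  }
  # p-value for the age effect in the selected model
  age_p <- if (!any(grepl("age", cand$terms))) {
    NA_real_
  } else if (cand$form == "linear") {
    smaller <- traj_glm(y, age, sex, "linear", drop_age = TRUE,
                        drop_sex = !("sex" %in% cand$terms))
    nested_f_test(smaller, cand)$p
  } else {
    # interaction/quadratic retained: age enters through several terms;
    # test against the intercept(+sex) model
    smaller <- traj_glm(y, age, sex, "linear", drop_age = TRUE,
                        drop_sex = !sex_varies)
    nested_f_test(smaller, cand)$p
  }
  attr(cand, "selection") <- do.call(rbind, comparisons)
  attr(cand, "age_p") <- age_p
  cand
}

#' Repeated-measures slope contrast between two edge classes
#'
#' Tests whether two within-subject streamline aggregates (e.g. thick
#' versus thin totals) decline at different rates over age, via the
#' difference-score regression: \eqn{d_i = A_i - B_i} is regressed on age
#' and the age coefficient's F-statistic with (1, n-2) degrees of freedom
#' tests slope equality. This is algebraically the class-by-age
#' interaction test of a long-format model with per-subject intercepts.
#'
#' @param totals_A,totals_B Per-subject class totals, same subjects, same
#'   order.
#' @param age Ages in years.
#' @param sex Optional sex indicator; when supplied and retained the
#'   difference model includes sex, changing df2 accordingly.
#' @param include_sex Include sex in the difference regression
#'   (default FALSE, giving the F(1, n-2) form).
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p} and the
#'   difference-slope estimate \code{slope_diff}.
#' @export
paired_slope_difference <- function(totals_A, totals_B, age, sex = NULL,
                                    include_sex = FALSE) {
  n <- length(totals_A)
  if (length(totals_B) != n || length(age) != n)
    stop("error: length mismatch between class totals and age")
  d <- totals_A - totals_B
  if (stats::sd(d) == 0)
    return(list(F = 0, df1 = 1, df2 = n - 2, p = 1, slope_diff = 0))
  if (include_sex && !is.null(sex)) {
    if (is.character(sex)) sex <- as.numeric(sex == "male")
    fit <- stats::lm(d ~ age + sex)
  } else {
    fit <- stats::lm(d ~ age)
  }
  sm <- summary(fit)$coefficients
  tval <- sm["age", "t value"]
  df2 <- fit$df.residual
  Fv <- tval^2
  list(F = Fv, df1 = 1, df2 = df2,
       p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
       slope_diff = sm["age", "Estimate"])
}

#' Chi-squared test of preferential streamline detachment
#'
#' Compares the observed split of streamline loss between two edge classes
#' with the split expected from class prevalence alone: under the null the
#' total loss distributes proportionally to the class edge counts. The
#' conventional observed losses are the model-predicted streamline losses
#' over the study's age span, \eqn{|\hat\beta_1|\times} span, from the
#' class-total GLM fits; see \code{\link{preferential_chi2_from_slopes}}.
#'
#' @param loss_A,loss_B Non-negative observed streamline losses per class.
#' @param n_A,n_B Class edge counts (prevalence).
#' @return List with \code{chi2}, \code{df} (= 1), \code{p}, and the
#'   expected losses \code{expected}.
#' @export
preferential_chi2 <- function(loss_A, loss_B, n_A, n_B) {
  if (loss_A < 0 || loss_B < 0) stop("error: losses must be non-negative")
  if (n_A < 1 || n_B < 1) stop("error: class edge counts must be >= 1")
  total <- loss_A + loss_B
  if (total <= 0) stop("error: total loss is zero")
  E <- total * c(n_A, n_B) / (n_A + n_B)
  if (any(E == 0)) stop("error: expected cell is zero")
  O <- c(loss_A, loss_B)
  chi2 <- sum((O - E)^2 / E)
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = E)
}

#' Preferential-detachment test from fitted class slopes
#'
#' Builds the observed losses of \code{\link{preferential_chi2}} from the
#' fitted age slopes of the two class totals: loss = |slope| x age span.
#'
#' @param slope_A,slope_B Fitted age slopes (streamlines/year) of the two
#'   class totals.
#' @param n_A,n_B Class edge counts.
#' @param age_span Width of the study age window in years (default 36,
#'   i.e. ages 4-40).
#' @return As \code{\link{preferential_chi2}}.
#' @export
preferential_chi2_from_slopes <- function(slope_A, slope_B, n_A, n_B,
                                          age_span = 36) {
  preferential_chi2(abs(slope_A) * age_span, abs(slope_B) * age_span,
                    n_A, n_B)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level \code{q}: rejects all hypotheses with
#' BH-adjusted p-value at most \code{q}.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with logical \code{rejected} and numeric \code{adjusted}
#'   (monotone BH-adjusted p-values).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("error: p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(rejected = adj <= q, adjusted = adj)
}

#' False-coverage-rate adjusted confidence intervals
#'
#' For parameters selected by an FDR procedure, ordinary marginal
#' confidence intervals undercover; the FCR adjustment widens them to
#' nominal level \eqn{1 - Rq/m} where R of m parameters were selected.
#' When all parameters are selected this reduces to the ordinary
#' \eqn{1 - q} interval.
#'
#' @param estimates,ses Point estimates and standard errors (length m).
#' @param rejected Logical selection flags (length m).
#' @param q FDR level used in selection (default 0.05).
#' @param df Degrees of freedom for the t reference (default \code{Inf},
#'   i.e. normal quantiles); recycled if scalar.
#' @return data.frame with columns \code{index}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{level} — one row per selected
#'   parameter (zero rows when none are selected).
#' @export
fcr_intervals <- function(estimates, ses, rejected, q = 0.05, df = Inf) {
  m <- length(estimates)
  stopifnot(length(ses) == m, length(rejected) == m)
  R <- sum(rejected)
  if (R == 0)
    return(data.frame(index = integer(0), estimate = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      level = numeric(0)))
  level <- 1 - R * q / m
  df <- rep_len(df, m)
  idx <- which(rejected)
  crit <- stats::qt(1 - (1 - level) / 2, df = df[idx])
  data.frame(index = idx,
             estimate = estimates[idx],
             lower = estimates[idx] - crit * ses[idx],
             upper = estimates[idx] + crit * ses[idx],
             level = level)
}

#' Edgewise developmental analysis over the common edge set
#'
#' For each edge present in every subject, fits the nested model-selection
#' procedure to its streamline count, corrects the age-effect p-values by
#' BH-FDR across edges, attaches FCR-adjusted confidence intervals for the
#' selected edges, and labels sex-specific effects: when the pooled
#' age-by-sex interaction is retained for an edge, per-sex age-only fits
#' decide whether the change is confined to one sex (\code{"male"} or
#' \code{"female"}), present in both, or in none.
#'
#' @param cohort A \code{cohort}.
#' @param edges Two-column matrix of edges (i < j), e.g. from
#'   \code{\link{common_edge_set}}; defaults to the cohort's common edges.
#' @param parc Parcellation; defaults to the cohort's.
#' @param q FDR level across edges (default 0.05).
#' @param alpha Significance level in model selection (default 0.05).
#' @return data.frame with one row per edge: ROI names, lobes, selected
#'   form, age slope/SE, raw and FDR-adjusted p, FCR interval bounds,
#'   significance flag and \code{sex_specific} in
#'   \code{\{both, male, female, none\}}.
#' @export
edgewise_age_analysis <- function(cohort, edges = common_edge_set(cohort),
                                  parc = attr(cohort, "parcellation"),
                                  q = 0.05, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(edges) == 0L) stop("error: empty edge set")
  meta <- cohort_meta(cohort)
  nE <- nrow(edges)
  Y <- vapply(cohort, function(s) s$W[edges], numeric(nE))
  if (nE == 1L) Y <- matrix(Y, nrow = 1)
  slope <- se <- rawp <- numeric(nE)
  form <- character(nE)
  sex_specific <- rep("none", nE)
  interaction_kept <- logical(nE)
  dfres <- integer(nE)
  for (e in seq_len(nE)) {
    y <- Y[e, ]
    if (stats::sd(y) == 0) {
      slope[e] <- 0; se[e] <- NA_real_; rawp[e] <- 1
      form[e] <- "constant"; dfres[e] <- length(y) - 1L
      next
    }
    fit <- select_model(y, meta$age, meta$sex01, alpha = alpha)
    form[e] <- if (any(grepl("age", fit$terms))) fit$form else "no-age"
    interaction_kept[e] <- "age:sex" %in% fit$terms
    has_age <- "age" %in% names(fit$coefficients)
    slope[e] <- if (has_age) fit$coefficients[["age"]] else 0
    se[e] <- if (has_age) fit$se[["age"]] else NA_real_
    p_age <- attr(fit, "age_p")
    rawp[e] <- if (is.na(p_age)) 1 else p_age
    dfres[e] <- fit$df_residual
  }
  fdr <- bh_fdr(rawp, q = q)
  # sex-specific labelling: per-sex age-only fits where the pooled
  # interaction was retained; significant slope in exactly one sex after
  # BH across the per-sex tests gives that sex's label
  cand <- which(interaction_kept)
  if (length(cand)) {
    ps <- matrix(1, length(cand), 2, dimnames = list(NULL, c("f", "m")))
    for (k in seq_along(cand)) {
      e <- cand[k]
      for (sx in c(0, 1)) {
        sel <- meta$sex01 == sx
        if (sum(sel) > 3 && stats::sd(Y[e, sel]) > 0) {
          f <- traj_glm(Y[e, sel], meta$age[sel], rep(0, sum(sel)),
                        "linear", drop_sex = TRUE)
          ps[k, sx + 1] <- f$p[["age"]]
        }
      }
    }
    adj <- matrix(stats::p.adjust(ps, method = "BH"), ncol = 2)
    sig <- adj <= q
    lab <- ifelse(sig[, 1] & sig[, 2], "both",
           ifelse(sig[, 1], "female",
           ifelse(sig[, 2], "male", "none")))
    sex_specific[cand] <- lab
  }
  sex_specific[!interaction_kept & fdr$rejected] <- "both"
  fcr <- fcr_intervals(slope, se, fdr$rejected & !is.na(se), q = q,
                       df = dfres)
  lower <- upper <- rep(NA_real_, nE)
  lower[fcr$index] <- fcr$lower
  upper[fcr$index] <- fcr$upper
  data.frame(
    i = edges[, 1], j = edges[, 2],
    roi_i = parc$name[edges[, 1]], roi_j = parc$name[edges[, 2]],
    lobe_i = parc$lobe[edges[, 1]], lobe_j = parc$lobe[edges[, 2]],
    form = form, slope = slope, se = se,
    p = rawp, p_fdr = fdr$adjusted, significant = fdr$rejected,
    ci_lower = lower, ci_upper = upper,
    sex_specific = sex_specific,
    stringsAsFactors = FALSE)
}

#' Nodal developmental analysis of module-role metrics
#'
#' Computes per-subject within-module strength z-scores and participation
#' coefficients (under per-subject partitions unless supplied), fits the
#' model-selection procedure per ROI and metric, and corrects across all
#' ROI-by-metric tests with BH-FDR.
#'
#' @param cohort A \code{cohort}.
#' @param partitions Optional list of per-subject partitions or a single
#'   consensus partition; detected per subject by default.
#' @param q FDR level (default 0.05).
#' @param alpha Model-selection significance level (default 0.05).
#' @param seed Seed for per-subject module detection.
#' @param n_restarts Louvain restarts per subject (default 10).
#' @return data.frame with one row per ROI and metric (2 x N rows):
#'   metric name, ROI, lobe, selected form, age slope, raw and adjusted p,
#'   significance and direction of change.
#' @export
nodal_metric_analysis <- function(cohort, partitions = NULL, q = 0.05,
                                  alpha = 0.05, seed = .default_seed,
                                  n_restarts = 10) {
  stopifnot(inherits(cohort, "cohort"))
  parc <- attr(cohort, "parcellation")
  meta <- cohort_meta(cohort)
  n <- nrow(parc)
  single <- inherits(partitions, "partition")
  wms <- pc <- matrix(0, n, length(cohort))
  for (k in seq_along(cohort)) {
    C <- cohort[[k]]
    P <- if (single) partitions
         else if (!is.null(partitions)) partitions[[k]]
         else detect_modules(C$W, seed = as.integer(seed) + k - 1L,
                             n_restarts = n_restarts)
    wms[, k] <- within_module_strength_z(C$W, P)
    pc[, k] <- participation_coefficient(C$W, P)
  }
  metric_rows <- function(M, metric) {
    slope <- rawp <- numeric(n)
    form <- character(n)
    for (i in seq_len(n)) {
      y <- M[i, ]
      if (stats::sd(y) == 0) {
        slope[i] <- 0; rawp[i] <- 1; form[i] <- "constant"; next
      }
      fit <- select_model(y, meta$age, meta$sex01, alpha = alpha)
      has_age <- "age" %in% names(fit$coefficients)
      slope[i] <- if (has_age) fit$coefficients[["age"]] else 0
      p_age <- attr(fit, "age_p")
      rawp[i] <- if (is.na(p_age)) 1 else p_age
      form[i] <- if (any(grepl("age", fit$terms))) fit$form else "no-age"
    }
    data.frame(metric = metric, roi = parc$name, lobe = parc$lobe,
               form = form, slope = slope, p = rawp,
               stringsAsFactors = FALSE)
  }
  out <- rbind(metric_rows(wms, "within_module_strength_z"),
               metric_rows(pc, "participation_coefficient"))
  fdr <- bh_fdr(out$p, q = q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$rejected
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$slope > 0, "increase", "decrease"))
  rownames(out) <- NULL
  out
}
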