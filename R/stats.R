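# Statistical machinery for the four paradigms: paired change tests,
# bivariate/partial/Bayesian correlations, 2x2 mixed ANOVA,
# repeated-measures ANOVA with sphericity correction, logistic
# regression of recognition group, and the memory-specificity analysis.
# No multiple-testing correction is applied anywhere (analyses are
# reported uncorrected); results carry their n and df.

#' Paired pre/post change test
#'
#' Paired t-test by default; `method = "auto"` switches to a Wilcoxon
#' signed-rank test (normal approximation, tie/zero handling) when a
#' Shapiro-Wilk check on the difference scores rejects normality at
#' `shapiro_alpha`. Effect size is Cohen's d (mean difference / SD of
#' differences) for the t-test and r = Z/sqrt(N) for Wilcoxon.
#'
#' @param pre,post equal-length numeric vectors (n >= 3), matched by
#'   observer.
#' @param method `"auto"`, `"t"` or `"wilcoxon"`.
#' @param shapiro_alpha alpha of the normality gate for `"auto"`.
#' @return one-row data.frame: `statistic`, `p`, `effect`, `test`, `n`.
#'   When all differences are exactly zero the Wilcoxon convention is
#'   Z = 0, p = 1; constant non-zero differences are a zero-variance
#'   error.
#' @export
paired_change_test <- function(pre, post, method = c("auto", "t", "wilcoxon"),
                               shapiro_alpha = 0.05) {
  method <- match.arg(method)
  if (length(pre) != length(post)) stop_domain("pre/post length mismatch")
  n <- length(pre)
  if (n < 3) stop_domain("need at least 3 pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (method == "wilcoxon" && all(d == 0)) {
      return(data.frame(statistic = 0, p = 1, effect = 0,
                        test = "wilcoxon", n = n))
    }
    stop_domain("zero-variance differences: change test undefined")
  }
  if (method == "auto") {
    method <- if (stats::shapiro.test(d)$p.value < shapiro_alpha)
      "wilcoxon" else "t"
  }
  if (method == "t") {
    tt <- stats::t.test(post, pre, paired = TRUE)
    data.frame(statistic = unname(tt$statistic), p = tt$p.value,
               effect = mean(d) / stats::sd(d), test = "paired_t", n = n)
  } else {
    dz <- d[d != 0]
    m <- length(dz)
    if (m == 0) return(data.frame(statistic = 0, p = 1, effect = 0,
                                  test = "wilcoxon", n = n))
    rk <- rank(abs(dz))
    w_pos <- sum(rk[dz > 0])
    mu <- m * (m + 1) / 4
    ties <- table(rk)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    data.frame(statistic = z, p = 2 * stats::pnorm(-abs(z)),
               effect = z / sqrt(n), test = "wilcoxon", n = n)
  }
}

# Jeffreys likelihood for a correlation: marginal density of the data
# as a function of the population correlation rho, up to a factor
# independent of rho. L(0) = 1.
.corr_likelihood <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) / (1 - rho * r)^(n - 3 / 2)
}

#' One-sided Bayes factor for a positive correlation
#'
#' Numerical integration of the Jeffreys correlation likelihood under a
#' stretched-beta prior of width 1 on rho (uniform on (-1, 1)),
#' truncated to rho > 0: `BF10+ = \int_0^1 L(rho) drho / L(0)`. Values
#' below 1 favour the null.
#'
#' @param r observed correlation.
#' @param n sample size (>= 4).
#' @param rel_tol integration tolerance.
#' @return scalar Bayes factor.
#' @export
bf10_corr_onesided <- function(r, n, rel_tol = 1e-8) {
  if (n < 4) stop_domain("need n >= 4 for the Bayes factor")
  2 * stats::integrate(function(rho) .corr_likelihood(rho, r, n) * 0.5,
                       0, 1, rel.tol = rel_tol)$value
}

#' Bivariate or partial association
#'
#' Pearson or Spearman correlation, optionally partial: both variables
#' (and the covariates) are residualized against the covariate matrix
#' and the correlation of the residuals is tested on n - 2 - k degrees
#' of freedom. Spearman rank-transforms *before* residualizing
#' (rank-then-residualize). p-values use the t approximation
#' `t = r * sqrt(df / (1 - r^2))`. Optionally adds the one-sided Bayes
#' factor for a positive association ([bf10_corr_onesided()]).
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @param covariates optional data.frame/matrix of covariates (full
#'   rank).
#' @param onesided_bayes logical; compute BF10 for rho > 0.
#' @return one-row data.frame: `r`, `p`, `method`, `partial`, `n`,
#'   `df`, `bf10_onesided` (NA unless requested).
#' @export
association <- function(x, y, method = c("pearson", "spearman"),
                        covariates = NULL, onesided_bayes = FALSE) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop_domain("x/y length mismatch")
  if (n < 4) stop_domain("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_domain(
    "constant input: correlation undefined")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (!is.null(covariates))
      covariates <- apply(as.matrix(covariates), 2, rank)
  }
  k <- 0
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (nrow(cv) != n) stop_domain("covariate length mismatch")
    if (qr(cbind(1, cv))$rank < ncol(cv) + 1) stop_domain(
      "covariate matrix is rank-deficient")
    k <- ncol(cv)
    x <- stats::resid(stats::lm.fit(cbind(1, cv), x))
    y <- stats::resid(stats::lm.fit(cbind(1, cv), y))
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  bf <- if (onesided_bayes) bf10_corr_onesided(r, n - k) else NA_real_
  data.frame(r = r, p = p, method = method, partial = k > 0, n = n,
             df = df, bf10_onesided = bf)
}

#' 2 x 2 mixed ANOVA (between group x within phase)
#'
#' The exact decomposition for one between factor and one two-level
#' within factor: the between-group effect is tested on subject means,
#' the within (phase) main effect and the interaction on subject
#' difference scores with sum-to-zero group coding (so the phase effect
#' is the unweighted mean of group mean changes — the Type III
#' convention under imbalance).
#'
#' @param outcome numeric vector (long format).
#' @param group between-subjects factor (2 levels).
#' @param phase within-subjects factor (2 levels; the second level minus
#'   the first defines the change).
#' @param id subject identifier.
#' @return data.frame with rows `group`, `phase`, `group:phase`:
#'   `F`, `df1`, `df2`, `p`, `eta_p2`.
#' @export
mixed_anova_2x2 <- function(outcome, group, phase, id) {
  group <- factor(group); phase <- factor(phase); id <- factor(id)
  if (nlevels(group) != 2 || nlevels(phase) != 2) stop_domain(
    "group and phase must each have exactly 2 levels")
  tab <- table(unique(data.frame(id, group))$group)
  if (any(tab < 2)) stop_domain(
    "empty or singleton cell: each group needs >= 2 subjects")
  wide <- stats::reshape(
    data.frame(outcome, phase, id), direction = "wide",
    idvar = "id", timevar = "phase", v.names = "outcome")
  if (any(is.na(wide))) stop_domain("incomplete within-subject data")
  g <- factor(vapply(as.character(wide$id), function(i)
    as.character(group[id == i][1]), ""))
  y1 <- wide[[paste0("outcome.", levels(phase)[1])]]
  y2 <- wide[[paste0("outcome.", levels(phase)[2])]]
  means <- (y1 + y2) / 2
  diffs <- y2 - y1
  n <- length(means)
  res <- function(fit, which) {
    s <- summary(fit)$coefficients
    tv <- s[which, "t value"]
    if (is.nan(tv)) tv <- 0 # zero effect with zero error variance
    Fv <- tv^2
    df2 <- fit$df.residual
    data.frame(F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               eta_p2 = Fv / (Fv + df2))
  }
  gc_ <- g; stats::contrasts(gc_) <- stats::contr.sum(2)
  fit_b <- stats::lm(means ~ gc_)
  fit_w <- stats::lm(diffs ~ gc_)
  out <- rbind(res(fit_b, 2), res(fit_w, 1), res(fit_w, 2))
  cbind(effect = c("group", "phase", "group:phase"), out)
}

# orthonormal polynomial contrast matrix for q levels (q-1 x q)
.ortho_contrasts <- function(q) t(stats::contr.poly(q))

# Greenhouse-Geisser epsilon for an effect with contrast matrix C
# applied to the n x m matrix of within-cell scores.
.gg_epsilon <- function(scores, C) {
  S <- stats::cov(scores)
  D <- C %*% S %*% t(C)
  sum(diag(D))^2 / (nrow(D) * sum(D^2))
}

#' Two-factor repeated-measures ANOVA with sphericity correction
#'
#' Fully within-subjects two-factor ANOVA (e.g. exposure 2 x block 8)
#' on a complete long-format table. Each effect is tested against its
#' own subject-by-effect error term; degrees of freedom are multiplied
#' by the Greenhouse-Geisser epsilon (Huynh-Feldt behind the
#' `correction` flag), giving the fractional dfs such designs report.
#' A linear-trend contrast over the levels of `factor_b` (on subject
#' scores collapsed over `factor_a`) is appended as row
#' `"<factor_b>_linear"`.
#'
#' @param outcome numeric vector (long format).
#' @param factor_a,factor_b within-subject factors.
#' @param id subject identifier.
#' @param correction `"greenhouse_geisser"` (default), `"huynh_feldt"`
#'   or `"none"`.
#' @return data.frame with rows for both main effects, the interaction
#'   and the linear trend: `F`, `df1`, `df2` (corrected, possibly
#'   fractional), `epsilon`, `p`, `eta_p2`.
#' @export
rm_anova <- function(outcome, factor_a, factor_b, id,
                     correction = c("greenhouse_geisser", "huynh_feldt",
                                    "none")) {
  correction <- match.arg(correction)
  A <- factor(factor_a); B <- factor(factor_b); S <- factor(id)
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  if (any(table(A, B, S) != 1)) stop_domain(
    "incomplete within-subject table: need exactly one observation per cell")
  Y <- array(0, c(n, a, b))
  Y[cbind(as.integer(S), as.integer(A), as.integer(B))] <- outcome
  M <- mean(Y)
  Am <- apply(Y, 2, mean); Bm <- apply(Y, 3, mean)
  Sm <- apply(Y, 1, mean)
  SAm <- apply(Y, c(1, 2), mean); SBm <- apply(Y, c(1, 3), mean)
  ABm <- apply(Y, c(2, 3), mean)
  ss_a <- n * b * sum((Am - M)^2)
  ss_as <- b * sum(sweep(sweep(SAm, 2, Am), 1, Sm - M)^2)
  ss_b <- n * a * sum((Bm - M)^2)
  ss_bs <- a * sum(sweep(sweep(SBm, 2, Bm), 1, Sm - M)^2)
  ss_ab <- n * sum((sweep(sweep(ABm, 1, Am), 2, Bm) + M)^2)
  resid <- Y
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    resid[i, j, k] <- Y[i, j, k] - ABm[j, k] - SAm[i, j] - SBm[i, k] +
      Am[j] + Bm[k] + Sm[i] - M
  ss_abs <- sum(resid^2)
  eff <- function(name, ss, df1, ss_err, df2, eps) {
    Fv <- (ss / df1) / (ss_err / df2)
    data.frame(effect = name, F = Fv, df1 = eps * df1, df2 = eps * df2,
               epsilon = eps,
               p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
               eta_p2 = ss / (ss + ss_err))
  }
  Ca <- .ortho_contrasts(a); Cb <- .ortho_contrasts(b)
  eps_for <- function(scores, C, df1) {
    gg <- min(.gg_epsilon(scores, C), 1)
    if (correction == "none") return(1)
    if (correction == "huynh_feldt") {
      hf <- (n * df1 * gg - 2) / (df1 * (n - 1 - df1 * gg))
      return(min(hf, 1))
    }
    gg
  }
  # n x (a*b) cell matrix, column order (j, k) with k varying fastest
  cells <- matrix(0, n, a * b)
  for (j in 1:a) for (k in 1:b) cells[, (j - 1) * b + k] <- Y[, j, k]
  Cab <- kronecker(Ca, Cb)
  out <- rbind(
    eff("factor_a", ss_a, a - 1, ss_as, (a - 1) * (n - 1),
        eps_for(SAm, Ca, a - 1)),
    eff("factor_b", ss_b, b - 1, ss_bs, (b - 1) * (n - 1),
        eps_for(SBm, Cb, b - 1)),
    eff("factor_a:factor_b", ss_ab, (a - 1) * (b - 1), ss_abs,
        (a - 1) * (b - 1) * (n - 1),
        eps_for(cells, Cab, (a - 1) * (b - 1))))
  # linear trend over factor_b on subject scores collapsed over factor_a
  w <- stats::contr.poly(b)[, 1]
  L <- SBm %*% w
  tval <- mean(L) / (stats::sd(L) / sqrt(n))
  Fv <- tval^2
  out <- rbind(out, data.frame(
    effect = "factor_b_linear", F = Fv, df1 = 1, df2 = n - 1,
    epsilon = 1, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
    eta_p2 = Fv / (Fv + (n - 1))))
  rownames(out) <- NULL
  out
}

#' Logistic regression of recognition group
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of a
#' binary recognition outcome on one or more predictors, reporting Wald
#' z and p, odds ratios and 95% Wald confidence intervals. Perfect or
#' quasi-perfect separation aborts with an error naming the offending
#' predictor.
#'
#' @param recognized logical (or 0/1) outcome with both classes present,
#'   n >= 20.
#' @param predictors data.frame of numeric predictors.
#' @return data.frame, one row per coefficient: `term`, `estimate`,
#'   `z`, `p`, `OR`, `ci_lo`, `ci_hi`, plus attribute `n`.
#' @export
logistic_recognition <- function(recognized, predictors) {
  y <- as.integer(recognized)
  n <- length(y)
  if (n < 20) stop_domain("need n >= 20")
  if (length(unique(y)) < 2) stop_domain(
    "outcome must contain both recognizers and non-recognizers")
  predictors <- as.data.frame(predictors)
  dat <- cbind(.y = y, predictors)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep_warned || any(abs(co[-1, "Estimate"] *
                              apply(predictors, 2, stats::sd)) > 15)) {
    std <- abs(co[-1, "Estimate"]) * apply(predictors, 2, stats::sd)
    stop_domain("perfect separation detected on predictor '%s'",
                names(predictors)[which.max(std)])
  }
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  out <- data.frame(term = rownames(co), estimate = est,
                    z = co[, "z value"], p = co[, "Pr(>|z|)"],
                    OR = exp(est), ci_lo = exp(est - 1.959964 * se),
                    ci_hi = exp(est + 1.959964 * se),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}

#' Per-observer memory scores
#'
#' Collapses a Remember/Know/New response table into the three scores
#' the specificity analysis needs: Remember count for hidden words,
#' endorsement (R or K) of lure items (matched and NART-style foils),
#' and endorsement of NART words.
#'
#' @param responses data.frame from [simulate_memory()] (columns
#'   `participant`, `category`, `response`).
#' @return data.frame: `participant`, `hidden_r`, `lure_endorse`,
#'   `nart_mem`.
#' @export
memory_scores <- function(responses) {
  if (!all(c("hidden", "matched_foil", "nart", "nart_foil") %in%
             responses$category)) stop_domain(
    "responses are missing memory-list categories")
  sp <- split(responses, responses$participant)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    participant = d$participant[1],
    hidden_r = sum(d$category == "hidden" & d$response == "R"),
    lure_endorse = sum(d$category %in% c("matched_foil", "nart_foil") &
                         d$response != "N"),
    nart_mem = sum(d$category == "nart" & d$response != "N"),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Memory-specificity correlation set
#'
#' Spearman correlations of auditory hallucination-proneness with
#' (i) Remember counts for hidden words, (ii) lure endorsement,
#' (iii) NART-word memory, plus the partial correlation of (i)
#' controlling for NART. The dissociation expected under the
#' naive-listening account is (i) positive with (ii) and (iii) null.
#'
#' @param cohort data.frame with `id`, `lshs_a`, `nart`.
#' @param responses Remember/Know/New table ([simulate_memory()]).
#' @return data.frame of [association()] rows with an `outcome` label
#'   column.
#' @export
memory_analysis <- function(cohort, responses) {
  sc <- memory_scores(responses)
  m <- merge(cohort, sc, by.x = "id", by.y = "participant")
  rows <- rbind(
    cbind(outcome = "hidden_r",
          association(m$lshs_a, m$hidden_r, "spearman")),
    cbind(outcome = "lure_endorse",
          association(m$lshs_a, m$lure_endorse, "spearman")),
    cbind(outcome = "nart_mem",
          association(m$lshs_a, m$nart_mem, "spearman")),
    cbind(outcome = "hidden_r_partial_nart",
          association(m$lshs_a, m$hidden_r, "spearman",
                      covariates = m["nart"])))
  rownames(rows) <- NULL
  rows
}
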