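test_that("paired change test matches a hand computation on toy data", {
  pre <- c(1.2, 0.8, 1.5, 1.1, 0.9, 1.3)
  post <- c(1.9, 1.1, 2.2, 1.4, 1.5, 1.8)
  res <- paired_change_test(pre, post, method = "t")
  # textbook computation: t = mean(d) / (sd(d)/sqrt(n)), df = n - 1
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  p_hand <- 2 * pt(-abs(t_hand), 5)
  expect_equal(res$statistic, t_hand, tolerance = 1e-6)
  expect_equal(res$p, p_hand, tolerance = 1e-6)
  expect_equal(res$effect, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$test, "paired_t")
})

test_that("degenerate difference scores are handled per convention", {
  x <- c(1, 2, 3, 4)
  expect_error(paired_change_test(x, x + 1), "zero-variance")
  res <- paired_change_test(x, x, method = "wilcoxon")
  expect_equal(res$p, 1)
  expect_equal(res$statistic, 0)
})

test_that("the auto gate reroutes non-normal differences to Wilcoxon", {
  set.seed(5)
  pre <- rnorm(40)
  post_skew <- pre + exp(rnorm(40, sd = 1.5)) # heavily skewed changes
  expect_equal(paired_change_test(pre, post_skew)$test, "wilcoxon")
  post_norm <- pre + rnorm(40, 0.5, 0.3)
  expect_equal(paired_change_test(pre, post_norm)$test, "paired_t")
  # Wilcoxon Z agrees with the normal-approximation wilcox.test
  w <- paired_change_test(pre, post_skew, method = "wilcoxon")
  ref <- wilcox.test(post_skew, pre, paired = TRUE, exact = FALSE,
                     correct = FALSE)
  expect_equal(2 * pnorm(-abs(w$statistic)), ref$p.value, tolerance = 1e-9)
  expect_equal(w$effect, w$statistic / sqrt(40))
})

test_that("association recovers exact and null relations", {
  x <- 1:20
  expect_equal(association(x, x)$r, 1)
  expect_equal(association(x, -x, "spearman")$r, -1)
  expect_error(association(rep(1, 10), 1:10), "constant")
  # plain Pearson agrees with cor.test
  set.seed(2)
  a <- rnorm(30); b <- a + rnorm(30)
  ct <- cor.test(a, b)
  res <- association(a, b)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
})

test_that("partial correlation residualizes both sides against covariates", {
  set.seed(3)
  z <- rnorm(50)
  x <- z + rnorm(50, sd = 0.5)
  y <- z + rnorm(50, sd = 0.5)
  plain <- association(x, y)
  part <- association(x, y, covariates = data.frame(z = z))
  expect_lt(abs(part$r), abs(plain$r)) # shared cause explained away
  expect_equal(part$df, 50 - 3)
  # oracle: correlation of lm residuals with the partial-df t test
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  r_hand <- cor(rx, ry)
  t_hand <- r_hand * sqrt(47 / (1 - r_hand^2))
  expect_equal(part$r, r_hand, tolerance = 1e-12)
  expect_equal(part$p, 2 * pt(-abs(t_hand), 47), tolerance = 1e-12)
  expect_error(association(x, y, covariates = cbind(z, z)),
               "rank-deficient")
})

test_that("the one-sided correlation Bayes factor behaves like a Bayes factor", {
  # near-zero observed correlation: data favour the null
  expect_lt(bf10_corr_onesided(0.02, 60), 1)
  # strong positive correlation: overwhelming evidence
  expect_gt(bf10_corr_onesided(0.6, 60), 100)
  # negative correlation under a positive-only prior: strong null support
  expect_lt(bf10_corr_onesided(-0.4, 60), bf10_corr_onesided(0, 60))
  # oracle: direct trapezoid integration of the Jeffreys likelihood
  r <- 0.25; n <- 40
  rho <- seq(0, 1 - 1e-9, length.out = 200001)
  lik <- (1 - rho^2)^((n - 1) / 2) / (1 - rho * r)^(n - 3 / 2)
  bf_trap <- mean(lik[-1] + lik[-length(lik)]) / 2
  expect_equal(bf10_corr_onesided(r, n), bf_trap, tolerance = 1e-5)
})

test_that("correlation test keeps its nominal type-I error", {
  set.seed(11)
  rej <- mean(replicate(1000, {
    association(rnorm(60), rnorm(60))$p < 0.05
  }))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("2x2 mixed ANOVA matches aov on balanced data", {
  set.seed(7)
  n <- 20
  id <- rep(sprintf("s%02d", 1:n), each = 2)
  group <- rep(rep(c("a", "b"), each = n / 2), each = 2)
  phase <- rep(c("pre", "post"), n)
  y <- rnorm(2 * n) + (group == "a") * 0.5 + (phase == "post") * 0.8 +
    (group == "a" & phase == "post") * 0.4
  res <- mixed_anova_2x2(y, group, phase, id)
  fit <- summary(aov(y ~ group * phase + Error(factor(id) / phase)))
  Fb <- fit[["Error: factor(id)"]][[1]]["group", "F value"]
  Fw <- fit[["Error: factor(id):phase"]][[1]][c("phase", "group:phase"),
                                              "F value"]
  expect_equal(res$F, unname(c(Fb, Fw)), tolerance = 1e-6)
  expect_true(all(res$df1 == 1) && all(res$df2 == n - 2))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("phase-constant outcomes give a null phase effect", {
  n <- 12
  id <- rep(1:n, each = 2)
  group <- rep(rep(c("a", "b"), each = n / 2), each = 2)
  phase <- rep(c("pre", "post"), n)
  y <- rep(rnorm(n), each = 2) # identical across phase
  res <- mixed_anova_2x2(y, group, phase, id)
  expect_equal(res$F[res$effect == "phase"], 0, tolerance = 1e-12)
  expect_error(mixed_anova_2x2(y[group == "a"], group[group == "a"],
                               phase[group == "a"], id[group == "a"]),
               "2 levels")
})

test_that("mixed-ANOVA interaction keeps its type-I error under permutation", {
  set.seed(13)
  n <- 24
  id <- rep(1:n, each = 2)
  phase <- rep(c("pre", "post"), n)
  y <- rnorm(2 * n)
  rej <- mean(replicate(400, {
    g <- rep(sample(rep(c("a", "b"), each = n / 2)), each = 2)
    res <- mixed_anova_2x2(y, g, phase, id)
    res$p[res$effect == "group:phase"] < 0.05
  }))
  expect_gt(rej, 0.025); expect_lt(rej, 0.08)
})

test_that("repeated-measures ANOVA with GG correction matches car", {
  set.seed(17)
  n <- 20
  dat <- expand.grid(id = 1:n, exposure = c("pre", "post"), block = 1:4)
  dat$y <- rnorm(nrow(dat)) + as.numeric(dat$block) * 0.2 +
    (dat$exposure == "post") * 0.5
  res <- rm_anova(dat$y, dat$exposure, dat$block, dat$id)
  # independent route: car::Anova on the multivariate lm;
  # build the n x 8 response matrix in (exposure, block) order
  M <- matrix(0, n, 8)
  k <- 0
  for (e in c("pre", "post")) for (b in 1:4) {
    k <- k + 1
    M[, k] <- dat$y[dat$exposure == e & dat$block == b][order(
      dat$id[dat$exposure == e & dat$block == b])]
  }
  idata <- expand.grid(block = factor(1:4), exposure = factor(c("pre", "post")))
  idata <- idata[, c("exposure", "block")]
  fit <- car::Anova(lm(M ~ 1), idata = idata,
                    idesign = ~ exposure * block, type = 3)
  s <- suppressWarnings(summary(fit, multivariate = FALSE))
  uni <- s$univariate.tests
  expect_equal(res$F[1], uni["exposure", "F value"], tolerance = 1e-8)
  expect_equal(res$F[2], uni["block", "F value"], tolerance = 1e-8)
  expect_equal(res$F[3], uni["exposure:block", "F value"], tolerance = 1e-8)
  gg <- s$pval.adjustments
  expect_equal(res$epsilon[2], unname(gg["block", "GG eps"]), tolerance = 1e-8)
  expect_equal(res$epsilon[3], unname(gg["exposure:block", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(res$p[3], unname(gg["exposure:block", "Pr(>F[GG])"]),
               tolerance = 1e-8)
  # a two-level factor is always spherical: epsilon = 1, df uncorrected
  expect_equal(res$epsilon[1], 1)
  expect_equal(res$df1[1], 1)
  expect_error(rm_anova(dat$y[-1], dat$exposure[-1], dat$block[-1],
                        dat$id[-1]), "incomplete")
})

test_that("linear block trends dominate when block means are exactly linear", {
  n <- 15; b <- 8
  dat <- expand.grid(id = 1:n, exposure = c("pre", "post"), block = 1:b)
  set.seed(19)
  dat$y <- 0.3 * as.numeric(dat$block) + rnorm(nrow(dat), sd = 0.2)
  res <- rm_anova(dat$y, dat$exposure, dat$block, dat$id)
  expect_gt(res$F[res$effect == "factor_b_linear"],
            res$F[res$effect == "factor_b"])
  expect_true(all(res$df1 > 0 & res$df2 > 0))
})

test_that("logistic recognition model matches the contingency-table odds ratio", {
  # 20/30 recognizers among high-trait, 10/30 among low-trait
  rec <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  hi <- c(rep(1, 30), rep(0, 30))
  res <- logistic_recognition(rec, data.frame(hi = hi))
  expect_equal(res$OR[2], (20 * 20) / (10 * 10), tolerance = 1e-6)
  # label swap inverts the odds ratio exactly
  res2 <- logistic_recognition(1 - rec, data.frame(hi = hi))
  expect_equal(res$OR[2] * res2$OR[2], 1, tolerance = 1e-9)
  expect_true(res$ci_lo[2] < res$ci_hi[2])
  # intercept-only at 50:50: intercept near zero
  res3 <- logistic_recognition(rep(0:1, 25), data.frame(x = rnorm(50)))
  expect_lt(abs(res3$estimate[1]), 0.5)
  expect_error(logistic_recognition(rep(1, 30), data.frame(x = rnorm(30))),
               "both")
})

test_that("perfect separation is detected and named", {
  x <- c(rnorm(15, -3), rnorm(15, 3))
  y <- as.integer(x > 0)
  expect_error(logistic_recognition(y, data.frame(sep_var = x, ok = rnorm(30))),
               "sep_var")
})

test_that("the recognition effect is detectable at the study's sample size", {
  set.seed(23)
  hits <- replicate(300, {
    p <- scenario_params("naive", n = 134,
                         seed = sample.int(1e6, 1))
    co <- simulate_naive_listening(sample_cohort(p), p,
                                   seed = sample.int(1e6, 1))
    if (sum(co$recognized) < 5 || sum(!co$recognized) < 5) return(NA)
    res <- logistic_recognition(co$recognized, co["lshs_a"])
    res$OR[2] > 1 && res$p[2] < 0.05
  })
  expect_gt(mean(hits, na.rm = TRUE), 0.8)
})

test_that("memory analysis shows the hidden-word dissociation only when present", {
  p <- scenario_params("naive", n = 5000, seed = 51)
  co <- simulate_naive_listening(sample_cohort(p), p, seed = 8)
  e3 <- build_exp3_design(6)
  mem <- simulate_memory(co, e3$memory, p, seed = 9)
  ma <- memory_analysis(co, mem)
  get <- function(o) ma[ma$outcome == o, ]
  expect_gt(get("hidden_r")$r, 0.15)
  expect_lt(get("hidden_r")$p, 0.001)
  expect_lt(abs(get("lure_endorse")$r), 0.05)
  expect_lt(abs(get("nart_mem")$r), 0.05)
  expect_true(get("hidden_r_partial_nart")$partial)
  # no decoding signal: hidden-word correlation collapses to null
  p0 <- scenario_params("naive", n = 5000, q_encode = 0.05, r_base = 0.05,
                        seed = 52)
  co0 <- simulate_naive_listening(sample_cohort(p0), p0, seed = 10)
  mem0 <- simulate_memory(co0, e3$memory, p0, seed = 11)
  ma0 <- memory_analysis(co0, mem0)
  expect_lt(abs(ma0$r[ma0$outcome == "hidden_r"]), 0.05)
  # constant questionnaire scores are an error, not a silent NA
  co$lshs_a <- 10L
  expect_error(memory_analysis(co, mem), "constant")
})
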