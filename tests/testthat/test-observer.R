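test_that("cohorts are reproducible and parameter validation names fields", {
  p <- cohort_params(n = 50, seed = 7)
  expect_identical(sample_cohort(p), sample_cohort(p))
  p2 <- cohort_params(n = 50, seed = 8)
  expect_false(identical(sample_cohort(p), sample_cohort(p2)))
  err <- tryCatch(cohort_params(n = 1, q_encode = 2, noise_sd = -1),
                  error = conditionMessage)
  expect_match(err, "n \\(must be >= 2\\)")
  expect_match(err, "q_encode")
  expect_match(err, "noise_sd")
})

test_that("trait-change coupling follows the generative model's closed form", {
  # null coupling: trait and latent change are uncorrelated
  p0 <- cohort_params(n = 10000, gamma_mod = 0, seed = 21)
  co0 <- sample_cohort(p0)
  expect_lt(abs(cor(co0$trait_h, co0$dprime_post - co0$dprime_pre)), 0.03)
  # gamma_mod = 0.3, noise_sd = 0.3: the post increment is
  # gain + gamma*trait + e2, so corr = gamma / sqrt(gamma^2 + sd^2)
  p1 <- cohort_params(n = 10000, gamma_mod = 0.3, noise_sd = 0.3, seed = 22)
  co1 <- sample_cohort(p1)
  expect_equal(cor(co1$trait_h, co1$dprime_post - co1$dprime_pre),
               0.3 / sqrt(0.09 + 0.09), tolerance = 0.05)
})

test_that("questionnaire scores are monotone in the latent trait and in range", {
  co <- sample_cohort(cohort_params(n = 10000, seed = 13))
  expect_true(all(co$lshs_a >= 5 & co$lshs_a <= 20))
  bins <- cut(co$trait_h, stats::quantile(co$trait_h, 0:5 / 5),
              include.lowest = TRUE)
  expect_true(all(diff(tapply(co$lshs_a, bins, mean)) >= 0))
  expect_true(all(diff(tapply(co$caps_freq, bins, mean)) >= 0))
  expect_true(all(co$caps_freq >= 0 & co$pdi_freq >= 0))
  # NART independent of the trait by default
  expect_lt(abs(cor(co$trait_h, co$nart)), 0.03)
  co_r <- sample_cohort(cohort_params(n = 10000, rho_nart = 0.5, seed = 13))
  expect_equal(cor(co_r$trait_h, co_r$nart), 0.5, tolerance = 0.05)
})

test_that("discrimination responses follow the SDT response model", {
  mk_obs <- function(d, c_, n = 1) data.frame(
    id = sprintf("o%d", seq_len(n)), trait_h = 0, lshs_a = 10,
    caps_freq = 0, pdi_freq = 0, nart = 35,
    dprime_pre = d, dprime_post = d, criterion = c_)
  # chance observer: yes-rate 0.5 for both kinds
  cnt <- simulate_detection_counts(mk_obs(0, 0), 10000, 10000, "pre", seed = 1)
  expect_equal(cnt$hits / 10000, 0.5, tolerance = 0.02)
  expect_equal(cnt$false_alarms / 10000, 0.5, tolerance = 0.02)
  # conservative criterion c = +1 with d' = 0: yes-rate ~ pnorm(-1)
  cnt1 <- simulate_detection_counts(mk_obs(0, 1), 10000, 10000, "pre", seed = 2)
  expect_equal(cnt1$hits / 10000, pnorm(-1), tolerance = 0.05)
  expect_equal(cnt1$false_alarms / 10000, pnorm(-1), tolerance = 0.05)
  # trial-level and count-level simulators share the response model
  obs <- mk_obs(1.5, 0.2)
  resp <- simulate_discrimination(obs, build_exp1_design(1), seed = 3)
  expect_equal(nrow(resp), 180)
  expect_true(all(resp$said_speech %in% 0:1))
  expect_identical(resp, simulate_discrimination(obs, build_exp1_design(1),
                                                 seed = 3))
})

test_that("d' and criterion are recovered from simulated 90-trial runs", {
  n <- 500
  co <- data.frame(id = sprintf("o%03d", 1:n), trait_h = 0, lshs_a = 10,
                   caps_freq = 0, pdi_freq = 0, nart = 35,
                   dprime_pre = 1.5, dprime_post = 1.5, criterion = 0)
  cnt <- simulate_detection_counts(co, 45, 45, "pre", seed = 5)
  o <- sdt_outcome(cnt$hits, 45, cnt$false_alarms, 45)
  expect_equal(mean(o$d_prime), 1.5, tolerance = 0.1)
  expect_equal(mean(o$criterion_c), 0, tolerance = 0.05)
})

test_that("spontaneous recognition follows the logistic trait model", {
  p <- cohort_params(n = 10000, gamma_naive = 0, beta_nart = 0,
                     alpha_naive = 0.5, seed = 31)
  co <- simulate_naive_listening(sample_cohort(p), p, seed = 4)
  expect_equal(mean(co$recognized), plogis(0.5), tolerance = 0.015)
  expect_true(all(co$recognition_block[co$recognized] %in% 1:6))
  expect_true(all(is.na(co$recognition_block[!co$recognized])))
  p2 <- cohort_params(n = 10000, gamma_naive = 1, seed = 32)
  co2 <- simulate_naive_listening(sample_cohort(p2), p2, seed = 5)
  expect_gt(mean(co2$trait_h[co2$recognized]),
            mean(co2$trait_h[!co2$recognized]))
  # recognition tends to come earlier for higher-trait observers
  blk <- co2$recognition_block[co2$recognized]
  expect_lt(cor(co2$trait_h[co2$recognized], blk), 0)
})

test_that("memory responses saturate and stay flat where the model says so", {
  e3 <- build_exp3_design(3)
  base <- cohort_params(n = 2, seed = 1)
  co <- sample_cohort(base)
  # non-recognizer with zero base rates: no Remember responses at all
  p0 <- cohort_params(n = 2, r_base = 0, k_rate = 0, fa_lure = 0,
                      m_nart = 0, seed = 1)
  co$recognized <- FALSE; co$recognition_block <- NA_integer_
  m0 <- simulate_memory(co, e3$memory, p0, seed = 2)
  expect_equal(sum(m0$response != "N"), 0)
  # block-1 recognizer with q_encode = 1 remembers all 18 hidden words
  p1 <- cohort_params(n = 2, q_encode = 1, r_base = 0, k_rate = 0,
                      fa_lure = 0, m_nart = 0, seed = 1)
  co$recognized <- TRUE; co$recognition_block <- 1L
  m1 <- simulate_memory(co, e3$memory, p1, seed = 3)
  expect_equal(sum(m1$response == "R" & m1$category == "hidden"), 36) # 2 obs
  expect_true(all(m1$response[m1$category != "hidden"] == "N"))
  expect_error(simulate_memory(co, e3$memory[1:10, ], p1, seed = 1),
               "valid memory list")
})

test_that("foil endorsement is independent of the trait", {
  p <- scenario_params("naive", n = 10000, seed = 41)
  co <- simulate_naive_listening(sample_cohort(p), p, seed = 6)
  e3 <- build_exp3_design(4)
  mem <- simulate_memory(co, e3$memory, p, seed = 7)
  sc <- memory_scores(mem)
  m <- merge(co, sc, by.x = "id", by.y = "participant")
  expect_lt(abs(cor(m$trait_h, m$lure_endorse)), 0.03)
})
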