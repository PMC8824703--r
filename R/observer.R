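# Latent-trait generative model of listener cohorts. One standard-normal
# latent trait (hallucination-proneness) drives, with separately
# switchable couplings, (i) the exposure-related change in
# discrimination ("modulation" route) and (ii) spontaneous recognition
# of speech in degraded stimuli ("naive listening" route); questionnaire
# scores are monotone noisy transforms of the same trait. All randomness
# descends from one root seed via derive_seed() sub-streams.

#' Cohort-generator parameters
#'
#' Defaults encode the study conditions the package's paradigms assume:
#' baseline sensitivity near d' = 1.5 improving by ~0.7 after template
#' exposure (the magnitudes the one-shot paradigm reports), a mildly
#' conservative criterion, no trait coupling anywhere (a pure null
#' cohort). Scenario presets ([scenario_params()]) switch on the
#' modulation or naive-listening couplings.
#'
#' @param n number of observers (>= 2).
#' @param mu_dprime_pre mean pre-exposure sensitivity (z-units).
#' @param exposure_gain mean post - pre shift in d' (z-units).
#' @param gamma_pre trait coupling onto baseline d' (z-units per
#'   trait SD).
#' @param gamma_mod trait coupling onto the exposure gain (z-units per
#'   trait SD); the "modulation of expectation" effect.
#' @param noise_sd SD of the observer-level noise added independently to
#'   the pre equation and to the post increment (z-units).
#' @param mu_criterion,sd_criterion mean and SD of the response
#'   criterion c (z-units).
#' @param alpha_naive intercept of the recognition model (log-odds).
#' @param gamma_naive trait coupling onto spontaneous recognition
#'   (log-odds per trait SD); the "naive listening" effect.
#' @param beta_nart NART coupling onto recognition (log-odds per NART
#'   point, centred).
#' @param block_p base success probability of the truncated-geometric
#'   recognition-block distribution (blocks 1-6; mode early).
#' @param block_gamma trait coupling onto the block distribution's
#'   success probability (log-odds per trait SD; earlier recognition for
#'   higher trait).
#' @param q_encode probability a hidden word heard after the recognition
#'   point is later given a Remember response.
#' @param r_base Remember base rate for hidden words not decoded
#'   (pre-recognition or non-recognizers).
#' @param k_rate Know rate applied to non-Remembered hidden words.
#' @param fa_lure probability a foil (matched or NART-style) is endorsed
#'   (R or K), independent of the trait.
#' @param m_nart probability a NART word (actually presented during the
#'   reading test) is endorsed, independent of the trait.
#' @param nart_mean,nart_sd,rho_nart NART score distribution and its
#'   optional correlation with the trait (default independent; positive
#'   values reproduce the confounding pattern where NART absorbs the
#'   recognition effect).
#' @param lshs_loading per-item loading of the 5-item auditory
#'   hallucination scale on the trait (items rated 1-4; totals 5-20).
#' @param lshs_thresholds 3 increasing thresholds cutting the item
#'   latent into ratings 1-4.
#' @param caps_mu,caps_size,caps_beta,pdi_mu,pdi_size,pdi_beta
#'   negative-binomial (log-link on the trait) settings for the
#'   anomalous-perception and delusion-proneness frequency totals
#'   (over-dispersed right-skewed counts).
#' @param seed integer root seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n = 60,
                          mu_dprime_pre = 1.5, exposure_gain = 0.7,
                          gamma_pre = 0, gamma_mod = 0, noise_sd = 0.5,
                          mu_criterion = 0.2, sd_criterion = 0.3,
                          alpha_naive = 0.5, gamma_naive = 0,
                          beta_nart = 0,
                          block_p = 0.35, block_gamma = 0.25,
                          q_encode = 0.5, r_base = 0.05, k_rate = 0.25,
                          fa_lure = 0.15, m_nart = 0.3,
                          nart_mean = 35, nart_sd = 8, rho_nart = 0,
                          lshs_loading = 0.7,
                          lshs_thresholds = c(-0.35, 1.0, 2.0),
                          caps_mu = 10, caps_size = 3, caps_beta = 0.5,
                          pdi_mu = 6, pdi_size = 2.5, pdi_beta = 0.5,
                          seed = 1) {
  p <- as.list(environment())
  bad <- character(0)
  chk <- function(cond, field) if (!cond) bad <<- c(bad, field)
  chk(n >= 2, "n (must be >= 2)")
  for (f in c("q_encode", "r_base", "k_rate", "fa_lure", "m_nart",
              "block_p", "lshs_loading"))
    chk(p[[f]] >= 0 && p[[f]] <= 1, sprintf("%s (must be in [0, 1])", f))
  for (f in c("noise_sd", "sd_criterion", "nart_sd"))
    chk(p[[f]] >= 0, sprintf("%s (must be >= 0)", f))
  chk(abs(rho_nart) <= 1, "rho_nart (must be in [-1, 1])")
  chk(block_p > 0, "block_p (must be > 0)")
  chk(all(diff(lshs_thresholds) > 0) && length(lshs_thresholds) == 3,
      "lshs_thresholds (3 increasing values)")
  chk(caps_mu > 0 && caps_size > 0, "caps_mu/caps_size (must be > 0)")
  chk(pdi_mu > 0 && pdi_size > 0, "pdi_mu/pdi_size (must be > 0)")
  if (length(bad)) stop_domain("invalid cohort parameters: %s",
                               paste(bad, collapse = "; "))
  structure(p, class = "cohort_params")
}

#' Scenario presets for the cohort generator
#'
#' * `null` — no trait coupling anywhere (for type-I error studies).
#' * `modulation` — the trait amplifies the exposure-related d' gain
#'   (`gamma_mod = 0.3`).
#' * `naive` — the trait drives spontaneous recognition and hence
#'   hidden-word memory (`gamma_naive = 1.2`), with no modulation
#'   coupling; the structure behind the naive-listening result pattern.
#'   The coupling strength was fixed by an a-priori power analysis so
#'   the recognition and memory effects are clearly detectable at the
#'   paradigm's sample size (n = 134); see the vignette.
#'
#' @param scenario one of `"null"`, `"modulation"`, `"naive"`.
#' @param ... overrides passed to [cohort_params()].
#' @return a [cohort_params()] object.
#' @export
scenario_params <- function(scenario = c("null", "modulation", "naive"),
                            ...) {
  scenario <- match.arg(scenario)
  over <- list(...)
  base <- switch(scenario,
                 null = list(gamma_mod = 0, gamma_naive = 0),
                 modulation = list(gamma_mod = 0.3, gamma_naive = 0),
                 naive = list(gamma_mod = 0, gamma_naive = 1.2))
  do.call(cohort_params, utils::modifyList(base, over))
}

#' Draw a cohort of synthetic observers
#'
#' The generative model: `trait_h ~ N(0, 1)`;
#' `dprime_pre  = mu_dprime_pre + gamma_pre * trait_h + e1`;
#' `dprime_post = dprime_pre + exposure_gain + gamma_mod * trait_h + e2`
#' with `e1, e2 ~ N(0, noise_sd^2)` independent, so the latent change
#' score correlates with the trait as
#' `gamma_mod / sqrt(gamma_mod^2 + noise_sd^2)`. Questionnaire scores
#' are monotone noisy transforms of the trait (graded-threshold items
#' for the 5-item auditory scale; over-dispersed counts for the two
#' frequency totals); the NART score is independent of the trait unless
#' `rho_nart` is set.
#'
#' @param params a [cohort_params()] object.
#' @return a data.frame, one row per observer: `id`, `trait_h`,
#'   `lshs_a`, `caps_freq`, `pdi_freq`, `nart`, `dprime_pre`,
#'   `dprime_post`, `criterion`.
#' @export
sample_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  with_seed(derive_seed(p$seed, "cohort"), {
    n <- p$n
    trait <- stats::rnorm(n)
    dpre <- p$mu_dprime_pre + p$gamma_pre * trait +
      stats::rnorm(n, 0, p$noise_sd)
    dpost <- dpre + p$exposure_gain + p$gamma_mod * trait +
      stats::rnorm(n, 0, p$noise_sd)
    crit <- stats::rnorm(n, p$mu_criterion, p$sd_criterion)
    # 5 graded items, each loading on the trait
    lam <- p$lshs_loading
    item_lat <- lam * matrix(trait, n, 5) +
      sqrt(1 - lam^2) * matrix(stats::rnorm(5 * n), n, 5)
    ratings <- matrix(1L, n, 5)
    for (thr in p$lshs_thresholds) ratings <- ratings + (item_lat > thr)
    lshs <- as.integer(rowSums(ratings))
    caps <- stats::rnbinom(n, size = p$caps_size,
                           mu = p$caps_mu * exp(p$caps_beta * trait))
    pdi <- stats::rnbinom(n, size = p$pdi_size,
                          mu = p$pdi_mu * exp(p$pdi_beta * trait))
    nart <- as.integer(round(p$nart_mean + p$nart_sd *
      (p$rho_nart * trait +
         sqrt(1 - p$rho_nart^2) * stats::rnorm(n))))
    data.frame(id = sprintf("obs_%04d", seq_len(n)), trait_h = trait,
               lshs_a = lshs, caps_freq = caps, pdi_freq = pdi,
               nart = nart, dprime_pre = dpre, dprime_post = dpost,
               criterion = crit, stringsAsFactors = FALSE)
  })
}

# per-phase latent d' lookup
.phase_dprime <- function(cohort, phase) {
  ifelse(phase == "post", cohort$dprime_post, cohort$dprime_pre)
}

#' Simulate yes/no discrimination responses on a design
#'
#' Equal-variance SDT response model, matching the measurement model of
#' [sdt_outcome()]: on each trial
#' `P(yes | intelligible)  = pnorm( d'/2 - c)` and
#' `P(yes | unintelligible) = pnorm(-d'/2 - c)`, with the phase-specific
#' latent d' (pre or post) and the observer's criterion; independent
#' Bernoulli draws, seeded per observer.
#'
#' @param cohort data.frame from [sample_cohort()] (one or more rows).
#' @param design a design data.frame (e.g. [build_exp1_design()]); only
#'   phases `pre` and `post` generate responses.
#' @param seed integer seed (combined with each observer's id).
#' @return long data.frame: `participant`, `phase`, `kind`, `position`,
#'   `said_speech`.
#' @export
simulate_discrimination <- function(cohort, design, seed = 1) {
  d <- design[design$phase %in% c("pre", "post"), , drop = FALSE]
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    dp <- .phase_dprime(cohort[i, ], d$phase)
    mu <- ifelse(d$kind == "intelligible", dp / 2, -dp / 2)
    p_yes <- stats::pnorm(mu - cohort$criterion[i])
    yes <- with_seed(derive_seed(seed, "discrim", cohort$id[i]),
                     stats::rbinom(nrow(d), 1, p_yes))
    out[[i]] <- data.frame(participant = cohort$id[i], phase = d$phase,
                           kind = d$kind, position = d$position,
                           said_speech = yes, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate discrimination hit/false-alarm counts directly
#'
#' Count-level shortcut for Monte-Carlo work: per-trial Bernoulli
#' responses summed within a cell are Binomial, so cells are drawn
#' directly as binomial counts under the same response model as
#' [simulate_discrimination()].
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param n_signal,n_noise trials per phase of each kind.
#' @param phases phases to simulate.
#' @param seed integer seed.
#' @return data.frame: `participant`, `phase`, `hits`, `n_signal`,
#'   `false_alarms`, `n_noise`.
#' @export
simulate_detection_counts <- function(cohort, n_signal = 45, n_noise = 45,
                                      phases = c("pre", "post"),
                                      seed = 1) {
  grid <- expand.grid(i = seq_len(nrow(cohort)), phase = phases,
                      stringsAsFactors = FALSE)
  dp <- .phase_dprime(cohort[grid$i, ], grid$phase)
  crit <- cohort$criterion[grid$i]
  with_seed(derive_seed(seed, "counts"), {
    hits <- stats::rbinom(nrow(grid), n_signal, stats::pnorm(dp / 2 - crit))
    fas <- stats::rbinom(nrow(grid), n_noise, stats::pnorm(-dp / 2 - crit))
    data.frame(participant = cohort$id[grid$i], phase = grid$phase,
               hits = hits, n_signal = n_signal, false_alarms = fas,
               n_noise = n_noise, stringsAsFactors = FALSE)
  })
}

#' Simulate spontaneous recognition in the naive-listening task
#'
#' `P(recognized) = plogis(alpha_naive + gamma_naive * trait_h +
#' beta_nart * (nart - nart_mean))`; recognizers get a recognition block
#' drawn from a geometric distribution truncated to blocks 1-6, whose
#' success probability increases with the trait (earlier recognition for
#' more hallucination-prone observers).
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param params the [cohort_params()] used to build it.
#' @param seed integer seed.
#' @return the cohort with logical `recognized` and integer
#'   `recognition_block` (NA for non-recognizers — never imputed)
#'   columns added.
#' @export
simulate_naive_listening <- function(cohort, params, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  lp <- p$alpha_naive + p$gamma_naive * cohort$trait_h +
    p$beta_nart * (cohort$nart - p$nart_mean)
  with_seed(derive_seed(seed, "naive"), {
    rec <- stats::runif(nrow(cohort)) < stats::plogis(lp)
    pg <- stats::plogis(stats::qlogis(p$block_p) +
                          p$block_gamma * cohort$trait_h)
    # truncated geometric on 1..6
    blk <- vapply(seq_len(nrow(cohort)), function(i) {
      probs <- pg[i] * (1 - pg[i])^(0:5)
      sample.int(6, 1, prob = probs / sum(probs))
    }, 1L)
    cohort$recognized <- rec
    cohort$recognition_block <- ifelse(rec, blk, NA_integer_)
    cohort
  })
}

#' Simulate Remember/Know/New memory responses
#'
#' Hidden words occurring at or after an observer's recognition point
#' are Remembered with probability `q_encode` (else Know with `k_rate`,
#' else New); hidden words before recognition — or all of them for
#' non-recognizers — are Remembered only at the base rate `r_base`.
#' Foils (matched and NART-style) are endorsed with probability
#' `fa_lure`, and NART words with `m_nart`, both independent of the
#' trait — the structure behind the memory-specificity controls.
#'
#' @param cohort data.frame from [simulate_naive_listening()] (must
#'   carry `recognized` / `recognition_block`).
#' @param memory_list the `memory` element of [build_exp3_design()].
#' @param params the [cohort_params()] in use.
#' @param seed integer seed.
#' @return long data.frame: `participant`, `word`, `category`,
#'   `block_of_occurrence`, `response` (`R`/`K`/`N`).
#' @export
simulate_memory <- function(cohort, memory_list, params, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(cohort$recognized)) stop_domain(
    "cohort lacks recognition columns; run simulate_naive_listening() first")
  need <- c("word", "category", "block_of_occurrence")
  counts <- table(factor(memory_list$category,
                         c("hidden", "matched_foil", "nart", "nart_foil")))
  if (!all(need %in% names(memory_list)) ||
      !identical(as.integer(counts), c(18L, 18L, 5L, 5L))) stop_domain(
    "memory_list is not a valid memory list (need columns %s and category counts 18/18/5/5)",
    paste(need, collapse = ", "))
  p <- params
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    out[[i]] <- with_seed(derive_seed(seed, "memory", cohort$id[i]), {
      m <- memory_list
      n_w <- nrow(m)
      decoded <- m$category == "hidden" & cohort$recognized[i] &
        !is.na(m$block_of_occurrence) &
        m$block_of_occurrence >= cohort$recognition_block[i]
      resp <- character(n_w)
      u <- stats::runif(n_w)
      v <- stats::runif(n_w)
      for (j in seq_len(n_w)) {
        resp[j] <- switch(
          m$category[j],
          hidden = {
            pr <- if (decoded[j]) p$q_encode else p$r_base
            if (u[j] < pr) "R" else if (v[j] < p$k_rate) "K" else "N"
          },
          matched_foil = ,
          nart_foil = {
            if (u[j] < p$fa_lure) (if (v[j] < 0.3) "R" else "K") else "N"
          },
          nart = {
            if (u[j] < p$m_nart) (if (v[j] < 0.5) "R" else "K") else "N"
          })
      }
      data.frame(participant = cohort$id[i], word = m$word,
                 category = m$category,
                 block_of_occurrence = m$block_of_occurrence,
                 response = resp, stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

#' Write a cohort table to CSV
#' @param cohort data.frame from [sample_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
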