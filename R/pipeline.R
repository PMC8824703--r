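#' Run one simulated study end to end
#'
#' Generates a cohort under the given parameters, runs it through the
#' one-shot discrimination design (90 trials pre, template exposure, 90
#' trials post), scores the responses with the SDT module, simulates the
#' naive-listening task and the Remember/Know/New memory test on the
#' six-block design, and applies the statistical pipeline:
#'
#' * paired change test on d' (exposure effect),
#' * correlation of the d' change with auditory hallucination-proneness
#'   (the modulation-of-expectation test),
#' * logistic regression of recognition group on hallucination-proneness,
#' * the memory-specificity correlation set.
#'
#' The returned `pattern` flags give a qualitative reading of the run:
#' a significant positive exposure gain; a *null* modulation
#' correlation (|r| below `small_r`, the conventional small-effect
#' bound); a significant positive recognition effect (OR > 1); and the
#' memory dissociation — the hidden-word correlation significantly
#' positive and larger than both specificity-control correlations
#' (lure endorsement, NART-word memory). The controls' null behaviour
#' *on average* is a separate property of the generator, checked in the
#' test suite; per run the dissociation is an ordering statement, which
#' keeps the flag a test of the generative structure rather than of the
#' sampling noise of two null correlations.
#'
#' @param params a [cohort_params()] / [scenario_params()] object.
#' @param seed integer seed for designs and response simulation.
#' @param small_r absolute-correlation bound treated as a qualitative
#'   null (default 0.2).
#' @return a list with elements `cohort`, `outcomes`, `change_test`,
#'   `modulation`, `recognition`, `memory`, and logical vector
#'   `pattern`.
#' @export
run_study <- function(params, seed = 1, small_r = 0.2) {
  stopifnot(inherits(params, "cohort_params"))
  cohort <- sample_cohort(params)
  design <- build_exp1_design(derive_seed(seed, "design"))
  resp <- simulate_discrimination(cohort, design,
                                  seed = derive_seed(seed, "resp"))
  outcomes <- sdt_from_responses(resp)
  pre <- outcomes[outcomes$phase == "pre", ]
  post <- outcomes[outcomes$phase == "post", ]
  ord <- order(pre$participant)
  pre <- pre[ord, ]; post <- post[order(post$participant), ]
  change <- change_scores(pre, post)
  ct <- paired_change_test(pre$d_prime, post$d_prime, method = "t")
  modulation <- association(cohort$lshs_a[order(cohort$id)],
                            change$delta_d_prime)
  cohort <- simulate_naive_listening(cohort, params,
                                     seed = derive_seed(seed, "naive"))
  e3 <- build_exp3_design(derive_seed(seed, "exp3"))
  mem_resp <- simulate_memory(cohort, e3$memory, params,
                              seed = derive_seed(seed, "mem"))
  recognition <- logistic_recognition(cohort$recognized,
                                      cohort["lshs_a"])
  memory <- memory_analysis(cohort, mem_resp)
  mk <- function(o) memory[memory$outcome == o, ]
  pattern <- c(
    exposure_gain = ct$p < 0.05 && mean(change$delta_d_prime) > 0,
    modulation_null = abs(modulation$r) < small_r,
    recognition_positive = recognition$OR[2] > 1 && recognition$p[2] < 0.05,
    memory_dissociation = mk("hidden_r")$r > 0 && mk("hidden_r")$p < 0.05 &&
      mk("hidden_r")$r > mk("lure_endorse")$r &&
      mk("hidden_r")$r > mk("nart_mem")$r)
  list(cohort = cohort, outcomes = outcomes, change_test = ct,
       modulation = modulation, recognition = recognition,
       memory = memory, pattern = pattern)
}
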