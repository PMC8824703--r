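# Trial-schedule generators. Every design is an ordered data.frame
# ("one row per presentation") and is exactly reproducible from
# (experiment, seed, counterbalance_index).

new_trials <- function(experiment, phase, block, position, kind,
                       stimulus_id, sentence_a = NA, sentence_b = NA) {
  data.frame(experiment = experiment, phase = phase, block = block,
             position = position, kind = kind, stimulus_id = stimulus_id,
             sentence_a = sentence_a, sentence_b = sentence_b,
             stringsAsFactors = FALSE)
}

#' One-shot discrimination design (Experiments 1a/1b)
#'
#' Pre-exposure run of 90 trials (45 intelligible + 45 unintelligible,
#' shuffled), one exposure pass over the 45 clear-speech templates the
#' intelligible trials are based on, then a post-exposure run of the
#' same 90 trials freshly reshuffled.
#'
#' @param seed integer seed.
#' @param experiment label, `"1a"` (default) or `"1b"`.
#' @return a data.frame of ordered trials with columns `experiment`,
#'   `phase` (`pre`/`exposure`/`post`), `block`, `position`, `kind`,
#'   `stimulus_id`, `sentence_a`, `sentence_b`.
#' @export
build_exp1_design <- function(seed, experiment = "1a") {
  with_seed(derive_seed(seed, "exp1", experiment), {
    int_ids <- sprintf("sws_int_%02d", 1:45)
    unint_ids <- sprintf("sws_unint_%02d", 1:45)
    pool <- new_trials(experiment, "pre", 1L, NA_integer_,
                       rep(c("intelligible", "unintelligible"), each = 45),
                       c(int_ids, unint_ids))
    pre <- pool[sample.int(90), ]
    pre$position <- 1:90
    expo <- new_trials(experiment, "exposure", 1L, 1:45, "template",
                       sprintf("template_%02d", sample.int(45)))
    post <- pool[sample.int(90), ]
    post$phase <- "post"
    post$position <- 1:90
    out <- rbind(pre, expo, post)
    rownames(out) <- NULL
    out
  })
}

#' Cyclic exposure design (Experiment 2)
#'
#' One session: 8 cycles, each a pre-exposure block of ten trials (five
#' intelligible, five unintelligible, randomized), exposure to the five
#' clear target sentences, then the same ten trials reshuffled
#' post-exposure — 80 trials pre and 80 post, 160 in total. Every
#' sentence identity (target or masker) is used only once across the
#' session; exposure templates are the clear versions of that cycle's
#' five intelligible targets. The counterbalance index selects the
#' acoustic condition of the session and rotates the sentence-set
#' assignment.
#'
#' @param counterbalance_index positive integer; `(index - 1) %% 10 + 1`
#'   picks the session's acoustic condition from the 10-cell grid
#'   ([stimulus_grid()]), and the index also rotates which sentences
#'   serve which cycle.
#' @param seed integer seed.
#' @param n_sentences size of the available sentence pool (>= 160).
#' @return a data.frame of ordered trials; attributes `n_bands` and
#'   `snr_db` record the acoustic condition.
#' @export
build_exp2_session <- function(counterbalance_index = 1, seed = 1,
                               n_sentences = 160) {
  need <- 160 # 8 cycles x 10 trials x 2 sentences per trial
  if (n_sentences < need) stop_domain(
    "sentence pool too small: need %d distinct sentences, have %d",
    need, n_sentences)
  grid <- stimulus_grid()
  grid <- grid[grid$kind == "intelligible", ] # acoustic cells only
  cond <- grid[(counterbalance_index - 1) %% nrow(grid) + 1, ]
  with_seed(derive_seed(seed, "exp2", counterbalance_index), {
    ids <- sprintf("bkb_%03d", 1:n_sentences)
    # rotate the pool by the counterbalance index, then draw without
    # replacement so no sentence repeats within the session
    rot <- (counterbalance_index - 1) %% n_sentences
    if (rot > 0) ids <- c(ids[(rot + 1):n_sentences], ids[1:rot])
    draw <- sample(ids, need)
    out <- vector("list", 8)
    for (cyc in 1:8) {
      s <- draw[(cyc - 1) * 20 + 1:20]
      a_int <- s[1:5]; a_unint <- s[6:10]
      b_mask <- s[11:20]
      cycle_trials <- new_trials(
        "2", "pre", cyc, NA_integer_,
        rep(c("intelligible", "unintelligible"), each = 5),
        sprintf("svs_c%d_%02d", cyc, 1:10),
        sentence_a = c(a_int, a_unint), sentence_b = b_mask)
      pre <- cycle_trials[sample.int(10), ]
      pre$position <- 1:10
      expo <- new_trials("2", "exposure", cyc, 1:5, "template",
                         paste0("template_", a_int), sentence_a = a_int)
      post <- cycle_trials[sample.int(10), ]
      post$phase <- "post"
      post$position <- 1:10
      out[[cyc]] <- rbind(pre, expo, post)
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    attr(out, "n_bands") <- cond$n_bands
    attr(out, "snr_db") <- cond$snr_db
    out
  })
}

# word pools for the recognition-memory list (synthetic stand-ins for
# the study's word sets: simple concrete nouns for hidden words and
# their matched foils, irregularly spelled words in the NART style)
.noun_pool <- c(
  "candle", "garden", "window", "bottle", "carpet", "pencil", "basket",
  "mirror", "jacket", "ladder", "kettle", "button", "saddle", "tunnel",
  "ribbon", "hammer", "pillow", "wallet", "barrel", "shovel", "collar",
  "napkin", "anchor", "magnet", "turnip", "puddle", "blanket", "lantern",
  "whistle", "curtain", "sponge", "marble", "copper", "timber", "velvet",
  "cousin", "meadow", "harbor", "valley", "spider")
.nart_pool <- c("ache", "debt", "gauge", "subtle", "naive",
                "depot", "bouquet", "psalm", "thyme", "chord")
.nart_foil_pool <- c("plaid", "heir", "aisle", "corps", "quay",
                     "gnome", "suave", "beau", "ewe", "tsar")

#' Naive-listening design and memory list (Experiment 3)
#'
#' Main task: six blocks of 15 sine-vocoded stimuli (45 intelligible and
#' 45 unintelligible in total) plus three "scratchy" targets per block,
#' in a pseudo-random order with no more than two stimuli of the same
#' kind consecutively (checked on the concatenated sequence; rejection
#' sampling with a bounded retry count, never silently violated). An
#' 8-trial familiarization preamble (3 targets, 5 unintelligible) is
#' flagged `phase = "familiarization"` and excluded from analysis
#' tables. The memory list holds 46 words: 18 hidden words (3 per
#' block), 18 foils matched for length and complexity, 5 NART words and
#' 5 NART-style foils, shuffled.
#'
#' @param seed integer seed.
#' @param max_retries bound on rejection-sampling retries for the
#'   run-length constraint.
#' @return a list with elements `trials` (ordered data.frame) and
#'   `memory` (data.frame with columns `word`, `category`,
#'   `block_of_occurrence`).
#' @export
build_exp3_design <- function(seed, max_retries = 10000) {
  with_seed(derive_seed(seed, "exp3"), {
    # per-block intelligible counts: 45 over 6 blocks of 15
    n_int <- rep(7:8, 3)[sample.int(6)]
    kinds_by_block <- lapply(1:6, function(b)
      c(rep("intelligible", n_int[b]),
        rep("unintelligible", 15 - n_int[b]), rep("target", 3)))
    # block-wise rejection sampling: each block is reshuffled until the
    # concatenated sequence (including the previous block's tail) has no
    # run longer than 2; bounded retries, never silently violated
    seqs <- vector("list", 6)
    tail2 <- character(0)
    for (b in 1:6) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- sample(kinds_by_block[[b]])
        if (max(rle(c(tail2, cand))$lengths) <= 2) { ok <- TRUE; break }
      }
      if (!ok) stop_domain(
        "run-length constraint unsatisfied after %d retries", max_retries)
      seqs[[b]] <- cand
      tail2 <- utils::tail(cand, 2)
    }
    fam <- new_trials("3", "familiarization", 0L, 1:8,
                      sample(c(rep("target", 3), rep("unintelligible", 5))),
                      NA_character_)
    fam$stimulus_id <- sprintf("fam_%02d", 1:8)
    blocks <- lapply(1:6, function(b) {
      k <- seqs[[b]]
      new_trials("3", "naive", b, seq_along(k), k,
                 sprintf("e3_b%d_%02d", b, seq_along(k)))
    })
    trials <- rbind(fam, do.call(rbind, blocks))
    rownames(trials) <- NULL
    words <- sample(.noun_pool, 36)
    hidden <- words[1:18]
    memory <- data.frame(
      word = c(hidden, words[19:36],
               sample(.nart_pool, 5), sample(.nart_foil_pool, 5)),
      category = rep(c("hidden", "matched_foil", "nart", "nart_foil"),
                     c(18, 18, 5, 5)),
      block_of_occurrence = c(rep(1:6, each = 3), rep(NA_integer_, 28)),
      stringsAsFactors = FALSE)
    memory <- memory[sample.int(46), ]
    rownames(memory) <- NULL
    list(trials = trials, memory = memory)
  })
}

#' Priming-group assignment (Experiment 1b)
#'
#' Splits `n` participants evenly into `primed` and `control` by a
#' seeded permutation.
#'
#' @param n even number of participants.
#' @param seed integer seed.
#' @return character vector of length `n` with values
#'   `"primed"`/`"control"`.
#' @export
build_prime_assignment <- function(n, seed) {
  if (n %% 2 != 0) stop_domain("n must be even (got %d)", n)
  with_seed(derive_seed(seed, "prime", n),
            sample(rep(c("primed", "control"), each = n / 2)))
}

#' Write a design table to CSV
#'
#' @param design a design data.frame (or the `$trials` element of
#'   [build_exp3_design()]).
#' @param path output file.
#' @param participant_slot optional slot label column.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path, participant_slot = NA) {
  design$participant_slot <- participant_slot
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}
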