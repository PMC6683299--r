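#' Construct a Markov chain over AOI states
#'
#' @param labels state names.
#' @param P row-stochastic square matrix of transition probabilities (rows
#'   may be all-zero only when constructed internally from counts).
#' @param start optional initial distribution over the states (defaults to
#'   uniform).
#' @param validate check row sums.
#' @return object of class `markov_chain` (`labels`, `P`, `start`).
#' @export
markov_chain <- function(labels, P, start = NULL, validate = TRUE) {
  labels <- as.character(labels)
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(labels), ncol(P) == length(labels))
  dimnames(P) <- list(labels, labels)
  if (validate) {
    if (any(P < 0)) stop("negative transition probabilities")
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-8)) stop("rows must sum to 1")
  }
  if (is.null(start)) start <- rep(1 / length(labels), length(labels))
  stopifnot(length(start) == length(labels), all(start >= 0),
            abs(sum(start) - 1) < 1e-8)
  structure(list(labels = labels, P = P, start = as.numeric(start)),
            class = "markov_chain")
}

#' Perturb a Markov chain by a given magnitude
#'
#' Each row is mixed with a row-specific alternative:
#' `(1 - magnitude) * row + magnitude * alternative`. The default
#' alternative cyclically shifts the row's probabilities one state to the
#' right, a deterministic redistribution that leaves every row stochastic.
#' Magnitude 0 returns the chain unchanged; magnitude 1 returns the
#' alternative rows exactly.
#'
#' @param chain a [markov_chain()].
#' @param magnitude mixing weight in \[0, 1\].
#' @param alternative optional matrix of alternative rows (row-stochastic,
#'   same shape).
#' @return the perturbed `markov_chain`.
#' @export
perturb_chain <- function(chain, magnitude, alternative = NULL) {
  stopifnot(inherits(chain, "markov_chain"),
            magnitude >= 0, magnitude <= 1)
  L <- length(chain$labels)
  if (is.null(alternative)) {
    alternative <- chain$P[, c(L, seq_len(L - 1L)), drop = FALSE]
    colnames(alternative) <- chain$labels
  }
  markov_chain(chain$labels,
               (1 - magnitude) * chain$P + magnitude * alternative,
               start = chain$start)
}

# Vectorised sampling of AOI state sequences: n trials stepped in parallel,
# column by column, grouping trials by current state. Lengths may differ;
# the matrix is padded to the longest trial.
sample_state_matrix <- function(chain, n_trials, lens) {
  L <- length(chain$labels)
  max_len <- max(lens)
  S <- matrix(NA_integer_, n_trials, max_len)
  S[, 1L] <- sample.int(L, n_trials, replace = TRUE, prob = chain$start)
  if (max_len > 1L) {
    for (j in 2:max_len) {
      active <- which(lens >= j)
      if (!length(active)) break
      cur <- S[active, j - 1L]
      for (s in unique(cur)) {
        sel <- active[cur == s]
        S[sel, j] <- sample.int(L, length(sel), replace = TRUE,
                                prob = chain$P[s, ])
      }
    }
  }
  S
}

# Exact truncated-normal sampling by inverse-CDF, vectorised.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, pl, ph)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi - 1e-9)
}

#' Simulate one scanpath from a Markov chain over AOIs
#'
#' The AOI state sequence is sampled from the chain; each fixation's
#' coordinates are drawn from a 2-D Gaussian centred on its AOI's midpoint,
#' truncated to the AOI rectangle (so the generating AOI is exactly
#' recoverable from the coordinates); durations are log-normal; onsets
#' accumulate durations plus a fixed 30 ms saccade gap.
#'
#' @param chain a [markov_chain()] whose states name regions of `aois`.
#' @param n_fix number of fixations (>= 1).
#' @param aois an `aoi_set` providing the state rectangles.
#' @param scatter_sd within-AOI scatter (pixels).
#' @param duration_meanlog,duration_sdlog log-normal duration parameters
#'   (log-milliseconds).
#' @return data.frame of `fix_index`, `aoi`, `x`, `y`, `duration_ms`,
#'   `onset_ms`.
#' @export
simulate_scanpath <- function(chain, n_fix, aois, scatter_sd = 18,
                              duration_meanlog = log(250),
                              duration_sdlog = 0.4) {
  stopifnot(n_fix >= 1)
  states <- as.integer(sample_state_matrix(chain, 1L, n_fix)[1L, seq_len(n_fix)])
  reg <- aois$regions[match(chain$labels, aois$regions$name), ]
  if (anyNA(reg$name)) stop("chain state not present in the AOI set")
  x <- rtrunc_norm(n_fix, (reg$x0[states] + reg$x1[states]) / 2, scatter_sd,
                   reg$x0[states], reg$x1[states])
  y <- rtrunc_norm(n_fix, (reg$y0[states] + reg$y1[states]) / 2, scatter_sd,
                   reg$y0[states], reg$y1[states])
  dur <- stats::rlnorm(n_fix, duration_meanlog, duration_sdlog)
  onset <- cumsum(c(0, utils::head(dur, -1L) + 30))
  data.frame(fix_index = seq_len(n_fix), aoi = chain$labels[states],
             x = x, y = y, duration_ms = dur, onset_ms = onset)
}

#' Default 12-lead ECG stimulus layout (synthetic)
#'
#' A synthetic stand-in for a researcher-drawn lead map: a 1280 x 1024
#' canvas with the standard 12 leads arranged in the conventional 4-column
#' by 3-row print layout plus a rhythm strip along the bottom.
#'
#' @param stimulus_id identifier to stamp on the layout.
#' @return a [stimulus_layout()].
#' @export
default_ecg_layout <- function(stimulus_id = "ecg") {
  lead_names <- c("I", "aVR", "V1", "V4",
                  "II", "aVL", "V2", "V5",
                  "III", "aVF", "V3", "V6")
  w <- 1280; h <- 1024
  cw <- w / 4; rh <- 820 / 3
  cols <- rep(0:3, times = 3); rows <- rep(0:2, each = 4)
  regions <- data.frame(name = lead_names,
                        x0 = cols * cw, y0 = rows * rh,
                        x1 = (cols + 1) * cw, y1 = (rows + 1) * rh)
  regions <- rbind(regions,
                   data.frame(name = "rhythm", x0 = 0, y0 = 820,
                              x1 = w, y1 = h))
  stimulus_layout(stimulus_id, w, h, regions)
}

# A plausible ECG-reading base chain over the lead AOIs: mostly dwell
# within the current lead, a bias toward the next lead in reading order,
# and a small uniform exploration term.
.reading_chain <- function(labels, p_stay = 0.5, p_next = 0.3) {
  L <- length(labels)
  P <- matrix((1 - p_stay - p_next) / L, L, L)
  diag(P) <- diag(P) + p_stay
  nxt <- c(seq_len(L)[-1L], 1L)
  P[cbind(seq_len(L), nxt)] <- P[cbind(seq_len(L), nxt)] + p_next
  markov_chain(labels, P)
}

#' Default synthetic answer key (synthetic stand-in)
#'
#' Nine diagnoses typical of a 12-lead ECG interpretation study, each with
#' common synonyms and acronyms accepted as correct.
#'
#' @return an [answer_key()] with stimuli `ecg1` ... `ecg9`.
#' @export
default_answer_key <- function() {
  diagnoses <- list(
    list(canonical = "anterolateral STEMI",
         accepted = c("anterolateral ST elevation MI",
                      "anterolateral myocardial infarction")),
    list(canonical = "left bundle branch block",
         accepted = c("LBBB", "left bundle branch")),
    list(canonical = "lateral STEMI",
         accepted = c("lateral ST elevation MI")),
    list(canonical = "atrial fibrillation", accepted = c("AF", "a fib")),
    list(canonical = "right bundle branch block",
         accepted = c("RBBB", "right bundle branch")),
    list(canonical = "inferior STEMI with atrial fibrillation",
         accepted = c("inferior STEMI and AF", "inferior MI with AF")),
    list(canonical = "anterior STEMI",
         accepted = c("anterior ST elevation MI")),
    list(canonical = "high lateral STEMI",
         accepted = c("high lateral ST elevation MI")),
    list(canonical = "inferolateral STEMI",
         accepted = c("inferolateral ST elevation MI")))
  names(diagnoses) <- paste0("ecg", 1:9)
  answer_key(diagnoses)
}

#' Parameterise a synthetic study
#'
#' The default scenario mirrors the structure of a counterbalanced
#' repeated-measures ECG reading study: 31 participants split alternately
#' into history-first (16) and history-last (15) order groups, 9 stimuli
#' seen twice (once per condition), a negative-binomial fixation count per
#' trial, within-AOI Gaussian scatter truncated to the AOI, log-normal
#' fixation durations, and per-group Bernoulli response accuracy. The two
#' order groups scan according to group-specific Markov chains over the
#' lead AOIs; by default group 2's chain is a magnitude-0.25 perturbation
#' of group 1's, so the default world contains a detectable transition
#' difference.
#'
#' @param n_per_group length-2 counts of participants per order group.
#' @param n_stimuli number of stimuli (each viewed in both conditions).
#' @param layout a [stimulus_layout()] shared by all stimuli.
#' @param aois generation AOI set (defaults to the layout's lead AOIs; the
#'   chain states must name its regions).
#' @param group_chains list of two [markov_chain()]s, one per order group.
#' @param fixations_mean,fixations_size negative-binomial mean and
#'   dispersion of fixations per trial (floored at 2 so every trial has at
#'   least one transition).
#' @param scatter_sd within-AOI scatter, pixels.
#' @param duration_meanlog,duration_sdlog log-normal duration parameters.
#' @param accuracy matrix of correct-response probabilities, 2 rows (order
#'   groups) x `n_stimuli` columns; default 0.64 everywhere.
#' @param answer_key an [answer_key()] naming the stimuli.
#' @param seed integer master seed.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_per_group = c(16L, 15L), n_stimuli = 9L,
                                layout = default_ecg_layout(),
                                aois = NULL, group_chains = NULL,
                                fixations_mean = 60, fixations_size = 10,
                                scatter_sd = 18,
                                duration_meanlog = log(250),
                                duration_sdlog = 0.4,
                                accuracy = NULL, answer_key = NULL,
                                seed = 1L) {
  if (is.null(aois)) aois <- lead_aois(layout)
  if (is.null(group_chains)) {
    gen_labels <- setdiff(aois$labels, aois$outside_label)
    base <- .reading_chain(gen_labels)
    group_chains <- list(base, perturb_chain(base, 0.25))
  }
  stopifnot(length(group_chains) == 2L,
            all(vapply(group_chains, inherits, logical(1), "markov_chain")))
  if (is.null(accuracy)) accuracy <- matrix(0.64, 2L, n_stimuli)
  stopifnot(nrow(accuracy) == 2L, ncol(accuracy) == n_stimuli,
            all(accuracy >= 0 & accuracy <= 1),
            all(n_per_group >= 1), fixations_mean > 0)
  if (is.null(answer_key)) {
    answer_key <- if (n_stimuli == 9L) default_answer_key() else {
      ids <- paste0("ecg", seq_len(n_stimuli))
      answer_key(stats::setNames(lapply(ids, function(s) {
        list(canonical = paste("diagnosis", s), accepted = character(0))
      }), ids))
    }
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_stimuli = as.integer(n_stimuli), layout = layout,
                 aois = aois, group_chains = group_chains,
                 fixations_mean = fixations_mean,
                 fixations_size = fixations_size, scatter_sd = scatter_sd,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog, accuracy = accuracy,
                 answer_key = answer_key, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Simulate a complete synthetic study
#'
#' Generates the full trial grid (every participant views every stimulus in
#' both conditions), scanpaths from the participant's order-group chain,
#' and Bernoulli correct/incorrect responses rendered as free text (the
#' canonical diagnosis when correct, an umbrella non-answer when not).
#' Bitwise-reproducible for a fixed scenario seed; the caller's RNG state
#' is untouched.
#'
#' @param scenario a [simulation_scenario()].
#' @return object of class `simulated_study`: `dataset` (a validated
#'   [study_dataset()]) and `scenario`.
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  with_seed(scenario$seed, .simulate_study_impl(scenario))
}

.simulate_study_impl <- function(sc) {
  n_total <- sum(sc$n_per_group)
  ids <- sprintf("P%02d", seq_len(n_total))
  # counterbalancing: order groups assigned alternately by participant index
  grp_idx <- rep(c(1L, 2L), length.out = n_total)
  # honour the requested group sizes if alternation does not match them
  if (sum(grp_idx == 1L) != sc$n_per_group[1L]) {
    grp_idx <- rep(c(1L, 2L), c(sc$n_per_group[1L], sc$n_per_group[2L]))
  }
  order_group <- ORDER_GROUPS[grp_idx]
  stimuli <- paste0("ecg", seq_len(sc$n_stimuli))

  trials <- expand.grid(participant = ids, stimulus = stimuli,
                        condition = CONDITIONS, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  trials <- trials[order(trials$participant, trials$stimulus,
                         trials$condition), ]
  trials$group <- grp_idx[match(trials$participant, ids)]
  trials$n_fix <- pmax(2L, stats::rnbinom(nrow(trials),
                                          mu = sc$fixations_mean,
                                          size = sc$fixations_size))
  aois <- sc$aois
  fx_parts <- vector("list", 2L)
  for (g in 1:2) {
    rows <- which(trials$group == g)
    chain <- sc$group_chains[[g]]
    reg <- aois$regions[match(chain$labels, aois$regions$name), ]
    if (anyNA(reg$name)) stop("generation error: chain state missing from AOI set")
    S <- sample_state_matrix(chain, length(rows), trials$n_fix[rows])
    lens <- trials$n_fix[rows]
    states <- unlist(lapply(seq_along(rows),
                            function(i) S[i, seq_len(lens[i])]),
                     use.names = FALSE)
    n_fx <- length(states)
    x <- rtrunc_norm(n_fx, (reg$x0[states] + reg$x1[states]) / 2,
                     sc$scatter_sd, reg$x0[states], reg$x1[states])
    y <- rtrunc_norm(n_fx, (reg$y0[states] + reg$y1[states]) / 2,
                     sc$scatter_sd, reg$y0[states], reg$y1[states])
    dur <- stats::rlnorm(n_fx, sc$duration_meanlog, sc$duration_sdlog)
    trial_id <- rep(rows, lens)
    fix_index <- sequence(lens)
    onset <- stats::ave(dur, trial_id,
                        FUN = function(v) cumsum(c(0, utils::head(v, -1) + 30)))
    fx_parts[[g]] <- data.frame(
      participant = trials$participant[trial_id],
      stimulus = trials$stimulus[trial_id],
      condition = trials$condition[trial_id],
      order_group = order_group[match(trials$participant[trial_id], ids)],
      fix_index = fix_index, x = x, y = y, duration_ms = dur,
      onset_ms = onset)
  }
  fx <- do.call(rbind, fx_parts)

  p_correct <- sc$accuracy[cbind(trials$group,
                                 match(trials$stimulus, stimuli))]
  correct <- stats::runif(nrow(trials)) < p_correct
  key <- sc$answer_key
  resp_text <- vapply(seq_len(nrow(trials)), function(i) {
    if (correct[i] && !is.null(key)) key[[trials$stimulus[i]]]$canonical
    else if (correct[i]) paste0("diagnosis ", trials$stimulus[i])
    else "arrhythmia"
  }, character(1))
  responses <- data.frame(participant = trials$participant,
                          stimulus = trials$stimulus,
                          condition = trials$condition,
                          response = resp_text,
                          correct_truth = correct)
  participants <- data.frame(participant = ids, order_group = order_group)
  ds <- study_dataset(fx, responses = responses, participants = participants)
  structure(list(dataset = ds, scenario = sc), class = "simulated_study")
}
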