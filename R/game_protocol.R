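#' Session plan: trial order, bad Sender, forced-error trials
#'
#' Randomized plan for one 16-trial session. Half of the trials require a
#' 180° rotation and half do not, with the constraint that each half of the
#' session contains 4 rotation and 4 non-rotation trials. One Sender is
#' chosen uniformly as the unreliable ("bad") Sender, whose transmitted
#' decision is forced to be incorrect in 10 of the 16 trials, in both
#' rounds of each forced trial.
#'
#' @param seed Integer seed; the plan is fully reproducible.
#' @param n_trials Number of trials (16 in the reference design; must be a
#'   multiple of 4 so the balance constraint is well defined).
#' @param n_forced Number of forced-error trials for the bad Sender (10).
#' @return An object of class `"session_plan"`: list with `trials`
#'   (0/1 required actions), `bad_sender` (1 or 2), `forced_error_trials`
#'   (sorted trial indices) and `seed`.
#' @export
make_session_plan <- function(seed = 1L, n_trials = 16L, n_forced = 10L) {
  stopifnot(n_trials %% 4L == 0L, n_forced <= n_trials)
  half <- n_trials %/% 2L
  withr_seed(seed, {
    trials <- c(sample(rep(c(0L, 1L), half %/% 2L)),
                sample(rep(c(0L, 1L), half %/% 2L)))
    bad_sender <- sample(1:2, 1L)
    forced <- sort(sample(n_trials, n_forced))
    structure(list(trials = trials, bad_sender = bad_sender,
                   forced_error_trials = forced, seed = as.integer(seed),
                   n_trials = n_trials),
              class = "session_plan")
  })
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d trials (%d rotate), bad sender %d, %d forced-error trials\n",
              x$n_trials, sum(x$trials), x$bad_sender,
              length(x$forced_error_trials)))
  invisible(x)
}

#' Trial state of the two-round block game
#'
#' A single falling block with two orientations (0° and 180°; two rotations
#' compose to the identity). `needs_rotation` says which action clears the
#' line from the starting orientation. Each of the two rounds offers one
#' chance to rotate; after round 1 the block drops halfway, after round 2
#' the trial resolves. The trial clears iff the net orientation matches the
#' gap.
#'
#' @param needs_rotation 1 if the block must be rotated from its starting
#'   orientation to fit the gap, 0 otherwise.
#' @param trial Trial index.
#' @return An object of class `"trial_state"`.
#' @export
trial_state <- function(needs_rotation, trial = NA_integer_) {
  stopifnot(needs_rotation %in% c(0, 1))
  structure(list(orientation = 0L,
                 gap_fit = as.integer(needs_rotation) * 180L,
                 round = 1L, phase = "start", outcome = "pending",
                 trial = trial),
            class = "trial_state")
}

#' The currently correct action for a trial state
#'
#' 1 (rotate) if the block's current orientation differs from the one that
#' fits the gap, else 0. In round 2 this depends on what happened in round
#' 1: a wrong round-1 rotation makes "rotate again" the correct action.
#'
#' @param state A [trial_state()].
#' @return 0 or 1.
#' @export
correct_action <- function(state) {
  as.integer(state$orientation != state$gap_fit)
}

#' Advance a trial by one Receiver decision
#'
#' Round 1 rotates (or not) and drops the block halfway; round 2 rotates
#' (or not) and resolves the trial. The outcome is `"cleared"` iff the
#' final orientation matches the gap.
#'
#' @param state A [trial_state()] not yet resolved.
#' @param receiver_value 0 or 1, the Receiver's action this round.
#' @return The updated [trial_state()].
#' @export
advance <- function(state, receiver_value) {
  stopifnot(inherits(state, "trial_state"), receiver_value %in% c(0, 1))
  if (state$phase == "resolved") stop("cannot advance a resolved trial")
  if (receiver_value == 1) state$orientation <- (state$orientation + 180L) %% 360L
  if (state$round == 1L) {
    state$phase <- "midway"
    state$round <- 2L
  } else {
    state$phase <- "resolved"
    state$outcome <- if (state$orientation == state$gap_fit) "cleared" else "failed"
  }
  state
}

#' Force the bad Sender's transmitted decision to be incorrect
#'
#' On a forced-error trial the decision sent onward is the incorrect action
#' for the *current* game state (recomputed each round, since correctness
#' in round 2 depends on the round-1 action), regardless of what the Sender
#' intended. On other trials the decision passes through unchanged.
#'
#' @param value The bad Sender's decoded decision (0/1).
#' @param plan A [make_session_plan()].
#' @param state The current [trial_state()].
#' @param sender Which Sender (1 or 2) the decision belongs to; must be the
#'   plan's designated bad Sender.
#' @return The transmitted 0/1 value.
#' @export
apply_forced_error <- function(value, plan, state, sender) {
  stopifnot(value %in% c(0, 1))
  if (sender != plan$bad_sender)
    stop("forced errors apply only to the designated bad Sender")
  if (state$trial %in% plan$forced_error_trials)
    return(1L - correct_action(state))
  as.integer(value)
}

#' Simulated phosphene stimulation channel
#'
#' Parameters of the 1-bit occipital-stimulation channel: a "Yes" decision
#' is delivered at an intensity above the Receiver's absolute phosphene
#' threshold (a flash is perceived), "No" below it (no flash). Perception
#' is imperfect: each percept flips with probability `perception_noise`.
#' Pulses to the Receiver are separated by `inter_pulse_delay` seconds of
#' simulated (logical) time.
#'
#' @param absolute_threshold 50%-phosphene stimulator intensity, % of max.
#' @param yes_intensity,no_intensity Intensities used for "Yes"/"No";
#'   must straddle the threshold.
#' @param perception_noise Probability in \[0, 0.5\] that a percept flips.
#' @param inter_pulse_delay Seconds between the two Senders' pulses (8).
#' @return An object of class `"channel_model"`.
#' @export
channel_model <- function(absolute_threshold = 62, yes_intensity = 72,
                          no_intensity = 52, perception_noise = 0.05,
                          inter_pulse_delay = 8) {
  if (!(no_intensity < absolute_threshold && absolute_threshold < yes_intensity))
    stop("intensities must satisfy no_intensity < absolute_threshold < yes_intensity")
  if (perception_noise < 0 || perception_noise > 0.5)
    stop("perception_noise must be in [0, 0.5]")
  structure(list(absolute_threshold = absolute_threshold,
                 yes_intensity = yes_intensity, no_intensity = no_intensity,
                 perception_noise = perception_noise,
                 inter_pulse_delay = inter_pulse_delay),
            class = "channel_model")
}

#' Transmit one decision through the phosphene channel
#'
#' A transmitted 1 ("Yes") becomes a phosphene percept, 0 becomes no
#' phosphene, each flipped with probability `perception_noise`. Uses the
#' current RNG stream; seed at the session level for reproducibility.
#'
#' @param value Transmitted 0/1 decision.
#' @param channel A [channel_model()].
#' @return Integer percept: 1 = phosphene perceived, 0 = none.
#' @export
transmit <- function(value, channel) {
  stopifnot(value %in% c(0, 1))
  flip <- stats::runif(1) < channel$perception_noise
  as.integer(xor(value == 1, flip))
}

#' Estimate the absolute phosphene threshold by PEST
#'
#' Adaptive staircase (Parameter Estimation by Sequential Testing) locating
#' the 50% point of a simulated psychometric function. Classic step rules:
#' a phosphene response lowers the intensity, a miss raises it; the step
#' halves on every direction reversal and doubles after three consecutive
#' steps in the same direction; the run stops once the step falls below
#' `min_step`.
#'
#' @param psychometric_sim Function of intensity returning the probability
#'   of perceiving a phosphene; must be nondecreasing.
#' @param start_intensity Starting intensity, % of stimulator max.
#' @param initial_step Initial step size in intensity percent.
#' @param min_step Stopping step size.
#' @param max_trials Safety cap on staircase trials.
#' @return The estimated threshold (% of max).
#' @export
#' @examples
#' psy <- function(i) plogis((i - 62) / 2)
#' set.seed(1)
#' pest_calibrate(psy, start_intensity = 40)
pest_calibrate <- function(psychometric_sim, start_intensity,
                           initial_step = 8, min_step = 0.5,
                           max_trials = 200L) {
  grid <- seq(0, 100, by = 5)
  p <- vapply(grid, psychometric_sim, numeric(1))
  if (any(diff(p) < -1e-8))
    stop("psychometric_sim must be a nondecreasing function of intensity")
  intensity <- start_intensity
  step <- initial_step
  dir <- 0L
  run_len <- 0L
  for (k in seq_len(max_trials)) {
    seen <- stats::runif(1) < psychometric_sim(intensity)
    new_dir <- if (seen) -1L else 1L
    if (dir != 0L && new_dir != dir) {
      step <- step / 2
      run_len <- 1L
    } else {
      run_len <- run_len + 1L
      if (run_len >= 3L) step <- step * 2
    }
    if (step < min_step) break
    dir <- new_dir
    intensity <- max(0, min(100, intensity + new_dir * step))
  }
  intensity
}

#' Find the supra- and sub-threshold stimulation levels
#'
#' Starting at the absolute threshold, the intensity is raised in 5%
#' increments until 10 consecutive simulated pulses all elicit phosphenes;
#' that level carries "Rotate". Symmetrically, the intensity is lowered in
#' 5% increments until 10 consecutive pulses elicit none; that level
#' carries "Do Not Rotate".
#'
#' @param absolute_threshold Threshold from [pest_calibrate()].
#' @param psychometric_sim Probability-of-phosphene function of intensity.
#' @param step Increment in intensity percent (5).
#' @param n_consecutive Consecutive-pulse criterion (10).
#' @return List with `yes_intensity` and `no_intensity`.
#' @export
staircase_levels <- function(absolute_threshold, psychometric_sim,
                             step = 5, n_consecutive = 10L) {
  probe <- function(intensity, want) {
    all((stats::runif(n_consecutive) < psychometric_sim(intensity)) == want)
  }
  yes <- absolute_threshold
  repeat {
    yes <- yes + step
    if (yes > 100) stop("no supra-threshold level with 10/10 phosphenes within bounds")
    if (probe(yes, TRUE)) break
  }
  no <- absolute_threshold
  repeat {
    no <- no - step
    if (no < 0) stop("no sub-threshold level with 10/10 misses within bounds")
    if (probe(no, FALSE)) break
  }
  list(yes_intensity = yes, no_intensity = no)
}

#' Run one full simulated session
#'
#' Executes 16 trials of two rounds each, end to end: each Sender forms an
#' intent (correct with probability `competence`), renders it as synthetic
#' SSVEP EEG (17 Hz for rotate, 15 Hz for not) which is decoded by the
#' standard pipeline; the bad Sender's decision is forced incorrect on the
#' plan's forced-error trials; both decisions cross the phosphene channel;
#' the Receiver integrates the two percepts under its trust weights,
#' renders its own intent as EEG (acquired at `receiver_fs` and decimated
#' to `receiver_decode_fs` before decoding), and acts; the game state
#' advances; at the end of each trial all agents see the outcome and the
#' Receiver updates its trust in each Sender.
#'
#' All randomness derives from `seed`; identical seeds give identical logs.
#'
#' @param plan A [make_session_plan()].
#' @param agents An [agent_params()] bundle (Sender competences, Receiver
#'   trust prior).
#' @param decoder_cfg A [decoder_config()].
#' @param channel A [channel_model()].
#' @param seed Integer seed for the session.
#' @param snr SSVEP signal-to-noise ratio used for every rendered
#'   recording.
#' @param simulate_eeg If `FALSE`, intents skip the EEG render/decode stage
#'   (useful for fast protocol-level studies); the channel and agents are
#'   unchanged.
#' @param sender_fs,receiver_fs,receiver_decode_fs Sampling rates in Hz:
#'   Senders 250; Receiver acquired at 5000 and decimated to 500.
#' @param trust0 Optional initial [trust_state()] (e.g. a pre-trained
#'   Receiver); defaults to a fresh state with the agents' prior.
#' @return A `"session_log"`: data frame with one row per trial x round
#'   (columns trial, round, truth, correct_action, s1_intent, s1_decoded,
#'   s1_sent, s2_intent, s2_decoded, s2_sent, percept1, percept2,
#'   receiver_intent, receiver_decision, outcome, forced_flag,
#'   excluded_flag, sim_time_s), with the plan, trust trajectory and seeds
#'   attached as attributes.
#' @export
run_session <- function(plan, agents = agent_params(),
                        decoder_cfg = decoder_config(),
                        channel = channel_model(), seed = 1L,
                        snr = 4, simulate_eeg = TRUE,
                        sender_fs = 250, receiver_fs = 5000,
                        receiver_decode_fs = 500, trust0 = NULL) {
  withr_seed(seed, {
    trust <- if (is.null(trust0)) trust_state(prior = agents$trust_prior) else trust0
    n_rounds <- 2L
    rows <- vector("list", plan$n_trials * n_rounds)
    trust_traj <- matrix(NA_real_, nrow = plan$n_trials, ncol = 2,
                         dimnames = list(NULL, c("w1", "w2")))
    sim_time <- 0
    eeg_seed <- function() sample.int(.Machine$integer.max, 1L)

    render_decode <- function(value, fs, decode_fs) {
      if (!simulate_eeg) return(as.integer(value))
      f <- if (value == 1) decoder_cfg$f_yes else decoder_cfg$f_no
      rec <- generate_ssvep(ssvep_spec(f, snr = snr, seed = eeg_seed()),
                            duration = decoder_cfg$window_len, fs = fs)
      if (decode_fs < fs) rec <- downsample(rec, decode_fs)
      decode(rec, decoder_cfg)$decision$value
    }

    k <- 0L
    for (tr in seq_len(plan$n_trials)) {
      state <- trial_state(plan$trials[tr], trial = tr)
      correct_by_round <- integer(n_rounds)
      percepts_by_round <- matrix(NA_integer_, n_rounds, 2)
      for (rd in seq_len(n_rounds)) {
        truth_now <- correct_action(state)
        correct_by_round[rd] <- truth_now
        s_int <- s_dec <- s_sent <- integer(2)
        for (s in 1:2) {
          s_int[s] <- sender_intent(truth_now, agents$senders[[s]])
          s_dec[s] <- render_decode(s_int[s], sender_fs, sender_fs)
          s_sent[s] <- if (s == plan$bad_sender)
            apply_forced_error(s_dec[s], plan, state, s) else s_dec[s]
        }
        percept <- integer(2)
        for (s in 1:2) {
          percept[s] <- transmit(s_sent[s], channel)
          sim_time <- sim_time + channel$inter_pulse_delay
        }
        percepts_by_round[rd, ] <- percept
        r_int <- receiver_decide(percept, trust, policy = agents$receiver_policy)
        r_dec <- render_decode(r_int, receiver_fs, receiver_decode_fs)
        state <- advance(state, r_dec)
        k <- k + 1L
        rows[[k]] <- data.frame(
          trial = tr, round = rd, truth = plan$trials[tr],
          correct_action = truth_now,
          s1_intent = s_int[1], s1_decoded = s_dec[1], s1_sent = s_sent[1],
          s2_intent = s_int[2], s2_decoded = s_dec[2], s2_sent = s_sent[2],
          percept1 = percept[1], percept2 = percept[2],
          receiver_intent = r_int, receiver_decision = r_dec,
          outcome = NA_character_,
          forced_flag = tr %in% plan$forced_error_trials,
          excluded_flag = FALSE, sim_time_s = sim_time)
      }
      for (rd in seq_len(n_rounds)) {
        trust <- trust_update(trust, percepts_by_round[rd, ],
                              correct_by_round[rd])
      }
      trust_traj[tr, ] <- trust_weights(trust)
      outcome <- state$outcome
      rows[[k - 1L]]$outcome <- outcome
      rows[[k]]$outcome <- outcome
    }
    log <- do.call(rbind, rows)
    structure(log, class = c("session_log", "data.frame"),
              plan = plan, seed = as.integer(seed),
              trust_trajectory = trust_traj,
              channel = channel, snr = snr,
              simulate_eeg = simulate_eeg)
  })
}

#' @export
print.session_log <- function(x, ...) {
  n_tr <- length(unique(x$trial))
  cleared <- sum(x$outcome[x$round == 2] == "cleared")
  cat(sprintf("<session_log> %d trials, %d cleared (seed %d)\n",
              n_tr, cleared, attr(x, "seed")))
  invisible(x)
}
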