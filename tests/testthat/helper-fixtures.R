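# Shared fixtures built in code.

# Brute-force evaluation of the MI definition on a 2x2 count table,
# written directly from the formula; independent of mutual_information().
mi_oracle <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pr <- rowSums(p); ps <- colSums(p)
  total <- 0
  for (i in 1:2) for (j in 1:2)
    if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (pr[i] * ps[j]))
  total
}

counts_to_vectors <- function(counts) {
  r <- s <- integer(0)
  for (i in 1:2) for (j in 1:2) {
    k <- counts[i, j]
    r <- c(r, rep(i - 1L, k)); s <- c(s, rep(j - 1L, k))
  }
  list(r = r, s = s)
}

# Minimal session-log data frame for statistics tests: `outcomes` is a
# character vector over trials; excluded marks trials dropped from analysis.
fake_log <- function(outcomes, excluded = integer(0), bad_sender = 2L) {
  n <- length(outcomes)
  rows <- do.call(rbind, lapply(seq_len(n), function(tr) {
    data.frame(trial = tr, round = 1:2, truth = tr %% 2L,
               correct_action = c(tr %% 2L, 0L),
               s1_intent = 0L, s1_decoded = 0L, s1_sent = 0L,
               s2_intent = 0L, s2_decoded = 0L, s2_sent = 0L,
               percept1 = 0L, percept2 = 0L,
               receiver_intent = 0L, receiver_decision = 0L,
               outcome = outcomes[tr],
               forced_flag = FALSE, excluded_flag = tr %in% excluded,
               sim_time_s = 16 * tr)
  }))
  plan <- structure(list(trials = rows$truth[rows$round == 1L],
                         bad_sender = bad_sender,
                         forced_error_trials = integer(0),
                         seed = 0L, n_trials = n),
                    class = "session_plan")
  structure(rows, class = c("session_log", "data.frame"),
            plan = plan, seed = 0L)
}

# Session configured so every stage is error-free: noiseless EEG, a
# noiseless channel, perfectly competent Senders, and a Receiver whose
# trust already favours the good Sender (argmax policy).
ideal_session <- function(seed = 1L, plan = make_session_plan(seed)) {
  trust0 <- trust_state()
  good <- 3L - plan$bad_sender
  trust0$counts[good, "agree"] <- 100
  trust0$counts[plan$bad_sender, "disagree"] <- 100
  run_session(plan,
              agents = agent_params(receiver_policy = "argmax"),
              channel = channel_model(perception_noise = 0),
              seed = seed, snr = Inf, trust0 = trust0)
}
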