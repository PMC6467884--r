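#' Sender behavioural model
#'
#' A Sender intends the correct action with probability `competence`. The
#' human Senders in the reference design could see the whole game screen
#' and were simply tasked with being correct, so the default is 1; lower
#' values model inattention or task error upstream of the EEG interface.
#'
#' @param competence Probability in \[0, 1\] of intending the correct
#'   action each round.
#' @return An object of class `"sender_model"`.
#' @export
sender_model <- function(competence = 1) {
  stopifnot(competence >= 0, competence <= 1)
  structure(list(competence = competence), class = "sender_model")
}

#' Draw a Sender's intended decision
#'
#' Correct with probability `model$competence`, flipped otherwise. Uses
#' the current RNG stream.
#'
#' @param true_action The currently correct 0/1 action.
#' @param model A [sender_model()].
#' @return Intended 0/1 decision.
#' @export
sender_intent <- function(true_action, model) {
  stopifnot(true_action %in% c(0, 1))
  if (stats::runif(1) < model$competence) as.integer(true_action)
  else 1L - as.integer(true_action)
}

#' Receiver trust state over the two Senders
#'
#' Per-Sender evidence counts (agreements and disagreements between the
#' Sender's percept-implied action and the revealed correct action) under
#' a Beta-Bernoulli model. Each Sender's weight is the posterior mean
#' reliability `(prior + agreements) / (2 * prior + agreements +
#' disagreements)`; with the default uniform Beta(1, 1) prior both weights
#' start at 0.5.
#'
#' @param prior Symmetric Beta pseudo-count (1 = uniform prior).
#' @return An object of class `"trust_state"` with matrix `counts`
#'   (2 Senders x agree/disagree) and the prior.
#' @export
trust_state <- function(prior = 1) {
  structure(list(counts = matrix(0, 2, 2,
                                 dimnames = list(c("sender-1", "sender-2"),
                                                 c("agree", "disagree"))),
                 prior = prior),
            class = "trust_state")
}

#' Posterior-mean trust weights
#'
#' @param trust A [trust_state()].
#' @return Numeric vector of two weights in \[0, 1\].
#' @export
trust_weights <- function(trust) {
  (trust$prior + trust$counts[, "agree"]) /
    (2 * trust$prior + rowSums(trust$counts))
}

#' Receiver decision from two percepts
#'
#' If the two percept-implied decisions agree, that value is taken. On
#' disagreement the trust state arbitrates, under one of two policies:
#' \describe{
#'   \item{`"argmax"`}{the higher-weight Sender wins; with exactly equal
#'     weights the tie is broken by a coin flip from the current RNG
#'     stream (seeded at the session level).}
#'   \item{`"thompson"`}{one reliability draw per Sender from its Beta
#'     posterior; the Sender with the higher draw wins. Early in a
#'     session the posteriors are wide and the choice is near-random;
#'     as evidence accumulates the choice concentrates on the reliable
#'     Sender, giving the gradual block-wise learning trajectory seen in
#'     human Receivers (the argmax rule instead saturates after the
#'     first feedback).}
#' }
#' Percepts are taken at face value: the model has no awareness of
#' channel errors.
#'
#' @param percepts Integer pair (Sender 1, Sender 2), 1 = phosphene
#'   (rotate), 0 = none.
#' @param trust A [trust_state()].
#' @param policy `"argmax"` or `"thompson"`.
#' @return 0/1 decision.
#' @export
receiver_decide <- function(percepts, trust, policy = c("argmax", "thompson")) {
  stopifnot(length(percepts) == 2L, all(percepts %in% c(0, 1)))
  policy <- match.arg(policy)
  if (percepts[1] == percepts[2]) return(as.integer(percepts[1]))
  if (policy == "thompson") {
    a <- trust$prior + trust$counts[, "agree"]
    b <- trust$prior + trust$counts[, "disagree"]
    draw <- stats::rbeta(2, a, b)
    return(as.integer(percepts[which.max(draw)]))
  }
  w <- trust_weights(trust)
  if (w[1] > w[2]) as.integer(percepts[1])
  else if (w[2] > w[1]) as.integer(percepts[2])
  else as.integer(percepts[sample(1:2, 1L)])
}

#' Update trust from end-of-trial feedback
#'
#' After a trial resolves, all participants see the outcome; the Receiver
#' can then compare each Sender's percept-implied action with the action
#' that was actually correct in that round and increment the matching
#' evidence count. Updates happen only on end-of-trial feedback, never
#' mid-trial.
#'
#' @param trust A [trust_state()].
#' @param percepts Integer pair of percepts for one round.
#' @param correct The correct 0/1 action for that round.
#' @return The updated [trust_state()].
#' @export
trust_update <- function(trust, percepts, correct) {
  stopifnot(length(percepts) == 2L, correct %in% c(0, 1))
  for (s in 1:2) {
    col <- if (percepts[s] == correct) "agree" else "disagree"
    trust$counts[s, col] <- trust$counts[s, col] + 1
  }
  trust
}

#' Agent parameter bundle for a session
#'
#' @param sender1,sender2 [sender_model()]s for the two Senders.
#' @param trust_prior Beta pseudo-count for the Receiver's
#'   [trust_state()]. The session-level default of 8 encodes a
#'   conservative prior — prior evidence worth half a session of feedback
#'   per outcome — so that posterior uncertainty decays over the course
#'   of a session rather than within the first trial, as it does for
#'   human Receivers.
#' @param receiver_policy Disagreement policy for [receiver_decide()];
#'   posterior sampling (`"thompson"`) by default, which reproduces the
#'   gradual reliability learning of human Receivers.
#' @return An object of class `"agent_params"`.
#' @export
agent_params <- function(sender1 = sender_model(), sender2 = sender_model(),
                         trust_prior = 8,
                         receiver_policy = c("thompson", "argmax")) {
  structure(list(senders = list(sender1, sender2), trust_prior = trust_prior,
                 receiver_policy = match.arg(receiver_policy)),
            class = "agent_params")
}
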