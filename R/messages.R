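# Message protocol: constructing honest and deceptive claims, drawing the
# blush cue, and the receiver-side evaluation quantities (surprise,
# confession, blush likelihood ratio, honesty weight).

#' Construct an honest message
#'
#' An honest speaker transmits its current belief on the topic unchanged,
#' as the tuple `(mu, la)`.
#'
#' @param speaker_belief_on_topic The speaker's belief state about the topic
#'   agent's honesty.
#' @return The communicated claim (a belief state).
#' @export
construct_honest_message <- function(speaker_belief_on_topic) {
  as_belief(speaker_belief_on_topic)
}

#' Construct a lie
#'
#' A lying speaker anchors the claim at its theory-of-mind estimate of the
#' receiver's current belief on the topic (to sound convincing) and shifts
#' the mean by adding `alpha` pseudo-counts: to `mu` for a positive lie, to
#' `la` for a negative one (to take influence).
#'
#' @param tom_estimate The speaker's estimate of the receiver's belief on
#'   the topic (a belief state).
#' @param direction `"positive"` or `"negative"`.
#' @param alpha Positive lie shift in pseudo-counts (default 2).
#' @return The communicated claim (a belief state).
#' @examples
#' construct_lie(belief(5, 18), "positive", alpha = 2)  # (7, 18)
#' @export
construct_lie <- function(tom_estimate, direction = c("positive", "negative"),
                          alpha = 2) {
  direction <- match.arg(direction)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  b <- as_belief(tom_estimate)
  if (direction == "positive") belief(b[[1]] + alpha, b[[2]])
  else belief(b[[1]], b[[2]] + alpha)
}

#' Draw the blush cue
#'
#' A blush is an involuntary deception cue: it never accompanies a truth,
#' and accompanies a lie with probability `blush_prob` -- unless the speaker
#' suppresses blushing altogether (the destructive strategy).
#'
#' @param truth_flag Logical; was the statement honest?
#' @param suppresses_blush Logical; does the speaker never blush when lying?
#' @param blush_prob Probability of blushing on a non-suppressed lie.
#' @return Logical: whether a blush is emitted.
#' @export
draw_blush <- function(truth_flag, suppresses_blush = FALSE, blush_prob = 0.1) {
  if (!is.numeric(blush_prob) || blush_prob < 0 || blush_prob > 1)
    stop("'blush_prob' must be a probability", call. = FALSE)
  if (isTRUE(truth_flag) || isTRUE(suppresses_blush)) return(FALSE)
  runif(1) < blush_prob
}

#' Construct a message object
#'
#' Bundles a communicated claim with its routing information and the
#' engine-only ground truth. The `truth_flag` is never visible to receiving
#' agents; it exists for logging and for the hard invariant that a blush
#' never accompanies a truth.
#'
#' @param speaker,receiver,topic Agent identifiers.
#' @param claim The communicated belief state.
#' @param blush Logical blush cue.
#' @param truth_flag Logical ground truth (engine-only); `NA` if unknown.
#' @return An object of class `rg_message`.
#' @export
rg_message <- function(speaker, receiver, topic, claim, blush = FALSE,
                       truth_flag = NA) {
  claim <- as_belief(claim)
  if (isTRUE(blush) && isTRUE(truth_flag))
    stop("invalid message: a blush can never accompany a truth", call. = FALSE)
  if (identical(speaker, receiver))
    stop("invalid message: speaker and receiver must differ", call. = FALSE)
  structure(list(speaker = speaker, receiver = receiver, topic = topic,
                 claim = claim, blush = isTRUE(blush),
                 truth_flag = truth_flag),
            class = "rg_message")
}

#' Blush-frequency beliefs
#'
#' The pair of belief states an agent holds about the blush frequencies:
#' `lie_freq` over the probability of a blush given a lie, and `truth_freq`
#' over the probability of a blush given a truth.
#'
#' @param lie_freq,truth_freq Belief states.
#' @return An object of class `rg_blush_beliefs`.
#' @export
blush_beliefs <- function(lie_freq = belief(), truth_freq = belief()) {
  structure(list(lie_freq = as_belief(lie_freq),
                 truth_freq = as_belief(truth_freq)),
            class = "rg_blush_beliefs")
}

#' Surprise of an incoming claim
#'
#' The KL divergence (nats) of the communicated claim from the receiver's
#' prior belief on the topic. Large surprise lowers the perceived
#' credibility of the message, which keeps effective lies small.
#'
#' @param claim The communicated belief state.
#' @param receiver_prior_on_topic The receiver's prior belief on the topic.
#' @return A nonnegative number (nats); zero iff the claim equals the prior.
#' @export
surprise <- function(claim, receiver_prior_on_topic) {
  kl_beta(claim, receiver_prior_on_topic)
}

#' Per-observation (predictive) surprise of an incoming claim
#'
#' The KL divergence between the Bernoulli next-event distributions implied
#' by the posterior means of the claim and of the receiver's prior:
#' `m_c log(m_c/m_p) + (1 - m_c) log((1 - m_c)/(1 - m_p))`. This is the
#' surprise measure entering the credibility ratio during belief updating:
#' unlike the full beta divergence of [surprise()], it is bounded for means
#' inside (0, 1) and does not grow with the sharpness of the two beliefs,
#' so skepticism is driven by how far the claimed frequency sits from the
#' receiver's estimate rather than by accumulated evidence volume.
#'
#' @inheritParams surprise
#' @return A nonnegative number (nats); zero iff the two means coincide.
#' @export
predictive_surprise <- function(claim, receiver_prior_on_topic) {
  claim <- as_belief(claim)
  prior <- as_belief(receiver_prior_on_topic)
  cpp_pred_surprise(claim[[1]], claim[[2]], prior[[1]], prior[[2]])
}

#' Is a message a confession?
#'
#' A confession is a self-directed message (topic equals speaker) whose
#' claimed mean is strictly worse than the opinion the receiver already
#' holds of the speaker. Confessions are always believed: even if such a
#' statement were a lie, adopting it lowers the liar's reputation.
#'
#' @param msg An [rg_message()].
#' @param receiver_belief_on_speaker The receiver's belief about the
#'   speaker's honesty.
#' @return Logical.
#' @export
is_confession <- function(msg, receiver_belief_on_speaker) {
  if (!inherits(msg, "rg_message")) stop("'msg' must be an rg_message", call. = FALSE)
  identical(msg$topic, msg$speaker) &&
    belief_mean(msg$claim) < belief_mean(receiver_belief_on_speaker)
}

#' Blush likelihood ratio
#'
#' The ratio between the likelihoods of the observed cue under the lie
#' versus the truth hypothesis, evaluated at the means of the agent's
#' blush-frequency beliefs: `mean(lie_freq) / mean(truth_freq)` when a
#' blush was observed, `(1 - mean(lie_freq)) / (1 - mean(truth_freq))`
#' otherwise. Always finite because belief means are strictly inside (0, 1).
#'
#' @param blush Logical; was a blush observed?
#' @param bb An [blush_beliefs()] object.
#' @return A positive number.
#' @export
blush_likelihood_ratio <- function(blush, bb) {
  if (!inherits(bb, "rg_blush_beliefs"))
    stop("'bb' must be an rg_blush_beliefs object", call. = FALSE)
  fl <- belief_mean(bb$lie_freq)
  ft <- belief_mean(bb$truth_freq)
  if (isTRUE(blush)) fl / ft else (1 - fl) / (1 - ft)
}

#' Combine blush ratio and surprise into a lie/truth evidence ratio
#'
#' The total evidence ratio used in [honesty_weight()]:
#' `R_total = R_blush * exp(gamma * surprise)`, with the exponent capped at
#' `max_exponent` to guard against overflow.
#'
#' @param blush_ratio Output of [blush_likelihood_ratio()].
#' @param surprise_nats Output of [surprise()].
#' @param gamma Nonnegative weight of the surprise term (default 1).
#' @param max_exponent Cap on `gamma * surprise` (default 50).
#' @return A nonnegative number.
#' @export
credibility_ratio <- function(blush_ratio, surprise_nats, gamma = 1,
                              max_exponent = 50) {
  if (gamma < 0) stop("'gamma' must be nonnegative", call. = FALSE)
  blush_ratio * exp(min(gamma * surprise_nats, max_exponent))
}

#' Honesty weight of a received message
#'
#' The probability the receiver assigns to the message being honest. A
#' confession is believed outright (weight 1). Otherwise the speaker's
#' reputation mean `x` is combined with the total lie/truth evidence ratio
#' `r` by posterior odds: `y = x / (x + (1 - x) * r)`. The weight increases
#' with reputation and decreases with the evidence ratio.
#'
#' @param speaker_reputation_mean The mean of the receiver's belief about
#'   the speaker's honesty.
#' @param total_ratio Nonnegative evidence ratio (see [credibility_ratio()]);
#'   may be `Inf`.
#' @param confession Logical.
#' @return A probability in `[0, 1]`.
#' @examples
#' honesty_weight(0.9, 9)    # 0.5
#' honesty_weight(0.5, 1)    # 0.5
#' honesty_weight(0.2, 3, confession = TRUE)  # 1
#' @export
honesty_weight <- function(speaker_reputation_mean, total_ratio,
                           confession = FALSE) {
  x <- speaker_reputation_mean
  if (!is.numeric(x) || x < 0 || x > 1)
    stop("'speaker_reputation_mean' must be a probability", call. = FALSE)
  if (isTRUE(confession)) return(1)
  if (is.infinite(total_ratio)) return(0)
  x / (x + (1 - x) * total_ratio)
}
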