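# Receiver-side learning: the joint update of speaker-honesty belief, topic
# belief, blush-frequency beliefs, theory of mind and friendship from one
# received message; speaker self-observation; and the LICS predicate.

#' Process one received message
#'
#' Applies the full receiver-side update for one message:
#'
#' 1. the honesty weight `y_h` is computed from the confession test, the
#'    surprise (KL divergence of the claim from the receiver's prior on the
#'    topic), and the blush likelihood ratio;
#' 2. the speaker-honesty belief gains one unit of evidence split as
#'    `mu += y_h`, `la += 1 - y_h`;
#' 3. the topic belief becomes the compression of the two-component mixture
#'    `{y_h: fuse(prior, claim); 1 - y_h: prior}` (under the lie hypothesis
#'    the content is discarded and the prior kept);
#' 4. the blush-frequency beliefs gain one unit of evidence split between
#'    the lie and truth channels by `1 - y_h` and `y_h`;
#' 5. the theory-of-mind entry for (speaker, topic) becomes the compression
#'    of `{y_h: claim; 1 - y_h: previous estimate}`;
#' 6. if the topic is the receiver itself, the friendship ledger is updated.
#'
#' In oracle mode (`known_frequencies = TRUE`) a blush certifies a lie
#' (`y_h = 0` exactly) and blush-frequency learning is disabled.
#'
#' @param world An `rg_world`.
#' @param msg An [rg_message()]; `msg$receiver` must differ from
#'   `msg$speaker`.
#' @param params An [model_params()] object.
#' @return A list with elements `world` (the updated world) and `trace`
#'   (a list with `y_h`, `surprise`, `ratio_blush`, `confession`).
#' @export
receive <- function(world, msg, params = model_params()) {
  if (!inherits(msg, "rg_message")) stop("'msg' must be an rg_message", call. = FALSE)
  r <- agent_index(world, msg$receiver)
  s <- agent_index(world, msg$speaker)
  t <- agent_index(world, msg$topic)
  if (r == s) stop("an agent cannot receive its own message", call. = FALSE)
  res <- cpp_receive(world, params_for_core(params), r - 1L, s - 1L, t - 1L,
                     msg$claim[[1]], msg$claim[[2]], msg$blush)
  list(world = rehydrate_world(res$world, world), trace = res$trace)
}

#' Speaker self-observation
#'
#' After emitting a message the speaker records exact counts of its own
#' behavior in its blush-frequency beliefs -- the one channel of reliable
#' self-perception: a blushing lie increments `lie_freq.mu`, a non-blushing
#' lie `lie_freq.la`, and a truth `truth_freq.la` (truths never blush).
#' Honesty beliefs are not touched; agents learn about their own honesty
#' only through what others tell them. Disabled in oracle mode.
#'
#' @param world An `rg_world`.
#' @param agent The speaking agent.
#' @param truth_flag Logical; was the statement honest?
#' @param blush Logical; did the speaker blush?
#' @param params An [model_params()] object.
#' @return The updated world.
#' @export
self_observe <- function(world, agent, truth_flag, blush,
                         params = model_params()) {
  if (isTRUE(blush) && isTRUE(truth_flag))
    stop("a blush can never accompany a truth", call. = FALSE)
  a <- agent_index(world, agent)
  state <- cpp_self_observe(world, params_for_core(params), a - 1L,
                            isTRUE(truth_flag), isTRUE(blush))
  rehydrate_world(state, world)
}

#' LICS predicate
#'
#' An agent has learned the insignificance of the blush cue when its
#' estimated blush frequencies are too similar:
#' `upper_margin * mean(truth_freq) > lower_margin * mean(lie_freq)`.
#' With the default margins (1.1, 0.9) the flag flips exactly at a
#' frequency ratio `lie/truth` of 11/9.
#'
#' @param bb An [blush_beliefs()] object.
#' @param upper_margin,lower_margin Margins of the inequality.
#' @return Logical.
#' @examples
#' lics_flag(blush_beliefs(belief(1, 9), belief(0, 20)))   # FALSE: ratio large
#' lics_flag(blush_beliefs(belief(1, 9), belief(1, 9)))    # TRUE: equal means
#' @export
lics_flag <- function(bb, upper_margin = 1.1, lower_margin = 0.9) {
  if (!inherits(bb, "rg_blush_beliefs"))
    stop("'bb' must be an rg_blush_beliefs object", call. = FALSE)
  upper_margin * belief_mean(bb$truth_freq) >
    lower_margin * belief_mean(bb$lie_freq)
}
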