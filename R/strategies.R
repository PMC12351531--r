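# Per-strategy behavior: honesty draw, partner and topic selection, lie
# direction, blush suppression, and the friendship ledger. The compiled
# engine uses the same kernels; these functions expose them on single
# worlds for inspection and testing.

#' Draw whether an agent speaks honestly
#'
#' A Bernoulli draw with the agent's intrinsic honesty as success
#' probability, taken from the current R random stream.
#'
#' @param world An `rg_world`.
#' @param agent Agent id (or index).
#' @return Logical.
#' @export
decide_honest <- function(world, agent) {
  a <- agent_index(world, agent)
  runif(1) < world$honesty[[a]]
}

#' Partner-selection weights for a strategy
#'
#' Ordinary and deceptive agents pick uniformly; manipulative agents prefer
#' agents they believe dishonest (weight `1 - mean`); dominant and
#' destructive agents prefer agents they believe honest (weight `mean`).
#'
#' @param strategy A strategy name.
#' @param candidate_means Means of the selecting agent's honesty beliefs
#'   about each candidate.
#' @return Normalized selection probabilities.
#' @export
partner_weights <- function(strategy, candidate_means) {
  strategy_code(strategy)
  w <- switch(strategy,
              manipulative = 1 - candidate_means,
              dominant = candidate_means,
              destructive = candidate_means,
              rep(1, length(candidate_means)))
  w / sum(w)
}

#' Select a conversation partner
#'
#' @param world An `rg_world`.
#' @param agent The initiating agent.
#' @param candidates Candidate ids; defaults to everyone else.
#' @return The selected partner id.
#' @export
select_partner <- function(world, agent, candidates = NULL) {
  a <- agent_index(world, agent)
  if (is.null(candidates)) candidates <- setdiff(world$ids, world$ids[a])
  if (length(candidates) == 0)
    stop("no candidate partners available", call. = FALSE)
  idx <- agent_index(world, candidates)
  if (a %in% idx) stop("candidates must exclude the agent itself", call. = FALSE)
  means <- vapply(idx, function(b)
    belief_mean(honesty_belief(world, a, b)), numeric(1))
  w <- partner_weights(world$strategy[[a]], means)
  world$ids[idx[sample.int(length(idx), 1, prob = w)]]
}

#' Select a conversation topic
#'
#' Ordinary and deceptive agents pick uniformly over the whole roster
#' (including themselves and the partner); manipulative agents always pick
#' the partner; dominant agents pick themselves half of the time and
#' otherwise uniformly over the roster; destructive agents pick uniformly
#' over their current enemies, falling back to everyone but themselves if
#' no enemies exist yet.
#'
#' @param world An `rg_world`.
#' @param agent The initiating agent.
#' @param partner The selected partner.
#' @return The selected topic id.
#' @export
select_topic <- function(world, agent, partner) {
  a <- agent_index(world, agent)
  p <- agent_index(world, partner)
  ids <- world$ids
  switch(world$strategy[[a]],
    manipulative = ids[p],
    dominant = if (runif(1) < 0.5) ids[a] else ids[sample.int(world$n, 1)],
    destructive = {
      enemies <- ids[vapply(seq_len(world$n), function(c)
        c != a && friendship_status(world, a, c) == "enemy", logical(1))]
      if (length(enemies) > 0) enemies[sample.int(length(enemies), 1)]
      else {
        others <- ids[-a]
        others[sample.int(length(others), 1)]
      }
    },
    ids[sample.int(world$n, 1)]
  )
}

#' Direction of a lie
#'
#' Lies about oneself are positive; manipulative agents flatter their
#' conversation partner (positive); otherwise lies about friends and
#' neutral agents are positive and lies about enemies negative.
#'
#' @param world An `rg_world`.
#' @param speaker,receiver,topic Agent ids (or indices).
#' @return `"positive"` or `"negative"`.
#' @export
lie_direction <- function(world, speaker, receiver, topic) {
  s <- agent_index(world, speaker)
  r <- agent_index(world, receiver)
  t <- agent_index(world, topic)
  if (t == s) return("positive")
  if (world$strategy[[s]] == "manipulative" && t == r) return("positive")
  if (friendship_status(world, s, t) == "enemy") "negative" else "positive"
}

#' Friendship classification
#'
#' A counterpart is a friend if its running mean of communicated opinions
#' about oneself exceeds the grand mean of all opinions received about
#' oneself (pooled over all speakers), an enemy if it falls below, and
#' neutral on ties or when no opinion has been received from it.
#'
#' @param world An `rg_world`.
#' @param agent,counterpart Agent ids (or indices).
#' @return `"friend"`, `"enemy"` or `"neutral"`.
#' @export
friendship_status <- function(world, agent, counterpart) {
  a <- agent_index(world, agent)
  c <- agent_index(world, counterpart)
  code <- cpp_fstatus(world, a - 1L, c - 1L)
  c("enemy", "neutral", "friend")[code + 2L]
}

#' Record a received opinion about oneself in the friendship ledger
#'
#' Only messages whose topic is the receiving agent itself feed the ledger:
#' the claim's mean is appended to the speaker's running record.
#'
#' @param world An `rg_world`.
#' @param msg An [rg_message()] with `topic == receiver`.
#' @return The updated world.
#' @export
update_friendship <- function(world, msg) {
  if (!inherits(msg, "rg_message")) stop("'msg' must be an rg_message", call. = FALSE)
  if (!identical(msg$topic, msg$receiver))
    stop("only messages about the receiving agent feed the ledger", call. = FALSE)
  r <- agent_index(world, msg$receiver)
  s <- agent_index(world, msg$speaker)
  world$fr_cnt[r, s] <- world$fr_cnt[r, s] + 1
  world$fr_sum[r, s] <- world$fr_sum[r, s] + belief_mean(msg$claim)
  world
}
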