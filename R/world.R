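# World state: the joint internal state of all agents in a run. Stored as
# flat numeric matrices/arrays so the compiled engine can work on it
# directly; the accessors below present it in terms of belief states.
#
# Layout (n agents, indexed in roster order):
#   hb_mu, hb_la  n x n   [a, b] = agent a's belief about b's honesty
#   bb            n x 4   lie_mu, lie_la, truth_mu, truth_la per agent
#   tom_mu/tom_la n x n x n  [a, c, t] = a's estimate of c's belief about t
#   fr_cnt/fr_sum n x n   friendship ledger: count and sum of claim means
#                          of messages c sent to a about a itself

#' Strategy names
#'
#' The five communication strategies. All strategies other than `ordinary`
#' imply an intrinsic honesty of 0.
#'
#' @return A character vector of the valid strategy names.
#' @export
rg_strategies <- function() {
  c("ordinary", "deceptive", "manipulative", "dominant", "destructive")
}

strategy_code <- function(strategy) {
  code <- match(strategy, rg_strategies())
  if (anyNA(code))
    stop("unknown strategy: ", paste(strategy[is.na(code)], collapse = ", "),
         call. = FALSE)
  as.integer(code - 1L)
}

#' Create an agent roster
#'
#' @param id Character vector of unique agent identifiers.
#' @param honesty Intrinsic honesties in `[0, 1]`; must be 0 for every
#'   non-ordinary strategy.
#' @param strategy Strategy names (see [rg_strategies()]).
#' @return A data frame with columns `id`, `honesty`, `strategy`.
#' @export
agent_roster <- function(id, honesty, strategy = "ordinary") {
  id <- as.character(id)
  strategy <- rep_len(strategy, length(id))
  honesty <- rep_len(honesty, length(id))
  if (anyDuplicated(id)) stop("agent ids must be unique", call. = FALSE)
  if (any(honesty < 0 | honesty > 1))
    stop("'honesty' values must lie in [0, 1]", call. = FALSE)
  strategy_code(strategy)  # validates names
  special <- strategy != "ordinary"
  if (any(special & honesty != 0))
    stop("non-ordinary strategies require intrinsic honesty 0", call. = FALSE)
  data.frame(id = id, honesty = honesty, strategy = strategy,
             stringsAsFactors = FALSE)
}

#' Create a fresh world
#'
#' All honesty beliefs, theory-of-mind entries, blush-frequency beliefs and
#' friendship ledgers start uninformed (all pseudo-counts zero).
#'
#' @param agents An [agent_roster()] data frame.
#' @return An object of class `rg_world`.
#' @export
new_world <- function(agents) {
  agents <- agent_roster(agents$id, agents$honesty, agents$strategy)
  n <- nrow(agents)
  if (n < 2) stop("a world needs at least 2 agents", call. = FALSE)
  ids <- agents$id
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  structure(list(
    n = n,
    ids = ids,
    honesty = setNames(agents$honesty, ids),
    strategy = setNames(agents$strategy, ids),
    strategy_code = strategy_code(agents$strategy),
    hb_mu = m, hb_la = m,
    bb = matrix(0, n, 4,
                dimnames = list(ids, c("lie_mu", "lie_la", "truth_mu", "truth_la"))),
    tom_mu = array(0, c(n, n, n), dimnames = list(ids, ids, ids)),
    tom_la = array(0, c(n, n, n), dimnames = list(ids, ids, ids)),
    fr_cnt = m, fr_sum = m,
    t_end = 0
  ), class = "rg_world")
}

#' @export
print.rg_world <- function(x, ...) {
  cat(sprintf("<rg_world: %d agents [%s] at t=%d>\n", x$n,
              paste(sprintf("%s(%s,%.2f)", x$ids, substr(x$strategy, 1, 3),
                            x$honesty), collapse = ", "),
              as.integer(x$t_end)))
  invisible(x)
}

agent_index <- function(world, id) {
  if (is.numeric(id)) {
    idx <- as.integer(id)
  } else {
    idx <- match(as.character(id), world$ids)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > world$n))
    stop("unknown agent: ", paste(id, collapse = ", "), call. = FALSE)
  idx
}

# restore R-side metadata after the compiled core returns a bare state list
rehydrate_world <- function(state, template) {
  ids <- template$ids
  out <- template
  out$hb_mu <- state$hb_mu
  out$hb_la <- state$hb_la
  out$bb <- state$bb
  out$tom_mu <- state$tom_mu
  out$tom_la <- state$tom_la
  out$fr_cnt <- state$fr_cnt
  out$fr_sum <- state$fr_sum
  dimnames(out$hb_mu) <- dimnames(out$hb_la) <- list(ids, ids)
  dimnames(out$fr_cnt) <- dimnames(out$fr_sum) <- list(ids, ids)
  dimnames(out$bb) <- list(ids, c("lie_mu", "lie_la", "truth_mu", "truth_la"))
  dimnames(out$tom_mu) <- dimnames(out$tom_la) <- list(ids, ids, ids)
  out
}

#' Extract an agent's honesty belief about another agent
#'
#' @param world An `rg_world`.
#' @param agent,about Agent ids (or indices).
#' @return A belief state.
#' @export
honesty_belief <- function(world, agent, about) {
  a <- agent_index(world, agent)
  b <- agent_index(world, about)
  belief(world$hb_mu[a, b], world$hb_la[a, b])
}

#' Extract an agent's blush-frequency beliefs
#'
#' @param world An `rg_world`.
#' @param agent Agent id (or index).
#' @return An [blush_beliefs()] object.
#' @export
blush_beliefs_of <- function(world, agent) {
  a <- agent_index(world, agent)
  blush_beliefs(lie_freq = belief(world$bb[a, 1], world$bb[a, 2]),
                truth_freq = belief(world$bb[a, 3], world$bb[a, 4]))
}

#' Extract a theory-of-mind entry
#'
#' Agent `agent`'s estimate of `counterpart`'s belief about `topic`.
#'
#' @param world An `rg_world`.
#' @param agent,counterpart,topic Agent ids (or indices).
#' @return A belief state.
#' @export
tom_belief <- function(world, agent, counterpart, topic) {
  a <- agent_index(world, agent)
  c <- agent_index(world, counterpart)
  t <- agent_index(world, topic)
  belief(world$tom_mu[a, c, t], world$tom_la[a, c, t])
}

#' Reputation of an agent
#'
#' The average honesty of `target` as perceived by the others: the
#' arithmetic mean, over all agents `a != target`, of the mean of `a`'s
#' belief about `target`.
#'
#' @param world An `rg_world`.
#' @param target Agent id (or index).
#' @return A probability.
#' @export
reputation <- function(world, target) {
  b <- agent_index(world, target)
  others <- setdiff(seq_len(world$n), b)
  mean((world$hb_mu[others, b] + 1) /
       (world$hb_mu[others, b] + world$hb_la[others, b] + 2))
}

#' Informedness of an agent
#'
#' An index of how accurately an agent's honesty beliefs place probability
#' mass on the true intrinsic honesties around it: the mean, over the
#' in-scope agents (including the agent itself), of the log-density of the
#' agent's belief evaluated at the true honesty (clamped to
#' `[1e-6, 1 - 1e-6]`). Zero for fully uninformed beliefs; grows with both
#' accuracy and sharpness.
#'
#' @param world An `rg_world`.
#' @param agent Agent id (or index).
#' @param true_honesties Optional named vector of true honesties; defaults
#'   to the world's intrinsic honesties.
#' @param scope `"all"` (every agent) or `"ordinary_only"` (only agents
#'   playing the ordinary strategy).
#' @return A real number; higher means better informed.
#' @export
informedness <- function(world, agent, true_honesties = NULL,
                         scope = c("all", "ordinary_only")) {
  scope <- match.arg(scope)
  a <- agent_index(world, agent)
  truths <- if (is.null(true_honesties)) world$honesty
            else true_honesties[world$ids]
  cpp_informedness(world, a - 1L, as.numeric(truths),
                   scope == "ordinary_only")
}
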