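# Run configuration: model constants plus the agent roster and scheduling
# options for a single simulation.

#' Model parameters
#'
#' The constants of the communication model, shared by single-message
#' operations and full runs.
#'
#' @param blush_prob Probability that a (non-suppressed) lie is accompanied
#'   by a blush. Default 0.1.
#' @param alpha Lie shift in pseudo-counts. Default 2.
#' @param gamma Weight of the surprise term in the credibility ratio.
#'   Default 1.
#' @param known_frequencies Oracle mode: agents evaluate blushes at the
#'   exact frequencies (`blush_prob` for lies, 0 for truths) and blush
#'   learning is disabled. Default `FALSE`.
#' @param lics_margins Two numbers `(upper, lower)`: an agent is in a LICS
#'   state when `upper * mean(truth_freq) > lower * mean(lie_freq)`.
#'   Default `c(1.1, 0.9)`, i.e. a boundary ratio of 11/9.
#' @param max_exponent Cap on `gamma * surprise` before exponentiation.
#'   Default 50.
#' @param evidence_cap Maximum observations' worth of novel evidence a
#'   single message may contribute to the receiver's topic belief.
#' @param self_weight Pseudo-count weight of one self-observation in the
#'   speaker's belief about its own honesty (0 = self-image is pure social
#'   information, 1 = perfect self-knowledge).
#' @param initiator `"random"` (uniform each timestep) or `"round_robin"`.
#' @return A list of class `rg_params`.
#' @export
model_params <- function(blush_prob = 0.1, alpha = 2, gamma = 1,
                         known_frequencies = FALSE,
                         lics_margins = c(1.1, 0.9), max_exponent = 50,
                         evidence_cap = 2, self_weight = 1,
                         initiator = c("random", "round_robin")) {
  initiator <- match.arg(initiator)
  stopifnot(blush_prob >= 0, blush_prob <= 1, alpha > 0, gamma >= 0,
            length(lics_margins) == 2, all(lics_margins > 0),
            max_exponent > 0, evidence_cap > 0,
            self_weight >= 0, self_weight <= 1)
  structure(list(blush_prob = blush_prob, alpha = alpha, gamma = gamma,
                 known_frequencies = isTRUE(known_frequencies),
                 lics_margins = as.numeric(lics_margins),
                 max_exponent = max_exponent, evidence_cap = evidence_cap,
                 self_weight = self_weight, initiator = initiator),
            class = "rg_params")
}

#' Simulation configuration
#'
#' Full specification of one run: the roster, the number of conversations,
#' the model constants, the seed, and recording options. One timestep is
#' one conversation and produces exactly two messages (the initiator's and
#' the partner's response).
#'
#' @param agents An [agent_roster()] data frame (at least two agents).
#' @param n_timesteps Number of conversations. Default 4500.
#' @param seed Integer seed for the run; every source of randomness in the
#'   run derives from it.
#' @param params An [model_params()] object.
#' @param record_every Trajectory recording cadence in timesteps (default
#'   1: record every step). LICS episodes are always tracked at every step.
#' @param record_messages Whether to keep the per-message log.
#' @return A list of class `rg_config`.
#' @export
sim_config <- function(agents, n_timesteps = 4500, seed = 1L,
                       params = model_params(), record_every = 1L,
                       record_messages = FALSE) {
  agents <- agent_roster(agents$id, agents$honesty, agents$strategy)
  problems <- character(0)
  if (nrow(agents) < 2) problems <- c(problems, "need at least 2 agents")
  if (!is.numeric(n_timesteps) || n_timesteps < 1)
    problems <- c(problems, "'n_timesteps' must be a positive integer")
  if (!inherits(params, "rg_params"))
    problems <- c(problems, "'params' must come from model_params()")
  if (length(problems) > 0)
    stop("invalid configuration: ", paste(problems, collapse = "; "),
         call. = FALSE)
  n_special <- sum(agents$strategy != "ordinary")
  if (n_special > 1)
    warning("more than one special-strategy agent in the roster", call. = FALSE)
  structure(list(agents = agents,
                 n_timesteps = as.integer(n_timesteps),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 params = params,
                 record_every = as.integer(record_every),
                 record_messages = isTRUE(record_messages)),
            class = "rg_config")
}

# flat key-value representation used by the compiled core
params_for_core <- function(params) {
  list(blush_prob = params$blush_prob, alpha = params$alpha,
       gamma = params$gamma, lics_margins = params$lics_margins,
       max_exponent = params$max_exponent,
       evidence_cap = params$evidence_cap,
       self_weight = params$self_weight,
       known_frequencies = params$known_frequencies,
       initiator = params$initiator)
}

#' Read a simulation configuration from a YAML file
#'
#' The file mirrors the [sim_config()] fields: an `agents` list of
#' `(id, honesty, strategy)` entries, `n_timesteps`, `seed`,
#' `record_every`, `record_messages`, and any [model_params()] fields at
#' the top level.
#'
#' @param path Path to a YAML file.
#' @return An `rg_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  ag <- do.call(rbind, lapply(raw$agents, function(a)
    data.frame(id = a$id, honesty = a$honesty,
               strategy = if (is.null(a$strategy)) "ordinary" else a$strategy,
               stringsAsFactors = FALSE)))
  pkeys <- c("blush_prob", "alpha", "gamma", "known_frequencies",
             "lics_margins", "max_exponent", "evidence_cap", "self_weight",
             "initiator")
  pargs <- raw[intersect(names(raw), pkeys)]
  params <- do.call(model_params, pargs)
  sim_config(agents = ag,
             n_timesteps = if (is.null(raw$n_timesteps)) 4500 else raw$n_timesteps,
             seed = if (is.null(raw$seed)) 1L else raw$seed,
             params = params,
             record_every = if (is.null(raw$record_every)) 1L else raw$record_every,
             record_messages = isTRUE(raw$record_messages))
}

#' Write a simulation configuration to a YAML file
#'
#' @param config An `rg_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configuration files",
         call. = FALSE)
  agents <- lapply(seq_len(nrow(config$agents)), function(i)
    list(id = config$agents$id[i], honesty = config$agents$honesty[i],
         strategy = config$agents$strategy[i]))
  out <- c(list(agents = agents, n_timesteps = config$n_timesteps,
                seed = config$seed, record_every = config$record_every,
                record_messages = config$record_messages),
           unclass(config$params))
  yaml::write_yaml(out, path)
  invisible(path)
}
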