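# Single-run driver: scheduling, RNG management, trajectory recording.

traj_colnames <- function(ids) {
  n <- length(ids)
  rep_cols <- character(0)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    rep_cols <- c(rep_cols, paste0("rep_", ids[a], "_", ids[b]))
  }
  agent_cols <- unlist(lapply(ids, function(id)
    paste0(c("fblie_", "fbtruth_", "lics_", "info_all_", "info_ord_"), id)))
  c("t", rep_cols, agent_cols, "msgs", "honest_msgs")
}

#' Run one simulation
#'
#' Executes `n_timesteps` conversations. Each timestep: an initiator is
#' drawn, selects a partner and a topic according to its strategy, composes
#' and sends a message (honesty draw, lie construction, blush draw,
#' self-observation), which the partner processes; the partner then
#' composes a response on the same topic -- after updating on the
#' initiator's message -- which the initiator processes. A timestep thus
#' produces exactly two messages. Runs are fully deterministic given the
#' configuration and its seed.
#'
#' @param config An [sim_config()].
#' @param world Optional starting world (for continuations); defaults to a
#'   fresh uninformed world built from `config$agents`.
#' @param set_seed Whether to call `set.seed(config$seed)` before running.
#'   Set to `FALSE` to continue consuming an already-seeded stream.
#' @return An object of class `rg_sim`: a list with
#'   \describe{
#'     \item{trajectory}{data frame, one row per recorded timestep: `t`,
#'       pairwise reputation means `rep_<a>_<b>` (b as seen by a), per-agent
#'       blush-frequency means `fblie_*`/`fbtruth_*`, LICS flags `lics_*`,
#'       informedness `info_all_*`/`info_ord_*`, and cumulative message
#'       counts.}
#'     \item{messages}{data frame message log (if requested): `t`,
#'       `speaker`, `receiver`, `topic`, `honest`, `blush`, `y_h`,
#'       `surprise`, `ratio_blush`, `confession`.}
#'     \item{episodes}{data frame of LICS episodes: `agent`, `start`,
#'       `end`, `ongoing`.}
#'     \item{counts}{per-agent message counts: sent, honest, lies,
#'       blushes.}
#'     \item{world}{the final world state.}
#'     \item{summary}{final reputations, honest-message fraction, episode
#'       table, configuration echo.}
#'   }
#' @examples
#' cfg <- sim_config(agent_roster(c("black", "cyan", "red"),
#'                                c(0.97, 0.80, 0.14)),
#'                   n_timesteps = 200, seed = 7)
#' sim <- run_simulation(cfg)
#' sim$summary$final_reputation
#' @export
run_simulation <- function(config, world = NULL, set_seed = TRUE) {
  if (!inherits(config, "rg_config"))
    stop("'config' must come from sim_config()", call. = FALSE)
  if (is.null(world)) world <- new_world(config$agents)
  if (!inherits(world, "rg_world")) stop("'world' must be an rg_world", call. = FALSE)
  if (isTRUE(set_seed)) {
    if (is.null(config$seed)) stop("config has no seed", call. = FALSE)
    set.seed(config$seed)
  }
  ids <- world$ids
  res <- cpp_run(world, params_for_core(config$params), config$n_timesteps,
                 as.integer(world$t_end), config$record_every,
                 config$record_messages)

  traj <- as.data.frame(res$trajectory)
  names(traj) <- traj_colnames(ids)

  msgs <- NULL
  if (config$record_messages) {
    m <- res$messages
    msgs <- data.frame(t = m[, 1],
                       speaker = ids[m[, 2]],
                       receiver = ids[m[, 3]],
                       topic = ids[m[, 4]],
                       honest = m[, 5] > 0.5,
                       blush = m[, 6] > 0.5,
                       y_h = m[, 7],
                       surprise = m[, 8],
                       ratio_blush = m[, 9],
                       confession = m[, 10] > 0.5,
                       stringsAsFactors = FALSE)
  }

  ep <- res$episodes
  episodes <- data.frame(agent = if (nrow(ep)) ids[ep[, 1]] else character(0),
                         start = ep[, 2], end = ep[, 3],
                         ongoing = ep[, 4] > 0.5,
                         stringsAsFactors = FALSE)

  counts <- res$counts
  dimnames(counts) <- list(ids, c("sent", "honest", "lies", "blushes"))

  final <- rehydrate_world(res$world, world)
  final$t_end <- res$t_end

  summary <- list(
    final_reputation = setNames(
      vapply(ids, function(id) reputation(final, id), numeric(1)), ids),
    honest_fraction = sum(counts[, "honest"]) / sum(counts[, "sent"]),
    ever_lics = setNames(ids %in% episodes$agent, ids),
    episodes = episodes,
    seed = config$seed,
    n_timesteps = config$n_timesteps,
    agents = config$agents,
    params = config$params
  )

  structure(list(trajectory = traj, messages = msgs, episodes = episodes,
                 counts = counts, world = final, summary = summary,
                 config = config),
            class = "rg_sim")
}

#' @export
print.rg_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<rg_sim: %d steps, honest fraction %.3f>\n",
              s$n_timesteps, s$honest_fraction))
  cat("final reputations:\n")
  print(round(s$final_reputation, 3))
  if (nrow(x$episodes) > 0) {
    cat(sprintf("LICS episodes: %d (agents: %s)\n", nrow(x$episodes),
                paste(unique(x$episodes$agent), collapse = ", ")))
  } else cat("LICS episodes: none\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes the trajectory CSV, the message-log CSV (when recorded), and a
#' run-level JSON summary (final reputations, LICS episode intervals, seed,
#' configuration echo).
#'
#' @param sim An `rg_sim` result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$trajectory, file.path(dir, "trajectory.csv"), row.names = FALSE)
  if (!is.null(sim$messages))
    write.csv(sim$messages, file.path(dir, "messages.csv"), row.names = FALSE)
  s <- sim$summary
  jsonlite::write_json(
    list(final_reputation = as.list(s$final_reputation),
         honest_fraction = s$honest_fraction,
         ever_lics = as.list(s$ever_lics),
         lics_episodes = s$episodes,
         seed = s$seed,
         n_timesteps = s$n_timesteps,
         agents = s$agents,
         params = unclass(s$params)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
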