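# Batch experiment drivers: learning-run ensembles per strategy, the
# uniform-honesty sweep, rehabilitation runs and continuation runs. All
# batches derive run seeds as seed0 + run_index - 1 so that strategy arms
# can be compared on matched seeds.

#' Exposed honesty
#'
#' The average intrinsic honesty of the other agents in a system: the
#' honesty of the statements an agent is exposed to.
#'
#' @param honesties Named or unnamed vector of intrinsic honesties.
#' @param agent Index or name of the focal agent.
#' @return The mean of the other agents' honesties.
#' @examples
#' exposed_honesty(c(0.14, 0.80, 0.97), 2)   # (0.14 + 0.97) / 2
#' @export
exposed_honesty <- function(honesties, agent) {
  if (is.character(agent)) agent <- match(agent, names(honesties))
  mean(honesties[-agent])
}

default_roster <- function(special_strategy = "ordinary",
                           honesties = c(black = 0.97, cyan = 0.80, red = 0.14)) {
  strategies <- c("ordinary", "ordinary", special_strategy)
  if (special_strategy != "ordinary") honesties[3] <- 0
  agent_roster(names(honesties), unname(honesties), strategies)
}

# recorded trajectory rows falling inside any LICS episode of `agent`,
# extended by `lead_in` timesteps before each episode start
lics_window_mask <- function(traj_t, episodes, agent, lead_in = 500) {
  eps <- episodes[episodes$agent == agent, , drop = FALSE]
  mask <- rep(FALSE, length(traj_t))
  for (e in seq_len(nrow(eps)))
    mask <- mask | (traj_t >= eps$start[e] - lead_in & traj_t <= eps$end[e])
  mask
}

#' Did an agent develop a LICS after the initial ignorance transient?
#'
#' Fresh agents start with equal (uninformed) blush-frequency means, which
#' satisfies the LICS inequality trivially. An agent therefore counts as
#' having developed a LICS only if it is still -- or again -- inside an
#' episode at or after `burn_in` timesteps into the run.
#'
#' @param episodes The `episodes` data frame of an `rg_sim` result.
#' @param agent Agent id.
#' @param burn_in Timesteps granted to the initial learning transient.
#' @param t0 Timestep at which the run started (nonzero for continuations).
#' @param min_duration Minimum episode length in timesteps.
#' @return Logical.
#' @export
developed_lics <- function(episodes, agent, burn_in = 500, t0 = 0,
                           min_duration = 1) {
  eps <- episodes[episodes$agent == agent &
                    episodes$end - episodes$start + 1 >= min_duration, ,
                  drop = FALSE]
  any(eps$end >= t0 + burn_in)
}

#' Run an ensemble of learning runs
#'
#' Runs `n_runs` seeded simulations of the standard three-agent roster --
#' two ordinary agents (black, 97% honest; cyan, 80% honest) and agent red
#' playing `special_strategy` (ordinary red keeps 14% honesty; any other
#' strategy implies honesty 0) -- and tabulates LICS incidence, final
#' reputations, the honest-message fraction, and reputation/informedness
#' of ordinary agents conditional on being inside a LICS window (episodes
#' extended by `lead_in` preceding timesteps).
#'
#' @param special_strategy Strategy played by agent red.
#' @param n_runs Number of runs.
#' @param n_timesteps Conversations per run.
#' @param seed0 Base seed; run `k` uses `seed0 + k - 1`.
#' @param honesties Named honesty vector for the roster (defaults to the
#'   standard 0.97/0.80/0.14 setup).
#' @param params Model parameters.
#' @param record_every Trajectory cadence used for the conditional
#'   statistics.
#' @param lead_in Timesteps before each episode counted as part of its
#'   window.
#' @param min_duration Minimum episode length (in timesteps) to count as a
#'   LICS occurrence.
#' @return An object of class `rg_batch`; see the `summary` element.
#' @export
run_learning_batch <- function(special_strategy = "ordinary", n_runs = 200,
                               n_timesteps = 4500, seed0 = 1L,
                               honesties = c(black = 0.97, cyan = 0.80, red = 0.14),
                               params = model_params(), record_every = 10L,
                               lead_in = 500L, min_duration = 1L,
                               burn_in = 500L) {
  roster <- default_roster(special_strategy, honesties)
  ids <- roster$id
  special_id <- ids[which(roster$strategy != "ordinary")[1]]
  ordinary_ids <- ids[roster$strategy == "ordinary"]

  ever <- matrix(FALSE, n_runs, length(ids), dimnames = list(NULL, ids))
  finrep <- matrix(NA_real_, n_runs, length(ids), dimnames = list(NULL, ids))
  honest_sent <- total_sent <- 0
  acc <- list()  # pooled conditional sums per ordinary agent
  for (id in ordinary_ids)
    acc[[id]] <- c(info_all_in = 0, info_all_out = 0, info_ord_in = 0,
                   info_ord_out = 0, rep_in = 0, rep_out = 0,
                   n_in = 0, n_out = 0)
  per_run <- vector("list", n_runs)

  for (k in seq_len(n_runs)) {
    cfg <- sim_config(roster, n_timesteps = n_timesteps, seed = seed0 + k - 1L,
                      params = params, record_every = record_every)
    sim <- run_simulation(cfg)
    eps <- sim$episodes
    ever[k, ] <- vapply(ids, function(id)
      developed_lics(eps, id, burn_in, min_duration = min_duration),
      logical(1))
    eps <- eps[eps$end - eps$start + 1 >= min_duration, , drop = FALSE]
    finrep[k, ] <- sim$summary$final_reputation[ids]
    honest_sent <- honest_sent + sum(sim$counts[, "honest"])
    total_sent <- total_sent + sum(sim$counts[, "sent"])

    tt <- sim$trajectory$t
    for (id in ordinary_ids) {
      mask <- lics_window_mask(tt, eps, id, lead_in)
      rep_col <- if (!is.na(special_id))
        sim$trajectory[[paste0("rep_", id, "_", special_id)]] else NULL
      ia <- sim$trajectory[[paste0("info_all_", id)]]
      io <- sim$trajectory[[paste0("info_ord_", id)]]
      acc[[id]]["info_all_in"] <- acc[[id]]["info_all_in"] + sum(ia[mask])
      acc[[id]]["info_all_out"] <- acc[[id]]["info_all_out"] + sum(ia[!mask])
      acc[[id]]["info_ord_in"] <- acc[[id]]["info_ord_in"] + sum(io[mask])
      acc[[id]]["info_ord_out"] <- acc[[id]]["info_ord_out"] + sum(io[!mask])
      if (!is.null(rep_col)) {
        acc[[id]]["rep_in"] <- acc[[id]]["rep_in"] + sum(rep_col[mask])
        acc[[id]]["rep_out"] <- acc[[id]]["rep_out"] + sum(rep_col[!mask])
      }
      acc[[id]]["n_in"] <- acc[[id]]["n_in"] + sum(mask)
      acc[[id]]["n_out"] <- acc[[id]]["n_out"] + sum(!mask)
    }
    per_run[[k]] <- data.frame(run = k, seed = seed0 + k - 1L,
                               honest_fraction = sim$summary$honest_fraction,
                               t(setNames(as.numeric(ever[k, ]),
                                          paste0("lics_", ids))),
                               t(setNames(finrep[k, ], paste0("rep_", ids))))
  }

  conditional <- do.call(rbind, lapply(ordinary_ids, function(id) {
    a <- acc[[id]]
    data.frame(agent = id,
               state = c("lics", "no_lics"),
               n_steps = c(a["n_in"], a["n_out"]),
               mean_info_all = c(a["info_all_in"] / max(a["n_in"], 1),
                                 a["info_all_out"] / max(a["n_out"], 1)),
               mean_info_ord = c(a["info_ord_in"] / max(a["n_in"], 1),
                                 a["info_ord_out"] / max(a["n_out"], 1)),
               mean_rep_special = if (!is.na(special_id))
                 c(a["rep_in"] / max(a["n_in"], 1),
                   a["rep_out"] / max(a["n_out"], 1)) else c(NA_real_, NA_real_),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  structure(list(
    strategy = special_strategy,
    n_runs = n_runs,
    summary = list(
      lics_fraction = colMeans(ever),
      any_lics_fraction = mean(rowSums(ever) > 0),
      mean_final_reputation = colMeans(finrep),
      honest_fraction = honest_sent / total_sent,
      conditional = conditional),
    per_run = do.call(rbind, per_run),
    seed0 = seed0
  ), class = "rg_batch")
}

#' @export
print.rg_batch <- function(x, ...) {
  cat(sprintf("<rg_batch: strategy '%s', %d runs>\n", x$strategy, x$n_runs))
  cat(sprintf("runs with any LICS: %.1f%%\n", 100 * x$summary$any_lics_fraction))
  cat("LICS fraction per agent:\n")
  print(round(x$summary$lics_fraction, 3))
  cat(sprintf("honest-message fraction: %.3f\n", x$summary$honest_fraction))
  invisible(x)
}

#' Uniform-honesty sweep
#'
#' Runs three ordinary agents whose intrinsic honesties are drawn uniformly
#' on (0, 1) in each run, sorted so that red is the least honest, cyan the
#' median and black the most honest. For every agent it reports the
#' exposed honesty (mean of the other two honesties), the time-average of
#' the log blush likelihood-ratio estimate `log(fblie / fbtruth)`, and
#' whether it ever satisfied the LICS predicate. The LICS boundary ratio
#' is attached as the `"threshold"` attribute.
#'
#' @param n_runs Number of runs.
#' @param n_timesteps Conversations per run.
#' @param seed0 Base seed.
#' @param params Model parameters.
#' @param record_every Trajectory cadence.
#' @return A data frame with one row per run and agent.
#' @export
run_honesty_sweep <- function(n_runs = 300, n_timesteps = 4500, seed0 = 1L,
                              params = model_params(), record_every = 10L,
                              burn_in = 500L) {
  ids <- c("red", "cyan", "black")
  rows <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    set.seed(seed0 + k - 1L)
    h <- sort(runif(3))  # red = min, cyan = median, black = max
    roster <- agent_roster(ids, h)
    cfg <- sim_config(roster, n_timesteps = n_timesteps, seed = NULL,
                      params = params, record_every = record_every)
    sim <- run_simulation(cfg, set_seed = FALSE)
    rows[[k]] <- do.call(rbind, lapply(seq_along(ids), function(i) {
      fl <- sim$trajectory[[paste0("fblie_", ids[i])]]
      ft <- sim$trajectory[[paste0("fbtruth_", ids[i])]]
      data.frame(run = k, seed = seed0 + k - 1L, agent = ids[i],
                 honesty = h[i],
                 exposed_honesty = exposed_honesty(h, i),
                 mean_log_r = mean(log(fl / ft)),
                 ever_lics = developed_lics(sim$episodes, ids[i], burn_in),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  margins <- params$lics_margins
  attr(out, "threshold") <- margins[1] / margins[2]
  out
}

#' Rehabilitation runs
#'
#' Transfers an agent -- typically one that developed a LICS -- with its
#' complete internal state into a fresh environment of two new ordinary
#' agents whose intrinsic honesties are drawn uniformly on (0, 1) per run
#' (expected exposed honesty 0.5). The new agents start uninformed; the
#' transferred agent's beliefs about agents from its old roster are
#' retained untouched and re-exported with each rehabilitated snapshot.
#'
#' @param snapshot An `rg_snapshot` of the transferred agent.
#' @param n_runs Number of rehabilitation runs (default 20).
#' @param n_timesteps Conversations per run.
#' @param seed0 Base seed.
#' @param new_ids Identifiers of the two fresh ordinary agents.
#' @param params Model parameters.
#' @param record_every Trajectory cadence.
#' @return A list with `per_run` (exposure, end-of-run LICS status and
#'   blush-frequency means per run), `mean_blush_trajectory` (the focal
#'   agent's blush-frequency means averaged across runs), `snapshots`
#'   (one rehabilitated snapshot per run) and `recovered_fraction`.
#' @export
run_rehabilitation <- function(snapshot, n_runs = 20, n_timesteps = 4500,
                               seed0 = 1L, new_ids = c("green", "yellow"),
                               params = model_params(), record_every = 10L) {
  if (!inherits(snapshot, "rg_snapshot"))
    stop("'snapshot' must be an rg_snapshot", call. = FALSE)
  if (snapshot$id %in% new_ids)
    stop("'new_ids' must not contain the transferred agent's id", call. = FALSE)
  focal <- snapshot$id
  margins <- params$lics_margins
  per_run <- vector("list", n_runs)
  snaps <- vector("list", n_runs)
  traj_fl <- traj_ft <- NULL
  for (k in seq_len(n_runs)) {
    set.seed(seed0 + k - 1L)
    h_new <- runif(length(new_ids))
    roster <- agent_roster(c(focal, new_ids),
                           c(snapshot$intrinsic_honesty, h_new),
                           c(snapshot$strategy, rep("ordinary", length(new_ids))))
    world <- insert_snapshot(new_world(roster), snapshot)
    world$t_end <- 0
    cfg <- sim_config(roster, n_timesteps = n_timesteps, seed = NULL,
                      params = params, record_every = record_every)
    sim <- run_simulation(cfg, world = world, set_seed = FALSE)
    bb <- blush_beliefs_of(sim$world, focal)
    fl <- belief_mean(bb$lie_freq)
    ft <- belief_mean(bb$truth_freq)
    per_run[[k]] <- data.frame(
      run = k, seed = seed0 + k - 1L,
      exposed_honesty = mean(h_new),
      end_fblie = fl, end_fbtruth = ft,
      end_ratio = fl / ft,
      end_lics = lics_flag(bb, margins[1], margins[2]),
      stringsAsFactors = FALSE)
    snaps[[k]] <- merge_dormant(
      take_snapshot(sim$world, focal, run_id = sprintf("rehab-%d", k)),
      snapshot)
    flv <- sim$trajectory[[paste0("fblie_", focal)]]
    ftv <- sim$trajectory[[paste0("fbtruth_", focal)]]
    if (is.null(traj_fl)) { traj_fl <- flv; traj_ft <- ftv; tvec <- sim$trajectory$t }
    else { traj_fl <- traj_fl + flv; traj_ft <- traj_ft + ftv }
  }
  per_run <- do.call(rbind, per_run)
  list(per_run = per_run,
       mean_blush_trajectory = data.frame(t = tvec,
                                          fblie = traj_fl / n_runs,
                                          fbtruth = traj_ft / n_runs),
       snapshots = snaps,
       recovered_fraction = mean(!per_run$end_lics))
}

#' Continuation runs
#'
#' Continues a finished learning run for additional timesteps across
#' several seeds, either unchanged (`mode = "baseline"`) or with the focal
#' agent's internal state replaced by a rehabilitated snapshot at the
#' continuation start (`mode = "reinserted"`).
#'
#' @param world The final `rg_world` of the learning run.
#' @param n_runs Number of continuation runs (default 20).
#' @param extra_timesteps Additional conversations (default 7500).
#' @param seed0 Base seed.
#' @param mode `"baseline"` or `"reinserted"`.
#' @param snapshot The rehabilitated snapshot (required for reinsertion).
#' @param params Model parameters.
#' @param record_every Trajectory cadence.
#' @return A list with `per_run` (end-of-run LICS status and
#'   blush-frequency means of the focal agent), `start_lics` (the focal
#'   agent's LICS status at continuation start), `focal`,
#'   `mean_blush_trajectory`, and `lics_time_fraction` (the fraction of
#'   recorded continuation steps the focal agent spends in a LICS state,
#'   averaged over runs).
#' @export
run_continuation <- function(world, n_runs = 20, extra_timesteps = 7500,
                             seed0 = 1L, mode = c("baseline", "reinserted"),
                             snapshot = NULL, params = model_params(),
                             record_every = 10L, focal = NULL) {
  mode <- match.arg(mode)
  if (!inherits(world, "rg_world")) stop("'world' must be an rg_world", call. = FALSE)
  if (mode == "reinserted") {
    if (is.null(snapshot))
      stop("reinserted mode requires a rehabilitated snapshot", call. = FALSE)
    world <- insert_snapshot(world, snapshot)
    if (is.null(focal)) focal <- snapshot$id
  }
  if (is.null(focal)) stop("'focal' agent id is required in baseline mode",
                           call. = FALSE)
  margins <- params$lics_margins
  roster <- agent_roster(world$ids, unname(world$honesty), unname(world$strategy))
  bb0 <- blush_beliefs_of(world, focal)
  start_lics <- lics_flag(bb0, margins[1], margins[2])
  per_run <- vector("list", n_runs)
  traj_fl <- traj_ft <- NULL
  lics_frac <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    cfg <- sim_config(roster, n_timesteps = extra_timesteps,
                      seed = seed0 + k - 1L, params = params,
                      record_every = record_every)
    sim <- run_simulation(cfg, world = world)
    bb <- blush_beliefs_of(sim$world, focal)
    lics_col <- sim$trajectory[[paste0("lics_", focal)]]
    lics_frac[k] <- mean(lics_col)
    per_run[[k]] <- data.frame(
      run = k, seed = seed0 + k - 1L,
      end_fblie = belief_mean(bb$lie_freq),
      end_fbtruth = belief_mean(bb$truth_freq),
      end_lics = lics_flag(bb, margins[1], margins[2]),
      lics_time_fraction = lics_frac[k],
      stringsAsFactors = FALSE)
    flv <- sim$trajectory[[paste0("fblie_", focal)]]
    ftv <- sim$trajectory[[paste0("fbtruth_", focal)]]
    if (is.null(traj_fl)) { traj_fl <- flv; traj_ft <- ftv; tvec <- sim$trajectory$t }
    else { traj_fl <- traj_fl + flv; traj_ft <- traj_ft + ftv }
  }
  list(per_run = do.call(rbind, per_run),
       start_lics = start_lics,
       focal = focal,
       mode = mode,
       mean_blush_trajectory = data.frame(t = tvec,
                                          fblie = traj_fl / n_runs,
                                          fbtruth = traj_ft / n_runs),
       lics_time_fraction = mean(lics_frac))
}
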