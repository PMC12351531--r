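# Agent snapshots: the full internal state of one agent, keyed by agent
# ids so it can be carried between rosters (rehabilitation, reinsertion).
# Beliefs about agents absent from the current roster are retained
# untouched and restored when the agent meets them again.

SNAPSHOT_SCHEMA <- "rg-snapshot-1"

#' Take a snapshot of one agent's internal state
#'
#' Captures the agent's strategy, intrinsic honesty, honesty beliefs about
#' every agent in the roster (including itself), blush-frequency beliefs,
#' theory-of-mind table and friendship ledger, all keyed by agent id.
#'
#' @param world An `rg_world`.
#' @param agent Agent id.
#' @param run_id Optional provenance label.
#' @return An object of class `rg_snapshot`.
#' @export
take_snapshot <- function(world, agent, run_id = NA_character_) {
  a <- agent_index(world, agent)
  ids <- world$ids
  hb <- lapply(seq_along(ids), function(b)
    c(world$hb_mu[a, b], world$hb_la[a, b]))
  names(hb) <- ids
  tom <- lapply(seq_along(ids), function(cp) {
    entries <- lapply(seq_along(ids), function(tp)
      c(world$tom_mu[a, cp, tp], world$tom_la[a, cp, tp]))
    names(entries) <- ids
    entries
  })
  names(tom) <- ids
  fr <- lapply(seq_along(ids), function(cp)
    c(world$fr_cnt[a, cp], world$fr_sum[a, cp]))
  names(fr) <- ids
  structure(list(
    schema = SNAPSHOT_SCHEMA,
    id = ids[a],
    strategy = unname(world$strategy[[a]]),
    intrinsic_honesty = unname(world$honesty[[a]]),
    honesty_beliefs = hb,
    blush_beliefs = list(lie = c(world$bb[a, 1], world$bb[a, 2]),
                         truth = c(world$bb[a, 3], world$bb[a, 4])),
    tom = tom,
    friendship = fr,
    provenance = list(run_id = run_id, timestep = world$t_end)
  ), class = "rg_snapshot")
}

#' @export
print.rg_snapshot <- function(x, ...) {
  bb <- blush_beliefs(belief(x$blush_beliefs$lie[1], x$blush_beliefs$lie[2]),
                      belief(x$blush_beliefs$truth[1], x$blush_beliefs$truth[2]))
  cat(sprintf("<rg_snapshot of '%s' (%s, honesty %.2f) at t=%d; fblie=%.4f fbtruth=%.4f%s>\n",
              x$id, x$strategy, x$intrinsic_honesty,
              as.integer(x$provenance$timestep),
              belief_mean(bb$lie_freq), belief_mean(bb$truth_freq),
              if (lics_flag(bb)) " [LICS]" else ""))
  invisible(x)
}

#' Save a snapshot as JSON
#'
#' @param snapshot An `rg_snapshot`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(snapshot, path) {
  if (!inherits(snapshot, "rg_snapshot"))
    stop("'snapshot' must be an rg_snapshot", call. = FALSE)
  jsonlite::write_json(unclass(snapshot), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a snapshot from JSON
#'
#' @param path Path to a snapshot written by [save_snapshot()].
#' @return An `rg_snapshot`.
#' @export
load_snapshot <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$schema, SNAPSHOT_SCHEMA))
    stop("unknown snapshot schema: ", raw$schema, call. = FALSE)
  num2 <- function(x) c(as.numeric(x[[1]]), as.numeric(x[[2]]))
  snap <- list(
    schema = raw$schema,
    id = raw$id,
    strategy = raw$strategy,
    intrinsic_honesty = as.numeric(raw$intrinsic_honesty),
    honesty_beliefs = lapply(raw$honesty_beliefs, num2),
    blush_beliefs = list(lie = num2(raw$blush_beliefs$lie),
                         truth = num2(raw$blush_beliefs$truth)),
    tom = lapply(raw$tom, function(cp) lapply(cp, num2)),
    friendship = lapply(raw$friendship, num2),
    provenance = list(run_id = if (is.null(raw$provenance$run_id)) NA_character_
                               else raw$provenance$run_id,
                      timestep = as.numeric(raw$provenance$timestep))
  )
  structure(snap, class = "rg_snapshot")
}

#' Insert a snapshot into a world
#'
#' Replaces the focal agent's internal state in `world` with the state
#' recorded in `snapshot`, matching entries by agent id. Roster members the
#' snapshot knows nothing about keep uninformed entries; snapshot entries
#' about agents absent from the roster are simply not installed (they stay
#' in the snapshot, untouched, for a later reinsertion).
#'
#' @param world An `rg_world` whose roster contains `snapshot$id`.
#' @param snapshot An `rg_snapshot`.
#' @return The updated world.
#' @export
insert_snapshot <- function(world, snapshot) {
  if (!inherits(snapshot, "rg_snapshot"))
    stop("'snapshot' must be an rg_snapshot", call. = FALSE)
  if (!(snapshot$id %in% world$ids))
    stop("roster mismatch: world has no agent '", snapshot$id, "'", call. = FALSE)
  a <- agent_index(world, snapshot$id)
  if (!identical(unname(world$strategy[[a]]), snapshot$strategy) ||
      world$honesty[[a]] != snapshot$intrinsic_honesty)
    stop("roster mismatch: strategy/honesty of '", snapshot$id,
         "' differ from the snapshot", call. = FALSE)
  for (id in intersect(names(snapshot$honesty_beliefs), world$ids)) {
    b <- agent_index(world, id)
    world$hb_mu[a, b] <- snapshot$honesty_beliefs[[id]][1]
    world$hb_la[a, b] <- snapshot$honesty_beliefs[[id]][2]
  }
  world$bb[a, 1:2] <- snapshot$blush_beliefs$lie
  world$bb[a, 3:4] <- snapshot$blush_beliefs$truth
  for (cp in intersect(names(snapshot$tom), world$ids)) {
    ci <- agent_index(world, cp)
    for (tp in intersect(names(snapshot$tom[[cp]]), world$ids)) {
      ti <- agent_index(world, tp)
      world$tom_mu[a, ci, ti] <- snapshot$tom[[cp]][[tp]][1]
      world$tom_la[a, ci, ti] <- snapshot$tom[[cp]][[tp]][2]
    }
  }
  for (cp in intersect(names(snapshot$friendship), world$ids)) {
    ci <- agent_index(world, cp)
    world$fr_cnt[a, ci] <- snapshot$friendship[[cp]][1]
    world$fr_sum[a, ci] <- snapshot$friendship[[cp]][2]
  }
  world
}

# carry forward beliefs about agents the new roster never contained:
# entries present in `old` but absent from `new` are appended unchanged
merge_dormant <- function(new, old) {
  stopifnot(inherits(new, "rg_snapshot"), inherits(old, "rg_snapshot"))
  add <- setdiff(names(old$honesty_beliefs), names(new$honesty_beliefs))
  new$honesty_beliefs <- c(new$honesty_beliefs, old$honesty_beliefs[add])
  addf <- setdiff(names(old$friendship), names(new$friendship))
  new$friendship <- c(new$friendship, old$friendship[addf])
  addt <- setdiff(names(old$tom), names(new$tom))
  new$tom <- c(new$tom, old$tom[addt])
  for (cp in intersect(names(new$tom), names(old$tom))) {
    addtp <- setdiff(names(old$tom[[cp]]), names(new$tom[[cp]]))
    new$tom[[cp]] <- c(new$tom[[cp]], old$tom[[cp]][addtp])
  }
  new
}

#' Save a world as JSON
#'
#' Serializes the complete world state (all agents) for continuation runs.
#'
#' @param world An `rg_world`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_world <- function(world, path) {
  out <- list(schema = "rg-world-1",
              ids = world$ids,
              honesty = unname(world$honesty),
              strategy = unname(world$strategy),
              t_end = world$t_end,
              hb_mu = world$hb_mu, hb_la = world$hb_la,
              bb = world$bb,
              tom_mu = as.numeric(world$tom_mu),
              tom_la = as.numeric(world$tom_la),
              fr_cnt = world$fr_cnt, fr_sum = world$fr_sum)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a world from JSON
#'
#' @param path Path to a world written by [save_world()].
#' @return An `rg_world`.
#' @export
load_world <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, "rg-world-1"))
    stop("unknown world schema: ", raw$schema, call. = FALSE)
  world <- new_world(data.frame(id = raw$ids, honesty = raw$honesty,
                                strategy = raw$strategy,
                                stringsAsFactors = FALSE))
  n <- world$n
  world$hb_mu[, ] <- as.matrix(raw$hb_mu)
  world$hb_la[, ] <- as.matrix(raw$hb_la)
  world$bb[, ] <- as.matrix(raw$bb)
  world$tom_mu[] <- raw$tom_mu
  world$tom_la[] <- raw$tom_la
  world$fr_cnt[, ] <- as.matrix(raw$fr_cnt)
  world$fr_sum[, ] <- as.matrix(raw$fr_sum)
  world$t_end <- raw$t_end
  world
}
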