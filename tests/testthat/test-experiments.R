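# Batch drivers, snapshots, rehabilitation and continuation plumbing.

test_that("batches are deterministic in (seed0, run index)", {
  b1 <- run_learning_batch("ordinary", n_runs = 3, n_timesteps = 300, seed0 = 7)
  b2 <- run_learning_batch("ordinary", n_runs = 3, n_timesteps = 300, seed0 = 7)
  expect_identical(b1$per_run, b2$per_run)
  expect_identical(b1$summary, b2$summary)
})

test_that("a one-run batch reduces to a single simulation", {
  b <- run_learning_batch("ordinary", n_runs = 1, n_timesteps = 300, seed0 = 11)
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 300,
                                   seed = 11, record_every = 10L))
  expect_equal(b$summary$honest_fraction, sim$summary$honest_fraction)
  expect_equal(unname(b$summary$mean_final_reputation),
               unname(sim$summary$final_reputation[c("black", "cyan", "red")]))
})

test_that("batch LICS fractions are recomputable from the per-run table", {
  b <- run_learning_batch("dominant", n_runs = 5, n_timesteps = 600, seed0 = 3)
  for (id in c("black", "cyan", "red")) {
    expect_equal(unname(b$summary$lics_fraction[id]),
                 mean(b$per_run[[paste0("lics_", id)]]))
  }
  expect_equal(b$summary$any_lics_fraction,
               mean(rowSums(b$per_run[, paste0("lics_",
                                               c("black", "cyan", "red"))]) > 0))
})

test_that("snapshots round-trip byte-identically through JSON", {
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 200,
                                   seed = 31))
  snap <- take_snapshot(sim$world, "cyan", run_id = "t31")
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  save_snapshot(snap, p1)
  reloaded <- load_snapshot(p1)
  save_snapshot(reloaded, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(reloaded$honesty_beliefs, snap$honesty_beliefs)
  expect_equal(reloaded$tom, snap$tom)
})

test_that("snapshot insertion maps entries by id and checks the roster", {
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 200,
                                   seed = 32))
  snap <- take_snapshot(sim$world, "cyan")
  roster <- agent_roster(c("cyan", "green", "yellow"), c(0.80, 0.5, 0.5))
  w <- insert_snapshot(new_world(roster), snap)
  # the focal agent's own state is carried over ...
  expect_equal(unname(w$bb[1, ]), unname(sim$world$bb[2, ]))
  expect_equal(w$hb_mu[1, 1], sim$world$hb_mu[2, 2])  # self-belief
  # ... while entries about the new, unknown agents stay uninformed
  expect_equal(unname(w$hb_mu[1, 2:3]), c(0, 0))
  # and the new agents start fully uninformed
  expect_equal(unname(w$hb_mu[2, ]), c(0, 0, 0))

  bad <- new_world(agent_roster(c("green", "yellow"), c(0.5, 0.5)))
  expect_error(insert_snapshot(bad, snap), "roster mismatch")
  wrong <- new_world(agent_roster(c("cyan", "green"), c(0.3, 0.5)))
  expect_error(insert_snapshot(wrong, snap), "roster mismatch")
})

test_that("rehabilitation retains beliefs about absent agents", {
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 300,
                                   seed = 33))
  snap <- take_snapshot(sim$world, "cyan")
  rehab <- run_rehabilitation(snap, n_runs = 2, n_timesteps = 200, seed0 = 5)
  out <- rehab$snapshots[[1]]
  # dormant entries about the old roster survive untouched
  expect_equal(out$honesty_beliefs$black, snap$honesty_beliefs$black)
  expect_equal(out$honesty_beliefs$red, snap$honesty_beliefs$red)
  expect_true(all(c("green", "yellow") %in% names(out$honesty_beliefs)))
  expect_equal(nrow(rehab$per_run), 2)
  expect_true(all(rehab$per_run$exposed_honesty >= 0 &
                  rehab$per_run$exposed_honesty <= 1))
  expect_error(run_rehabilitation(snap, new_ids = c("cyan", "x")),
               "must not contain")
})

test_that("baseline continuation resumes the saved world exactly", {
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 300,
                                   seed = 41))
  cont <- run_continuation(sim$world, n_runs = 2, extra_timesteps = 100,
                           seed0 = 9, mode = "baseline", focal = "cyan")
  direct <- run_simulation(sim_config(standard_roster(), n_timesteps = 100,
                                      seed = 9, record_every = 10L),
                           world = sim$world)
  bb <- blush_beliefs_of(direct$world, "cyan")
  expect_equal(cont$per_run$end_fblie[1], belief_mean(bb$lie_freq))
  expect_equal(cont$per_run$end_fbtruth[1], belief_mean(bb$truth_freq))
  expect_equal(cont$mean_blush_trajectory$t[1], 310)
})

test_that("the honesty sweep sorts colors and reports the threshold", {
  sw <- run_honesty_sweep(n_runs = 4, n_timesteps = 300, seed0 = 13)
  expect_equal(nrow(sw), 12)
  expect_setequal(unique(sw$agent), c("red", "cyan", "black"))
  for (k in unique(sw$run)) {
    h <- sw[sw$run == k, ]
    expect_lt(h$honesty[h$agent == "red"], h$honesty[h$agent == "cyan"])
    expect_lt(h$honesty[h$agent == "cyan"], h$honesty[h$agent == "black"])
    expect_equal(h$exposed_honesty[h$agent == "red"],
                 mean(h$honesty[h$agent != "red"]))
  }
  expect_equal(attr(sw, "threshold"), 11 / 9)
  expect_true(all(is.finite(sw$mean_log_r)))
})

test_that("run outputs are written as CSV and JSON", {
  sim <- run_simulation(sim_config(standard_roster(), n_timesteps = 100,
                                   seed = 2, record_messages = TRUE,
                                   record_every = 10L))
  dir <- tempfile()
  write_run_outputs(sim, dir)
  expect_true(file.exists(file.path(dir, "trajectory.csv")))
  expect_true(file.exists(file.path(dir, "messages.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_timesteps, 100)
  expect_length(js$final_reputation, 3)
})
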