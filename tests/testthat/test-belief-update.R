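# Receiver-side learning: the joint update from one message, speaker
# self-observation, and the LICS predicate.

fresh_world <- function(honesty = c(0.9, 0.8, 0.2)) {
  new_world(agent_roster(c("a", "b", "c"), honesty))
}

test_that("an oracle-mode blush certifies a lie", {
  w <- fresh_world()
  params <- model_params(known_frequencies = TRUE)
  msg <- rg_message("b", "a", "c", belief(4, 1), blush = TRUE,
                    truth_flag = FALSE)
  before_mu <- w$hb_mu[1, 2]
  before_la <- w$hb_la[1, 2]
  topic_before <- honesty_belief(w, "a", "c")
  res <- receive(w, msg, params)
  expect_equal(res$trace$y_h, 0)
  expect_equal(res$world$hb_mu[1, 2], before_mu)
  expect_equal(res$world$hb_la[1, 2], before_la + 1)
  expect_equal(honesty_belief(res$world, "a", "c"), topic_before)
})

test_that("a confession is believed outright and its content adopted", {
  w <- fresh_world()
  w$hb_mu[1, 2] <- 5; w$hb_la[1, 2] <- 5    # a's view of b: mean 0.5
  claim <- belief(2, 10)                     # mean 3/14 < 0.5
  msg <- rg_message("b", "a", "b", claim)
  res <- receive(w, msg)
  expect_true(res$trace$confession)
  expect_equal(res$trace$y_h, 1)
  # speaker-honesty belief gains one full honest count, then the content
  # (novel relative to an empty theory of mind) is fused in full
  expect_equal(res$world$hb_mu[1, 2], 5 + 1 + 2)
  expect_equal(res$world$hb_la[1, 2], 5 + 10)
})

test_that("one message moves the honesty evidence by at most one unit", {
  # the information-optimal update adds up to one pseudo-count for a
  # decisive message and may slightly widen the belief (negative gain)
  # when the classification contradicts the prior's lean
  set.seed(31)
  for (i in 1:20) {
    w <- fresh_world()
    w$hb_mu[1, 2] <- runif(1, 0, 20)
    w$hb_la[1, 2] <- runif(1, 0, 20)
    msg <- rg_message("b", "a", "c",
                      belief(runif(1, 0, 10), runif(1, 0, 10)),
                      blush = runif(1) < 0.3, truth_flag = FALSE)
    res <- receive(w, msg)
    gain <- (res$world$hb_mu[1, 2] + res$world$hb_la[1, 2]) -
            (w$hb_mu[1, 2] + w$hb_la[1, 2])
    expect_gte(gain, -1)
    expect_lte(gain, 1 + 1e-9)
    expect_gte(res$trace$y_h, 0)
    expect_lte(res$trace$y_h, 1)
  }
  # a decisive classification adds exactly one count
  w <- fresh_world()
  w$hb_mu[1, 2] <- 4; w$hb_la[1, 2] <- 6
  msg <- rg_message("b", "a", "c", belief(3, 3), blush = TRUE,
                    truth_flag = FALSE)
  res <- receive(w, msg, model_params(known_frequencies = TRUE))
  expect_equal(res$world$hb_mu[1, 2] + res$world$hb_la[1, 2], 11)
})

test_that("a higher prior reputation never lowers the honesty weight", {
  msg <- rg_message("b", "a", "c", belief(6, 2), blush = TRUE,
                    truth_flag = FALSE)
  y <- vapply(seq(0.1, 0.9, by = 0.1), function(x) {
    w <- fresh_world()
    w$hb_mu[1, 2] <- x * 100 - 1
    w$hb_la[1, 2] <- (1 - x) * 100 - 1
    receive(w, msg)$trace$y_h
  }, numeric(1))
  expect_true(all(diff(y) >= -1e-12))
})

test_that("uncertain messages split blush evidence probabilistically", {
  # symmetric setup: uninformed blush beliefs, claim equal to the prior,
  # reputation 0.5, no blush. The evidence ratio is then (1-fl)/(1-ft) = 1
  # and y_h = 0.5, so both channels get a half-weight failed trial.
  w <- fresh_world()
  msg <- rg_message("b", "a", "c", belief(0, 0))
  res <- receive(w, msg)
  expect_equal(res$trace$y_h, 0.5)
  ref <- compress_mixture(c(0.5, 0.5), list(belief(0, 1), belief(0, 0)))
  expect_equal(unname(res$world$bb[1, 1:2]), unname(unclass(ref)),
               tolerance = 1e-9)   # lie channel
  expect_equal(unname(res$world$bb[1, 3:4]), unname(unclass(ref)),
               tolerance = 1e-9)   # truth channel
})

test_that("self-observation keeps exact counts of own behavior", {
  w <- fresh_world()
  for (i in 1:100) w <- self_observe(w, "a", truth_flag = TRUE, blush = FALSE)
  bb <- blush_beliefs_of(w, "a")
  expect_equal(unclass(bb$truth_freq), c(mu = 0, la = 100))
  expect_equal(belief_mean(bb$truth_freq), 1 / 102)
  expect_equal(w$hb_mu[1, 1], 100)  # self-knowledge of own honesty

  w <- self_observe(w, "a", truth_flag = FALSE, blush = TRUE)
  w <- self_observe(w, "a", truth_flag = FALSE, blush = FALSE)
  bb <- blush_beliefs_of(w, "a")
  expect_equal(unclass(bb$lie_freq), c(mu = 1, la = 1))
  expect_error(self_observe(w, "a", truth_flag = TRUE, blush = TRUE),
               "never accompany")
})

test_that("a destructive agent's own lie channel collapses to zero", {
  cfg <- sim_config(special_roster("destructive"), n_timesteps = 1500,
                    seed = 17)
  sim <- run_simulation(cfg)
  bb <- blush_beliefs_of(sim$world, "red")
  expect_lt(belief_mean(bb$lie_freq), 0.01)
  expect_true(lics_flag(bb))
})

test_that("the LICS flag flips exactly at the 11/9 frequency ratio", {
  expect_true(lics_flag(blush_beliefs(belief(1, 9), belief(1, 9))))
  expect_true(lics_flag(blush_beliefs(
    belief(0.055 * 1000 - 1, 0.945 * 1000 - 1),
    belief(0.05 * 1000 - 1, 0.95 * 1000 - 1))))
  expect_false(lics_flag(blush_beliefs(
    belief(0.10 * 1000 - 1, 0.90 * 1000 - 1),
    belief(0.01 * 1000 - 1, 0.99 * 1000 - 1))))
  # boundary: mean(lie)/mean(truth) exactly 11/9 is not a LICS (strict >),
  # infinitesimally below it is
  t0 <- 0.09
  l0 <- t0 * 11 / 9
  mk <- function(m) belief(m * 2000 - 1, (1 - m) * 2000 - 1)
  expect_false(lics_flag(blush_beliefs(mk(l0), mk(t0))))
  expect_true(lics_flag(blush_beliefs(mk(l0 * (1 - 1e-9)), mk(t0))))
})

test_that("oracle mode never produces a LICS and classifies every blush as a lie", {
  cfg <- sim_config(standard_roster(), n_timesteps = 800, seed = 23,
                    params = model_params(known_frequencies = TRUE, gamma = 0),
                    record_messages = TRUE)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$episodes), 0)
  blushes <- sim$messages[sim$messages$blush, ]
  expect_gt(nrow(blushes), 0)
  expect_true(all(blushes$y_h == 0))
  expect_false(any(sim$trajectory[, grep("^lics_", names(sim$trajectory))] > 0))
})
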