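test_that("classical schedules have the configured appearance statistics", {
  cfg <- classical_config(total_time = 7200)
  # expected appearances per stimulus over 2 h: 7200 * 0.0015 = 10.8
  set.seed(1)
  counts <- replicate(30, {
    sch <- generate_classical_schedule(cfg)
    nrow(sch$stimuli) / cfg$n_stimuli
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10.8), 3 * se + 0.3)

  # durations inside the configured range, rewards only for the CS
  set.seed(2)
  sch <- generate_classical_schedule(cfg)
  dur <- sch$stimuli$offset - sch$stimuli$onset
  expect_true(all(dur > 0 & dur <= cfg$duration_range[2] + 1e-9))
  n_cs <- sum(sch$stimuli$stimulus == cfg$cs_index &
                sch$stimuli$onset + cfg$reward_delay_range[2] < cfg$total_time)
  expect_lte(nrow(sch$rewards), n_cs + 1L)

  # degenerate probability: empty schedule
  empty <- generate_classical_schedule(classical_config(appear_prob = 0))
  expect_identical(nrow(empty$stimuli), 0L)
  expect_identical(nrow(empty$rewards), 0L)
})

test_that("brief-variant rewards arrive after the CS has ceased", {
  cfg <- classical_config(brief = TRUE, total_time = 36000)
  set.seed(3)
  sch <- generate_classical_schedule(cfg)
  cs <- sch$stimuli[sch$stimuli$stimulus == cfg$cs_index, ]
  expect_true(all(cs$offset - cs$onset <= 2 + 1e-9))
  for (k in seq_len(nrow(sch$rewards))) {
    gap <- sch$rewards$time[k] - cs$offset
    gap <- gap[gap >= 0]
    expect_true(length(gap) > 0 && min(gap) <= 5 + 1e-9)
  }
})

test_that("without rewards and without baseline, weights are frozen", {
  pp <- plasticity_params(baseline = 0)
  net <- small_network(seed = 6)
  w0 <- net$w
  rec <- run_classical(net, pp,
                       classical_config(n_stimuli = 2, total_time = 120,
                                        appear_prob = 0.05,
                                        reward_magnitude = 0),
                       seed = 15)
  expect_identical(rec$network$w, w0)
})

test_that("with a negative baseline and no rewards, a cued pathway decays", {
  pp <- plasticity_params(baseline = -0.001)
  net <- build_network(small_net_params(), group_spec(inputs = "S1",
                                                      outputs = "A0"),
                       seed = 7)
  # a previously conditioned pathway, cued often but never rewarded again
  net$w[pathway_index(net, "S1", "A0")] <- 0.5
  cfg <- classical_config(n_stimuli = 1, total_time = 300, appear_prob = 0.05,
                          duration_range = c(5, 10), reward_magnitude = 0)
  s0 <- pathway_strength(net, "S1", "A0")
  rec <- run_classical(net, pp, cfg, seed = 16)
  expect_lte(pathway_strength(rec$network, "S1", "A0"), s0)
})

test_that("single-episode weight gain decreases with reward delay like the trace", {
  # one stimulus, one output, one reward; sweep the post-offset delay
  pp <- plasticity_params(baseline = 0)
  gains <- vapply(c(0.5, 1, 2, 4), function(d) {
    net <- build_network(small_net_params(),
                         group_spec(inputs = "S1", outputs = "A0"), seed = 8)
    cfg <- classical_config(n_stimuli = 1, total_time = 40, appear_prob = 0,
                            fixed_delay = d)
    sch <- structure(list(
      stimuli = data.frame(stimulus = 1L, onset = 10, offset = 11.4),
      rewards = data.frame(time = 11.4 + d, magnitude = 1),
      total_time = 40), class = "rchp_schedule")
    s0 <- pathway_strength(net, "S1", "A0")
    rec <- run_classical(net, pp, cfg, schedule = sch, seed = 17)
    pathway_strength(rec$network, "S1", "A0") - s0
  }, 0)
  expect_true(all(diff(gains) < 0))            # monotone attenuation
  # attenuation consistent with exp(-d / tau_c) within discretization slack
  ratio <- gains[4] / gains[1]
  expect_equal(ratio, exp(-(4 - 0.5) / 4), tolerance = 0.25)
})

test_that("action selection follows threshold crossing then argmax", {
  # clear winner above threshold
  h <- rbind(c(0.05, 0.04, 0.05), c(0.9, 0.05, 0.06))
  expect_identical(select_action(h), 1L)
  # nobody crosses: highest at window end wins, even by a small margin
  h <- rbind(c(0.1, 0.1, 0.1), c(0.2, 0.21, 0.2))
  expect_identical(select_action(h), 2L)
  # exact tie at the end: lowest index
  h <- rbind(c(0.1, 0.1), c(0.25, 0.25))
  expect_identical(select_action(h), 1L)
  # earliest crossing wins over a later, larger crossing
  h <- rbind(c(0.35, 0.0), c(0.0, 0.9))
  expect_identical(select_action(h), 1L)
  # simultaneous crossings: the stronger one wins
  h <- rbind(c(0.4, 0.6), c(0, 0))
  expect_identical(select_action(h), 2L)
  expect_error(select_action(matrix(numeric(0), 0, 3)), "empty")
})

test_that("operant choices explore several actions before learning", {
  cfg <- operant_config(n_colors = 1L, total_time = 200)
  chosen <- unlist(lapply(1:3, function(s) {
    rec <- run_operant(config = cfg, policy = reward_policy(1L), seed = 100 + s)
    rec$trials$chosen
  }))
  expect_gte(length(unique(chosen[!is.na(chosen)])), 3L)
})

test_that("rewarded color-action pathways become dominant for their color", {
  cfg <- operant_config(n_colors = 2L, total_time = 600)
  rec <- run_operant(config = cfg, policy = reward_policy(c(1L, 2L)),
                     seed = 19)
  fs <- rec$final$pathway_strength
  s10 <- fs[grep("^S10->", names(fs))]
  s11 <- fs[grep("^S11->", names(fs))]
  expect_identical(names(which.max(s10)), "S10->A1")
  expect_identical(names(which.max(s11)), "S11->A2")
})

test_that("reversal decrements the punished pathway and converges, then relearns", {
  # the five-color environment keeps running; the tutor reverses one mapping
  cfg <- operant_config(total_time = 3600)
  policy <- reward_policy(1:5, reversal = list(time = 1200, stimulus = 1L,
                                               new_action = 6L))
  rec <- run_reversal(config = cfg, policy = policy, seed = 20)
  tr <- rec$trials
  pw <- rec$pathways[, "S10->A1"]
  pt <- rec$pathway_time

  # the pathway decreases across each of the first punished trials
  punished <- tr[tr$time >= 1200 & tr$color == 1L & tr$chosen == 1L &
                   !is.na(tr$chosen), ]
  expect_gte(nrow(punished), 1L)
  for (k in seq_len(min(3L, nrow(punished)))) {
    t0 <- punished$time[k]
    before <- pw[findInterval(t0, pt)]
    after <- pw[findInterval(t0 + 50, pt)]
    expect_lt(after, before)
  }

  # a single punishment does not flip an established belief: the next trial
  # of that color still names the old action
  first <- punished[1L, ]
  nxt <- tr[tr$time > first$time & tr$color == 1L, ][1L, ]
  expect_identical(nxt$chosen, 1L)

  # four-phase trajectory detected; both the old and the new action appear
  # after the switch
  ph <- segment_reversal_phases(rec)
  expect_true(ph$detected)
  post <- tr[tr$time >= ph$switch & tr$color == 1L & !is.na(tr$chosen), ]
  expect_gte(length(unique(post$chosen)), 2L)
  expect_true(6L %in% post$chosen)
})

test_that("punishment and reward of equal size move a pathway comparably", {
  # identical seed gives an identical trajectory up to the first reward
  # episode; the runs differ only in its sign, so the episode's weight change
  # should be close to symmetric
  cfg <- operant_config(n_colors = 1L, total_time = 120,
                        reward_correct = 1, reward_delay_range = c(2, 2))
  # an established mid-interval association, away from both weight bounds,
  # as in a trained network facing a whimsical tutor
  base <- build_network(network_params(),
                        group_spec(inputs = "S10",
                                   outputs = paste0("A", 1:8)), seed = 22)
  for (a in paste0("A", 1:8))
    base$w[pathway_index(base, "S10", a)] <- 0.4
  ppn <- plasticity_params(baseline = 0)
  probe <- run_operant(base, ppn, config = cfg, policy = reward_policy(1L),
                       seed = 21)
  chosen <- probe$trials$chosen[1L]
  other <- if (chosen == 1L) 2L else 1L
  # run A: the first choice is correct, rewarded +5
  runA <- run_operant(base, ppn, config = cfg, policy = reward_policy(chosen),
                      seed = 21)
  # run B: the same first choice is wrong, punished at full magnitude -5
  cfgB <- operant_config(n_colors = 1L, total_time = 120,
                         reward_correct = 1, reward_delay_range = c(2, 2),
                         reward_wrong = -cfg$reward_correct)
  runB <- run_operant(base, ppn, config = cfgB, policy = reward_policy(other),
                      seed = 21)
  expect_identical(runA$trials$chosen[1L], chosen)
  expect_identical(runB$trials$chosen[1L], chosen)
  lab <- paste0("S10->A", chosen)
  t0 <- probe$trials$time[1L]
  at <- function(rec, tt) rec$pathways[max(1L, findInterval(tt, rec$pathway_time)), lab]
  inc <- at(runA, t0 + 15) - at(runA, t0 + 1)
  dec <- at(runB, t0 + 15) - at(runB, t0 + 1)
  expect_gt(inc, 0)
  expect_lt(dec, 0)
  expect_lt(abs(abs(dec) - abs(inc)) / abs(inc), 0.25)
})
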