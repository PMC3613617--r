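#' Classical-conditioning scenario configuration
#'
#' Nine binary stimuli appear independently (Bernoulli per step at
#' \code{appear_prob} per second) and persist for a uniform random duration.
#' One designated stimulus, the conditioned stimulus (CS), triggers a reward
#' delivered after a uniform random delay; the other eight act as disturbers.
#' In the brief-stimulus variant stimuli last only 1-2 s and the CS reward is
#' delayed relative to stimulus offset, so the cue is already gone when the
#' reward arrives (the distal-reward regime proper).
#'
#' @param n_stimuli Number of stimulus channels.
#' @param cs_index Which stimulus is the CS.
#' @param appear_prob Per-second appearance probability of each stimulus.
#' @param duration_range Stimulus duration bounds, seconds.
#' @param reward_delay_range Reward delay bounds, seconds (after CS onset;
#'   after CS offset in the brief variant).
#' @param reward_magnitude Reward r(t) magnitude.
#' @param reward_duration How long r(t) holds its magnitude per episode,
#'   seconds; the unconditioned stimulus is a sustained touch of the hand,
#'   modeled as a 1-s pulse by default.
#' @param total_time Run horizon, seconds.
#' @param brief Use the brief-stimulus variant.
#' @param brief_duration_range Duration bounds in the brief variant, seconds.
#' @param fixed_delay If non-NULL, replaces the random reward delay with this
#'   fixed post-offset delay (used by the delay-capacity sweep).
#' @param response_threshold Output-group activity at or above which a
#'   conditioned response is flagged during CS-only intervals.
#' @return An object of class \code{rchp_classical_config}.
#' @export
classical_config <- function(n_stimuli = 9L,
                             cs_index = 1L,
                             appear_prob = 0.0015,
                             duration_range = c(3, 30),
                             reward_delay_range = c(0, 5),
                             reward_magnitude = 1,
                             reward_duration = 1,
                             total_time = 7200,
                             brief = FALSE,
                             brief_duration_range = c(1, 2),
                             fixed_delay = NULL,
                             response_threshold = 0.5) {
  cfg <- list(n_stimuli = as.integer(n_stimuli), cs_index = as.integer(cs_index),
              appear_prob = appear_prob, duration_range = duration_range,
              reward_delay_range = reward_delay_range,
              reward_magnitude = reward_magnitude,
              reward_duration = reward_duration, total_time = total_time,
              brief = isTRUE(brief), brief_duration_range = brief_duration_range,
              fixed_delay = fixed_delay,
              response_threshold = response_threshold)
  if (cfg$appear_prob < 0 || cfg$appear_prob > 1)
    stop("appear_prob must lie in [0, 1]")
  if (cfg$cs_index < 1L || cfg$cs_index > cfg$n_stimuli)
    stop("cs_index must name one of the stimuli")
  if (diff(cfg$duration_range) < 0 || diff(cfg$reward_delay_range) < 0 ||
      diff(cfg$brief_duration_range) < 0)
    stop("ranges must be ordered")
  if (cfg$total_time <= 0) stop("total_time must be positive")
  structure(cfg, class = "rchp_classical_config")
}

#' Generate a stimulus/reward event schedule for classical conditioning
#'
#' Each currently-absent stimulus turns on with probability
#' \code{appear_prob * dt} per step; on onset a duration is drawn uniformly.
#' Every CS appearance schedules one reward at onset (or offset, brief
#' variant) plus the configured delay. Draws come from R's RNG, so the
#' schedule is reproducible under \code{set.seed()}.
#'
#' @param config A [classical_config()] object.
#' @param dt Sampling time, seconds.
#' @return An object of class \code{rchp_schedule}: data frames
#'   \code{stimuli} (stimulus, onset, offset) and \code{rewards}
#'   (time, magnitude), plus \code{total_time}.
#' @export
generate_classical_schedule <- function(config, dt = 0.2) {
  stopifnot(inherits(config, "rchp_classical_config"))
  nsteps <- round(config$total_time / dt)
  p_step <- config$appear_prob * dt
  dr <- if (config$brief) config$brief_duration_range else config$duration_range
  stim <- list()
  rew <- list()
  if (p_step > 0) {
    for (s in seq_len(config$n_stimuli)) {
      t_step <- 0L
      repeat {
        gap <- stats::rgeom(1L, p_step) + 1L
        onset_step <- t_step + gap
        if (onset_step > nsteps) break
        onset <- (onset_step - 1L) * dt
        dur <- stats::runif(1L, dr[1L], dr[2L])
        offset <- min(onset + dur, config$total_time)
        stim[[length(stim) + 1L]] <- c(s, onset, offset)
        if (s == config$cs_index) {
          anchor <- if (config$brief || !is.null(config$fixed_delay)) offset else onset
          delay <- if (!is.null(config$fixed_delay)) config$fixed_delay
                   else stats::runif(1L, config$reward_delay_range[1L],
                                     config$reward_delay_range[2L])
          rtime <- anchor + delay
          if (rtime < config$total_time)
            rew[[length(rew) + 1L]] <- c(rtime, config$reward_magnitude)
        }
        t_step <- as.integer(ceiling(offset / dt))
      }
    }
  }
  stimuli <- if (length(stim)) {
    m <- do.call(rbind, stim)
    data.frame(stimulus = as.integer(m[, 1L]), onset = m[, 2L], offset = m[, 3L])
  } else data.frame(stimulus = integer(0), onset = numeric(0), offset = numeric(0))
  stimuli <- stimuli[order(stimuli$onset), , drop = FALSE]
  rownames(stimuli) <- NULL
  rewards <- if (length(rew)) {
    m <- do.call(rbind, rew)
    data.frame(time = m[, 1L], magnitude = m[, 2L])
  } else data.frame(time = numeric(0), magnitude = numeric(0))
  rewards <- rewards[order(rewards$time), , drop = FALSE]
  rownames(rewards) <- NULL
  structure(list(stimuli = stimuli, rewards = rewards,
                 total_time = config$total_time),
            class = "rchp_schedule")
}

# stimulus matrix (n_stimuli x nsteps) and per-step reward vector; each
# reward holds its magnitude for reward_duration seconds
rasterize_schedule <- function(schedule, n_stimuli, nsteps, dt,
                               reward_duration = dt) {
  stim_on <- matrix(0L, n_stimuli, nsteps)
  if (nrow(schedule$stimuli)) {
    for (k in seq_len(nrow(schedule$stimuli))) {
      first <- floor(schedule$stimuli$onset[k] / dt) + 1L
      last <- min(nsteps, ceiling(schedule$stimuli$offset[k] / dt))
      if (last >= first) stim_on[schedule$stimuli$stimulus[k], first:last] <- 1L
    }
  }
  r_step <- numeric(nsteps)
  width <- max(1L, as.integer(round(reward_duration / dt)))
  if (nrow(schedule$rewards)) {
    for (k in seq_len(nrow(schedule$rewards))) {
      first <- floor(schedule$rewards$time[k] / dt) + 1L
      last <- min(nsteps, first + width - 1L)
      if (first <= nsteps)
        r_step[first:last] <- r_step[first:last] + schedule$rewards$magnitude[k]
    }
  }
  list(stim_on = stim_on, r_step = r_step)
}

#' Run the classical-conditioning scenario
#'
#' Closed-loop simulation of the 9-stimulus classical-conditioning protocol:
#' stimuli from the schedule drive their input groups, CS-triggered rewards
#' hold r(t) at the configured magnitude for \code{reward_duration} seconds
#' (the sustained touch of the hand), and the full plasticity cascade runs
#' every step. Records per-step group activities, modulation, thresholds and
#' correlation rates, per-second pathway strengths from every stimulus group
#' to the output group, and flags a conditioned response whenever the output
#' group's activity reaches the response threshold during a CS-only interval.
#'
#' @param network An `rchp_network` built with \code{n_stimuli} input groups
#'   and one output group, or NULL to build one (labels S1..Sn, A0).
#' @param plasticity A [plasticity_params()] object.
#' @param config A [classical_config()] object.
#' @param schedule Optional precomputed [generate_classical_schedule()]
#'   result; generated from \code{config} when NULL.
#' @param seed Optional integer seed covering network construction, schedule
#'   and neural noise.
#' @param net_params Used when \code{network} is NULL.
#' @param record_pathways_every Pathway sampling interval, seconds.
#' @return An object of class \code{rchp_recording}.
#' @export
run_classical <- function(network = NULL, plasticity = plasticity_params(),
                          config = classical_config(), schedule = NULL,
                          seed = NULL, net_params = network_params(),
                          record_pathways_every = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(network)) {
    network <- build_network(net_params,
                             group_spec(inputs = paste0("S", seq_len(config$n_stimuli)),
                                        outputs = "A0"))
  }
  labels <- names(network$groups)
  roles <- vapply(network$groups, function(g) g$role, "")
  in_labels <- labels[roles == "input"]
  out_label <- labels[roles == "output"][1L]
  if (length(in_labels) != config$n_stimuli)
    stop("network input-group count does not match config$n_stimuli")
  dt <- network$params$dt
  if (is.null(schedule)) schedule <- generate_classical_schedule(config, dt)
  if (abs(schedule$total_time - config$total_time) > dt)
    stop("schedule horizon does not match config$total_time")
  nsteps <- round(config$total_time / dt)
  ras <- rasterize_schedule(schedule, config$n_stimuli, nsteps, dt,
                            config$reward_duration %||% dt)

  pnames <- paste0(in_labels, "->", out_label)
  pidx <- lapply(in_labels, function(l) pathway_index(network, l, out_label))
  record_every <- max(1L, round(record_pathways_every / dt))
  out <- cpp_run_schedule(network, network$params, plasticity,
                          ras$stim_on, match(in_labels, labels),
                          ras$r_step, pidx, record_every)

  network$w <- out$w
  network$state <- out$state
  cs_label <- in_labels[config$cs_index]
  rec <- new_recording(
    type = "classical", network = network, plasticity = plasticity,
    config = config, seed = seed, nsteps = nsteps, dt = dt,
    engine_out = out, pathway_names = pnames, group_labels = labels,
    schedule = schedule, cs_label = cs_label, out_label = out_label)
  rec$events <- classical_events(rec, ras)
  rec
}

# events table: stimulus on/off, rewards, conditioned-response episodes
classical_events <- function(rec, ras) {
  sch <- rec$schedule
  ev <- list()
  if (nrow(sch$stimuli)) {
    lab <- paste0("S", sch$stimuli$stimulus)
    ev[[1L]] <- data.frame(time = sch$stimuli$onset, type = "stimulus_on",
                           label = lab, value = NA_real_)
    ev[[2L]] <- data.frame(time = sch$stimuli$offset, type = "stimulus_off",
                           label = lab, value = NA_real_)
  }
  if (nrow(sch$rewards))
    ev[[length(ev) + 1L]] <- data.frame(time = sch$rewards$time, type = "reward",
                                        label = "US", value = sch$rewards$magnitude)
  cs_row <- rec$config$cs_index
  act <- rec$series[[paste0("act_", rec$out_label)]]
  cs_only <- ras$stim_on[cs_row, ] == 1L &
    colSums(ras$stim_on[-cs_row, , drop = FALSE]) == 0L
  hits <- cs_only & act >= rec$config$response_threshold
  if (any(hits)) {
    runs <- rle(hits)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    on <- runs$values
    ev[[length(ev) + 1L]] <- data.frame(
      time = rec$series$time[starts[on]], type = "conditioned_response",
      label = rec$cs_label,
      value = vapply(which(on), function(k) max(act[starts[k]:ends[k]]), 0))
  }
  ev <- if (length(ev)) do.call(rbind, ev)
        else data.frame(time = numeric(0), type = character(0),
                        label = character(0), value = numeric(0))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Conditioned-response episodes of a classical recording
#'
#' @param recording An `rchp_recording` from [run_classical()].
#' @return The conditioned-response rows of the event table.
#' @export
conditioned_responses <- function(recording) {
  recording$events[recording$events$type == "conditioned_response", ,
                   drop = FALSE]
}

#' Does the CS pathway end dominant?
#'
#' TRUE when the final mean weight of the CS-to-output pathway strictly
#' exceeds that of every disturbing pathway.
#'
#' @param recording An `rchp_recording` from [run_classical()].
#' @return Logical.
#' @export
cs_dominant <- function(recording) {
  fs <- recording$final$pathway_strength
  cs <- paste0(recording$cs_label, "->", recording$out_label)
  unname(fs[cs] > max(fs[setdiff(names(fs), cs)]))
}

#' Operant-conditioning scenario configuration
#'
#' One colored-object stimulus is presented every \code{period} seconds,
#' sequentially and circularly over the colors. Output-group activity is
#' monitored over a 1-s decision window; the selected action receives
#' winner-take-all feedback and, depending on the tutor policy, a delayed
#' reward (+5 when correct) or a small negative reward (-0.5 otherwise).
#'
#' @param n_colors Number of color stimuli (input groups S10, S11, ...).
#' @param n_actions Number of actions (output groups A1..A8).
#' @param period Presentation period, seconds.
#' @param reward_correct Reward magnitude for a correct answer.
#' @param reward_wrong Reward magnitude for a wrong answer (0 to ignore).
#' @param reward_delay_range Reward delay bounds after the action, seconds.
#' @param decision_window Activity-monitoring window, seconds.
#' @param decision_threshold_frac Fraction of the maximum attainable activity
#'   that triggers an early decision.
#' @param stimulus_duration How long the stimulus stays on, seconds.
#' @param feedback_duration Winner-take-all feedback duration, seconds.
#' @param total_time Run horizon, seconds.
#' @return An object of class \code{rchp_operant_config}.
#' @export
operant_config <- function(n_colors = 5L,
                           n_actions = 8L,
                           period = 20,
                           reward_correct = 5,
                           reward_wrong = -0.5,
                           reward_delay_range = c(0, 5),
                           decision_window = 1,
                           decision_threshold_frac = 0.30,
                           stimulus_duration = 2,
                           feedback_duration = 1,
                           total_time = 1800) {
  cfg <- list(n_colors = as.integer(n_colors), n_actions = as.integer(n_actions),
              period = period, reward_correct = reward_correct,
              reward_wrong = reward_wrong,
              reward_delay_range = reward_delay_range,
              decision_window = decision_window,
              decision_threshold_frac = decision_threshold_frac,
              stimulus_duration = stimulus_duration,
              feedback_duration = feedback_duration,
              total_time = total_time)
  if (cfg$n_colors > cfg$n_actions)
    stop("n_colors must not exceed n_actions")
  if (cfg$period <= cfg$decision_window)
    stop("period must exceed the decision window")
  if (diff(cfg$reward_delay_range) < 0) stop("reward_delay_range must be ordered")
  structure(cfg, class = "rchp_operant_config")
}

#' Tutor reward policy for operant conditioning
#'
#' @param mapping Integer vector: correct action id for each color.
#' @param punish_wrong Deliver \code{reward_wrong} for incorrect answers
#'   (FALSE ignores them, as the tutor ignoring a wrong color).
#' @param reversal Optional list \code{(time, stimulus, new_action)}: from
#'   \code{time} (seconds into the run) on, the named color's correct action
#'   becomes \code{new_action}, and choosing the previously correct action is
#'   punished with a reward of opposite sign and equal magnitude.
#' @return An object of class \code{rchp_reward_policy}.
#' @export
reward_policy <- function(mapping, punish_wrong = TRUE, reversal = NULL) {
  mapping <- as.integer(mapping)
  if (anyNA(mapping)) stop("mapping must be complete over the colors")
  if (!is.null(reversal)) {
    stopifnot(all(c("time", "stimulus", "new_action") %in% names(reversal)))
    if (reversal$stimulus < 1L || reversal$stimulus > length(mapping))
      stop("reversal$stimulus must name one of the colors")
  }
  structure(list(mapping = mapping, punish_wrong = isTRUE(punish_wrong),
                 reversal = reversal),
            class = "rchp_reward_policy")
}

#' Select an action from output-group activity over the decision window
#'
#' At the earliest step where at least one group reaches the activity
#' threshold, the highest-activity group among those crossing wins (exact
#' ties break to the lowest group index). If none crosses within the window,
#' the group with the highest activity at the window end wins, even by a
#' small margin.
#'
#' @param activity_history Matrix (steps x groups) of group activities over
#'   the window.
#' @param threshold_frac Fraction of \code{max_activity} that triggers an
#'   early decision.
#' @param max_activity Maximum attainable group activity (tanh bound, 1).
#' @return The winning group (column) index.
#' @export
select_action <- function(activity_history, threshold_frac = 0.3,
                          max_activity = 1) {
  if (is.null(dim(activity_history)))
    activity_history <- matrix(activity_history, nrow = 1L)
  if (nrow(activity_history) == 0L || ncol(activity_history) == 0L)
    stop("empty activity history")
  th <- threshold_frac * max_activity
  for (t in seq_len(nrow(activity_history))) {
    row <- activity_history[t, ]
    cross <- which(row >= th)
    if (length(cross)) return(cross[which.max(row[cross])])
  }
  unname(which.max(activity_history[nrow(activity_history), ]))
}

#' Run the operant-conditioning scenario
#'
#' Closed-loop trial-and-error learning of color-to-action associations:
#' every \code{period} seconds the next color (sequential-circular) drives
#' its input group, the action groups compete over the decision window, the
#' winner receives action-to-network feedback, and the tutor policy schedules
#' a delayed reward or punishment. Supports behavior reversal through the
#' policy's \code{reversal} field.
#'
#' @param network An `rchp_network` with \code{n_colors} input groups and
#'   \code{n_actions} output groups, or NULL to build one (labels S10...,
#'   A1..A8). Passing the network of a previous recording continues learning
#'   from its weights (the trial clock restarts at zero).
#' @param plasticity A [plasticity_params()] object.
#' @param config An [operant_config()] object.
#' @param policy A [reward_policy()] object.
#' @param seed Optional integer seed.
#' @param net_params Used when \code{network} is NULL.
#' @param record_pathways_every Pathway sampling interval, seconds.
#' @return An object of class \code{rchp_recording} with a per-trial table
#'   (\code{$trials}: color, chosen and correct action, reward, times).
#' @export
run_operant <- function(network = NULL, plasticity = plasticity_params(),
                        config = operant_config(),
                        policy = reward_policy(seq_len(config$n_colors)),
                        seed = NULL, net_params = network_params(),
                        record_pathways_every = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (length(policy$mapping) != config$n_colors)
    stop("policy mapping must cover all colors")
  if (any(policy$mapping < 1L | policy$mapping > config$n_actions))
    stop("policy mapping refers to unknown actions")
  if (is.null(network)) {
    network <- build_network(
      net_params,
      group_spec(inputs = paste0("S", 9L + seq_len(config$n_colors)),
                 outputs = paste0("A", seq_len(config$n_actions))))
  }
  labels <- names(network$groups)
  roles <- vapply(network$groups, function(g) g$role, "")
  in_labels <- labels[roles == "input"]
  out_labels <- labels[roles == "output"]
  if (length(in_labels) != config$n_colors ||
      length(out_labels) != config$n_actions)
    stop("network group layout does not match the operant config")
  dt <- network$params$dt
  nsteps <- round(config$total_time / dt)

  n_trials <- floor(config$total_time / config$period)
  onset_time <- (seq_len(n_trials) - 1) * config$period
  onset_step <- as.integer(round(onset_time / dt))     # 0-based for the engine
  color <- ((seq_len(n_trials) - 1L) %% config$n_colors) + 1L
  correct <- policy$mapping[color]
  punished <- integer(n_trials)
  if (!is.null(policy$reversal)) {
    rv <- policy$reversal
    flip <- onset_time >= rv$time & color == rv$stimulus
    correct[flip] <- rv$new_action
    punished[flip] <- policy$mapping[rv$stimulus]
  }
  reward_wrong <- if (policy$punish_wrong) config$reward_wrong else 0

  pnames <- as.vector(outer(in_labels, out_labels, paste, sep = "->"))
  pidx <- lapply(seq_along(pnames), function(k) {
    i <- (k - 1L) %% length(in_labels) + 1L
    j <- (k - 1L) %/% length(in_labels) + 1L
    pathway_index(network, in_labels[i], out_labels[j])
  })
  record_every <- max(1L, round(record_pathways_every / dt))
  out <- cpp_run_operant(
    network, network$params, plasticity, nsteps,
    onset_step, match(in_labels, labels)[color],
    as.integer(correct), as.integer(punished),
    config$reward_correct, reward_wrong, -config$reward_correct,
    config$reward_delay_range[1L], config$reward_delay_range[2L],
    as.integer(round(config$stimulus_duration / dt)),
    as.integer(round(config$decision_window / dt)),
    as.integer(round(config$feedback_duration / dt)),
    config$decision_threshold_frac * 1.0,
    match(out_labels, labels), pidx, record_every)

  network$w <- out$w
  network$state <- out$state
  trials <- data.frame(
    trial = seq_len(n_trials),
    time = onset_time,
    color = color,
    stimulus = in_labels[color],
    chosen = out$chosen,
    action = ifelse(is.na(out$chosen), NA_character_, out_labels[out$chosen]),
    correct_action = correct,
    correct = !is.na(out$chosen) & out$chosen == correct,
    punished_action = ifelse(punished == 0L, NA_integer_, punished),
    reward = out$reward_mag,
    decision_time = out$decision_step * dt,
    reward_time = out$reward_step * dt)

  rec <- new_recording(
    type = if (is.null(policy$reversal)) "operant" else "reversal",
    network = network, plasticity = plasticity, config = config,
    seed = seed, nsteps = nsteps, dt = dt, engine_out = out,
    pathway_names = pnames, group_labels = labels,
    schedule = NULL, cs_label = NA_character_, out_label = NA_character_)
  rec$policy <- policy
  rec$trials <- trials
  rec$events <- operant_events(trials)
  rec
}

operant_events <- function(trials) {
  ev <- rbind(
    data.frame(time = trials$time, type = "stimulus_on",
               label = trials$stimulus, value = NA_real_),
    data.frame(time = trials$decision_time, type = "action",
               label = trials$action, value = as.numeric(trials$chosen)),
    data.frame(time = trials$reward_time, type = "reward", label = "US",
               value = trials$reward))
  ev <- ev[!is.na(ev$time), , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Run a behavior-reversal experiment
#'
#' Convenience wrapper over [run_operant()] with a mandatory reversal in the
#' policy: the tutor first rewards the original mapping, then from the switch
#' time punishes the previously-correct action (reward of opposite sign) and
#' rewards the new one, driving the four-phase trajectory exploit-old,
#' weight convergence, re-exploration, exploit-new (see
#' [segment_reversal_phases()]).
#'
#' @inheritParams run_operant
#' @export
run_reversal <- function(network = NULL, plasticity = plasticity_params(),
                         config = operant_config(), policy, seed = NULL,
                         net_params = network_params(),
                         record_pathways_every = 1) {
  if (is.null(policy$reversal))
    stop("run_reversal() needs a policy with a reversal spec")
  run_operant(network, plasticity, config, policy, seed, net_params,
              record_pathways_every)
}

#' When was each color-action association learned?
#'
#' A color counts as learned at time T when the correct action is chosen on
#' its trial at T and on every subsequent trial of that color (trials whose
#' decision fell beyond the horizon are ignored).
#'
#' @param recording An `rchp_recording` from [run_operant()].
#' @return Named numeric vector of learned-at times in seconds (Inf when a
#'   color never reaches a trailing all-correct streak), with attribute
#'   \code{"overall"} = the maximum.
#' @export
learning_times <- function(recording) {
  trials <- recording$trials
  if (is.null(trials)) stop("recording has no trials (not an operant run)")
  trials <- trials[!is.na(trials$chosen), , drop = FALSE]
  colors <- sort(unique(trials$color))
  out <- vapply(colors, function(cl) {
    tr <- trials[trials$color == cl, , drop = FALSE]
    if (nrow(tr) == 0L) return(Inf)
    ok <- rev(cumprod(rev(tr$correct))) == 1   # trailing all-correct streak
    if (!any(ok)) return(Inf)
    tr$time[which(ok)[1L]]
  }, 0)
  names(out) <- paste0("color", colors)
  attr(out, "overall") <- max(out)
  out
}

#' Sweep the reward delay to find the delay capacity
#'
#' Brief-stimulus classical conditioning with a fixed post-offset reward
#' delay d: for each delay several independent runs are executed and the CS
#' pathway's final dominance is checked. The delay capacity is the largest
#' swept d at which a majority of runs still ends CS-dominant.
#'
#' @param delays Delays to sweep, seconds.
#' @param n_seeds Independent runs per delay.
#' @param duration Run horizon, seconds.
#' @param plasticity,net_params Model parameters.
#' @param base_seed Integer from which per-run seeds are derived.
#' @return Data frame (delay, successes, runs, success_frac) with attribute
#'   \code{"capacity"}: the largest delay with success_frac > 0.5 (NA when
#'   none).
#' @export
sweep_delay <- function(delays = c(4, 6, 8, 10, 12), n_seeds = 5L,
                        duration = 7200, plasticity = plasticity_params(),
                        net_params = network_params(), base_seed = 1L) {
  successes <- integer(length(delays))
  for (di in seq_along(delays)) {
    cfg <- classical_config(brief = TRUE, fixed_delay = delays[di],
                            total_time = duration)
    for (s in seq_len(n_seeds)) {
      rec <- run_classical(plasticity = plasticity, config = cfg,
                           seed = mix_seed(base_seed, di * 1000L + s),
                           net_params = net_params)
      if (isTRUE(cs_dominant(rec))) successes[di] <- successes[di] + 1L
    }
  }
  out <- data.frame(delay = delays, successes = successes,
                    runs = as.integer(n_seeds),
                    success_frac = successes / n_seeds)
  ok <- out$delay[out$success_frac > 0.5]
  attr(out, "capacity") <- if (length(ok)) max(ok) else NA_real_
  out
}

# deterministic per-run seed derivation, kept inside 32-bit integer range
mix_seed <- function(base, k) {
  as.integer((as.double(base) * 7919 + as.double(k) * 104729) %% 2147483646) + 1L
}
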