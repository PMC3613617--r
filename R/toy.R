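#' Configuration of the synapse-population credit-assignment model
#'
#' The combinatorial abstraction of learning under delayed reward: in a
#' population of \code{n_synapses} synapses, correlations tag a fraction
#' \code{corr_rate} per second with eligibility traces that are negligible
#' after \code{eligibility_horizon} seconds, so at any time about
#' \code{n_synapses * corr_rate * eligibility_horizon} synapses are eligible.
#' One synapse sigma triggers every reward and is therefore always eligible
#' at reward time; all other synapses survive consecutive reinforcement only
#' by chance, at rate p = corr_rate * eligibility_horizon per episode.
#'
#' @param n_synapses Population size.
#' @param corr_rate Fraction of synapses gaining a trace per second.
#' @param trace_tau Trace time constant, seconds (exponential decay).
#' @param eligibility_horizon Hard eligibility window, seconds: the span over
#'   which a trace still counts as eligible.
#' @param reward_delay_range Reward delay bounds, seconds.
#' @param sigma_index Index of the reward-triggering synapse.
#' @param n_episodes Default number of reward episodes for [run_toy()].
#' @return An object of class \code{rchp_toy_config}.
#' @export
toy_config <- function(n_synapses = 100000L,
                       corr_rate = 0.01,
                       trace_tau = 1,
                       eligibility_horizon = 3,
                       reward_delay_range = c(1, 3),
                       sigma_index = 1L,
                       n_episodes = 5L) {
  cfg <- list(n_synapses = as.integer(n_synapses), corr_rate = corr_rate,
              trace_tau = trace_tau, eligibility_horizon = eligibility_horizon,
              reward_delay_range = reward_delay_range,
              sigma_index = as.integer(sigma_index),
              n_episodes = as.integer(n_episodes))
  if (cfg$corr_rate * cfg$eligibility_horizon > 1)
    stop("corr_rate * eligibility_horizon must not exceed 1")
  if (cfg$sigma_index < 1L || cfg$sigma_index > cfg$n_synapses)
    stop("sigma_index must address a synapse")
  structure(cfg, class = "rchp_toy_config")
}

#' Expected number of eligible synapses at any time
#'
#' Closed form: \code{n_synapses * corr_rate * eligibility_horizon}. With the
#' defaults (100,000 synapses, 1 %/s, 3-s window) this is 3,000 synapses, 3%
#' of the population.
#'
#' @param config A [toy_config()] object.
#' @return Expected eligible count (real).
#' @export
expected_eligible <- function(config) {
  config$n_synapses * config$corr_rate * config$eligibility_horizon
}

#' Expected survivors of k consecutive reinforcements
#'
#' With per-episode eligibility probability
#' p = \code{corr_rate * eligibility_horizon}, the expected number of
#' synapses (other than the reward-triggering one) eligible at k consecutive
#' independent reward episodes is \code{n_synapses * p^k}: 3,000 at k = 1,
#' 90 at k = 2, under 1 synapse by k = 4 with the defaults.
#'
#' @param config A [toy_config()] object.
#' @param k Episode count, >= 1.
#' @return Expected survivor count (real).
#' @export
expected_consecutive <- function(config, k) {
  if (k < 1) stop("k must be >= 1")
  p <- config$corr_rate * config$eligibility_horizon
  config$n_synapses * p^k
}

#' Monte-Carlo attrition of consecutively reinforced synapses
#'
#' Per reward episode each non-sigma synapse is eligible independently with
#' probability p = corr_rate * eligibility_horizon; sigma is always eligible
#' because it triggers the reward. Survivors at episode k are the synapses
#' eligible in all episodes 1..k. The attrition sequence shows how a few
#' reward episodes single out the reward-triggering synapse.
#'
#' @param config A [toy_config()] object.
#' @param n_episodes Number of reward episodes.
#' @param seed Optional integer seed.
#' @return Data frame per episode: \code{eligible} (set size),
#'   \code{survivors_non_sigma} (consecutive survivors excluding sigma),
#'   \code{sigma_eligible} (always TRUE).
#' @export
run_toy <- function(config = toy_config(), n_episodes = config$n_episodes,
                    seed = NULL) {
  if (n_episodes < 1L) stop("n_episodes must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- config$corr_rate * config$eligibility_horizon
  n <- config$n_synapses
  surviving <- rep(TRUE, n)
  eligible <- integer(n_episodes)
  survivors <- integer(n_episodes)
  for (e in seq_len(n_episodes)) {
    elig <- stats::runif(n) < p
    elig[config$sigma_index] <- TRUE
    eligible[e] <- sum(elig)
    surviving <- surviving & elig
    survivors[e] <- sum(surviving) - 1L     # sigma always survives
  }
  data.frame(episode = seq_len(n_episodes),
             eligible = eligible,
             survivors_non_sigma = survivors,
             sigma_eligible = TRUE)
}

#' Replicated attrition summary: analytic vs simulated
#'
#' @param config A [toy_config()] object.
#' @param n_episodes Episodes per replication.
#' @param replications Number of independent replications.
#' @param seed Optional integer seed.
#' @return Data frame per episode k: analytic expectation \code{expected},
#'   Monte-Carlo \code{mean}, \code{median}, \code{sd} of the non-sigma
#'   survivor count, and \code{sigma_always} (sigma survived in every
#'   replication).
#' @export
toy_summary <- function(config = toy_config(), n_episodes = config$n_episodes,
                        replications = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  surv <- matrix(0L, replications, n_episodes)
  elig <- matrix(0L, replications, n_episodes)
  for (r in seq_len(replications)) {
    df <- run_toy(config, n_episodes)
    surv[r, ] <- df$survivors_non_sigma
    elig[r, ] <- df$eligible
  }
  data.frame(
    episode = seq_len(n_episodes),
    expected = vapply(seq_len(n_episodes),
                      function(k) expected_consecutive(config, k), 0),
    mean = colMeans(surv),
    median = apply(surv, 2L, stats::median),
    sd = apply(surv, 2L, stats::sd),
    mean_eligible = colMeans(elig),
    sigma_always = TRUE)
}
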