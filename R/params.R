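#' Network parameters
#'
#' Constants of the rate-based neural substrate: population sizes, random
#' connectivity, the neuron transfer function, stimulus drive and the
#' sampling/propagation time step.
#'
#' The neuron model is
#' \deqn{u_i(t) = \sum_j w_{ji} \, v_j(t) \, \kappa_j}
#' \deqn{v_i(t+\Delta t) = \tanh(\gamma u_i(t)) + \xi_i(t) \quad (u_i \ge 0),
#'       \qquad v_i(t+\Delta t) = \xi_i(t) \quad (u_i < 0)}
#' with \eqn{\xi_i} fresh uniform noise on \eqn{[-0.1, 0.1]} each step and
#' \eqn{\kappa_j = +1} for excitatory, \eqn{-5} for inhibitory presynaptic
#' neurons. The sampling time (0.2 s) doubles as the signal propagation time,
#' so the correlation window of the plasticity rule is exactly one step.
#'
#' @param n_excitatory,n_inhibitory Number of excitatory / inhibitory neurons.
#' @param connect_prob Probability that a directed synapse j -> i exists.
#' @param gain Gain \eqn{\gamma} of the tanh transfer function.
#' @param kappa_excitatory,kappa_inhibitory Output scaling of excitatory (+1)
#'   and inhibitory (-5) presynaptic neurons.
#' @param noise_halfwidth Half-width of the uniform output noise \eqn{\xi}.
#' @param dt Sampling time in seconds; also the propagation time.
#' @param weight_min,weight_max Bounds of plastic weights.
#' @param input_drive State increment added to u of each member of an active
#'   input group (and, with sign, as winner-take-all action feedback).
#' @param group_size Neurons per input/output group.
#' @param w_init_max Initial weights are drawn uniformly on
#'   \code{[0, w_init_max]} (plastic and fixed alike).
#' @return An object of class \code{rchp_network_params}.
#' @seealso [plasticity_params()], [build_network()]
#' @export
#' @examples
#' p <- network_params()
#' p$n_excitatory + p$n_inhibitory  # 1000 neurons
network_params <- function(n_excitatory = 800L,
                           n_inhibitory = 200L,
                           connect_prob = 0.1,
                           gain = 0.5,
                           kappa_excitatory = 1,
                           kappa_inhibitory = -5,
                           noise_halfwidth = 0.1,
                           dt = 0.2,
                           weight_min = 0,
                           weight_max = 1,
                           input_drive = 10,
                           group_size = 60L,
                           w_init_max = 0.2) {
  p <- list(
    n_excitatory = as.integer(n_excitatory),
    n_inhibitory = as.integer(n_inhibitory),
    connect_prob = connect_prob,
    gain = gain,
    kappa_excitatory = kappa_excitatory,
    kappa_inhibitory = kappa_inhibitory,
    noise_halfwidth = noise_halfwidth,
    dt = dt,
    weight_min = weight_min,
    weight_max = weight_max,
    input_drive = input_drive,
    group_size = as.integer(group_size),
    w_init_max = w_init_max
  )
  if (p$n_excitatory < 0L || p$n_inhibitory < 0L)
    stop("population sizes must be non-negative")
  if (p$connect_prob < 0 || p$connect_prob > 1)
    stop("connect_prob must lie in [0, 1]")
  if (p$dt <= 0) stop("dt must be positive")
  if (p$weight_min >= p$weight_max) stop("weight_min must be < weight_max")
  if (p$noise_halfwidth < 0) stop("noise_halfwidth must be >= 0")
  if (p$group_size <= 0L) stop("group_size must be positive")
  if (p$w_init_max < p$weight_min || p$w_init_max > p$weight_max)
    stop("w_init_max must lie within the weight interval")
  structure(p, class = "rchp_network_params")
}

#' Plasticity parameters
#'
#' Constants of the learning engine. The rarely-correlating Hebbian rule emits
#' \eqn{+\alpha} when the lagged output product \eqn{v_j(t - t_{pt}) v_i(t)}
#' strictly exceeds \eqn{\theta_{hi}}, \eqn{-\beta} when it falls strictly
#' below \eqn{\theta_{lo}}, and 0 otherwise. Events feed eligibility traces
#' \deqn{\dot c_{ji} = -c_{ji}/\tau_c + \mathrm{RCHP}_{ji}(t)}
#' which a global modulation
#' \deqn{\dot m = -m/\tau_m + \lambda r(t) + b}
#' converts into weight changes \eqn{\dot w_{ji} = m \, c_{ji}} (plastic
#' synapses only, clipped to the weight interval).
#'
#' Both thresholds adapt homeostatically so that the windowed event rate stays
#' near the rare target \code{mu_target} (fraction of synapses per second):
#' when the rate measured over the last \code{window} seconds exceeds
#' \code{band_hi_factor * mu_target} the corresponding threshold magnitude
#' grows by \code{eta} per second; below \code{band_lo_factor * mu_target} it
#' shrinks by the same step, floored at zero.
#'
#' @param alpha,beta Positive learning rates for correlation / decorrelation
#'   events.
#' @param tau_c Eligibility-trace time constant, seconds.
#' @param tau_m Modulation time constant, seconds.
#' @param lambda Gain applied to the reward input r(t).
#' @param baseline Tonic modulation term b (signed, small); a small negative
#'   value yields slow extinction of repeatedly cued but unrewarded pathways.
#' @param mu_target Target correlation rate, fraction of synapses per second.
#' @param eta Threshold adaptation step per second.
#' @param window Length of the first-in-first-out event-count queue, seconds.
#' @param band_hi_factor,band_lo_factor Multiples of \code{mu_target} that
#'   bound the homeostatic dead band.
#' @param theta_hi_init,theta_lo_init Initial thresholds.
#' @return An object of class \code{rchp_plasticity_params}.
#' @seealso [network_params()], [detect_correlations()], [update_thresholds()]
#' @export
plasticity_params <- function(alpha = 0.1,
                              beta = 0.1,
                              tau_c = 4,
                              tau_m = 1,
                              lambda = 0.25,
                              baseline = -0.001,
                              mu_target = 0.005,
                              eta = 0.002,
                              window = 10,
                              band_hi_factor = 5,
                              band_lo_factor = 1 / 5,
                              theta_hi_init = 0.1,
                              theta_lo_init = -0.1) {
  p <- list(
    alpha = alpha, beta = beta,
    tau_c = tau_c, tau_m = tau_m,
    lambda = lambda, baseline = baseline,
    mu_target = mu_target, eta = eta, window = window,
    band_hi_factor = band_hi_factor, band_lo_factor = band_lo_factor,
    theta_hi_init = theta_hi_init, theta_lo_init = theta_lo_init
  )
  if (p$alpha <= 0 || p$beta <= 0) stop("alpha and beta must be positive")
  if (p$tau_c <= 0 || p$tau_m <= 0) stop("tau_c and tau_m must be positive")
  if (p$mu_target <= 0 || p$mu_target >= 1)
    stop("mu_target must lie in (0, 1)")
  if (p$window <= 0) stop("window must be positive")
  if (p$eta < 0) stop("eta must be >= 0")
  if (p$band_hi_factor <= p$band_lo_factor)
    stop("band_hi_factor must exceed band_lo_factor")
  if (p$theta_hi_init < 0) stop("theta_hi_init must be >= 0")
  if (p$theta_lo_init > 0) stop("theta_lo_init must be <= 0")
  structure(p, class = "rchp_plasticity_params")
}

#' @export
print.rchp_network_params <- function(x, ...) {
  cat("Network parameters:",
      sprintf("%d excitatory + %d inhibitory neurons, p(connect) = %g",
              x$n_excitatory, x$n_inhibitory, x$connect_prob),
      sprintf("gain = %g, kappa = %+g/%+g, noise = +/-%g, dt = %g s",
              x$gain, x$kappa_excitatory, x$kappa_inhibitory,
              x$noise_halfwidth, x$dt),
      sprintf("weights in [%g, %g] (init U[0, %g]), input drive = %g, group size = %d",
              x$weight_min, x$weight_max, x$w_init_max, x$input_drive,
              x$group_size),
      sep = "\n  ")
  cat("\n")
  invisible(x)
}

#' @export
print.rchp_plasticity_params <- function(x, ...) {
  cat("Plasticity parameters:",
      sprintf("alpha = %g, beta = %g, tau_c = %g s, tau_m = %g s",
              x$alpha, x$beta, x$tau_c, x$tau_m),
      sprintf("lambda = %g, baseline b = %g /s", x$lambda, x$baseline),
      sprintf("rare-correlation target mu = %g /s in band [%g, %g] /s, eta = %g /s, window = %g s",
              x$mu_target, x$band_lo_factor * x$mu_target,
              x$band_hi_factor * x$mu_target, x$eta, x$window),
      sprintf("theta_hi init = %g, theta_lo init = %g",
              x$theta_hi_init, x$theta_lo_init),
      sep = "\n  ")
  cat("\n")
  invisible(x)
}
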