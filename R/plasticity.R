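#' Detect rare correlation and decorrelation events
#'
#' The rarely-correlating Hebbian rule: for every existing synapse (j, i) the
#' lagged output product \eqn{v_j(t - t_{pt}) \, v_i(t)} is compared against
#' the adaptive thresholds. Strictly above \code{theta_hi} the synapse emits
#' \code{+alpha}; strictly below \code{theta_lo} it emits \code{-beta}; ties
#' and everything in between emit nothing. With thresholds tuned to keep
#' events rare, only a small fraction of synapses is tagged at any step.
#'
#' @param v_prev Output vector one sampling step (= the propagation time)
#'   before \code{v_curr}.
#' @param v_curr Current output vector.
#' @param pre,post Integer vectors of presynaptic / postsynaptic neuron
#'   indices of the existing synapses.
#' @param theta_hi,theta_lo Current correlation / decorrelation thresholds.
#' @param alpha,beta Positive event magnitudes.
#' @return A list: \code{idx} (synapse positions with an event), \code{delta}
#'   (event values, \code{+alpha} or \code{-beta}), and the step counts
#'   \code{n_corr}, \code{n_decorr}.
#' @export
#' @examples
#' # high pre followed by high post crosses theta_hi = 0.1
#' detect_correlations(c(0.9, 0), c(0, 0.9), pre = 1L, post = 2L,
#'                     theta_hi = 0.1, theta_lo = -0.1)
detect_correlations <- function(v_prev, v_curr, pre, post,
                                theta_hi, theta_lo,
                                alpha = 0.1, beta = 0.1) {
  prod <- v_prev[pre] * v_curr[post]
  hi <- prod > theta_hi
  lo <- prod < theta_lo
  idx <- which(hi | lo)
  delta <- numeric(length(idx))
  delta[hi[idx]] <- alpha
  delta[lo[idx]] <- -beta
  list(idx = idx, delta = delta,
       n_corr = sum(hi), n_decorr = sum(lo))
}

#' Homeostatic threshold adaptation
#'
#' Pushes the current step's event counts into first-in-first-out queues
#' covering the last \code{window} seconds and compares the windowed mean
#' event rate (fraction of monitored synapses per second) with the band
#' \code{[band_lo_factor, band_hi_factor] * mu_target}. Above the band the
#' threshold magnitude grows by \code{eta * dt}; below it, it shrinks by the
#' same step, floored at zero. \code{theta_hi} follows the correlation queue,
#' \code{|theta_lo|} symmetrically follows the decorrelation queue.
#'
#' @param thresholds List with \code{theta_hi}, \code{theta_lo},
#'   \code{corr_queue}, \code{decorr_queue} (queues oldest first).
#' @param n_corr,n_decorr Event counts of the current step.
#' @param n_synapses Number of synapses monitored by the rule.
#' @param params A [plasticity_params()] object.
#' @param dt Sampling time, seconds.
#' @return The updated thresholds list.
#' @export
update_thresholds <- function(thresholds, n_corr, n_decorr, n_synapses,
                              params, dt) {
  if (n_synapses <= 0L) stop("n_synapses must be positive")
  qlen <- max(1L, as.integer(round(params$window / dt)))
  step <- params$eta * dt
  hi_band <- params$band_hi_factor * params$mu_target
  lo_band <- params$band_lo_factor * params$mu_target

  cq <- c(thresholds$corr_queue, n_corr)
  if (length(cq) > qlen) cq <- cq[(length(cq) - qlen + 1L):length(cq)]
  rate_c <- sum(cq) / (length(cq) * dt * n_synapses)
  theta_hi <- thresholds$theta_hi
  if (rate_c > hi_band) theta_hi <- theta_hi + step
  else if (rate_c < lo_band) theta_hi <- max(0, theta_hi - step)

  dq <- c(thresholds$decorr_queue, n_decorr)
  if (length(dq) > qlen) dq <- dq[(length(dq) - qlen + 1L):length(dq)]
  rate_d <- sum(dq) / (length(dq) * dt * n_synapses)
  theta_lo <- thresholds$theta_lo
  if (rate_d > hi_band) theta_lo <- theta_lo - step
  else if (rate_d < lo_band) theta_lo <- min(0, theta_lo + step)

  list(theta_hi = theta_hi, theta_lo = theta_lo,
       corr_queue = cq, decorr_queue = dq,
       corr_rate = rate_c, decorr_rate = rate_d)
}

#' Eligibility-trace update
#'
#' Explicit first-order integration of the trace dynamics
#' \eqn{\dot c = -c/\tau_c + \mathrm{RCHP}(t)}: every trace decays by the
#' factor \code{1 - dt/tau_c} and event values are added at full magnitude at
#' the event step. Traces are not clipped; their decay bounds them.
#'
#' @param c Trace vector over existing synapses.
#' @param events Either the list returned by [detect_correlations()] or a
#'   full-length vector of event values.
#' @param tau_c Trace time constant, seconds.
#' @param dt Sampling time, seconds; must not exceed \code{tau_c}.
#' @return The updated trace vector.
#' @export
#' @examples
#' update_traces(1, list(idx = integer(0), delta = numeric(0)), 4, 0.2)  # 0.95
update_traces <- function(c, events, tau_c, dt) {
  if (dt > tau_c) stop("dt must not exceed tau_c")
  out <- c * (1 - dt / tau_c)
  if (is.list(events)) {
    if (length(events$idx)) out[events$idx] <- out[events$idx] + events$delta
  } else if (length(events)) {
    out <- out + events
  }
  out
}

#' Modulation update
#'
#' Explicit first-order integration of
#' \eqn{\dot m = -m/\tau_m + \lambda r(t) + b}: the modulation decays with
#' time constant \code{tau_m} and integrates the reward input and the tonic
#' baseline. With constant r and b the map converges to the fixed point
#' \eqn{m^* = \tau_m (\lambda r + b)}.
#'
#' @param m Current modulation level.
#' @param r Reward input for this step.
#' @param params A [plasticity_params()] object (uses \code{tau_m},
#'   \code{lambda}, \code{baseline}).
#' @param dt Sampling time, seconds.
#' @return The updated modulation level.
#' @export
update_modulation <- function(m, r, params, dt) {
  m * (1 - dt / params$tau_m) + (params$lambda * r + params$baseline) * dt
}

#' Modulated weight update
#'
#' Euler step of \eqn{\dot w_{ji} = m \, c_{ji}} applied to plastic synapses
#' only, with the result clipped to the weight interval. Fixed synapses are
#' returned untouched; with \code{m = 0} the weights are returned exactly
#' unchanged.
#'
#' @param w Weight vector over existing synapses.
#' @param plastic Logical vector marking plastic synapses.
#' @param m Modulation level.
#' @param c Trace vector.
#' @param dt Sampling time, seconds.
#' @param weight_min,weight_max Clipping interval.
#' @return The updated weight vector.
#' @export
apply_weight_update <- function(w, plastic, m, c, dt,
                                weight_min = 0, weight_max = 1) {
  if (m == 0) return(w)
  out <- w
  idx <- which(plastic)
  out[idx] <- pmin(weight_max, pmax(weight_min, w[idx] + m * dt * c[idx]))
  out
}
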