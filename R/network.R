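#' Specify input and output neuron groups
#'
#' @param inputs Character vector of input-group labels (stimulus channels).
#' @param outputs Character vector of output-group labels (action channels).
#' @return A data frame with columns \code{label} and \code{role}.
#' @export
#' @examples
#' group_spec(inputs = paste0("S", 1:9), outputs = "A0")
group_spec <- function(inputs = character(), outputs = character()) {
  labels <- c(inputs, outputs)
  if (anyDuplicated(labels)) stop("group labels must be unique")
  data.frame(label = labels,
             role = c(rep("input", length(inputs)),
                      rep("output", length(outputs))),
             stringsAsFactors = FALSE)
}

#' Build a random recurrent network with input and output groups
#'
#' Constructs the neural substrate: \code{n_excitatory + n_inhibitory} neurons,
#' a directed synapse j -> i existing with probability \code{connect_prob}
#' (no self-connections), and disjoint groups of \code{group_size} randomly
#' selected excitatory neurons serving as stimulus (input) or action (output)
#' channels. Input-group members receive no connections from the network;
#' output-group members project none into it, so persistent stimuli cannot
#' ignite self-sustained recurrent activity through the channel neurons.
#'
#' Afferent synapses of excitatory neurons are plastic on
#' \code{[weight_min, weight_max]}; afferents of inhibitory neurons are fixed.
#' All weights initialize uniformly on \code{[0, w_init_max]}.
#'
#' @param params A [network_params()] object.
#' @param groups A data frame from [group_spec()] (columns \code{label},
#'   \code{role}).
#' @param seed Optional integer; when given, \code{set.seed(seed)} is called
#'   first so construction is reproducible.
#' @return An object of class \code{rchp_network}: synapse arrays
#'   (\code{pre}, \code{post}, \code{w}, \code{plastic}), per-neuron
#'   \code{kappa}, the group list, and the dynamical \code{state} (outputs
#'   \code{v}, traces \code{c}, modulation \code{m}, thresholds and event
#'   queues, simulated \code{time}).
#' @export
build_network <- function(params, groups, seed = NULL) {
  stopifnot(inherits(params, "rchp_network_params"))
  if (!is.data.frame(groups) || !all(c("label", "role") %in% names(groups)))
    stop("groups must be a data frame with columns label and role (see group_spec())")
  if (!all(groups$role %in% c("input", "output")))
    stop("group roles must be 'input' or 'output'")
  if (!is.null(seed)) set.seed(seed)

  n_exc <- params$n_excitatory
  n_inh <- params$n_inhibitory
  n <- n_exc + n_inh
  k <- nrow(groups)
  need <- k * params$group_size
  if (need > n_exc)
    stop(sprintf("group demand (%d groups x %d neurons = %d) exceeds the excitatory pool (%d)",
                 k, params$group_size, need, n_exc))

  # disjoint membership, sampled without replacement from the excitatory pool
  pool <- if (need > 0L) sample.int(n_exc, need) else integer(0)
  glist <- vector("list", k)
  for (g in seq_len(k)) {
    members <- sort(pool[((g - 1L) * params$group_size + 1L):(g * params$group_size)])
    glist[[g]] <- list(label = groups$label[g], role = groups$role[g],
                       members = members)
  }
  names(glist) <- groups$label
  input_members <- unlist(lapply(glist, function(g)
    if (g$role == "input") g$members else integer(0)), use.names = FALSE)
  output_members <- unlist(lapply(glist, function(g)
    if (g$role == "output") g$members else integer(0)), use.names = FALSE)

  # adjacency: rows = presynaptic j, cols = postsynaptic i
  exists <- matrix(stats::runif(as.double(n) * n) < params$connect_prob, n, n)
  diag(exists) <- FALSE
  if (length(input_members)) exists[, input_members] <- FALSE
  if (length(output_members)) exists[output_members, ] <- FALSE
  idx <- which(exists)
  pre <- as.integer((idx - 1L) %% n + 1L)
  post <- as.integer((idx - 1L) %/% n + 1L)
  ns <- length(idx)
  w <- stats::runif(ns, 0, params$w_init_max)
  plastic <- post <= n_exc
  kappa <- c(rep(params$kappa_excitatory, n_exc),
             rep(params$kappa_inhibitory, n_inh))

  structure(list(
    params = params,
    n = n, n_excitatory = n_exc, n_inhibitory = n_inh,
    pre = pre, post = post, w = w, plastic = plastic,
    kappa = kappa,
    groups = glist,
    state = list(
      v = numeric(n),
      c = numeric(ns),
      m = 0,
      theta_hi = NA_real_,       # initialized from plasticity params at first use
      theta_lo = NA_real_,
      corr_queue = numeric(0),   # oldest first
      decorr_queue = numeric(0),
      time = 0
    )
  ), class = "rchp_network")
}

#' @export
print.rchp_network <- function(x, ...) {
  roles <- vapply(x$groups, function(g) g$role, "")
  cat(sprintf("rchp network: %d neurons (%d exc + %d inh), %d synapses (%d plastic)\n",
              x$n, x$n_excitatory, x$n_inhibitory, length(x$w), sum(x$plastic)))
  cat(sprintf("  groups: %d input (%s), %d output (%s)\n",
              sum(roles == "input"),
              paste(names(x$groups)[roles == "input"], collapse = ", "),
              sum(roles == "output"),
              paste(names(x$groups)[roles == "output"], collapse = ", ")))
  cat(sprintf("  state: t = %g s, m = %.4g, theta_hi = %s, theta_lo = %s\n",
              x$state$time, x$state$m,
              format(x$state$theta_hi, digits = 4),
              format(x$state$theta_lo, digits = 4)))
  invisible(x)
}

#' Mean activity of a neuron group
#'
#' Sum of the outputs of all neurons in the group, normalized by group size.
#'
#' @param v Output vector of the whole network (or an `rchp_network`, whose
#'   current state is then used).
#' @param group A group element of the network (list with \code{members}), a
#'   group label, or an integer vector of neuron indices.
#' @param network Needed to resolve `group` when it is a label.
#' @return Scalar mean output of the group members.
#' @export
group_activity <- function(v, group, network = NULL) {
  if (inherits(v, "rchp_network")) {
    network <- v
    v <- network$state$v
  }
  members <- resolve_members(group, network)
  if (length(members) == 0L) stop("group is empty")
  sum(v[members]) / length(members)
}

resolve_members <- function(group, network = NULL) {
  if (is.list(group) && !is.null(group$members)) return(group$members)
  if (is.character(group)) {
    if (is.null(network)) stop("a network is required to resolve a group label")
    g <- network$groups[[group]]
    if (is.null(g)) stop(sprintf("no group labelled '%s'", group))
    return(g$members)
  }
  if (is.numeric(group)) return(as.integer(group))
  stop("cannot interpret 'group'")
}

#' Advance the network dynamics by one sampling step
#'
#' Pure substrate update (no plasticity): recompute neuron states u from the
#' previous outputs, add stimulus drive for active input groups and optional
#' winner-take-all action feedback, then emit new outputs through the noisy
#' tanh transfer function. Used as the single-step reference path; long runs
#' go through the compiled engines in [run_classical()] / [run_operant()].
#'
#' @param network An `rchp_network`.
#' @param active Character vector of input-group labels currently stimulated.
#' @param feedback Optional list(winner = label, losers = labels): members of
#'   the winner output group get +input_drive added to u, members of the loser
#'   groups get -input_drive.
#' @return The network with updated \code{state$v} (and \code{state$time});
#'   the previous outputs are kept in \code{state$v_prev} for the lagged
#'   correlation product.
#' @export
step_network <- function(network, active = character(), feedback = NULL) {
  p <- network$params
  st <- network$state
  n <- network$n
  # external drive first, then ordered synaptic accumulation (the compiled
  # engine uses the same order, so trajectories agree to rounding)
  u <- numeric(n)
  for (lab in active) {
    g <- network$groups[[lab]]
    if (is.null(g)) stop(sprintf("no group labelled '%s'", lab))
    u[g$members] <- u[g$members] + p$input_drive
  }
  if (!is.null(feedback)) {
    u[resolve_members(feedback$winner, network)] <-
      u[resolve_members(feedback$winner, network)] + p$input_drive
    for (lab in feedback$losers)
      u[resolve_members(lab, network)] <-
        u[resolve_members(lab, network)] - p$input_drive
  }
  contrib <- network$w * (st$v[network$pre] * network$kappa[network$pre])
  for (s in seq_along(contrib))
    u[network$post[s]] <- u[network$post[s]] + contrib[s]
  xi <- stats::runif(n, -p$noise_halfwidth, p$noise_halfwidth)
  v_new <- ifelse(u >= 0, tanh(p$gain * u) + xi, xi)
  st$u <- u
  st$v_prev <- st$v
  st$v <- v_new
  st$time <- st$time + p$dt
  network$state <- st
  network
}

#' One full network + plasticity step (reference implementation)
#'
#' Composes [step_network()] with the plasticity operations in their defined
#' order: detect rare correlations on the lagged output product, update the
#' modulation with the reward input, decay traces and add events, apply the
#' modulated weight update to plastic synapses, then adapt the thresholds
#' homeostatically. The compiled engines implement exactly this sequence;
#' a test holds them to it step for step.
#'
#' @inheritParams step_network
#' @param plasticity A [plasticity_params()] object.
#' @param r Reward input r(t) for this step (held for one step).
#' @return The updated network.
#' @export
step_rchp <- function(network, plasticity, active = character(),
                      feedback = NULL, r = 0) {
  p <- network$params
  pp <- plasticity
  if (is.na(network$state$theta_hi)) {
    network$state$theta_hi <- pp$theta_hi_init
    network$state$theta_lo <- pp$theta_lo_init
  }
  network <- step_network(network, active = active, feedback = feedback)
  st <- network$state

  ev <- detect_correlations(st$v_prev, st$v, network$pre, network$post,
                            st$theta_hi, st$theta_lo,
                            alpha = pp$alpha, beta = pp$beta)
  st$m <- update_modulation(st$m, r, plasticity, p$dt)
  st$c <- update_traces(st$c, ev, pp$tau_c, p$dt)
  network$w <- apply_weight_update(network$w, network$plastic, st$m, st$c,
                                   p$dt, p$weight_min, p$weight_max)
  th <- update_thresholds(
    list(theta_hi = st$theta_hi, theta_lo = st$theta_lo,
         corr_queue = st$corr_queue, decorr_queue = st$decorr_queue),
    ev$n_corr, ev$n_decorr, length(network$w), plasticity, p$dt)
  st$theta_hi <- th$theta_hi
  st$theta_lo <- th$theta_lo
  st$corr_queue <- th$corr_queue
  st$decorr_queue <- th$decorr_queue
  network$state <- st
  network
}

#' Mean weight of the synapses connecting two groups
#'
#' The macroscopic readout of learning: the mean of W over the synapses that
#' exist from members of \code{from} to members of \code{to}. Absent synapses
#' are excluded from the mean; if no synapse exists between the groups the
#' strength is defined as 0 with a warning.
#'
#' @param network An `rchp_network` (or a recording, whose final network is
#'   then used).
#' @param from,to Group labels.
#' @return Scalar mean weight.
#' @export
pathway_strength <- function(network, from, to) {
  if (inherits(network, "rchp_recording")) network <- network$network
  if (identical(from, to)) stop("within-group pathways are not defined")
  idx <- pathway_index(network, from, to)
  if (length(idx) == 0L) {
    warning(sprintf("no synapses exist from '%s' to '%s'; strength defined as 0",
                    from, to))
    return(0)
  }
  mean(network$w[idx])
}

#' Synapse indices of a pathway
#'
#' Positions (into the network's synapse arrays) of the synapses that exist
#' from members of \code{from} to members of \code{to}.
#'
#' @param network An `rchp_network`.
#' @param from,to Group labels (or member index vectors).
#' @return Integer vector of synapse positions (possibly empty).
#' @export
pathway_index <- function(network, from, to) {
  fm <- resolve_members(from, network)
  tm <- resolve_members(to, network)
  which(network$pre %in% fm & network$post %in% tm)
}
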