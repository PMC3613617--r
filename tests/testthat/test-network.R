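test_that("parameter constructors validate their invariants", {
  expect_error(network_params(connect_prob = 1.5), "connect_prob")
  expect_error(network_params(dt = 0), "dt")
  expect_error(network_params(weight_min = 1, weight_max = 1), "weight_min")
  expect_error(plasticity_params(alpha = 0), "alpha")
  expect_error(plasticity_params(mu_target = 0), "mu_target")
  expect_error(plasticity_params(theta_lo_init = 0.1), "theta_lo")
})

test_that("degenerate connection probability gives an empty weight matrix", {
  net <- build_network(small_net_params(connect_prob = 0),
                       group_spec(inputs = "S1", outputs = "A0"), seed = 1)
  expect_identical(length(net$w), 0L)
  expect_identical(length(net$pre), 0L)
})

test_that("groups occupy distinct excitatory neurons and demand is checked", {
  p <- network_params()
  net <- build_network(p, group_spec(inputs = paste0("S", 1:9),
                                     outputs = "A0"), seed = 3)
  members <- unlist(lapply(net$groups, function(g) g$members))
  expect_length(members, 600L)                  # 10 groups x 60, disjoint
  expect_false(anyDuplicated(members) > 0L)
  expect_true(all(members <= p$n_excitatory))   # all excitatory
  expect_error(
    build_network(network_params(n_excitatory = 100L),
                  group_spec(inputs = c("a", "b"), outputs = "c")),
    "exceeds the excitatory pool")
})

test_that("input groups receive no afferents, output groups project none", {
  net <- build_network(network_params(),
                       group_spec(inputs = paste0("S", 1:9), outputs = "A0"),
                       seed = 7)
  inputs <- unlist(lapply(net$groups[1:9], function(g) g$members))
  outputs <- net$groups[["A0"]]$members
  expect_false(any(net$post %in% inputs))
  expect_false(any(net$pre %in% outputs))
  expect_false(any(net$pre == net$post))        # no self-connections
  # plasticity mask: afferents of excitatory neurons only
  expect_identical(net$plastic, net$post <= net$n_excitatory)
  # topology and fixed weights survive simulation
  pp <- plasticity_params()
  before <- list(pre = net$pre, post = net$post,
                 fixed_w = net$w[!net$plastic])
  rec <- run_classical(net, pp,
                       classical_config(total_time = 60, appear_prob = 0.02),
                       seed = 11)
  after <- rec$network
  expect_identical(after$pre, before$pre)
  expect_identical(after$post, before$post)
  expect_identical(after$w[!after$plastic], before$fixed_w)
})

test_that("between-group synapse counts match the binomial mean", {
  # two disjoint 60-neuron groups at p = 0.1: expect about 360 synapses
  counts <- vapply(1:25, function(s) {
    net <- build_network(network_params(),
                         group_spec(inputs = "S1", outputs = "A0"), seed = s)
    length(pathway_index(net, "S1", "A0"))
  }, 0L)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 360), 3 * se + 1e-9)
})

test_that("network step follows the noisy tanh rate dynamics", {
  # zero weights, no stimulus: outputs are pure noise in [-0.1, 0.1]
  net <- small_network(seed = 2)
  net$w[] <- 0
  set.seed(5)
  net0 <- step_network(net)
  expect_true(all(abs(net0$state$v) <= net0$params$noise_halfwidth))

  # one stimulated group, zero weights: members at tanh(10 gamma) +/- noise
  set.seed(6)
  net1 <- step_network(net, active = "S1")
  mem <- net1$groups[["S1"]]$members
  expect_true(all(abs(net1$state$v[mem] - tanh(10 * net1$params$gain)) <= 0.1 + 1e-12))
  expect_equal(group_activity(net1, "S1"), 1, tolerance = 0.05)

  # a single inhibitory afferent drives u negative: output is noise only
  p <- small_net_params()
  net2 <- build_network(p, group_spec(), seed = 3)
  inh <- p$n_excitatory + 1L   # an inhibitory neuron
  net2$pre <- c(inh); net2$post <- 1L
  net2$w <- 1; net2$plastic <- TRUE
  net2$state$c <- 0
  net2$state$v <- numeric(net2$n); net2$state$v[inh] <- 0.5
  set.seed(8)
  net2 <- step_network(net2)
  expect_equal(net2$state$u[1L], 0.5 * 1 * p$kappa_inhibitory)  # -2.5
  expect_true(abs(net2$state$v[1L]) <= 0.1)
})

test_that("outputs stay within the tanh-plus-noise bounds over a long run", {
  rec <- run_classical(small_network(seed = 4), plasticity_params(),
                       classical_config(n_stimuli = 2, total_time = 120, appear_prob = 0.05),
                       seed = 9)
  act <- as.matrix(rec$series[, grep("^act_", names(rec$series))])
  expect_true(all(act >= -0.1 - 1e-12 & act <= 1.1 + 1e-12))
})

test_that("group activity is the normalized sum of member outputs", {
  net <- small_network(seed = 1)
  v <- numeric(net$n)
  g <- net$groups[["S1"]]
  v[g$members] <- 1
  expect_identical(group_activity(v, g), 1)
  expect_identical(group_activity(numeric(net$n), g), 0)
  v[g$members] <- c(rep(0.5, 5), rep(0.25, 5))
  expect_equal(group_activity(v, g), 0.375)
  expect_error(group_activity(v, list(members = integer(0))), "empty")
})

test_that("identical seed and config reproduce the trajectory bit-exactly", {
  r1 <- run_classical(config = classical_config(n_stimuli = 2, total_time = 120),
                      net_params = small_net_params(), seed = 42)
  r2 <- run_classical(config = classical_config(n_stimuli = 2, total_time = 120),
                      net_params = small_net_params(), seed = 42)
  expect_identical(r1$network$w, r2$network$w)
  expect_identical(r1$series, r2$series)
})
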