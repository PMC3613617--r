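test_that("pathway strength averages existing between-group weights only", {
  net <- small_network(seed = 1)
  idx <- pathway_index(net, "S1", "A0")
  net$w[idx] <- 0.4
  expect_identical(pathway_strength(net, "S1", "A0"), 0.4)
  expect_error(pathway_strength(net, "S1", "S1"), "within-group")
  # no synapses between the groups: strength 0 with a warning
  net2 <- small_network(seed = 1)
  drop <- pathway_index(net2, "S2", "A0")
  keep <- setdiff(seq_along(net2$w), drop)
  net2$pre <- net2$pre[keep]; net2$post <- net2$post[keep]
  net2$w <- net2$w[keep]; net2$plastic <- net2$plastic[keep]
  net2$state$c <- net2$state$c[keep]
  expect_warning(s <- pathway_strength(net2, "S2", "A0"), "no synapses")
  expect_identical(s, 0)
})

test_that("fresh-network pathway strength concentrates near the init mean", {
  vals <- vapply(1:20, function(s) {
    net <- build_network(network_params(w_init_max = 0.2),
                         group_spec(inputs = "S1", outputs = "A0"), seed = s)
    pathway_strength(net, "S1", "A0")
  }, 0)
  # uniform [0, 0.2] mean 0.1, spread ~ 0.058 / sqrt(~360 synapses)
  expect_equal(mean(vals), 0.1, tolerance = 0.02)
  expect_lt(sd(vals), 3 * 0.2 / sqrt(12) / sqrt(300))
})

test_that("run summaries reproduce order statistics and verdicts", {
  recs <- lapply(1:4, function(s)
    run_classical(small_network(seed = s), plasticity_params(),
                  classical_config(n_stimuli = 2, total_time = 120,
                                   appear_prob = 0.02),
                  seed = 50 + s))
  sm <- summarize_runs(recs, bin = 60)
  expect_s3_class(sm, "rchp_run_summary")
  expect_identical(dim(sm$stats), c(2L, 2L, 5L))
  # single-run summary: median equals the run itself, zero IQR
  sm1 <- summarize_runs(recs[1], bin = 60)
  expect_identical(sm1$stats[, , "q25"], sm1$stats[, , "q75"])
  # quartiles agree with a sort-based oracle
  vals <- vapply(recs, function(r)
    r$pathways[findInterval(60, r$pathway_time), "S1->A0"], 0)
  expect_equal(unname(sm$stats[1, "S1->A0", "median"]), sort_quantile(vals, 0.5))
  expect_equal(unname(sm$stats[1, "S1->A0", "q25"]), sort_quantile(vals, 0.25))
  expect_equal(unname(sm$stats[1, "S1->A0", "q75"]), sort_quantile(vals, 0.75))
  expect_identical(unname(sm$stats[1, "S1->A0", "min"]), min(vals))
  # verdict bookkeeping
  expect_identical(nrow(sm$verdicts), 4L)
  expect_type(sm$verdicts$cs_dominant, "logical")
  expect_error(summarize_runs(list()), "no recordings")
})

test_that("learned-at times implement the correct-thereafter criterion", {
  rec <- list(trials = data.frame(
    color = c(1, 1, 1, 1, 2, 2, 2),
    time = c(0, 100, 200, 300, 50, 150, 250),
    chosen = c(2L, 1L, 1L, 1L, 9L, 9L, 9L),
    correct = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  lt <- learning_times(rec)
  expect_identical(unname(lt["color1"]), 100)
  expect_identical(unname(lt["color2"]), Inf)
  expect_identical(attr(lt, "overall"), Inf)
})
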