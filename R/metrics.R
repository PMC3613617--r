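#' Summarize a set of recordings over time bins
#'
#' For every time bin (3 minutes by default) and pathway, the box-plot
#' statistics across runs (median, quartiles, extremes) of the pathway
#' strength sampled at the bin end, plus per-run verdicts: CS dominance for
#' classical runs, per-color learned-at times for operant runs.
#'
#' @param recordings List of `rchp_recording` objects sharing a configuration.
#' @param bin Bin width, seconds.
#' @return An object of class \code{rchp_run_summary}: \code{stats}, an array
#'   (bins x pathways x 5) of median/q25/q75/min/max, and \code{verdicts},
#'   one row per run.
#' @export
summarize_runs <- function(recordings, bin = 180) {
  if (length(recordings) == 0L) stop("no recordings given")
  if (!all(vapply(recordings, inherits, TRUE, "rchp_recording")))
    stop("all elements must be rchp_recording objects")
  type <- recordings[[1L]]$type
  pnames <- colnames(recordings[[1L]]$pathways)
  for (r in recordings)
    if (!identical(colnames(r$pathways), pnames))
      stop("recordings do not share a pathway layout")

  horizon <- min(vapply(recordings, function(r) max(r$pathway_time), 0))
  bin_ends <- seq(bin, horizon, by = bin)
  nb <- length(bin_ends)
  np <- length(pnames)
  nr <- length(recordings)
  vals <- array(NA_real_, c(nb, np, nr))
  for (ri in seq_len(nr)) {
    r <- recordings[[ri]]
    at <- findInterval(bin_ends, r$pathway_time)
    at[at < 1L] <- 1L
    vals[, , ri] <- r$pathways[at, , drop = FALSE]
  }
  stats_arr <- array(NA_real_, c(nb, np, 5L),
                     dimnames = list(NULL, pnames,
                                     c("median", "q25", "q75", "min", "max")))
  for (b in seq_len(nb)) {
    for (p in seq_len(np)) {
      x <- vals[b, p, ]
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      stats_arr[b, p, ] <- c(q[2L], q[1L], q[3L], min(x), max(x))
    }
  }

  verdicts <- if (type == "classical") {
    data.frame(
      run = seq_len(nr),
      seed = vapply(recordings, function(r) as.numeric(r$seed %||% NA_real_), 0),
      cs_dominant = vapply(recordings, cs_dominant, TRUE),
      cs_final = vapply(recordings, function(r)
        unname(r$final$pathway_strength[paste0(r$cs_label, "->", r$out_label)]), 0),
      max_disturber = vapply(recordings, function(r) {
        fs <- r$final$pathway_strength
        max(fs[setdiff(names(fs), paste0(r$cs_label, "->", r$out_label))])
      }, 0))
  } else {
    lt <- lapply(recordings, learning_times)
    data.frame(
      run = seq_len(nr),
      seed = vapply(recordings, function(r) as.numeric(r$seed %||% NA_real_), 0),
      all_learned = vapply(lt, function(x) all(is.finite(x)), TRUE),
      learned_at = vapply(lt, function(x) attr(x, "overall"), 0))
  }
  structure(list(type = type, bin = bin, time = bin_ends, pathways = pnames,
                 stats = stats_arr, verdicts = verdicts, n_runs = nr),
            class = "rchp_run_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rchp_run_summary <- function(x, ...) {
  cat(sprintf("rchp run summary: %d %s runs, %d bins of %g s\n",
              x$n_runs, x$type, length(x$time), x$bin))
  if (x$type == "classical") {
    cat(sprintf("  CS pathway dominant in %d/%d runs (final CS strength median %.3f, max disturber median %.3f)\n",
                sum(x$verdicts$cs_dominant), x$n_runs,
                stats::median(x$verdicts$cs_final),
                stats::median(x$verdicts$max_disturber)))
  } else {
    fin <- x$verdicts$learned_at[is.finite(x$verdicts$learned_at)]
    cat(sprintf("  all associations learned in %d/%d runs%s\n",
                sum(x$verdicts$all_learned), x$n_runs,
                if (length(fin)) sprintf("; learned-at max %.1f min", max(fin) / 60)
                else ""))
  }
  invisible(x)
}

#' Segment a behavior-reversal run into its four phases
#'
#' Detects the trajectory exploit-old -> weight convergence ->
#' re-exploration -> exploit-new from the trial record and the pathway
#' series of the reversed color: the old action is exploited up to the
#' policy switch; punishments then drive the efferent pathway strengths of
#' the color toward each other until their spread drops below
#' \code{conv_spread}; choices vary while no pathway dominates; finally the
#' newly rewarded action is chosen on every remaining trial.
#'
#' @param recording A recording from [run_reversal()].
#' @param conv_spread Pathway-strength spread (max - min) below which the
#'   weights count as converged.
#' @return List with the switch time, one \code{c(start, end)} interval per
#'   phase (NA bounds when a phase is not found), the distinct actions chosen
#'   during re-exploration, and \code{detected}: TRUE when all four phases
#'   are present in order.
#' @export
segment_reversal_phases <- function(recording, conv_spread = 0.2) {
  policy <- recording$policy
  if (is.null(policy) || is.null(policy$reversal))
    stop("recording does not come from a reversal run")
  rv <- policy$reversal
  old_action <- policy$mapping[rv$stimulus]
  new_action <- rv$new_action
  tr <- recording$trials
  tr <- tr[tr$color == rv$stimulus & !is.na(tr$chosen), , drop = FALSE]
  pre <- tr[tr$time < rv$time, , drop = FALSE]
  post <- tr[tr$time >= rv$time, , drop = FALSE]

  # exploit-old: trailing pre-switch streak of old-action choices
  t_old <- NA_real_
  if (nrow(pre)) {
    ok <- rev(cumprod(rev(pre$chosen == old_action))) == 1
    if (any(ok) && sum(ok) >= 2L) t_old <- pre$time[which(ok)[1L]]
  }

  # convergence: spread of the color's efferent pathways falls below threshold
  stim_lab <- tr$stimulus[1L]
  cols <- grep(paste0("^", stim_lab, "->"), colnames(recording$pathways))
  pt <- recording$pathway_time
  spread <- apply(recording$pathways[, cols, drop = FALSE], 1L, function(x)
    max(x) - min(x))
  conv_at <- pt[pt >= rv$time & spread < conv_spread]
  t_conv <- if (length(conv_at)) conv_at[1L] else NA_real_

  # exploit-new: trailing post-switch streak of new-action choices (>= 2)
  t_new <- NA_real_
  if (nrow(post)) {
    ok <- rev(cumprod(rev(post$chosen == new_action))) == 1
    if (any(ok) && sum(ok) >= 2L) t_new <- post$time[which(ok)[1L]]
  }

  explore_tr <- if (!is.na(t_conv) && !is.na(t_new))
    post[post$time >= t_conv & post$time < t_new, , drop = FALSE]
  else post[0L, , drop = FALSE]
  horizon <- recording$nsteps * recording$dt
  detected <- !is.na(t_old) && !is.na(t_conv) && !is.na(t_new) &&
    t_old < rv$time && rv$time <= t_conv && t_conv <= t_new
  list(switch = rv$time,
       exploit_old = c(t_old, rv$time),
       converge = c(rv$time, t_conv),
       explore = c(t_conv, t_new),
       exploit_new = c(t_new, horizon),
       explore_actions = sort(unique(explore_tr$chosen)),
       detected = detected)
}
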