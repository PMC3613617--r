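# Assemble an rchp_recording from an engine result. Scalar series are kept
# per step; pathway strengths at the (coarser) pathway sampling times.
new_recording <- function(type, network, plasticity, config, seed, nsteps, dt,
                          engine_out, pathway_names, group_labels,
                          schedule = NULL, cs_label = NA_character_,
                          out_label = NA_character_) {
  act <- t(engine_out$activity)
  colnames(act) <- paste0("act_", group_labels)
  series <- data.frame(
    time = seq_len(nsteps) * dt,
    m = engine_out$m,
    theta_hi = engine_out$theta_hi,
    theta_lo = engine_out$theta_lo,
    corr_rate_pct = engine_out$corr_rate * 100,    # %/s of synapses
    decorr_rate_pct = engine_out$decorr_rate * 100)
  series <- cbind(series, as.data.frame(act))
  pathways <- t(engine_out$pathways)
  colnames(pathways) <- pathway_names
  final_strength <- pathways[nrow(pathways), ]
  names(final_strength) <- pathway_names

  structure(list(
    type = type,
    seed = seed,
    dt = dt,
    nsteps = nsteps,
    config = config,
    plasticity = plasticity,
    net_params = network$params,
    cs_label = cs_label,
    out_label = out_label,
    series = series,
    pathways = pathways,
    pathway_time = as.numeric(engine_out$pathway_time),
    schedule = schedule,
    trials = NULL,
    events = NULL,
    final = list(pathway_strength = final_strength,
                 m = network$state$m,
                 theta_hi = network$state$theta_hi,
                 theta_lo = network$state$theta_lo,
                 time = network$state$time),
    network = network,
    meta = list(package = "rchp",
                version = as.character(utils::packageVersion("rchp")),
                seed = seed,
                config_hash = hash_config(list(config = unclass(config),
                                               plasticity = unclass(plasticity),
                                               net = unclass(network$params))))
  ), class = "rchp_recording")
}

# md5 of the canonical JSON serialization; stamps outputs for reproducibility
hash_config <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

#' @export
print.rchp_recording <- function(x, ...) {
  cat(sprintf("rchp %s recording: %.1f min simulated (%d steps of %g s), seed %s\n",
              x$type, x$nsteps * x$dt / 60, x$nsteps, x$dt,
              ifelse(is.null(x$seed), "unset", x$seed)))
  fs <- sort(x$final$pathway_strength, decreasing = TRUE)
  k <- min(5L, length(fs))
  cat("  strongest pathways:",
      paste(sprintf("%s = %.3f", names(fs)[seq_len(k)], fs[seq_len(k)]),
            collapse = ", "), "\n")
  if (!is.null(x$trials))
    cat(sprintf("  trials: %d, correct: %d\n", nrow(x$trials),
                sum(x$trials$correct, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.rchp_recording <- function(object, ...) {
  x <- object
  cat(sprintf("== rchp %s recording ==\n", x$type))
  print(x)
  cat(sprintf("  final m = %.4g, theta_hi = %.4g, theta_lo = %.4g\n",
              x$final$m, x$final$theta_hi, x$final$theta_lo))
  cat(sprintf("  mean correlation rate %.3f %%/s (last half of run)\n",
              mean(x$series$corr_rate_pct[(x$nsteps %/% 2):x$nsteps])))
  if (x$type == "classical") {
    cat(sprintf("  CS pathway %s->%s dominant: %s\n", x$cs_label, x$out_label,
                cs_dominant(x)))
    cat(sprintf("  conditioned responses: %d\n", nrow(conditioned_responses(x))))
  }
  if (!is.null(x$trials)) {
    lt <- learning_times(x)
    cat(sprintf("  learned-at times (s): %s; overall %.0f s\n",
                paste(sprintf("%s=%.0f", names(lt), lt), collapse = ", "),
                attr(lt, "overall")))
  }
  invisible(x)
}

#' Plot a recording
#'
#' Three stacked panels: pathway strengths over time, the modulation signal,
#' and the output-group activity (classical) or per-trial reward (operant).
#'
#' @param x An `rchp_recording`.
#' @param ... Unused.
#' @export
plot.rchp_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tmin <- x$pathway_time / 60
  graphics::matplot(tmin, x$pathways, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(x$pathways), "Dark 3"),
                    xlab = "", ylab = "pathway strength",
                    main = sprintf("%s run", x$type))
  if (x$type == "classical") {
    cs <- paste0(x$cs_label, "->", x$out_label)
    graphics::lines(tmin, x$pathways[, cs], lwd = 2.5)
  }
  graphics::plot(x$series$time / 60, x$series$m, type = "l",
                 xlab = "", ylab = "modulation m")
  graphics::abline(h = 0, lty = 3)
  if (x$type == "classical") {
    graphics::plot(x$series$time / 60, x$series[[paste0("act_", x$out_label)]],
                   type = "l", xlab = "time (min)", ylab = "output activity")
    graphics::abline(h = x$config$response_threshold, lty = 3)
  } else if (!is.null(x$trials)) {
    graphics::plot(x$trials$time / 60, x$trials$reward, type = "h",
                   xlab = "time (min)", ylab = "trial reward")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
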