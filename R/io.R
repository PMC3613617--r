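# format numeric columns so doubles survive a CSV round trip bit-exactly
full_precision <- function(df) {
  for (k in seq_along(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
  df
}

#' Write a recording to a directory of plain-text files
#'
#' Scalar series and pathway strengths go to CSV, the event log to JSON-lines,
#' trials (operant) to CSV, and a summary (type, seed, config hash, final
#' pathway strengths, verdicts) to JSON. The summary is written with
#' full-precision numbers so identical runs produce byte-identical files.
#'
#' @param recording An `rchp_recording`.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(full_precision(recording$series),
                   file.path(dir, "series.csv"), row.names = FALSE)
  pw <- data.frame(time = recording$pathway_time,
                   recording$pathways, check.names = FALSE)
  utils::write.csv(full_precision(pw), file.path(dir, "pathways.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "events.jsonl"), "w")
  jsonlite::stream_out(recording$events, con, verbose = FALSE)
  close(con)
  if (!is.null(recording$trials))
    utils::write.csv(recording$trials, file.path(dir, "trials.csv"),
                     row.names = FALSE)
  if (!is.null(recording$schedule)) {
    utils::write.csv(recording$schedule$stimuli,
                     file.path(dir, "schedule_stimuli.csv"), row.names = FALSE)
    utils::write.csv(recording$schedule$rewards,
                     file.path(dir, "schedule_rewards.csv"), row.names = FALSE)
  }
  summary <- list(
    type = recording$type,
    seed = recording$seed,
    dt = recording$dt,
    nsteps = recording$nsteps,
    meta = recording$meta,
    final_pathway_strength = as.list(recording$final$pathway_strength),
    final_m = recording$final$m,
    final_theta_hi = recording$final$theta_hi,
    final_theta_lo = recording$final$theta_lo)
  if (recording$type == "classical") {
    summary$cs_pathway <- paste0(recording$cs_label, "->", recording$out_label)
    summary$cs_dominant <- cs_dominant(recording)
    summary$n_conditioned_responses <- nrow(conditioned_responses(recording))
  }
  if (!is.null(recording$trials)) {
    lt <- learning_times(recording)
    summary$learned_at <- as.list(lt)
    summary$learned_at_overall <- attr(lt, "overall")
    summary$n_trials <- nrow(recording$trials)
    summary$n_correct <- sum(recording$trials$correct, na.rm = TRUE)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' Reconstructs the series, pathways, events, trials, schedule and summary
#' (the simulated network itself is stored separately; see
#' [write_network()]).
#'
#' @param dir Directory written by [write_recording()].
#' @return A list of class \code{rchp_recording_files}.
#' @export
read_recording <- function(dir) {
  summary <- jsonlite::read_json(file.path(dir, "summary.json"),
                                 simplifyVector = TRUE)
  series <- utils::read.csv(file.path(dir, "series.csv"), check.names = FALSE)
  pw <- utils::read.csv(file.path(dir, "pathways.csv"), check.names = FALSE)
  events <- jsonlite::stream_in(file(file.path(dir, "events.jsonl")),
                                verbose = FALSE)
  out <- list(type = summary$type, summary = summary, series = series,
              pathway_time = pw$time,
              pathways = as.matrix(pw[, -1L, drop = FALSE]),
              events = events)
  tf <- file.path(dir, "trials.csv")
  if (file.exists(tf)) out$trials <- utils::read.csv(tf)
  sf <- file.path(dir, "schedule_stimuli.csv")
  if (file.exists(sf))
    out$schedule <- list(
      stimuli = utils::read.csv(sf),
      rewards = utils::read.csv(file.path(dir, "schedule_rewards.csv")))
  structure(out, class = "rchp_recording_files")
}

#' Serialize a network (weights, traces, thresholds) to plain-text files
#'
#' Synapses (pre, post, weight, plastic flag, trace) and neurons (kappa,
#' output) go to CSV; groups, parameters and the scalar state (modulation,
#' thresholds, event queues, time) to JSON. A network restored with
#' [read_network()] resumes a run bit-exactly given the same RNG state.
#'
#' @param network An `rchp_network`.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    full_precision(data.frame(pre = network$pre, post = network$post,
                              w = network$w, plastic = network$plastic,
                              trace = network$state$c)),
    file.path(dir, "synapses.csv"), row.names = FALSE)
  utils::write.csv(
    full_precision(data.frame(neuron = seq_len(network$n),
                              kappa = network$kappa, v = network$state$v)),
    file.path(dir, "neurons.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(network$groups, function(g)
      list(label = g$label, role = g$role, members = g$members)),
    file.path(dir, "groups.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(network$params), file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  st <- network$state
  jsonlite::write_json(
    list(m = st$m, theta_hi = st$theta_hi, theta_lo = st$theta_lo,
         corr_queue = st$corr_queue, decorr_queue = st$decorr_queue,
         time = st$time),
    file.path(dir, "state.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Restore a network written by [write_network()]
#'
#' @param dir Directory written by [write_network()].
#' @return An `rchp_network`.
#' @export
read_network <- function(dir) {
  syn <- utils::read.csv(file.path(dir, "synapses.csv"))
  neu <- utils::read.csv(file.path(dir, "neurons.csv"))
  grs <- jsonlite::read_json(file.path(dir, "groups.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pars <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  st <- jsonlite::read_json(file.path(dir, "state.json"),
                            simplifyVector = TRUE)
  params <- do.call(network_params, pars)
  groups <- lapply(grs, function(g)
    list(label = g$label, role = g$role, members = as.integer(unlist(g$members))))
  names(groups) <- vapply(groups, function(g) g$label, "")
  structure(list(
    params = params,
    n = nrow(neu),
    n_excitatory = params$n_excitatory,
    n_inhibitory = params$n_inhibitory,
    pre = as.integer(syn$pre), post = as.integer(syn$post),
    w = as.numeric(syn$w), plastic = as.logical(syn$plastic),
    kappa = as.numeric(neu$kappa),
    groups = groups,
    state = list(v = as.numeric(neu$v), c = as.numeric(syn$trace), m = st$m,
                 theta_hi = st$theta_hi %||% NA_real_,
                 theta_lo = st$theta_lo %||% NA_real_,
                 corr_queue = as.numeric(unlist(st$corr_queue)),
                 decorr_queue = as.numeric(unlist(st$decorr_queue)),
                 time = st$time)
  ), class = "rchp_network")
}

#' Read a scenario configuration from a YAML file
#'
#' Sections \code{network}, \code{plasticity}, \code{classical},
#' \code{operant} and \code{toy} override the package defaults; omitted
#' fields keep their default values.
#'
#' @param path YAML file path.
#' @return List with elements \code{network} ([network_params()]),
#'   \code{plasticity} ([plasticity_params()]), \code{classical}
#'   ([classical_config()]), \code{operant} ([operant_config()]) and
#'   \code{toy} ([toy_config()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    args <- y[[section]]
    if (is.null(args)) args <- list()
    do.call(ctor, args)
  }
  list(network = build(network_params, "network"),
       plasticity = build(plasticity_params, "plasticity"),
       classical = build(classical_config, "classical"),
       operant = build(operant_config, "operant"),
       toy = build(toy_config, "toy"))
}
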