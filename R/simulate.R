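#' @keywords internal
.STATES <- c("U", "NP", "PS", "WW", "LLWW", "RS", "PROD")

# amplitude class of each kinetic state; PROD depends on site orientation
.state_class <- function(states, orientation) {
  cls <- c(U = "high", NP = "mid", PS = "mid",
           WW = "low", LLWW = "low", RS = "low",
           PROD = if (orientation == "head_to_tail") "low" else "high")
  unname(cls[states])
}

# per-molecule seed derivation: deterministic, order-independent counter
# scheme (stream 1 = trajectory, stream 2 = rendering, ...)
.derive_seed <- function(master, molecule, stream = 1L) {
  as.integer((as.numeric(master) * 48271 + molecule * 7919 + stream * 104729) %%
               2147483647)
}

#' Simulate one state trajectory (exact Gillespie realization)
#'
#' Draws an exact continuous-time Markov-chain path of the recombination
#' pathway: from `U`, binding partitions into the non-productive (`NP`) or
#' pre-synaptic (`PS`) channel with pseudo-first-order rates
#' `k_NPf * [E]` and `k_PSf * [E]`; `NP` dissociates back to `U` at `k_NPd`;
#' `PS` commits to a recombinogenic (`RS`, rate `k_RSf`), wayward (`WW`,
#' `k_WWf`) or long-lived wayward (`LLWW`, `k_star_WWf`) synapse; wayward
#' synapses decay (`k_WWd` / `k_star_WWd`) back to `PS` with probability
#' `p_ww_to_ps`, otherwise to `U`; `RS` completes strand exchange to the
#' absorbing `PROD` at `k_REC` or reverses the Holliday junction to `PS` at
#' `k_REV`. Simulation stops at `config$duration` or upon absorption.
#'
#' @param scheme a [kinetic_scheme]
#' @param config an [experiment_config]
#' @param seed integer seed; the trajectory is deterministic given the seed
#' @return an object of class `state_trajectory`: a list with `states`
#'   (character), `entry_times` (seconds, strictly increasing, first `(U, 0)`),
#'   `end_time`, and `absorbed` (logical)
#' @export
simulate_trajectory <- function(scheme, config, seed = config$seed) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(config, "experiment_config"))
  set.seed(seed)
  E <- config$enzyme_concentration
  # outgoing channels per state: target states and rates
  channels <- function(s) {
    switch(s,
      U    = list(to = c("NP", "PS"),
                  rate = c(scheme$k_NPf * E, scheme$k_PSf * E)),
      NP   = list(to = "U", rate = scheme$k_NPd),
      PS   = list(to = c("RS", "WW", "LLWW"),
                  rate = c(scheme$k_RSf, scheme$k_WWf, scheme$k_star_WWf)),
      WW   = list(to = c("PS", "U"),
                  rate = scheme$k_WWd * c(scheme$p_ww_to_ps,
                                          1 - scheme$p_ww_to_ps)),
      LLWW = list(to = c("PS", "U"),
                  rate = scheme$k_star_WWd * c(scheme$p_ww_to_ps,
                                               1 - scheme$p_ww_to_ps)),
      RS   = list(to = c("PROD", "PS"),
                  rate = c(scheme$k_REC, scheme$k_REV)),
      PROD = list(to = character(0), rate = numeric(0)))
  }
  states <- "U"; times <- 0
  cur <- "U"; t <- 0; absorbed <- FALSE
  repeat {
    ch <- channels(cur)
    total <- sum(ch$rate)
    if (total <= 0) { absorbed <- cur == "PROD"; break }
    t <- t + stats::rexp(1L, rate = total)
    if (t >= config$duration) break
    cur <- if (length(ch$to) == 1L) ch$to else
      sample(ch$to, 1L, prob = ch$rate / total)
    states <- c(states, cur); times <- c(times, t)
  }
  structure(list(states = states, entry_times = times,
                 end_time = config$duration, absorbed = absorbed),
            class = "state_trajectory")
}

# state occupied at each query time (vectorized)
.state_at <- function(trajectory, t) {
  idx <- findInterval(t, trajectory$entry_times)
  trajectory$states[pmax(idx, 1L)]
}

#' Render a trajectory as a noisy BM-amplitude time trace
#'
#' Each frame emits the amplitude of the class of the occupied state
#' (high / intermediate-high / low, see [emission_model]) plus a fixed
#' per-molecule offset and per-frame Gaussian noise. The number of frames is
#' `floor(duration / frame_interval)`; frame `j` samples the state at time
#' `(j - 1) * frame_interval`. Amplitudes are floored at a small positive
#' value so they remain physical.
#'
#' @param trajectory a `state_trajectory`
#' @param emission an [emission_model]
#' @param config an [experiment_config]
#' @param seed integer seed
#' @param molecule_id identifier carried into the trace
#' @return an object of class `time_trace`: list with `molecule_id`, `time_s`,
#'   `amplitude_nm`, `quench_time`, and `post_sds` (`NA` until [apply_sds] is
#'   consulted by the ensemble driver)
#' @export
render_trace <- function(trajectory, emission, config, seed = config$seed,
                         molecule_id = 1L) {
  stopifnot(inherits(trajectory, "state_trajectory"),
            inherits(emission, "emission_model"),
            inherits(config, "experiment_config"))
  set.seed(seed)
  n <- floor(config$duration / config$frame_interval)
  tt <- (seq_len(n) - 1L) * config$frame_interval
  cls <- .state_class(.state_at(trajectory, tt), config$orientation)
  mu <- c(high = emission$mean_high, mid = emission$mean_mid,
          low = emission$mean_low)[cls]
  offset <- stats::rnorm(1L, 0, emission$sd_molecule)
  amp <- mu + offset + stats::rnorm(n, 0, emission$sd_frame)
  amp <- pmax(amp, 0.1)
  structure(list(molecule_id = molecule_id, time_s = tt,
                 amplitude_nm = unname(amp),
                 quench_time = config$duration, post_sds = NA_character_),
            class = "time_trace")
}

#' SDS-challenge readout of a terminated trajectory
#'
#' SDS strips protein from DNA. Molecules whose final state involves no
#' covalent strand exchange (`U`, `NP`, `PS`, `WW`, `LLWW`) return to the
#' high substrate amplitude. A recombinogenic synapse at the quench is read
#' as a trapped Holliday junction and stays low for either site orientation.
#' A completed product stays low for head-to-tail sites (excision shortens
#' the tether) but reads high for head-to-head sites, where the inversion
#' product has the same length as the substrate.
#'
#' @param trajectory a `state_trajectory` that ran to its quench time
#' @param orientation `"head_to_tail"` or `"head_to_head"`
#' @return `"low"` or `"high"`
#' @export
apply_sds <- function(trajectory,
                      orientation = c("head_to_tail", "head_to_head")) {
  orientation <- match.arg(orientation)
  if (!inherits(trajectory, "state_trajectory") ||
      is.null(trajectory$end_time))
    stop("trajectory has not been terminated at a quench time", call. = FALSE)
  final <- trajectory$states[length(trajectory$states)]
  if (final == "RS") return("low")
  if (final == "PROD")
    return(if (orientation == "head_to_tail") "low" else "high")
  "high"
}

#' Simulate an ensemble of molecules
#'
#' Runs `n_molecules` independent trajectory + rendering + SDS-readout
#' replicates. Per-molecule seeds are derived from the master seed by a
#' fixed counter scheme, so any molecule can be regenerated independently
#' and the ensemble is reproducible given `(seed, n_molecules)`.
#'
#' @inheritParams simulate_trajectory
#' @param emission an [emission_model]
#' @param n_molecules number of molecules (>= 1)
#' @param seed master seed
#' @return an object of class `tpm_ensemble`: list with `trajectories`,
#'   `traces`, `post_sds` (character vector), `scheme`, `emission`, `config`
#' @export
simulate_ensemble <- function(scheme, emission, config, n_molecules,
                              seed = config$seed) {
  if (!is.numeric(n_molecules) || n_molecules < 1)
    stop("n_molecules must be >= 1", call. = FALSE)
  n_molecules <- as.integer(n_molecules)
  trajectories <- vector("list", n_molecules)
  traces <- vector("list", n_molecules)
  post <- character(n_molecules)
  for (i in seq_len(n_molecules)) {
    trj <- simulate_trajectory(scheme, config, seed = .derive_seed(seed, i, 1L))
    trc <- render_trace(trj, emission, config,
                        seed = .derive_seed(seed, i, 2L), molecule_id = i)
    trc$post_sds <- apply_sds(trj, config$orientation)
    trajectories[[i]] <- trj
    traces[[i]] <- trc
    post[i] <- trc$post_sds
  }
  structure(list(trajectories = trajectories, traces = traces,
                 post_sds = post, scheme = scheme, emission = emission,
                 config = config, seed = as.integer(seed)),
            class = "tpm_ensemble")
}

#' Write / read an ensemble's traces
#'
#' Traces are stored as one tab-separated file (`molecule_id`, `time_s`,
#' `amplitude_nm`) plus a JSON sidecar holding the configuration, quench
#' time, post-SDS classes and — for synthetic data — the ground-truth
#' trajectories. The analysis pipeline never reads the ground truth except
#' in validation mode.
#'
#' @param ensemble a `tpm_ensemble`
#' @param path basename for output; writes `<path>.tsv` and `<path>.json`
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns a list with `traces` and `meta`
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "tpm_ensemble"))
  tab <- do.call(rbind, lapply(ensemble$traces, function(tr)
    data.frame(molecule_id = tr$molecule_id, time_s = tr$time_s,
               amplitude_nm = round(tr$amplitude_nm, 3))))
  utils::write.table(tab, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(
    config = unclass(ensemble$config),
    emission = unclass(ensemble$emission),
    scheme = unclass(ensemble$scheme),
    seed = ensemble$seed,
    quench_time = ensemble$config$duration,
    post_sds = as.list(stats::setNames(ensemble$post_sds,
                                       vapply(ensemble$traces,
                                              function(tr) as.character(tr$molecule_id),
                                              character(1)))),
    ground_truth = lapply(ensemble$trajectories, function(trj)
      list(states = trj$states, entry_times = trj$entry_times,
           absorbed = trj$absorbed)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ensemble
#' @param use_ground_truth read the ground-truth trajectories from the
#'   sidecar (validation mode only)
#' @export
read_ensemble <- function(path, use_ground_truth = FALSE) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  if (!file.exists(tsv)) stop("trace file not found: ", tsv, call. = FALSE)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  if (nrow(tab) == 0L) stop("empty trace file: ", tsv, call. = FALSE)
  meta <- if (file.exists(js))
    jsonlite::read_json(js, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else NULL
  if (!isTRUE(use_ground_truth) && !is.null(meta)) meta$ground_truth <- NULL
  quench <- if (!is.null(meta)) meta$quench_time else max(tab$time_s)
  traces <- lapply(split(tab, tab$molecule_id), function(d) {
    d <- d[order(d$time_s), ]
    id <- d$molecule_id[1]
    ps <- NA_character_
    if (!is.null(meta) && !is.null(meta$post_sds[[as.character(id)]]))
      ps <- meta$post_sds[[as.character(id)]]
    structure(list(molecule_id = id, time_s = d$time_s,
                   amplitude_nm = d$amplitude_nm, quench_time = quench,
                   post_sds = ps),
              class = "time_trace")
  })
  names(traces) <- NULL
  list(traces = traces, meta = meta)
}
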