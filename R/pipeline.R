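#' Assemble a run configuration
#'
#' Bundles a protein preset (or explicit scheme) with the experiment,
#' emission, segmentation and fit parameters driving an end-to-end run.
#' Every field has the documented default, so a run is reproducible from
#' the configuration and the seed alone.
#'
#' @param preset protein preset name (see [preset_names]); ignored when
#'   `scheme` is supplied
#' @param scheme explicit [kinetic_scheme] (optional)
#' @param enzyme_concentration molar; defaults to the preset's assay value
#' @param n_molecules ensemble size
#' @param duration,orientation,frame_interval see [experiment_config]
#' @param emission an [emission_model]
#' @param min_dwell,band segmentation parameters, see [segment_trace]
#' @param seed master seed
#' @return an object of class `run_config`
#' @export
run_config <- function(preset = "Cre", scheme = NULL,
                       enzyme_concentration = NULL, n_molecules = 100L,
                       duration = 1800, orientation = "head_to_tail",
                       frame_interval = 0.1,
                       emission = emission_model(),
                       min_dwell = 2, band = 2, seed = 1L) {
  if (is.null(scheme)) {
    ps <- preset_scheme(preset)
    scheme <- ps$scheme
    if (is.null(enzyme_concentration))
      enzyme_concentration <- ps$enzyme_concentration
  } else if (is.null(enzyme_concentration)) {
    stop("an explicit scheme needs an explicit enzyme_concentration",
         call. = FALSE)
  }
  cfg <- experiment_config(enzyme_concentration = enzyme_concentration,
                           duration = duration, orientation = orientation,
                           frame_interval = frame_interval, seed = seed)
  structure(list(preset = if (is.null(scheme$name)) preset else scheme$name,
                 scheme = scheme, config = cfg, emission = emission,
                 n_molecules = as.integer(n_molecules),
                 min_dwell = min_dwell, band = band, seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate an ensemble and write trace files
#'
#' @param rc a [run_config]
#' @param out_prefix basename for the `.tsv` trace file and `.json` sidecar
#' @param quiet suppress the run log
#' @return the `tpm_ensemble`, invisibly
#' @export
run_simulate <- function(rc, out_prefix, quiet = FALSE) {
  stopifnot(inherits(rc, "run_config"))
  en <- simulate_ensemble(rc$scheme, rc$emission, rc$config,
                          n_molecules = rc$n_molecules, seed = rc$seed)
  write_ensemble(en, out_prefix)
  if (!quiet) {
    message(sprintf("simulated %d molecules, preset '%s', seed %d",
                    rc$n_molecules, rc$preset, rc$seed))
    message(sprintf("  [E] = %g M, duration %g s, frame %g s, %s",
                    rc$config$enzyme_concentration, rc$config$duration,
                    rc$config$frame_interval, rc$config$orientation))
    message(sprintf("  wrote %s.tsv / %s.json", out_prefix, out_prefix))
  }
  invisible(en)
}

#' Analyze an ensemble end to end
#'
#' Segments every trace, classifies molecules, builds the complex census,
#' extracts low-state dwells and fits them with single- and two-component
#' models (binned least squares and unbinned MLE) including model
#' selection, and summarizes synapse amplitudes. The ground-truth sidecar
#' is never consulted.
#'
#' @param traces list of `time_trace` (e.g. from [read_ensemble] or a
#'   `tpm_ensemble`'s `$traces`)
#' @param rc the [run_config] describing segmentation/fit parameters and
#'   orientation (concentration is needed to report second-order binding
#'   constants)
#' @param long_lived_cutoff see [classify_molecule]
#' @return an object of class `tpm_analysis`: list with `segmentations`,
#'   `labels`, `census`, `dwells` (low state), `fits` (binned/MLE, 1 and 2
#'   components where estimable), `selection`, `binding` (pseudo-first and
#'   second-order association constants), `amplitudes`
#' @export
run_analyze <- function(traces, rc, long_lived_cutoff = Inf) {
  if (inherits(traces, "tpm_ensemble")) traces <- traces$traces
  stopifnot(length(traces) >= 1L, inherits(rc, "run_config"))
  thr <- default_thresholds(rc$emission)
  segs <- lapply(traces, segment_trace, thresholds = thr,
                 min_dwell = rc$min_dwell, band = rc$band,
                 emission = rc$emission)
  have_sds <- !vapply(segs, function(sg) is.na(sg$post_sds), logical(1))
  labels <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    labels[[i]] <- if (have_sds[i])
      classify_molecule(segs[[i]], orientation = rc$config$orientation,
                        long_lived_cutoff = long_lived_cutoff)
    else {
      if (i == 1L)
        warning("post-SDS metadata missing; recombinogenic calls suppressed",
                call. = FALSE)
      classify_molecule(segs[[i]], post_sds = "high",
                        orientation = rc$config$orientation,
                        long_lived_cutoff = long_lived_cutoff)
    }
  }
  cen <- census(labels)

  low_dwells <- extract_dwells(segs, "low")
  fits <- list(); selection <- NULL
  if (sum(!low_dwells$censored) >= 10L) {
    fits$binned_1 <- fit_exponential_binned(low_dwells, 1L)
    fits$mle_1 <- fit_exponential_mle(low_dwells, 1L,
                                      censoring = "right_censor",
                                      min_observable = rc$min_dwell)
    fits$binned_2 <- tryCatch(fit_exponential_binned(low_dwells, 2L),
                              error = function(e) NULL)
    fits$mle_2 <- tryCatch(
      fit_exponential_mle(low_dwells, 2L, censoring = "right_censor",
                          min_observable = rc$min_dwell),
      error = function(e) NULL)
    if (!is.null(fits$mle_2))
      selection <- select_model(fits$mle_1, fits$mle_2)
  }

  # binding: waiting time from start to first departure from the high state
  first_exit <- vapply(segs, function(sg) {
    s <- sg$segments
    if (nrow(s) >= 1L && s$state_class[1] == "high" && nrow(s) > 1L)
      s$end_s[1]
    else if (s$state_class[1] != "high") NA_real_  # bound before frame 1
    else Inf                                       # never bound
  }, numeric(1))
  bind_t <- first_exit[is.finite(first_exit) & !is.na(first_exit)]
  n_cens <- sum(is.infinite(first_exit))
  binding <- NULL
  if (length(bind_t) >= 5L) {
    bd <- dwell_set(c(bind_t, rep(rc$config$duration, n_cens)),
                    c(rep(FALSE, length(bind_t)), rep(TRUE, n_cens)))
    bf <- fit_exponential_mle(bd, 1L, censoring = "right_censor")
    binding <- list(k_obs = bf$k1,
                    k_second_order = to_second_order(
                      bf$k1, rc$config$enzyme_concentration),
                    n = bf$n)
  }

  amplitudes <- list(
    high = tryCatch(amplitude_stats(segs, "high", "per_molecule"),
                    error = function(e) NULL),
    low = tryCatch(amplitude_stats(segs, "low", "per_event"),
                   error = function(e) NULL))

  structure(list(segmentations = segs, labels = labels, census = cen,
                 dwells = low_dwells, fits = fits, selection = selection,
                 binding = binding, amplitudes = amplitudes, run_config = rc),
            class = "tpm_analysis")
}

#' @export
print.tpm_analysis <- function(x, ...) {
  print(x$census)
  if (!is.null(x$binding))
    cat(sprintf("binding: k_obs = %.3g s^-1, k2nd = %.3g M^-1 s^-1 (n = %d)\n",
                x$binding$k_obs, x$binding$k_second_order, x$binding$n))
  if (!is.null(x$fits$mle_1)) {
    cat("low-state dwell fits:\n")
    print(x$fits$mle_1)
    if (!is.null(x$selection))
      cat(sprintf("model selection: %d process(es) — %s\n",
                  x$selection$choice, x$selection$rationale))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `segment`, `fit`, `census`,
#' `report` and `validate`. Invoke through the launcher installed at
#' `system.file("cli", "tpmkin.R", package = "tpmkin")`:
#' `Rscript tpmkin.R simulate --preset Cre --n 50 --seed 7 --out run1`.
#'
#' @param args character vector of command-line arguments
#' @return exit status, invisibly (0 on success)
#' @export
tpm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tpmkin <simulate|segment|fit|census|report|validate> [options]",
    "  common options: --preset NAME --n INT --seed INT --out PREFIX",
    "                  --duration S --orientation head_to_tail|head_to_head",
    "                  --traces PREFIX (analysis commands)", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 0L || i == length(rest)) default else rest[i + 1L]
  }
  preset <- opt("--preset", "Cre")
  seed <- as.integer(opt("--seed", "1"))
  n <- as.integer(opt("--n", "100"))
  out <- opt("--out", "tpmkin_run")
  duration <- as.numeric(opt("--duration", "1800"))
  orientation <- opt("--orientation", "head_to_tail")
  traces_prefix <- opt("--traces", out)

  rc <- run_config(preset = preset, n_molecules = n, duration = duration,
                   orientation = orientation, seed = seed)

  analyze_from_files <- function() {
    re <- read_ensemble(traces_prefix)
    run_analyze(re$traces, rc)
  }

  status <- 0L
  switch(cmd,
    simulate = run_simulate(rc, out),
    segment = {
      an <- analyze_from_files()
      tab <- do.call(rbind, lapply(an$segmentations, function(sg)
        cbind(molecule_id = sg$molecule_id, sg$segments)))
      utils::write.table(tab, paste0(out, "_segments.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      message("wrote ", out, "_segments.tsv")
    },
    fit = {
      an <- analyze_from_files()
      if (is.null(an$fits$mle_1)) message("too few dwells to fit")
      else { print(an$fits$mle_1); if (!is.null(an$selection))
        message("selected ", an$selection$choice, " process(es): ",
                an$selection$rationale) }
    },
    census = {
      an <- analyze_from_files()
      print(an$census)
    },
    report = {
      an <- analyze_from_files()
      print(an)
      tab <- data.frame(molecule_id = vapply(an$segmentations,
                                             function(s) s$molecule_id, numeric(1)),
                        final_call = vapply(an$labels,
                                            function(l) l$final_call, character(1)),
                        synapse = vapply(an$labels,
                                         function(l) l$synapse, character(1)))
      utils::write.table(tab, paste0(out, "_labels.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      message("wrote ", out, "_labels.tsv")
    },
    validate = {
      en <- run_simulate(rc, out, quiet = TRUE)
      an <- run_analyze(en, rc)
      acc <- frame_accuracy(en, an$segmentations)
      message(sprintf("frame-level segmentation accuracy vs ground truth: %.3f",
                      acc))
      if (!is.null(an$fits$mle_1))
        message(sprintf("low-state exit rate (1-comp MLE): %.4g s^-1",
                        an$fits$mle_1$k1))
    },
    { message("unknown command '", cmd, "'\n", usage); status <- 1L })
  invisible(status)
}

#' Frame-level segmentation accuracy against simulator ground truth
#'
#' Validation-mode helper: fraction of frames whose called amplitude class
#' matches the class of the true simulated state.
#'
#' @param ensemble a `tpm_ensemble`
#' @param segmentations matching list of `segmentation_result`
#' @return accuracy in `[0, 1]`
#' @export
frame_accuracy <- function(ensemble, segmentations) {
  stopifnot(inherits(ensemble, "tpm_ensemble"),
            length(segmentations) == length(ensemble$trajectories))
  ok <- 0; tot <- 0
  for (i in seq_along(segmentations)) {
    tr <- ensemble$traces[[i]]
    truth <- .state_class(.state_at(ensemble$trajectories[[i]], tr$time_s),
                          ensemble$config$orientation)
    s <- segmentations[[i]]$segments
    called <- s$state_class[findInterval(tr$time_s, s$start_s)]
    ok <- ok + sum(called == truth)
    tot <- tot + length(truth)
  }
  ok / tot
}
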