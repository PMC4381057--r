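# shared fixtures: everything is generated in code at test time

noiseless_emission <- function() emission_model(sd_frame = 0, sd_molecule = 0)

# hand-built trajectory (bypasses the simulator) for rendering/segmentation
make_trajectory <- function(states, entry_times, end_time = 1800,
                            absorbed = FALSE) {
  structure(list(states = states, entry_times = entry_times,
                 end_time = end_time, absorbed = absorbed),
            class = "state_trajectory")
}

# hand-built segmentation for classifier unit tests
make_segmentation <- function(classes, bounds, quench = 1800,
                              post_sds = "high", means = NULL) {
  if (is.null(means))
    means <- c(high = 81, mid = 65, low = 44)[classes]
  structure(list(
    segments = data.frame(state_class = classes,
                          start_s = bounds[-length(bounds)],
                          end_s = bounds[-1], mean_nm = unname(means),
                          stringsAsFactors = FALSE),
    molecule_id = 1L, quench_time = 1800, frame_interval = 0.1,
    post_sds = post_sds, offset_nm = 0),
    class = "segmentation_result")
}

# Independent truth-table mapping of a simulated trajectory to the complex
# taxonomy (oracle for the classifier). Works from the true state path:
# the path is sampled on the frame grid and episodes shorter than the
# observability dead time are absorbed into the preceding episode — the
# stated observability model — then the decision table is applied to the
# resulting class run sequence.
truth_final_call <- function(trj, post_sds, config, min_dwell = 2,
                             orientation = config$orientation) {
  tt <- (seq_len(floor(config$duration / config$frame_interval)) - 1L) *
    config$frame_interval
  idx <- findInterval(tt, trj$entry_times)
  states <- trj$states[pmax(idx, 1L)]
  cls_map <- c(U = "high", NP = "mid", PS = "mid", WW = "low", LLWW = "low",
               RS = "low",
               PROD = if (orientation == "head_to_tail") "low" else "high")
  cls <- unname(cls_map[states])
  r <- rle(cls)
  min_frames <- max(1L, round(min_dwell / config$frame_interval))
  conf <- r$lengths >= min_frames
  seqc <- if (any(conf)) {
    v <- r$values[conf][pmax(cumsum(conf), 1L)]
    rle(v)$values
  } else names(which.max(tapply(r$lengths, r$values, sum)))
  if (all(seqc == "high")) return("unresponsive")
  if (post_sds == "low") return("recombinogenic")
  if (any(seqc == "low")) return("wayward")
  # mid-only molecules: a censored terminal mid is a poised pre-synaptic
  # complex, which outranks completed non-productive episodes
  if (seqc[length(seqc)] == "mid") return("pre_synaptic")
  "non_productive"
}
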