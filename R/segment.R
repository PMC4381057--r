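#' Default segmentation thresholds
#'
#' Midpoints between adjacent emission means: frames above the upper cutoff
#' are `high`, below the lower cutoff `low`, otherwise `mid`.
#'
#' @param emission an [emission_model]
#' @return numeric vector `c(low_cut, high_cut)` in nm
#' @export
default_thresholds <- function(emission = emission_model()) {
  c((emission$mean_low + emission$mean_mid) / 2,
    (emission$mean_mid + emission$mean_high) / 2)
}

#' Segment a time trace into amplitude states
#'
#' Frames are classified against the two cutoffs with hysteresis: while a
#' segment of class `c` is open, a frame only counts as leaving `c` if it
#' crosses the relevant cutoff by more than `band` nm (frames exactly on a
#' threshold stay with the current segment). A candidate excursion opens a
#' new segment only if it persists for at least `min_dwell` seconds; shorter
#' excursions are merged into the flanking segment. Dwells shorter than
#' `min_dwell` are therefore unobservable by construction — downstream fits
#' must treat `min_dwell` as the minimum observable dwell.
#'
#' When an [emission_model] is supplied, the molecule's fixed amplitude
#' offset is first estimated by maximum a-posteriori profile likelihood
#' (each frame assigned to its best-fitting level, Gaussian prior with the
#' between-molecule SD) and classification runs on the offset-corrected
#' amplitudes; reported segment means remain on the raw scale, so
#' between-molecule amplitude variability stays observable downstream.
#'
#' @param trace a `time_trace`
#' @param thresholds `c(low_cut, high_cut)` nm, ordered
#' @param min_dwell minimum dwell opened as its own segment, seconds
#' @param band hysteresis half-width, nm
#' @param emission optional [emission_model] enabling per-molecule offset
#'   correction
#' @return an object of class `segmentation_result`: data frame `segments`
#'   with columns `state_class`, `start_s`, `end_s`, `mean_nm`, plus
#'   `molecule_id`, `quench_time`, `frame_interval`
#' @export
segment_trace <- function(trace, thresholds = default_thresholds(),
                          min_dwell = 2, band = 2, emission = NULL) {
  stopifnot(inherits(trace, "time_trace"), length(thresholds) == 2L)
  thresholds <- sort(as.numeric(thresholds))
  dt <- if (length(trace$time_s) > 1L) diff(trace$time_s[1:2]) else
    trace$quench_time
  if (min_dwell < dt)
    stop("min_dwell must be at least one frame interval", call. = FALSE)
  n <- length(trace$amplitude_nm)
  if (n * dt < min_dwell)
    stop("degenerate input: trace shorter than min_dwell", call. = FALSE)
  amp <- trace$amplitude_nm
  offset <- if (is.null(emission)) 0 else .estimate_offset(amp, emission)
  camp <- amp - offset
  lo <- thresholds[1]; hi <- thresholds[2]
  # plain per-frame classification (1 = low, 2 = mid, 3 = high)
  raw <- findInterval(camp, c(lo, hi), left.open = TRUE) + 1L

  # hysteresis pass: a frame leaves the current class only if it clears the
  # cutoff by > band; ties and shallow crossings keep the current class.
  # Precompute the widened classification once so the sequential pass is a
  # cheap integer state machine.
  wide <- findInterval(camp, c(lo - band, lo + band, hi - band, hi + band)) + 1L
  # wide: 1 = < lo-band, 2 = [lo-band, lo+band], 3 = (lo+band, hi-band),
  #       4 = [hi-band, hi+band], 5 = > hi+band
  cls <- integer(n)
  cur <- raw[1]
  for (i in seq_len(n)) {
    w <- wide[i]
    cur <- if (cur == 1L) { if (w >= 5L) 3L else if (w >= 3L) 2L else 1L
    } else if (cur == 2L) { if (w == 1L) 1L else if (w == 5L) 3L else 2L
    } else { if (w == 1L) 1L else if (w <= 3L) 2L else 3L }
    cls[i] <- cur
  }

  # majority (mode) filter at the min_dwell scale: each frame takes the
  # most frequent hysteresis class in a centred window of ~min_frames
  # frames. Isolated noise flips vanish while a clean step edge moves by
  # at most one frame (the window majority switches exactly at the edge).
  min_frames <- max(1L, round(min_dwell / dt))
  if (min_frames > 2L && n > min_frames) {
    half <- (min_frames - (1 - min_frames %% 2)) %/% 2  # odd window half
    loidx <- pmax(seq_len(n) - half, 1L)
    hiidx <- pmin(seq_len(n) + half, n)
    counts <- vapply(1:3, function(cc) {
      cs <- cumsum(c(0L, cls == cc))
      cs[hiidx + 1L] - cs[loidx]
    }, numeric(n))
    cls <- max.col(counts, ties.method = "last")
  }

  # enforce min_dwell: runs of at least min_frames are confirmed segments;
  # shorter excursions are absorbed into the preceding confirmed segment
  # (tie-break toward continuity; leading short runs join the first
  # confirmed one)
  r <- rle(cls)
  conf <- r$lengths >= min_frames
  if (any(conf)) {
    anchor <- cumsum(conf)
    vals <- r$values[conf]
    r$values <- vals[pmax(anchor, 1L)]
    cls <- inverse.rle(r)
  } else {
    # no run long enough: a single segment of the duration-weighted
    # majority class
    agg <- tapply(r$lengths, r$values, sum)
    cls <- rep(as.integer(names(which.max(agg))), n)
  }

  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  seg <- data.frame(
    state_class = c("low", "mid", "high")[r$values],
    start_s = trace$time_s[starts],
    end_s = c(trace$time_s[utils::head(ends, -1L) + 1L], trace$quench_time),
    mean_nm = vapply(seq_along(starts), function(j)
      mean(amp[starts[j]:ends[j]]), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(segments = seg, molecule_id = trace$molecule_id,
                 quench_time = trace$quench_time, frame_interval = dt,
                 post_sds = trace$post_sds, offset_nm = offset),
            class = "segmentation_result")
}

# MAP estimate of the per-molecule amplitude offset. The trace is modeled
# as a three-component Gaussian mixture with known level means and frame
# SD; EM estimates the offset and the occupancy weights jointly (a hard
# min-distance profile would instead favor offsets that park the template
# between two levels when the frame noise is comparable to half the level
# spacing). Two regularizers enter the M-step and the model score: a
# Gaussian prior on the offset (between-molecule SD) and an anchor on the
# first ~2 s of frames — the assay starts at protein addition, so every
# molecule begins unbound at the high level, which breaks the
# label-switching degeneracy of a single-level trace. EM runs from several
# starts; the best posterior score wins. Frames are thinned for speed.
.estimate_offset <- function(amp, emission) {
  if (emission$sd_molecule <= 0 || emission$sd_frame <= 0) return(0)
  a <- if (length(amp) > 4000L)
    amp[round(seq(1L, length(amp), length.out = 4000L))] else amp
  n <- length(a)
  mus <- c(emission$mean_high, emission$mean_mid, emission$mean_low)
  sf <- emission$sd_frame
  sf2 <- sf^2
  sm2 <- emission$sd_molecule^2
  n0 <- min(20L, length(amp))
  m0 <- stats::median(amp[seq_len(n0)])

  run_em <- function(o) {
    pi_c <- rep(1 / 3, 3)
    for (it in 1:25) {
      d <- vapply(1:3, function(cc)
        pi_c[cc] * stats::dnorm(a, mus[cc] + o, sf), numeric(n))
      tot <- rowSums(d) + 1e-300
      r <- d / tot
      pi_c <- colMeans(r)
      num <- sum(r %*% (-mus) + a) / sf2 + n0 * (m0 - mus[1]) / sf2
      den <- (n + n0) / sf2 + 1 / sm2
      o_new <- num / den
      if (abs(o_new - o) < 1e-4) { o <- o_new; break }
      o <- o_new
    }
    d <- vapply(1:3, function(cc)
      pi_c[cc] * stats::dnorm(a, mus[cc] + o, sf), numeric(n))
    score <- sum(log(rowSums(d) + 1e-300)) - o^2 / (2 * sm2) -
      (m0 - o - mus[1])^2 / (2 * sf2 / n0)
    list(o = o, score = score)
  }

  sdm <- emission$sd_molecule
  starts <- unique(c(m0 - mus[1], 0, -sdm, sdm, -2 * sdm, 2 * sdm))
  fits <- lapply(starts, run_em)
  fits[[which.max(vapply(fits, function(f) f$score, numeric(1)))]]$o
}

#' Extract dwell times for one amplitude class
#'
#' One dwell per maximal segment of `state_class`; a segment that runs into
#' the quench is flagged right-censored.
#'
#' @param segmentation a `segmentation_result` (or list of them)
#' @param state_class `"high"`, `"mid"` or `"low"`
#' @param quench_time quench time, seconds (defaults to the segmentation's)
#' @return an object of class `dwell_set`: data frame with `duration_s`,
#'   `censored`, `molecule_id`, plus attribute `state_class`
#' @export
extract_dwells <- function(segmentation, state_class,
                           quench_time = NULL) {
  if (inherits(segmentation, "segmentation_result"))
    segmentation <- list(segmentation)
  rows <- lapply(segmentation, function(sg) {
    stopifnot(inherits(sg, "segmentation_result"))
    q <- if (is.null(quench_time)) sg$quench_time else quench_time
    s <- sg$segments
    keep <- s$state_class == state_class
    if (!any(keep)) return(NULL)
    s <- s[keep, , drop = FALSE]
    data.frame(duration_s = s$end_s - s$start_s,
               censored = abs(s$end_s - q) < 1e-9,
               molecule_id = sg$molecule_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(duration_s = numeric(0), censored = logical(0),
                      molecule_id = integer(0))
  structure(out, state_class = state_class, class = c("dwell_set",
                                                      "data.frame"))
}

#' Construct a dwell set directly from durations
#'
#' Convenience constructor used when dwell times come from an external
#' source or a parametric draw rather than segmentation.
#'
#' @param duration_s dwell durations, seconds
#' @param censored logical right-censoring flags (default all `FALSE`)
#' @param state_class label for the state the dwells describe
#' @return a `dwell_set`
#' @export
dwell_set <- function(duration_s, censored = rep(FALSE, length(duration_s)),
                      state_class = "low") {
  stopifnot(length(duration_s) == length(censored), all(duration_s > 0))
  structure(data.frame(duration_s = duration_s, censored = censored,
                       molecule_id = seq_along(duration_s)),
            state_class = state_class, class = c("dwell_set", "data.frame"))
}

#' Amplitude statistics for one state class
#'
#' Mean and SD of per-molecule (or per-event) mean amplitudes, with the
#' count `N` reported in the chosen unit: `per_molecule` averages all frames
#' a molecule spends in the class (one value per molecule), `per_event`
#' takes one value per maximal segment (synaptic event).
#'
#' @param segmentations list of `segmentation_result`
#' @param state_class `"high"`, `"mid"` or `"low"`
#' @param unit `"per_molecule"` or `"per_event"`
#' @return an object of class `amplitude_stats`: list with `mean_nm`,
#'   `sd_nm`, `n`, `unit`, `state_class`, and the underlying `values`
#' @export
amplitude_stats <- function(segmentations, state_class,
                            unit = c("per_molecule", "per_event")) {
  unit <- match.arg(unit)
  if (inherits(segmentations, "segmentation_result"))
    segmentations <- list(segmentations)
  vals <- unlist(lapply(segmentations, function(sg) {
    s <- sg$segments
    s <- s[s$state_class == state_class, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    if (unit == "per_event") s$mean_nm
    else sum(s$mean_nm * (s$end_s - s$start_s)) / sum(s$end_s - s$start_s)
  }))
  if (length(vals) == 0L)
    stop("empty statistics: no segment of class '", state_class, "'",
         call. = FALSE)
  structure(list(mean_nm = mean(vals),
                 sd_nm = if (length(vals) > 1L) stats::sd(vals) else 0,
                 n = length(vals), unit = unit, state_class = state_class,
                 values = vals),
            class = "amplitude_stats")
}

#' @export
print.amplitude_stats <- function(x, ...) {
  cat(sprintf("%s amplitude (%s): %.1f +/- %.1f nm (N = %d)\n",
              x$state_class, x$unit, x$mean_nm, x$sd_nm, x$n))
  invisible(x)
}
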