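#' Classify one molecule into the complex taxonomy
#'
#' Decision rules, applied to the segment sequence plus the post-SDS
#' readout:
#' * never leaves `high` — not responded;
#' * a `mid` segment that returns to `high` without reaching `low` — a
#'   non-productive episode;
#' * `mid` followed by `low` — a pre-synaptic complex that synapsed;
#' * a `low` segment that reverts spontaneously to `mid`/`high`, or a final
#'   `low` with post-SDS `high` — wayward;
#' * `low` retained after the SDS challenge — recombinogenic (head-to-tail:
#'   Holliday junction or excision; head-to-head: Holliday junction);
#' * for head-to-head sites a wayward call is additionally annotated
#'   `"wayward_or_completed_inversion"`, since a completed inversion is
#'   indistinguishable from a dissociating wayward synapse.
#'
#' A `low` dwell longer than `long_lived_cutoff` seconds is labelled
#' long-lived wayward (the Cre(K201A) phenotype); the default `Inf`
#' disables the label.
#'
#' The mutually exclusive final call is the furthest-progressed state:
#' recombinogenic > long-lived wayward > wayward > pre-synaptic >
#' non-productive. The synapse character is `stable` when the molecule ends
#' low and survives SDS, `fluctuating` when it showed at least one
#' low-to-higher transition or lost the low state upon SDS, else `none`.
#'
#' @param segmentation a `segmentation_result`
#' @param post_sds `"high"` or `"low"` (the SDS-challenge readout)
#' @param orientation `"head_to_tail"` or `"head_to_head"`
#' @param long_lived_cutoff seconds; low dwells exceeding it are called
#'   long-lived wayward
#' @return an object of class `molecule_label`: list with `responded`,
#'   `labels` (character subset of the taxonomy), `synapse` (none /
#'   fluctuating / stable), `final_call`, `first_complex`
#'   (`"non_productive"`, `"pre_synaptic"` or `NA`), `annotation`
#' @export
classify_molecule <- function(segmentation, post_sds = segmentation$post_sds,
                              orientation = c("head_to_tail", "head_to_head"),
                              long_lived_cutoff = Inf) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(segmentation, "segmentation_result"))
  if (is.null(post_sds) || is.na(post_sds))
    stop("post-SDS readout missing", call. = FALSE)
  s <- segmentation$segments
  cls <- s$state_class
  if (all(cls == "high")) {
    if (post_sds == "low")
      stop("classification error: post-SDS low but molecule never left high",
           call. = FALSE)
    return(structure(list(responded = FALSE, labels = character(0),
                          synapse = "none", final_call = "unresponsive",
                          first_complex = NA_character_,
                          annotation = NA_character_),
                     class = "molecule_label"))
  }
  labels <- character(0)
  n <- length(cls)
  nxt <- c(cls[-1L], NA)
  # non-productive episode: mid that goes back to high (or is the last
  # segment of a molecule that never reached low)
  np_epi <- cls == "mid" & (!is.na(nxt) & nxt == "high")
  if (any(np_epi)) labels <- c(labels, "non_productive")
  # pre-synaptic: mid followed by low
  if (any(cls == "mid" & !is.na(nxt) & nxt == "low"))
    labels <- c(labels, "pre_synaptic")
  low_idx <- which(cls == "low")
  has_low <- length(low_idx) > 0L
  # wayward: low reverting spontaneously, or final low lost upon SDS
  low_revert <- any(cls == "low" & !is.na(nxt) & nxt %in% c("mid", "high"))
  final_low <- cls[n] == "low"
  if (low_revert || (final_low && post_sds == "high"))
    labels <- c(labels, "wayward")
  if (has_low && is.finite(long_lived_cutoff)) {
    dur <- s$end_s[low_idx] - s$start_s[low_idx]
    if (any(dur > long_lived_cutoff)) labels <- c(labels, "long_lived_wayward")
  }
  recomb <- final_low && post_sds == "low"
  if (recomb) labels <- c(labels, "recombinogenic")
  if (post_sds == "low" && !final_low)
    stop("classification error: post-SDS low without a terminal low segment",
         call. = FALSE)
  # mid held to the quench with no prior low: poised pre-synaptic complex
  if (!has_low && cls[n] == "mid" && !"pre_synaptic" %in% labels &&
      !any(np_epi)) labels <- c(labels, "pre_synaptic")

  order_rank <- c(non_productive = 1, pre_synaptic = 2, wayward = 3,
                  long_lived_wayward = 4, recombinogenic = 5)
  final_call <- if (length(labels))
    names(order_rank)[max(order_rank[labels])] else "pre_synaptic"

  synapse <- if (recomb) "stable"
             else if (has_low) "fluctuating"
             else "none"

  first_mid <- which(cls == "mid")[1]
  first_complex <- if (is.na(first_mid)) NA_character_
    else {
      after <- cls[seq.int(first_mid + 1L, length.out = n - first_mid)]
      if (length(after) && after[1] == "low") "pre_synaptic"
      else if (length(after) && after[1] == "high") "non_productive"
      else "pre_synaptic"   # censored first complex: poised, not yet failed
    }

  annotation <- if (orientation == "head_to_head" &&
                    final_call %in% c("wayward", "long_lived_wayward"))
    "wayward_or_completed_inversion" else NA_character_

  structure(list(responded = TRUE, labels = unique(labels),
                 synapse = synapse, final_call = final_call,
                 first_complex = first_complex, annotation = annotation),
            class = "molecule_label")
}

#' Ensemble census of complex types
#'
#' Counts molecules per final call and normalizes to the recombinase-bound
#' (responded) fraction. `frac_first_non_productive` reports the share of
#' responded molecules whose *first* bound complex was non-productive — the
#' quantity that reflects how binding partitions between the non-productive
#' and pre-synaptic channels, independent of later re-binding rounds.
#'
#' @param labels list of `molecule_label`
#' @return an object of class `complex_census`: list with `n_total`,
#'   `n_responded`, `frac_responded`, `fractions` (named, mutually exclusive
#'   final calls among responded, summing to 1), `frac_first_non_productive`,
#'   and `flagged` (TRUE when no molecule responded)
#' @export
census <- function(labels) {
  stopifnot(length(labels) >= 1L)
  responded <- vapply(labels, function(l) isTRUE(l$responded), logical(1))
  n_total <- length(labels)
  n_resp <- sum(responded)
  cats <- c("non_productive", "pre_synaptic", "wayward",
            "long_lived_wayward", "recombinogenic")
  if (n_resp == 0L) {
    return(structure(list(n_total = n_total, n_responded = 0L,
                          frac_responded = 0,
                          fractions = stats::setNames(rep(NA_real_, length(cats)), cats),
                          frac_first_non_productive = NA_real_,
                          flagged = TRUE),
                     class = "complex_census"))
  }
  finals <- vapply(labels[responded], function(l) l$final_call, character(1))
  firsts <- vapply(labels[responded], function(l)
    if (is.na(l$first_complex)) "none" else l$first_complex, character(1))
  fractions <- vapply(cats, function(cc) mean(finals == cc), numeric(1))
  structure(list(n_total = n_total, n_responded = n_resp,
                 frac_responded = n_resp / n_total,
                 fractions = fractions,
                 frac_first_non_productive = mean(firsts == "non_productive"),
                 flagged = FALSE),
            class = "complex_census")
}

#' @export
print.complex_census <- function(x, ...) {
  cat(sprintf("complex census: %d molecules, %d responded (%.0f%%)\n",
              x$n_total, x$n_responded, 100 * x$frac_responded))
  if (!x$flagged)
    for (nm in names(x$fractions))
      cat(sprintf("  %-20s %.3f\n", nm, x$fractions[[nm]]))
  invisible(x)
}
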