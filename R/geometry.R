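#' Compare synapse amplitudes between two groups
#'
#' Welch's unequal-variance two-sample comparison of per-molecule or
#' per-event mean amplitudes (two-sided). Group SDs in these assays differ
#' and counts are small, which is what Welch's test is built for.
#'
#' @param a,b [amplitude_stats] objects (or bare numeric vectors of
#'   per-molecule/per-event amplitudes)
#' @param labels character pair naming the groups
#' @return an object of class `group_comparison`: list with `labels`,
#'   `stats` (per-group amplitude summaries), `difference_nm` (mean(a) -
#'   mean(b)), `statistic`, `df`, `p_value`
#' @export
compare_groups <- function(a, b, labels = c("A", "B")) {
  va <- if (inherits(a, "amplitude_stats")) a$values else as.numeric(a)
  vb <- if (inherits(b, "amplitude_stats")) b$values else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L)
    stop("each group needs N >= 2", call. = FALSE)
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  structure(list(labels = labels,
                 stats = list(a = c(mean = mean(va), sd = stats::sd(va),
                                    n = length(va)),
                              b = c(mean = mean(vb), sd = stats::sd(vb),
                                    n = length(vb))),
                 difference_nm = mean(va) - mean(vb),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: difference %.2f nm, t = %.2f (df = %.1f), p = %.4g\n",
              x$labels[1], x$labels[2], x$difference_nm, x$statistic,
              x$df, x$p_value))
  invisible(x)
}

#' Synapse-amplitude summary table across proteins
#'
#' For each classified ensemble, reports substrate (protein-free high
#' state, counted per molecule), stable / long-lived synapse, and
#' fluctuating synapse amplitudes (both counted per synaptic event), as
#' `mean +/- sd (N)` cells. A cell with no qualifying molecules is left
#' blank, as for catalytically dead mutants that never form a stable
#' synapse.
#'
#' @param ensembles named list; each element a list with `segmentations`
#'   (list of `segmentation_result`) and `labels` (list of `molecule_label`)
#' @return data frame with columns `protein`, `substrate`,
#'   `stable_synapse`, `fluctuating_synapse` plus numeric companions
#'   (`*_mean`, `*_sd`, `*_n`)
#' @export
synapse_amplitude_table <- function(ensembles) {
  cell <- function(st) {
    if (is.null(st)) return(list(txt = "", mean = NA_real_, sd = NA_real_,
                                 n = 0L))
    list(txt = sprintf("%.1f ± %.1f (N = %d)", st$mean_nm, st$sd_nm,
                       st$n),
         mean = st$mean_nm, sd = st$sd_nm, n = st$n)
  }
  rows <- lapply(names(ensembles), function(nm) {
    en <- ensembles[[nm]]
    segs <- en$segmentations
    labs <- en$labels
    syn <- vapply(labs, function(l) l$synapse, character(1))
    ll <- vapply(labs, function(l)
      "long_lived_wayward" %in% l$labels, logical(1))
    substrate_idx <- vapply(labs, function(l) !isTRUE(l$responded),
                            logical(1))
    safe_stats <- function(idx, cls, unit) {
      if (!any(idx)) return(NULL)
      tryCatch(amplitude_stats(segs[idx], cls, unit),
               error = function(e) NULL)
    }
    sub <- safe_stats(substrate_idx, "high", "per_molecule")
    stable <- safe_stats(syn == "stable" | ll, "low", "per_event")
    fluct <- safe_stats(syn == "fluctuating" & !ll, "low", "per_event")
    cs <- cell(sub); cst <- cell(stable); cf <- cell(fluct)
    data.frame(protein = nm,
               substrate = cs$txt, stable_synapse = cst$txt,
               fluctuating_synapse = cf$txt,
               substrate_mean = cs$mean, substrate_sd = cs$sd,
               substrate_n = cs$n,
               stable_mean = cst$mean, stable_sd = cst$sd, stable_n = cst$n,
               fluctuating_mean = cf$mean, fluctuating_sd = cf$sd,
               fluctuating_n = cf$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
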