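#' Kinetic scheme of the recombination pathway
#'
#' Defines the continuous-time Markov chain underlying a TPM recombination
#' assay. States are `U` (free substrate, high amplitude), `NP`
#' (non-productive complex), `PS` (pre-synaptic complex), `WW` (wayward
#' synapse), `LLWW` (long-lived wayward synapse), `RS` (recombinogenic
#' synapse) and the absorbing `PROD` (completed strand exchange).
#'
#' Second-order rates (`k_NPf`, `k_PSf`, units M^-1 s^-1) are multiplied by
#' the enzyme concentration to give pseudo-first-order channels out of `U`.
#' All other rates are first order (s^-1). Absent optional rates are zero.
#'
#' @param k_NPf substrate -> non-productive complex formation, M^-1 s^-1
#' @param k_NPd non-productive complex dissociation, s^-1
#' @param k_PSf substrate -> pre-synaptic complex formation, M^-1 s^-1
#' @param k_RSf pre-synaptic -> recombinogenic synapse, s^-1
#' @param k_WWf pre-synaptic -> wayward synapse, s^-1
#' @param k_WWd wayward synapse decay, s^-1
#' @param k_star_WWf pre-synaptic -> long-lived wayward synapse, s^-1
#' @param k_star_WWd long-lived wayward synapse decay, s^-1
#' @param k_REC recombinogenic synapse -> product, s^-1
#' @param k_REV recombinogenic synapse -> pre-synaptic (Holliday-junction
#'   reversal), s^-1
#' @param p_ww_to_ps probability that a decaying wayward synapse returns to
#'   the pre-synaptic state rather than to the free substrate
#' @param name optional label (e.g. the protein the scheme describes)
#' @return an object of class `kinetic_scheme`
#' @examples
#' sc <- kinetic_scheme(k_PSf = 6.1e4, k_WWf = 0.77, k_WWd = 2.7e-2)
#' sc$k_PSf
#' @export
kinetic_scheme <- function(k_NPf = 0, k_NPd = 0, k_PSf = 0, k_RSf = 0,
                           k_WWf = 0, k_WWd = 0,
                           k_star_WWf = 0, k_star_WWd = 0,
                           k_REC = 0, k_REV = 0,
                           p_ww_to_ps = 0.5, name = NULL) {
  rates <- list(k_NPf = k_NPf, k_NPd = k_NPd, k_PSf = k_PSf, k_RSf = k_RSf,
                k_WWf = k_WWf, k_WWd = k_WWd,
                k_star_WWf = k_star_WWf, k_star_WWd = k_star_WWd,
                k_REC = k_REC, k_REV = k_REV)
  for (nm in names(rates)) {
    v <- rates[[nm]]
    if (is.null(v)) rates[[nm]] <- 0
    else if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("invalid scheme: rate '", nm,
           "' must be a single finite non-negative number", call. = FALSE)
  }
  if (!is.numeric(p_ww_to_ps) || length(p_ww_to_ps) != 1L ||
      !is.finite(p_ww_to_ps) || p_ww_to_ps < 0 || p_ww_to_ps > 1)
    stop("invalid scheme: p_ww_to_ps must lie in [0, 1]", call. = FALSE)
  structure(c(rates, list(p_ww_to_ps = p_ww_to_ps, name = name)),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  r <- unlist(x[setdiff(names(x), "name")])
  for (nm in names(r)) cat(sprintf("  %-11s %g\n", nm, r[[nm]]))
  invisible(x)
}

#' Experimental configuration of a TPM run
#'
#' @param enzyme_concentration molar recombinase concentration (5e-8 for
#'   50 nM Cre, 2e-7 for 200 nM Flp)
#' @param duration observation window before the SDS quench, seconds
#' @param orientation `"head_to_tail"` (excision substrate) or
#'   `"head_to_head"` (inversion substrate)
#' @param frame_interval seconds per sampled frame
#' @param seed integer random seed used when the configuration drives an
#'   ensemble simulation
#' @return an object of class `experiment_config`
#' @export
experiment_config <- function(enzyme_concentration = 5e-8, duration = 1800,
                              orientation = c("head_to_tail", "head_to_head"),
                              frame_interval = 0.1, seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(is.numeric(enzyme_concentration), length(enzyme_concentration) == 1L)
  if (!is.finite(enzyme_concentration) || enzyme_concentration <= 0)
    stop("enzyme_concentration must be finite and > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  structure(list(enzyme_concentration = enzyme_concentration,
                 duration = duration, orientation = orientation,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Amplitude emission model
#'
#' Maps kinetic states to bead Brownian-motion (BM) amplitude levels:
#' `U` emits at `mean_high`, recombinase-bound bent sites (`NP`, `PS`) at
#' `mean_mid`, synapsed states (`WW`, `LLWW`, `RS`) at `mean_low`. A
#' completed product emits low for head-to-tail sites (shortened excision
#' circle left a shorter tether) and high for head-to-head sites (inversion
#' conserves length). Per-frame noise is Gaussian with `sd_frame`; each
#' molecule additionally carries a fixed Gaussian offset with `sd_molecule`.
#'
#' @param mean_high substrate amplitude, nm
#' @param mean_mid recombinase-bound (bent-site) amplitude, nm
#' @param mean_low synapsed amplitude, nm
#' @param sd_frame per-frame noise SD, nm
#' @param sd_molecule between-molecule offset SD, nm
#' @return an object of class `emission_model`
#' @export
emission_model <- function(mean_high = 81, mean_mid = 65, mean_low = 44,
                           sd_frame = 8, sd_molecule = 4) {
  if (!(mean_high > mean_mid && mean_mid > mean_low && mean_low > 0))
    stop("invalid emission model: need mean_high > mean_mid > mean_low > 0",
         call. = FALSE)
  if (sd_frame < 0 || sd_molecule < 0)
    stop("invalid emission model: sd values must be >= 0", call. = FALSE)
  structure(list(mean_high = mean_high, mean_mid = mean_mid,
                 mean_low = mean_low, sd_frame = sd_frame,
                 sd_molecule = sd_molecule),
            class = "emission_model")
}

# Tabulated rate constants for the wild-type proteins and their catalytic
# pentad / nucleophile mutants. NP formation/decay rates for the wild types
# are not tabulated alongside the pathway constants; the Cre entry uses the
# published R173A-assay values as a stand-in, while the Flpe entry derives
# k_NPf from the ~3% non-productive share of bound molecules. The Y324F /
# Y343F entries reuse the wild-type binding constants (binding is unaffected
# by loss of the nucleophile) with the measured wayward-decay rates.
.preset_table <- function() {
  list(
    "Cre" = list(conc = 5e-8, k_NPf = 1.9e4, k_NPd = 2.9e-2,
                 k_PSf = 6.1e4, k_RSf = 4.2e-1, k_WWf = 7.7e-1,
                 k_WWd = 2.7e-2, k_REC = 2.0e-3, k_REV = 2.0e-3),
    "Cre(R173A)" = list(conc = 5e-8, k_NPf = 1.9e4, k_NPd = 2.9e-2,
                        k_PSf = 1.5e4, k_WWf = 4.2e-1, k_WWd = 2.3e-2),
    "Cre(K201A)" = list(conc = 5e-8, k_NPf = 1.9e4, k_NPd = 2.9e-2,
                        k_PSf = 1.5e4, k_WWf = 10.3e-1, k_WWd = 4.1e-2,
                        k_star_WWf = 9.3e-1, k_star_WWd = 2.6e-3),
    "Cre(H289A)" = list(conc = 5e-8, k_NPf = 2.8e4, k_NPd = 7.1e-3,
                        k_PSf = 1.6e4, k_RSf = 5.1e-1, k_WWf = 6.7e-1,
                        k_WWd = 2.0e-2, k_REC = 2.3e-3, k_REV = 2.3e-3),
    "Cre(R292A)" = list(conc = 5e-8, k_NPf = 1.8e4, k_NPd = 2.4e-2,
                        k_PSf = 1.9e4, k_WWf = 4.1e-1, k_WWd = 2.2e-2),
    "Cre(W315F)" = list(conc = 5e-8, k_NPf = 3.6e4, k_NPd = 4.0e-2,
                        k_PSf = 1.5e4, k_RSf = 6.1e-1, k_WWf = 8.7e-1,
                        k_WWd = 1.5e-2, k_REC = 1.8e-3, k_REV = 1.8e-3),
    "Cre(Y324F)" = list(conc = 5e-8, k_NPf = 1.9e4, k_NPd = 2.9e-2,
                        k_PSf = 6.1e4, k_WWf = 7.7e-1, k_WWd = 3.2e-2),
    "Flpe" = list(conc = 2e-7, k_NPf = 1.9e3, k_NPd = 2.2e-2,
                  k_PSf = 6.0e4, k_RSf = 4.9e-2, k_WWf = 1.7e-2,
                  k_WWd = 1.6e-2, k_REC = 1.7e-3),
    "Flpe(R191A)" = list(conc = 2e-7, k_NPf = 4.1e4, k_NPd = 2.2e-2,
                         k_PSf = 8.3e4, k_WWf = 6.1e-3, k_WWd = 1.8e-2),
    "Flpe(H305A)" = list(conc = 2e-7, k_NPf = 5.4e4, k_NPd = 1.8e-2,
                         k_PSf = 1.3e5, k_WWf = 8.4e-3, k_WWd = 1.4e-2),
    "Flpe(R308A)" = list(conc = 2e-7, k_NPf = 3.2e4, k_NPd = 2.5e-2,
                         k_PSf = 4.1e4, k_WWf = 1.0e-2, k_WWd = 1.7e-2),
    "Flpe(W330F)" = list(conc = 2e-7, k_NPf = 2.0e4, k_NPd = 2.7e-2,
                         k_PSf = 5.5e4, k_RSf = 2.5e-2, k_WWf = 2.3e-2,
                         k_WWd = 2.5e-2, k_REC = 2.6e-3),
    "Flpe(Y343F)" = list(conc = 2e-7, k_NPf = 1.9e3, k_NPd = 2.2e-2,
                         k_PSf = 6.0e4, k_WWf = 1.7e-2, k_WWd = 1.3e-2)
  )
}

#' Protein scheme presets
#'
#' Returns the kinetic scheme (and the enzyme concentration at which its
#' constants were measured) for a named recombinase or mutant. Rates absent
#' from a preset are zero: a catalytically dead mutant has `k_RSf = 0` and
#' `k_REC = 0`, so its trajectories can never reach the product state. The
#' long-lived wayward branch (`k_star_WWf`, `k_star_WWd`) is populated only
#' for Cre(K201A). For Cre presets that recombine on head-to-tail sites the
#' slow phase of the synaptic-dwell decay reflects Holliday-junction
#' reversal, so `k_REV` is set equal to `k_REC`; Flp reversal is a minor
#' process and `k_REV` is left at zero.
#'
#' @param name preset name; see `preset_names()`
#' @return a list with elements `scheme` (a [kinetic_scheme]) and
#'   `enzyme_concentration` (molar)
#' @examples
#' preset_scheme("Cre")$scheme$k_PSf
#' @export
preset_scheme <- function(name) {
  tab <- .preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  p <- tab[[name]]
  g <- function(f) if (is.null(p[[f]])) 0 else p[[f]]
  sc <- kinetic_scheme(k_NPf = g("k_NPf"), k_NPd = g("k_NPd"),
                       k_PSf = g("k_PSf"), k_RSf = g("k_RSf"),
                       k_WWf = g("k_WWf"), k_WWd = g("k_WWd"),
                       k_star_WWf = g("k_star_WWf"),
                       k_star_WWd = g("k_star_WWd"),
                       k_REC = g("k_REC"), k_REV = g("k_REV"),
                       name = name)
  list(scheme = sc, enzyme_concentration = p$conc)
}

#' @rdname preset_scheme
#' @export
preset_names <- function() names(.preset_table())

#' Tabulated first-order rate constants across all presets
#'
#' Enumerates every first-order rate constant carried by the scheme
#' presets, with its fitting role: rates whose dwell histograms are fitted
#' alone (`single`) versus the pairs the decay of synapsed molecules
#' resolves by a double-exponential fit — wayward dissociation together
#' with recombination (`pair_fast` / `pair_slow`), or the two wayward
#' populations of Cre(K201A).
#'
#' @return data frame with columns `protein`, `rate`, `value` (s^-1),
#'   `role`, `pair_id`
#' @export
preset_rate_table <- function() {
  tab <- .preset_table()
  rows <- list()
  for (nm in names(tab)) {
    p <- tab[[nm]]
    g <- function(f) if (is.null(p[[f]])) 0 else p[[f]]
    pair <- NULL
    if (g("k_star_WWd") > 0) pair <- c("k_WWd", "k_star_WWd")
    else if (g("k_REC") > 0) pair <- c("k_WWd", "k_REC")
    for (rn in c("k_RSf", "k_WWf", "k_WWd", "k_star_WWf", "k_star_WWd",
                 "k_REC")) {
      v <- g(rn)
      if (v <= 0) next
      role <- if (!is.null(pair) && rn == pair[1]) "pair_fast"
              else if (!is.null(pair) && rn == pair[2]) "pair_slow"
              else "single"
      rows[[length(rows) + 1L]] <- data.frame(
        protein = nm, rate = rn, value = v, role = role,
        pair_id = if (role == "single") NA_character_ else nm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
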