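test_that("scheme and config validation rejects bad inputs", {
  expect_error(kinetic_scheme(k_PSf = -1), "invalid scheme")
  expect_error(kinetic_scheme(k_WWd = NaN), "invalid scheme")
  expect_error(kinetic_scheme(p_ww_to_ps = 1.2), "p_ww_to_ps")
  expect_error(experiment_config(enzyme_concentration = 0), "enzyme")
  expect_error(emission_model(mean_high = 50, mean_mid = 65), "emission")
})

test_that("zero-rate scheme produces no transitions", {
  trj <- simulate_trajectory(kinetic_scheme(), experiment_config(), seed = 1)
  expect_identical(trj$states, "U")
  expect_identical(trj$entry_times, 0)
  expect_false(trj$absorbed)
})

test_that("U -> PS waiting time matches the analytic exponential mean", {
  # single channel k_PSf [E]: waiting time ~ Exp(rate), mean 1/rate
  sc <- kinetic_scheme(k_PSf = 6.1e4)
  cfg <- experiment_config(enzyme_concentration = 5e-8, duration = 1e7)
  rate <- 6.1e4 * 5e-8
  n <- 10000L
  w <- vapply(seq_len(n),
              function(i) simulate_trajectory(sc, cfg, seed = i)$entry_times[2],
              numeric(1))
  se <- (1 / rate) / sqrt(n)
  expect_lt(abs(mean(w) - 1 / rate), 3 * se)
})

test_that("branching from PS matches competing-rate ratios within 3 sigma", {
  # k_WWf = k_RSf: P(WW first) = 1/2
  sc <- kinetic_scheme(k_PSf = 1e9, k_RSf = 0.3, k_WWf = 0.3)
  cfg <- experiment_config(enzyme_concentration = 1e-6, duration = 1e6)
  n <- 10000L
  first_syn <- vapply(seq_len(n), function(i) {
    s <- simulate_trajectory(sc, cfg, seed = i)$states
    s[which(s %in% c("WW", "RS"))[1]]
  }, character(1))
  p_hat <- mean(first_syn == "WW")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("Gillespie waiting times pass a KS test against Exponential(r)", {
  sc <- kinetic_scheme(k_NPf = 1.9e4, k_PSf = 6.1e4)
  cfg <- experiment_config(enzyme_concentration = 5e-8, duration = 1e7)
  r <- (1.9e4 + 6.1e4) * 5e-8
  w <- vapply(1:10000,
              function(i) simulate_trajectory(sc, cfg, seed = i)$entry_times[2],
              numeric(1))
  expect_gt(stats::ks.test(w, stats::pexp, rate = r)$p.value, 0.01)
})

test_that("PROD is unreachable when k_REC = 0", {
  sc <- kinetic_scheme(k_NPf = 2e4, k_NPd = 3e-2, k_PSf = 6e4, k_RSf = 0.4,
                       k_WWf = 0.8, k_WWd = 3e-2)
  cfg <- experiment_config(enzyme_concentration = 5e-8)
  for (i in 1:100) {
    trj <- simulate_trajectory(sc, cfg, seed = i)
    expect_false("PROD" %in% trj$states)
    expect_false(trj$absorbed)
  }
})

test_that("trajectory invariants hold across preset simulations", {
  cfg <- experiment_config(enzyme_concentration = 5e-8)
  edges <- list(U = c("NP", "PS"), NP = "U", PS = c("RS", "WW", "LLWW"),
                WW = c("PS", "U"), LLWW = c("PS", "U"), RS = c("PROD", "PS"))
  for (nm in c("Cre", "Cre(K201A)", "Flpe")) {
    sc <- preset_scheme(nm)$scheme
    for (i in 1:50) {
      trj <- simulate_trajectory(sc, cfg, seed = i)
      expect_true(all(diff(trj$entry_times) > 0))
      expect_identical(trj$states[1], "U")
      if (length(trj$states) > 1L)
        for (j in seq_len(length(trj$states) - 1L))
          expect_true(trj$states[j + 1L] %in% edges[[trj$states[j]]])
    }
  }
})

test_that("noiseless rendering is piecewise constant at the emission means", {
  trj <- make_trajectory(c("U", "PS", "WW"), c(0, 600, 900))
  cfg <- experiment_config(5e-8)
  tr <- render_trace(trj, noiseless_emission(), cfg, seed = 1)
  expect_length(tr$amplitude_nm, 18000L)
  expect_setequal(unique(tr$amplitude_nm), c(81, 65, 44))
  expect_equal(unname(tr$amplitude_nm[1]), 81)
  expect_equal(unname(tr$amplitude_nm[6001]), 65)
  expect_equal(unname(tr$amplitude_nm[9001]), 44)
})

test_that("frame count is floor(duration / frame_interval)", {
  trj <- make_trajectory("U", 0, end_time = 100)
  cfg <- experiment_config(5e-8, duration = 100, frame_interval = 0.3)
  tr <- render_trace(trj, noiseless_emission(), cfg, seed = 1)
  expect_length(tr$amplitude_nm, floor(100 / 0.3))
})

test_that("rendered frame mean obeys the CLT at Table-anchored parameters", {
  em <- emission_model(mean_high = 80.9, sd_frame = 5.3, sd_molecule = 0)
  trj <- make_trajectory("U", 0)
  cfg <- experiment_config(5e-8)
  tr <- render_trace(trj, em, cfg, seed = 7)
  expect_lt(abs(mean(tr$amplitude_nm) - 80.9), 3 * 5.3 / sqrt(18000))
})

test_that("rendering then averaging frames per true state recovers means", {
  sc <- preset_scheme("Cre")$scheme
  cfg <- experiment_config(5e-8, seed = 11)
  em <- emission_model(sd_frame = 8, sd_molecule = 0)
  trj <- simulate_trajectory(sc, cfg, seed = 11)
  tr <- render_trace(trj, em, cfg, seed = 12)
  truth <- tpmkin:::.state_class(tpmkin:::.state_at(trj, tr$time_s),
                                 "head_to_tail")
  mus <- c(high = 81, mid = 65, low = 44)
  for (cl in unique(truth)) {
    nn <- sum(truth == cl)
    if (nn < 30) next
    expect_lt(abs(mean(tr$amplitude_nm[truth == cl]) - mus[[cl]]),
              3 * 8 / sqrt(nn) + 0.02)  # small allowance for the 0.1 floor
  }
})

test_that("SDS readout follows the strand-exchange truth table", {
  end_in <- function(states, times) make_trajectory(states, times)
  expect_identical(apply_sds(end_in(c("U", "PS", "WW"), c(0, 10, 20)),
                             "head_to_tail"), "high")
  expect_identical(apply_sds(end_in(c("U", "PS", "RS", "PROD"),
                                    c(0, 10, 20, 30)), "head_to_tail"), "low")
  expect_identical(apply_sds(end_in(c("U", "PS", "RS", "PROD"),
                                    c(0, 10, 20, 30)), "head_to_head"), "high")
  expect_identical(apply_sds(end_in(c("U", "PS", "RS"), c(0, 10, 20)),
                             "head_to_head"), "low")
  expect_identical(apply_sds(end_in("U", 0), "head_to_tail"), "high")
  expect_identical(apply_sds(end_in(c("U", "NP"), c(0, 5)), "head_to_tail"),
                   "high")
})

test_that("ensembles are deterministic and order-independent", {
  sc <- preset_scheme("Cre")$scheme
  cfg <- experiment_config(5e-8, duration = 300)
  em <- emission_model()
  e1 <- simulate_ensemble(sc, em, cfg, n_molecules = 3, seed = 99)
  e2 <- simulate_ensemble(sc, em, cfg, n_molecules = 3, seed = 99)
  expect_identical(e1$traces, e2$traces)
  expect_identical(e1$post_sds, e2$post_sds)
  # molecule i is unchanged by growing the ensemble
  e3 <- simulate_ensemble(sc, em, cfg, n_molecules = 5, seed = 99)
  expect_identical(e3$traces[[2]], e1$traces[[2]])
  expect_error(simulate_ensemble(sc, em, cfg, n_molecules = 0, seed = 1),
               "n_molecules")
})

test_that("all-zero scheme yields an all-high, SDS-high ensemble", {
  cfg <- experiment_config(5e-8, duration = 60)
  en <- simulate_ensemble(kinetic_scheme(), noiseless_emission(), cfg,
                          n_molecules = 100, seed = 5)
  expect_true(all(en$post_sds == "high"))
  expect_true(all(vapply(en$traces,
                         function(tr) all(tr$amplitude_nm == 81),
                         logical(1))))
})

test_that("Cre preset response fraction is consistent with binding rates", {
  sc <- preset_scheme("Cre")$scheme
  cfg <- experiment_config(5e-8)
  n <- 1000L
  left_U <- vapply(seq_len(n), function(i)
    length(simulate_trajectory(sc, cfg, seed = i)$states) > 1L, logical(1))
  p <- mean(left_U)
  lower <- 1 - exp(-(sc$k_NPf + sc$k_PSf) * 5e-8 * 1800)
  expect_gte(p, 0.6)
  expect_lte(p, 1.0)
  expect_gt(p, lower - 3 * sqrt(lower * (1 - lower) / n))
})
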