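lib <- default_library()

test_that("instrument config rejects unphysical parameters", {
  expect_error(instrument_config(I_r = 0), "positive")
  expect_error(instrument_config(t_r = -1), "positive")
  expect_error(instrument_config(phi = 1.5), "phi")
  expect_error(instrument_config(background = -1), "background")
})

test_that("expected channel rates follow the pseudo-first-order model", {
  cfg <- instrument_config()
  chf <- library_entry(lib, "chloroform", "O2+")
  expect_equal(unname(expected_channel_rate(0, chf, config = cfg)),
               c(0, 0, 0))
  r1 <- expected_channel_rate(1.5, chf, config = cfg)
  r2 <- expected_channel_rate(3.0, chf, config = cfg)
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # two-chlorine envelope proportions at m/z 83/85/87
  expect_equal(unname(r2 / sum(r2)), c(0.5625, 0.375, 0.0625),
               tolerance = 1e-12)
  expect_identical(names(r2), c("83", "85", "87"))
  expect_error(expected_channel_rate(-1, chf, config = cfg),
               "non-negative")
})

test_that("flux is conserved across channels, isotopologues and hydrates", {
  cfg <- default_study_config()
  for (entry in lib) {
    conc <- 0.7
    total <- 0
    for (i in seq_len(nrow(entry$channels)))
      total <- total + sum(expected_channel_rate(conc, entry,
                                                 entry$channels[i, ], cfg))
    n_ft <- cfg$phi * conc * 6.02214076e23 / (entry$molar_mass * 1e6)
    expect_equal(total, cfg$I_r * entry$k * n_ft * cfg$t_r,
                 tolerance = 1e-12, label = entry$compound)
  }
})

test_that("unknown compounds are rejected", {
  samp <- headspace_sample(c(unobtainium = 1))
  expect_error(expected_spectrum_rates(samp, default_study_config(), lib),
               "unobtainium")
})

test_that("simulation is deterministic under a fixed seed", {
  samp <- profile_sample("4", "anaerobic")
  cfg <- default_study_config(seed = 123)
  a <- simulate_spectrum(samp, cfg, lib, "O2+")
  b <- simulate_spectrum(samp, cfg, lib, "O2+")
  expect_identical(a, b)
  expect_identical(a$meta$seed, 123L)
})

test_that("zero input gives a zero spectrum when background is off", {
  cfg <- default_study_config(background = 1e-12, seed = 1)
  cfg$background <- 0
  samp <- headspace_sample(c(chloroform = 0))
  sp <- simulate_spectrum(samp, cfg, lib, "O2+")
  expect_identical(length(sp$counts), 0L)
})

test_that("observed isotopologue ratio matches the 9:6 envelope (Poisson)", {
  # chloroform-only sample scaled so the m/z 83 mean is >= 1e4 counts:
  # the 83:85 count ratio must sit within 3 sigma of 9/6 = 1.5
  chf <- library_entry(lib, "chloroform", "O2+")
  cfg <- default_study_config(seed = 17)
  cfg$background <- 0
  rate_1mg <- sum(expected_channel_rate(1, chf, config = cfg))
  conc <- 2e4 / rate_1mg
  samp <- headspace_sample(c(chloroform = conc))
  sp <- simulate_spectrum(samp, cfg, lib, "O2+")
  n83 <- spectrum_counts(sp, 83); n85 <- spectrum_counts(sp, 85)
  ratio <- n83 / n85
  sd_ratio <- 1.5 * sqrt(1 / (2e4 * 0.5625) + 1 / (2e4 * 0.375))
  expect_lt(abs(ratio - 1.5), 3 * sd_ratio)
})

test_that("empirical Poisson means converge to the expected rates", {
  chf <- library_entry(lib, "chloroform", "O2+")
  cfg <- default_study_config()
  samp <- headspace_sample(c(chloroform = 2))
  expected <- expected_spectrum_rates(samp, cfg, lib, "O2+")
  lambda83 <- expected[["83"]] + cfg$background
  set.seed(29)
  n_draws <- 400
  draws <- vapply(seq_len(n_draws), function(i) {
    cfg$seed <- sample.int(2^31 - 1, 1)
    spectrum_counts(simulate_spectrum(samp, cfg, lib, "O2+"), 83)
  }, numeric(1))
  se <- sqrt(lambda83 / n_draws)
  expect_lt(abs(mean(draws) - lambda83), 3 * se)
})

test_that("the default study has the right shape and composition", {
  design <- default_study_design()
  spectra <- simulate_study(design, default_study_config(), lib, seed = 5)
  # 5 groups x 2 conditions x 3 replicates x 3 reagent ions
  expect_identical(length(spectra), 90L)
  params <- detection_params()
  for (sp in spectra) {
    if (sp$meta$group == "control" && sp$reagent == "O2+") {
      # no dichloromethyl triplet above LOD in control spectra
      expect_true(all(spectrum_counts(sp, c(83, 85, 87)) <= params$lod))
    }
    if (sp$meta$group %in% c("1", "2", "3", "4") && sp$reagent == "H3O+") {
      # acetonitrile hydrate ladder present in hypochlorite groups
      expect_true(all(spectrum_counts(sp, c(42, 60, 78, 96)) > params$lod))
    }
  }
  # replicate determinism of the whole study
  spectra2 <- simulate_study(design, default_study_config(), lib, seed = 5)
  expect_identical(unclass(spectra), unclass(spectra2))
})
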