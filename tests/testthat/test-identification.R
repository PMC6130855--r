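lib <- default_library()

test_that("the reference two-chlorine triplet is detected", {
  sp <- sift_spectrum(c(`83` = 1644, `85` = 1342, `87` = 152), "O2+")
  hits <- detect_chlorine_patterns(sp)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$base_mz, 83L)
  expect_identical(hits$n_cl, 2L)
  expect_true(hits$passes)
  # deviations by direct arithmetic from the counts:
  # fractions 1644/3138, 1342/3138, 152/3138 vs 0.5625/0.375/0.0625
  obs <- c(1644, 1342, 152) / 3138
  expect_equal(hits$observed_fractions[[1]], obs)
  expect_equal(hits$max_abs_deviation,
               max(abs(obs - c(0.5625, 0.375, 0.0625))))
  expect_lt(hits$max_abs_deviation, 0.06)
})

test_that("an exact 3:1 doublet is a one-chlorine hit", {
  sp <- sift_spectrum(c(`83` = 900, `85` = 300), "O2+")
  hits <- detect_chlorine_patterns(sp)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$n_cl, 1L)
  expect_equal(hits$max_abs_deviation, 0)
})

test_that("a 1:1 doublet yields no passing hit at the default tolerance", {
  sp <- sift_spectrum(c(`83` = 500, `85` = 500), "O2+")
  expect_identical(nrow(detect_chlorine_patterns(sp)), 0L)
  # the failing candidates are still inspectable
  all_cand <- detect_chlorine_patterns(sp, keep_failing = TRUE)
  expect_true(all(!all_cand$passes))
})

test_that("two-chlorine interpretation wins over nested one-chlorine", {
  # a clean 9:6:1 triplet also contains a candidate 85/87 doublet; the
  # larger chlorine count must absorb the overlapping peaks
  sp <- sift_spectrum(c(`83` = 900, `85` = 600, `87` = 100), "O2+")
  hits <- detect_chlorine_patterns(sp)
  expect_identical(hits$n_cl, 2L)
  expect_identical(nrow(hits), 1L)
})

test_that("detection is invariant to uniform count scaling", {
  base <- c(`83` = 931, `85` = 487, `87` = 112)
  h1 <- detect_chlorine_patterns(sift_spectrum(base, "O2+"))
  h2 <- detect_chlorine_patterns(sift_spectrum(base * 10, "O2+"))
  expect_identical(h1$n_cl, h2$n_cl)
  expect_equal(h1$max_abs_deviation, h2$max_abs_deviation)
})

test_that("non-O2+ spectra are analysed with a warning", {
  sp <- sift_spectrum(c(`83` = 900, `85` = 300), "H3O+")
  expect_warning(hits <- detect_chlorine_patterns(sp), "O2\\+")
  expect_identical(nrow(hits), 1L)
})

test_that("all experimental reference triplets pass, controls never", {
  ref <- reference_chcl2_counts()
  for (i in seq_len(nrow(ref))) {
    counts <- c(ref$mz83[i], ref$mz85[i], ref$mz87[i])
    if (anyNA(counts)) {  # control rows: non-detectable
      sp <- sift_spectrum(numeric(0), "O2+")
      expect_identical(nrow(detect_chlorine_patterns(sp)), 0L)
    } else {
      sp <- sift_spectrum(stats::setNames(counts, c(83, 85, 87)), "O2+")
      hits <- detect_chlorine_patterns(sp)
      expect_identical(hits$n_cl, 2L,
                       label = paste("group", ref$group[i], ref$condition[i]))
      expect_true(hits$passes)
    }
  }
})

test_that("hydrate ladders are maximal 18-spaced chains", {
  sp <- sift_spectrum(c(`42` = 900, `60` = 300, `78` = 90, `96` = 30),
                      "H3O+")
  ser <- detect_hydrate_series(sp, library = lib)
  expect_identical(nrow(ser), 1L)
  expect_identical(ser$base_mz, 42L)
  expect_identical(ser$n_members, 4L)
  expect_identical(ser$candidates, "acetonitrile")

  two <- detect_hydrate_series(
    sift_spectrum(c(`88` = 50, `106` = 20), "H3O+"), library = lib)
  expect_identical(two$base_mz, 88L)
  expect_identical(two$n_members, 2L)
  expect_identical(two$candidates, "pentylamine|butyramide")
})

test_that("a below-LOD gap breaks a hydrate chain", {
  sp <- sift_spectrum(c(`42` = 900, `78` = 90), "H3O+")
  expect_identical(nrow(detect_hydrate_series(sp)), 0L)
  # the gap member present but below LOD still breaks the chain
  sp2 <- sift_spectrum(c(`42` = 900, `60` = 2, `78` = 90), "H3O+")
  expect_identical(nrow(detect_hydrate_series(sp2)), 0L)
})

test_that("assignment covers every peak and preserves ambiguity", {
  empty <- assign_compounds(sift_spectrum(numeric(0), "H3O+"), lib)
  expect_identical(nrow(empty), 0L)

  amb <- assign_compounds(sift_spectrum(c(`88` = 60, `106` = 25), "H3O+"),
                          lib)
  expect_identical(unique(amb$compounds), "pentylamine|butyramide")
  expect_true(all(!amb$unambiguous))
  expect_identical(unique(amb$evidence), "hydrate_series")

  # a simulated group-4 O2+ spectrum assigns chloroform unambiguously
  sp <- simulate_spectrum(profile_sample("4", "aerobic"),
                          default_study_config(seed = 41), lib, "O2+")
  asg <- assign_compounds(sp, lib)
  chf <- asg[asg$compounds %in% "chloroform", ]
  expect_setequal(chf$mz, c(83L, 85L, 87L))
  expect_true(all(chf$unambiguous))
  expect_identical(unique(chf$evidence), "cl_pattern")
  # everything above LOD is either assigned or explicitly unassigned
  expect_true(all(asg$evidence %in%
                  c("cl_pattern", "hydrate_series", "library",
                    "unassigned")))
})

test_that("detection parameter validation", {
  expect_error(detection_params(cl_tolerance = 0.6), "0, 0.5")
  expect_error(detection_params(background_mean = -1), ">= 0")
  expect_identical(detection_params(background_mean = 1)$lod, 4)
})
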