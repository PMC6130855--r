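test_that("replicate aggregation mirrors the mean[range] convention", {
  two <- aggregate_replicates(c(0.048, 0.065))
  expect_equal(two$mean, (0.048 + 0.065) / 2)
  expect_equal(c(two$min, two$max), c(0.048, 0.065))
  expect_identical(two$label, "0.057[0.048-0.065]")

  allnd <- aggregate_replicates(c(NA_real_, NA_real_, NA_real_))
  expect_true(allnd$all_nd)
  expect_identical(allnd$label, "n/d")
  expect_identical(allnd$n_detected, 0L)

  # a single non-detect counts as zero in the mean and as n/d in the range
  mix <- aggregate_replicates(c(NA, 0.017, 0.010))
  expect_equal(mix$mean, (0.017 + 0.010) / 3)
  expect_match(mix$label, "n/d-0.017", fixed = TRUE)

  flat <- aggregate_replicates(c(0.1, 0.1, 0.1))
  expect_equal(flat$mean, 0.1)
  expect_identical(flat$label, "0.100[0.100-0.100]")

  expect_error(aggregate_replicates(numeric(0)), "at least one")
})

test_that("reference count table exposes non-detects as NA", {
  ref <- reference_chcl2_counts()
  expect_identical(nrow(ref), 10L)
  ctl <- ref[ref$group == "control", ]
  expect_true(all(is.na(ctl$mz83)))
  expect_identical(sum(!is.na(ref$mz83)), 8L)
  expect_equal(ref$chcl3_mg_per_L[ref$group == "4" &
                                  ref$condition == "aerobic"], 3.474)
})

test_that("the default study pipeline reproduces the study's structure", {
  report <- run_study(default_study_design(replicates = 2), seed = 21,
                      n_perm = 199)
  s <- report$summary
  # chloroform and acetonitrile: absent in control, present in groups 1-4
  for (cd in c("aerobic", "anaerobic")) {
    expect_identical(s$label[s$group == "control" & s$condition == cd &
                             s$compound == "chloroform"], "n/d")
    expect_identical(s$label[s$group == "control" & s$condition == cd &
                             s$compound == "acetonitrile"], "n/d")
    for (g in c("1", "2", "3", "4")) {
      acn <- s[s$group == g & s$condition == cd &
               s$compound == "acetonitrile", ]
      expect_identical(acn$n_detected, acn$n)
      chf <- s[s$group == g & s$condition == cd &
               s$compound == "chloroform", ]
      expect_identical(chf$n_detected, chf$n)
    }
  }
  # triplet table: control n/d, experimental cells carry percentages
  trip <- report$cl_triplet
  expect_true(all(is.na(trip$mz83[trip$group == "control"])))
  expe <- trip[trip$group != "control", ]
  expect_true(all(!is.na(expe$pct83)))
  # replicate summaries respect min <= mean <= max where fully detected
  full <- s[s$n_detected == s$n & s$n_detected > 0, ]
  expect_true(all(full$min <= full$mean + 1e-12 &
                  full$mean <= full$max + 1e-12))
})

test_that("identical seed and configuration give identical reports", {
  r1 <- run_study(default_study_design(replicates = 2), seed = 8,
                  n_perm = 99)
  r2 <- run_study(default_study_design(replicates = 2), seed = 8,
                  n_perm = 99)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$cl_triplet, r2$cl_triplet)
  expect_identical(r1$comparison$per_compound, r2$comparison$per_compound)
  expect_identical(r1$concentrations, r2$concentrations)
})

test_that("the analysis is reproducible from saved spectrum files alone", {
  out <- tempfile("studyrun")
  report <- run_study(default_study_design(replicates = 2), seed = 13,
                      n_perm = 99, out_dir = out)
  expect_true(file.exists(file.path(out, "run_log.txt")))
  expect_true(file.exists(file.path(out, "condition_comparison.json")))
  reloaded <- analyze_study(file.path(out, "spectra"),
                            config = default_study_config(),
                            n_perm = 99, seed = 13 + 1L)
  expect_identical(reloaded$summary, report$summary)
  expect_identical(reloaded$cl_triplet, report$cl_triplet)
  expect_identical(reloaded$comparison$per_compound,
                   report$comparison$per_compound)
})

test_that("an anaerobic acetone excess is flagged, and only acetone", {
  # three-compound design: acetone 4x higher anaerobically in groups 1-3
  # (as in the emulated study's concentration table), everything else
  # identical between conditions
  groups <- c("control", "1", "2", "3", "4")
  profiles <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("aerobic", "anaerobic"), function(cd) {
      acetone <- if (g %in% c("1", "2", "3") && cd == "anaerobic")
        0.4 else 0.1
      data.frame(group = g, condition = cd,
                 compound = c("acetone", "ethanol", "ammonia"),
                 mean_mg_per_L = c(acetone, 0.08, 0.3))
    }))
  }))
  design <- study_design(profiles, replicates = 3, check = FALSE)
  n_runs <- 20
  flagged <- matrix(FALSE, n_runs, 3,
                    dimnames = list(NULL, c("acetone", "ethanol",
                                            "ammonia")))
  for (i in seq_len(n_runs)) {
    spectra <- simulate_study(design, default_study_config(),
                              seed = 1000 + i, reagents = "H3O+")
    rep_i <- analyze_study(spectra, config = default_study_config(),
                           n_perm = 499, seed = 2000 + i)
    pc <- rep_i$comparison$per_compound
    for (cmp in colnames(flagged))
      flagged[i, cmp] <- pc$significant[pc$compound == cmp]
  }
  expect_gte(sum(flagged[, "acetone"]), 16)  # high power for a 4x shift
  expect_lte(sum(flagged[, "ethanol"]), 4)   # null compounds stay quiet
  expect_lte(sum(flagged[, "ammonia"]), 4)
})
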