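# Forward kinetic model of SIFT-MS: headspace composition -> expected
# product-ion count rates -> Poisson-noisy unit-resolution spectra, for the
# whole two-condition, five-group study design.

.AVOGADRO <- 6.02214076e23

#' Instrument configuration for the forward model
#'
#' Parameters of the pseudo-first-order (low-depletion) SIFT-MS kinetics.
#' Headspace gas enters the helium carrier through a calibrated capillary;
#' `phi` is the effective dilution of headspace analyte into the flow tube.
#'
#' @param I_r Reagent-ion count rate, counts/s.
#' @param t_r Reaction time in the flow tube, s.
#' @param phi Effective headspace dilution fraction in the carrier gas
#'   (dimensionless, in (0, 1)). See [default_study_config()] for the value
#'   used when emulating the study's count scale.
#' @param temperature Headspace temperature, K (37 C incubation).
#' @param pressure Headspace pressure, Pa.
#' @param background Mean background count rate per m/z channel, counts/s.
#' @param seed RNG seed; recorded in simulated spectra. `NULL` leaves the
#'   RNG stream untouched.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(I_r = 1e6, t_r = 1e-3, phi = 0.01,
                              temperature = 310.15, pressure = 101325,
                              background = 1, seed = NULL) {
  vals <- c(I_r = I_r, t_r = t_r, phi = phi, temperature = temperature,
            pressure = pressure)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0L)
    stop("instrument parameters must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (phi >= 1) stop("phi must lie in (0, 1)", call. = FALSE)
  if (!is.finite(background) || background < 0)
    stop("background must be >= 0", call. = FALSE)
  structure(
    list(I_r = I_r, t_r = t_r, phi = phi, temperature = temperature,
         pressure = pressure, background = background, seed = seed),
    class = "instrument_config"
  )
}

#' Instrument configuration matching the emulated study's count scale
#'
#' Identical to [instrument_config()] except that the effective dilution
#' `phi` is set to `1e-7`, which folds the capillary sample-flow fraction
#' and the roughly three-orders-of-magnitude pressure drop from the
#' atmospheric headspace to the ~1 mbar flow tube into a single factor.
#' With the default kinetics library this places product-ion count rates
#' for analytes at a few mg/L in the 10^2-10^3 counts/s range, the scale
#' of the dichloromethyl ion counts the study design emulates.
#'
#' @param ... Passed on to [instrument_config()] to override defaults.
#' @return An `instrument_config`.
#' @export
default_study_config <- function(...) {
  args <- list(...)
  if (is.null(args$phi)) args$phi <- 1e-7
  do.call(instrument_config, args)
}

# Headspace number density (molecules per cm^3) of an analyte at
# `conc` mg per litre of headspace gas: mg/L = 1e-6 g/cm^3.
headspace_number_density <- function(conc_mg_per_L, molar_mass) {
  conc_mg_per_L * .AVOGADRO / (molar_mass * 1e6)
}

#' Default hydrate partition for hydrating channels
#'
#' Fractions of a hydrating channel's flux appearing as the bare ion and
#' its mono-, di- and trihydrate under humid hydronium chemistry; a
#' decreasing ladder. Exact humidity partitioning is sample dependent, so
#' these are generator defaults, not measured values.
#' @format Numeric vector of length 4 summing to 1.
#' @export
DEFAULT_HYDRATE_FRACTIONS <- c(0.4, 0.3, 0.2, 0.1)

#' A headspace sample for simulation
#'
#' @param composition Named numeric vector: compound -> headspace
#'   concentration in mg per litre of headspace gas (>= 0). Names must
#'   match kinetics-library compounds.
#' @param hydrate_fractions Fractions f0..f3 of each hydrating channel's
#'   flux carried by the 0..3-water cluster ions; must sum to 1.
#' @param sample_id,group,condition,replicate Metadata as in
#'   [sift_spectrum()].
#' @return An object of class `headspace_sample`.
#' @export
headspace_sample <- function(composition,
                             hydrate_fractions = DEFAULT_HYDRATE_FRACTIONS,
                             sample_id = NA_character_,
                             group = NA_character_,
                             condition = NA_character_,
                             replicate = NA_integer_) {
  if (length(composition) > 0L &&
      (is.null(names(composition)) || any(!nzchar(names(composition)))))
    stop("composition must be a named compound -> mg/L map", call. = FALSE)
  if (any(composition < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (length(hydrate_fractions) != 4L ||
      abs(sum(hydrate_fractions) - 1) > 1e-9 || any(hydrate_fractions < 0))
    stop("hydrate_fractions must be 4 non-negative values summing to 1",
         call. = FALSE)
  structure(
    list(composition = composition, hydrate_fractions = hydrate_fractions,
         meta = list(sample_id = sample_id, group = group,
                     condition = condition,
                     replicate = as.integer(replicate))),
    class = "headspace_sample"
  )
}

#' Expected product-ion count rates for one channel
#'
#' The pseudo-first-order forward model. The headspace number density
#' n_hs = c N_A / (M 1e6) (mg/L -> molecules/cm^3) is diluted into the
#' flow tube, n_ft = phi n_hs, and the total product-ion rate is
#' I_p = I_r k n_ft t_r (low-depletion limit). One channel's flux is
#' I_p x branching, spread over its chlorine isotopologues (binomial
#' envelope) and, for hydrating channels, the water-cluster ladder.
#' Background is not included; rates from distinct compounds sharing an
#' m/z simply add.
#'
#' @param concentration Headspace concentration, mg/L (>= 0).
#' @param entry A `kinetics_entry` (supplies `k` and `molar_mass`).
#' @param channel One row of `entry$channels`; default the first.
#' @param config An [instrument_config()].
#' @param hydrate_fractions See [headspace_sample()].
#' @param p_heavy Heavy-chlorine probability for the isotopologue envelope.
#' @return Named numeric vector: m/z -> expected count rate (counts/s).
#' @export
expected_channel_rate <- function(concentration, entry,
                                  channel = entry$channels[1, ],
                                  config = instrument_config(),
                                  hydrate_fractions = DEFAULT_HYDRATE_FRACTIONS,
                                  p_heavy = 0.25) {
  if (length(concentration) != 1L || !is.finite(concentration) ||
      concentration < 0)
    stop("concentration must be a single non-negative number", call. = FALSE)
  n_ft <- config$phi * headspace_number_density(concentration,
                                                entry$molar_mass)
  I_p <- config$I_r * entry$k * n_ft * config$t_r
  env <- chlorine_envelope(channel$base_mz, channel$n_chlorine,
                           p_heavy = p_heavy)
  wat_frac <- if (isTRUE(channel$hydrates)) hydrate_fractions else 1
  grid <- expand.grid(iso = seq_along(env$fractions),
                      wat = seq_along(wat_frac))
  mz <- env$mz_values[grid$iso] + 18L * (grid$wat - 1L)
  rate <- I_p * channel$branching * env$fractions[grid$iso] *
    wat_frac[grid$wat]
  out <- tapply(rate, mz, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Expected spectrum (all compounds, one reagent ion)
#'
#' Sums [expected_channel_rate()] over every compound of a sample with a
#' library entry under the given reagent ion, adding rates where channels
#' share an m/z. Compounds with no entry under this reagent contribute
#' nothing (e.g. chloroform under H3O+). Background is not included.
#'
#' @param sample A [headspace_sample()].
#' @param config An [instrument_config()].
#' @param library A `kinetics_library`.
#' @param reagent Reagent ion.
#' @param p_heavy Heavy-chlorine probability.
#' @return Named numeric vector m/z -> expected count rate; zero-length if
#'   nothing reacts.
#' @export
expected_spectrum_rates <- function(sample, config = instrument_config(),
                                    library = default_library(),
                                    reagent = "H3O+", p_heavy = 0.25) {
  total <- numeric(0)
  for (compound in names(sample$composition)) {
    entry <- library_entry(library, compound, reagent)
    if (is.null(entry)) {
      any_entry <- any(vapply(library, function(e) e$compound == compound,
                              logical(1)))
      if (!any_entry)
        stop("compound not in kinetics library: ", compound, call. = FALSE)
      next
    }
    for (i in seq_len(nrow(entry$channels))) {
      r <- expected_channel_rate(sample$composition[[compound]], entry,
                                 entry$channels[i, ], config,
                                 sample$hydrate_fractions, p_heavy)
      for (mz in names(r))
        total[mz] <- (if (mz %in% names(total)) total[[mz]] else 0) + r[[mz]]
    }
  }
  if (length(total) > 0L)
    total <- total[order(as.integer(names(total)))]
  total
}

#' Simulate one spectrum
#'
#' Every m/z channel in the scan range receives an observed count drawn
#' from a Poisson law with mean = expected analyte rate + background
#' (`noise = TRUE`), or exactly that mean (`noise = FALSE`, for
#' noise-free round-trip checks). When `config$seed` is set the RNG is
#' seeded first, so reruns are bitwise identical; the seed is recorded in
#' the spectrum metadata.
#'
#' @inheritParams expected_spectrum_rates
#' @param noise Draw Poisson counts (default) or return exact means.
#' @return A `sift_spectrum` with the reagent-ion record attached
#'   (`reagent_count_rate = config$I_r`).
#' @export
simulate_spectrum <- function(sample, config = instrument_config(),
                              library = default_library(),
                              reagent = "H3O+", p_heavy = 0.25,
                              noise = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  scan <- .DEFAULT_SCAN_RANGE
  mz_all <- scan[1]:scan[2]
  lambda <- rep(config$background, length(mz_all))
  names(lambda) <- mz_all
  rates <- expected_spectrum_rates(sample, config, library, reagent, p_heavy)
  keep <- names(rates)[as.integer(names(rates)) >= scan[1] &
                       as.integer(names(rates)) <= scan[2]]
  lambda[keep] <- lambda[keep] + rates[keep]
  counts <- if (noise) stats::rpois(length(lambda), lambda) else lambda
  names(counts) <- mz_all
  sift_spectrum(counts[counts > 0], reagent,
                sample_id = sample$meta$sample_id,
                group = sample$meta$group,
                condition = sample$meta$condition,
                replicate = sample$meta$replicate,
                reagent_count_rate = config$I_r,
                scan_range = scan,
                seed = if (is.null(config$seed)) NA_integer_
                       else as.integer(config$seed))
}

#' Study design: groups x conditions x replicates
#'
#' Defines the simulated study layout: a control group and experimental
#' groups 1-4, each incubated aerobically and anaerobically in
#' `replicates` replicates, with per-cell mean concentration profiles and
#' a lognormal replicate-to-replicate coefficient of variation. The
#' control profile must contain neither chloroform nor acetonitrile
#' (hypochlorite reaction products); groups 1-4 must contain both.
#'
#' @param profiles Data.frame with columns `group`, `condition`,
#'   `compound`, `mean_mg_per_L`.
#' @param replicates Replicates per group x condition cell.
#' @param cv Lognormal coefficient of variation of replicate
#'   concentrations around the cell mean.
#' @param check Validate the control/experimental composition invariants.
#' @return An object of class `study_design`.
#' @seealso [default_study_design()]
#' @export
study_design <- function(profiles, replicates = 3, cv = 0.35, check = TRUE) {
  need <- c("group", "condition", "compound", "mean_mg_per_L")
  if (!all(need %in% names(profiles)))
    stop("profiles must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (replicates < 1 || replicates != round(replicates))
    stop("replicates must be a positive integer", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (check) {
    ctl <- profiles[profiles$group == "control" & profiles$mean_mg_per_L > 0, ]
    if (any(ctl$compound %in% c("chloroform", "acetonitrile")))
      stop("control profile must contain no chloroform and no acetonitrile",
           call. = FALSE)
    for (g in setdiff(unique(profiles$group), "control")) {
      gp <- profiles[profiles$group == g & profiles$mean_mg_per_L > 0, ]
      if (!all(c("chloroform", "acetonitrile") %in% gp$compound))
        stop("experimental group ", g,
             " must contain chloroform and acetonitrile", call. = FALSE)
    }
  }
  structure(
    list(profiles = profiles,
         groups = unique(profiles$group),
         conditions = unique(profiles$condition),
         replicates = as.integer(replicates),
         cv = cv),
    class = "study_design"
  )
}

#' Default group concentration profiles
#'
#' Mean headspace concentrations (mg/L) per group and incubation
#' condition used by the default study design: the biogenic compounds
#' common to biological media in all groups, and acetonitrile plus
#' chloroform (and the two minor nitrogen-compound candidate sets) only
#' in the hypochlorite-containing groups 1-4.
#'
#' @return Data.frame `group`, `condition`, `compound`, `mean_mg_per_L`.
#' @export
default_group_profiles <- function() {
  utils::read.csv(
    system.file("extdata", "group_voc_profiles.csv", package = "siftvoc",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' The default study design
#'
#' [study_design()] built from [default_group_profiles()] with triplicate
#' samples per cell and a lognormal replicate CV of 0.35 (wide
#' replicate-to-replicate spreads are characteristic of headspace
#' measurements of reacting samples).
#'
#' @param replicates,cv Override the defaults.
#' @return A `study_design`.
#' @export
default_study_design <- function(replicates = 3, cv = 0.35) {
  study_design(default_group_profiles(), replicates = replicates, cv = cv)
}

#' Simulate a whole study
#'
#' Draws replicate headspace compositions for every group x condition cell
#' (lognormal variation with the design's CV around the cell means, mean
#' preserved) and simulates one spectrum per replicate under each
#' requested reagent ion. All randomness flows from `seed`: replicate
#' composition draws and per-spectrum sub-seeds are taken from one seeded
#' stream, so identical seed + design + config give bitwise-identical
#' output.
#'
#' @param design A [study_design()].
#' @param config An [instrument_config()]; default [default_study_config()].
#' @param library A `kinetics_library`.
#' @param seed Integer master seed.
#' @param reagents Reagent ions to scan; default all three.
#' @return A list of `sift_spectrum` (class `sift_study`), ordered by
#'   group, condition, replicate, reagent.
#' @export
simulate_study <- function(design = default_study_design(),
                           config = default_study_config(),
                           library = default_library(),
                           seed = 1L,
                           reagents = .REAGENT_IONS) {
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + design$cv^2))
  spectra <- list()
  cells <- unique(design$profiles[, c("group", "condition")])
  for (i in seq_len(nrow(cells))) {
    g <- cells$group[i]; cond <- cells$condition[i]
    prof <- design$profiles[design$profiles$group == g &
                            design$profiles$condition == cond, ]
    means <- stats::setNames(prof$mean_mg_per_L, prof$compound)
    for (rep_i in seq_len(design$replicates)) {
      # lognormal multiplier with unit mean: meanlog = -sdlog^2 / 2
      mult <- stats::rlnorm(length(means), meanlog = -sdlog^2 / 2,
                            sdlog = sdlog)
      conc <- means * mult
      samp <- headspace_sample(
        conc,
        sample_id = sprintf("g%s-%s-r%d", g, cond, rep_i),
        group = g, condition = cond, replicate = rep_i)
      for (rg in reagents) {
        sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        cfg <- config
        cfg$seed <- sub_seed
        spectra[[length(spectra) + 1L]] <-
          simulate_spectrum(samp, cfg, library, rg)
        # re-seed the master stream so the sub-seeded draw does not
        # perturb subsequent replicate draws
        set.seed(sub_seed)
      }
    }
  }
  structure(spectra, class = "sift_study",
            design = design, config = config, seed = seed)
}

#' @export
print.sift_study <- function(x, ...) {
  cat(sprintf("<sift_study> %d spectra (seed %s)\n", length(x),
              attr(x, "seed")))
  invisible(x)
}
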