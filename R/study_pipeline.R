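# End-to-end orchestration: simulate (or load) a study, analyse every
# spectrum, aggregate replicates into summary tables, and compare aerobic
# against anaerobic incubation with a stratified permutation test.

#' Reference dichloromethyl ion count data
#'
#' The m/z 83/85/87 count-rate triplets, their printed relative
#' percentages and the chloroform concentrations reported per group and
#' incubation condition in the root-canal irrigant headspace study this
#' package emulates. Non-detectable cells ("n/d", the two control rows)
#' are returned as `NA`.
#'
#' @return Data.frame with columns `group`, `condition`, `mz83`, `mz85`,
#'   `mz87`, `pct83`, `pct85`, `pct87`, `chcl3_mg_per_L`.
#' @export
reference_chcl2_counts <- function() {
  df <- utils::read.csv(
    system.file("extdata", "chcl2_reference_counts.csv",
                package = "siftvoc", mustWork = TRUE),
    stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c("group", "condition")))
    df[[col]] <- suppressWarnings(as.numeric(ifelse(df[[col]] == "n/d",
                                                    NA, df[[col]])))
  df
}

#' Aggregate replicate concentrations into a summary entry
#'
#' Mean and range over the replicates of one group x condition x compound
#' cell. Non-detectable replicates (passed as `NA`) count as zero in the
#' mean; the range covers detected replicates only, and the printed label
#' shows "n/d" as the lower bound whenever any replicate was below the
#' limit of detection (e.g. `"0.009[n/d-0.017]"`). A cell with no
#' detected replicate is reported as `"n/d"`.
#'
#' @param values Numeric vector of replicate concentrations; `NA` means
#'   non-detectable.
#' @return List with `mean`, `min`, `max` (NA when all non-detectable),
#'   `n_detected`, `n`, `all_nd`, and the formatted `label`.
#' @examples
#' aggregate_replicates(c(0.048, 0.065))
#' aggregate_replicates(c(NA, NA, NA))
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L)
    stop("at least one replicate is required", call. = FALSE)
  detected <- values[!is.na(values)]
  n <- length(values)
  if (length(detected) == 0L)
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_,
                n_detected = 0L, n = n, all_nd = TRUE, label = "n/d"))
  m <- sum(detected) / n  # n/d counted as 0
  lo <- min(detected); hi <- max(detected)
  any_nd <- anyNA(values)
  label <- sprintf("%.3f[%s-%.3f]", m,
                   if (any_nd) "n/d" else sprintf("%.3f", lo), hi)
  list(mean = m, min = lo, max = hi, n_detected = length(detected),
       n = n, all_nd = FALSE, label = label)
}

#' Compare aerobic and anaerobic conditions
#'
#' Per-compound stratified permutation test of the aerobic/anaerobic
#' contrast, with per-group concentration ratios. The test statistic is
#' the mean, over groups, of the difference between condition means of
#' replicate concentrations; condition labels are shuffled within each
#' group (a group-stratified permutation, so group-to-group level
#' differences cannot masquerade as condition effects), and the two-sided
#' p-value is `(1 + #{|T*| >= |T|}) / (n_perm + 1)`. Per-group
#' anaerobic/aerobic mean ratios carry a bootstrap percentile interval
#' (replicates resampled within each condition). Benjamini-Hochberg
#' adjustment across compounds is reported alongside the raw p-values.
#'
#' @param concentrations Data.frame with columns `group`, `condition`
#'   (`"aerobic"`/`"anaerobic"`), `replicate`, `compound`,
#'   `concentration` (`NA` = non-detectable, treated as 0).
#' @param n_perm Number of label permutations (>= 999 recommended).
#' @param n_boot Bootstrap resamples for the ratio intervals.
#' @param alpha Nominal significance level.
#' @param seed Optional RNG seed for the permutations and bootstrap.
#' @return An object of class `condition_comparison`: list with
#'   `per_compound` (compound, statistic, p_value, p_adjusted,
#'   significant) and `per_group` (compound, group, ratio, lo, hi).
#' @export
compare_conditions <- function(concentrations, n_perm = 999, n_boot = 999,
                               alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- concentrations
  conc$concentration[is.na(conc$concentration)] <- 0
  compounds <- unique(conc$compound)
  groups <- unique(conc$group)
  per_compound <- list(); per_group <- list()
  for (cmp in compounds) {
    sub <- conc[conc$compound == cmp, ]
    # observed statistic and per-group value lists
    vals <- list(); labs <- list(); d_obs <- numeric(0)
    for (g in groups) {
      sg <- sub[sub$group == g, ]
      aer <- sg$concentration[sg$condition == "aerobic"]
      ana <- sg$concentration[sg$condition == "anaerobic"]
      if (length(aer) == 0L || length(ana) == 0L) next
      vals[[g]] <- c(aer, ana)
      labs[[g]] <- c(rep(FALSE, length(aer)), rep(TRUE, length(ana)))
      d_obs <- c(d_obs, mean(ana) - mean(aer))
      # ratio with bootstrap interval
      ratio <- if (mean(aer) > 0) mean(ana) / mean(aer) else NA_real_
      lo <- hi <- NA_real_
      if (!is.na(ratio) && n_boot > 0) {
        rb <- vapply(seq_len(n_boot), function(b) {
          a2 <- sample(aer, replace = TRUE)
          n2 <- sample(ana, replace = TRUE)
          if (mean(a2) > 0) mean(n2) / mean(a2) else NA_real_
        }, numeric(1))
        qs <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
        lo <- qs[1]; hi <- qs[2]
      }
      per_group[[length(per_group) + 1L]] <- data.frame(
        compound = cmp, group = g, ratio = ratio, lo = lo, hi = hi,
        stringsAsFactors = FALSE)
    }
    t_obs <- mean(d_obs)
    # stratified permutation null
    t_null <- vapply(seq_len(n_perm), function(b) {
      d <- vapply(names(vals), function(g) {
        v <- vals[[g]]
        lb <- sample(labs[[g]])
        mean(v[lb]) - mean(v[!lb])
      }, numeric(1))
      mean(d)
    }, numeric(1))
    p <- (1 + sum(abs(t_null) >= abs(t_obs))) / (n_perm + 1)
    per_compound[[length(per_compound) + 1L]] <- data.frame(
      compound = cmp, statistic = t_obs, p_value = p,
      stringsAsFactors = FALSE)
  }
  pc <- do.call(rbind, per_compound)
  pc$p_adjusted <- stats::p.adjust(pc$p_value, method = "BH")
  pc$significant <- pc$p_adjusted < alpha
  structure(
    list(per_compound = pc,
         per_group = if (length(per_group)) do.call(rbind, per_group)
                     else data.frame(compound = character(),
                                     group = character(), ratio = numeric(),
                                     lo = numeric(), hi = numeric()),
         n_perm = n_perm, alpha = alpha),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %d permutations, alpha = %.2f\n",
              x$n_perm, x$alpha))
  print(x$per_compound, row.names = FALSE)
  invisible(x)
}

# Locate one spectrum in a list by sample coordinates; NULL when absent.
find_spectrum <- function(spectra, group, condition, replicate, reagent) {
  for (sp in spectra) {
    m <- sp$meta
    if (identical(m$group, group) && identical(m$condition, condition) &&
        identical(m$replicate, as.integer(replicate)) &&
        identical(sp$reagent, reagent))
      return(sp)
  }
  NULL
}

#' Analyse a set of study spectra
#'
#' The analysis half of the pipeline, run on simulated spectra or on
#' spectra loaded from files (pass a directory of spectrum CSVs): every
#' compound of the kinetics library is quantified in every sample from
#' the spectrum of its library reagent ion, replicates are aggregated
#' into a concentration summary table, the m/z 83/85/87 dichloromethyl
#' triplet is tabulated with its relative percentages and chloroform
#' concentration, and the two incubation conditions are compared with
#' [compare_conditions()]. Reports depend only on the spectrum files'
#' content (counts, metadata, reagent-ion record) plus the analysis
#' configuration, never on simulator internals.
#'
#' @param spectra A `sift_study` / list of `sift_spectrum`, or a directory
#'   containing spectrum CSV files.
#' @param library A `kinetics_library`.
#' @param config [instrument_config()] used for the kinetic inversion.
#' @param params [detection_params()].
#' @param n_perm,alpha Passed to [compare_conditions()].
#' @param seed Seed for the permutation/bootstrap stream.
#' @return An object of class `sift_study_report`: list with
#'   `concentrations` (long replicate-level data.frame), `summary`
#'   (group x condition x compound means and ranges), `cl_triplet`
#'   (dichloromethyl counts, percentages and chloroform concentration per
#'   cell) and `comparison`.
#' @export
analyze_study <- function(spectra,
                          library = default_library(),
                          config = default_study_config(),
                          params = detection_params(
                            background_mean = config$background),
                          n_perm = 999, alpha = 0.05, seed = NULL) {
  if (is.character(spectra)) {
    files <- sort(list.files(spectra, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no spectrum CSV files found in ", spectra, call. = FALSE)
    spectra <- lapply(files, read_spectrum)
  }
  cells <- unique(do.call(rbind, lapply(spectra, function(sp)
    data.frame(group = sp$meta$group, condition = sp$meta$condition,
               replicate = sp$meta$replicate, stringsAsFactors = FALSE))))
  cells <- cells[order(cells$group, cells$condition, cells$replicate), ]
  # preferred entry per compound = first library occurrence
  compounds <- unique(vapply(library, function(e) e$compound, character(1)))
  entries <- lapply(compounds, function(cmp)
    library[[which(vapply(library, function(e) e$compound == cmp,
                          logical(1)))[1]]])
  names(entries) <- compounds
  conc_rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    for (cmp in compounds) {
      entry <- entries[[cmp]]
      sp <- find_spectrum(spectra, cell$group, cell$condition,
                          cell$replicate, entry$reagent)
      if (is.null(sp)) next
      res <- concentration_from_counts(sp, entry, config, params = params)
      conc_rows[[length(conc_rows) + 1L]] <- data.frame(
        group = cell$group, condition = cell$condition,
        replicate = cell$replicate, compound = cmp,
        concentration = if (res$n_d) NA_real_ else res$concentration,
        n_d = res$n_d, ambiguous = res$ambiguous,
        stringsAsFactors = FALSE)
    }
  }
  conc <- do.call(rbind, conc_rows)
  # summary table: mean and range per group x condition x compound
  sum_rows <- list()
  for (g in unique(conc$group)) for (cd in unique(conc$condition))
    for (cmp in unique(conc$compound)) {
      v <- conc$concentration[conc$group == g & conc$condition == cd &
                              conc$compound == cmp]
      if (length(v) == 0L) next
      agg <- aggregate_replicates(v)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        group = g, condition = cd, compound = cmp, mean = agg$mean,
        min = agg$min, max = agg$max, n_detected = agg$n_detected,
        n = agg$n, label = agg$label, stringsAsFactors = FALSE)
    }
  summary_tab <- do.call(rbind, sum_rows)
  # dichloromethyl triplet table from the O2+ spectra
  trip_rows <- list()
  cells2 <- unique(cells[, c("group", "condition")])
  for (i in seq_len(nrow(cells2))) {
    g <- cells2$group[i]; cd <- cells2$condition[i]
    reps <- cells$replicate[cells$group == g & cells$condition == cd]
    trip <- vapply(reps, function(r) {
      sp <- find_spectrum(spectra, g, cd, r, "O2+")
      if (is.null(sp)) rep(NA_real_, 3) else spectrum_counts(sp, c(83, 85, 87))
    }, numeric(3))
    if (all(is.na(trip))) next
    mean_counts <- rowMeans(trip, na.rm = TRUE)
    detected <- any(mean_counts > params$lod)
    pct <- if (detected) relative_percentages(mean_counts)
           else rep(NA_integer_, 3)
    chcl3 <- summary_tab$mean[summary_tab$group == g &
                              summary_tab$condition == cd &
                              summary_tab$compound == "chloroform"]
    trip_rows[[length(trip_rows) + 1L]] <- data.frame(
      group = g, condition = cd,
      mz83 = if (detected) mean_counts[1] else NA_real_,
      mz85 = if (detected) mean_counts[2] else NA_real_,
      mz87 = if (detected) mean_counts[3] else NA_real_,
      pct83 = pct[1], pct85 = pct[2], pct87 = pct[3],
      chcl3_mg_per_L = if (length(chcl3)) chcl3 else NA_real_,
      stringsAsFactors = FALSE)
  }
  cl_triplet <- do.call(rbind, trip_rows)
  comparison <- NULL
  if (length(unique(conc$condition)) == 2L)
    comparison <- compare_conditions(conc, n_perm = n_perm, alpha = alpha,
                                     seed = seed)
  structure(
    list(concentrations = conc, summary = summary_tab,
         cl_triplet = cl_triplet, comparison = comparison),
    class = "sift_study_report")
}

#' @export
print.sift_study_report <- function(x, ...) {
  cat("<sift_study_report>\n\nConcentration summary (mg/L):\n")
  print(x$summary[, c("group", "condition", "compound", "label")],
        row.names = FALSE)
  cat("\nDichloromethyl triplet (m/z 83/85/87):\n")
  print(x$cl_triplet, row.names = FALSE, digits = 4)
  if (!is.null(x$comparison)) {
    cat("\nAerobic vs anaerobic:\n")
    print(x$comparison$per_compound, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Run the full simulated study
#'
#' [simulate_study()] followed by [analyze_study()]. With `out_dir` set,
#' writes every spectrum CSV (under `out_dir/spectra/`), the summary and
#' triplet tables as CSV, the condition comparison as JSON, and a run log
#' recording the seed and parameters, so the analysis can be reproduced
#' from the saved files alone. Identical seed and configuration give
#' byte-identical outputs.
#'
#' @param design A [study_design()].
#' @param config An [instrument_config()].
#' @param params A [detection_params()].
#' @param library A `kinetics_library`.
#' @param seed Master seed for simulation; the analysis permutation
#'   stream is seeded with `seed + 1`.
#' @param n_perm,alpha Passed to [compare_conditions()].
#' @param out_dir Optional output directory.
#' @return A `sift_study_report` with the simulated spectra attached as
#'   `$spectra`.
#' @export
run_study <- function(design = default_study_design(),
                      config = default_study_config(),
                      params = detection_params(
                        background_mean = config$background),
                      library = default_library(),
                      seed = 1L, n_perm = 999, alpha = 0.05,
                      out_dir = NULL) {
  spectra <- simulate_study(design, config, library, seed = seed)
  report <- analyze_study(spectra, library = library, config = config,
                          params = params, n_perm = n_perm, alpha = alpha,
                          seed = seed + 1L)
  report$spectra <- spectra
  report$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "spectra"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_along(spectra)) {
      sp <- spectra[[i]]
      fname <- sprintf("%s_%s.csv", sp$meta$sample_id,
                       gsub("[^A-Za-z0-9]", "", sp$reagent))
      write_spectrum(sp, file.path(out_dir, "spectra", fname))
    }
    utils::write.csv(report$summary,
                     file.path(out_dir, "concentration_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(report$cl_triplet,
                     file.path(out_dir, "cl_triplet.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(per_compound = report$comparison$per_compound,
           per_group = report$comparison$per_group),
      file.path(out_dir, "condition_comparison.json"),
      dataframe = "rows", na = "null", digits = NA)
    writeLines(c(
      sprintf("seed: %d", seed),
      sprintf("permutation_seed: %d", seed + 1L),
      sprintf("n_perm: %d", n_perm),
      sprintf("alpha: %g", alpha),
      sprintf("replicates: %d", design$replicates),
      sprintf("cv: %g", design$cv),
      sprintf("I_r: %g", config$I_r),
      sprintf("t_r: %g", config$t_r),
      sprintf("phi: %g", config$phi),
      sprintf("background: %g", config$background),
      sprintf("lod: %g", params$lod),
      sprintf("cl_tolerance: %g", params$cl_tolerance)),
      file.path(out_dir, "run_log.txt"))
  }
  report
}
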