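# Inversion of the forward kinetics to headspace concentrations, relative
# percentage tables, and hypochlorite solution-chemistry helpers.

#' Molar mass of sodium hypochlorite, g/mol
#' @format A length-one numeric, 74.44.
#' @export
NAOCL_MOLAR_MASS <- 74.44

#' Headspace concentration from product-ion count rates
#'
#' Exact inverse of the forward model: all count rates on the compound's
#' expanded m/z set (every channel x chlorine isotopologue x hydrate) are
#' summed, the mean background is subtracted per channel, and the net
#' total I_p is converted back through the pseudo-first-order kinetics,
#' n_hs = I_p / (I_r k t_r phi), then to mg per litre of headspace gas
#' via the molar mass. Because branching fractions, envelope fractions
#' and hydrate fractions each sum to 1, the summed inverse does not
#' depend on how the flux was partitioned.
#'
#' A compound none of whose channels exceeds the limit of detection is
#' flagged non-detectable (`n_d = TRUE`, concentration `NA`), mirroring
#' the "n/d" notation of headspace studies; a negative net total after
#' background subtraction is clamped to non-detectable with a warning.
#'
#' @param counts Named numeric vector (m/z -> count rate) or a
#'   `sift_spectrum`.
#' @param entry The compound's `kinetics_entry`.
#' @param config The [instrument_config()] the spectrum was (or would have
#'   been) acquired under; supplies `k`-independent parameters `t_r` and
#'   `phi`, and the per-channel mean background.
#' @param I_r Reagent-ion count rate; defaults to the spectrum's recorded
#'   reagent-ion record, else `config$I_r`.
#' @param params A [detection_params()] supplying the LOD.
#' @return An object of class `concentration_result`: list with
#'   `compound`, `concentration` (mg/L, `NA` when non-detectable), `n_d`,
#'   `ambiguous` (TRUE for unresolved candidate sets), `channels` (the
#'   m/z set used) and `total_rate` (summed raw count rate).
#' @export
concentration_from_counts <- function(counts, entry,
                                      config = default_study_config(),
                                      I_r = NULL,
                                      params = detection_params(
                                        background_mean = config$background)) {
  if (inherits(counts, "sift_spectrum")) {
    if (is.null(I_r) && !is.na(counts$meta$reagent_count_rate))
      I_r <- counts$meta$reagent_count_rate
    counts <- stats::setNames(as.numeric(counts$counts),
                              names(counts$counts))
  }
  if (is.null(I_r)) I_r <- config$I_r
  if (!is.finite(I_r) || I_r <= 0)
    stop("I_r must be > 0", call. = FALSE)
  mz_set <- sort(unique(unlist(
    lapply(seq_len(nrow(entry$channels)),
           function(i) channel_mz_set(entry$channels[i, ])$mz))))
  obs <- rep(0, length(mz_set))
  idx <- match(as.character(mz_set), names(counts))
  obs[!is.na(idx)] <- as.numeric(counts[idx[!is.na(idx)]])
  total <- sum(obs)
  ambiguous <- grepl("|", entry$compound, fixed = TRUE)
  result <- function(conc, n_d) {
    structure(
      list(compound = entry$compound, concentration = conc, n_d = n_d,
           ambiguous = ambiguous, channels = mz_set, total_rate = total),
      class = "concentration_result")
  }
  if (!any(obs > params$lod)) return(result(NA_real_, TRUE))
  net <- total - length(mz_set) * config$background
  if (net < 0) {
    warning("background-subtracted total is negative for ",
            entry$compound, "; reporting n/d", call. = FALSE)
    return(result(NA_real_, TRUE))
  }
  n_hs <- net / (I_r * entry$k * config$t_r * config$phi)
  conc <- n_hs * entry$molar_mass * 1e6 / .AVOGADRO
  result(conc, FALSE)
}

#' @export
print.concentration_result <- function(x, ...) {
  val <- if (x$n_d) "n/d" else sprintf("%.3g mg/L", x$concentration)
  cat(sprintf("<concentration_result> %s: %s (channels %s)\n",
              x$compound, val, paste(x$channels, collapse = ",")))
  invisible(x)
}

#' Relative percentages of a count vector
#'
#' 100 x count / total, rounded half-up to integers. Rows are not forced
#' to sum to 100: rounding residue is left as printed in conventional
#' count-rate tables.
#'
#' @param counts Non-negative numeric vector with a positive sum.
#' @return Integer vector of the same length.
#' @examples
#' relative_percentages(c(1644, 1342, 152)) # 52 43 5
#' @export
relative_percentages <- function(counts) {
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) <= 0)
    stop("total count must be > 0", call. = FALSE)
  as.integer(floor(100 * counts / sum(counts) + 0.5))
}

#' Hypochlorite molarity from mass percent
#'
#' mol/L = 10 x percent / 74.44 for sodium hypochlorite: a x% w/v
#' solution carries 10x g/L. (Commercial labels often say "% v/v"; only
#' the w/v reading makes 2.5% correspond to 0.34 M.) Reported to two
#' decimals.
#'
#' @param percent Mass percent (% w/v), >= 0.
#' @param molar_mass Solute molar mass, g/mol.
#' @return Molarity, mol/L, rounded to 2 decimals.
#' @examples
#' molarity_from_percent_wv(2.5) # 0.34
#' @export
molarity_from_percent_wv <- function(percent, molar_mass = NAOCL_MOLAR_MASS) {
  if (any(percent < 0)) stop("percent must be >= 0", call. = FALSE)
  round(percent * 10 / molar_mass, 2)
}

#' @rdname molarity_from_percent_wv
#' @param molarity Molarity, mol/L, >= 0.
#' @return `percent_wv_from_molarity()`: mass percent, rounded to 2
#'   decimals.
#' @examples
#' percent_wv_from_molarity(1.474) # 10.97
#' @export
percent_wv_from_molarity <- function(molarity,
                                     molar_mass = NAOCL_MOLAR_MASS) {
  if (any(molarity < 0)) stop("molarity must be >= 0", call. = FALSE)
  round(molarity * molar_mass / 10, 2)
}

#' Hypochlorite molarity from an iodometric titration
#'
#' Standard iodine/thiosulfate determination. Hypochlorite liberates
#' iodine, OCl- + 2 I- + 2 H+ -> I2 + Cl- + H2O, and the iodine is
#' titrated, I2 + 2 S2O3^2- -> 2 I- + S4O6^2-, so each mole of
#' hypochlorite consumes two moles of thiosulfate:
#' M = (M_thio V_thio / 2) / V_aliquot x dilution_factor.
#'
#' @param v_thiosulfate Titre volume of thiosulfate, L (>= 0).
#' @param m_thiosulfate Thiosulfate molarity, mol/L (> 0).
#' @param v_aliquot Volume of the titrated hypochlorite aliquot, L (> 0).
#' @param dilution_factor Dilution applied to the stock before titration
#'   (> 0; 1 = none).
#' @return Hypochlorite molarity of the (undiluted) solution, mol/L.
#' @examples
#' titration_molarity(13.4e-3, 0.22, 1.00e-3) # 1.474
#' @export
titration_molarity <- function(v_thiosulfate, m_thiosulfate, v_aliquot,
                               dilution_factor = 1) {
  if (v_thiosulfate < 0)
    stop("v_thiosulfate must be >= 0", call. = FALSE)
  if (m_thiosulfate <= 0 || v_aliquot <= 0 || dilution_factor <= 0)
    stop("m_thiosulfate, v_aliquot and dilution_factor must be > 0",
         call. = FALSE)
  (m_thiosulfate * v_thiosulfate / 2) / v_aliquot * dilution_factor
}
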