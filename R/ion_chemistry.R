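# Nominal-mass arithmetic, chlorine isotopologue envelopes and hydrate-series
# generation for unit-resolution SIFT-MS ion bookkeeping.

# Integer nominal mass of the most abundant isotope of each supported element.
# Electron mass is ignored; every species handled here carries charge +1.
.NOMINAL_MASS <- c(H = 1L, C = 12L, N = 14L, O = 16L, Cl = 35L)

#' Natural abundance of the heavy chlorine isotope
#'
#' Fraction of chlorine atoms that are \eqn{^{37}}Cl in nature. The
#' identification rules in this package default to the idealised
#' statistical ratio 3:1 (`p_heavy = 0.25`); pass this constant as
#' `p_heavy` wherever the natural-abundance envelope is wanted instead.
#'
#' @format A length-one numeric, 0.2423.
#' @export
CL37_NATURAL_ABUNDANCE <- 0.2423

#' Integer nominal mass of an ion composition
#'
#' Sums integer nominal masses of the most abundant isotopes
#' (H = 1, C = 12, N = 14, O = 16, Cl = 35). Unit-resolution quadrupole
#' instruments report integer m/z, so no exact-mass mode is provided, and
#' for singly charged cations the nominal mass equals the nominal m/z.
#'
#' @param composition Named numeric vector or named list mapping element
#'   symbols to atom counts, e.g. `c(C = 1, H = 1, Cl = 2)`. Only C, H, N,
#'   O and Cl are supported; counts must be positive integers.
#' @return Integer nominal mass (= nominal m/z for a +1 ion).
#' @examples
#' nominal_mass(c(C = 1, H = 1, Cl = 2)) # 83, the dichloromethyl cation
#' nominal_mass(c(H = 3, O = 1))         # 19, hydronium
#' @export
nominal_mass <- function(composition) {
  comp <- unlist(composition)
  if (length(comp) == 0L)
    stop("composition must be non-empty", call. = FALSE)
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    stop("composition must be a named element -> count map", call. = FALSE)
  unknown <- setdiff(names(comp), names(.NOMINAL_MASS))
  if (length(unknown) > 0L)
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         " (supported: ", paste(names(.NOMINAL_MASS), collapse = ", "), ")",
         call. = FALSE)
  if (any(comp <= 0) || any(comp != round(comp)))
    stop("element counts must be positive integers", call. = FALSE)
  as.integer(sum(.NOMINAL_MASS[names(comp)] * comp))
}

#' Construct an ion species
#'
#' An analyte or reagent ion with its elemental composition. The chlorine
#' count and nominal m/z are derived from the composition; the charge is
#' always +1 in this domain.
#'
#' @param label Short conventional name, e.g. `"CHCl2+"`.
#' @param composition As in [nominal_mass()].
#' @return An object of class `ion_species` with fields `label`,
#'   `composition`, `charge`, `n_chlorine` and `mz`.
#' @examples
#' ion_species("CHCl2+", c(C = 1, H = 1, Cl = 2))
#' @export
ion_species <- function(label, composition) {
  mz <- nominal_mass(composition)
  comp <- unlist(composition)
  n_cl <- if ("Cl" %in% names(comp)) as.integer(comp[["Cl"]]) else 0L
  structure(
    list(label = label, composition = comp, charge = 1L,
         n_chlorine = n_cl, mz = mz),
    class = "ion_species"
  )
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  m/z %d  (charge +1, %d Cl)\n",
              x$label, x$mz, x$n_chlorine))
  invisible(x)
}

#' Chlorine isotopologue envelope of an ion
#'
#' Relative abundances of the isotopologues of an ion containing `n_cl`
#' chlorine atoms. Each chlorine is independently heavy (\eqn{^{37}}Cl)
#' with probability `p_heavy`, so the abundance at m/z offset `2j` follows
#' the binomial law \eqn{C(n, j) p^j (1-p)^{n-j}}. With the statistical
#' 3:1 convention (`p_heavy = 0.25`) a one-chlorine ion gives 75%:25% and
#' a two-chlorine ion 56.25%:37.5%:6.25% -- the 3:1 and 9:6:1 multiplet
#' signatures used to recognise chlorinated analyte ions.
#'
#' @param base_mz Integer nominal m/z of the all-\eqn{^{35}}Cl isotopologue.
#' @param n_cl Number of chlorine atoms (>= 0).
#' @param p_heavy Probability that one chlorine is \eqn{^{37}}Cl. Default
#'   0.25 (the idealised statistical ratio); see [CL37_NATURAL_ABUNDANCE].
#' @return An object of class `isotopologue_envelope`: list with `base_mz`,
#'   `offsets` (0, 2, ..., 2 n_cl), `mz_values`, and `fractions` summing
#'   to 1.
#' @examples
#' chlorine_envelope(83, 2)  # 0.5625 0.3750 0.0625 at m/z 83/85/87
#' @export
chlorine_envelope <- function(base_mz, n_cl, p_heavy = 0.25) {
  if (length(n_cl) != 1L || n_cl < 0 || n_cl != round(n_cl))
    stop("n_cl must be a single non-negative integer", call. = FALSE)
  if (length(p_heavy) != 1L || p_heavy < 0 || p_heavy > 1)
    stop("p_heavy must lie in [0, 1]", call. = FALSE)
  if (length(base_mz) != 1L || base_mz <= 0 || base_mz != round(base_mz))
    stop("base_mz must be a single positive integer", call. = FALSE)
  n_cl <- as.integer(n_cl)
  offsets <- 2L * (0:n_cl)
  # explicit binomial product rather than dbinom(): for the small n and
  # dyadic p used here (0.25) every term is exact in double precision,
  # so 37.5% stays exactly 37.5, which integer half-up rounding relies on
  j <- 0:n_cl
  fractions <- choose(n_cl, j) * p_heavy^j * (1 - p_heavy)^(n_cl - j)
  structure(
    list(base_mz = as.integer(base_mz), offsets = offsets,
         mz_values = as.integer(base_mz) + offsets,
         fractions = fractions, n_chlorine = n_cl, p_heavy = p_heavy),
    class = "isotopologue_envelope"
  )
}

#' @export
print.isotopologue_envelope <- function(x, ...) {
  cat(sprintf("<isotopologue_envelope> %d Cl, p_heavy = %.4f\n",
              x$n_chlorine, x$p_heavy))
  print(stats::setNames(round(x$fractions, 4), x$mz_values))
  invisible(x)
}

#' Hydrate (water cluster) ion series
#'
#' m/z ladder of the ligand-switching products M.H+(H2O)_0..n formed in
#' humid samples under hydronium chemistry; successive members differ by
#' 18 m/z units. Protonated acetonitrile, for example, appears at
#' m/z 42, 60, 78 and 96.
#'
#' @param base_mz Integer m/z of the unhydrated protonated ion.
#' @param n_max Maximum number of attached water molecules (>= 0).
#' @return An object of class `hydrate_series` with fields `base_mz`,
#'   `n_max` and `mz_values` (length `n_max + 1`).
#' @examples
#' hydrate_series(42, 3)$mz_values # 42 60 78 96
#' @export
hydrate_series <- function(base_mz, n_max) {
  if (length(n_max) != 1L || n_max < 0 || n_max != round(n_max))
    stop("n_max must be a single non-negative integer", call. = FALSE)
  if (length(base_mz) != 1L || base_mz <= 0 || base_mz != round(base_mz))
    stop("base_mz must be a single positive integer", call. = FALSE)
  structure(
    list(base_mz = as.integer(base_mz), n_max = as.integer(n_max),
         mz_values = as.integer(base_mz) + 18L * (0:as.integer(n_max))),
    class = "hydrate_series"
  )
}

#' @export
print.hydrate_series <- function(x, ...) {
  cat(sprintf("<hydrate_series> base m/z %d + %d waters: %s\n",
              x$base_mz, x$n_max, paste(x$mz_values, collapse = ", ")))
  invisible(x)
}
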