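# Kinetics library: (reagent ion, compound) -> product-ion channels, the
# stand-in for the proprietary kinetics database of a SIFT-MS instrument.

.REAGENT_IONS <- c("H3O+", "NO+", "O2+")

# Maximum waters attached in a hydrate series; hydronium chemistry in humid
# headspace rarely shows clusters beyond the trihydrate at unit resolution.
.HYDRATE_N_MAX <- 3L

#' Read a kinetics library from a YAML file
#'
#' The file holds one entry per (compound, reagent ion) reaction; the schema
#' is documented in the header of the shipped library (see
#' `system.file("extdata", "kinetics_library.yaml", package = "siftvoc")`).
#' Entries are validated on load: a positive rate coefficient, a known
#' reagent ion, at least one channel, and channel branching fractions in
#' (0, 1] summing to 1.
#'
#' @param path Path to the YAML library file.
#' @return A `kinetics_library`: a list of `kinetics_entry` objects, each a
#'   list with `compound`, `molar_mass`, `reagent`, `k` and a data.frame
#'   `channels` (`base_mz`, `branching`, `n_chlorine`, `hydrates`).
#' @seealso [default_library()], [candidates_for_ion()]
#' @export
read_kinetics_library <- function(path) {
  if (!file.exists(path))
    stop("kinetics library file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$compounds))
    stop("kinetics library file has no 'compounds' section: ", path,
         call. = FALSE)
  entries <- lapply(raw$compounds, function(e) {
    ch <- do.call(rbind, lapply(e$channels, function(c0)
      data.frame(base_mz = as.integer(c0$base_mz),
                 branching = as.numeric(c0$branching),
                 n_chlorine = as.integer(c0$n_chlorine),
                 hydrates = isTRUE(c0$hydrates))))
    entry <- structure(
      list(compound = e$compound, molar_mass = as.numeric(e$molar_mass),
           reagent = e$reagent, k = as.numeric(e$k), channels = ch),
      class = "kinetics_entry"
    )
    validate_kinetics_entry(entry)
    entry
  })
  names(entries) <- vapply(entries, function(e)
    paste(e$compound, e$reagent, sep = "/"), character(1))
  structure(entries, class = "kinetics_library")
}

validate_kinetics_entry <- function(entry) {
  if (!entry$reagent %in% .REAGENT_IONS)
    stop("unknown reagent ion '", entry$reagent, "' for compound ",
         entry$compound, call. = FALSE)
  if (!is.finite(entry$k) || entry$k <= 0)
    stop("rate coefficient must be > 0 for ", entry$compound, call. = FALSE)
  if (!is.finite(entry$molar_mass) || entry$molar_mass <= 0)
    stop("molar mass must be > 0 for ", entry$compound, call. = FALSE)
  ch <- entry$channels
  if (is.null(ch) || nrow(ch) == 0L)
    stop("entry for ", entry$compound, " has no product channels",
         call. = FALSE)
  if (any(ch$branching <= 0 | ch$branching > 1))
    stop("branching fractions must lie in (0, 1] for ", entry$compound,
         call. = FALSE)
  if (abs(sum(ch$branching) - 1) > 1e-9)
    stop("branching fractions must sum to 1 for ", entry$compound,
         call. = FALSE)
  if (any(ch$base_mz <= 0) || any(ch$n_chlorine < 0))
    stop("invalid channel for ", entry$compound, call. = FALSE)
  invisible(entry)
}

#' The default compound kinetics library
#'
#' Loads the library shipped with the package, covering the compounds
#' reported in hypochlorite/organic-matter headspace work: ammonia (under
#' both hydronium and dioxygenyl reagent ions), acetaldehyde, acetone,
#' methanol, ethanol and acetonitrile under H3O+, acetic acid under NO+,
#' chloroform under O2+ (whose product, the dichloromethyl cation CHCl2+,
#' carries two chlorines at base m/z 83), and the two unresolved
#' nitrogen-compound candidate sets at m/z 88 and 102. Chlorinated organics
#' react too slowly with H3O+ and NO+ to be useful, so chloroform appears
#' under O2+ only.
#'
#' Rate coefficients are literature-scale defaults recorded in the shipped
#' YAML file; they fix the absolute concentration scale of simulation and
#' quantification (which invert each other consistently) but are not
#' instrument-calibrated.
#'
#' @return A `kinetics_library`; see [read_kinetics_library()].
#' @examples
#' lib <- default_library()
#' library_entry(lib, "chloroform", "O2+")$channels
#' @export
default_library <- function() {
  read_kinetics_library(
    system.file("extdata", "kinetics_library.yaml", package = "siftvoc",
                mustWork = TRUE))
}

#' Look up one library entry
#'
#' @param library A `kinetics_library`.
#' @param compound Compound name as stored in the library (candidate sets
#'   use pipe-separated names, e.g. `"pentylamine|butyramide"`).
#' @param reagent Reagent ion, one of `"H3O+"`, `"NO+"`, `"O2+"`.
#' @return The matching `kinetics_entry`, or `NULL` when the compound has
#'   no entry under that reagent ion (e.g. chloroform under H3O+).
#' @export
library_entry <- function(library, compound, reagent) {
  key <- paste(compound, reagent, sep = "/")
  if (key %in% names(library)) library[[key]] else NULL
}

#' @export
print.kinetics_entry <- function(x, ...) {
  cat(sprintf("<kinetics_entry> %s + %s  k = %.2g cm^3/s\n",
              x$compound, x$reagent, x$k))
  print(x$channels)
  invisible(x)
}

#' @export
print.kinetics_library <- function(x, ...) {
  cat(sprintf("<kinetics_library> %d entries:\n", length(x)))
  for (nm in names(x)) cat("  ", nm, "\n")
  invisible(x)
}

#' All m/z values a product channel can appear at
#'
#' Expands a channel's base m/z by its chlorine isotopologue offsets
#' (steps of 2) and, for hydrating channels, the water-cluster ladder
#' (steps of 18, up to the trihydrate).
#'
#' @param channel One row of a `kinetics_entry`'s `channels` data.frame.
#' @param n_hydrates_max Maximum waters considered for hydrating channels.
#' @return Data.frame with columns `mz`, `iso_offset` (0, 2, ...),
#'   `n_waters`.
#' @export
channel_mz_set <- function(channel, n_hydrates_max = .HYDRATE_N_MAX) {
  iso <- 2L * (0:channel$n_chlorine)
  wat <- if (isTRUE(channel$hydrates)) 0:n_hydrates_max else 0L
  grid <- expand.grid(iso_offset = iso, n_waters = wat)
  grid$mz <- as.integer(channel$base_mz + grid$iso_offset + 18L * grid$n_waters)
  grid[, c("mz", "iso_offset", "n_waters")]
}

#' Candidate compounds for an observed ion
#'
#' Inverse of the forward channel expansion: every library channel whose
#' base m/z, any hydrate m/z, or any chlorine isotopologue m/z equals the
#' observed m/z under the given reagent ion. Ambiguity is preserved: an
#' unresolved candidate set such as pentylamine|butyramide is returned as
#' such and never silently collapsed to one compound.
#'
#' @param reagent Reagent ion.
#' @param mz Observed integer m/z (> 0).
#' @param library A `kinetics_library`; default [default_library()].
#' @return Data.frame with one row per matching channel: `compound`,
#'   `candidates` (pipe-separated member names), `n_candidates`,
#'   `base_mz`, `n_chlorine`, `hydrates`, `iso_offset`, `n_waters`.
#'   Zero rows when nothing matches.
#' @examples
#' candidates_for_ion("H3O+", 88)  # pentylamine|butyramide
#' candidates_for_ion("H3O+", 60)  # acetonitrile monohydrate
#' @export
candidates_for_ion <- function(reagent, mz, library = default_library()) {
  if (length(mz) != 1L || mz <= 0 || mz != round(mz))
    stop("mz must be a single positive integer", call. = FALSE)
  out <- list()
  for (entry in library) {
    if (entry$reagent != reagent) next
    for (i in seq_len(nrow(entry$channels))) {
      ch <- entry$channels[i, ]
      exp_set <- channel_mz_set(ch)
      hit <- exp_set[exp_set$mz == mz, ]
      if (nrow(hit) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          compound = entry$compound,
          candidates = entry$compound,
          n_candidates = length(strsplit(entry$compound, "|",
                                         fixed = TRUE)[[1]]),
          base_mz = ch$base_mz,
          n_chlorine = ch$n_chlorine,
          hydrates = ch$hydrates,
          iso_offset = hit$iso_offset[1],
          n_waters = hit$n_waters[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(compound = character(), candidates = character(),
                      n_candidates = integer(), base_mz = integer(),
                      n_chlorine = integer(), hydrates = logical(),
                      iso_offset = integer(), n_waters = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
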