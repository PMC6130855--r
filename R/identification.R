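# Qualitative spectral interpretation: delta-2 m/z chlorine multiplets,
# 18 m/z hydrate ladders, and ambiguity-preserving compound assignment.

#' Detection parameters
#'
#' @param background_mean Mean background count rate per channel
#'   (counts/s), used for the limit of detection.
#' @param cl_tolerance Maximum absolute deviation allowed between each
#'   observed isotopologue fraction and its binomial expectation for a
#'   chlorine-pattern hit to pass. The default 0.10 is a deliberately
#'   loose ratio window: observed multiplets drift from the ideal 3:1 /
#'   9:6:1 ratios by more than Poisson counting error alone (mass
#'   discrimination, overlapping fragments), so a strict counting-error
#'   test would reject genuine chlorine patterns.
#' @param max_n_cl Largest chlorine count searched for.
#' @param min_series_members Minimum chain length for a hydrate series.
#' @param p_heavy Heavy-chlorine probability for expected fractions.
#' @return An object of class `detection_params` with the derived `lod`
#'   (background_mean + 3 sqrt(background_mean): a peak is real when its
#'   count rate exceeds the mean background by three standard deviations
#'   of the background counting noise).
#' @export
detection_params <- function(background_mean = 1, cl_tolerance = 0.10,
                             max_n_cl = 3, min_series_members = 2,
                             p_heavy = 0.25) {
  if (cl_tolerance <= 0 || cl_tolerance >= 0.5)
    stop("cl_tolerance must lie in (0, 0.5)", call. = FALSE)
  if (background_mean < 0)
    stop("background_mean must be >= 0", call. = FALSE)
  if (max_n_cl < 1 || min_series_members < 2)
    stop("max_n_cl must be >= 1 and min_series_members >= 2", call. = FALSE)
  structure(
    list(background_mean = background_mean,
         lod = background_mean + 3 * sqrt(background_mean),
         cl_tolerance = cl_tolerance,
         max_n_cl = as.integer(max_n_cl),
         min_series_members = as.integer(min_series_members),
         p_heavy = p_heavy),
    class = "detection_params"
  )
}

# Above-LOD peaks of a spectrum as a data.frame(mz, counts).
above_lod_peaks <- function(spectrum, params) {
  df <- as.data.frame(spectrum)
  df[df$counts > params$lod, , drop = FALSE]
}

#' Detect chlorine isotopologue patterns
#'
#' Searches a spectrum for groups of peaks separated by 2 m/z units whose
#' intensity fractions match the binomial chlorine envelope: 3:1 for one
#' chlorine, 9:6:1 for two, and so on. For each above-LOD peak taken as
#' the all-35Cl base and each chlorine count up to `max_n_cl`, the peaks
#' at base, base+2, ..., base+2 n must all exceed the LOD; the group
#' passes when every observed fraction is within `cl_tolerance` of its
#' binomial expectation. Overlapping passing groups are resolved in
#' favour of the largest chlorine count, then the smallest maximum
#' deviation; accepted hits are returned sorted by base m/z.
#'
#' Chlorinated organics are interpreted under the O2+ reagent ion (they
#' react only slowly with H3O+ and NO+); other reagents are analysed with
#' a warning, not refused.
#'
#' @param spectrum A `sift_spectrum`.
#' @param params A [detection_params()].
#' @param p_heavy Heavy-chlorine probability (default from `params`).
#' @param keep_failing Also return evaluated candidate groups that failed
#'   the tolerance rule (before overlap resolution).
#' @return Data.frame with one row per hit: `base_mz`, `n_cl`,
#'   `max_abs_deviation`, `passes`, and list-columns `mz`,
#'   `observed_counts`, `observed_fractions`, `expected_fractions`.
#' @examples
#' sp <- sift_spectrum(c(`83` = 1644, `85` = 1342, `87` = 152), "O2+")
#' detect_chlorine_patterns(sp)
#' @export
detect_chlorine_patterns <- function(spectrum, params = detection_params(),
                                     p_heavy = params$p_heavy,
                                     keep_failing = FALSE) {
  if (spectrum$reagent != "O2+")
    warning("chlorine-pattern detection is intended for O2+ spectra; got ",
            spectrum$reagent, call. = FALSE)
  peaks <- above_lod_peaks(spectrum, params)
  hits <- list()
  for (base in peaks$mz) {
    for (n_cl in seq_len(params$max_n_cl)) {
      members <- base + 2L * (0:n_cl)
      if (!all(members %in% peaks$mz)) next
      cnt <- peaks$counts[match(members, peaks$mz)]
      obs <- cnt / sum(cnt)
      expf <- chlorine_envelope(base, n_cl, p_heavy)$fractions
      dev <- max(abs(obs - expf))
      hits[[length(hits) + 1L]] <- data.frame(
        base_mz = base, n_cl = n_cl,
        mz = I(list(members)),
        observed_counts = I(list(cnt)),
        observed_fractions = I(list(obs)),
        expected_fractions = I(list(expf)),
        max_abs_deviation = dev,
        passes = dev <= params$cl_tolerance)
    }
  }
  empty <- data.frame(base_mz = integer(), n_cl = integer(),
                      mz = I(list()), observed_counts = I(list()),
                      observed_fractions = I(list()),
                      expected_fractions = I(list()),
                      max_abs_deviation = numeric(), passes = logical())
  if (length(hits) == 0L) return(empty)
  all_hits <- do.call(rbind, hits)
  if (keep_failing) {
    all_hits <- all_hits[order(all_hits$base_mz, all_hits$n_cl), ]
    rownames(all_hits) <- NULL
    return(all_hits)
  }
  passing <- all_hits[all_hits$passes, , drop = FALSE]
  if (nrow(passing) == 0L) return(empty)
  # overlap resolution: prefer larger n_cl, then smaller deviation;
  # greedily keep hits whose member m/z do not intersect accepted ones
  passing <- passing[order(-passing$n_cl, passing$max_abs_deviation), ]
  taken <- integer(0)
  keep <- logical(nrow(passing))
  for (i in seq_len(nrow(passing))) {
    members <- passing$mz[[i]]
    if (length(intersect(members, taken)) == 0L) {
      keep[i] <- TRUE
      taken <- c(taken, members)
    }
  }
  out <- passing[keep, , drop = FALSE]
  out <- out[order(out$base_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect hydrate (water cluster) ion series
#'
#' Finds maximal chains of above-LOD peaks spaced exactly 18 m/z units
#' apart in a hydronium spectrum. A chain is reported from its lowest
#' member and is never extended through a below-LOD gap; chains shorter
#' than `min_series_members` are not reported.
#'
#' @param spectrum A `sift_spectrum` (hydrate chemistry is a hydronium
#'   phenomenon; other reagents are searched as given).
#' @param params A [detection_params()].
#' @param library Optional `kinetics_library`; when supplied, each series
#'   base is matched against hydrating channels to fill the candidate set.
#' @return Data.frame: `base_mz`, `n_members`, `candidates`
#'   (pipe-separated, `NA` when unmatched), and list-columns `mz`,
#'   `counts`.
#' @examples
#' sp <- sift_spectrum(c(`42` = 900, `60` = 300, `78` = 90, `96` = 30),
#'                     "H3O+")
#' detect_hydrate_series(sp)
#' @export
detect_hydrate_series <- function(spectrum, params = detection_params(),
                                  library = NULL) {
  peaks <- above_lod_peaks(spectrum, params)
  present <- peaks$mz
  out <- list()
  for (base in sort(present)) {
    if ((base - 18L) %in% present) next  # not a chain start
    chain <- base
    while ((chain[length(chain)] + 18L) %in% present)
      chain <- c(chain, chain[length(chain)] + 18L)
    if (length(chain) < params$min_series_members) next
    cand <- NA_character_
    if (!is.null(library)) {
      m <- candidates_for_ion(spectrum$reagent, base, library)
      m <- m[m$hydrates & m$base_mz == base, , drop = FALSE]
      if (nrow(m) > 0L) cand <- paste(unique(m$compound), collapse = "|")
    }
    out[[length(out) + 1L]] <- data.frame(
      base_mz = base, n_members = length(chain),
      candidates = cand,
      mz = I(list(chain)),
      counts = I(list(peaks$counts[match(chain, peaks$mz)])))
  }
  if (length(out) == 0L)
    return(data.frame(base_mz = integer(), n_members = integer(),
                      candidates = character(), mz = I(list()),
                      counts = I(list())))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign compounds to the peaks of a spectrum
#'
#' Every above-LOD peak is either assigned -- through a chlorine-pattern
#' hit (O2+ spectra), a hydrate series (H3O+ spectra), or a direct
#' kinetics-library match -- or listed as unassigned. Ambiguous candidate
#' sets are preserved (a peak at m/z 88 under H3O+ reports
#' pentylamine|butyramide with `unambiguous = FALSE`). Each peak
#' contributes to exactly one assignment, with pattern evidence taking
#' precedence over direct matches: a passing two-chlorine hit based at
#' m/z 83 under O2+ is assigned to chloroform, the only candidate for the
#' dichloromethyl cation. Chlorine-carrying channels are never assigned
#' from a bare m/z match -- without the delta-2 isotopologue pattern a
#' single peak at such an m/z stays unassigned, which keeps the false
#' chloroform call rate at zero on clean control spectra.
#'
#' @param spectrum A `sift_spectrum`.
#' @param library A `kinetics_library`.
#' @param params A [detection_params()].
#' @return Data.frame with one row per above-LOD peak: `mz`, `counts`,
#'   `evidence` (`"cl_pattern"`, `"hydrate_series"`, `"library"`,
#'   `"unassigned"`), `compounds` (pipe-separated candidates, `NA` if
#'   unassigned), `unambiguous` (logical, `NA` if unassigned).
#' @export
assign_compounds <- function(spectrum, library = default_library(),
                             params = detection_params()) {
  peaks <- above_lod_peaks(spectrum, params)
  if (nrow(peaks) == 0L)
    return(data.frame(mz = integer(), counts = numeric(),
                      evidence = character(), compounds = character(),
                      unambiguous = logical()))
  assignment <- data.frame(mz = peaks$mz, counts = peaks$counts,
                           evidence = "unassigned",
                           compounds = NA_character_,
                           unambiguous = NA,
                           stringsAsFactors = FALSE)
  claim <- function(asg, mzs, evidence, compounds) {
    rows <- match(mzs, asg$mz)
    rows <- rows[!is.na(rows)]
    rows <- rows[asg$evidence[rows] == "unassigned"]
    if (length(rows) > 0L && !is.na(compounds)) {
      asg$evidence[rows] <- evidence
      asg$compounds[rows] <- compounds
      asg$unambiguous[rows] <-
        length(strsplit(compounds, "|", fixed = TRUE)[[1]]) == 1L
    }
    asg
  }
  # 1. chlorine multiplets (O2+ chemistry)
  if (spectrum$reagent == "O2+") {
    cl_hits <- detect_chlorine_patterns(spectrum, params)
    for (i in seq_len(nrow(cl_hits))) {
      hit <- cl_hits[i, ]
      cands <- character(0)
      for (entry in library) {
        if (entry$reagent != spectrum$reagent) next
        ok <- entry$channels$base_mz == hit$base_mz &
          entry$channels$n_chlorine == hit$n_cl
        if (any(ok)) cands <- c(cands, entry$compound)
      }
      if (length(cands) > 0L)
        assignment <- claim(assignment, hit$mz[[1]], "cl_pattern",
                            paste(unique(cands), collapse = "|"))
    }
  }
  # 2. hydrate ladders (hydronium chemistry)
  if (spectrum$reagent == "H3O+") {
    series <- detect_hydrate_series(spectrum, params, library)
    for (i in seq_len(nrow(series))) {
      if (!is.na(series$candidates[i]))
        assignment <- claim(assignment, series$mz[[i]], "hydrate_series",
                            series$candidates[i])
    }
  }
  # 3. direct library matches for whatever is left; chlorinated channels
  # are excluded here -- a chlorine-carrying ion is only credible through
  # its delta-2 isotopologue pattern, never from a bare m/z coincidence
  for (r in which(assignment$evidence == "unassigned")) {
    m <- candidates_for_ion(spectrum$reagent, assignment$mz[r], library)
    m <- m[m$n_chlorine == 0L, , drop = FALSE]
    if (nrow(m) > 0L)
      assignment <- claim(assignment, assignment$mz[r], "library",
                          paste(unique(m$compound), collapse = "|"))
  }
  assignment
}
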