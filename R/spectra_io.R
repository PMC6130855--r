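# Spectrum container and its CSV file format: the boundary between
# instrument-like data and the analysis.

.DEFAULT_SCAN_RANGE <- c(10L, 200L)

#' Construct a SIFT-MS spectrum
#'
#' A unit-resolution full-scan spectrum under one reagent ion: a sparse
#' map from integer m/z to non-negative count rate (counts per second),
#' plus sample metadata. m/z values absent from the map are zero counts.
#'
#' @param counts Named numeric vector; names are integer m/z values within
#'   the scan range, values are count rates >= 0. Zeros may be dropped.
#' @param reagent One of `"H3O+"`, `"NO+"`, `"O2+"`.
#' @param sample_id Sample identifier string.
#' @param group Group label: `"control"`, `"1"`, `"2"`, `"3"` or `"4"`.
#' @param condition `"aerobic"` or `"anaerobic"`.
#' @param replicate Replicate index (integer >= 1).
#' @param reagent_count_rate Reagent-ion count rate (counts/s) measured at
#'   the reagent ion's m/z (and its hydrates for H3O+); must be > 0 for a
#'   spectrum used in quantification. `NA` if unrecorded.
#' @param scan_range Length-2 integer vector, inclusive m/z limits.
#' @param seed RNG seed recorded by the simulator, `NA` for real data.
#' @return An object of class `sift_spectrum`.
#' @examples
#' sift_spectrum(c(`83` = 1644, `85` = 1342, `87` = 152), "O2+",
#'               sample_id = "g4a1", group = "4", condition = "aerobic",
#'               replicate = 1)
#' @export
sift_spectrum <- function(counts, reagent,
                          sample_id = NA_character_,
                          group = NA_character_,
                          condition = NA_character_,
                          replicate = NA_integer_,
                          reagent_count_rate = NA_real_,
                          scan_range = .DEFAULT_SCAN_RANGE,
                          seed = NA_integer_) {
  if (length(reagent) != 1L || !reagent %in% .REAGENT_IONS)
    stop("reagent must be one of ", paste(.REAGENT_IONS, collapse = ", "),
         call. = FALSE)
  if (length(counts) > 0L) {
    mz <- suppressWarnings(as.numeric(names(counts)))
    if (anyNA(mz) || any(mz != round(mz)))
      stop("all m/z keys must be integers", call. = FALSE)
    if (any(mz < scan_range[1] | mz > scan_range[2]))
      stop("m/z keys outside scan range [", scan_range[1], ", ",
           scan_range[2], "]", call. = FALSE)
    if (any(counts < 0))
      stop("count rates must be non-negative", call. = FALSE)
    counts <- counts[counts > 0]
    counts <- counts[order(as.integer(names(counts)))]
  }
  if (!is.na(reagent_count_rate) && reagent_count_rate <= 0)
    stop("reagent_count_rate must be > 0", call. = FALSE)
  structure(
    list(reagent = reagent,
         counts = counts,
         scan_range = as.integer(scan_range),
         meta = list(sample_id = sample_id, group = group,
                     condition = condition,
                     replicate = as.integer(replicate),
                     reagent_count_rate = reagent_count_rate,
                     seed = seed)),
    class = "sift_spectrum"
  )
}

#' @export
print.sift_spectrum <- function(x, ...) {
  cat(sprintf("<sift_spectrum> %s  %d peaks  [sample %s, group %s, %s, rep %s]\n",
              x$reagent, length(x$counts),
              x$meta$sample_id, x$meta$group, x$meta$condition,
              x$meta$replicate))
  invisible(x)
}

#' @export
as.data.frame.sift_spectrum <- function(x, ...) {
  data.frame(mz = as.integer(names(x$counts)),
             counts = as.numeric(x$counts))
}

#' Count rate at given m/z values (0 where absent)
#'
#' @param spectrum A `sift_spectrum`.
#' @param mz Integer m/z values.
#' @return Numeric vector of count rates, one per `mz`.
#' @export
spectrum_counts <- function(spectrum, mz) {
  out <- rep(0, length(mz))
  idx <- match(as.character(mz), names(spectrum$counts))
  out[!is.na(idx)] <- as.numeric(spectrum$counts[idx[!is.na(idx)]])
  out
}

#' Write a spectrum to a CSV file
#'
#' One spectrum per file: a `# key: value` front-matter block carrying the
#' reagent ion and sample metadata, then a `mz,counts` table. The round
#' trip through [read_spectrum()] is lossless.
#'
#' @param spectrum A `sift_spectrum`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- spectrum$meta
  header <- c(
    sprintf("# reagent: %s", spectrum$reagent),
    sprintf("# sample_id: %s", m$sample_id),
    sprintf("# group: %s", m$group),
    sprintf("# condition: %s", m$condition),
    sprintf("# replicate: %s", m$replicate),
    sprintf("# reagent_count_rate: %s",
            format(m$reagent_count_rate, digits = 15)),
    sprintf("# seed: %s", m$seed),
    sprintf("# scan_range: %d-%d", spectrum$scan_range[1],
            spectrum$scan_range[2]),
    "mz,counts"
  )
  body <- sprintf("%s,%s", names(spectrum$counts),
                  vapply(as.numeric(spectrum$counts),
                         function(v) format(v, digits = 15), character(1)))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a spectrum from a CSV file
#'
#' Parses the format written by [write_spectrum()]. Malformed rows are
#' rejected with the offending line number; a file declaring more than one
#' reagent ion, non-integer m/z values or negative counts is an error.
#'
#' @param path Path to a spectrum CSV file.
#' @return A `sift_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    stop("spectrum file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  header_n <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      key <- trimws(sub(":.*$", "", kv))
      val <- trimws(sub("^[^:]*:\\s*", "", kv))
      if (key == "reagent" && !is.null(meta$reagent))
        stop("line ", i, ": spectrum file declares more than one reagent ion",
             call. = FALSE)
      meta[[key]] <- val
      header_n <- i
    } else break
  }
  if (is.null(meta$reagent))
    stop("spectrum file missing '# reagent:' front matter: ", path,
         call. = FALSE)
  if (header_n + 1L > length(lines) ||
      trimws(lines[header_n + 1L]) != "mz,counts")
    stop("line ", header_n + 1L, ": expected 'mz,counts' header",
         call. = FALSE)
  body <- lines[-seq_len(header_n + 1L)]
  body <- body[nzchar(trimws(body))]
  mz <- numeric(0); cnt <- numeric(0)
  for (j in seq_along(body)) {
    line_no <- header_n + 1L + j
    parts <- strsplit(body[j], ",", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("line ", line_no, ": malformed row '", body[j], "'",
           call. = FALSE)
    mzv <- suppressWarnings(as.numeric(parts[1]))
    cv <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(mzv) || is.na(cv))
      stop("line ", line_no, ": malformed row '", body[j], "'",
           call. = FALSE)
    if (mzv != round(mzv))
      stop("line ", line_no, ": non-integer m/z value ", parts[1],
           call. = FALSE)
    if (cv < 0)
      stop("line ", line_no, ": negative count rate ", parts[2],
           call. = FALSE)
    mz <- c(mz, mzv); cnt <- c(cnt, cv)
  }
  scan_range <- .DEFAULT_SCAN_RANGE
  if (!is.null(meta$scan_range)) {
    sr <- as.integer(strsplit(meta$scan_range, "-", fixed = TRUE)[[1]])
    if (length(sr) == 2L && !anyNA(sr)) scan_range <- sr
  }
  num_or_na <- function(x) {
    if (is.null(x) || x %in% c("NA", "")) NA_real_ else as.numeric(x)
  }
  chr_or_na <- function(x) {
    if (is.null(x) || x %in% c("NA", "")) NA_character_ else x
  }
  sift_spectrum(
    counts = stats::setNames(cnt, format(mz, scientific = FALSE, trim = TRUE)),
    reagent = meta$reagent,
    sample_id = chr_or_na(meta$sample_id),
    group = chr_or_na(meta$group),
    condition = chr_or_na(meta$condition),
    replicate = as.integer(num_or_na(meta$replicate)),
    reagent_count_rate = num_or_na(meta$reagent_count_rate),
    scan_range = scan_range,
    seed = as.integer(num_or_na(meta$seed))
  )
}

#' Highest peaks of a spectrum
#'
#' @param spectrum A `sift_spectrum`.
#' @param k Number of peaks wanted (>= 1); if larger than the number of
#'   non-zero peaks, all peaks are returned.
#' @return Data.frame `mz`, `counts`, ordered by descending count rate
#'   with ties broken by ascending m/z.
#' @export
top_peaks <- function(spectrum, k) {
  if (length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single integer >= 1", call. = FALSE)
  df <- as.data.frame(spectrum)
  df <- df[order(-df$counts, df$mz), , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  df
}
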