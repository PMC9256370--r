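#' Standard 10/20 montage and coherence pair list
#'
#' The 19-electrode international 10/20 set used for resting-state QEEG,
#' and the 16 electrode pairs over which band coherence is computed:
#' six left intrahemispheric, six right intrahemispheric and four
#' interhemispheric pairs. The interhemispheric temporal pair is T7-T8.
#'
#' @return `eeg_montage()` returns a character vector of 19 electrode labels.
#' @export
eeg_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

#' @rdname eeg_montage
#' @return `default_pairs()` returns a list of length-2 character vectors,
#'   ordered left-intra, right-intra, inter.
#' @export
default_pairs <- function() {
  list(
    c("F3", "C3"), c("F3", "P3"), c("F3", "T5"),
    c("C3", "P3"), c("C3", "T5"), c("P3", "T5"),
    c("F4", "C4"), c("F4", "P4"), c("F4", "T6"),
    c("C4", "P4"), c("C4", "T6"), c("P4", "T6"),
    c("F3", "F4"), c("C3", "C4"), c("P3", "P4"), c("T7", "T8")
  )
}

#' Clinical EEG frequency bands
#'
#' Conventional delta, theta and alpha band edges in Hz. The band limits are
#' configurable wherever a band definition is accepted.
#'
#' @return Named list of `band_definition` objects.
#' @export
default_bands <- function() {
  list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13)
  )
}

#' Define a frequency band
#'
#' @param name Band name (e.g. "alpha").
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `band_definition` list with elements `name`, `lo`, `hi`.
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo > 0 && lo < hi)) stop("band edges must satisfy 0 < lo < hi")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Canonical feature names for a pair/band grid
#'
#' Feature columns are ordered pair-major then band, e.g. `F3-C3_delta`,
#' `F3-C3_theta`, `F3-C3_alpha`, `F3-P3_delta`, ...
#'
#' @param pairs List of electrode pairs (length-2 character vectors).
#' @param bands Named list of band definitions.
#' @return Character vector of `<PAIR>_<BAND>` names.
#' @export
feature_names <- function(pairs = default_pairs(), bands = default_bands()) {
  unlist(lapply(pairs, function(p) {
    paste0(p[1], "-", p[2], "_", names(bands))
  }))
}

pair_key <- function(pair) paste0(pair[1], "-", pair[2])
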