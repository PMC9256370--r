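#' Configuration for coherence feature extraction
#'
#' @param pairs Electrode pair list (default: the 16-pair montage).
#' @param bands Named list of band definitions (default delta/theta/alpha).
#' @param bp_lo,bp_hi Pre-filtering band-pass edges in Hz.
#' @param win_ms Analysis window length in milliseconds.
#' @param overlap Fractional window overlap.
#' @param fisher_convention Fisher-Z convention, `"sqrt"` or `"direct"`.
#' @return A `feature_config` list.
#' @export
feature_config <- function(pairs = default_pairs(),
                           bands = default_bands(),
                           bp_lo = 0.15, bp_hi = 30,
                           win_ms = 650, overlap = 0.5,
                           fisher_convention = "sqrt") {
  structure(list(pairs = pairs, bands = bands, bp_lo = bp_lo, bp_hi = bp_hi,
                 win_ms = win_ms, overlap = overlap,
                 fisher_convention = fisher_convention),
            class = "feature_config")
}

#' Build the subjects-by-features coherence matrix
#'
#' For each recording: zero-phase band-pass, segmentation into overlapping
#' Hanning windows, Welch magnitude-squared coherence per electrode pair,
#' arithmetic band averaging for each configured band, and a Fisher-Z
#' transform of the band-averaged value. Features are ordered pair-major,
#' then band (`F3-C3_delta`, `F3-C3_theta`, `F3-C3_alpha`, `F3-P3_delta`,
#' ...); the default grid is 16 pairs x 3 bands = 48 features.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param config A [feature_config()].
#' @return A `coherence_features` object: `values` (numeric matrix, subjects
#'   x features), `feature_names`, `labels` (factor), `subject_ids`.
#' @export
build_feature_matrix <- function(cohort, config = feature_config()) {
  stopifnot(length(cohort) >= 1)
  fnames <- feature_names(config$pairs, config$bands)
  rows <- lapply(cohort, function(rec) .subject_features(rec, config))
  values <- do.call(rbind, rows)
  colnames(values) <- fnames
  ids <- vapply(cohort, function(r) r$subject_id, character(1))
  rownames(values) <- ids
  labels <- factor(vapply(cohort, function(r) as.character(r$label),
                          character(1)))
  structure(list(values = values, feature_names = fnames,
                 labels = labels, subject_ids = ids),
            class = "coherence_features")
}

#' @export
print.coherence_features <- function(x, ...) {
  cat(sprintf("<coherence_features> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

.subject_features <- function(rec, config) {
  stopifnot(inherits(rec, "eeg_recording"))
  needed <- unique(unlist(config$pairs))
  missing <- setdiff(needed, rec$channels)
  if (length(missing))
    stop(sprintf("recording %s lacks electrode(s): %s",
                 rec$subject_id, paste(missing, collapse = ", ")))
  rec <- eeg_bandpass(rec, config$bp_lo, config$bp_hi)
  # segment + FFT once per needed channel, reuse across pairs
  specs <- lapply(needed, function(ch) {
    w <- segment_windows(rec$data[ch, ], rec$fs, config$win_ms, config$overlap)
    .windowed_fft(w)
  })
  names(specs) <- needed
  win <- floor(config$win_ms * rec$fs / 1000)
  nseg <- ncol(specs[[1]])
  if (nseg < 2)
    stop(sprintf("recording %s too short for a 2-segment Welch estimate",
                 rec$subject_id))
  half <- seq_len(floor(win / 2) + 1L)
  freqs <- (half - 1) * rec$fs / win
  out <- numeric(0)
  for (p in config$pairs) {
    Fx <- specs[[p[1]]][half, , drop = FALSE]
    Fy <- specs[[p[2]]][half, , drop = FALSE]
    Pxx <- rowMeans(Mod(Fx)^2)
    Pyy <- rowMeans(Mod(Fy)^2)
    Pxy <- rowMeans(Fx * Conj(Fy))
    denom <- Pxx * Pyy
    msc <- ifelse(denom > 0, Mod(Pxy)^2 / denom, 0)
    msc <- pmin(pmax(msc, 0), 1)
    for (b in config$bands) {
      inb <- freqs >= b$lo & freqs <= b$hi
      if (!any(inb)) stop(sprintf("no frequency bins inside band %s", b$name))
      out <- c(out, fisher_z(mean(msc[inb]),
                             convention = config$fisher_convention,
                             clamp = TRUE))
    }
  }
  out
}

#' Write / read a coherence feature matrix as CSV
#'
#' Layout: `subject_id,label,<PAIR>_<BAND>,...`, one row per subject.
#'
#' @param features A `coherence_features` object.
#' @param path Output CSV path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a `coherence_features` object.
#' @export
write_feature_matrix <- function(features, path) {
  stopifnot(inherits(features, "coherence_features"))
  df <- data.frame(subject_id = features$subject_ids,
                   label = as.character(features$labels),
                   features$values, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("subject_id", "label") %in% names(df)))
    stop("feature CSV must have subject_id and label columns")
  values <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                         drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values, feature_names = colnames(values),
                 labels = factor(df$label), subject_ids = df$subject_id),
            class = "coherence_features")
}

#' Assemble a feature object from a plain matrix
#'
#' Convenience constructor used by simulation studies and tests that build
#' feature matrices directly rather than from recordings.
#'
#' @param values Numeric matrix, subjects x features.
#' @param labels Class labels (coerced to factor, two levels).
#' @param subject_ids Optional subject identifiers.
#' @return A `coherence_features` object.
#' @export
as_coherence_features <- function(values, labels, subject_ids = NULL) {
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.null(subject_ids))
    subject_ids <- paste0("s", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(list(values = values, feature_names = colnames(values),
                 labels = factor(labels), subject_ids = subject_ids),
            class = "coherence_features")
}
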