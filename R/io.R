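#' Write / read a cohort as delimited files plus a manifest
#'
#' Each subject is stored as one CSV with a header row of channel labels and
#' one column per channel (samples down the rows); `manifest.csv` lists
#' `subject_id`, `path` (relative to the manifest), and `label`.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns the manifest path invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fname <- paste0(rec$subject_id, ".csv")
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channels
    data.table::fwrite(df, file.path(dir, fname))
    data.frame(subject_id = rec$subject_id, path = fname,
               label = as.character(rec$label), fs = rec$fs)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  data.table::fwrite(manifest, mpath)
  invisible(mpath)
}

#' @rdname write_cohort
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_cohort()] (or hand-built with the same columns).
#' @param fs Sampling rate used when the manifest has no `fs` column.
#' @return `read_cohort()` returns a list of [eeg_recording()] objects.
#' @export
read_cohort <- function(manifest_path, fs = 250) {
  man <- data.table::fread(manifest_path, data.table = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns subject_id, path, label")
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    df <- data.table::fread(file.path(base, man$path[i]), data.table = FALSE)
    rate <- if ("fs" %in% names(man)) man$fs[i] else fs
    eeg_recording(t(as.matrix(df)), fs = rate, channels = names(df),
                  subject_id = man$subject_id[i], label = man$label[i])
  })
}

#' Provenance block for result files
#'
#' Every artifact the pipeline writes carries the package version, the seed,
#' and a content hash of the configuration that produced it, so that two
#' runs can be compared for identity.
#'
#' @param config Any serializable configuration object.
#' @param seed Integer seed of the run.
#' @return Named list with `package`, `version`, `seed`, `config_hash`,
#'   `created`.
#' @export
provenance <- function(config, seed = NA_integer_) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  list(package = "cohaco",
       version = as.character(utils::packageVersion("cohaco")),
       seed = seed,
       config_hash = .fnv1a(as.character(js)),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

# FNV-1a 32-bit hash, hex string; avoids an external digest dependency.
# Arithmetic is split 16/16 so intermediates stay exact in doubles.
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a search result to JSON (plus a convergence trace CSV)
#'
#' The JSON carries the selected feature names, the binary mask, accuracy,
#' fitness and evaluation count with a provenance block; the companion
#' `<stem>_trace.csv` holds the per-iteration best/mean fitness for
#' convergence plots.
#'
#' @param result A `search_result`.
#' @param path Output JSON path.
#' @param n_features Total feature count (for the mask).
#' @param config,seed Forwarded to [provenance()].
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path, n_features =
                                  max(result$best$subset),
                                config = NULL, seed = NA_integer_) {
  mask <- integer(n_features)
  mask[result$best$subset] <- 1L
  out <- list(method = result$method,
              selected_features = result$best$feature_names,
              mask = mask,
              n_selected = result$best$n_selected,
              accuracy = result$best$accuracy,
              fitness = result$best$fitness,
              evaluations = result$evaluations,
              provenance = provenance(config, seed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(result$history)) {
    trace_path <- sub("\\.json$", "_trace.csv", path)
    data.table::fwrite(result$history[, c("iteration", "best_fitness",
                                          "mean_fitness")], trace_path)
  }
  invisible(path)
}

#' Write a nested-CV report
#'
#' Emits `report.json` (per-fold subsets and metrics, aggregate means,
#' global best), `roc.csv` (per-fold FPR/TPR curves from the decision
#' scores), and `selected_features.csv` (fold, feature, pair, band of every
#' selected feature).
#'
#' @param report A `cv_report` from [run_nested_cv()].
#' @param dir Output directory.
#' @param config,seed Forwarded to [provenance()].
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir, config = NULL, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fold_json <- lapply(report$folds, function(f)
    list(fold = f$fold, n_selected = f$n_selected,
         feature_names = f$feature_names,
         accuracy = f$accuracy, sensitivity = f$sensitivity, auc = f$auc))
  out <- list(fs_method = report$fs_method,
              positive = report$positive,
              folds = fold_json,
              aggregate = report$aggregate,
              global_best = list(fold = report$global_best$fold,
                                 n_selected = report$global_best$n_selected,
                                 feature_names = report$global_best$feature_names,
                                 fitness = report$global_best_fitness),
              provenance = provenance(config, seed))
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  roc <- do.call(rbind, lapply(report$folds, function(f)
    cbind(fold = f$fold, .roc_points(f$scores, f$truth, report$positive))))
  data.table::fwrite(roc, file.path(dir, "roc.csv"))
  sel <- do.call(rbind, lapply(report$folds, function(f) {
    if (f$n_selected == 0) return(NULL)
    parts <- strsplit(f$feature_names, "_", fixed = TRUE)
    data.frame(fold = f$fold, feature = f$feature_names,
               pair = vapply(parts, `[`, character(1), 1),
               band = vapply(parts, `[`, character(1), 2))
  }))
  data.table::fwrite(sel, file.path(dir, "selected_features.csv"))
  invisible(dir)
}

.roc_points <- function(scores, truth, positive) {
  is_pos <- truth == positive
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  data.frame(fpr = c(0, fp / max(1, sum(!is_pos))),
             tpr = c(0, tp / max(1, sum(is_pos))))
}

#' Write the method-comparison table
#'
#' @param tab A [compare_methods()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compare_table <- function(tab, path) {
  data.table::fwrite(as.data.frame(tab), path)
  invisible(path)
}
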