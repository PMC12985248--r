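# End-to-end orchestration and on-disk containers: simulate -> preprocess
# -> train -> translate -> evaluate, each stage a plain function over the
# package's core, with per-stage error context.

#' Write paired recordings to a directory container
#'
#' One gzip-compressed CSV of samples per record plus a `metadata.csv`
#' sidecar (record id, rhythm, PTT, sampling rate, peak indices).
#'
#' @param records List of paired recordings ([generate_dataset()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recordings <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(records, function(r)
    data.frame(record_id = r$record_id, rhythm = r$rhythm, ptt_s = r$ptt_s,
               fs = r$fs, n_samples = length(r$ecg),
               r_peaks = paste(r$r_peaks, collapse = ";"))))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (r in records) {
    f <- gzfile(file.path(dir, sprintf("record_%04d.csv.gz", r$record_id)), "w")
    utils::write.csv(data.frame(ecg = r$ecg, ppg = r$ppg), f,
                     row.names = FALSE)
    close(f)
  }
  invisible(dir)
}

#' Read a paired-recording container written by [write_recordings()]
#'
#' @param dir Container directory.
#' @return A list of paired recordings.
#' @export
read_recordings <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    sig <- utils::read.csv(file.path(
      dir, sprintf("record_%04d.csv.gz", meta$record_id[i])))
    list(ecg = sig$ecg, ppg = sig$ppg,
         r_peaks = as.integer(strsplit(meta$r_peaks[i], ";")[[1]]),
         rhythm = meta$rhythm[i], ptt_s = meta$ptt_s[i], fs = meta$fs[i],
         record_id = meta$record_id[i])
  })
}

#' Write model-ready signal windows to a single container file
#'
#' Gzip CSV in long layout: one row per (window, sample) with columns for
#' both channels and the mask, plus JSON-encoded per-window metadata
#' (peaks, normalization parameters) in a sidecar column-free header row
#' handled via a companion `.meta.json` file.
#'
#' @param windows List of signal windows ([make_windows()]).
#' @param path Output path (`.csv.gz`); the metadata sidecar gets the
#'   extension `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  L <- length(windows[[1L]]$ecg)
  wide <- do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(window = i, sample = seq_len(L), ppg = w$ppg, ecg = w$ecg,
               mask = w$mask)
  }))
  f <- gzfile(path, "w")
  utils::write.csv(wide, f, row.names = FALSE)
  close(f)
  meta <- lapply(windows, function(w)
    list(r_peaks = w$r_peaks, fs = w$fs, norm_ppg = unname(w$norm_ppg),
         norm_ecg = unname(w$norm_ecg), degenerate = w$degenerate,
         window_index = w$window_index, record_id = w$record_id,
         rhythm = w$rhythm))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a window container written by [write_windows()]
#'
#' @param path Container path (`.csv.gz`).
#' @return A list of signal windows.
#' @export
read_windows <- function(path) {
  wide <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  lapply(sort(unique(wide$window)), function(i) {
    rows <- wide[wide$window == i, ]
    m <- meta[[i]]
    list(ppg = rows$ppg, ecg = rows$ecg, mask = as.integer(rows$mask),
         r_peaks = as.integer(unlist(m$r_peaks)), fs = m$fs,
         norm_ppg = as.numeric(unlist(m$norm_ppg)),
         norm_ecg = as.numeric(unlist(m$norm_ecg)),
         degenerate = isTRUE(m$degenerate),
         window_index = m$window_index, record_id = m$record_id,
         rhythm = m$rhythm)
  })
}

#' Simulate a dataset and persist it
#'
#' @param n_records Number of records.
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param ... Passed to [generate_dataset()].
#' @return The records, invisibly (container written to `dir`).
#' @export
run_simulate <- function(n_records, config, dir, ...) {
  if (n_records < 1) stop("simulate stage: n_records must be >= 1")
  records <- .stage("simulate", generate_dataset(n_records, config, ...))
  .stage("simulate", write_recordings(records, dir))
  invisible(records)
}

#' Translate a container of PPG windows with a model checkpoint
#'
#' @param model A `"physdiff"` object or path to an RDS checkpoint.
#' @param windows List of signal windows (their `ppg` fields are used).
#' @param seed Sampler seed.
#' @param out Optional path for a gzip CSV of the generated windows
#'   (one column per window).
#' @return L x B matrix of generated ECG windows.
#' @export
run_translate <- function(model, windows, seed = 1L, out = NULL) {
  if (is.character(model)) model <- readRDS(model)
  L <- length(windows[[1L]]$ppg)
  if (L != model$cfg$L)
    stop(sprintf("translate stage: window length %d does not match checkpoint L = %d",
                 L, model$cfg$L))
  gen <- .stage("translate", predict(model, windows, seed = seed))
  if (!is.null(out)) {
    f <- gzfile(out, "w")
    utils::write.csv(as.data.frame(gen), f, row.names = FALSE)
    close(f)
  }
  gen
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Desk-scale end-to-end smoke run
#'
#' Simulates paired records (heart rate 60-90 BPM, PTT 0.2-0.3 s by
#' default), preprocesses them into 4-s windows at 128 Hz, trains a tiny
#' model, translates held-out PPG windows, and evaluates RMSE / HR-MAE /
#' FD against the held-out ECG, also reporting the untrained model's RMSE
#' for reference.
#'
#' @param n_train_windows,n_eval_windows Window budget for the two splits.
#' @param steps,batch_size,base_width,T_steps Tiny training configuration.
#' @param seed Global seed (propagated to simulator, trainer, sampler).
#' @param verbose Print stage progress and loss lines.
#' @return A list with `metrics` (an `"evaluate_windows"` report),
#'   `rmse_untrained`, `model`, and the held-out `windows`.
#' @export
e2e_smoke <- function(n_train_windows = 200L, n_eval_windows = 32L,
                      steps = 500L, batch_size = 16L, base_width = 16L,
                      T_steps = 50L, seed = 1L, verbose = FALSE) {
  cfg <- sim_config(duration_s = 20, noise_sd = 0.02,
                    baseline_wander_amp = 0.1, seed = seed)
  per_rec <- floor(20 / 4)
  n_rec <- ceiling((n_train_windows + n_eval_windows) / per_rec) + 2L
  records <- .stage("simulate",
                    generate_dataset(n_rec, cfg, seed = seed,
                                     hr_range = c(60, 90),
                                     ptt_range = c(0.2, 0.3)))
  windows <- .stage("preprocess", make_windows(records))
  need <- n_train_windows + n_eval_windows
  if (length(windows) < need)
    stop("[stage preprocess] not enough windows generated")
  train_w <- windows[seq_len(n_train_windows)]
  eval_w <- windows[(n_train_windows + 1L):need]
  untrained <- .stage("train",
                      physdiff(train_w, steps = 0L, batch_size = batch_size,
                               base_width = base_width, T_steps = T_steps,
                               seed = seed))
  model <- .stage("train",
                  physdiff_train(untrained, train_w, steps,
                                 verbose = verbose))
  true_ecg <- vapply(eval_w, `[[`, numeric(model$cfg$L), "ecg")
  gen <- .stage("translate", predict(model, eval_w, seed = seed + 1L))
  gen0 <- .stage("translate", predict(untrained, eval_w, seed = seed + 1L))
  metrics <- .stage("evaluate", evaluate_windows(true_ecg, gen, fs = 128))
  list(metrics = metrics,
       rmse_untrained = metric_rmse(true_ecg, gen0),
       model = model, windows = eval_w, generated = gen)
}

#' Write a metrics report as JSON
#'
#' @param metrics A `"physdiff_metrics"` object ([evaluate_windows()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
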