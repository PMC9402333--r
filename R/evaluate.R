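# Monte-Carlo evaluation of the denoiser over a noise-kind x SNR grid.

# Deterministic per-cell seed derived from (master_seed, kind, level, rep)
# by a small modular string hash, so every cell is independently
# re-runnable. Stays below 2^31.
derive_cell_seed <- function(master_seed, kind, level, rep) {
  p <- 2147483629
  h <- as.numeric(master_seed) %% p
  mix <- function(h, v) (h * 131 + v) %% p
  for (ch in utf8ToInt(as.character(kind))) h <- mix(h, ch)
  for (ch in utf8ToInt(sprintf("%.10g", level))) h <- mix(h, ch)
  h <- mix(h, rep)
  as.integer(h) + 1L
}

grid_noise <- function(kind, n, fs, seed) {
  if (kind == "emg+gaussian") {
    # Equal-power sum of the two components before SNR scaling.
    e <- gen_noise("emg", n, fs, seed = seed)
    g <- gen_noise("gaussian", n, fs, seed = seed + 1L)
    e / rms(e) + g / rms(g)
  } else {
    gen_noise(kind, n, fs, seed = seed)
  }
}

#' Run the Monte-Carlo denoising evaluation grid
#'
#' For every combination of noise kind, input SNR level and repetition:
#' generate noise with a per-cell seed derived from `master_seed`, mix it
#' into the clean record at the exact target SNR, denoise, and score the
#' result with [snr_improvement()], [mse()] and [prd()]. Rows with a
#' degenerate (non-finite) metric are dropped with a logged `key=value`
#' warning count. Deterministic end-to-end for a fixed `master_seed`.
#'
#' @param base_signal Clean reference [ecg_signal()].
#' @param noise_kinds Character vector drawn from `"gaussian"`, `"emg"`,
#'   `"powerline"`, `"baseline"`, `"emg+gaussian"`.
#' @param snr_levels_db Numeric vector of input SNR levels in dB.
#' @param reps Repetitions per cell.
#' @param sift_cfg A [sift_config()].
#' @param den_cfg A [denoise_config()].
#' @param master_seed Integer master seed.
#' @return An object of class `"ecg_evaluation"`: `rows` (one data-frame
#'   row per trial), `aggregates` (per kind x level mean/sd of each metric
#'   and `n_reps`), `dropped` (count of degenerate rows), `config`
#'   (snapshot of every applied setting) and `master_seed`.
#' @export
run_grid <- function(base_signal,
                     noise_kinds = c("gaussian", "emg", "powerline"),
                     snr_levels_db = seq(0, 25, by = 5),
                     reps = 100L,
                     sift_cfg = sift_config(),
                     den_cfg = denoise_config(),
                     master_seed = 1L) {
  stopifnot(inherits(base_signal, "ecg_signal"))
  allowed <- c("gaussian", "emg", "powerline", "baseline", "emg+gaussian")
  if (length(noise_kinds) == 0L || !all(noise_kinds %in% allowed))
    stop(sprintf("noise kinds must be among: %s", paste(allowed, collapse = ", ")))
  if (length(snr_levels_db) == 0L)
    stop("'snr_levels_db' must be non-empty")
  check_scalar(reps, "reps", lower = 1)
  reps <- as.integer(reps)

  config <- list(
    fs = base_signal$fs, n = length(base_signal$samples),
    noise_kinds = noise_kinds, snr_levels_db = snr_levels_db, reps = reps,
    nsd_threshold = sift_cfg$nsd_threshold,
    max_sift_iters = sift_cfg$max_sift_iters, max_imfs = sift_cfg$max_imfs,
    boundary_extrema = sift_cfg$boundary_extrema,
    zero_floor = sift_cfg$zero_floor,
    mean_threshold_factor = den_cfg$mean_threshold_factor,
    power_fraction = den_cfg$power_fraction,
    max_noise_imfs = den_cfg$max_noise_imfs,
    attenuation_mode = den_cfg$attenuation_mode,
    baseline_segment_seconds = den_cfg$baseline_segment_seconds,
    baseline_max_hz = den_cfg$baseline_max_hz,
    remove_baseline = den_cfg$remove_baseline
  )
  do.call(log_kv, c(list(event = "grid_config"),
                    lapply(config, function(v) paste(v, collapse = "|"))))

  clean <- base_signal$samples
  n <- length(clean)
  cells <- expand.grid(rep = seq_len(reps), input_snr_db = snr_levels_db,
                       noise_kind = noise_kinds, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    kind <- cells$noise_kind[i]
    level <- cells$input_snr_db[i]
    rep_i <- cells$rep[i]
    seed <- derive_cell_seed(master_seed, kind, level, rep_i)
    noise <- grid_noise(kind, n, base_signal$fs, seed)
    mixed <- mix_at_snr(base_signal, noise, level)
    den <- ecg_denoise(mixed$corrupted, sift_cfg = sift_cfg, den_cfg = den_cfg)
    est <- fitted(den)
    rows[[i]] <- data.frame(
      noise_kind = kind, input_snr_db = level, rep = rep_i, seed = seed,
      snr_improvement_db = snr_improvement(clean, mixed$corrupted$samples, est),
      mse = mse(clean, est),
      prd = prd(clean, est),
      stringsAsFactors = FALSE
    )
  }
  rows <- do.call(rbind, rows)
  finite <- is.finite(rows$snr_improvement_db) & is.finite(rows$mse) & is.finite(rows$prd)
  dropped <- sum(!finite)
  if (dropped > 0L)
    log_kv("degenerate_rows_dropped", count = dropped)
  rows <- rows[finite, , drop = FALSE]
  rownames(rows) <- NULL

  agg <- stats::aggregate(
    rows[, c("snr_improvement_db", "mse", "prd")],
    by = rows[, c("noise_kind", "input_snr_db")],
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v))
  )
  aggregates <- data.frame(
    noise_kind = agg$noise_kind, input_snr_db = agg$input_snr_db,
    mean_snr_improvement_db = agg$snr_improvement_db[, "mean"],
    sd_snr_improvement_db = agg$snr_improvement_db[, "sd"],
    mean_mse = agg$mse[, "mean"], sd_mse = agg$mse[, "sd"],
    mean_prd = agg$prd[, "mean"], sd_prd = agg$prd[, "sd"],
    n_reps = as.vector(table(interaction(rows$noise_kind, rows$input_snr_db,
                                         drop = TRUE))[
      interaction(agg$noise_kind, agg$input_snr_db, drop = TRUE)]),
    stringsAsFactors = FALSE
  )
  o <- order(aggregates$noise_kind, aggregates$input_snr_db)
  aggregates <- aggregates[o, , drop = FALSE]
  rownames(aggregates) <- NULL

  structure(list(rows = rows, aggregates = aggregates, dropped = dropped,
                 config = config, master_seed = as.integer(master_seed)),
            class = "ecg_evaluation")
}

#' @export
print.ecg_evaluation <- function(x, ...) {
  cat(sprintf("ECG denoising evaluation: %d trials (%d dropped), master seed %d\n",
              nrow(x$rows) + x$dropped, x$dropped, x$master_seed))
  print(x$aggregates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an evaluation report
#'
#' `format = "json"` writes a single document embedding the configuration
#' snapshot, master seed, per-trial rows and aggregates (read it back with
#' [read_report()]). `format = "csv"` writes the rows to `path` and the
#' aggregates next to it with an `_aggregates.csv` suffix.
#'
#' @param result An `"ecg_evaluation"` from [run_grid()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv")) {
  stopifnot(inherits(result, "ecg_evaluation"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(schema = "emdecg-evaluation/1", master_seed = result$master_seed,
           dropped = result$dropped, config = result$config,
           rows = result$rows, aggregates = result$aggregates),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
  } else {
    utils::write.csv(result$rows, path, row.names = FALSE)
    agg_path <- if (grepl("\\.csv$", path)) {
      sub("\\.csv$", "_aggregates.csv", path)
    } else paste0(path, "_aggregates.csv")
    utils::write.csv(result$aggregates, agg_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return An `"ecg_evaluation"` equal to the one that was written.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "emdecg-evaluation/1"))
    stop("not an emdecg evaluation report")
  structure(list(rows = as.data.frame(doc$rows),
                 aggregates = as.data.frame(doc$aggregates),
                 dropped = doc$dropped,
                 config = doc$config,
                 master_seed = as.integer(doc$master_seed)),
            class = "ecg_evaluation")
}
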