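# Binary event-packet format and tidy CSV conversion.
#
# One packet per metronome event window, 12 bytes, little-endian:
#   bytes 1-4   tone onset, unsigned 32-bit integer milliseconds
#   bytes 5-12  four signed 16-bit relative tap times (tap - tone, ms),
#               in tapper order; unused slots and missed taps hold the
#               sentinel -32768 (INT16_MIN, outside any legal half-IOI
#               window). A `.gem` file is a plain concatenation of packets,
#               optionally with a JSON sidecar carrying the trial config.

GEM_MISSING_SENTINEL <- -32768L
GEM_PACKET_BYTES <- 12L

u32_to_raw <- function(x) {
  # R integers are signed 32-bit; go through doubles to cover the full range
  x <- as.double(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
}

raw_to_u32 <- function(b) {
  sum(as.double(b) * c(1, 256, 65536, 16777216))
}

#' Serialize window records to event packets
#'
#' @param tone_times Numeric vector of tone onsets (ms); truncated to integer
#'   ms on serialization and must fit in an unsigned 32-bit integer.
#' @param tap_rel Matrix (`length(tone_times)` rows, up to 4 columns) of
#'   relative tap times in ms, NA = missed; rounded to integer ms. Trials
#'   with fewer than 4 tappers pad the unused slots with the missing
#'   sentinel.
#' @return Raw vector of `12 * length(tone_times)` bytes.
#' @export
#' @examples
#' length(write_packets(10000, matrix(c(-20, 10, NA, 40), 1)))  # 12
write_packets <- function(tone_times, tap_rel) {
  tap_rel <- as.matrix(tap_rel)
  n <- length(tone_times)
  stopifnot(nrow(tap_rel) == n, ncol(tap_rel) <= 4)
  onset <- trunc(as.double(tone_times))
  if (any(onset < 0 | onset > 4294967295))
    stop("tone onset out of unsigned 32-bit range", call. = FALSE)
  rel <- round(tap_rel)
  if (any(!is.na(rel) & (rel < -32767 | rel > 32767)))
    stop("relative tap time out of signed 16-bit range", call. = FALSE)
  slots <- matrix(GEM_MISSING_SENTINEL, nrow = n, ncol = 4L)
  if (ncol(rel) > 0) {
    filled <- !is.na(rel)
    slots[, seq_len(ncol(rel))][filled] <- as.integer(rel[filled])
  }
  out <- raw(GEM_PACKET_BYTES * n)
  for (w in seq_len(n)) {
    off <- (w - 1L) * GEM_PACKET_BYTES
    out[off + 1:4] <- u32_to_raw(onset[w])
    out[off + 5:12] <- writeBin(slots[w, ], raw(), size = 2L, endian = "little")
  }
  out
}

#' Parse a stream of event packets
#'
#' @param bytes Raw vector; length must be a multiple of 12, else a parse
#'   error reports the byte offset of the truncated packet.
#' @return List with `tone_times` (numeric) and `tap_rel` (n x 4 matrix, NA
#'   where a slot holds the missing sentinel). Non-monotonic onsets are
#'   flagged with a warning.
#' @export
read_packets <- function(bytes) {
  stopifnot(is.raw(bytes))
  n_bytes <- length(bytes)
  if (n_bytes %% GEM_PACKET_BYTES != 0L)
    stop(sprintf("truncated packet stream: %d bytes is not a multiple of 12 (error at offset %d)",
                 n_bytes, (n_bytes %/% GEM_PACKET_BYTES) * GEM_PACKET_BYTES),
         call. = FALSE)
  n <- n_bytes %/% GEM_PACKET_BYTES
  tone_times <- numeric(n)
  tap_rel <- matrix(NA_real_, n, 4L)
  for (w in seq_len(n)) {
    off <- (w - 1L) * GEM_PACKET_BYTES
    tone_times[w] <- raw_to_u32(bytes[off + 1:4])
    slots <- readBin(bytes[off + 5:12], integer(), n = 4L, size = 2L,
                     signed = TRUE, endian = "little")
    keep <- slots != GEM_MISSING_SENTINEL
    tap_rel[w, keep] <- as.double(slots[keep])
  }
  if (n > 1 && any(diff(tone_times) <= 0))
    warning("non-monotonic tone onsets in packet stream", call. = FALSE)
  list(tone_times = tone_times, tap_rel = tap_rel)
}

#' Write a trial to a `.gem` binary file
#'
#' Concatenated 12-byte packets plus a JSON sidecar (`<path>.json`) holding
#' the trial config and seed, so the binary is self-describing.
#'
#' @param trial A `gem_trial`.
#' @param path Output file path.
#' @param sidecar Write the JSON config sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_gem <- function(trial, path, sidecar = TRUE) {
  stopifnot(inherits(trial, "gem_trial"))
  bytes <- write_packets(trial$tone_times, trial$tap_rel)
  writeBin(bytes, path)
  if (sidecar) {
    meta <- c(unclass(trial$config),
              list(seed = trial$seed, trial_id = trial$trial_id))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a `.gem` binary file back into a trial
#'
#' @param path `.gem` file path. If the JSON sidecar is present it supplies
#'   the trial config; otherwise supply `config`.
#' @param config Optional [trial_config()] overriding/replacing the sidecar.
#' @return A `gem_trial`.
#' @export
read_gem <- function(path, config = NULL) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  parsed <- read_packets(bytes)
  sidecar <- paste0(path, ".json")
  seed <- NA_integer_; trial_id <- NA_character_
  if (is.null(config)) {
    if (!file.exists(sidecar))
      stop("no sidecar found for ", path, "; supply `config`", call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    config <- trial_config(ioi = meta$ioi, alpha = meta$alpha,
                           n_tones = meta$n_tones, n_tappers = meta$n_tappers,
                           feedback = meta$feedback,
                           start_time = meta$start_time)
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
    if (!is.null(meta$trial_id) && !is.na(meta$trial_id))
      trial_id <- as.character(meta$trial_id)
  }
  stopifnot(length(parsed$tone_times) == config$n_tones)
  new_gem_trial(config, parsed$tone_times,
                parsed$tap_rel[, seq_len(config$n_tappers), drop = FALSE],
                seed = seed, trial_id = trial_id)
}

#' Convert a trial to the tidy window-level table
#'
#' One row per window per tapper: `trial_id, alpha, tone_index, tone_time,
#' tapper_id, tap_rel, missed`. `tone_index` is 0-based (matching the
#' device's window numbering); a missed tap has an empty `tap_rel` (NA) and
#' `missed = 1`.
#'
#' @param trial A `gem_trial`.
#' @param trial_id Identifier; defaults to the trial's own.
#' @return A `data.frame`.
#' @export
trial_to_df <- function(trial, trial_id = trial$trial_id) {
  n <- trial$config$n_tones
  I <- trial$config$n_tappers
  data.frame(
    trial_id = if (is.na(trial_id)) "trial001" else trial_id,
    alpha = trial$config$alpha,
    tone_index = rep(seq_len(n) - 1L, times = I),
    tone_time = rep(trial$tone_times, times = I),
    tapper_id = rep(sprintf("tapper%d", seq_len(I)), each = n),
    tap_rel = as.vector(trial$tap_rel),
    missed = as.integer(is.na(as.vector(trial$tap_rel))),
    stringsAsFactors = FALSE
  )
}

#' Rebuild a trial from the tidy table
#'
#' Inverse of [trial_to_df()] for integer-millisecond data (lossless round
#' trip on serialized trials).
#'
#' @param df Tidy window-level `data.frame` for a single trial.
#' @param config Optional [trial_config()]; reconstructed from the table
#'   (IOI inferred from the first inter-tone interval) if omitted.
#' @return A `gem_trial`.
#' @export
df_to_trial <- function(df, config = NULL) {
  needed <- c("trial_id", "alpha", "tone_index", "tone_time", "tapper_id",
              "tap_rel", "missed")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), needed)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (length(unique(df$trial_id)) != 1L)
    stop("`df` must contain exactly one trial", call. = FALSE)
  tappers <- sort(unique(df$tapper_id))
  df <- df[order(match(df$tapper_id, tappers), df$tone_index), ]
  n <- length(unique(df$tone_index))
  I <- length(tappers)
  tone_times <- df$tone_time[seq_len(n)]
  tap_rel <- matrix(df$tap_rel, nrow = n, ncol = I)
  tap_rel[matrix(df$missed == 1L, n, I)] <- NA_real_
  if (is.null(config))
    config <- trial_config(ioi = tone_times[2] - tone_times[1],
                           alpha = df$alpha[1], n_tones = n, n_tappers = I,
                           start_time = tone_times[1])
  new_gem_trial(config, tone_times, tap_rel,
                trial_id = as.character(df$trial_id[1]))
}

#' Write / read the tidy CSV layout
#'
#' @param trials A `gem_trial` or list of them.
#' @param path CSV path.
#' @return `write_trial_csv`: `path` invisibly. `read_trial_csv`: list of
#'   `gem_trial` objects (one per `trial_id`).
#' @export
write_trial_csv <- function(trials, path) {
  if (inherits(trials, "gem_trial")) trials <- list(trials)
  ids <- vapply(seq_along(trials), function(k) {
    id <- trials[[k]]$trial_id
    if (is.na(id)) sprintf("trial%03d", k) else id
  }, character(1))
  df <- do.call(rbind, Map(trial_to_df, trials, ids))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$trial_id), df_to_trial)
}
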