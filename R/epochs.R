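# Epoched-recording data model: EpochSet, RegionMap, and the plain-text
# exchange format.

#' Construct an epoch set
#'
#' An `epoch_set` holds labeled single-trial multichannel voltage series:
#' a `trials x channels x samples` array plus the per-trial class labels,
#' sampling rate, channel names, and the time of the first sample relative
#' to stimulus onset.
#'
#' @param data numeric array `trials x channels x samples` (microvolts).
#' @param labels integer-like class label per trial.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per channel.
#' @param t0 time of the first sample relative to stimulus onset, ms.
#' @return an object of class `epoch_set`.
#' @examples
#' x <- array(rnorm(2 * 3 * 64), c(2, 3, 64))
#' ep <- epoch_set(x, labels = c(1, 2), fs = 64,
#'                 channel_names = c("Fz", "Cz", "Pz"), t0 = 0)
#' dim(ep$data)
#' @export
epoch_set <- function(data, labels, fs, channel_names = NULL, t0 = 0) {
  abort_if(!is.array(data) || length(dim(data)) != 3L,
           "`data` must be a 3-d array trials x channels x samples")
  d <- dim(data)
  abort_if(d[1] < 1L, "need at least one trial")
  abort_if(length(labels) != d[1],
           "labels length (%d) does not match trial count (%d)",
           length(labels), d[1])
  abort_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0, "`fs` must be > 0")
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(d[2]))
  }
  abort_if(length(channel_names) != d[2],
           "channel_names length (%d) != channel count (%d)",
           length(channel_names), d[2])
  abort_if(anyDuplicated(channel_names) > 0, "duplicate channel names")
  structure(list(
    data = data,
    labels = as.integer(labels),
    fs = as.numeric(fs),
    channel_names = as.character(channel_names),
    t0 = as.numeric(t0)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  time %g .. %g ms, classes: %s\n",
              x$t0, x$t0 + (d[3] - 1) / x$fs * 1000,
              paste(sprintf("%d (n=%d)", as.integer(names(table(x$labels))),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

# Per-sample times in ms relative to stimulus onset.
epoch_times_ms <- function(ep) {
  ep$t0 + (seq_len(dim(ep$data)[3]) - 1) / ep$fs * 1000
}

#' @export
n_trials <- function(x) UseMethod("n_trials")
#' @export
n_trials.epoch_set <- function(x) dim(x$data)[1]

# ---------------------------------------------------------------------------
# Region map

REGION_NAMES <- c("frontal-left", "frontal-right",
                  "posterior-left", "posterior-right")

#' Construct a channel-to-region map
#'
#' Maps each channel name to one of the four scalp quadrants used for the
#' regional features (`frontal-left`, `frontal-right`, `posterior-left`,
#' `posterior-right`) or to `"excluded"`.
#'
#' @param regions named character vector: names are channel names, values
#'   are region labels.
#' @return an object of class `region_map`.
#' @seealso [default_region_map()]
#' @export
region_map <- function(regions) {
  abort_if(is.null(names(regions)) || any(names(regions) == ""),
           "`regions` must be a named character vector (channel -> region)")
  bad <- setdiff(unique(regions), c(REGION_NAMES, "excluded"))
  abort_if(length(bad) > 0, "unknown region label(s): %s",
           paste(bad, collapse = ", "))
  structure(list(regions = regions), class = "region_map")
}

#' Default region map for the 32-channel extended 10-20 montage
#'
#' Laterality follows the odd/even electrode-number convention (odd = left,
#' even = right); the anterior/posterior split follows the label family
#' (AF/FP/F/FC = frontal, C/CP/P/PO/O/T = posterior). Midline channels
#' (Fz, Cz, Pz, Oz) are excluded from region features.
#'
#' @param channel_names channels to map; defaults to the standard 32.
#' @return a `region_map`.
#' @export
default_region_map <- function(channel_names = default_montage()) {
  side <- function(nm) {
    num <- suppressWarnings(as.integer(gsub("[^0-9]", "", nm)))
    if (is.na(num)) return(NA_character_)           # midline (z)
    if (num %% 2L == 1L) "left" else "right"
  }
  ap <- function(nm) {
    fam <- toupper(gsub("[0-9z]", "", nm))
    if (fam %in% c("AF", "FP", "F", "FC")) "frontal"
    else if (fam %in% c("C", "CP", "P", "PO", "O", "T")) "posterior"
    else NA_character_
  }
  reg <- vapply(channel_names, function(nm) {
    s <- side(nm); a <- ap(nm)
    if (is.na(s) || is.na(a)) "excluded" else paste(a, s, sep = "-")
  }, character(1))
  region_map(reg)
}

#' The 32-channel montage used as the package default
#' @return character vector of 32 channel names (extended 10-20 layout).
#' @export
default_montage <- function() {
  c("AF3", "AF4", "FC1", "FC2", "FC5", "FC6", "FP1", "FP2",
    "F7", "F3", "Fz", "F4", "F8", "C3", "Cz", "C4",
    "CP1", "CP2", "CP5", "CP6", "P7", "PO3", "PO4", "P3",
    "Pz", "P4", "P8", "T7", "T8", "O1", "Oz", "O2")
}

# Channel indices per region, in the canonical region order. Errors if a
# requested region has no member channel.
region_indices <- function(rmap, channel_names) {
  miss <- setdiff(channel_names, names(rmap$regions))
  abort_if(length(miss) > 0, "region map does not cover channel(s): %s",
           paste(miss, collapse = ", "))
  out <- lapply(REGION_NAMES, function(r) {
    which(channel_names %in% names(rmap$regions)[rmap$regions == r])
  })
  names(out) <- REGION_NAMES
  empty <- REGION_NAMES[vapply(out, length, 1L) == 0L]
  abort_if(length(empty) > 0, "region(s) with no channels: %s",
           paste(empty, collapse = ", "))
  out
}

# ---------------------------------------------------------------------------
# Exchange format: <dir>/meta.json + <dir>/data.tsv (one row per trial,
# channels x samples flattened channel-major), all plain text.

#' Write an epoch set to the plain-text exchange layout
#'
#' The layout is a directory holding `meta.json` (labels, fs,
#' channel_names, t0, dims) and `data.tsv` (one row per trial, the
#' `channels x samples` matrix flattened channel-major).
#'
#' @param ep an `epoch_set`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(ep, dir) {
  stopifnot(inherits(ep, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ep$data)
  meta <- list(labels = ep$labels, fs = ep$fs,
               channel_names = ep$channel_names, t0 = ep$t0,
               n_trials = d[1], n_channels = d[2], n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(dir, "data.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' Read an epoch set from the plain-text exchange layout
#' @param dir directory written by [write_epochs()].
#' @return an `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.tsv"),
                                      sep = "\t", header = FALSE,
                                      colClasses = "numeric"))
  d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
  abort_if(nrow(flat) != d[1] || ncol(flat) != d[2] * d[3],
           "data.tsv dims do not match meta.json")
  data <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(data, meta$labels, meta$fs, meta$channel_names, meta$t0)
}
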