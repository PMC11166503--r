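#' Write an epoch set to the package's on-disk layout
#'
#' One directory per participant: `data.bin` (little-endian float64,
#' trial-major), `meta.json` (dims, time axis, sampling rate, channel
#' labels) and `trials.csv` (the trial table). The layout is the same
#' "array + sidecar JSON" convention accepted by [read_epochs()], so
#' externally preprocessed data can be mounted by writing these three
#' files.
#'
#' @param epochs an `epoch_set`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "data.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(dims = dim(epochs$data), times = epochs$times,
               sfreq = epochs$sfreq, channel_names = epochs$channel_names)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(epochs$trial_table, file.path(path, "trials.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read an epoch set from the on-disk layout
#'
#' @param path directory written by [write_epochs()] (or assembled by hand
#'   in the same array + sidecar JSON convention).
#' @param montage optional montage to attach.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path, montage = NULL) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  con <- file(file.path(path, "data.bin"), "rb")
  x <- readBin(con, "double", n = prod(dims), size = 8, endian = "little")
  close(con)
  tt <- utils::read.csv(file.path(path, "trials.csv"),
                        stringsAsFactors = FALSE)
  epoch_set(array(x, dims), as.numeric(meta$times), meta$sfreq,
            as.character(meta$channel_names), tt, montage = montage)
}

#' Write / read a behavioral score table
#'
#' CSV with columns `participant, condition, identification, gist, detail`.
#'
#' @param behavior data.frame as produced by [simulate_behavior()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_behavior <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a stack of per-rater dissimilarity ratings
#'
#' Long CSV with columns `rater, item_i, item_j, rating`; reading restores
#' the raters x items x items array.
#'
#' @param stack 3-D array `raters x items x items` with item dimnames.
#' @param path CSV path.
#' @return `path` (write) or the array (read).
#' @export
write_ratings <- function(stack, path) {
  d <- dim(stack)
  items <- dimnames(stack)[[2]]
  idx <- which(upper.tri(matrix(0, d[2], d[3])) |
               lower.tri(matrix(0, d[2], d[3])), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(r) {
    data.frame(rater = r, item_i = items[idx[, 1]], item_j = items[idx[, 2]],
               rating = stack[r, ][ (idx[, 2] - 1) * d[2] + idx[, 1] ])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- sort(unique(c(df$item_i, df$item_j)))
  raters <- sort(unique(df$rater))
  out <- array(NA_real_, c(length(raters), length(items), length(items)),
               dimnames = list(NULL, items, items))
  for (k in seq_len(nrow(df))) {
    out[match(df$rater[k], raters), df$item_i[k], df$item_j[k]] <- df$rating[k]
  }
  out
}
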