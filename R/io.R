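## Reading and writing the benchmark episode dialect: one CSV per episode
## with header "Hours,<channel names>" and one row per event (blank cells =
## unmeasured), plus a listfile index with columns "stay,y_true".
## Floats are written with 6 significant digits; round-trips are lossless at
## that precision.

fmt6 <- function(x) formatC(x, format = "g", digits = 6)

#' Write episodes in the benchmark CSV dialect
#'
#' @param episodes list of `raw_episode`.
#' @param dir output directory (created if needed).
#' @param channels channel table (column names).
#' @param listfile name of the index file written inside `dir`.
#' @return invisibly, the paths of the written episode files.
#' @export
write_episodes <- function(episodes, dir, channels = default_channel_table(),
                           listfile = "listfile.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste(c("Hours", channels$name), collapse = ",")
  paths <- character(length(episodes))
  for (i in seq_along(episodes)) {
    e <- episodes[[i]]
    fname <- paste0(e$episode_id, ".csv")
    paths[i] <- file.path(dir, fname)
    ev <- e$events
    cells <- matrix("", nrow(ev), nrow(channels))
    cells[cbind(seq_len(nrow(ev)), ev$channel)] <- fmt6(ev$value)
    lines <- paste(fmt6(ev$time),
                   apply(cells, 1, paste, collapse = ","), sep = ",")
    writeLines(c(header, lines), paths[i])
  }
  idx <- data.frame(
    stay = vapply(episodes, function(e) paste0(e$episode_id, ".csv"),
                  character(1)),
    y_true = episode_labels(episodes)
  )
  utils::write.csv(idx, file.path(dir, listfile), row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' Read episodes written by [write_episodes()]
#'
#' @param dir directory holding the per-episode CSVs and the listfile.
#' @param channels channel table used to map columns back to indices.
#' @param listfile index file name.
#' @return list of `raw_episode` (severity is `NA`: it is generator-only).
#' @export
read_episodes <- function(dir, channels = default_channel_table(),
                          listfile = "listfile.csv") {
  idx <- utils::read.csv(file.path(dir, listfile), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(i) {
    tab <- utils::read.csv(file.path(dir, idx$stay[i]), check.names = FALSE,
                           colClasses = "numeric")
    long <- which(!is.na(as.matrix(tab[, -1, drop = FALSE])), arr.ind = TRUE)
    o <- order(tab$Hours[long[, 1]], long[, 1], method = "radix")
    structure(
      list(
        episode_id = sub("\\.csv$", "", idx$stay[i]),
        events = data.frame(
          time = tab$Hours[long[o, 1]],
          channel = as.integer(long[o, 2]),
          value = as.matrix(tab[, -1, drop = FALSE])[long[o, , drop = FALSE]]
        ),
        label = as.integer(idx$y_true[i]),
        severity = NA_real_
      ),
      class = "raw_episode"
    )
  })
}

#' Write a mask as a plain-text 0/1 grid
#'
#' @param mask an `ehr_mask` (or plain 0/1 matrix).
#' @param path output file; one line per hourly row, bits space-separated.
#' @export
write_mask <- function(mask, path) {
  m <- unclass(mask)
  writeLines(apply(m, 1, paste, collapse = " "), path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path input file.
#' @param origin origin tag for the restored mask.
#' @return an `ehr_mask`.
#' @export
read_mask <- function(path, origin = "clean") {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  m <- do.call(rbind, lapply(rows, as.integer))
  new_mask(m, origin)
}
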