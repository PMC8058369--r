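# header lines carrying the id -> type map (GDF-compatible core: data lines
# are whitespace-separated `neuron_id time_ms`)
spike_file_header <- function(placement) {
  rng <- attr(placement, "id_ranges")
  lines <- c("# cerebscaffold spike record", "# columns: id time_ms")
  for (tp in cell_type_order()) {
    r <- rng[[tp]]
    if (!is.null(r) && !is.na(r[1])) {
      lines <- c(lines, sprintf("# type %s ids %d-%d", tp, r[1], r[2]))
    }
  }
  lines
}

#' Write / read spike records as whitespace-separated text
#'
#' The file dialect is GDF-compatible: one \code{neuron_id time_ms} event
#' per line, with a \code{#}-comment header carrying the id-to-cell-type
#' map. Reading restores canonical event ordering (time, then id), so
#' per-neuron spike times are non-decreasing even for shuffled files.
#'
#' @param rec A spike record.
#' @param path File path.
#' @return \code{write_spikes} returns \code{path} invisibly;
#'   \code{read_spikes} returns a \code{spike_record} tibble.
#' @export
write_spikes <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c("# cerebscaffold spike record", "# columns: id time_ms")
  rng <- attr(rec, "id_ranges")
  for (tp in cell_type_order()) {
    r <- rng[[tp]]
    if (!is.null(r) && !is.na(r[1])) {
      header <- c(header, sprintf("# type %s ids %d-%d", tp, r[1], r[2]))
    }
  }
  writeLines(header, con)
  if (nrow(rec)) {
    utils::write.table(data.frame(rec$id, rec$time_ms), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^\\s*#", lines)
  hdr <- lines[is_comment]
  ranges <- list()
  m <- regmatches(hdr, regexec("^# type (\\w+) ids (\\d+)-(\\d+)$", hdr))
  for (mm in m) {
    if (length(mm) == 4) {
      ranges[[mm[2]]] <- c(as.integer(mm[3]), as.integer(mm[4]))
    }
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body)) {
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop(sprintf("malformed spike line %d: '%s'",
                   which(!is_comment & nzchar(trimws(lines)))[bad[1]],
                   body[bad[1]]), call. = FALSE)
    }
    id <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
    tm <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
    if (anyNA(id) || anyNA(tm)) {
      bad1 <- which(is.na(id) | is.na(tm))[1]
      stop(sprintf("malformed spike line %d: '%s'",
                   which(!is_comment & nzchar(trimws(lines)))[bad1],
                   body[bad1]), call. = FALSE)
    }
  } else {
    id <- integer(); tm <- numeric()
  }
  o <- order(tm, id)
  id <- id[o]; tm <- tm[o]
  ct <- rep(NA_character_, length(id))
  n_cells <- stats::setNames(rep(0L, length(cell_type_order())),
                             cell_type_order())
  for (tp in names(ranges)) {
    r <- ranges[[tp]]
    ct[id >= r[1] & id <= r[2]] <- tp
    n_cells[tp] <- r[2] - r[1] + 1L
  }
  out <- tibble::tibble(id = id, time_ms = tm, cell_type = ct)
  structure(out, id_ranges = ranges,
            n_cells = as.table(n_cells),
            class = c("spike_record", class(out)))
}
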