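#' Read a TPS landmark file
#'
#' Parses landmark configurations from the TPS dialect written by the tpsDig
#' digitizing tools: each record starts with an \code{LM=<k>} line, followed by
#' \code{k} whitespace-separated \code{x y} coordinate lines (image pixels, y
#' increasing upward), and optional \code{ID=}, \code{IMAGE=} and \code{SCALE=}
#' lines.  \code{IMAGE=} lines are ignored.
#'
#' @param path Path to a TPS file.
#' @return A list of \code{tps_record} objects, in file order.  Each record has
#'   \code{specimen_id}, \code{coords} (a \code{k x 2} numeric matrix with
#'   columns \code{x}, \code{y}) and optional \code{scale} (pixels-to-mm
#'   factor).
#' @seealso [write_tps()], [as_landmark_configs()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", line, ignore.case = TRUE)) {
      stop("TPS parse error at line ", i, ": expected 'LM=' line, got '", line, "'")
    }
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", line, ignore.case = TRUE)))
    if (is.na(k) || k < 1L) stop("TPS parse error at line ", i, ": bad landmark count")
    coords <- matrix(NA_real_, nrow = k, ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
    for (j in seq_len(k)) {
      li <- i + j
      if (li > n || grepl("^(LM|ID|IMAGE|SCALE)\\s*=", trimws(lines[[li]]), ignore.case = TRUE)) {
        stop("TPS parse error at line ", i, ": LM=", k,
             " but only ", j - 1L, " coordinate lines found")
      }
      parts <- strsplit(trimws(lines[[li]]), "\\s+")[[1]]
      if (length(parts) != 2L) {
        stop("TPS parse error at line ", li, ": expected two coordinates")
      }
      xy <- suppressWarnings(as.numeric(parts))
      if (any(is.na(xy)) || any(!is.finite(xy))) {
        stop("TPS parse error at line ", li, ": non-numeric coordinate '",
             trimws(lines[[li]]), "'")
      }
      coords[j, ] <- xy
    }
    i <- i + k + 1L
    specimen_id <- NA_character_
    scale <- NULL
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (line == "") { i <- i + 1L; next }
      if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        specimen_id <- sub("^ID\\s*=\\s*", "", line, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
        # image file name: not used
      } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
        scale <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", line,
                                                 ignore.case = TRUE)))
        if (is.na(scale) || scale <= 0) {
          stop("TPS parse error at line ", i, ": bad SCALE value")
        }
      } else if (grepl("^LM\\s*=", line, ignore.case = TRUE)) {
        break
      } else {
        stop("TPS parse error at line ", i, ": unexpected line '", line, "'")
      }
      i <- i + 1L
    }
    if (is.na(specimen_id)) specimen_id <- paste0("specimen", length(records) + 1L)
    rec <- structure(list(specimen_id = specimen_id, landmark_count = k,
                          coords = coords, scale = scale),
                     class = "tps_record")
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write landmark records to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written with full precision
#' (\code{format(..., digits = 17)}) so a read/write round-trip is lossless.
#'
#' @param records A list of \code{tps_record} objects (or objects coercible via
#'   \code{specimen_id}/\code{coords} fields).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_tps <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    coords <- rec$coords
    out <- c(out,
             paste0("LM=", nrow(coords)),
             paste(format(coords[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                   format(coords[, 2], digits = 17, trim = TRUE, scientific = FALSE)),
             paste0("ID=", rec$specimen_id))
    if (!is.null(rec$scale)) out <- c(out, paste0("SCALE=", format(rec$scale, digits = 17)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Convert TPS records to landmark configurations
#'
#' Attaches taxon labels (matched by specimen id) and validates that all
#' records share the same landmark count.
#'
#' @param records List of \code{tps_record}s from [read_tps()].
#' @param taxa Optional named character vector mapping specimen id to taxon.
#' @return A \code{landmark_configs} object: list with \code{coords} (a
#'   \code{k x 2 x n} array), \code{specimen_id} and \code{taxon} vectors.
#' @export
as_landmark_configs <- function(records, taxa = NULL) {
  ks <- vapply(records, function(r) nrow(r$coords), integer(1))
  if (length(unique(ks)) > 1L) {
    stop("shape mismatch: records have differing landmark counts (",
         paste(unique(ks), collapse = ", "), ")")
  }
  k <- ks[[1]]
  n <- length(records)
  arr <- array(NA_real_, dim = c(k, 2, n))
  ids <- vapply(records, `[[`, character(1), "specimen_id")
  for (i in seq_len(n)) arr[, , i] <- records[[i]]$coords
  taxon <- rep(NA_character_, n)
  if (!is.null(taxa)) taxon <- unname(taxa[ids])
  structure(list(coords = arr, specimen_id = ids, taxon = taxon),
            class = "landmark_configs")
}
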