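MERISTIC_CHARACTERS <- c("NSLL", "NSALL", "NSULL", "NRDF", "NRPF", "NRAF")

#' Read a meristic count table
#'
#' Reads a CSV table of the six meristic characters used for the species key:
#' scales of the lateral line (NSLL), above (NSALL) and under (NSULL) the
#' lateral line, and rays of the dorsal (NRDF), left pectoral (NRPF) and anal
#' (NRAF) fins.  Column names are matched case-insensitively; a
#' \code{specimen_id} column is required, a \code{taxon} column is optional.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data frame with columns \code{specimen_id}, \code{taxon}
#'   (\code{NA} when absent from the file) and the six integer counts.
#' @export
read_meristic_csv <- function(path) {
  if (!file.exists(path)) stop("meristic CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- trimws(names(df))
  upper <- toupper(names(df))
  missing <- setdiff(MERISTIC_CHARACTERS, upper)
  if (length(missing)) {
    stop("meristic schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  id_col <- match("SPECIMEN_ID", upper)
  if (is.na(id_col)) stop("meristic schema error: missing required column(s): specimen_id")
  taxon_col <- match("TAXON", upper)
  out <- data.frame(specimen_id = as.character(df[[id_col]]),
                    taxon = if (is.na(taxon_col)) NA_character_ else
                      as.character(df[[taxon_col]]),
                    stringsAsFactors = FALSE)
  for (ch in MERISTIC_CHARACTERS) {
    col <- df[[match(ch, upper)]]
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) | num != round(num) | num < 0
    if (any(bad)) {
      stop("meristic parse error: non-integer or negative ", ch, " value '",
           col[which(bad)[1]], "' in row ", which(bad)[1])
    }
    out[[ch]] <- as.integer(num)
  }
  out
}

#' Write a meristic count table
#' @param meristics Data frame as returned by [read_meristic_csv()].
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_meristic_csv <- function(meristics, path) {
  utils::write.csv(meristics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
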