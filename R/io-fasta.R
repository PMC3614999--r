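MARKERS <- c("cytb", "rag1", "cyfunp")

#' Construct a sequence set
#'
#' Container for a set of DNA sequences of one marker.  Residues are restricted
#' to \code{A,C,G,T,N,-}; the set is flagged \code{aligned} when all sequences
#' have equal length.
#'
#' @param seqs Named character vector of sequences (names are FASTA headers in
#'   the \code{"specimenID|taxon"} convention, taxon optional).
#' @param marker One of \code{"cytb"}, \code{"rag1"}, \code{"cyfunp"}.
#' @return A \code{sequence_set}: list with \code{marker}, \code{specimen_id},
#'   \code{taxon}, \code{seq} (uppercase character vector) and \code{aligned}.
#' @export
sequence_set <- function(seqs, marker) {
  marker <- match.arg(marker, MARKERS)
  if (length(seqs) == 0L) stop("empty sequence set")
  headers <- names(seqs)
  if (is.null(headers)) headers <- paste0("seq", seq_along(seqs))
  seqs <- toupper(as.character(seqs))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN-]", seqs[[i]])
    if (bad > 0L) {
      stop("illegal residue '", substr(seqs[[i]], bad, bad), "' in record '",
           headers[[i]], "' at position ", bad)
    }
  }
  parts <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  taxon <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else "unknown",
                  character(1))
  structure(list(marker = marker, specimen_id = ids, taxon = taxon,
                 seq = unname(seqs),
                 aligned = length(unique(nchar(seqs))) == 1L),
            class = "sequence_set")
}

#' Read a FASTA file into a sequence set
#'
#' Headers follow the \code{">specimenID|taxon"} convention with the taxon
#' label optional (defaulting to \code{"unknown"}).  Residues are upper-cased;
#' characters outside \code{A,C,G,T,N,-} raise a parse error naming the record
#' and position.
#'
#' @param path Path to a FASTA file.
#' @param marker One of \code{"cytb"}, \code{"rag1"}, \code{"cyfunp"}.
#' @return A \code{sequence_set}.
#' @export
read_fasta <- function(path, marker) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  sequence_set(stats::setNames(as.character(ss), names(ss)), marker)
}

#' Write a sequence set to FASTA
#' @param set A \code{sequence_set}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(set, path) {
  headers <- ifelse(is.na(set$taxon) | set$taxon == "unknown",
                    set$specimen_id,
                    paste0(set$specimen_id, "|", set$taxon))
  writeLines(paste0(">", headers, "\n", set$seq), path, sep = "\n")
  invisible(path)
}

#' Alignment as a character matrix (specimens x sites)
#' @param set An aligned \code{sequence_set}.
#' @return Character matrix, rownames = specimen ids.
#' @keywords internal
alignment_matrix <- function(set) {
  if (!set$aligned) stop("sequence set is not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(set$seq, ""))
  rownames(m) <- set$specimen_id
  m
}

require_taxa <- function(set) {
  if (any(is.na(set$taxon) | set$taxon == "unknown")) {
    stop("grouped operation requires explicit taxon labels; found 'unknown'")
  }
  invisible(set)
}

#' Fetch GenBank sequences (thin optional downloader)
#'
#' Downloads nucleotide records from NCBI efetch into one FASTA file.  Requires
#' network access; intended as a convenience for assembling the deposited study
#' sequences, never called by the analysis functions.
#'
#' @param accessions Character vector of accession numbers.
#' @param path Destination FASTA path.
#' @return Invisibly, \code{path}.
#' @export
fetch_genbank <- function(accessions, path) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=",
                paste(accessions, collapse = ","))
  utils::download.file(url, path, quiet = TRUE)
  invisible(path)
}
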