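#' Construct a validated set of protein records
#'
#' A `protein_records` object is a data frame with one row per protein and
#' columns `accession`, `entry_name`, `organism`, `description`, `sequence`
#' and `length`. Sequences are uppercased, trailing translation-stop `'*'`
#' characters are stripped, and the residue alphabet is restricted to the 20
#' standard amino acids plus `X`, `U` (selenocysteine), `B` and `Z`.
#' An internal `'*'` or any other letter is a validation error naming the
#' offending record and position.
#'
#' @param accession character vector of primary identifiers.
#' @param sequence character vector of residue strings (same length).
#' @param entry_name optional entry names; defaults to `accession`.
#' @param organism optional organism names; defaults to `""`.
#' @param description optional free-text descriptions; defaults to `""`.
#' @return A data frame of class `protein_records`.
#' @examples
#' protein_records("p1", "mskl")      # uppercased, length 4
#' @export
protein_records <- function(accession, sequence, entry_name = accession,
                            organism = "", description = "") {
  n <- length(sequence)
  stopifnot(length(accession) == n)
  sequence <- toupper(sequence)
  # '*' is permitted terminally only (translated-ORF convention)
  sequence <- sub("\\*+$", "", sequence)
  for (i in seq_len(n)) {
    if (!nzchar(sequence[i])) {
      stop(sprintf("record %d (%s): empty sequence", i, accession[i]),
           call. = FALSE)
    }
    ch <- strsplit(sequence[i], "")[[1]]
    bad <- which(!(ch %in% AA_EXTENDED))
    if (length(bad)) {
      stop(sprintf("record %d (%s): disallowed residue '%s' at position %d",
                   i, accession[i], ch[bad[1]], bad[1]), call. = FALSE)
    }
  }
  out <- data.frame(accession = as.character(accession),
                    entry_name = rep_len(as.character(entry_name), n),
                    organism = rep_len(as.character(organism), n),
                    description = rep_len(as.character(description), n),
                    sequence = sequence,
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Parse a FASTA header line
#'
#' Understands the UniProt `db|ACCESSION|ENTRY_NAME description OS=Organism`
#' dialect; any other header degrades to a bare parse in which the first
#' whitespace-delimited token is both accession and entry name. Parsing is
#' total: every header yields a usable accession.
#'
#' @param header header line without the leading `">"`.
#' @return Named list with `accession`, `entry_name`, `organism` and
#'   (as a convenience for record construction) `description`.
#' @examples
#' parse_uniprot_header("sp|Q6DG85|URIC_DANRE Uricase OS=Danio rerio")
#' @export
parse_uniprot_header <- function(header) {
  header <- trimws(header)
  if (grepl("^[A-Za-z]{2}\\|[^|[:space:]]+\\|[^[:space:]]+", header)) {
    token <- sub("[[:space:]].*$", "", header)
    parts <- strsplit(token, "|", fixed = TRUE)[[1]]
    rest <- trimws(sub("^[^[:space:]]+", "", header))
    organism <- ""
    if (grepl("OS=", rest, fixed = TRUE)) {
      organism <- sub("^.*OS=", "", rest)
      organism <- trimws(sub("[A-Z]{2}=.*$", "", organism))
      rest <- trimws(sub("OS=.*$", "", rest))
    }
    return(list(accession = parts[2], entry_name = parts[3],
                organism = organism, description = rest))
  }
  token <- sub("[[:space:]].*$", "", header)
  if (!nzchar(token)) token <- header
  list(accession = token, entry_name = token, organism = "",
       description = trimws(sub("^[^[:space:]]+", "", header)))
}

#' Read a protein FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file into a
#' [protein_records()] data frame, in file order. Headers are parsed with
#' [parse_uniprot_header()]; residues are uppercased and validated.
#'
#' @param path path to a FASTA file.
#' @return A `protein_records` data frame.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) {
                   stop("not a readable FASTA file: ", path, " (",
                        conditionMessage(e), ")", call. = FALSE)
                 })
  if (length(aa) == 0) {
    stop("FASTA format error: no '>' header found in ", path, call. = FALSE)
  }
  hdr <- lapply(names(aa), parse_uniprot_header)
  protein_records(accession = vapply(hdr, `[[`, "", "accession"),
                  sequence = as.character(aa),
                  entry_name = vapply(hdr, `[[`, "", "entry_name"),
                  organism = vapply(hdr, `[[`, "", "organism"),
                  description = vapply(hdr, `[[`, "", "description"))
}

#' Write protein records to FASTA
#'
#' @param records a `protein_records` data frame.
#' @param path output path.
#' @param width sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nzchar(records$description),
                      paste(records$accession, records$description),
                      records$accession)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}
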