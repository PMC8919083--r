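# N-terminal PTS2 nonapeptide detection.

#' Default PTS2 nonapeptide pattern
#'
#' Nine residue-set strings (an empty set string or `"*"` means any
#' residue). The default is the classical PTS2 consensus
#' `R/K - L/V/I - x - x - L/V/I/H - L/S/G/A - x - H/Q - L/A/F` widened at
#' positions 2 (Q), 5 (Q), 6 (K/V/R) and 9 (I), so that the experimentally
#' tested zebrafish Uraha nonapeptide `RLQHIRGHI` is admitted.
#'
#' @return Character vector of length 9.
#' @export
pts2_default_pattern <- function() {
  c("RK", "LVIQ", "*", "*", "LVIHQ", "LSGAKVR", "*", "HQ", "LAFI")
}

.pts2_regex <- function(pattern) {
  stopifnot(length(pattern) == 9L)
  parts <- vapply(pattern, function(s) {
    if (s == "*" || !nzchar(s)) "." else paste0("[", s, "]")
  }, character(1))
  paste0("(?=(", paste(parts, collapse = ""), "))")
}

#' Find candidate PTS2 nonapeptides
#'
#' Scans the first `window` residues of a protein for nonapeptides matching
#' a 9-position residue-set pattern. PTS2 signals are N-terminal (and often
#' cleaved after import), hence the windowed search. Overlapping matches
#' are all reported, ordered by offset. Matching is qualitative: the
#' screen reports PTS2 candidates but does not score them.
#'
#' @param x a single sequence string or a one-row `protein_records` slice.
#' @param window N-terminal search window in residues (>= 9); a match must
#'   start at 0-based offset `<= window - 9`.
#' @param pattern nine residue-set strings; see [pts2_default_pattern()].
#' @return Data frame with columns `offset` (0-based) and `nonapeptide`;
#'   zero rows when there is no hit.
#' @examples
#' find_pts2("RLQHIRGHIAAAAA")  # hit at offset 0
#' @export
find_pts2 <- function(x, window = 40L, pattern = pts2_default_pattern()) {
  seq <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  stopifnot(length(seq) == 1L)
  if (window < 9L) stop("window must be at least 9", call. = FALSE)
  region <- substr(seq, 1L, min(nchar(seq), window))
  empty <- data.frame(offset = integer(0), nonapeptide = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(region) < 9L) return(empty)
  m <- gregexpr(.pts2_regex(pattern), region, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  data.frame(offset = starts - 1L,
             nonapeptide = substring(region, starts, starts + 8L),
             stringsAsFactors = FALSE)
}
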