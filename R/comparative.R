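# Cross-species PTS1 motif comparison: per-position frequency matrices,
# paired score comparison, and gain/loss/non-canonical status calls.

PTS1_STATUSES <- c("CANONICAL", "NON_CANONICAL", "ABSENT_PTS1",
                   "ABSENT_PROTEIN")
ORTHOLOG_CATEGORIES <- c("CONSERVED", "WEAKENED", "STRENGTHENED",
                         "GAINED", "LOST", "PROTEIN_ABSENT")

#' Position-wise residue frequency matrix of PTS1 dodecamers
#'
#' The per-position relative abundance of the 20 standard residues over a
#' set of C-terminal 12-mers -- the numeric form of a sequence logo.
#' `X` (padding) cells are excluded position-wise from both numerator and
#' denominator, so every column of actual observations sums to 1.
#'
#' @param dodecamers non-empty character vector of 12-mers.
#' @return A 12 x 20 matrix (rows: positions 1-12; columns: residues)
#'   with attribute `n_sequences`.
#' @examples
#' m <- build_frequency_matrix(rep("AAAAAAAAASKL", 5))
#' m[12, "L"]  # 1
#' @export
build_frequency_matrix <- function(dodecamers) {
  dodecamers <- toupper(as.character(dodecamers))
  if (length(dodecamers) == 0L) {
    stop("empty dodecamer list", call. = FALSE)
  }
  if (any(nchar(dodecamers) != 12L)) {
    stop("all sequences must have exactly 12 residues", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(dodecamers, ""))
  freqs <- matrix(NA_real_, 12L, 20L,
                  dimnames = list(position = 1:12, residue = AA_STANDARD))
  for (p in 1:12) {
    obs <- chars[, p][chars[, p] %in% AA_STANDARD]
    if (length(obs)) {
      freqs[p, ] <- as.numeric(table(factor(obs, levels = AA_STANDARD))) /
        length(obs)
    }
  }
  attr(freqs, "n_sequences") <- length(dodecamers)
  freqs
}

#' Write a frequency matrix as TSV (12 rows x 20 residue columns)
#'
#' @param freqs matrix from [build_frequency_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(freqs, path) {
  df <- data.frame(position = seq_len(nrow(freqs)), freqs,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the PTS1 status of a protein (or absent protein)
#'
#' Status calls mirror the cross-species comparison: **CANONICAL** -- a
#' consensus-matching C-terminus the model classifies TARGETED;
#' **NON_CANONICAL** -- consensus-matching but TWILIGHT (a weak signal);
#' **ABSENT_PTS1** -- no consensus match or a REJECTED score;
#' **ABSENT_PROTEIN** -- the protein itself is missing from the species
#' (pass `NA` or `NULL`).
#'
#' @param x a sequence string, a one-row `protein_records` slice, or
#'   `NA`/`NULL` for an absent protein.
#' @param model a [pts1_model()].
#' @return One of `"CANONICAL"`, `"NON_CANONICAL"`, `"ABSENT_PTS1"`,
#'   `"ABSENT_PROTEIN"`.
#' @export
classify_pts1_status <- function(x, model = pts1_default_model()) {
  if (is.null(x) || (is.atomic(x) && length(x) == 1L && is.na(x))) {
    return("ABSENT_PROTEIN")
  }
  seq <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  stopifnot(length(seq) == 1L)
  res <- score_pts1(model, extract_cterm12(seq)$dodecamer)
  switch(as.character(res$category),
         TARGETED = "CANONICAL",
         TWILIGHT = "NON_CANONICAL",
         "ABSENT_PTS1")
}

#' Compare PTS1 signals across ortholog pairs
#'
#' For each pair of orthologous proteins (side a vs side b; either side
#' may be absent), classifies both PTS1 statuses and assigns a pair
#' category: **CONSERVED** (same status on both sides), **WEAKENED**
#' (canonical on a, non-canonical on b), **STRENGTHENED** (the reverse),
#' **LOST** (a carries a PTS1, b has none), **GAINED** (the reverse), or
#' **PROTEIN_ABSENT** (either protein missing). The paired scores are
#' emitted for x-y plotting of the two species' predictions.
#'
#' @param pairs data frame with columns `id_a`, `seq_a`, `id_b`, `seq_b`;
#'   `NA` or `"-"` marks an absent protein.
#' @param model_a model used for side a.
#' @param model_b model used for side b; by default the same model is
#'   shared by both species.
#' @return Data frame with columns `id_a`, `id_b`, `score_a`, `score_b`
#'   (NA when absent or no consensus), `status_a`, `status_b`,
#'   `category`.
#' @export
compare_orthologs <- function(pairs, model_a = pts1_default_model(),
                              model_b = model_a) {
  stopifnot(all(c("id_a", "seq_a", "id_b", "seq_b") %in% names(pairs)))
  absent <- function(s) is.na(s) | s == "-" | !nzchar(s)
  one_side <- function(seq, model) {
    if (absent(seq)) {
      return(list(score = NA_real_, status = "ABSENT_PROTEIN"))
    }
    res <- score_pts1(model, extract_cterm12(seq)$dodecamer)
    list(score = if (is.finite(res$score)) res$score else NA_real_,
         status = classify_pts1_status(seq, model))
  }
  n <- nrow(pairs)
  out <- data.frame(id_a = as.character(pairs$id_a),
                    id_b = as.character(pairs$id_b),
                    score_a = NA_real_, score_b = NA_real_,
                    status_a = NA_character_, status_b = NA_character_,
                    category = NA_character_,
                    stringsAsFactors = FALSE)
  has_pts1 <- c("CANONICAL", "NON_CANONICAL")
  for (i in seq_len(n)) {
    a <- one_side(pairs$seq_a[i], model_a)
    b <- one_side(pairs$seq_b[i], model_b)
    out$score_a[i] <- a$score
    out$score_b[i] <- b$score
    out$status_a[i] <- a$status
    out$status_b[i] <- b$status
    out$category[i] <-
      if (a$status == "ABSENT_PROTEIN" || b$status == "ABSENT_PROTEIN") {
        "PROTEIN_ABSENT"
      } else if (a$status %in% has_pts1 && b$status == "ABSENT_PTS1") {
        "LOST"
      } else if (b$status %in% has_pts1 && a$status == "ABSENT_PTS1") {
        "GAINED"
      } else if (a$status == "CANONICAL" && b$status == "NON_CANONICAL") {
        "WEAKENED"
      } else if (a$status == "NON_CANONICAL" && b$status == "CANONICAL") {
        "STRENGTHENED"
      } else {
        # same status on both sides (incl. conserved absence of a PTS1)
        "CONSERVED"
      }
  }
  out
}
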