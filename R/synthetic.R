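# Synthetic proteome generator with planted, labelled targeting signals.

SYNTH_LABELS <- c("canonical_pts1", "twilight_pts1", "pts2",
                  "tm_pts1_decoy", "er_pts1_decoy", "background")

#' Specification of a synthetic proteome
#'
#' Class composition of a generated proteome. The defaults emulate the
#' structure of the screened proteome at test scale: a majority of
#' background proteins, soluble PTS1 proteins of both strengths, PTS2
#' proteins, and the two decoy classes the exclusion filters exist for
#' (membrane-anchored and secretory proteins carrying a PTS1-like
#' C-terminus).
#'
#' @param n_canonical_pts1 soluble proteins with a planted TARGETED
#'   C-terminal 12-mer.
#' @param n_twilight_pts1 soluble proteins with a planted TWILIGHT
#'   (weak) 12-mer.
#' @param n_pts2 proteins with a planted N-terminal PTS2 nonapeptide and
#'   no PTS1 consensus.
#' @param n_tm_pts1_decoy membrane decoys: PTS1-like C-terminus plus a
#'   23-residue hydrophobic core planted at residue >= 70 (or at residue
#'   10 with `tm_decoy_early = TRUE`, exercising the signal-peptide
#'   exemption).
#' @param n_er_pts1_decoy secretory decoys: PTS1-like C-terminus plus an
#'   N-terminal signal peptide.
#' @param n_background plain background proteins with a guaranteed
#'   non-matching C-terminus.
#' @param length_range integer (min, max) protein length; min >= 30.
#' @param seed integer RNG seed; generation is deterministic under it.
#' @param tm_decoy_early place the decoy hydrophobic core at residue 10
#'   instead of >= 70.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_canonical_pts1 = 100L, n_twilight_pts1 = 50L,
                           n_pts2 = 50L, n_tm_pts1_decoy = 100L,
                           n_er_pts1_decoy = 100L, n_background = 600L,
                           length_range = c(120L, 600L), seed = 1L,
                           tm_decoy_early = FALSE) {
  counts <- c(n_canonical_pts1, n_twilight_pts1, n_pts2,
              n_tm_pts1_decoy, n_er_pts1_decoy, n_background)
  if (any(counts < 0)) stop("class counts must be >= 0", call. = FALSE)
  if (sum(counts) < 1) stop("at least one record required", call. = FALSE)
  if (length(length_range) != 2L || length_range[1] < 30L ||
      length_range[1] > length_range[2]) {
    stop("length_range must be (min, max) with min >= 30", call. = FALSE)
  }
  structure(list(n_canonical_pts1 = as.integer(n_canonical_pts1),
                 n_twilight_pts1 = as.integer(n_twilight_pts1),
                 n_pts2 = as.integer(n_pts2),
                 n_tm_pts1_decoy = as.integer(n_tm_pts1_decoy),
                 n_er_pts1_decoy = as.integer(n_er_pts1_decoy),
                 n_background = as.integer(n_background),
                 length_range = as.integer(length_range),
                 seed = as.integer(seed),
                 tm_decoy_early = isTRUE(tm_decoy_early)),
            class = "synthetic_spec")
}

#' Overwrite a span of a sequence with a motif
#'
#' Plants `motif` into `sequence` either flush with the C-terminus or at a
#' fixed 0-based offset; the sequence length is unchanged.
#'
#' @param sequence residue string.
#' @param motif residue string to plant.
#' @param position `"C_TERM"` or `"AT_OFFSET"`.
#' @param offset 0-based start (only for `"AT_OFFSET"`).
#' @return The modified sequence.
#' @examples
#' plant_motif(strrep("A", 30), "SKL", "C_TERM")
#' @export
plant_motif <- function(sequence, motif, position = c("C_TERM", "AT_OFFSET"),
                        offset = 0L) {
  position <- match.arg(position)
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m > n) stop("motif longer than sequence", call. = FALSE)
  start <- if (position == "C_TERM") n - m + 1L else offset + 1L
  if (start < 1L || start + m - 1L > n) {
    stop("offset out of range for motif of length ", m, call. = FALSE)
  }
  paste0(substr(sequence, 1L, start - 1L), motif,
         substr(sequence, start + m, n))
}

#' Generate a labelled synthetic proteome
#'
#' Emits protein records of the six [synthetic_spec()] classes together
#' with a ground-truth table. Background residues are drawn i.i.d. from
#' the bundled vertebrate-average composition ([background_composition()]).
#' PTS1-class C-termini are drawn from the curated 12-mer pool and
#' verified against `model` before emission (TARGETED for the canonical
#' and decoy classes, TWILIGHT for the twilight class), resampling on
#' mismatch up to 100 times and failing loudly afterwards. PTS2-class
#' records get a pattern-matching nonapeptide inside the first 40
#' residues and a non-matching C-terminus; background C-termini are
#' guaranteed non-matching. Generation is deterministic under
#' `spec$seed` and restores the caller's RNG state.
#'
#' @param spec a [synthetic_spec()].
#' @param model PTS1 model used to verify planted categories.
#' @param pool candidate 12-mers for planting; default the bundled
#'   curated training set.
#' @return List with elements `records` (a `protein_records` data frame)
#'   and `truth` (data frame: `accession`, `label`, `motif`, `start`,
#'   `end`; coordinates 0-based half-open, `NA` for background).
#' @export
generate_proteome <- function(spec, model = pts1_default_model(),
                              pool = pts1_training_set()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  comp <- background_composition()
  rand_seq <- function(len) {
    paste(sample(names(comp), len, replace = TRUE, prob = comp),
          collapse = "")
  }
  rand_len <- function(min_len = spec$length_range[1]) {
    lo <- max(spec$length_range[1], min_len)
    hi <- max(spec$length_range[2], lo)
    sample(lo:hi, 1L)
  }
  draw_cterm <- function(category, class_name) {
    for (try in 1:100) {
      cand <- sample(pool, 1L)
      if (as.character(score_pts1(model, cand)$category) == category) {
        return(cand)
      }
    }
    stop("could not plant a ", category, " 12-mer for class '", class_name,
         "' after 100 resamples", call. = FALSE)
  }
  scramble_tail <- function(seq) {
    # guaranteed non-matching C-terminal tripeptide
    while (match_consensus(substr(seq, nchar(seq) - 2L, nchar(seq)))) {
      seq <- plant_motif(seq, rand_seq(3L), "C_TERM")
    }
    seq
  }
  draw_pts2_nonapeptide <- function(pattern = pts2_default_pattern()) {
    paste(vapply(pattern, function(s) {
      set <- if (s == "*") names(comp) else strsplit(s, "")[[1]]
      if (length(set) == 1L) set else
        sample(set, 1L, prob = if (s == "*") comp else NULL)
    }, character(1)), collapse = "")
  }

  seqs <- character(0)
  truth <- list()
  add <- function(label, sequence, motif = NA_character_,
                  start = NA_integer_, end = NA_integer_) {
    seqs[[length(seqs) + 1L]] <<- sequence
    truth[[length(truth) + 1L]] <<-
      data.frame(label = label, motif = motif, start = start, end = end,
                 stringsAsFactors = FALSE)
  }

  for (k in seq_len(spec$n_canonical_pts1)) {
    len <- rand_len()
    cterm <- draw_cterm("TARGETED", "canonical_pts1")
    add("canonical_pts1", plant_motif(rand_seq(len), cterm, "C_TERM"),
        cterm, len - 12L, len)
  }
  for (k in seq_len(spec$n_twilight_pts1)) {
    len <- rand_len()
    cterm <- draw_cterm("TWILIGHT", "twilight_pts1")
    add("twilight_pts1", plant_motif(rand_seq(len), cterm, "C_TERM"),
        cterm, len - 12L, len)
  }
  for (k in seq_len(spec$n_pts2)) {
    len <- rand_len()
    nona <- draw_pts2_nonapeptide()
    off <- sample(0:31, 1L)
    seq <- plant_motif(scramble_tail(rand_seq(len)), nona, "AT_OFFSET", off)
    add("pts2", seq, nona, off, off + 9L)
  }
  for (k in seq_len(spec$n_tm_pts1_decoy)) {
    core_start <- if (spec$tm_decoy_early) 10L else NA_integer_
    min_len <- if (spec$tm_decoy_early) 120L else 110L
    len <- rand_len(min_len)
    if (is.na(core_start)) {
      core_start <- sample(70:(len - 35L), 1L)  # 0-based; clears the 12-mer
    }
    core <- paste(sample(c("L", "I", "V"), 23L, replace = TRUE),
                  collapse = "")
    seq <- plant_motif(rand_seq(len), core, "AT_OFFSET", core_start)
    seq <- plant_motif(seq, draw_cterm("TARGETED", "tm_pts1_decoy"),
                       "C_TERM")
    add("tm_pts1_decoy", seq, core, core_start, core_start + 23L)
  }
  for (k in seq_len(spec$n_er_pts1_decoy)) {
    len <- rand_len()
    n_region <- sample(names(comp), 4L, replace = TRUE, prob = comp)
    n_region[sample(4L, 1L)] <- sample(c("K", "R"), 1L)
    h_region <- paste(sample(c("L", "I", "V", "F", "A"), 10L,
                             replace = TRUE), collapse = "")
    head <- paste0("M", paste(n_region, collapse = ""), h_region)
    seq <- plant_motif(rand_seq(len), head, "AT_OFFSET", 0L)
    seq <- plant_motif(seq, draw_cterm("TARGETED", "er_pts1_decoy"),
                       "C_TERM")
    add("er_pts1_decoy", seq, head, 0L, nchar(head))
  }
  for (k in seq_len(spec$n_background)) {
    add("background", scramble_tail(rand_seq(rand_len())))
  }

  truth <- do.call(rbind, truth)
  acc <- sprintf("SYN%05d", seq_along(seqs))
  records <- protein_records(accession = acc,
                             sequence = unlist(seqs),
                             entry_name = paste0(acc, "_SYNTH"),
                             organism = "synthetic",
                             description = truth$label)
  truth <- cbind(data.frame(accession = acc, stringsAsFactors = FALSE),
                 truth)
  list(records = records, truth = truth)
}

#' Write a ground-truth table as TSV
#'
#' Columns: `accession`, `label`, `motif`, `start`, `end` (0-based,
#' half-open).
#'
#' @param truth the `truth` element of [generate_proteome()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
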