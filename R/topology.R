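# Hydropathy-based stand-ins for the membrane-topology and sorting-signal
# exclusion stages of the screen. These are deliberately simple, fully
# deterministic heuristics with explicit contracts -- not re-implementations
# of the HMM/posterior-probability predictors used for the original screen.

#' Transmembrane-helix propensity profile
#'
#' Computes per-residue Kyte-Doolittle hydropathy averaged over a centred
#' sliding window (truncated at the termini). Residues whose windowed
#' hydropathy reaches `threshold` get propensity 1; maximal runs of at
#' least `min_run` such residues become predicted transmembrane segments,
#' while shorter runs are zeroed. `exp_aa` is the expected number of
#' residues in transmembrane helices (the sum of the propensity) and
#' `exp_aa_60` the same sum restricted to the first 60 residues.
#'
#' @param x a single sequence string or one-row `protein_records` slice.
#' @param window odd window width (>= 5), default 19.
#' @param threshold windowed-hydropathy threshold, default 1.6.
#' @param min_run minimum run length for a transmembrane segment,
#'   default 15 residues.
#' @return An object of class `tm_profile`: list with `propensity`
#'   (0/1 per residue), `segments` (data frame of 0-based half-open
#'   `start`,`end` intervals), `exp_aa`, `exp_aa_60` and `topology`
#'   (`"TM"` or `"NONE"`).
#' @seealso [apply_tm_rule()]
#' @export
tm_profile <- function(x, window = 19L, threshold = 1.6, min_run = 15L) {
  seq <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  stopifnot(length(seq) == 1L)
  if (window < 5L || window %% 2L == 0L) {
    stop("window must be odd and at least 5", call. = FALSE)
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  kd <- unname(KYTE_DOOLITTLE[ch])
  kd[is.na(kd)] <- 0
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(kd))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  wm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  prop <- as.integer(wm >= threshold)

  segments <- data.frame(start = integer(0), end = integer(0))
  if (any(prop == 1L)) {
    r <- rle(prop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values == 1L & r$lengths >= min_run
    drop <- r$values == 1L & r$lengths < min_run
    for (k in which(drop)) prop[starts[k]:ends[k]] <- 0L
    if (any(keep)) {
      segments <- data.frame(start = starts[keep] - 1L, end = ends[keep])
    }
  }
  structure(list(propensity = prop, segments = segments,
                 exp_aa = sum(prop),
                 exp_aa_60 = sum(prop[seq_len(min(60L, n))]),
                 topology = if (nrow(segments)) "TM" else "NONE"),
            class = "tm_profile")
}

#' @export
print.tm_profile <- function(x, ...) {
  cat(sprintf("tm_profile: topology %s, %d segment(s), ExpAA %.1f (first 60: %.1f)\n",
              x$topology, nrow(x$segments), x$exp_aa, x$exp_aa_60))
  invisible(x)
}

#' Transmembrane retention rule
#'
#' Proteins without predicted transmembrane helices are kept. Proteins
#' with helices are kept only when the helix signal is concentrated in the
#' first 60 residues -- `exp_aa_60 / exp_aa >= ratio_threshold` -- i.e.
#' when the hydrophobic stretch is compatible with a cleavable signal
#' peptide rather than a genuine membrane anchor.
#'
#' @param profile a [tm_profile()].
#' @param ratio_threshold minimum first-60 fraction, default 0.9.
#' @return `TRUE` to keep the protein, `FALSE` to discard it.
#' @export
apply_tm_rule <- function(profile, ratio_threshold = 0.9) {
  stopifnot(inherits(profile, "tm_profile"))
  if (profile$topology == "NONE") return(TRUE)
  (profile$exp_aa_60 / profile$exp_aa) >= ratio_threshold
}

#' Secretory / ER sorting heuristics
#'
#' A precision-oriented stand-in for the subcellular-localisation stage
#' that removed ER-routed entries from the screen. A secretory signal
#' peptide is called when all three classical elements are present:
#' (a) initiator methionine, (b) an n-region with at least one K/R in
#' residues 1-5, and (c) an h-region -- a run of >= 8 residues with
#' Kyte-Doolittle hydropathy >= 1.6 within residues 6-30. The signal score
#' is the longest qualifying h-run length / 15, capped at 1. ER retention
#' is called from a C-terminal `[KRHQSA]-[DE]-E-L` (KDEL-type) motif.
#' Sequences shorter than 15 residues are never called secretory; the
#' retention motif needs at least 4 residues. The conjunction is
#' deliberate: this call deletes candidates from the screen, so false ER
#' calls silently remove true peroxisomal proteins.
#'
#' @param x a single sequence string or one-row `protein_records` slice.
#' @param er_motif four residue-set strings for the retention motif.
#' @return List of class `sorting_call`: `secretory_signal` (logical),
#'   `signal_score` (0-1), `er_retention` (logical), `mts_score` (0-1,
#'   from [mts_score()]).
#' @export
detect_secretory_signal <- function(x, er_motif = c("KRHQSA", "DE", "E", "L")) {
  seq <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  stopifnot(length(seq) == 1L)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)

  secretory <- FALSE
  signal_score <- 0
  if (n >= 15L) {
    has_m <- ch[1] == "M"
    has_n_region <- any(ch[1:5] %in% c("K", "R"))
    h <- ch[6:min(30L, n)]
    kd <- unname(KYTE_DOOLITTLE[h])
    kd[is.na(kd)] <- 0
    runs <- rle(kd >= 1.6)
    longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (longest >= 8L) signal_score <- min(longest / 15, 1)
    secretory <- has_m && has_n_region && longest >= 8L
  }

  er <- FALSE
  if (n >= 4L) {
    tail4 <- ch[(n - 3L):n]
    sets <- strsplit(er_motif, "")
    er <- all(mapply(function(res, set) res %in% set, tail4, sets))
  }

  structure(list(secretory_signal = secretory, signal_score = signal_score,
                 er_retention = er, mts_score = mts_score(seq)),
            class = "sorting_call")
}

#' Crude N-terminal mitochondrial targeting propensity
#'
#' Mitochondrial presequences are enriched in basic and depleted in acidic
#' residues. The score is `(count(R,K) - count(D,E))` over the first 25
#' residues, divided by 8 and clamped to \[0, 1\]. Advisory only: it is
#' reported in screen output but never used to drop records, mirroring the
#' role of mitochondrial-targeting checks as post-hoc validation.
#'
#' @param x a single sequence string or one-row `protein_records` slice.
#' @return A number in \[0, 1\]; 0 for sequences shorter than 25 residues.
#' @export
mts_score <- function(x) {
  seq <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  stopifnot(length(seq) == 1L)
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) < 25L) return(0)
  head25 <- ch[1:25]
  raw <- (sum(head25 %in% c("R", "K")) - sum(head25 %in% c("D", "E"))) / 8
  max(0, min(1, raw))
}
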