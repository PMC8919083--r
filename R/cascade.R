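# The staged screening cascade with per-stage accounting.

CASCADE_FATES <- c("DROP_NO_CONSENSUS", "DROP_TM", "DROP_ER",
                   "DROP_NO_PTS1_HIT", "CANDIDATE_TARGETED",
                   "CANDIDATE_TWILIGHT")

#' Screening cascade configuration
#'
#' Collects every tunable threshold of the screen. Defaults are the
#' standard textbook hydropathy settings (Kyte-Doolittle, window 19,
#' threshold 1.6, minimum helix run 15), the first-60 helix-concentration
#' ratio 0.9, and the default PTS2 pattern and 40-residue window.
#'
#' @param tm_window hydropathy window (odd, >= 5).
#' @param tm_threshold windowed hydropathy threshold.
#' @param tm_min_run minimum transmembrane run length.
#' @param tm_ratio minimum `exp_aa_60 / exp_aa` ratio for keeping a
#'   helix-bearing protein (signal-peptide exemption).
#' @param er_filter logical; apply the secretory/ER exclusion stage.
#' @param er_motif four residue-set strings for the ER retention motif.
#' @param pts2_window N-terminal PTS2 search window.
#' @param pts2_pattern nine residue-set strings for the PTS2 matcher.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(tm_window = 19L, tm_threshold = 1.6,
                           tm_min_run = 15L, tm_ratio = 0.9,
                           er_filter = TRUE,
                           er_motif = c("KRHQSA", "DE", "E", "L"),
                           pts2_window = 40L,
                           pts2_pattern = pts2_default_pattern()) {
  structure(list(tm_window = as.integer(tm_window),
                 tm_threshold = tm_threshold,
                 tm_min_run = as.integer(tm_min_run),
                 tm_ratio = tm_ratio,
                 er_filter = isTRUE(er_filter),
                 er_motif = er_motif,
                 pts2_window = as.integer(pts2_window),
                 pts2_pattern = pts2_pattern),
            class = "cascade_config")
}

#' Read / write a cascade configuration as YAML
#'
#' @param path file path.
#' @param config a [cascade_config()].
#' @return `read_cascade_config()` returns a `cascade_config`;
#'   `write_cascade_config()` returns `path` invisibly.
#' @export
read_cascade_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cascade_config, y)
}

#' @rdname read_cascade_config
#' @export
write_cascade_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the peroxisomal-protein screening cascade
#'
#' Applies, in order: (1) the broad C-terminal PTS1 consensus gate;
#' (2) the transmembrane filter ([tm_profile()] + [apply_tm_rule()]);
#' (3) the secretory/ER exclusion ([detect_secretory_signal()]); and
#' (4) the PTS1 scoring model ([score_pts1()]), where REJECTED scores
#' (<= -10) count as "no predictor hit" and are dropped, while TARGETED
#' and TWILIGHT proteins become candidates. Each record receives exactly
#' one fate. PTS2 hits and the mitochondrial propensity are recorded as
#' advisory annotations for every record that passes the consensus gate;
#' they never drop anything.
#'
#' @param records a non-empty `protein_records` data frame.
#' @param model a [pts1_model()]; default the bundled model.
#' @param config a [cascade_config()].
#' @return An object of class `cascade_report`: stage counts `n_input`,
#'   `n_consensus`, `n_tm_kept`, `n_not_er`, `n_pts1_candidates`,
#'   `n_twilight`, and `table`, a per-protein data frame (input order)
#'   with columns `accession`, `tripeptide`, `consensus_match`, `exp_aa`,
#'   `exp_aa_60`, `tm_kept`, `er_flagged`, `pts1_score`, `pts1_class`,
#'   `pts2_hit`, `mts_score`, `final_fate`.
#' @seealso [summary.cascade_report()], [write_screen_table()]
#' @export
run_cascade <- function(records, model = pts1_default_model(),
                        config = cascade_config()) {
  if (!inherits(records, "protein_records")) {
    records <- protein_records(
      accession = if (!is.null(names(records))) names(records)
                  else sprintf("seq%d", seq_along(records)),
      sequence = records)
  }
  if (nrow(records) == 0L) stop("no input records", call. = FALSE)
  stopifnot(inherits(model, "pts1_model"))

  n <- nrow(records)
  ctx <- extract_cterm12(records)
  consensus <- match_consensus(ctx$tripeptide)

  exp_aa <- exp_aa_60 <- pts1_score <- rep(NA_real_, n)
  tm_kept <- er_flagged <- pts2_hit <- rep(NA, n)
  mts <- rep(NA_real_, n)
  pts1_class <- rep(NA_character_, n)
  fate <- rep(NA_character_, n)
  pts2_hits <- vector("list", n)

  fate[!consensus] <- "DROP_NO_CONSENSUS"
  for (i in which(consensus)) {
    seq_i <- records$sequence[i]
    prof <- tm_profile(seq_i, window = config$tm_window,
                       threshold = config$tm_threshold,
                       min_run = config$tm_min_run)
    exp_aa[i] <- prof$exp_aa
    exp_aa_60[i] <- prof$exp_aa_60
    tm_kept[i] <- apply_tm_rule(prof, config$tm_ratio)

    # advisory annotations for every consensus-stage survivor
    hits <- find_pts2(seq_i, window = config$pts2_window,
                      pattern = config$pts2_pattern)
    pts2_hits[[i]] <- hits
    pts2_hit[i] <- nrow(hits) > 0L
    mts[i] <- mts_score(seq_i)

    if (!tm_kept[i]) {
      fate[i] <- "DROP_TM"
      next
    }
    if (config$er_filter) {
      sorting <- detect_secretory_signal(seq_i, er_motif = config$er_motif)
      er_flagged[i] <- sorting$secretory_signal || sorting$er_retention
    } else {
      er_flagged[i] <- FALSE
    }
    if (er_flagged[i]) {
      fate[i] <- "DROP_ER"
      next
    }
    res <- score_pts1(model, ctx$dodecamer[i])
    pts1_score[i] <- res$score
    pts1_class[i] <- as.character(res$category)
    fate[i] <- switch(pts1_class[i],
                      TARGETED = "CANDIDATE_TARGETED",
                      TWILIGHT = "CANDIDATE_TWILIGHT",
                      "DROP_NO_PTS1_HIT")
  }

  tab <- data.frame(accession = records$accession,
                    tripeptide = ctx$tripeptide,
                    consensus_match = consensus,
                    exp_aa = exp_aa, exp_aa_60 = exp_aa_60,
                    tm_kept = tm_kept, er_flagged = er_flagged,
                    pts1_score = pts1_score, pts1_class = pts1_class,
                    pts2_hit = pts2_hit, mts_score = mts,
                    final_fate = factor(fate, levels = CASCADE_FATES),
                    stringsAsFactors = FALSE)

  structure(list(n_input = n,
                 n_consensus = sum(consensus),
                 n_tm_kept = sum(tm_kept, na.rm = TRUE),
                 n_not_er = sum(!er_flagged, na.rm = TRUE),
                 n_pts1_candidates = sum(fate %in% c("CANDIDATE_TARGETED",
                                                     "CANDIDATE_TWILIGHT")),
                 n_twilight = sum(fate == "CANDIDATE_TWILIGHT"),
                 table = tab,
                 pts2_hits = pts2_hits),
            class = "cascade_report")
}

#' Per-stage summary of a cascade report
#'
#' @param object a `cascade_report` from [run_cascade()].
#' @param ... unused.
#' @return Data frame with columns `stage`, `count` and `pct`
#'   (percentage of input, one decimal).
#' @export
summary.cascade_report <- function(object, ...) {
  counts <- c(input = object$n_input,
              consensus = object$n_consensus,
              tm_kept = object$n_tm_kept,
              not_er = object$n_not_er,
              pts1_candidates = object$n_pts1_candidates)
  data.frame(stage = names(counts),
             count = as.integer(counts),
             pct = round(100 * counts / object$n_input, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("PTS screening cascade report\n")
  print(summary(x), row.names = FALSE)
  cat(sprintf("candidates: %d targeted, %d twilight\n",
              x$n_pts1_candidates - x$n_twilight, x$n_twilight))
  invisible(x)
}

#' Write a cascade report to disk
#'
#' The TSV format has one row per input protein, in input order, with
#' columns `accession`, `tripeptide`, `consensus_match`, `exp_aa`,
#' `exp_aa_60`, `tm_kept`, `er_flagged`, `pts1_score`, `pts1_class`,
#' `pts2_hit`, `final_fate`; floating values are printed with 4 decimals.
#' The JSON format additionally carries the stage counts.
#'
#' @param report a `cascade_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "cascade_report"))
  format <- match.arg(format)
  tab <- report$table
  cols <- c("accession", "tripeptide", "consensus_match", "exp_aa",
            "exp_aa_60", "tm_kept", "er_flagged", "pts1_score",
            "pts1_class", "pts2_hit", "final_fate")
  out <- tab[, cols]
  num4 <- function(v) ifelse(is.na(v), NA, sprintf("%.4f", v))
  if (format == "tsv") {
    out$exp_aa <- num4(out$exp_aa)
    out$exp_aa_60 <- num4(out$exp_aa_60)
    out$pts1_score <- num4(out$pts1_score)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    payload <- list(
      counts = list(n_input = report$n_input,
                    n_consensus = report$n_consensus,
                    n_tm_kept = report$n_tm_kept,
                    n_not_er = report$n_not_er,
                    n_pts1_candidates = report$n_pts1_candidates,
                    n_twilight = report$n_twilight),
      proteins = out)
    jsonlite::write_json(payload, path, dataframe = "rows", digits = 4,
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}
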