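# C-terminal PTS1 consensus matching and position-specific scoring.

# broad screening consensus for the C-terminal tripeptide
PTS1_CONSENSUS <- list(m3 = c("A", "S", "C", "N", "P", "H", "T", "G"),
                       m2 = c("R", "K", "H", "Q", "N", "S", "L"),
                       m1 = c("L", "M", "I", "V", "F"))

PTS1_CATEGORIES <- c("TARGETED", "TWILIGHT", "REJECTED", "NO_MATCH")

#' Extract the C-terminal 12-mer context of a protein
#'
#' PTS1 predictors evaluate the last 12 residues of a protein. Sequences
#' shorter than 12 residues are left-padded with `'X'` (missing evidence,
#' scored neutrally). The tripeptide is the last three characters of the
#' dodecamer.
#'
#' @param x a `protein_records` data frame or a character vector of
#'   residue strings.
#' @return Data frame with columns `dodecamer` and `tripeptide`, one row
#'   per input sequence.
#' @examples
#' extract_cterm12("MSKL")  # "XXXXXXXXMSKL", tripeptide "SKL"
#' @export
extract_cterm12 <- function(x) {
  seqs <- if (inherits(x, "protein_records")) x$sequence else as.character(x)
  if (any(!nzchar(seqs))) stop("empty sequence", call. = FALSE)
  n <- nchar(seqs)
  dode <- substring(seqs, pmax(1L, n - 11L), n)
  short <- nchar(dode) < 12L
  dode[short] <- paste0(strrep("X", 12L - nchar(dode[short])), dode[short])
  data.frame(dodecamer = dode,
             tripeptide = substring(dode, 10L, 12L),
             stringsAsFactors = FALSE)
}

#' Match the broad PTS1 consensus
#'
#' Tests tripeptides against the screening consensus
#' `[ASCNPHTG]-[RKHQNSL]-[LMIVF]`. `X` or `U` at any position never
#' matches.
#'
#' @param tripeptide character vector of 3-residue strings.
#' @return Logical vector.
#' @examples
#' match_consensus(c("SKL", "SKM", "QKL"))  # TRUE TRUE FALSE
#' @export
match_consensus <- function(tripeptide) {
  tripeptide <- as.character(tripeptide)
  if (any(nchar(tripeptide) != 3L)) {
    stop("tripeptide must have exactly 3 residues", call. = FALSE)
  }
  substring(tripeptide, 1, 1) %in% PTS1_CONSENSUS$m3 &
    substring(tripeptide, 2, 2) %in% PTS1_CONSENSUS$m2 &
    substring(tripeptide, 3, 3) %in% PTS1_CONSENSUS$m1
}

#' Fit a position-specific PTS1 scoring model
#'
#' Fits an additive log-odds position-specific scoring matrix (PSSM) over
#' the C-terminal 12 residues from a set of known PTS1 dodecamers. For
#' position `p` and residue `a` the weight is
#' \deqn{w_{p,a} = \log_2\frac{c_p(a) + \kappa\,b(a)}{\sum_r (c_p(r) + \kappa\,b(r))} - \log_2 b(a)}
#' with counts `c`, background frequencies `b` and pseudocount `kappa`.
#' A raw score is the sum of weights over the 12 positions; the reported
#' score subtracts a calibration offset. Consensus-matching dodecamers are
#' classified **TARGETED** (score > 0), **TWILIGHT** (-10 < score <= 0)
#' or **REJECTED** (score <= -10); the padding letters `X`/`U` score 0.
#'
#' The offset is calibrated from `calibration`, a named character vector
#' mapping dodecamers to required categories. Each TARGETED constraint
#' bounds the offset from above (`offset < raw`), each TWILIGHT constraint
#' brackets it (`raw <= offset < raw + 10`), each REJECTED constraint
#' bounds it from below (`offset >= raw + 10`). The fitted offset is the
#' midpoint of the feasible interval (for a one-sided interval, 5 score
#' units -- half the twilight bandwidth -- inside the bound); an empty
#' interval is an error. With no calibration the offset is the 5th
#' percentile of the training raw scores.
#'
#' @param training character vector of at least 10 training 12-mers, all
#'   consensus-matching at the tripeptide.
#' @param background 20 background residue frequencies summing to 1
#'   (named by residue, order [AA_STANDARD]); default uniform 1/20.
#' @param pseudocount positive pseudocount, default 1.
#' @param calibration named character vector (names: 12-mers; values:
#'   `"TARGETED"`, `"TWILIGHT"` or `"REJECTED"`), or `NULL`.
#' @return An object of class `pts1_model` with elements `weights`
#'   (12 x 21 matrix, columns the 20 residues plus `X`), `background`,
#'   `pseudocount`, `offset`, `t_target` (0), `t_twilight` (-10),
#'   `n_train`, `training` and `calibration`.
#' @seealso [predict.pts1_model()], [score_pts1()], [pts1_default_model()]
#' @examples
#' m <- pts1_model(rep("AAAAAAAAASKL", 10))
#' which.max(coef(m)[12, ])  # 'L'
#' @export
pts1_model <- function(training, background = NULL, pseudocount = 1,
                       calibration = NULL) {
  training <- toupper(as.character(training))
  if (length(training) < 10L) {
    stop("need at least 10 training 12-mers", call. = FALSE)
  }
  if (any(nchar(training) != 12L)) {
    stop("all training sequences must have exactly 12 residues",
         call. = FALSE)
  }
  if (!all(match_consensus(substring(training, 10L, 12L)))) {
    stop("all training 12-mers must match the PTS1 consensus at the ",
         "tripeptide", call. = FALSE)
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (length(background) != 20L) stop("background must have 20 frequencies")
  if (is.null(names(background))) names(background) <- AA_STANDARD
  background <- background[AA_STANDARD]
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }

  chars <- do.call(rbind, strsplit(training, ""))
  weights <- matrix(0, nrow = 12L, ncol = 21L,
                    dimnames = list(NULL, c(AA_STANDARD, "X")))
  for (p in 1:12) {
    counts <- table(factor(chars[, p], levels = AA_STANDARD))
    num <- as.numeric(counts) + pseudocount * background
    weights[p, AA_STANDARD] <- log2(num / sum(num)) - log2(background)
  }

  model <- structure(
    list(weights = weights, background = background,
         pseudocount = pseudocount, offset = 0,
         t_target = 0, t_twilight = -10,
         n_train = length(training), training = training,
         calibration = calibration),
    class = "pts1_model")

  raw_train <- .pts1_raw(model, training)
  if (is.null(calibration) || length(calibration) == 0L) {
    model$offset <- unname(stats::quantile(raw_train, 0.05, type = 7))
  } else {
    cats <- toupper(as.character(calibration))
    if (!all(cats %in% c("TARGETED", "TWILIGHT", "REJECTED"))) {
      stop("calibration categories must be TARGETED, TWILIGHT or REJECTED",
           call. = FALSE)
    }
    raw <- .pts1_raw(model, names(calibration))
    lo <- -Inf
    hi <- Inf
    for (i in seq_along(raw)) {
      if (cats[i] == "TARGETED") hi <- min(hi, raw[i])
      if (cats[i] == "TWILIGHT") {
        lo <- max(lo, raw[i])
        hi <- min(hi, raw[i] + 10)
      }
      if (cats[i] == "REJECTED") lo <- max(lo, raw[i] + 10)
    }
    if (!(lo < hi)) {
      stop("unsatisfiable calibration: no offset places all constrained ",
           "dodecamers in their required categories", call. = FALSE)
    }
    model$offset <-
      if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
      else if (is.finite(hi)) hi - 5
      else lo + 5
  }
  model
}

# raw (uncalibrated) PSSM sums; 'U' scores as 'X'
.pts1_raw <- function(model, dodecamers) {
  if (any(nchar(dodecamers) != 12L)) {
    stop("dodecamers must have exactly 12 characters", call. = FALSE)
  }
  cols <- colnames(model$weights)
  vapply(strsplit(toupper(dodecamers), ""), function(ch) {
    ch[!(ch %in% cols)] <- "X"
    sum(model$weights[cbind(1:12, match(ch, cols))])
  }, numeric(1))
}

#' Score C-terminal dodecamers with a PTS1 model
#'
#' The consensus gate runs first: a dodecamer whose tripeptide fails
#' [match_consensus()] is `NO_MATCH` with score `-Inf`. Otherwise the score
#' is the PSSM sum minus the calibration offset, and the category is
#' TARGETED (> 0), TWILIGHT (-10, 0] or REJECTED (<= -10).
#'
#' @param model a [pts1_model()].
#' @param dodecamer character vector of 12-mers (e.g. from
#'   [extract_cterm12()]).
#' @return Data frame with columns `dodecamer`, `tripeptide`, `score`,
#'   `category`.
#' @export
score_pts1 <- function(model, dodecamer) {
  stopifnot(inherits(model, "pts1_model"))
  dodecamer <- toupper(as.character(dodecamer))
  tri <- substring(dodecamer, 10L, 12L)
  ok <- match_consensus(tri)
  score <- rep(-Inf, length(dodecamer))
  score[ok] <- .pts1_raw(model, dodecamer[ok]) - model$offset
  category <- rep("NO_MATCH", length(dodecamer))
  category[ok & score > model$t_target] <- "TARGETED"
  category[ok & score <= model$t_target & score > model$t_twilight] <- "TWILIGHT"
  category[ok & score <= model$t_twilight] <- "REJECTED"
  data.frame(dodecamer = dodecamer, tripeptide = tri, score = score,
             category = factor(category, levels = PTS1_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Predict PTS1 targeting for protein sequences
#'
#' Extracts the C-terminal 12-mer of each sequence ([extract_cterm12()])
#' and scores it with [score_pts1()].
#'
#' @param object a [pts1_model()].
#' @param newdata a `protein_records` data frame or character vector of
#'   full-length sequences.
#' @param ... unused.
#' @return Data frame with one row per sequence: `accession` (if records
#'   were given), `dodecamer`, `tripeptide`, `score`, `category`.
#' @export
predict.pts1_model <- function(object, newdata, ...) {
  ctx <- extract_cterm12(newdata)
  out <- score_pts1(object, ctx$dodecamer)
  if (inherits(newdata, "protein_records")) {
    out <- cbind(data.frame(accession = newdata$accession,
                            stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  out
}

#' @export
coef.pts1_model <- function(object, ...) object$weights

#' @export
print.pts1_model <- function(x, ...) {
  cat("PTS1 position-specific scoring model (12 C-terminal residues)\n")
  cat(sprintf("  training 12-mers : %d\n", x$n_train))
  cat(sprintf("  pseudocount      : %g\n", x$pseudocount))
  cat(sprintf("  offset           : %.4f\n", x$offset))
  cat(sprintf("  thresholds       : targeted > %g, twilight (%g, %g]\n",
              x$t_target, x$t_twilight, x$t_target))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated on    : %d constrained dodecamers\n",
                length(x$calibration)))
  }
  invisible(x)
}

#' @export
summary.pts1_model <- function(object, ...) {
  top <- apply(object$weights[, AA_STANDARD], 1, function(w) {
    AA_STANDARD[which.max(w)]
  })
  out <- list(model = object, preferred = paste(top, collapse = ""),
              raw_range = range(.pts1_raw(object, object$training)))
  class(out) <- "summary.pts1_model"
  out
}

#' @export
print.summary.pts1_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  preferred residue by position: %s\n", x$preferred))
  cat(sprintf("  training raw score range     : [%.2f, %.2f]\n",
              x$raw_range[1], x$raw_range[2]))
  invisible(x)
}

#' Read a PTS1 training file
#'
#' Plain-text format: one 12-mer per line; `'#'` starts a comment
#' (full-line or trailing); blank lines ignored.
#'
#' @param path path to the training file.
#' @return Character vector of 12-mers.
#' @export
read_pts1_training <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Serialise / restore a PTS1 model as JSON
#'
#' @param model a [pts1_model()].
#' @param path output (input) path.
#' @return `write_pts1_model()` returns `path` invisibly;
#'   `read_pts1_model()` returns the restored `pts1_model`.
#' @export
write_pts1_model <- function(model, path) {
  stopifnot(inherits(model, "pts1_model"))
  payload <- list(weights = model$weights,
                  residues = colnames(model$weights),
                  background = as.list(model$background),
                  pseudocount = model$pseudocount,
                  offset = model$offset,
                  t_target = model$t_target,
                  t_twilight = model$t_twilight,
                  n_train = model$n_train,
                  training = model$training,
                  calibration = as.list(model$calibration))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pts1_model
#' @export
read_pts1_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- matrix(as.numeric(p$weights), nrow = 12L,
                    dimnames = list(NULL, p$residues))
  calibration <- NULL
  if (length(p$calibration)) calibration <- unlist(p$calibration)
  structure(
    list(weights = weights,
         background = unlist(p$background)[AA_STANDARD],
         pseudocount = p$pseudocount, offset = p$offset,
         t_target = p$t_target, t_twilight = p$t_twilight,
         n_train = p$n_train, training = p$training,
         calibration = calibration),
    class = "pts1_model")
}

#' The bundled zebrafish-calibrated PTS1 model
#'
#' Builds (and caches) the default model from the bundled curated training
#' set ([pts1_training_set()]) with uniform background, pseudocount 1, and
#' the reporter-derived calibration constraints: the Cdc5l C-terminal
#' 12-mer is required TARGETED, the Meox2a and Kctd5a 12-mers TWILIGHT.
#' The build is fully deterministic, so repeated construction yields
#' bit-identical weights.
#'
#' @return A [pts1_model()].
#' @export
pts1_default_model <- function() {
  if (is.null(.ptsscreen_env$default_model)) {
    .ptsscreen_env$default_model <- pts1_model(
      training = pts1_training_set(),
      calibration = pts1_default_calibration())
  }
  .ptsscreen_env$default_model
}

#' @rdname pts1_default_model
#' @export
pts1_default_calibration <- function() {
  c(LMLDKQTLSSKI = "TARGETED",   # Cdc5l reporter: peroxisomal
    HDSDQSSDHAHL = "TWILIGHT",   # Meox2a reporter: weak/cytosolic
    KAKILQEQGSRM = "TWILIGHT")   # Kctd5a reporter: weak, partial import
}
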