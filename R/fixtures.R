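# Bundled data: curated training 12-mers, reporter constructs, the
# oxidase tripeptide table, and the background residue composition.

#' Bundled curated PTS1 training 12-mers
#'
#' The curated zebrafish PTS1 set: one C-terminal 12-mer per curated
#' peroxisomal matrix protein. The tripeptides are the literature motifs
#' (SKL, AKL, ARL, SRL, SRI, SSL, SNL, AKM, ARM, PKL, SHL, SKM, TKL, SKV,
#' SML, ANM, TRL, SRV, HKL); the nine upstream context residues are
#' synthetic (constructed once and frozen -- see the bundled file's
#' comments).
#'
#' @return Character vector of 12-mers.
#' @export
pts1_training_set <- function() {
  if (is.null(.ptsscreen_env$training_set)) {
    .ptsscreen_env$training_set <-
      read_pts1_training(.extdata("pts1_training_drerio_synthetic_context.txt"))
  }
  .ptsscreen_env$training_set
}

#' PTS1 reporter construct inserts
#'
#' The C-terminal reporter inserts used to test PTS1 functionality in
#' cells: zebrafish Urad, Meox2a, Cdc5l and Kctd5a, and human CDC5L.
#' Each insert's last 12 residues are the scored dodecamer.
#'
#' @return Data frame with columns `name`, `insert`, `dodecamer`,
#'   `tripeptide`.
#' @export
pts1_reporters <- function() {
  inserts <- c(Urad = "DLHSIVLSDIQTKL",
               Meox2a = "DLHDSDQSSDHAHL",
               Cdc5l = "DLLMLDKQTLSSKI",
               Kctd5a = "DLKAKILQEQGSRM",
               CDC5L_human = "DLLLEKETLKSKF")
  ctx <- extract_cterm12(unname(inserts))
  data.frame(name = names(inserts), insert = unname(inserts),
             dodecamer = ctx$dodecamer, tripeptide = ctx$tripeptide,
             stringsAsFactors = FALSE)
}

#' PTS2 reporter nonapeptide
#'
#' The zebrafish Uraha nonapeptide used in the PTS2 reporter construct.
#'
#' @return Named character scalar.
#' @export
pts2_reporter <- function() c(Uraha = "RLQHIRGHI")

#' Curated zebrafish oxidase tripeptide table
#'
#' Candidate peroxisomal oxidases with their curated PTS1 tripeptides
#' (`"-"` where none) and predicted localisation.
#'
#' @return Data frame with columns `name`, `symbol`, `uniprot`, `pts1`,
#'   `localisation`.
#' @export
oxidase_tripeptides <- function() {
  utils::read.delim(.extdata("oxidase_tripeptides.tsv"),
                    stringsAsFactors = FALSE)
}

#' Background amino-acid composition
#'
#' A fixed vertebrate-average residue composition used by the synthetic
#' proteome generator.
#'
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
background_composition <- function() {
  if (is.null(.ptsscreen_env$background_comp)) {
    df <- utils::read.delim(.extdata("background_composition.tsv"),
                            stringsAsFactors = FALSE)
    comp <- stats::setNames(df$frequency, df$residue)[AA_STANDARD]
    .ptsscreen_env$background_comp <- comp / sum(comp)
  }
  .ptsscreen_env$background_comp
}
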