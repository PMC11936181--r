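.extdata <- function(file) {
  path <- system.file("extdata", file, package = "DockTriage",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("packaged data file not found: ", file, call. = FALSE)
  path
}

#' Curated annotation table for the 51-compound screening library
#'
#' The 51 MAPK/NF-kB-pathway inhibitors of the screening library with
#' their PubChem CIDs and the literature-curated triage flags:
#' `anti_inflammatory` (a reported anti-inflammatory effect) and
#' `excluded_known_anti_oa` (an anti-osteoarthritis effect is already
#' reported, so the compound is excluded as a novel candidate —
#' Rutaecarpine). Flags were curated for the compounds that reached the
#' published top-10; the remaining compounds carry neutral FALSE/FALSE
#' defaults, which never enter the selection procedure.
#'
#' Chryseriol and Chrysoeriol are listed with the same CID (5280666) in
#' the source library; they are kept as distinct compound ids with a
#' warning. `dedupe_cids = TRUE` keeps only the first compound of each
#' CID instead.
#'
#' @param dedupe_cids Drop later rows sharing an earlier row's CID.
#' @return data.frame with columns `compound_id`, `pubchem_cid`,
#'   `anti_inflammatory`, `excluded_known_anti_oa`.
#' @export
screenAnnotations <- function(dedupe_cids = FALSE) {
  tab <- utils::read.csv(.extdata("compound_annotations.csv"),
                         stringsAsFactors = FALSE)
  tab$anti_inflammatory <- tab$anti_inflammatory == "true"
  tab$excluded_known_anti_oa <- tab$excluded_known_anti_oa == "true"
  dup <- duplicated(tab$pubchem_cid)
  if (any(dup)) {
    shared <- unique(tab$pubchem_cid[dup])
    if (dedupe_cids) {
      tab <- tab[!dup, , drop = FALSE]
      rownames(tab) <- NULL
    } else {
      warning("distinct compound ids share PubChem CID(s): ",
              paste(shared, collapse = ", "),
              " (use dedupe_cids = TRUE to keep first occurrences only)",
              call. = FALSE)
    }
  }
  tab
}

#' Published molecular descriptors of the five candidate compounds
#'
#' PubChem descriptor values (molecular weight, XLogP3, H-bond donor
#' and acceptor counts) for the five compounds that passed the full
#' triage, as tabulated in the source screen — the inputs to
#' [evaluateLibrary()].
#'
#' @return data.frame with the [evaluateLibrary()] input columns.
#' @export
candidateDescriptors <- function() {
  utils::read.csv(.extdata("candidate_descriptors.csv"),
                  stringsAsFactors = FALSE)
}

#' Pass-through ADMET / bioactivity / toxicity annotations
#'
#' External-predictor outputs for the five candidates (SwissADME
#' pharmacokinetics, Molinspiration bioactivity scores, ProTox
#' endpoints), shipped verbatim as pass-through fields for
#' [mergeReport()]; this package never recomputes them.
#'
#' @return data.frame keyed by `compound_id`.
#' @export
candidateProperties <- function() {
  utils::read.csv(.extdata("candidate_properties.csv"),
                  stringsAsFactors = FALSE)
}

#' Published top-10 compound rankings
#'
#' The top-10 compounds of the screening library under each preset
#' score scheme, in published ascending-score order, as a ranking table
#' compatible with [selectCandidates()].
#'
#' @param scheme `"score1"` or `"score2"`.
#' @return data.frame(rank, compound_id), ranks 1-10.
#' @export
publishedTopCompounds <- function(scheme = c("score1", "score2")) {
  scheme <- match.arg(scheme)
  tab <- utils::read.csv(.extdata("published_rankings.csv"),
                         stringsAsFactors = FALSE)
  out <- tab[tab$scheme == scheme, c("rank", "compound_id"), drop = FALSE]
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ramachandran quality summary of the five docking receptors
#'
#' Percentage of residues in the most-favoured Ramachandran regions for
#' each receptor structure used in the screen, with the good-model call
#' from [classifyModelQuality()] (> 90% strictly).
#'
#' @return data.frame with `protein_id`, `pdb_id`, `pct_most_favored`,
#'   `quality`.
#' @export
proteinQuality <- function() {
  tab <- utils::read.csv(.extdata("protein_quality.csv"),
                         stringsAsFactors = FALSE)
  tab$quality <- classifyModelQuality(tab$pct_most_favored)
  tab
}
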