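#' @import methods
NULL

#' Canonical docking target identifiers
#'
#' The five pathway proteins used throughout the package: the MAPK kinases
#' ERK2, JNK2 and p38, and the NF-kB components p65 and IkBa (the latter is
#' the anti-target: strong binding to it is undesirable). "IkBa" is the
#' ASCII identifier for I-kappa-B-alpha.
#'
#' @return Character vector of the five target identifiers.
#' @export
#' @examples
#' defaultTargets()
defaultTargets <- function() {
  c("ERK2", "JNK2", "p38", "p65", "IkBa")
}

#' EnergyMatrix: compound-by-target representative binding energies
#'
#' A dense matrix of representative docking binding energies (kcal/mol,
#' negative = more favourable), compounds as rows and targets as columns.
#' Every cell must be present and finite; missing pairs are a construction
#' error, never imputed, because the downstream score formulas need all
#' five energies per compound.
#'
#' @slot energies Numeric matrix with unique, non-empty rownames
#'   (compound ids) and colnames (target ids); all values finite.
#'
#' @seealso [buildEnergyMatrix()], [rankCompounds()], [thresholdFilter()]
#' @export
setClass("EnergyMatrix", representation(energies = "matrix"))

setValidity("EnergyMatrix", function(object) {
  e <- object@energies
  msgs <- character()
  if (!is.numeric(e)) {
    msgs <- c(msgs, "energies must be a numeric matrix")
  } else {
    if ((nrow(e) > 0L && is.null(rownames(e))) ||
        (ncol(e) > 0L && is.null(colnames(e))))
      msgs <- c(msgs, "energies must carry compound rownames and target colnames")
    else {
      if (anyDuplicated(rownames(e)))
        msgs <- c(msgs, "duplicate compound ids in rownames")
      if (anyDuplicated(colnames(e)))
        msgs <- c(msgs, "duplicate target ids in colnames")
    }
    if (length(e) && !all(is.finite(e)))
      msgs <- c(msgs, "all energies must be finite (no missing pairs)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnergyMatrix from a named numeric matrix
#'
#' @param energies Numeric matrix, compounds as rows (rownames = compound
#'   ids), targets as columns (colnames = target ids), kcal/mol.
#' @return An [EnergyMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(c(-8, -7.5, -6, -5), 2, 2,
#'             dimnames = list(c("cmpA", "cmpB"), c("ERK2", "IkBa")))
#' EnergyMatrix(m)
EnergyMatrix <- function(energies) {
  new("EnergyMatrix", energies = energies)
}

#' @describeIn EnergyMatrix-class Compound identifiers (row order).
#' @param x An `EnergyMatrix`.
#' @export
compoundIds <- function(x) {
  stopifnot(is(x, "EnergyMatrix"))
  rownames(x@energies)
}

#' @describeIn EnergyMatrix-class Target identifiers (column order).
#' @export
targetIds <- function(x) {
  stopifnot(is(x, "EnergyMatrix"))
  colnames(x@energies)
}

#' @describeIn EnergyMatrix-class The underlying numeric matrix (kcal/mol).
#' @export
energies <- function(x) {
  stopifnot(is(x, "EnergyMatrix"))
  x@energies
}

setMethod("show", "EnergyMatrix", function(object) {
  e <- object@energies
  cat(sprintf("EnergyMatrix: %d compounds x %d targets (kcal/mol)\n",
              nrow(e), ncol(e)))
  cat("targets:", paste(colnames(e), collapse = ", "), "\n")
  n <- min(nrow(e), 5L)
  if (n > 0L) print(round(e[seq_len(n), , drop = FALSE], 2))
  if (nrow(e) > n) cat(sprintf("... and %d more compounds\n", nrow(e) - n))
  invisible(NULL)
})

#' ScoreScheme: signed per-target weights for a multi-target score
#'
#' A score is the weighted sum of a compound's representative binding
#' energies, \eqn{S = \sum_t w_t E_t}. Targets carry positive weights;
#' the anti-target carries a negative weight so that strong (very
#' negative) anti-target binding penalises the score. Compounds are
#' ranked ascending (lowest score = best candidate).
#'
#' Two presets are built in:
#' \describe{
#'   \item{score1}{ERK2 +1, JNK2 +1, p38 +1, p65 +3, IkBa -1 (equal
#'     weight per pathway, split over each pathway's proteins).}
#'   \item{score2}{ERK2 +1, JNK2 +1, p38 +1, p65 +1, IkBa -1 (equal
#'     weight per protein).}
#' }
#'
#' @slot name Scheme label.
#' @slot weights Named numeric vector, target id -> signed weight.
#' @export
setClass("ScoreScheme",
         representation(name = "character", weights = "numeric"))

setValidity("ScoreScheme", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  w <- object@weights
  if (length(w) == 0L) msgs <- c(msgs, "weights must be non-empty")
  if (is.null(names(w)) || any(!nzchar(names(w))) || anyDuplicated(names(w)))
    msgs <- c(msgs, "weights must have unique non-empty target names")
  if (length(w) && !all(is.finite(w)))
    msgs <- c(msgs, "weights must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Create a score scheme (preset or custom)
#'
#' @param name `"score1"`, `"score2"`, or a label for a custom scheme.
#' @param weights For a custom scheme, a named numeric vector of signed
#'   per-target weights. Ignored for the presets.
#' @return A [ScoreScheme-class] object.
#' @export
#' @examples
#' scoreScheme("score1")
#' scoreScheme("flat", c(ERK2 = 1, JNK2 = 1, p38 = 1, p65 = 1, IkBa = -1))
scoreScheme <- function(name, weights = NULL) {
  if (is.null(weights)) {
    weights <- switch(name,
      score1 = c(ERK2 = 1, JNK2 = 1, p38 = 1, p65 = 3, IkBa = -1),
      score2 = c(ERK2 = 1, JNK2 = 1, p38 = 1, p65 = 1, IkBa = -1),
      stop("unknown preset '", name,
           "'; supply `weights` for a custom scheme", call. = FALSE))
  }
  new("ScoreScheme", name = name, weights = weights)
}

#' @describeIn ScoreScheme-class The named weight vector.
#' @param x A `ScoreScheme`.
#' @export
schemeWeights <- function(x) {
  stopifnot(is(x, "ScoreScheme"))
  x@weights
}

setMethod("show", "ScoreScheme", function(object) {
  w <- object@weights
  terms <- sprintf("%+g*E_%s", unname(w), names(w))
  cat(sprintf("ScoreScheme '%s': S = %s\n",
              object@name, paste(terms, collapse = " ")))
  invisible(NULL)
})

#' StandardCurve: linear nitrite calibration
#'
#' Ordinary least-squares line `od = slope * concentration + intercept`
#' fitted to kit standards; inverted by [nitriteConcentration()] to read
#' nitrite (uM) off a measured optical density.
#'
#' @slot slope Fitted slope (OD per uM); must be non-zero.
#' @slot intercept Fitted intercept (OD at zero nitrite).
#' @slot points data.frame(concentration, od) of the standards used.
#' @export
setClass("StandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        points = "data.frame"))

setValidity("StandardCurve", function(object) {
  msgs <- character()
  if (length(object@slope) != 1L || !is.finite(object@slope) ||
      object@slope == 0)
    msgs <- c(msgs, "slope must be a single finite non-zero number")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a single finite number")
  if (!all(c("concentration", "od") %in% names(object@points)))
    msgs <- c(msgs, "points must have columns concentration and od")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: od = %.6g * conc + %.6g (%d standards)\n",
              object@slope, object@intercept, nrow(object@points)))
  invisible(NULL)
})

#' SelectionReport: audit-trailed candidate selection
#'
#' Result of the selection procedure: take the top-N of an ascending
#' score ranking, keep compounds annotated as anti-inflammatory, then
#' drop compounds excluded as already-known actives. Every compound in
#' the ranking receives exactly one reason code in the audit table:
#' `selected`, `excluded`, `not_anti_inflammatory`, or `not_top_n`.
#'
#' @slot topN Ordered ids of the top-N compounds.
#' @slot antiInflammatory Ordered ids surviving the anti-inflammatory
#'   filter.
#' @slot final Ordered ids of the final candidates.
#' @slot audit data.frame(compound_id, reason), one row per ranked
#'   compound, in ranking order.
#' @export
setClass("SelectionReport",
         representation(topN = "character", antiInflammatory = "character",
                        final = "character", audit = "data.frame"))

setValidity("SelectionReport", function(object) {
  msgs <- character()
  if (!all(object@antiInflammatory %in% object@topN))
    msgs <- c(msgs, "antiInflammatory ids must be a subset of topN")
  if (!all(object@final %in% object@antiInflammatory))
    msgs <- c(msgs, "final ids must be a subset of antiInflammatory")
  if (!all(c("compound_id", "reason") %in% names(object@audit)))
    msgs <- c(msgs, "audit must have columns compound_id and reason")
  else {
    ok <- object@audit$reason %in%
      c("selected", "excluded", "not_anti_inflammatory", "not_top_n")
    if (!all(ok)) msgs <- c(msgs, "unknown audit reason code")
    if (anyDuplicated(object@audit$compound_id))
      msgs <- c(msgs, "audit must list each compound exactly once")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SelectionReport-class Final candidate ids, ranking order.
#' @param x A `SelectionReport`.
#' @export
selectedIds <- function(x) {
  stopifnot(is(x, "SelectionReport"))
  x@final
}

#' @describeIn SelectionReport-class The per-compound audit table.
#' @export
selectionAudit <- function(x) {
  stopifnot(is(x, "SelectionReport"))
  x@audit
}

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf("SelectionReport: %d ranked -> top %d -> %d anti-inflammatory -> %d selected\n",
              nrow(object@audit), length(object@topN),
              length(object@antiInflammatory), length(object@final)))
  cat("selected:", paste(object@final, collapse = ", "), "\n")
  invisible(NULL)
})
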