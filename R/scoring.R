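#' Weighted multi-target score of one compound's energies
#'
#' \eqn{S = \sum_t w_t E_t} over the scheme's targets. With the built-in
#' presets this is, e.g. for `score1`,
#' \eqn{S_1 = E_{ERK2} + E_{JNK2} + E_{p38} + 3 E_{p65} - E_{IkBa}}:
#' favourable (negative) energies on the four targets pull the score
#' down, favourable anti-target binding pushes it up. No normalisation
#' is applied; units are a kcal/mol-weighted sum.
#'
#' @param row Named numeric vector of representative energies
#'   (kcal/mol), supplying every target named in the scheme.
#' @param scheme A [ScoreScheme-class].
#' @return The score (single number).
#' @export
#' @examples
#' computeScore(c(ERK2 = -8, JNK2 = -7, p38 = -7.5, p65 = -8.2, IkBa = -6),
#'              scoreScheme("score1"))
computeScore <- function(row, scheme) {
  stopifnot(is(scheme, "ScoreScheme"))
  w <- schemeWeights(scheme)
  miss <- setdiff(names(w), names(row))
  if (length(miss))
    stop("missing energy for target(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vals <- row[names(w)]
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("energies must be finite numbers", call. = FALSE)
  sum(w * as.numeric(vals))
}

#' Rank compounds by a multi-target score, ascending
#'
#' Scores every compound of the matrix under the scheme and ranks from
#' lowest (best, rank 1) to highest; in docking, a lower binding energy
#' means a more stable complex, so lower weighted sums indicate stronger
#' multi-target binders. Ties are broken by ascending compound id for
#' determinism.
#'
#' @param x An [EnergyMatrix-class], dense over the scheme's targets.
#' @param scheme A [ScoreScheme-class].
#' @return data.frame(rank, compound_id, score), ordered by rank; empty
#'   for an empty matrix.
#' @export
rankCompounds <- function(x, scheme) {
  stopifnot(is(x, "EnergyMatrix"), is(scheme, "ScoreScheme"))
  e <- energies(x)
  w <- schemeWeights(scheme)
  miss <- setdiff(names(w), colnames(e))
  if (length(miss))
    stop("matrix lacks scheme target(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(e) == 0L)
    return(data.frame(rank = integer(), compound_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  scores <- as.numeric(e[, names(w), drop = FALSE] %*% w)
  ord <- order(scores, rownames(e), method = "radix")
  data.frame(rank = seq_along(ord),
             compound_id = rownames(e)[ord],
             score = scores[ord],
             stringsAsFactors = FALSE)
}

#' Threshold filter with an anti-target ceiling
#'
#' Retains a compound iff its representative energy is strictly below
#' `cutoff` on every target AND at or above `cutoff` on the anti-target
#' — i.e. it binds all intended targets strongly but not the protein
#' whose inhibition would be counter-productive. Comparisons are exact
#' (no epsilon): docking energies are reported at 0.1 kcal/mol
#' granularity, and the strict/non-strict pair partitions cleanly at the
#' cutoff.
#'
#' @param x An [EnergyMatrix-class] containing all targets and the
#'   anti-target.
#' @param cutoff Energy cutoff in kcal/mol (default -7).
#' @param targets Target ids that must bind strongly (default ERK2,
#'   JNK2, p38, p65).
#' @param antitarget Anti-target id that must not (default IkBa).
#' @return Character vector of retained compound ids, in matrix row
#'   order.
#' @export
thresholdFilter <- function(x, cutoff = -7,
                            targets = c("ERK2", "JNK2", "p38", "p65"),
                            antitarget = "IkBa") {
  stopifnot(is(x, "EnergyMatrix"), length(antitarget) == 1L)
  if (antitarget %in% targets)
    stop("antitarget must not appear among the targets", call. = FALSE)
  e <- energies(x)
  miss <- setdiff(targets, colnames(e))
  if (length(miss))
    stop("matrix lacks target(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!antitarget %in% colnames(e))
    stop("matrix lacks anti-target '", antitarget, "'", call. = FALSE)
  strong <- rowSums(e[, targets, drop = FALSE] < cutoff) == length(targets)
  weak_anti <- e[, antitarget] >= cutoff
  rownames(e)[strong & weak_anti]
}
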