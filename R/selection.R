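#' Candidate selection from a ranked list with annotation filters
#'
#' Applies the three-stage triage to an ascending score ranking:
#' (1) keep the top `top_n` compounds; (2) keep those annotated as
#' anti-inflammatory (inflammatory signalling being broadly shared, an
#' anti-inflammatory compound is a plausible chondro-protective
#' candidate); (3) drop compounds excluded because an anti-OA effect is
#' already reported for them, so they are no longer novel candidates.
#' The filters commute for the final set, but the audit reason depends
#' on order, so the order is fixed: a compound failing both filters is
#' coded `not_anti_inflammatory`.
#'
#' @param ranked data.frame with columns `rank` and `compound_id`
#'   (ascending-rank order), as produced by [rankCompounds()].
#' @param annotations data.frame with columns `compound_id`,
#'   `anti_inflammatory`, `excluded_known_anti_oa` (logical); one row
#'   per compound; every top-N compound must be annotated. Extra
#'   (pass-through) columns are permitted and untouched.
#' @param top_n Number of top-ranked compounds to carry forward
#'   (default 10).
#' @return A [SelectionReport-class] with ordered id lists and a
#'   per-compound audit table.
#' @export
selectCandidates <- function(ranked, annotations, top_n = 10L) {
  stopifnot(is.data.frame(ranked),
            all(c("rank", "compound_id") %in% names(ranked)))
  need <- c("compound_id", "anti_inflammatory", "excluded_known_anti_oa")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(annotations$compound_id))
    stop("duplicate compound_id in annotation table", call. = FALSE)
  if (length(top_n) != 1L || top_n < 1L)
    stop("top_n must be a single integer >= 1", call. = FALSE)
  ids <- ranked$compound_id[order(ranked$rank)]
  top <- utils::head(ids, top_n)
  unannotated <- setdiff(top, annotations$compound_id)
  if (length(unannotated))
    stop("no annotation for top-", top_n, " compound(s): ",
         paste(unannotated, collapse = ", "), call. = FALSE)
  ai_flag <- annotations$anti_inflammatory[match(top, annotations$compound_id)]
  ex_flag <- annotations$excluded_known_anti_oa[match(top, annotations$compound_id)]
  if (!is.logical(ai_flag) || !is.logical(ex_flag) ||
      anyNA(ai_flag) || anyNA(ex_flag))
    stop("annotation flags must be non-missing logicals", call. = FALSE)
  anti <- top[ai_flag]
  final <- anti[!ex_flag[ai_flag]]
  reason <- rep("not_top_n", length(ids))
  reason[ids %in% top] <- "not_anti_inflammatory"
  reason[ids %in% anti] <- "excluded"
  reason[ids %in% final] <- "selected"
  audit <- data.frame(compound_id = ids, reason = reason,
                      stringsAsFactors = FALSE)
  new("SelectionReport", topN = top, antiInflammatory = anti,
      final = final, audit = audit)
}

#' Merge a selection with drug-likeness results and annotations
#'
#' Builds the final candidate report: one row per selected compound, in
#' selection (ranking) order, carrying the Lipinski columns and every
#' annotation column. Pass-through annotation fields (ADMET calls,
#' bioactivity scores, toxicity flags produced by external predictors)
#' are copied verbatim — this module never reinterprets them.
#'
#' @param report A [SelectionReport-class].
#' @param lipinski data.frame from [evaluateLibrary()]; must cover every
#'   selected compound.
#' @param annotations Annotation data.frame (see [selectCandidates()]);
#'   must cover every selected compound.
#' @return data.frame, one row per selected compound.
#' @export
mergeReport <- function(report, lipinski, annotations) {
  stopifnot(is(report, "SelectionReport"))
  ids <- selectedIds(report)
  for (nm in c("lipinski", "annotations")) {
    tab <- get(nm)
    if (!is.data.frame(tab) || !"compound_id" %in% names(tab))
      stop(nm, " must be a data.frame with a compound_id column",
           call. = FALSE)
    miss <- setdiff(ids, tab$compound_id)
    if (length(miss))
      stop("selected compound(s) absent from ", nm, " table: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(ids) == 0L) {
    out <- cbind(lipinski[0, , drop = FALSE],
                 annotations[0, setdiff(names(annotations), "compound_id"),
                             drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  li <- lipinski[match(ids, lipinski$compound_id), , drop = FALSE]
  an <- annotations[match(ids, annotations$compound_id),
                    setdiff(names(annotations), "compound_id"), drop = FALSE]
  out <- cbind(li, an)
  rownames(out) <- NULL
  out
}
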