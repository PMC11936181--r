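#' Lipinski rule-of-5 evaluation for one descriptor set
#'
#' Counts violations of the four oral-drug-likeness rules against the
#' canonical inclusive boundaries: molecular weight <= 500 g/mol,
#' LogP <= 5, hydrogen-bond donors <= 5, hydrogen-bond acceptors <= 10
#' are compliant; a descriptor strictly above its boundary violates the
#' rule. Descriptors are tabulated database values (e.g. PubChem's
#' XLogP3 for LogP), not computed from structures here.
#'
#' By default a compound is drug-like only with zero violations;
#' `relaxed = TRUE` applies the common "at most one violation"
#' relaxation instead.
#'
#' @param molecular_weight Molecular weight in g/mol (> 0).
#' @param logp Octanol-water partition coefficient (XLogP3-style).
#' @param hbd_count Hydrogen-bond donor count (integer >= 0).
#' @param hba_count Hydrogen-bond acceptor count (integer >= 0).
#' @param relaxed Use the <= 1 violation drug-likeness rule.
#' @return A one-row data.frame: logical columns `mw_violation`,
#'   `logp_violation`, `hbd_violation`, `hba_violation`, plus
#'   `violated_rules` (comma-joined codes among MW, LogP, HBD, HBA),
#'   `violation_count` (0-4) and `druglike`.
#' @export
#' @examples
#' lipinskiViolations(634.5, 0.1, 11, 18)   # 3 violations: MW, HBD, HBA
#' lipinskiViolations(432.4, -0.1, 6, 10)   # 1 violation: HBD (HBA = 10 compliant)
lipinskiViolations <- function(molecular_weight, logp, hbd_count, hba_count,
                               relaxed = FALSE) {
  .checkDescriptors(molecular_weight, logp, hbd_count, hba_count)
  mw   <- molecular_weight > 500
  lp   <- logp > 5
  hbd  <- hbd_count > 5
  hba  <- hba_count > 10
  codes <- c("MW", "LogP", "HBD", "HBA")[c(mw, lp, hbd, hba)]
  n <- length(codes)
  data.frame(mw_violation = mw, logp_violation = lp,
             hbd_violation = hbd, hba_violation = hba,
             violated_rules = paste(codes, collapse = ","),
             violation_count = n,
             druglike = if (relaxed) n <= 1L else n == 0L,
             stringsAsFactors = FALSE)
}

.checkDescriptors <- function(mw, logp, hbd, hba) {
  scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  if (!scalar_num(mw) || mw <= 0)
    stop("molecular_weight must be a single positive number", call. = FALSE)
  if (!scalar_num(logp))
    stop("logp must be a single finite number", call. = FALSE)
  for (nm in c("hbd", "hba")) {
    v <- get(nm)
    if (!scalar_num(v) || v < 0 || v != round(v))
      stop(nm, "_count must be a single non-negative integer", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate Lipinski drug-likeness over a descriptor table
#'
#' @param descriptors data.frame with columns `compound_id`,
#'   `molecular_weight`, `logp`, `hbd_count`, `hba_count` (one row per
#'   compound, unique ids). Extra columns are ignored.
#' @param relaxed Passed to [lipinskiViolations()].
#' @return data.frame, one row per input row in input order:
#'   `compound_id` plus the [lipinskiViolations()] columns.
#' @export
#' @examples
#' tab <- data.frame(compound_id = c("a", "b"),
#'                   molecular_weight = c(634.5, 353.4),
#'                   logp = c(0.1, 2.8), hbd_count = c(11, 0),
#'                   hba_count = c(18, 6))
#' evaluateLibrary(tab)$violation_count   # 3 0
evaluateLibrary <- function(descriptors, relaxed = FALSE) {
  need <- c("compound_id", "molecular_weight", "logp", "hbd_count", "hba_count")
  miss <- setdiff(need, names(descriptors))
  if (length(miss))
    stop("descriptor table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(descriptors$compound_id))
    stop("duplicate compound_id in descriptor table: ",
         descriptors$compound_id[duplicated(descriptors$compound_id)][1L],
         call. = FALSE)
  if (nrow(descriptors) == 0L) {
    out <- lipinskiViolations(1, 0, 0, 0)[0, , drop = FALSE]
    return(cbind(data.frame(compound_id = character()), out))
  }
  rows <- lapply(seq_len(nrow(descriptors)), function(i)
    lipinskiViolations(descriptors$molecular_weight[i], descriptors$logp[i],
                       descriptors$hbd_count[i], descriptors$hba_count[i],
                       relaxed = relaxed))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(compound_id = descriptors$compound_id,
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
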