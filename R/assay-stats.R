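#' Cell viability as percent of the control group
#'
#' CCK-8 viability arithmetic: each treatment well's optical density
#' (450 nm) is expressed as a percentage of the control-group mean,
#' after optional blank subtraction,
#' `100 * (od - blank) / (mean(control) - blank)`. Blank correction is
#' off by default (`blank_od = 0`); supply a blank only when blank wells
#' were actually read.
#'
#' @param treatment_ods Numeric vector of treatment-well ODs.
#' @param control_ods Numeric vector of control-well ODs.
#' @param blank_od Single blank OD subtracted from both (default 0).
#' @return List with `replicate_pct` (one percentage per treatment
#'   well) and `group_mean_pct` (mean of those percentages).
#' @export
#' @examples
#' viabilityPercent(0.35, c(0.5, 0.5))$group_mean_pct  # 70
viabilityPercent <- function(treatment_ods, control_ods, blank_od = 0) {
  stopifnot(is.numeric(treatment_ods), is.numeric(control_ods),
            length(blank_od) == 1L, is.finite(blank_od))
  denom <- mean(control_ods) - blank_od
  if (!is.finite(denom) || denom <= 0)
    stop("control mean minus blank must be positive", call. = FALSE)
  pct <- 100 * (treatment_ods - blank_od) / denom
  list(replicate_pct = pct, group_mean_pct = mean(pct))
}

#' ISO 10993-5 cytotoxicity call from group viability
#'
#' A treatment group is noncytotoxic when its mean viability is at
#' least 70% of the control group's (inclusive boundary: exactly 70%
#' passes). The call applies to the group mean, not to individual
#' replicates.
#'
#' @param group_viability_pct Numeric vector of group-mean viability
#'   percentages.
#' @return Character vector, `"noncytotoxic"` or `"cytotoxic"`.
#' @export
#' @examples
#' classifyCytotoxicity(c(70, 69.9))  # "noncytotoxic" "cytotoxic"
classifyCytotoxicity <- function(group_viability_pct) {
  if (!is.numeric(group_viability_pct) || any(!is.finite(group_viability_pct)))
    stop("viability percentages must be finite", call. = FALSE)
  ifelse(group_viability_pct >= 70, "noncytotoxic", "cytotoxic")
}

#' Fit a linear nitrite standard curve
#'
#' Ordinary least squares of optical density (550 nm) on nitrite
#' concentration over the kit standards: `od = slope * conc +
#' intercept`. At least two distinct concentrations are required.
#'
#' @param concentration Numeric vector of standard concentrations (uM).
#' @param od Numeric vector of matching ODs.
#' @return A [StandardCurve-class].
#' @export
#' @examples
#' fitStandardCurve(c(0, 100), c(0.05, 0.55))  # slope 0.005, intercept 0.05
fitStandardCurve <- function(concentration, od) {
  stopifnot(is.numeric(concentration), is.numeric(od),
            length(concentration) == length(od))
  if (length(unique(concentration)) < 2L)
    stop("need at least two distinct standard concentrations", call. = FALSE)
  fit <- stats::lm(od ~ concentration)
  co <- stats::coef(fit)
  new("StandardCurve", slope = unname(co[["concentration"]]),
      intercept = unname(co[["(Intercept)"]]),
      points = data.frame(concentration = concentration, od = od))
}

#' Read nitrite concentration off a standard curve
#'
#' Inverts the fitted line: `conc = (od - intercept) / slope`. Inferred
#' concentrations below zero (measurement noise around the blank) are
#' clamped to 0 with a warning — nitrite is physically non-negative.
#'
#' @param od Numeric vector of sample ODs.
#' @param curve A [StandardCurve-class].
#' @return Numeric vector of nitrite concentrations (uM), >= 0.
#' @export
nitriteConcentration <- function(od, curve) {
  if (!is(curve, "StandardCurve"))
    stop("curve must be a fitted StandardCurve", call. = FALSE)
  stopifnot(is.numeric(od))
  conc <- (od - curve@intercept) / curve@slope
  neg <- conc < 0
  # warn only for genuine negatives, not rounding residue at the blank
  if (any(conc < -sqrt(.Machine$double.eps), na.rm = TRUE))
    warning(sum(neg), " nitrite value(s) below zero clamped to 0",
            call. = FALSE)
  conc[neg] <- 0
  conc
}

#' Two-tailed unpaired t-test between two groups
#'
#' Compares group means with the unpaired t-test, two-tailed. The
#' default `student` variant pools the variances (df = n_a + n_b - 2),
#' matching the conventional unpaired test of plate-assay software; the
#' `welch` variant drops the equal-variance assumption
#' (Welch-Satterthwaite df). Identical groups (zero variance, equal
#' means) yield t = 0, p = 1 rather than an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return List with `t_statistic`, `degrees_of_freedom`, `p_value`
#'   (two-tailed) and `stars` (see [significanceStars()]).
#' @export
#' @examples
#' unpairedTTest(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
unpairedTTest <- function(group_a, group_b,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least two values", call. = FALSE)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      df <- if (variant == "student")
        length(group_a) + length(group_b) - 2L else NA_real_
      return(list(t_statistic = 0, degrees_of_freedom = df,
                  p_value = 1, stars = "ns"))
    }
    stop("both groups have zero variance but different means", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t_statistic = unname(ht$statistic),
       degrees_of_freedom = unname(ht$parameter),
       p_value = ht$p.value,
       stars = significanceStars(ht$p.value))
}

#' Significance stars from a two-tailed p-value
#'
#' Strict thresholds, most extreme star wins: `****` for p < 0.0001,
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' `ns` (so p = 0.05 exactly is not significant).
#'
#' @param p_value Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star codes.
#' @export
#' @examples
#' significanceStars(c(0.04, 0.05, 0.00005))  # "*" "ns" "****"
significanceStars <- function(p_value) {
  if (!is.numeric(p_value) || any(!is.finite(p_value)) ||
      any(p_value < 0 | p_value > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- character(length(p_value))
  out[p_value >= 0.05] <- "ns"
  out[p_value < 0.05] <- "*"
  out[p_value < 0.01] <- "**"
  out[p_value < 0.001] <- "***"
  out[p_value < 0.0001] <- "****"
  out
}

#' Compare every treatment group of a plate against control
#'
#' Runs the unpaired t-test of each non-control group's ODs (or derived
#' values) against the control group's, annotating stars. Comparisons
#' are independent (each treatment vs control), with no multiplicity
#' correction by default; `holm = TRUE` applies a Holm adjustment
#' across the comparisons before starring.
#'
#' @param plate data.frame with columns `group`, `od` (long format; one
#'   row per well); may carry `concentration`, `replicate`.
#' @param control Label of the control group (default `"control"`).
#' @param variant Passed to [unpairedTTest()].
#' @param holm Apply Holm correction across treatment groups.
#' @return data.frame, one row per treatment group: `group`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `stars`.
#' @export
compareGroups <- function(plate, control = "control",
                          variant = c("student", "welch"), holm = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(plate), all(c("group", "od") %in% names(plate)))
  if (!control %in% plate$group)
    stop("no wells with control group label '", control, "'", call. = FALSE)
  ctrl <- plate$od[plate$group == control]
  groups <- setdiff(unique(plate$group), control)
  rows <- lapply(groups, function(g) {
    res <- unpairedTTest(plate$od[plate$group == g], ctrl, variant = variant)
    data.frame(group = g, t_statistic = res$t_statistic,
               degrees_of_freedom = res$degrees_of_freedom,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(group = character(), t_statistic = numeric(),
                      degrees_of_freedom = numeric(), p_value = numeric(),
                      stars = character(), stringsAsFactors = FALSE))
  p <- if (holm) stats::p.adjust(out$p_value, method = "holm") else out$p_value
  out$stars <- significanceStars(p)
  rownames(out) <- NULL
  out
}
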