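# Small fixtures and independent oracles shared across test files.

# A named energy matrix over the five canonical targets.
makeEnergyMatrix <- function(values, compounds) {
  m <- matrix(values, nrow = length(compounds), ncol = 5, byrow = TRUE,
              dimnames = list(compounds, defaultTargets()))
  EnergyMatrix(m)
}

# Brute-force ranking oracle: recompute each weighted sum from scratch
# with a scalar loop and sort by (score, id) using a comparison sort.
bruteForceRanking <- function(mat, weights) {
  ids <- rownames(mat)
  scores <- vapply(ids, function(id) {
    s <- 0
    for (t in names(weights)) s <- s + weights[[t]] * mat[id, t]
    s
  }, numeric(1))
  ord <- order(scores, ids)
  data.frame(rank = seq_along(ord), compound_id = ids[ord],
             score = unname(scores[ord]), stringsAsFactors = FALSE)
}

# Cell-by-cell threshold oracle.
bruteForceFilter <- function(mat, cutoff, targets, antitarget) {
  keep <- vapply(rownames(mat), function(id) {
    all(vapply(targets, function(t) mat[id, t] < cutoff, logical(1))) &&
      mat[id, antitarget] >= cutoff
  }, logical(1))
  rownames(mat)[keep]
}

# Pooled-variance two-sample t statistic and two-tailed p, closed form.
pooledTOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Closed-form simple OLS via the normal equations.
olsOracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

# Runs table for a single (compound, target) pair.
pairRuns <- function(compound, target, energies) {
  data.frame(compound_id = compound, target_id = target,
             configuration_index = seq_along(energies),
             energy_kcal_mol = energies, stringsAsFactors = FALSE)
}
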