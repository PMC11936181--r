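# Run expr under a fixed RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer (no implicit entropy)", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Describe a planted hit for the synthetic library
#'
#' A planted hit shifts the pair-mean energy of its compound: by
#' `target_offset` (default -5 kcal/mol, a strong favourable shift) on
#' every target, and by `antitarget_offset` (default +3 kcal/mol) on
#' the anti-target. The positive anti-target default models a genuinely
#' selective binder — weak anti-target affinity — so that a planted hit
#' both tops the weighted score and clears the anti-target ceiling of
#' the threshold filter.
#'
#' @param compound_id Identifier for the hit compound.
#' @param target_offset Shift (kcal/mol) added to the pair mean on each
#'   target.
#' @param antitarget_offset Shift (kcal/mol) added on the anti-target.
#' @return data.frame row describing the hit.
#' @export
plantedHit <- function(compound_id, target_offset = -5, antitarget_offset = 3) {
  stopifnot(length(compound_id) == 1L, is.finite(target_offset),
            is.finite(antitarget_offset))
  data.frame(compound_id = compound_id, target_offset = target_offset,
             antitarget_offset = antitarget_offset, stringsAsFactors = FALSE)
}

#' Specification of a synthetic docking library
#'
#' Defaults emulate the screening study's conditions: 51 compounds
#' docked against the five pathway proteins, 10-20 poses per
#' (compound, target) pair, pose energies i.i.d. Gaussian around
#' -6 kcal/mol with sd 1 kcal/mol. Decoys share the same marginal
#' energy distribution on all five proteins, so the anti-target term of
#' the score is exercised non-trivially. `n_compounds` counts decoys;
#' planted hits are additional compounds.
#'
#' @param n_compounds Number of decoy compounds (>= 1; default 51).
#' @param targets Ordered target ids (default [defaultTargets()]).
#' @param antitarget Which target is the anti-target (default `"IkBa"`).
#' @param configs_range Integer range (lo, hi) of poses per pair
#'   (default 10-20).
#' @param energy_mean,energy_sd Gaussian pose-energy parameters
#'   (kcal/mol; defaults -6 and 1).
#' @param planted_hits data.frame of [plantedHit()] rows, or NULL.
#' @param seed Mandatory integer seed.
#' @return A `librarySpec` list.
#' @export
librarySpec <- function(n_compounds = 51L, targets = defaultTargets(),
                        antitarget = "IkBa", configs_range = c(10L, 20L),
                        energy_mean = -6, energy_sd = 1,
                        planted_hits = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_compounds >= 1L, length(targets) >= 1L,
            antitarget %in% targets,
            length(configs_range) == 2L, configs_range[1L] >= 1L,
            configs_range[1L] <= configs_range[2L],
            is.finite(energy_mean), energy_sd > 0)
  if (!is.null(planted_hits)) {
    stopifnot(is.data.frame(planted_hits),
              all(c("compound_id", "target_offset", "antitarget_offset") %in%
                    names(planted_hits)))
    if (anyDuplicated(planted_hits$compound_id))
      stop("duplicate planted compound ids", call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds), targets = targets,
                 antitarget = antitarget,
                 configs_range = as.integer(configs_range),
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 planted_hits = planted_hits, seed = as.integer(seed)),
            class = "librarySpec")
}

#' Generate a seeded synthetic docking library
#'
#' Draws per-pose energies i.i.d. Normal(mean, sd) for every
#' (compound, target) pair, applying planted-hit offsets to the pair
#' mean; the pose count of each pair is uniform over `configs_range`.
#' Also fabricates a plausible molecular-descriptor table and an
#' annotation table in which planted hits are flagged anti-inflammatory
#' and not excluded (so a recovered hit can survive the full selection
#' procedure), while decoys get random flags. The same seed reproduces
#' every table exactly.
#'
#' @param spec A [librarySpec()].
#' @return List with elements `runs` (long pose-energy table),
#'   `descriptors`, `annotations`, and `truth` (planted-hit record:
#'   hit table, decoy ids, spec echo).
#' @export
generateLibrary <- function(spec) {
  stopifnot(inherits(spec, "librarySpec"))
  .withSeed(spec$seed, {
    decoys <- sprintf("cmp%03d", seq_len(spec$n_compounds))
    hits <- spec$planted_hits
    if (!is.null(hits) && any(hits$compound_id %in% decoys))
      stop("planted compound id collides with a decoy id", call. = FALSE)
    compounds <- c(decoys, if (!is.null(hits)) hits$compound_id)
    tg <- spec$targets
    n_pair <- length(compounds) * length(tg)
    cfg <- sample(seq.int(spec$configs_range[1L], spec$configs_range[2L]),
                  n_pair, replace = TRUE)
    pair_compound <- rep(compounds, each = length(tg))
    pair_target <- rep(tg, times = length(compounds))
    offset <- numeric(n_pair)
    if (!is.null(hits)) {
      for (i in seq_len(nrow(hits))) {
        is_hit <- pair_compound == hits$compound_id[i]
        offset[is_hit & pair_target != spec$antitarget] <- hits$target_offset[i]
        offset[is_hit & pair_target == spec$antitarget] <-
          hits$antitarget_offset[i]
      }
    }
    total <- sum(cfg)
    e <- stats::rnorm(total,
                      mean = rep(spec$energy_mean + offset, times = cfg),
                      sd = spec$energy_sd)
    runs <- data.frame(
      compound_id = rep(pair_compound, times = cfg),
      target_id = rep(pair_target, times = cfg),
      configuration_index = sequence(cfg),
      energy_kcal_mol = e,
      stringsAsFactors = FALSE)
    nC <- length(compounds)
    descriptors <- data.frame(
      compound_id = compounds,
      molecular_weight = round(stats::rlnorm(nC, log(350), 0.35), 1),
      logp = round(stats::rnorm(nC, 2.5, 1.5), 1),
      hbd_count = stats::rpois(nC, 2),
      hba_count = stats::rpois(nC, 5),
      stringsAsFactors = FALSE)
    is_hit_cmp <- compounds %in% (if (is.null(hits)) character() else hits$compound_id)
    annotations <- data.frame(
      compound_id = compounds,
      anti_inflammatory = is_hit_cmp |
        (stats::runif(nC) < 0.5 & !is_hit_cmp),
      excluded_known_anti_oa = !is_hit_cmp & stats::runif(nC) < 0.05,
      stringsAsFactors = FALSE)
    truth <- list(planted = hits, decoy_ids = decoys, spec = spec)
    list(runs = runs, descriptors = descriptors, annotations = annotations,
         truth = truth)
  })
}

#' Write a runs table as a pose-file tree
#'
#' One file per (compound, target) pair, named
#' `<compound>__<target>.pdbqt`, in the MODEL / REMARK VINA RESULT /
#' ENDMDL dialect read by [parsePoseFile()]. Energies are written in
#' full precision so the round trip through the parser is lossless.
#'
#' @param runs Runs table (see [readPoseDir()]).
#' @param dir Output directory (created if absent).
#' @param overwrite Allow clobbering existing pose files
#'   (default FALSE: collision is an error).
#' @return Invisibly, the paths written.
#' @export
generatePoseFiles <- function(runs, dir, overwrite = FALSE) {
  stopifnot(is.data.frame(runs),
            all(c("compound_id", "target_id", "configuration_index",
                  "energy_kcal_mol") %in% names(runs)))
  ids <- unique(c(runs$compound_id, runs$target_id))
  bad <- grepl("__|[/\\\\]", ids)
  if (any(bad))
    stop("id unsafe for pose filenames (contains '__' or a path separator): ",
         ids[bad][1L], call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pairs <- unique(runs[, c("compound_id", "target_id")])
  paths <- file.path(dir, paste0(pairs$compound_id, "__", pairs$target_id,
                                 ".pdbqt"))
  clash <- file.exists(paths)
  if (any(clash) && !overwrite)
    stop("pose file(s) already exist (use overwrite = TRUE): ",
         basename(paths[clash][1L]), call. = FALSE)
  for (i in seq_len(nrow(pairs))) {
    sel <- runs$compound_id == pairs$compound_id[i] &
      runs$target_id == pairs$target_id[i]
    e <- runs$energy_kcal_mol[sel][order(runs$configuration_index[sel])]
    lines <- unlist(lapply(seq_along(e), function(k) c(
      sprintf("MODEL %d", k),
      sprintf("REMARK VINA RESULT: %s 0.000 0.000",
              formatC(e[k], format = "g", digits = 17)),
      "ENDMDL")))
    writeLines(lines, paths[i])
  }
  invisible(paths)
}

#' Specification of a synthetic assay plate
#'
#' @param groups data.frame with columns `label`, `concentration`,
#'   `true_mean` (true well-level mean: OD for viability plates, or a
#'   value on whatever scale the assay reads), `n_replicates` (>= 2).
#' @param noise_sd Gaussian well noise sd (>= 0).
#' @param seed Mandatory integer seed.
#' @return A `plateSpec` list.
#' @export
plateSpec <- function(groups, noise_sd, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(is.data.frame(groups),
            all(c("label", "concentration", "true_mean", "n_replicates") %in%
                  names(groups)),
            all(groups$n_replicates >= 2L), noise_sd >= 0)
  structure(list(groups = groups, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "plateSpec")
}

#' Generate a seeded synthetic assay plate
#'
#' Each well's reading is drawn Normal(group true mean, noise sd). The
#' ground truth (the group table) is retained for recovery checks.
#'
#' @param spec A [plateSpec()].
#' @return List with `wells` (data.frame `group`, `concentration`,
#'   `replicate`, `od`) and `truth` (the group table).
#' @export
generateAssayPlates <- function(spec) {
  stopifnot(inherits(spec, "plateSpec"))
  .withSeed(spec$seed, {
    g <- spec$groups
    n <- as.integer(g$n_replicates)
    wells <- data.frame(
      group = rep(g$label, times = n),
      concentration = rep(g$concentration, times = n),
      replicate = sequence(n),
      od = stats::rnorm(sum(n), mean = rep(g$true_mean, times = n),
                        sd = spec$noise_sd),
      stringsAsFactors = FALSE)
    list(wells = wells, truth = g)
  })
}
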