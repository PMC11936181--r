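#' Parse per-pose binding energies from a docking pose file
#'
#' Reads the pose-annotated PDBQT dialect written by docking engines of
#' the Vina family: each MODEL block carries one
#' `REMARK VINA RESULT: <energy> <rmsd_lb> <rmsd_ub>` line whose first
#' numeric field is the pose's binding energy in kcal/mol. All other
#' content (atoms, geometry, torsions) is ignored; this module consumes
#' energies, not structures.
#'
#' @param path Path to a pose file.
#' @return Numeric vector of binding energies, in file order (one per
#'   result line).
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdbqt")
#' writeLines(c("MODEL 1", "REMARK VINA RESULT:    -7.2  0.000  0.000",
#'              "ENDMDL"), f)
#' parsePoseFile(f)
parsePoseFile <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hit <- grep("^REMARK VINA RESULT:", lines)
  if (length(hit) == 0L)
    stop("no 'REMARK VINA RESULT:' line found in ", path, call. = FALSE)
  fields <- sub("^REMARK VINA RESULT:[[:space:]]*", "", lines[hit])
  first <- vapply(strsplit(fields, "[[:space:]]+"), `[`, character(1), 1L)
  energies <- suppressWarnings(as.numeric(first))
  bad <- which(!is.finite(energies))
  if (length(bad))
    stop("malformed binding energy in ", path, " at line ", hit[bad[1L]],
         ": '", lines[hit[bad[1L]]], "'", call. = FALSE)
  energies
}

#' Read a directory tree of pose files into a runs table
#'
#' Expects one pose file per (compound, target) pair, named
#' `<compound>__<target>.pdbqt` as written by [generatePoseFiles()].
#'
#' @param dir Directory containing pose files.
#' @param pattern Filename filter (default `\\.pdbqt$`).
#' @return A runs table: data.frame with columns `compound_id`,
#'   `target_id`, `configuration_index`, `energy_kcal_mol`, one row per
#'   pose, poses in file order within each pair.
#' @seealso [parsePoseFile()], [buildEnergyMatrix()]
#' @export
readPoseDir <- function(dir, pattern = "\\.pdbqt$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L)
    stop("no pose files matching '", pattern, "' in ", dir, call. = FALSE)
  stems <- sub(pattern, "", basename(files))
  parts <- strsplit(stems, "__", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("pose filename not of the form <compound>__<target>: ",
         basename(files)[bad][1L], call. = FALSE)
  pieces <- lapply(seq_along(files), function(i) {
    e <- parsePoseFile(files[[i]])
    data.frame(compound_id = parts[[i]][1L], target_id = parts[[i]][2L],
               configuration_index = seq_along(e), energy_kcal_mol = e,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Parse a delimited compound x target x configuration energy table
#'
#' Accepts TSV or CSV (delimiter sniffed from the header line) with
#' columns `compound_id`, `target_id`, `energy_kcal_mol` and optionally
#' `configuration_index`. When the index column is absent, rows of each
#' (compound, target) group are numbered in file order.
#'
#' @param path Path to the delimited file.
#' @return A runs table (see [readPoseDir()] for the layout), rows
#'   ordered by compound, target, then configuration index.
#' @export
parseEnergyTable <- function(path) {
  if (!file.exists(path)) stop("energy table not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("compound_id", "target_id", "energy_kcal_mol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("energy table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  energy <- suppressWarnings(as.numeric(tab$energy_kcal_mol))
  bad <- which(!is.finite(energy))
  if (length(bad))
    stop("non-numeric energy in ", path, " at data row ", bad[1L],
         ": '", tab$energy_kcal_mol[bad[1L]], "'", call. = FALSE)
  if ("configuration_index" %in% names(tab)) {
    idx <- suppressWarnings(as.integer(tab$configuration_index))
    if (any(!is.finite(idx)))
      stop("non-integer configuration_index in ", path, call. = FALSE)
  } else {
    idx <- stats::ave(seq_len(nrow(tab)),
                      tab$compound_id, tab$target_id, FUN = seq_along)
  }
  key <- paste(tab$compound_id, tab$target_id, idx, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (compound, target, configuration) in ", path, ": ",
         gsub("\r", " / ", d, fixed = TRUE), call. = FALSE)
  }
  runs <- data.frame(compound_id = tab$compound_id, target_id = tab$target_id,
                     configuration_index = idx, energy_kcal_mol = energy,
                     stringsAsFactors = FALSE)
  runs <- runs[order(runs$compound_id, runs$target_id,
                     runs$configuration_index), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Reduce a run's configuration energies to one representative energy
#'
#' The docking engine reports one binding energy per pose; the screening
#' pipeline keeps a single number per (compound, target) pair. The
#' default takes the most favourable pose (minimum energy, i.e. the most
#' stable predicted complex); the `mean` mode averages all poses, a
#' reduction appropriate when a comprehensive binding picture is wanted
#' rather than the best single pose.
#'
#' @param energies Numeric vector of per-pose energies (kcal/mol),
#'   non-empty and finite.
#' @param mode `"minimum"` (default) or `"mean"`.
#' @return Single representative energy in kcal/mol.
#' @export
#' @examples
#' representativeEnergy(c(-7.2, -6.9, -6.5))           # -7.2
#' representativeEnergy(c(-7.2, -6.9, -6.5), "mean")   # -6.8667
representativeEnergy <- function(energies, mode = c("minimum", "mean")) {
  mode <- match.arg(mode)
  if (length(energies) == 0L)
    stop("empty configuration energy list", call. = FALSE)
  if (!is.numeric(energies) || !all(is.finite(energies)))
    stop("configuration energies must be finite numbers", call. = FALSE)
  if (mode == "minimum") min(energies) else mean(energies)
}

#' Assemble the dense compound x target energy matrix
#'
#' Reduces every (compound, target) run in a runs table to its
#' representative energy and arranges the results in the requested row
#' and column order. Each requested pair must be present exactly once:
#' a missing pair is a hard error (the score formulas need all target
#' energies), listing every absent pair. Runs for pairs outside the
#' requested index are dropped with a warning.
#'
#' @param runs Runs table (columns `compound_id`, `target_id`,
#'   `energy_kcal_mol`; see [readPoseDir()]).
#' @param compounds Ordered compound ids wanted as rows; default: the
#'   distinct compounds of `runs`, in first-appearance order.
#' @param targets Ordered target ids wanted as columns; default: the
#'   distinct targets of `runs`, in first-appearance order.
#' @param mode Reduction mode, passed to [representativeEnergy()].
#' @return An [EnergyMatrix-class].
#' @export
buildEnergyMatrix <- function(runs, compounds = unique(runs$compound_id),
                              targets = unique(runs$target_id),
                              mode = c("minimum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(runs),
            all(c("compound_id", "target_id", "energy_kcal_mol") %in% names(runs)))
  keep <- runs$compound_id %in% compounds & runs$target_id %in% targets
  if (any(!keep)) {
    extra <- unique(paste0(runs$compound_id[!keep], "/", runs$target_id[!keep]))
    warning("dropping runs for unrequested pair(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    runs <- runs[keep, , drop = FALSE]
  }
  ci <- factor(runs$compound_id, levels = compounds)
  ti <- factor(runs$target_id, levels = targets)
  fun <- if (mode == "minimum") min else mean
  m <- tapply(runs$energy_kcal_mol, list(ci, ti), fun)
  m <- matrix(as.numeric(m), nrow = length(compounds), ncol = length(targets),
              dimnames = list(compounds, targets))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    missing <- paste0(compounds[idx[, 1L]], "/", targets[idx[, 2L]])
    stop("missing (compound, target) pair(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  EnergyMatrix(m)
}

#' Write / read an energy matrix as TSV
#'
#' Compounds as rows, targets as columns, energies in 4-decimal
#' fixed-point, with a leading `compound_id` column.
#'
#' @param x An [EnergyMatrix-class].
#' @param path Output (or input) TSV path.
#' @return `writeEnergyMatrix` returns `path` invisibly;
#'   `readEnergyMatrix` returns an [EnergyMatrix-class].
#' @export
writeEnergyMatrix <- function(x, path) {
  stopifnot(is(x, "EnergyMatrix"))
  e <- energies(x)
  df <- data.frame(compound_id = rownames(e),
                   format(round(e, 4), nsmall = 4, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyMatrix
#' @export
readEnergyMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"compound_id" %in% names(df))
    stop("matrix file ", path, " lacks a compound_id column", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "compound_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$compound_id
  EnergyMatrix(m)
}

#' Classify protein-model quality from Ramachandran statistics
#'
#' A homology/crystal model is called a good-quality docking receptor
#' when strictly more than 90% of its residues fall in the most favoured
#' regions of the Ramachandran plot; exactly 90% does not qualify.
#'
#' @param pct_most_favored Percentage(s) in \[0, 100\] of residues in the
#'   most favoured regions.
#' @return Character vector, `"good"` or `"not_good"` per input.
#' @export
#' @examples
#' classifyModelQuality(c(90.3, 92.2, 90.8, 79.0, 80.9))
classifyModelQuality <- function(pct_most_favored) {
  if (!is.numeric(pct_most_favored) ||
      any(!is.finite(pct_most_favored)) ||
      any(pct_most_favored < 0 | pct_most_favored > 100))
    stop("pct_most_favored must lie in [0, 100]", call. = FALSE)
  ifelse(pct_most_favored > 90, "good", "not_good")
}
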