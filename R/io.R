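# File I/O: molecule readers, ladder CSV and metrics JSON writers, run
# manifests.

#' Read molecules from a SMILES or SDF file
#'
#' `.smi` files carry one SMILES per line with an optional
#' whitespace-separated identifier; anything else is treated as an SDF
#' of V2000 records.  Parse failures are reported (with their line or
#' record number), skipped, and collected in the `skipped` attribute;
#' input order is preserved.
#'
#' @param path input file.
#' @return named list of [Molecule] objects (names are the identifiers),
#'   with attribute `skipped` (data.frame of failures).
#' @export
readMolecules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, warn = FALSE)
  mols <- list()
  skipped <- data.frame(record = integer(0), id = character(0),
                        reason = character(0))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- txt[nzchar(trimws(txt))]
    if (length(lines) == 0) stop("empty input file: ", path)
    for (i in seq_along(lines)) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      id <- if (length(parts) > 1) parts[2] else sprintf("mol%d", i)
      res <- tryCatch(molFromSmiles(parts[1]), error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("line %d (%s) skipped: %s", i, id,
                        conditionMessage(res)))
        skipped <- rbind(skipped, data.frame(
          record = i, id = id, reason = conditionMessage(res)))
      } else mols[[id]] <- res
    }
  } else {
    recs <- strsplit(paste(txt, collapse = "\n"), "\\$\\$\\$\\$\n?")[[1]]
    recs <- recs[nzchar(trimws(recs))]
    if (length(recs) == 0) stop("empty input file: ", path)
    for (i in seq_along(recs)) {
      title <- trimws(strsplit(recs[i], "\n")[[1]][1])
      id <- if (nzchar(title)) title else sprintf("mol%d", i)
      res <- tryCatch(.parseMolblock(recs[i]), error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("record %d (%s) skipped: %s", i, id,
                        conditionMessage(res)))
        skipped <- rbind(skipped, data.frame(
          record = i, id = id, reason = conditionMessage(res)))
      } else mols[[id]] <- res
    }
  }
  if (length(mols) == 0) stop("no parseable molecules in ", path)
  attr(mols, "skipped") <- skipped
  mols
}

.LADDER_COLUMNS <- c("molecule_id", "input_smiles", "step_index",
                     "protonated_smiles", "deprotonated_smiles",
                     "center_atom_idx", "pka_mean", "pka_std")

#' Write protonation ladders to CSV
#'
#' One row per ladder step, stable column order, UTF-8, trailing
#' newline; pKa columns are written with 6 decimals.  An empty ladder
#' list produces a header-only file.
#'
#' @param ladders named list of [ProtonationLadder] objects (names are
#'   molecule ids) or a single ladder.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeLadderCsv <- function(ladders, path) {
  if (inherits(ladders, "ProtonationLadder")) ladders <- list(mol1 = ladders)
  rows <- lapply(seq_along(ladders), function(k) {
    lad <- ladders[[k]]
    id <- if (!is.null(names(ladders)) && nzchar(names(ladders)[k]))
      names(ladders)[k] else sprintf("mol%d", k)
    s <- lad@steps
    if (nrow(s) == 0) return(NULL)
    data.frame(molecule_id = id, input_smiles = lad@referenceSmiles,
               step_index = s$step_index,
               protonated_smiles = s$protonated_smiles,
               deprotonated_smiles = s$deprotonated_smiles,
               center_atom_idx = s$center_atom_idx,
               pka_mean = sprintf("%.6f", s$pka_mean),
               pka_std = sprintf("%.6f", s$pka_std),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- setNames(as.data.frame(matrix(nrow = 0, ncol =
                                          length(.LADDER_COLUMNS))),
                   .LADDER_COLUMNS)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metric report as JSON
#'
#' The field set is pinned by the schema file shipped at
#' `inst/schema/metrics_schema.json`.
#'
#' @param report a [MetricReport].
#' @param path destination JSON.
#' @return `path`, invisibly.
#' @export
writeMetricsJson <- function(report, path) {
  payload <- list(
    median_mae = report@medianMae,
    median_rmse = report@medianRmse,
    ci90_mae = report@ci90Mae,
    ci90_rmse = report@ci90Rmse,
    per_repetition = list(mae = report@maeValues,
                          rmse = report@rmseValues),
    n_repetitions = length(report@maeValues),
    n_samples = report@nSamples)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the command, configuration, seeds and package version of a
#' run so it can be re-executed exactly.
#'
#' @param path destination JSON.
#' @param command the command name.
#' @param config named list of effective settings.
#' @param seed the run seed.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, command, config = list(), seed = NA) {
  jsonlite::write_json(
    list(command = command, config = config, seed = seed,
         package = "pkaGraph",
         version = as.character(utils::packageVersion("pkaGraph")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
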