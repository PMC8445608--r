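## Snapshot output: cell tables (CSV), field snapshots (CSV + legacy VTK
## structured points) and a JSON manifest keyed by a config hash.

.atomicWrite <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

#' Hash of a simulation configuration
#'
#' md5 of the deparsed parameter list; changes iff any parameter changes.
#'
#' @param config A [SimConfig-class].
#' @return Character md5 string.
#' @export
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config@params[order(names(config@params))]), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a simulation snapshot
#'
#' Writes the cell table as CSV and each field as a flat CSV (node x, y, z,
#' value) plus a legacy-VTK structured-points file; all files are written
#' atomically and stamped with the simulation time.
#'
#' @param cells A [CellPopulation-class] or cell data.frame.
#' @param fields List of [MolecularField-class] objects (may be empty).
#' @param t Simulation time, hours (used in filenames).
#' @param dir Output directory (created if needed).
#' @return Character vector of files written.
#' @export
writeSnapshot <- function(cells, fields = list(), t, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create snapshot directory: ", dir)
  if (file.access(dir, 2L) != 0L) stop("snapshot path not writable: ", dir)
  stamp <- sprintf("t%08.1fh", t)
  files <- character()
  cellsPath <- file.path(dir, sprintf("cells_%s.csv", stamp))
  tab <- asCellTable(cells)
  .atomicWrite(function(f) write.csv(tab, f, row.names = FALSE), cellsPath)
  files <- c(files, cellsPath)
  for (f in fields) {
    base <- file.path(dir, sprintf("field_%s_%s", f@species, stamp))
    co <- f@mesh@coords
    df <- data.frame(x = co[, 1L], y = co[, 2L], z = co[, 3L],
                     value = f@values)
    .atomicWrite(function(p) write.csv(df, p, row.names = FALSE),
                 paste0(base, ".csv"))
    .atomicWrite(function(p) .writeVtk(f, p), paste0(base, ".vtk"))
    files <- c(files, paste0(base, ".csv"), paste0(base, ".vtk"))
  }
  files
}

## Legacy VTK structured points over the full enclosing grid; out-of-domain
## points carry -1 so visualization tools can threshold them away.
.writeVtk <- function(field, path) {
  mesh <- field@mesh
  arr <- rep(-1, prod(mesh@dims))
  arr[mesh@inMask] <- field@values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("dcisim field %s", field@species),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", mesh@dims[1L], mesh@dims[2L],
                       mesh@dims[3L]),
               sprintf("ORIGIN %g %g %g", mesh@origin[1L], mesh@origin[2L],
                       mesh@origin[3L]),
               sprintf("SPACING %g %g %g", mesh@spacing, mesh@spacing,
                       mesh@spacing),
               sprintf("POINT_DATA %d", length(arr)),
               sprintf("SCALARS %s double 1", field@species),
               "LOOKUP_TABLE default"), con)
  writeLines(format(arr, trim = TRUE, digits = 10), con)
  invisible(path)
}

#' Write the snapshot manifest
#'
#' JSON listing all snapshot files for a run together with the config hash.
#'
#' @param dir Snapshot directory.
#' @param files Files written during the run.
#' @param config The run's [SimConfig-class].
#' @return Manifest path, invisibly.
#' @export
writeSnapshotManifest <- function(dir, files, config) {
  path <- file.path(dir, "manifest.json")
  .atomicWrite(function(p)
    jsonlite::write_json(list(config_hash = configHash(config),
                              files = basename(files)),
                         p, auto_unbox = TRUE, pretty = TRUE),
    path)
  invisible(path)
}

#' Read a cell-table snapshot
#'
#' @param path CSV path written by [writeSnapshot()].
#' @return data.frame in the exchange schema.
#' @export
readCellSnapshot <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
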