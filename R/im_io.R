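#' Save an IM database to its binary container
#'
#' The container is a self-describing binary file: an `IMDB` magic tag and a
#' format version, followed by the serialized payload laid out as
#' coordinate-set definitions, the per-point records (q, E, g, H, x, r) and
#' the weighting metadata. The default filename is `im_database.h5`.
#' A save/load round trip is bit-identical on all numeric payloads.
#'
#' @param db an `im_database`
#' @param path output path (default `im_database.h5` in the working directory)
#' @return `path`, invisibly
#' @export
save_database <- function(db, path = "im_database.h5") {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("IMDB", con, nchars = 4, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")
  payload <- list(
    coords = list(bonds = db$ics$bonds, angles = db$ics$angles,
                  dihedrals = db$ics$dihedrals, n_atoms = db$ics$n_atoms),
    points = db$points,
    meta = list(mode = db$mode, exp_p = db$exp_p, exp_q = db$exp_q,
                version = db$version))
  raw <- serialize(payload, NULL, xdr = FALSE)
  writeBin(length(raw), con, size = 8, endian = "little")
  writeBin(raw, con)
  invisible(path)
}

#' Load an IM database from its binary container
#' @param path path to a file written by [save_database()]
#' @return an `im_database`
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("no such database file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(readChar(con, 4, useBytes = TRUE), error = function(e) "")
  if (!identical(magic, "IMDB")) {
    stop("not an IM database container: ", path, " (bad magic)")
  }
  ver <- readBin(con, integer(), size = 4, endian = "little")
  if (!length(ver) || ver != 1L) {
    stop("unsupported IM container version: ", paste(ver, collapse = ""),
         " (reader supports version 1)")
  }
  len <- readBin(con, integer(), size = 8, endian = "little")
  raw <- readBin(con, "raw", n = len)
  if (length(raw) < len) stop("truncated IM database container: ", path)
  payload <- tryCatch(unserialize(raw),
                      error = function(e) stop("corrupt IM database container: ",
                                               path, call. = FALSE))
  ics <- structure(list(bonds = payload$coords$bonds,
                        angles = payload$coords$angles,
                        dihedrals = payload$coords$dihedrals,
                        n_atoms = payload$coords$n_atoms),
                   class = "internal_coordinates")
  db <- im_database(ics, mode = payload$meta$mode,
                    exp_p = payload$meta$exp_p, exp_q = payload$meta$exp_q)
  db$version <- payload$meta$version
  db$points <- payload$points
  db
}
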