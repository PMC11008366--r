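# Plain-text geometry I/O: standard (multi-frame) XYZ plus the sidecar site
# annotation table that makes a bare XYZ usable as an annotated monomer.

#' Write / read (multi-frame) XYZ files
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` rows;
#' multiple frames are concatenated. Coordinates round-trip to 1e-6
#' Angstrom.
#'
#' @param frames a single geometry or a list of geometries; anything with
#'   `symbols` and `coords` ([monomer_geometry], `pair_pose`, or a bare
#'   list). Optional `comment` field per frame.
#' @param path file path.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` returns a list
#'   of frames, each `list(symbols, coords, comment)`.
#' @export
write_xyz <- function(frames, path) {
  if (!is.null(frames$symbols)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    comment <- if (is.null(f$comment)) "" else f$comment
    writeLines(c(as.character(length(f$symbols)), comment), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", f$symbols,
                       f$coords[, 1], f$coords[, 2], f$coords[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (i + 1L + nat > length(lines)) {
      stop("XYZ truncated: frame starting at line ", i, " wants ", nat,
           " atoms")
    }
    comment <- lines[i + 1L]
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + nat)]), "[[:space:]]+")
    symbols <- vapply(rows, `[`, character(1), 1)
    coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(symbols = symbols, coords = coords,
                                          comment = comment)
    i <- i + 2L + nat
  }
  frames
}

#' Export poses as a multi-frame XYZ
#'
#' One frame per pose; the comment line carries `flip`, `shift` and the
#' contact list so external optimizer input builders can consume the file.
#'
#' @param poses list of `pair_pose` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_poses_xyz <- function(poses, path) {
  frames <- lapply(poses, function(p) {
    a <- p$alignment
    list(symbols = p$symbols, coords = p$coords,
         comment = sprintf("flip=%d shift=%d contacts=%s collision=%d",
                           as.integer(a$flip), a$shift,
                           paste(sprintf("%d-%d", a$contacts[, 1],
                                         a$contacts[, 2]), collapse = ","),
                           as.integer(isTRUE(p$collision))))
  })
  write_xyz(frames, path)
}

#' Write / read the sidecar site-annotation table of a monomer
#'
#' CSV with one row per hydrogen-bonding site: `site`, `role`, `flavor`,
#' `heavy`, `hyd`, `dir_x`, `dir_y`, `dir_z`. Together with a bare XYZ file
#' this reconstructs an annotated [monomer_geometry]; amino nitrogens are
#' the heavy atoms of donor sites.
#'
#' @param geom a [monomer_geometry].
#' @param path CSV path.
#' @return `write_site_annotations` returns `path` invisibly.
#' @export
write_site_annotations <- function(geom, path) {
  utils::write.csv(geom$sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_site_annotations
#' @param xyz_path path of the monomer XYZ file (first frame used).
#' @param annot_path path of the sidecar CSV.
#' @export
read_monomer <- function(xyz_path, annot_path) {
  fr <- read_xyz(xyz_path)[[1]]
  sites <- utils::read.csv(annot_path, stringsAsFactors = FALSE)
  amine_n <- sites$heavy[sites$role == "D"]
  monomer_geometry(fr$symbols, fr$coords, sites, amine_n)
}
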