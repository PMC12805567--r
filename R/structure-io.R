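#' Coarse-grained protein structures as tibbles
#'
#' A `cg_protein` is a tibble with one row per CG bead and columns
#' `bead_id`, `resid`, `resname`, `atom` (bead name), `type` (bead type from
#' the mapping file), `charge` (elementary charges), `x`, `y`, `z`
#' (nm, internal unit) and `surface` (logical; environment-facing beads).
#' The per-bead exclusion radius used by interior-probe tests is carried as
#' the `occupancy_radius` attribute, and the source file format as `format`.
#'
#' @param beads a data frame with at least `resid`, `resname`, `atom`,
#'   `x`, `y`, `z`; `type`/`charge` are filled from `mapping` if missing.
#' @param mapping bead mapping tibble, see [read_bead_mapping()].
#' @param occupancy_radius exclusion radius in nm (default 0.264 nm, half a
#'   0.47 nm sigma plus margin).
#' @param format `"gro"` or `"pdb"`, used to echo outputs in the input format.
#' @return a `cg_protein` tibble.
#' @export
cg_protein <- function(beads, mapping = read_bead_mapping(),
                       occupancy_radius = 0.264, format = "gro") {
  beads <- as_tibble(beads)
  if (nrow(beads) < 1L) abort("a CG protein needs at least one bead")
  for (col in c("resid", "resname", "atom", "x", "y", "z"))
    if (!col %in% names(beads)) abort(sprintf("beads are missing column `%s`", col))
  if (!all(is.finite(beads$x)) || !all(is.finite(beads$y)) || !all(is.finite(beads$z)))
    abort("bead positions must be finite")
  if (!"type" %in% names(beads) || !"charge" %in% names(beads)) {
    key <- paste(beads$resname, beads$atom)
    mkey <- paste(mapping$resname, mapping$atom)
    idx <- match(key, mkey)
    if (anyNA(idx)) {
      missing <- unique(paste0(beads$resname[is.na(idx)], "/", beads$atom[is.na(idx)]))
      abort(sprintf("bead name(s) not in mapping file: %s", paste(missing, collapse = ", ")))
    }
    beads$type <- mapping$type[idx]
    beads$charge <- mapping$charge[idx]
  }
  if (any(abs(beads$charge) > 2)) abort("bead charges must lie in [-2, 2]")
  beads$bead_id <- seq_len(nrow(beads))
  if (!"surface" %in% names(beads)) beads$surface <- TRUE
  beads <- beads[, c("bead_id", "resid", "resname", "atom", "type", "charge",
                     "x", "y", "z", "surface")]
  structure(beads,
            occupancy_radius = occupancy_radius, format = format,
            class = c("cg_protein", class(tibble())))
}

coords <- function(protein) as.matrix(protein[, c("x", "y", "z")])

set_coords <- function(protein, xyz) {
  protein$x <- xyz[, 1]; protein$y <- xyz[, 2]; protein$z <- xyz[, 3]
  protein
}

#' Read a coarse-grained structure file
#'
#' Parses PDB or GRO coordinate files holding Martini-style CG beads.
#' Coordinates are converted to nm internally (PDB files are in Angstrom,
#' GRO files already in nm); the surface mask is initialized all-true.
#' Dummy membrane-marker atoms written by [write_oriented_structure()]
#' (resname `DUM`) are dropped on read.
#'
#' @param path file path.
#' @param format `"pdb"`, `"gro"`, or `"auto"` (from the file extension).
#' @param mapping bead mapping, see [read_bead_mapping()].
#' @param keep_dummies keep membrane-marker dummy beads (default FALSE).
#' @inheritParams cg_protein
#' @return a [cg_protein()] tibble.
#' @export
read_cg_structure <- function(path, format = c("auto", "pdb", "gro"),
                              mapping = read_bead_mapping(),
                              occupancy_radius = 0.264, keep_dummies = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     abort(sprintf("cannot infer format from extension '.%s'; pass format=", ext)))
  }
  beads <- if (format == "gro") parse_gro(path) else parse_pdb(path)
  if (!keep_dummies) beads <- beads[beads$resname != "DUM", , drop = FALSE]
  if (nrow(beads) == 0L) abort(sprintf("no beads parsed from %s", path))
  cg_protein(beads, mapping = mapping, occupancy_radius = occupancy_radius,
             format = format)
}

parse_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) abort(sprintf("format error in %s: truncated GRO file", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(sprintf("format error in %s line 2: expected atom count", path))
  if (length(lines) < 2L + n) abort(sprintf("format error in %s: %d atom lines expected", path, n))
  al <- lines[3:(2 + n)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  atom <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad))
    abort(sprintf("format error in %s line %d: unparsable GRO atom record", path, bad[1] + 2L))
  tibble(resid = resid, resname = resname, atom = atom, x = x, y = y, z = z)
}

parse_pdb <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(keep)) abort(sprintf("format error in %s: no ATOM/HETATM records", path))
  al <- lines[keep]
  atom <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))
  if (length(bad))
    abort(sprintf("format error in %s line %d: unparsable PDB atom record", path, keep[bad[1]]))
  # PDB coordinates are Angstrom; internal unit is nm
  tibble(resid = resid, resname = resname, atom = atom,
         x = x / 10, y = y / 10, z = z / 10)
}

write_gro <- function(protein, path, title = "memorient structure", box = NULL) {
  xyz <- coords(protein)
  box <- box %||% (apply(xyz, 2, function(v) diff(range(v))) + 4)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(protein)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     protein$resid %% 100000L, protein$resname, protein$atom,
                     protein$bead_id %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

write_pdb <- function(protein, path, title = "memorient structure") {
  xyz <- coords(protein) * 10  # nm -> Angstrom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", title), con)
  nm <- ifelse(nchar(protein$atom) < 4, paste0(" ", protein$atom), protein$atom)
  writeLines(sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                     protein$bead_id %% 100000L, substr(nm, 1, 4),
                     substr(protein$resname, 1, 4), protein$resid %% 10000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines("END", con)
  invisible(path)
}

#' Write a (possibly transformed) structure in its input format
#'
#' Applies a rigid-body [placement()] to the protein and writes the result in
#' the same format it was read from (Fig-style convention: output format
#' equals input format). Membrane reference planes are emitted as dummy
#' beads (resname `DUM`, atoms `MB1`/`MB2`) marking the head-group planes,
#' so the placement is visible in any structure viewer.
#'
#' @param protein a [cg_protein()].
#' @param placement a [placement()]; identity if NULL.
#' @param path output path.
#' @param membrane a [membrane_model()] used to place marker beads; omit with
#'   NULL.
#' @param format override the output format; default: same as input.
#' @return the path, invisibly.
#' @export
write_oriented_structure <- function(protein, placement = NULL, path,
                                     membrane = NULL, format = NULL) {
  format <- format %||% attr(protein, "format") %||% "gro"
  out <- protein
  if (!is.null(placement)) {
    xyz <- coords(protein) %*% t(placement_rotation(placement))
    xyz[, 3] <- xyz[, 3] + placement$z
    out <- set_coords(out, xyz)
  }
  if (!is.null(membrane)) {
    zs <- membrane_plane_zs(membrane)
    mark <- do.call(rbind, lapply(seq_along(zs), function(i) {
      g <- as.matrix(expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4)))
      tibble(resid = 9000L + i, resname = "DUM",
             atom = if (i %% 2 == 1) "MB1" else "MB2",
             type = "W", charge = 0,
             x = g[, 1], y = g[, 2], z = zs[i], surface = FALSE,
             bead_id = 0L)
    }))
    mark$bead_id <- max(out$bead_id) + seq_len(nrow(mark))
    out <- dplyr::bind_rows(out, mark)
  }
  if (format == "gro") write_gro(out, path) else write_pdb(out, path)
  invisible(path)
}
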