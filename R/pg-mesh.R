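#' Coarse-grained peptidoglycan meshes
#'
#' A `pg_mesh` holds the murein (NAG-NAM) units of a periodic cell wall:
#' one row per unit with its layer, lattice line, index along the line,
#' strand membership, position (nm) and cross-linking direction, plus a
#' tibble of peptide cross-links and the periodic cell lengths. Each unit is
#' exported as four beads (two sugar beads and a two-bead peptide stem).
#'
#' Glycan strands run along x; lines are spaced along y; layers stack along
#' z. Under periodic boundary conditions a freshly generated strand spans
#' the whole cell (an effectively infinite strand until broken).
#'
#' @param cell `c(lx, ly)` or `c(lx, ly, lz)` cell lengths, nm.
#' @param strand_spacing spacing between neighboring strands, nm.
#' @param unit_length length of one NAG-NAM unit along the strand, nm.
#' @param layers number of PG layers.
#' @param layer_spacing vertical spacing between layers, nm.
#' @param seed RNG seed (used for the left/right unit directions).
#' @return a `pg_mesh`.
#' @export
generate_pg_mesh <- function(cell = c(20, 20), strand_spacing = 2,
                             unit_length = 1, layers = 1, layer_spacing = 2,
                             seed = 1) {
  n_units <- round(cell[1] / unit_length)
  n_lines <- round(cell[2] / strand_spacing)
  if (n_units < 2 || n_lines < 2)
    abort("cell too small: need at least 2 units per strand and 2 strands")
  lz <- if (length(cell) >= 3) cell[3] else max(layers * layer_spacing, layer_spacing)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  units <- tidyr::expand_grid(layer = seq_len(layers) - 1L,
                              line = seq_len(n_lines) - 1L,
                              idx = seq_len(n_units) - 1L)
  units$unit_id <- seq_len(nrow(units))
  units$strand_id <- units$layer * n_lines + units$line + 1L
  units$x <- units$idx * unit_length
  units$y <- units$line * strand_spacing
  units$z <- units$layer * layer_spacing
  units$dir <- sample(c(-1L, 1L), nrow(units), replace = TRUE)
  structure(list(
    units = as_tibble(units[, c("unit_id", "layer", "line", "idx", "strand_id",
                                "x", "y", "z", "dir")]),
    crosslinks = tibble(unit1 = integer(), unit2 = integer(),
                        kind = character()),
    flagged = character(),
    cell = c(n_units * unit_length, n_lines * strand_spacing, lz),
    n_units_per_line = n_units, n_lines = n_lines, layers = layers,
    unit_length = unit_length, strand_spacing = strand_spacing,
    layer_spacing = layer_spacing, seed = seed
  ), class = "pg_mesh")
}

#' @export
print.pg_mesh <- function(x, ...) {
  cat(sprintf(paste0("<pg_mesh: %d units, %d strand(s), %d cross-link(s), ",
                     "%d layer(s), cell %.1f x %.1f x %.1f nm>\n"),
              nrow(x$units), length(unique(x$units$strand_id)),
              nrow(x$crosslinks), x$layers, x$cell[1], x$cell[2], x$cell[3]))
  invisible(x)
}

#' Strand length distribution of a mesh
#' @param mesh a `pg_mesh`.
#' @return tibble: `strand_id`, `length` (units).
#' @export
strand_lengths <- function(mesh) {
  dplyr::count(mesh$units, .data$strand_id, name = "length")
}

# bead sites of each unit (sugar pair along x, peptide stem along dir in y)
unit_bead_sites <- function(mesh) {
  u <- mesh$units
  ul <- mesh$unit_length
  purrr::map_dfr(c("GN", "GM", "PS1", "PS2"), function(nm) {
    off <- switch(nm,
      GN = c(-ul / 4, 0, 0), GM = c(ul / 4, 0, 0),
      PS1 = c(ul / 4, 0.2, -0.15), PS2 = c(ul / 4, 0.45, -0.3))
    tibble(unit_id = u$unit_id, atom = nm,
           x = u$x + off[1], y = u$y + off[2] * u$dir,
           z = u$z + off[3])
  }) |> dplyr::arrange(.data$unit_id)
}

#' Remove murein units colliding with a protein
#'
#' Units with any bead site within `clearance` of any protein bead are
#' removed; strands are split at the removals (units keep their lattice
#' indices, so later stages see the gaps).
#'
#' @param mesh a `pg_mesh`.
#' @param protein a [cg_protein()] positioned in the mesh frame.
#' @param clearance nm.
#' @return the carved mesh.
#' @export
carve_protein <- function(mesh, protein, clearance = 0.5) {
  sites <- unit_bead_sites(mesh)
  d <- cpp_min_dist(as.matrix(sites[, c("x", "y", "z")]), coords(protein))
  hit <- unique(sites$unit_id[d < clearance])
  if (!length(hit)) return(mesh)
  mesh$units <- mesh$units[!mesh$units$unit_id %in% hit, , drop = FALSE]
  if (!nrow(mesh$units)) warn("protein removed every murein unit; empty mesh")
  mesh$crosslinks <- mesh$crosslinks[
    !(mesh$crosslinks$unit1 %in% hit | mesh$crosslinks$unit2 %in% hit), ,
    drop = FALSE]
  relabel_strands(mesh)
}

# recompute strand ids from adjacency: consecutive lattice indices on the
# same line belong to one strand unless the bond between them is broken;
# preserves existing breaks (differing strand ids)
relabel_strands <- function(mesh) {
  u <- mesh$units
  L <- mesh$n_units_per_line
  new_id <- integer(nrow(u))
  nxt <- 0L
  for (key in split(seq_len(nrow(u)), list(u$layer, u$line), drop = TRUE)) {
    idx <- u$idx[key]
    sid <- u$strand_id[key]
    ord <- order(idx)
    key <- key[ord]; idx <- idx[ord]; sid <- sid[ord]
    n <- length(key)
    cut_after <- vapply(seq_len(n), function(i) {
      j <- i %% n + 1
      gap <- (idx[j] - idx[i]) %% L != 1
      gap || sid[i] != sid[j] || n == 1
    }, logical(1))
    if (!any(cut_after)) {       # intact cyclic line: one strand
      nxt <- nxt + 1L
      new_id[key] <- nxt
      next
    }
    start <- (which(cut_after)[1] %% n) + 1
    ordc <- ((start - 1 + seq_len(n) - 1) %% n) + 1
    nxt <- nxt + 1L
    for (i in ordc) {
      new_id[key[i]] <- nxt
      if (cut_after[i]) nxt <- nxt + 1L
    }
    if (cut_after[ordc[n]]) nxt <- nxt - 1L   # no unit started the last id
  }
  mesh$units$strand_id <- new_id
  mesh
}

#' Write mesh coordinates (.gro) and GROMACS topology (.itp)
#'
#' Each unit is exported as four beads: sugar beads `GN` (NAG) and `GM`
#' (NAM) plus the peptide stem `PS1`, `PS2` (residue `PGU`). The topology
#' lists the glycan backbone and stem bonds, backbone angles, and for every
#' peptide cross-link the two interpeptide-link angle potentials with
#' equilibrium angles 114 and 95 degrees and force constants 75 kJ/mol.
#'
#' @param mesh a `pg_mesh`.
#' @param out_prefix output path prefix (writes `<prefix>.gro` and
#'   `<prefix>.itp`).
#' @return named character vector of the written paths, invisibly.
#' @export
write_pg_topology <- function(mesh, out_prefix) {
  sites <- unit_bead_sites(mesh)
  sites$atom_id <- seq_len(nrow(sites))
  aid <- function(unit, atom) sites$atom_id[match(paste(unit, atom),
                                                  paste(sites$unit_id, sites$atom))]
  gro <- paste0(out_prefix, ".gro")
  itp <- paste0(out_prefix, ".itp")
  u <- mesh$units

  con <- file(gro, "w")
  writeLines("peptidoglycan mesh", con)
  writeLines(sprintf("%5d", nrow(sites)), con)
  resmap <- match(sites$unit_id, u$unit_id)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resmap %% 100000L, "PGU", sites$atom,
                     sites$atom_id %% 100000L, sites$x, sites$y, sites$z), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", mesh$cell[1], mesh$cell[2],
                     mesh$cell[3]), con)
  close(con)

  atom_types <- c(GN = "Nda", GM = "Nda", PS1 = "P5", PS2 = "Qa")
  atom_charge <- c(GN = 0, GM = 0, PS1 = 0, PS2 = -1)
  lines <- c("; peptidoglycan layer topology (memorient)",
             "[ moleculetype ]", "; name  nrexcl", "PG   1", "",
             "[ atoms ]", ";  nr  type  resnr  resid  atom  cgnr  charge")
  lines <- c(lines, sprintf("%6d  %-4s  %5d  PGU  %-4s  %6d  %6.2f",
                            sites$atom_id, atom_types[sites$atom], resmap,
                            sites$atom, sites$atom_id,
                            atom_charge[sites$atom]))
  bonds <- list()
  add_bond <- function(a, b, r0, k) bonds[[length(bonds) + 1L]] <<-
    sprintf("%6d %6d   1  %7.3f  %8.1f", a, b, r0, k)
  ul <- mesh$unit_length
  for (i in seq_len(nrow(u))) {
    id <- u$unit_id[i]
    add_bond(aid(id, "GN"), aid(id, "GM"), ul / 2, 7000)
    add_bond(aid(id, "GM"), aid(id, "PS1"), 0.35, 5000)
    add_bond(aid(id, "PS1"), aid(id, "PS2"), 0.35, 5000)
  }
  # glycan backbone bonds within strands (PBC neighbor on the same strand)
  L <- mesh$n_units_per_line
  nb <- strand_neighbors(mesh)
  for (i in seq_len(nrow(nb)))
    add_bond(aid(nb$unit1[i], "GM"), aid(nb$unit2[i], "GN"), ul / 2, 7000)
  lines <- c(lines, "", "[ bonds ]", ";  ai   aj  funct  r0(nm)  k",
             unlist(bonds))

  angles <- c()
  for (i in seq_len(nrow(nb)))
    angles <- c(angles, sprintf("%6d %6d %6d   2  %7.1f  %8.1f  ; glycan backbone",
                                aid(nb$unit1[i], "GN"), aid(nb$unit1[i], "GM"),
                                aid(nb$unit2[i], "GN"), 170, 25))
  cl <- mesh$crosslinks
  for (i in seq_len(nrow(cl))) {
    a <- cl$unit1[i]; b <- cl$unit2[i]
    angles <- c(angles,
      sprintf("%6d %6d %6d   2  %7.1f  %8.1f  ; interpeptide link",
              aid(a, "PS1"), aid(a, "PS2"), aid(b, "PS2"), 114, 75),
      sprintf("%6d %6d %6d   2  %7.1f  %8.1f  ; interpeptide link",
              aid(a, "PS2"), aid(b, "PS2"), aid(b, "PS1"), 95, 75))
  }
  if (nrow(cl))
    lines <- c(lines, "", "[ bonds ]", "; peptide cross-links",
               sprintf("%6d %6d   1  %7.3f  %8.1f",
                       aid(cl$unit1, "PS2"), aid(cl$unit2, "PS2"), 0.4, 5000))
  lines <- c(lines, "", "[ angles ]", ";  ai   aj   ak  funct  theta0  k",
             angles)
  writeLines(lines, itp)
  invisible(c(gro = gro, itp = itp))
}

# pairs of units adjacent along their strand (same strand id, consecutive
# lattice index under PBC)
strand_neighbors <- function(mesh) {
  u <- mesh$units
  L <- mesh$n_units_per_line
  key <- paste(u$layer, u$line, u$idx)
  nxt <- match(paste(u$layer, u$line, (u$idx + 1L) %% L), key)
  ok <- !is.na(nxt) & u$strand_id == u$strand_id[nxt] &
    !(L == 1)
  # a 2-unit cyclic strand would duplicate the bond; keep each once
  pair_id <- paste(pmin(u$unit_id, u$unit_id[nxt])[ok],
                   pmax(u$unit_id, u$unit_id[nxt])[ok])
  keep <- !duplicated(pair_id)
  tibble(unit1 = u$unit_id[ok][keep], unit2 = u$unit_id[nxt][ok][keep])
}

#' Read the angle entries of a generated PG topology file
#'
#' Utility for inspecting `.itp` output: returns all `[ angles ]` entries
#' with their equilibrium angles, force constants and trailing comments.
#'
#' @param path an `.itp` file written by [write_pg_topology()].
#' @return tibble: `ai`, `aj`, `ak`, `funct`, `theta0`, `fc`, `comment`.
#' @export
read_pg_topology_angles <- function(path) {
  lines <- readLines(path)
  sec <- cumsum(grepl("^\\[", lines))
  starts <- which(grepl("^\\[\\s*angles\\s*\\]", lines))
  out <- list()
  for (s in starts) {
    block <- lines[(s + 1):length(lines)]
    stop_at <- which(grepl("^\\[", block))[1]
    if (!is.na(stop_at)) block <- block[seq_len(stop_at - 1)]
    block <- block[!grepl("^\\s*;", block) & nzchar(trimws(block))]
    for (b in block) {
      parts <- strsplit(b, ";", fixed = TRUE)[[1]]
      v <- scan(text = parts[1], quiet = TRUE)
      out[[length(out) + 1L]] <- tibble(
        ai = v[1], aj = v[2], ak = v[3], funct = v[4], theta0 = v[5],
        fc = v[6], comment = trimws(parts[2] %||% ""))
    }
  }
  if (!length(out)) return(tibble(ai = numeric(), aj = numeric(),
                                  ak = numeric(), funct = numeric(),
                                  theta0 = numeric(), fc = numeric(),
                                  comment = character()))
  dplyr::bind_rows(out)
}
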