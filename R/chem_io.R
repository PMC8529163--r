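# I/O and unit handling: species-record tables, Gaussian-style cube grids,
# delimited descriptor tables. Internal canonical energy unit is eV; unit
# conversion happens only at the I/O boundary.

#' Hartree to electron-volt conversion factor (CODATA 2018)
#' @export
HARTREE_TO_EV <- 27.211386245988

#' Convert energies between hartree and eV
#'
#' @param x numeric vector of energies.
#' @param from,to one of \code{"ev"} or \code{"hartree"}.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(-0.22138, "hartree", "ev")  # -6.0241 eV
#' @export
convert_energy <- function(x, from = c("ev", "hartree"), to = c("ev", "hartree")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "hartree") x * HARTREE_TO_EV else x / HARTREE_TO_EV
}

#' Construct a validated species record
#'
#' One molecule/charge-state: frontier orbital energies (eV), optional
#' ground-state total energy (eV), charge and spin multiplicity.
#'
#' @param ligand_id character label.
#' @param charge integer total charge.
#' @param multiplicity positive integer spin multiplicity.
#' @param eps_homo,eps_lumo HOMO/LUMO orbital energies in eV (may be NA for
#'   charged species when only total energies are used).
#' @param e_total optional ground-state total energy in eV.
#' @param source free-text provenance (e.g. model chemistry, solvation).
#' @return a list of class \code{species_record}.
#' @export
species_record <- function(ligand_id, charge = 0L, multiplicity = 1L,
                           eps_homo = NA_real_, eps_lumo = NA_real_,
                           e_total = NA_real_, source = "") {
  stopifnot(is.character(ligand_id), length(ligand_id) == 1L, nzchar(ligand_id))
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L)
    stop("multiplicity must be a positive integer, got ", multiplicity)
  for (nm in c("eps_homo", "eps_lumo", "e_total")) {
    v <- get(nm)
    if (!is.na(v) && !is.finite(v)) stop(nm, " must be finite, got ", v)
  }
  if (!is.na(eps_homo) && !is.na(eps_lumo) && eps_homo >= eps_lumo)
    stop("invalid frontier gap for '", ligand_id,
         "': eps_homo (", eps_homo, ") must be < eps_lumo (", eps_lumo, ")")
  structure(list(ligand_id = ligand_id, charge = charge,
                 multiplicity = multiplicity,
                 eps_homo = as.numeric(eps_homo),
                 eps_lumo = as.numeric(eps_lumo),
                 e_total = as.numeric(e_total), source = as.character(source)),
            class = "species_record")
}

#' Bundle neutral, cation and anion records of one ligand
#'
#' @param neutral,cation,anion \code{species_record}s with charges 0, +1, -1
#'   and a shared \code{ligand_id}.
#' @return a list of class \code{species_triplet}.
#' @export
species_triplet <- function(neutral, cation, anion) {
  for (r in list(neutral, cation, anion))
    if (!inherits(r, "species_record")) stop("all members must be species_record")
  ids <- c(neutral$ligand_id, cation$ligand_id, anion$ligand_id)
  if (length(unique(ids)) != 1L)
    stop("triplet members disagree on ligand_id: ", paste(ids, collapse = ", "))
  if (neutral$charge != 0L) stop("neutral member must have charge 0, got ", neutral$charge)
  if (cation$charge != 1L) stop("cation member must have charge +1, got ", cation$charge)
  if (anion$charge != -1L) stop("anion member must have charge -1, got ", anion$charge)
  structure(list(neutral = neutral, cation = cation, anion = anion),
            class = "species_triplet")
}

#' Read a species table (CSV or TSV with header)
#'
#' Required columns: \code{ligand_id}, \code{charge}, \code{eps_homo},
#' \code{eps_lumo}; optional: \code{multiplicity}, \code{e_total},
#' \code{source}. Energies are converted to eV when \code{units = "hartree"}.
#'
#' @param path file path; delimiter inferred from content (comma or tab).
#' @param units unit of the energy columns in the file.
#' @return list of \code{species_record}.
#' @export
read_species_table <- function(path, units = c("ev", "hartree")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("species table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          strip.white = TRUE, stringsAsFactors = FALSE)
  required <- c("ligand_id", "charge", "eps_homo", "eps_lumo")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("species table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  parse_num <- function(col, row) {
    raw <- df[[col]][row]
    if (is.na(raw) || raw == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(raw))
    if (is.na(v))
      stop("parse error in column '", col, "', row ", row,
           ": non-numeric value '", raw, "'")
    v
  }
  lapply(seq_len(nrow(df)), function(i) {
    eh <- convert_energy(parse_num("eps_homo", i), units, "ev")
    el <- convert_energy(parse_num("eps_lumo", i), units, "ev")
    et <- if ("e_total" %in% names(df))
      convert_energy(parse_num("e_total", i), units, "ev") else NA_real_
    species_record(
      ligand_id = df$ligand_id[i],
      charge = as.integer(parse_num("charge", i)),
      multiplicity = if ("multiplicity" %in% names(df))
        as.integer(parse_num("multiplicity", i)) else 1L,
      eps_homo = eh, eps_lumo = el, e_total = et,
      source = if ("source" %in% names(df)) df$source[i] else "")
  })
}

#' Group a flat species list into triplets by ligand
#'
#' @param records list of \code{species_record} holding charges 0, +1, -1 per
#'   ligand.
#' @return named list of \code{species_triplet}.
#' @export
collate_triplets <- function(records) {
  ids <- vapply(records, function(r) r$ligand_id, character(1))
  out <- lapply(unique(ids), function(id) {
    members <- records[ids == id]
    chg <- vapply(members, function(r) r$charge, integer(1))
    if (!setequal(chg, c(0L, 1L, -1L)) || length(members) != 3L)
      stop("ligand '", id, "' needs exactly charges {0, +1, -1}, got {",
           paste(sort(chg), collapse = ", "), "}")
    species_triplet(members[[which(chg == 0L)]], members[[which(chg == 1L)]],
                    members[[which(chg == -1L)]])
  })
  names(out) <- unique(ids)
  out
}

# ---- volumetric density grids (cube format) --------------------------------

#' Construct a volumetric density grid
#'
#' Regular 3-D lattice of electron density (electrons/bohr^3) in the layout
#' used by Gaussian-style cube files: origin plus three voxel step vectors.
#'
#' @param origin numeric length-3, grid origin in bohr.
#' @param axes 3x3 matrix; row i is the step vector of axis i (bohr).
#' @param values numeric 3-D array; dimension i runs along axis i.
#' @param atoms optional data.frame with columns \code{z} (atomic number) and
#'   \code{x}, \code{y}, \code{z_pos} (bohr).
#' @return a list of class \code{density_grid}.
#' @export
density_grid <- function(origin, axes, values, atoms = NULL) {
  origin <- as.numeric(origin)
  axes <- as.matrix(axes)
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (any(dim(values) < 2L)) stop("all grid dimensions must be >= 2")
  if (!all(is.finite(values))) stop("grid values must all be finite")
  if (!all(is.finite(axes)) || !all(is.finite(origin)))
    stop("grid geometry must be finite")
  if (abs(det(axes)) <= 0) stop("voxel volume must be positive (singular step matrix)")
  structure(list(origin = origin, axes = axes, shape = dim(values),
                 values = values, atoms = atoms),
            class = "density_grid")
}

#' Voxel volume of a grid (bohr^3)
#' @param g a \code{density_grid}.
#' @export
voxel_volume <- function(g) abs(det(g$axes))

#' Read a cube-format volumetric grid
#'
#' Standard layout: two comment lines; natoms + origin; three voxel lines
#' (count + step vector, lengths in bohr for positive counts); natoms atom
#' lines; then values with the last (z) axis varying fastest.
#'
#' @param path cube file path.
#' @return a \code{density_grid}.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("cube file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 6L) stop("cube file truncated: fewer than 6 header lines")
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4]
  if (natoms < 0)
    stop("cube files with orbital blocks (negative natoms) are not supported")
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    v <- num(lines[3 + i])
    shape[i] <- as.integer(v[1])
    axes[i, ] <- v[2:4]
  }
  if (any(shape < 2L)) stop("cube grid dimensions must all be >= 2")
  atoms <- NULL
  if (natoms > 0) {
    am <- t(vapply(lines[7:(6 + natoms)], num, numeric(5)))
    atoms <- data.frame(z = as.integer(am[, 1]), x = am[, 3], y = am[, 4],
                        z_pos = am[, 5], row.names = NULL)
  }
  vals <- as.numeric(unlist(strsplit(trimws(lines[(7 + natoms):length(lines)]),
                                     "\\s+"), use.names = FALSE))
  vals <- vals[!is.na(vals) & nzchar(as.character(vals))]
  n_expect <- prod(shape)
  if (length(vals) != n_expect)
    stop("cube value block malformed: expected ", n_expect, " values, found ",
         length(vals))
  # file order: x slowest, z fastest -> fill an array with dim rev(shape)
  # then transpose so dimension i runs along axis i
  arr <- aperm(array(vals, dim = rev(shape)), c(3, 2, 1))
  density_grid(origin = origin, axes = axes, values = arr, atoms = atoms)
}

#' Write a grid to cube format
#'
#' Positive natoms convention (lengths in bohr), z-fastest value ordering,
#' six values per line, \code{\%13.5E} formatting.
#'
#' @param grid a \code{density_grid}.
#' @param path output path.
#' @param comment first comment line content.
#' @return \code{path}, invisibly.
#' @export
write_cube <- function(grid, path, comment = "cdftscreen volumetric grid") {
  stopifnot(inherits(grid, "density_grid"))
  if (voxel_volume(grid) <= 0) stop("refusing to write grid with zero voxel volume")
  atoms <- grid$atoms
  if (is.null(atoms) || nrow(atoms) == 0L)  # format requires >=1 atom line
    atoms <- data.frame(z = 1L, x = grid$origin[1], y = grid$origin[2],
                        z_pos = grid$origin[3])
  con <- file(path, "w")
  on.exit(close(con))
  fmt3 <- function(n, v) sprintf("%5d %11.6f %11.6f %11.6f", n, v[1], v[2], v[3])
  writeLines(c(comment, "values in electrons/bohr^3; z fastest"), con)
  writeLines(fmt3(nrow(atoms), grid$origin), con)
  for (i in 1:3) writeLines(fmt3(grid$shape[i], grid$axes[i, ]), con)
  for (k in seq_len(nrow(atoms)))
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$z[k], 0,
                       atoms$x[k], atoms$y[k], atoms$z_pos[k]), con)
  flat <- as.numeric(aperm(grid$values, c(3, 2, 1)))  # z fastest on disk
  n <- length(flat)
  idx <- seq(1L, n, by = 6L)
  out <- vapply(idx, function(i) {
    paste(sprintf("%13.5E", flat[i:min(i + 5L, n)]), collapse = " ")
  }, character(1))
  writeLines(out, con)
  invisible(path)
}

#' Riemann-sum integral of a grid
#'
#' Plain midpoint quadrature: sum of voxel values times voxel volume. Cube
#' grids are uniform, so this is the standard estimator for integrated
#' electron counts and Fukui-function norms.
#'
#' @param g a \code{density_grid}.
#' @return scalar integral (electrons for a density grid).
#' @export
grid_integral <- function(g) {
  stopifnot(inherits(g, "density_grid"))
  sum(g$values) * voxel_volume(g)
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid %dx%dx%d, voxel %.4g bohr^3, integral %.6g>\n",
              x$shape[1], x$shape[2], x$shape[3], voxel_volume(x),
              grid_integral(x)))
  invisible(x)
}
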