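# Seeded synthetic-data generators. Each generator is a deterministic
# function of its arguments plus a seed, and its outputs have properties
# known by construction (exact KID consistency, exact electron counts,
# threshold-straddling ADMET values, a known 4PL truth), so every pipeline
# stage has an oracle without any electronic-structure or wet-lab input.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate KID-consistent species triplets from target (I, A) pairs
#'
#' Constructs, per ligand, a neutral record with eps_HOMO = -I and
#' eps_LUMO = -A plus cation/anion records whose total energies satisfy
#' E(N-1) = E(N) + I and E(N+1) = E(N) - A, so Koopmans and Delta-SCF
#' routes agree exactly and KID deviations are zero. A perturbation on the
#' cation total energy injects a controlled KID error of exactly that size.
#'
#' @param ligands data.frame with columns ligand_id, I, A (eV; I > A).
#' @param e_neutral baseline total energy assigned to each neutral (eV).
#' @param perturb_cation_ev shift added to every cation total energy (eV);
#'   0 keeps the triplets exactly KID-consistent.
#' @return named list of \code{species_triplet}.
#' @export
gen_species <- function(ligands, e_neutral = -1000, perturb_cation_ev = 0) {
  stopifnot(is.data.frame(ligands),
            all(c("ligand_id", "I", "A") %in% names(ligands)),
            all(ligands$I > ligands$A))
  out <- lapply(seq_len(nrow(ligands)), function(i) {
    id <- ligands$ligand_id[i]
    I <- ligands$I[i]; A <- ligands$A[i]
    species_triplet(
      neutral = species_record(id, 0L, 1L, eps_homo = -I, eps_lumo = -A,
                               e_total = e_neutral, source = "synthetic"),
      cation = species_record(id, 1L, 2L,
                              e_total = e_neutral + I + perturb_cation_ev,
                              source = "synthetic"),
      anion = species_record(id, -1L, 2L, e_total = e_neutral - A,
                             source = "synthetic"))
  })
  names(out) <- ligands$ligand_id
  out
}

#' The five demo ligands' implied (I, A) pairs
#'
#' Back-computed (I = chi + eta/2, A = chi - eta/2) from the shipped global
#' descriptor reference table, so \code{gen_species} on these specs
#' regenerates that table.
#'
#' @return data.frame with ligand_id, I, A (eV).
#' @export
default_ligand_specs <- function() {
  ref <- utils::read.csv(system.file("extdata", "table4_descriptors.csv",
                                     package = "cdftscreen"),
                         stringsAsFactors = FALSE)
  data.frame(ligand_id = ref$ligand_id,
             I = ref$chi + ref$eta / 2,
             A = ref$chi - ref$eta / 2, stringsAsFactors = FALSE)
}

#' Write species triplets to a species table CSV
#'
#' @param triplets named list of \code{species_triplet}.
#' @param path output CSV (energies in eV).
#' @return \code{path}, invisibly.
#' @export
write_species_table <- function(triplets, path) {
  rows <- lapply(triplets, function(tr) {
    do.call(rbind, lapply(list(tr$neutral, tr$cation, tr$anion), function(r)
      data.frame(ligand_id = r$ligand_id, charge = r$charge,
                 multiplicity = r$multiplicity, eps_homo = r$eps_homo,
                 eps_lumo = r$eps_lumo, e_total = r$e_total,
                 source = r$source, stringsAsFactors = FALSE)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- density grids ---------------------------------------------------------

gaussian_density <- function(coords, centers, sigma, weights) {
  v <- numeric(nrow(coords))
  for (i in seq_len(nrow(centers))) {
    d2 <- (coords[, 1] - centers[i, 1])^2 + (coords[, 2] - centers[i, 2])^2 +
      (coords[, 3] - centers[i, 3])^2
    v <- v + weights[i] * exp(-d2 / (2 * sigma[i]^2)) / ((2 * pi * sigma[i]^2)^1.5)
  }
  v
}

#' Generate a neutral/cation/anion density triplet of Gaussian blobs
#'
#' Each density is a sum of isotropic atom-centered Gaussians, each
#' normalized in closed form to its assigned electron count. The charged
#' species redistribute exactly one electron according to
#' \code{anion_add} / \code{cation_remove}, so the exact Fukui functions
#' are known by construction.
#'
#' @param shape voxels per axis (length 1 or 3).
#' @param box_len cubic box edge length in bohr.
#' @param centers n_atoms x 3 matrix of atom positions (bohr).
#' @param sigma per-atom Gaussian width (bohr); recycled.
#' @param n_electrons per-atom electron counts of the neutral.
#' @param anion_add per-atom distribution of the added electron (sums to 1).
#' @param cation_remove per-atom distribution of the removed electron
#'   (sums to 1).
#' @param min_pad_sigma required clearance, in units of sigma, between every
#'   atom and every box face (default 5).
#' @return list with \code{neutral}, \code{cation}, \code{anion}
#'   \code{density_grid}s.
#' @export
gen_density_triplet <- function(shape = 32, box_len = 20,
                                centers = rbind(c(7, 10, 10), c(13, 10, 10)),
                                sigma = 1.0,
                                n_electrons = c(6, 4),
                                anion_add = c(0, 1),
                                cation_remove = c(1, 0),
                                min_pad_sigma = 5) {
  shape <- rep(as.integer(shape), length.out = 3)
  centers <- as.matrix(centers)
  n_atoms <- nrow(centers)
  sigma <- rep(sigma, length.out = n_atoms)
  stopifnot(length(n_electrons) == n_atoms, length(anion_add) == n_atoms,
            length(cation_remove) == n_atoms,
            abs(sum(anion_add) - 1) < 1e-12, abs(sum(cation_remove) - 1) < 1e-12)
  pad <- pmin(apply(centers, 1, min), box_len - apply(centers, 1, max))
  need <- min_pad_sigma * sigma
  if (any(pad < need))
    stop(sprintf(
      "box too small: every atom needs >= %.3g bohr clearance to each face (worst has %.3g); enlarge box_len or recenter atoms",
      max(need), min(pad)))
  step <- box_len / shape
  axes <- diag(step)
  origin <- step / 2  # voxel centers
  coords <- as.matrix(expand.grid(
    x = origin[1] + step[1] * (seq_len(shape[1]) - 1),
    y = origin[2] + step[2] * (seq_len(shape[2]) - 1),
    z = origin[3] + step[3] * (seq_len(shape[3]) - 1)))
  atoms <- data.frame(z = pmax(1L, round(n_electrons)), x = centers[, 1],
                      y = centers[, 2], z_pos = centers[, 3])
  mk <- function(weights) {
    vals <- array(gaussian_density(coords, centers, sigma, weights), dim = shape)
    density_grid(origin, axes, vals, atoms = atoms)
  }
  list(neutral = mk(n_electrons),
       cation = mk(n_electrons - cation_remove),
       anion = mk(n_electrons + anion_add))
}

# ---- tables and curves -----------------------------------------------------

#' Generate a synthetic ADMET table straddling every rule threshold
#'
#' Numeric properties are drawn uniformly from ranges that straddle the
#' default rulebook's thresholds (e.g. Caco-2 from 0.5-1.3 around the 0.90
#' cutoff) so both verdict branches of every rule occur with non-negligible
#' probability; flags are fair Bernoulli draws.
#'
#' @param n number of ligands.
#' @param seed RNG seed.
#' @return data.frame in the layout of \code{read_admet_table}'s output.
#' @export
gen_admet_table <- function(n = 50, seed = 1) {
  with_local_seed(seed, {
    runif2 <- function(lo, hi) stats::runif(n, lo, hi)
    flag <- function() stats::runif(n) > 0.5
    data.frame(
      ligand_id = sprintf("SYN-%03d", seq_len(n)),
      caco2 = runif2(0.5, 1.3),
      intestinal_absorption = runif2(0, 60),
      skin_logkp = runif2(-4, -1),
      vdss = runif2(-2.5, 0.5),
      fraction_unbound = runif2(0, 1),
      bbb_logbb = runif2(-2, 0.5),
      cns_logps = runif2(-6, -1),
      total_clearance = runif2(-0.5, 1),
      max_tolerated_dose = runif2(0.2, 2),
      orat_ld50 = runif2(1.5, 3),
      orct = runif2(2, 6),
      tpyriformis = runif2(-1.5, 0.5),
      pgp_substrate = flag(), pgp1_inhibitor = flag(), pgp2_inhibitor = flag(),
      cyp2d6_substrate = flag(), cyp3a4_substrate = flag(),
      cyp1a2_inhibitor = flag(), cyp2c19_inhibitor = flag(),
      cyp2c9_inhibitor = flag(), cyp2d6_inhibitor = flag(),
      cyp3a4_inhibitor = flag(),
      oct2_substrate = flag(), ames = flag(), herg1 = flag(), herg2 = flag(),
      hepatotoxicity = flag(), skin_sensitisation = flag(),
      stringsAsFactors = FALSE)
  })
}

#' Generate a noisy 4PL dose-response curve
#'
#' Inhibition percentages from the four-parameter logistic at log-spaced
#' doses, plus seeded Gaussian noise.
#'
#' @param ic50 true half-maximal dose (ug/mL).
#' @param hill true slope.
#' @param bottom,top true plateaus (percent).
#' @param noise_sd noise standard deviation in percent points (0 = exact).
#' @param doses dose vector; default 8 log-spaced doses over
#'   ic50/30 .. ic50*30.
#' @param seed RNG seed.
#' @param replicate_id label carried into the record.
#' @return a \code{dose_response}.
#' @export
gen_dose_response <- function(ic50 = 22.39, hill = 1, bottom = 0, top = 100,
                              noise_sd = 0, doses = NULL, seed = 1,
                              replicate_id = NA) {
  stopifnot(ic50 > 0, noise_sd >= 0)
  if (is.null(doses))
    doses <- exp(seq(log(ic50 / 30), log(ic50 * 30), length.out = 8))
  y <- logistic4(doses, bottom, top, ic50, hill)
  if (noise_sd > 0)
    y <- with_local_seed(seed, y + stats::rnorm(length(doses), 0, noise_sd))
  dose_response(doses, y, replicate_id = replicate_id)
}
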