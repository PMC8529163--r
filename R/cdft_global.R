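# Global conceptual-DFT reactivity descriptors.
#
# Working equations (all energies in eV):
#   chi        = (I + A) / 2          electronegativity (Mulliken)
#   eta        = I - A                global hardness
#   S          = 1 / eta              global softness
#   omega      = chi^2 / (2 eta)      electrophilicity (Parr)
#   N          = eps_HOMO - eps_HOMO(ref)   nucleophilicity, referenced scale
#   omega^-    = (3I + A)^2 / (16 eta)  electrodonating power (Gazquez)
#   omega^+    = (I + 3A)^2 / (16 eta)  electroaccepting power
#   net        = omega^- + omega^+      net electrophilicity
# I and A come either from frontier orbitals under the Koopmans-in-DFT
# approximation (I = -eps_HOMO, A = -eps_LUMO) or from total-energy
# differences of the N, N-1, N+1 electron systems (Delta-SCF).

#' Default nucleophilicity reference HOMO energy (eV)
#'
#' Reference frontier-orbital energy against which nucleophilicity N is
#' measured (N = eps_HOMO(ligand) - eps_HOMO(reference)); conventionally the
#' HOMO of tetracyanoethylene, the least nucleophilic organic anchor.
#' @export
DEFAULT_REF_HOMO_EV <- -8.7924

#' Vertical I and A from frontier orbitals (Koopmans-in-DFT)
#'
#' @param neutral a \code{species_record} with both orbital energies.
#' @return list of class \code{ionization_data}: \code{I}, \code{A} (eV),
#'   \code{method = "koopmans"}.
#' @export
vertical_ia_koopmans <- function(neutral) {
  stopifnot(inherits(neutral, "species_record"))
  if (is.na(neutral$eps_homo) || is.na(neutral$eps_lumo))
    stop("Koopmans route needs eps_homo and eps_lumo on the neutral record of '",
         neutral$ligand_id, "'")
  ionization_data(I = -neutral$eps_homo, A = -neutral$eps_lumo,
                  method = "koopmans")
}

#' Vertical I and A from total-energy differences (Delta-SCF)
#'
#' I = E(N-1) - E(N), A = E(N) - E(N+1), all at the neutral geometry.
#'
#' @param triplet a \code{species_triplet} with \code{e_total} on all members.
#' @return an \code{ionization_data} with \code{method = "delta_scf"}.
#' @export
vertical_ia_delta_scf <- function(triplet) {
  stopifnot(inherits(triplet, "species_triplet"))
  for (nm in c("neutral", "cation", "anion"))
    if (is.na(triplet[[nm]]$e_total))
      stop("Delta-SCF route needs e_total on the ", nm, " species of '",
           triplet$neutral$ligand_id, "'")
  ionization_data(I = triplet$cation$e_total - triplet$neutral$e_total,
                  A = triplet$neutral$e_total - triplet$anion$e_total,
                  method = "delta_scf")
}

#' Construct validated ionization data
#'
#' @param I vertical ionization potential (eV).
#' @param A vertical electron affinity (eV).
#' @param method \code{"koopmans"} or \code{"delta_scf"}.
#' @export
ionization_data <- function(I, A, method = c("koopmans", "delta_scf")) {
  method <- match.arg(method)
  if (!is.finite(I) || !is.finite(A)) stop("I and A must be finite")
  if (I <= A)
    stop("degenerate gap: I (", I, " eV) must exceed A (", A,
         " eV) or hardness would be non-positive")
  structure(list(I = I, A = A, method = method), class = "ionization_data")
}

#' The eight global reactivity descriptors for one ligand
#'
#' @param ia an \code{ionization_data}.
#' @param ref_homo_ev reference HOMO energy (eV) for the nucleophilicity
#'   scale; default \code{DEFAULT_REF_HOMO_EV}.
#' @param ligand_id optional label carried into the result.
#' @return list of class \code{global_descriptors} with fields \code{chi},
#'   \code{eta}, \code{omega}, \code{S}, \code{N_nu}, \code{omega_minus},
#'   \code{omega_plus}, \code{net_electrophilicity} (eV; S in 1/eV).
#' @examples
#' gd <- global_descriptors(ionization_data(6.19380, 2.07540), ligand_id = "Rutine")
#' round(gd$omega, 4)  # 2.0754
#' @export
global_descriptors <- function(ia, ref_homo_ev = DEFAULT_REF_HOMO_EV,
                               ligand_id = NA_character_) {
  stopifnot(inherits(ia, "ionization_data"))
  I <- ia$I; A <- ia$A
  eta <- I - A
  chi <- (I + A) / 2
  structure(list(
    ligand_id = ligand_id,
    chi = chi,
    eta = eta,
    omega = chi^2 / (2 * eta),
    S = 1 / eta,
    N_nu = (-I) - ref_homo_ev,
    omega_minus = (3 * I + A)^2 / (16 * eta),
    omega_plus = (I + 3 * A)^2 / (16 * eta),
    net_electrophilicity = (3 * I + A)^2 / (16 * eta) + (I + 3 * A)^2 / (16 * eta)
  ), class = "global_descriptors")
}

#' Invert descriptors back to (I, A)
#'
#' Exact inverse of the descriptor map: I = chi + eta/2, A = chi - eta/2.
#'
#' @param gd a \code{global_descriptors}, or anything with \code{chi} and
#'   \code{eta} fields.
#' @param method method tag for the resulting \code{ionization_data}.
#' @export
descriptors_to_ia <- function(gd, method = "koopmans") {
  ionization_data(I = gd$chi + gd$eta / 2, A = gd$chi - gd$eta / 2,
                  method = method)
}

#' Electrophilicity classification on the Domingo scale
#'
#' Strong for omega > 1.5 eV, moderate for 0.8 < omega <= 1.5 eV, marginal
#' for omega <= 0.8 eV. The scale's original inequalities are strict on both
#' sides of each boundary; the boundary values themselves are assigned
#' downward (1.5 -> moderate, 0.8 -> marginal).
#'
#' @param omega electrophilicity index (eV), non-negative.
#' @return one of \code{"strong"}, \code{"moderate"}, \code{"marginal"}.
#' @export
electrophilicity_class <- function(omega) {
  if (!is.finite(omega) || omega < 0)
    stop("omega must be a non-negative finite value, got ", omega)
  if (omega > 1.5) "strong" else if (omega > 0.8) "moderate" else "marginal"
}

#' Koopmans-in-DFT consistency check
#'
#' Measures how well the functional's frontier-orbital energies reproduce
#' the Delta-SCF ionization potential and electron affinity:
#' \code{j_i = |eps_HOMO + E(N-1) - E(N)|},
#' \code{j_a = |eps_LUMO + E(N) - E(N+1)|},
#' \code{j_hl = sqrt(j_i^2 + j_a^2)}.
#'
#' @param triplet a \code{species_triplet}; the neutral member needs both
#'   orbital energies and all members need \code{e_total}.
#' @param tol_ev pass tolerance in eV (default 0.05).
#' @return list of class \code{kid_report}: \code{ligand_id}, \code{j_i},
#'   \code{j_a}, \code{j_hl}, \code{passes}.
#' @export
kid_check <- function(triplet, tol_ev = 0.05) {
  stopifnot(inherits(triplet, "species_triplet"), tol_ev > 0)
  n <- triplet$neutral
  if (is.na(n$eps_homo) || is.na(n$eps_lumo))
    stop("KID check needs eps_homo and eps_lumo on the neutral species of '",
         n$ligand_id, "'")
  for (nm in c("neutral", "cation", "anion"))
    if (is.na(triplet[[nm]]$e_total))
      stop("KID check needs e_total on the ", nm, " species of '",
           n$ligand_id, "'")
  j_i <- abs(n$eps_homo + triplet$cation$e_total - n$e_total)
  j_a <- abs(n$eps_lumo + n$e_total - triplet$anion$e_total)
  structure(list(ligand_id = n$ligand_id, j_i = j_i, j_a = j_a,
                 j_hl = sqrt(j_i^2 + j_a^2),
                 passes = (j_i <= tol_ev && j_a <= tol_ev)),
            class = "kid_report")
}

#' Rank ligands by decreasing hardness
#'
#' The hardest (largest eta) ligand is the least reactive; ties break
#' lexicographically by ligand_id.
#'
#' @param table list of \code{global_descriptors}.
#' @return character vector of ligand_ids, least reactive first.
#' @export
hardness_ranking <- function(table) {
  if (!length(table)) stop("hardness_ranking needs a non-empty descriptor table")
  ids <- vapply(table, function(g) g$ligand_id, character(1))
  etas <- vapply(table, function(g) g$eta, numeric(1))
  ids[order(-etas, ids)]
}

#' Descriptor table for a set of ligands
#'
#' Convenience wrapper: one row per ligand with the eight descriptors and
#' the electrophilicity class.
#'
#' @param ia_list named list of \code{ionization_data} (names = ligand ids).
#' @param ref_homo_ev nucleophilicity reference (eV).
#' @return data.frame with columns ligand_id, chi, eta, omega, S, N,
#'   omega_minus, omega_plus, net_electrophilicity, electrophilicity_class.
#' @export
descriptor_table <- function(ia_list, ref_homo_ev = DEFAULT_REF_HOMO_EV) {
  stopifnot(length(ia_list) > 0, !is.null(names(ia_list)))
  rows <- lapply(names(ia_list), function(id) {
    g <- global_descriptors(ia_list[[id]], ref_homo_ev = ref_homo_ev,
                            ligand_id = id)
    data.frame(ligand_id = id, chi = g$chi, eta = g$eta, omega = g$omega,
               S = g$S, N = g$N_nu, omega_minus = g$omega_minus,
               omega_plus = g$omega_plus,
               net_electrophilicity = g$net_electrophilicity,
               electrophilicity_class = electrophilicity_class(g$omega),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
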