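# Finite-difference local reactivity on volumetric grids: nucleophilic and
# electrophilic Fukui functions f+ = rho_{N+1} - rho_N and
# f- = rho_N - rho_{N-1}, dual descriptor df = f+ - f-, condensed-to-atom
# indices from population charges, and sign-region summaries.

grids_compatible <- function(a, b, tol = 1e-6) {
  if (!all(a$shape == b$shape)) return("shape")
  if (max(abs(a$origin - b$origin)) > tol) return("origin")
  if (max(abs(a$axes - b$axes)) > tol) return("axes")
  NULL
}

#' Fukui functions and dual descriptor from density triplets
#'
#' Voxelwise finite differences over the N, N+1 and N-1 electron densities
#' (all at the neutral geometry). Exact f+/f- integrate to 1 and the dual
#' descriptor to 0; on a finite truncated grid the quadrature deviates, so
#' deviations beyond \code{norm_tol} raise a warning with the measured
#' integral rather than aborting.
#'
#' @param rho_n,rho_cation,rho_anion \code{density_grid}s with identical
#'   geometry (origin, axes, shape within 1e-6).
#' @param norm_tol tolerance on the normalization invariants (default 1e-2).
#' @return list of class \code{fukui_grids}: \code{f_plus}, \code{f_minus},
#'   \code{dual} (grids) plus \code{integrals} (named numeric).
#' @export
fukui_from_densities <- function(rho_n, rho_cation, rho_anion, norm_tol = 1e-2) {
  for (g in list(rho_n, rho_cation, rho_anion))
    stopifnot(inherits(g, "density_grid"))
  for (pair in list(list("cation", rho_cation), list("anion", rho_anion))) {
    bad <- grids_compatible(rho_n, pair[[2]])
    if (!is.null(bad))
      stop("grid geometry mismatch between neutral and ", pair[[1]],
           " densities: differing ", bad)
  }
  mk <- function(vals) density_grid(rho_n$origin, rho_n$axes, vals,
                                    atoms = rho_n$atoms)
  f_plus <- mk(rho_anion$values - rho_n$values)
  f_minus <- mk(rho_n$values - rho_cation$values)
  dual <- mk(f_plus$values - f_minus$values)
  ints <- c(f_plus = grid_integral(f_plus), f_minus = grid_integral(f_minus),
            dual = grid_integral(dual))
  if (abs(ints[["f_plus"]] - 1) > norm_tol)
    warning(sprintf("f+ integrates to %.6g, expected 1 +/- %g", ints[["f_plus"]], norm_tol))
  if (abs(ints[["f_minus"]] - 1) > norm_tol)
    warning(sprintf("f- integrates to %.6g, expected 1 +/- %g", ints[["f_minus"]], norm_tol))
  if (abs(ints[["dual"]]) > 2 * norm_tol)
    warning(sprintf("dual descriptor integrates to %.6g, expected 0 +/- %g",
                    ints[["dual"]], 2 * norm_tol))
  structure(list(f_plus = f_plus, f_minus = f_minus, dual = dual,
                 integrals = ints), class = "fukui_grids")
}

#' Condensed-to-atom Fukui indices from population charges
#'
#' In the atomic-charge convention: \code{f+_k = q_k(N) - q_k(N+1)},
#' \code{f-_k = q_k(N-1) - q_k(N)}, \code{dual_k = f+_k - f-_k}. Works with
#' any population-analysis scheme (Mulliken, Hirshfeld, NPA, ...); only the
#' total-charge bookkeeping is checked.
#'
#' @param charges_n,charges_cation,charges_anion equal-length numeric vectors
#'   of per-atom charges for the N, N-1 and N+1 electron systems; totals must
#'   differ from the neutral's by exactly +1 and -1 (within \code{tol}).
#' @param tol tolerance on the total-charge consistency check.
#' @return data.frame of class \code{condensed_fukui}: atom, f_plus_k,
#'   f_minus_k, dual_k; attribute \code{sums} carries the column sums.
#' @export
condensed_fukui <- function(charges_n, charges_cation, charges_anion,
                            tol = 1e-3) {
  n <- length(charges_n)
  if (length(charges_cation) != n || length(charges_anion) != n)
    stop("charge vectors differ in length: ", n, ", ", length(charges_cation),
         ", ", length(charges_anion))
  dq_cat <- sum(charges_cation) - sum(charges_n)
  dq_an <- sum(charges_anion) - sum(charges_n)
  if (abs(dq_cat - 1) > tol)
    stop(sprintf("cation total charge must exceed neutral by +1, got %+.4f", dq_cat))
  if (abs(dq_an + 1) > tol)
    stop(sprintf("anion total charge must be below neutral by -1, got %+.4f", dq_an))
  f_plus <- charges_n - charges_anion
  f_minus <- charges_cation - charges_n
  out <- data.frame(atom = seq_len(n), f_plus_k = f_plus, f_minus_k = f_minus,
                    dual_k = f_plus - f_minus)
  attr(out, "sums") <- c(f_plus = sum(f_plus), f_minus = sum(f_minus),
                         dual = sum(f_plus - f_minus))
  class(out) <- c("condensed_fukui", class(out))
  out
}

#' Sign-region summary of a dual-descriptor grid
#'
#' Voxel counts, volumes (bohr^3) and integrated dual-descriptor mass for the
#' electrophilic (dual > threshold) and nucleophilic (dual < -threshold)
#' regions.
#'
#' @param dual a \code{density_grid} holding the dual descriptor.
#' @param threshold non-negative isovalue cut (density units).
#' @return list with \code{positive} and \code{negative} sub-lists
#'   (\code{n_voxels}, \code{volume}, \code{mass}) and the threshold used.
#' @export
dual_sign_regions <- function(dual, threshold = 0) {
  stopifnot(inherits(dual, "density_grid"))
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be non-negative, got ", threshold)
  vv <- voxel_volume(dual)
  pos <- dual$values > threshold
  neg <- dual$values < -threshold
  region <- function(mask) list(
    n_voxels = sum(mask),
    volume = sum(mask) * vv,
    mass = sum(dual$values[mask]) * vv)
  list(threshold = threshold, positive = region(pos), negative = region(neg))
}
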