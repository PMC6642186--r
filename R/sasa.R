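## Solvent-accessible surface area (Shrake-Rupley sphere sampling) and
## PISA-style buried interface areas.
##
## Sample points come from a deterministic Fibonacci lattice -- no RNG --
## so areas are bit-reproducible for a given n_points.

# n points quasi-uniform on the unit sphere (golden-angle spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area
#'
#' Shrake-Rupley: each atom's sphere of radius (vdW + probe) is sampled at
#' `n_points` deterministic lattice points; a point is accessible when it
#' lies outside every neighbour's expanded sphere. Per-atom area is the
#' accessible fraction times the sphere area.
#'
#' @param model a `structure_model`.
#' @param probe_radius probe sphere radius, Angstrom (water: 1.4).
#' @param n_points lattice points per atom (>= 100; default 960).
#' @param atoms optional atom row indices; default selection honours the
#'   exclusion flags below.
#' @param exclude_waters,exclude_het drop waters / hetero atoms from the
#'   default selection (both TRUE: protein surface area).
#' @return object of class `sasa_result`: `total` (Angstrom^2), `per_atom`,
#'   `atoms` (row indices used), `probe_radius`, `n_points`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L, atoms = NULL,
                 exclude_waters = TRUE, exclude_het = TRUE) {
  if (n_points < 100) stop("n_points must be >= 100 for acceptable accuracy")
  a <- model$atoms
  if (is.null(atoms)) {
    keep <- a$element != "H"
    if (exclude_waters) keep <- keep & !(toupper(a$resname) %in%
                                           .water_resnames)
    if (exclude_het) keep <- keep & !a$het
    atoms <- which(keep)
  }
  if (!length(atoms)) stop("empty atom selection")
  xyz <- coords(model, atoms)
  R <- a$vdw[atoms] + probe_radius
  n <- length(atoms)
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  x2 <- rowSums(xyz^2)
  for (i in seq_len(n)) {
    d2 <- x2 + x2[i] - 2 * drop(xyz %*% xyz[i, ])
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    P <- sweep(pts * R[i], 2, xyz[i, ], "+")
    acc <- n_points
    if (length(nb)) {
      N <- xyz[nb, , drop = FALSE]
      dd <- outer(rowSums(P^2), rowSums(N^2), "+") - 2 * tcrossprod(P, N)
      blocked <- rowSums(dd <= matrix(R[nb]^2, n_points, length(nb),
                                      byrow = TRUE) + 1e-12) > 0
      acc <- sum(!blocked)
    }
    area[i] <- 4 * pi * R[i]^2 * acc / n_points
  }
  out <- list(total = sum(area), per_atom = area, atoms = atoms,
              probe_radius = probe_radius, n_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: total ", format(x$total, digits = 6), " A^2 over ",
      length(x$atoms), " atoms (probe ", x$probe_radius, " A, ",
      x$n_points, " points/atom)\n", sep = "")
  invisible(x)
}

#' Buried interface area between two chains
#'
#' PISA-style geometric burial: ligands, ions and waters (hetero records)
#' are stripped first, then
#' `buried = (SASA_A + SASA_B - SASA_AB) / 2`.
#' Only the geometric identity is reproduced here; interface chemistry
#' scoring is out of scope, and comparisons against PISA-derived figures
#' carry a documented +/- 5 percent tolerance.
#'
#' @param model a `structure_model` containing both chains.
#' @param chain_a,chain_b chain identifiers.
#' @param probe_radius,n_points passed to [sasa()].
#' @return object of class `interface_area`: `chain_pair`, `buried_area`,
#'   `sasa_a`, `sasa_b`, `sasa_ab` (Angstrom^2).
#' @export
buried_interface_area <- function(model, chain_a, chain_b,
                                  probe_radius = 1.4, n_points = 960L) {
  a <- model$atoms
  base <- a$element != "H" & !a$het &
    !(toupper(a$resname) %in% .water_resnames)
  ia <- which(base & a$chain == chain_a)
  ib <- which(base & a$chain == chain_b)
  if (!length(ia)) stop("chain ", chain_a, " is empty after stripping")
  if (!length(ib)) stop("chain ", chain_b, " is empty after stripping")
  sa <- sasa(model, probe_radius, n_points, atoms = ia)$total
  sb <- sasa(model, probe_radius, n_points, atoms = ib)$total
  sab <- sasa(model, probe_radius, n_points, atoms = c(ia, ib))$total
  out <- list(chain_pair = c(chain_a, chain_b),
              buried_area = max(0, (sa + sb - sab) / 2),
              sasa_a = sa, sasa_b = sb, sasa_ab = sab)
  class(out) <- "interface_area"
  out
}

#' @export
print.interface_area <- function(x, ...) {
  cat("interface_area ", x$chain_pair[1], "-", x$chain_pair[2],
      ": buried ", format(x$buried_area, digits = 6), " A^2",
      "  (SASA ", format(x$sasa_a, digits = 6), " + ",
      format(x$sasa_b, digits = 6), " - ",
      format(x$sasa_ab, digits = 6), ")\n", sep = "")
  invisible(x)
}
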