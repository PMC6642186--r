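## Pore-radius profile along the channel axis (simplified HOLE-style scan)
## and passability calls against a hydrated-ion radius.
##
## At each position z along the axis the pore radius is the radius of the
## largest probe sphere centred in the perpendicular plane that touches no
## van der Waals sphere: radius(c) = min_i(||c - x_i|| - r_vdw,i). With
## centre optimization on, the centre is searched in an in-plane box by a
## coarse grid followed by local refinement; off, the axis point itself is
## used. Curved (non-axial) pathways are out of scope.

plane_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

# min_i(||c - x_i|| - r_i) for a matrix of candidate centres
clearance <- function(centres, xyz, r) {
  d2 <- outer(rowSums(centres^2), rowSums(xyz^2), "+") -
    2 * tcrossprod(centres, xyz)
  best <- sqrt(pmax(0, d2)) - matrix(r, nrow(centres), length(r),
                                     byrow = TRUE)
  apply(best, 1, min)
}

#' Pore-radius profile along the channel axis
#'
#' @param model a `structure_model` (waters and hetero groups are excluded
#'   from the wall).
#' @param axis `"auto"` (principal axis of the Calpha inertia tensor, i.e.
#'   the pentamer's 5-fold axis) or a 3-vector.
#' @param z_step spacing of profile positions, Angstrom.
#' @param optimize_center search for the widest centre in each
#'   perpendicular plane (grid + refinement in a `box`-sized in-plane box);
#'   `FALSE` evaluates the axis point only.
#' @param z_range optional `c(min, max)` along the axis (relative to the
#'   Calpha centroid); defaults to the atom span.
#' @param box half-width of the in-plane search box, Angstrom.
#' @param fine_step refinement grid step, Angstrom.
#' @param constriction_threshold report local minima below this radius.
#' @return object of class `pore_profile`: data.frame with `z`, `radius`
#'   (negative clearances reported as 0), `blocked`, `nearest` residue key;
#'   constrictions in `attr(,"constrictions")`.
#' @export
pore_profile <- function(model, axis = "auto", z_step = 0.5,
                         optimize_center = TRUE, z_range = NULL,
                         box = 5, fine_step = 0.1,
                         constriction_threshold = 4.0) {
  a <- model$atoms
  wall <- which(a$element != "H" & !a$het &
                  !(toupper(a$resname) %in% .water_resnames))
  if (!length(wall)) stop("no wall atoms selected")
  xyz <- coords(model, wall)
  r <- a$vdw[wall]
  ca <- wall[a$name[wall] == "CA"]
  ref <- if (length(ca) >= 3) coords(model)[ca, , drop = FALSE] else xyz
  origin <- colMeans(ref)
  if (identical(axis, "auto")) {
    ev <- eigen(stats::cov(ref), symmetric = TRUE)
    u <- ev$vectors[, 1]   # largest-variance direction = channel axis
  } else {
    u <- as.numeric(axis)
  }
  B <- plane_basis(u)
  proj <- drop(sweep(xyz, 2, origin) %*% B$u)
  if (is.null(z_range)) z_range <- range(proj)
  zs <- seq(z_range[1], z_range[2], by = z_step)

  coarse <- as.matrix(expand.grid(seq(-box, box, by = 0.5),
                                  seq(-box, box, by = 0.5)))
  # refinement offsets are centred on 0 so a grid-perfect coarse optimum
  # is never degraded
  fo <- seq(-3 * fine_step, 3 * fine_step, by = fine_step)
  fine_off <- as.matrix(expand.grid(fo, fo))
  radius <- numeric(length(zs))
  nearest <- character(length(zs))
  centre_xy <- matrix(0, length(zs), 2)
  for (k in seq_along(zs)) {
    c0 <- origin + zs[k] * B$u
    if (optimize_center) {
      cen <- sweep(coarse[, 1, drop = FALSE] %*% rbind(B$e1) +
                     coarse[, 2, drop = FALSE] %*% rbind(B$e2), 2, c0, "+")
      cl <- clearance(cen, xyz, r)
      best <- which.max(cl)
      xy <- coarse[best, ]
      cen2 <- sweep(fine_off[, 1, drop = FALSE] %*% rbind(B$e1) +
                      fine_off[, 2, drop = FALSE] %*% rbind(B$e2), 2,
                    cen[best, ], "+")
      cl2 <- clearance(cen2, xyz, r)
      b2 <- which.max(cl2)
      radius[k] <- cl2[b2]
      xy <- xy + fine_off[b2, ]
      cbest <- cen2[b2, ]
    } else {
      radius[k] <- clearance(rbind(c0), xyz, r)
      xy <- c(0, 0)
      cbest <- c0
    }
    centre_xy[k, ] <- xy
    d <- sqrt(rowSums(sweep(xyz, 2, cbest)^2)) - r
    i <- wall[which.min(d)]
    nearest[k] <- paste(a$chain[i], a$resno[i], a$resname[i], sep = ":")
  }
  blocked <- radius < 0
  prof <- data.frame(z = zs, radius = pmax(0, radius), blocked = blocked,
                     nearest = nearest, stringsAsFactors = FALSE)
  # local minima below the report threshold
  con <- integer(0)
  for (k in seq_along(zs)) {
    lo <- if (k > 1) prof$radius[k - 1] else Inf
    hi <- if (k < length(zs)) prof$radius[k + 1] else Inf
    if (prof$radius[k] <= lo && prof$radius[k] <= hi &&
          prof$radius[k] < constriction_threshold)
      con <- c(con, k)
  }
  constr <- prof[con, c("z", "radius", "nearest"), drop = FALSE]
  rownames(constr) <- NULL
  class(prof) <- c("pore_profile", "data.frame")
  attr(prof, "constrictions") <- constr
  attr(prof, "axis") <- B$u
  attr(prof, "origin") <- origin
  prof
}

#' @export
print.pore_profile <- function(x, digits = 3, ...) {
  cat("pore_profile: ", nrow(x), " positions, z in [",
      format(min(x$z)), ", ", format(max(x$z)), "] A; min radius ",
      format(min(x$radius), digits = digits), " A at z = ",
      format(x$z[which.min(x$radius)]), " (", x$nearest[which.min(x$radius)],
      ")\n", sep = "")
  con <- attr(x, "constrictions")
  if (!is.null(con) && nrow(con)) {
    cat("  constrictions:\n")
    for (i in seq_len(nrow(con)))
      cat(sprintf("    z = %6.1f  radius = %5.2f A  %s\n", con$z[i],
                  con$radius[i], con$nearest[i]))
  }
  invisible(x)
}

#' @export
plot.pore_profile <- function(x, ion_radius = NULL,
                              xlab = "distance along pore axis (A)",
                              ylab = "pore radius (A)", type = "l", ...) {
  graphics::plot(x$z, x$radius, type = type, xlab = xlab, ylab = ylab, ...)
  if (!is.null(ion_radius))
    graphics::abline(h = ion_radius, lty = 2)
  invisible(x)
}

#' Barrier segments narrower than an ion
#'
#' Finds contiguous stretches of the profile whose radius falls below the
#' (hydrated) ion radius; the default 2.76 Angstrom is the approximate
#' radius of a hydrated Na+ ion.
#'
#' @param profile a `pore_profile`.
#' @param ion_radius Angstrom.
#' @return data.frame with one row per barrier: `z_start`, `z_end`,
#'   `min_radius`, `z_min` and the `nearest` residue at the minimum.
#' @export
passability <- function(profile, ion_radius = 2.76) {
  below <- profile$radius < ion_radius
  if (!any(below))
    return(data.frame(z_start = numeric(), z_end = numeric(),
                      min_radius = numeric(), z_min = numeric(),
                      nearest = character()))
  rl <- rle(below)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  seg <- which(rl$values)
  out <- lapply(seg, function(s) {
    idx <- starts[s]:ends[s]
    m <- idx[which.min(profile$radius[idx])]
    data.frame(z_start = profile$z[starts[s]], z_end = profile$z[ends[s]],
               min_radius = profile$radius[m], z_min = profile$z[m],
               nearest = profile$nearest[m], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate pore residues with M2 prime notation
#'
#' Joins a profile's nearest-residue calls against a prime-index table
#' (default: the bundled 5-HT3A M2 table, 9' = Leu260).
#'
#' @param profile a `pore_profile`.
#' @param table data.frame with `prime` and `resno` columns
#'   (default [m2_prime_table()]).
#' @return the profile data.frame with an added `prime` column (NA outside
#'   the table).
#' @export
annotate_prime <- function(profile, table = m2_prime_table()) {
  resno <- suppressWarnings(as.integer(
    vapply(strsplit(profile$nearest, ":"), `[`, "", 2)))
  profile$prime <- table$prime[match(resno, table$resno)]
  profile
}
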