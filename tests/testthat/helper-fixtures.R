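# Shared fixture builders and independent oracles. Oracles are written as
# direct, naive re-statements of each rule so they never share code with
# the implementation under test.

atom_row <- function(serial, name, element, resname, chain, resno, x, y, z,
                     het = FALSE, occupancy = 1, alt = "") {
  data.frame(serial = serial, name = name, element = element, alt = alt,
             resname = resname, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, occupancy = occupancy, b = 0, het = het,
             stringsAsFactors = FALSE)
}

# 3-residue toy peptide (ALA-GLY-SER) with full backbones
make_test_peptide <- function() {
  rows <- list(
    atom_row(1, "N", "N", "ALA", "A", 1, 0.0, 0.0, 0.0),
    atom_row(2, "CA", "C", "ALA", "A", 1, 1.5, 0.0, 0.0),
    atom_row(3, "C", "C", "ALA", "A", 1, 2.1, 1.4, 0.0),
    atom_row(4, "O", "O", "ALA", "A", 1, 1.4, 2.4, 0.0),
    atom_row(5, "CB", "C", "ALA", "A", 1, 2.0, -0.8, -1.2),
    atom_row(6, "N", "N", "GLY", "A", 2, 3.4, 1.5, 0.1),
    atom_row(7, "CA", "C", "GLY", "A", 2, 4.2, 2.7, 0.1),
    atom_row(8, "C", "C", "GLY", "A", 2, 5.7, 2.4, 0.2),
    atom_row(9, "O", "O", "GLY", "A", 2, 6.2, 1.3, 0.2),
    atom_row(10, "N", "N", "SER", "A", 3, 6.4, 3.5, 0.2),
    atom_row(11, "CA", "C", "SER", "A", 3, 7.9, 3.5, 0.3),
    atom_row(12, "C", "C", "SER", "A", 3, 8.5, 4.9, 0.3),
    atom_row(13, "O", "O", "SER", "A", 3, 7.8, 5.9, 0.3),
    atom_row(14, "CB", "C", "SER", "A", 3, 8.5, 2.7, -0.9),
    atom_row(15, "OG", "O", "SER", "A", 3, 8.2, 1.3, -0.8)
  )
  structure_model(do.call(rbind, rows))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_model <- function(model, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# --- independent oracles ---------------------------------------------------

# all-pairs carbon contact scan
oracle_apolar <- function(res_atoms, lig_atoms, cutoff = 4.5) {
  hit <- FALSE
  for (i in seq_len(nrow(res_atoms))) for (j in seq_len(nrow(lig_atoms))) {
    if (res_atoms$element[i] != "C" || lig_atoms$element[j] != "C") next
    d <- sqrt((res_atoms$x[i] - lig_atoms$x[j])^2 +
                (res_atoms$y[i] - lig_atoms$y[j])^2 +
                (res_atoms$z[i] - lig_atoms$z[j])^2)
    if (d <= cutoff) hit <- TRUE
  }
  as.integer(hit)
}

# exhaustive one- and two-water path search for a THR side chain (polar
# OG1 with antecedent CB) against ligand polar atoms with no bonds
oracle_water_bridges <- function(og1, cb, lig_polar_xyz, water_xyz,
                                 cutoff = 3.5, min_angle = 90) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  ang <- function(a, at, b) {
    u <- a - at; v <- b - at
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  nw <- nrow(water_xyz)
  hb_res <- function(w) d(water_xyz[w, ], og1) <= cutoff &&
    ang(cb, og1, water_xyz[w, ]) >= min_angle
  hb_lig <- function(w) any(vapply(seq_len(nrow(lig_polar_xyz)), function(j)
    d(water_xyz[w, ], lig_polar_xyz[j, ]) <= cutoff, logical(1)))
  one <- 0L; two <- 0L
  for (w in seq_len(nw))
    if (hb_lig(w) && hb_res(w)) one <- 1L
  for (w1 in seq_len(nw)) for (w2 in seq_len(nw)) {
    if (w1 == w2) next
    if (hb_lig(w1) && d(water_xyz[w1, ], water_xyz[w2, ]) <= cutoff &&
          hb_res(w2)) two <- 1L
  }
  c(one, two)
}

# ring census by subset enumeration: a vertex subset is a ring iff its
# induced subgraph is connected with every vertex of degree exactly 2
oracle_rings <- function(n, bonds, min_len = 3, max_len = 8) {
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(bonds))) {
    adj[bonds[k, 1], bonds[k, 2]] <- TRUE
    adj[bonds[k, 2], bonds[k, 1]] <- TRUE
  }
  out <- list()
  for (len in min_len:min(max_len, n)) {
    for (ss in utils::combn(n, len, simplify = FALSE)) {
      sub <- adj[ss, ss, drop = FALSE]
      if (!all(rowSums(sub) == 2)) next
      # connectivity of the induced 2-regular graph
      seen <- c(1L); frontier <- c(1L)
      while (length(frontier)) {
        nxt <- setdiff(which(apply(sub[frontier, , drop = FALSE], 2, any)),
                       seen)
        seen <- c(seen, nxt); frontier <- nxt
      }
      if (length(seen) == len) out[[length(out) + 1]] <- ss
    }
  }
  out
}

# two overlapping spheres: accessible area from the spherical-cap formula
oracle_two_sphere_area <- function(r1, r2, d) {
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  x2 <- (d^2 + r2^2 - r1^2) / (2 * d)
  a1 <- 4 * pi * r1^2 - 2 * pi * r1 * (r1 - x1)
  a2 <- 4 * pi * r2^2 - 2 * pi * r2 * (r2 - x2)
  a1 + a2
}

canonical_ring <- function(r) paste(sort(r), collapse = "-")
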