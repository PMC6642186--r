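## Seeded synthetic fixtures with planted ground truth, one per pipeline
## stage: a multi-residue complex instantiating each of the nine
## interaction types, two-state Markov chains with known stationary
## probability, metadynamics hill sets with known wells, pore geometries
## with analytic radius profiles, and two-body interfaces for SASA burial.
##
## Planted geometries sit 0.1 A inside the relevant cutoff so boundary
## behaviour never decides a truth table. Fixtures can be written as
## standard PDB / HILLS text so the real parsers are exercised.

new_atom <- function(serial, name, element, resname, chain, resno, x, y, z,
                     het = FALSE) {
  data.frame(serial = serial, name = name, element = element, alt = "",
             resname = resname, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, occupancy = 1, b = 0, het = het,
             stringsAsFactors = FALSE)
}

# Side-chain + backbone geometry of each planted residue, relative to its
# ligand site origin. The contact atom realizes the target interaction
# 0.1 A inside the cutoff; remaining atoms stack away from the ligand.
planted_residue_atoms <- function(bit) {
  hex <- function(cx, cy, cz, plane) {
    ang <- seq(0, 300, by = 60) * pi / 180
    if (plane == "xy") cbind(cx + 1.4 * cos(ang), cy + 1.4 * sin(ang), cz)
    else cbind(cx, cy + 1.4 * cos(ang), cz + 1.4 * sin(ang))
  }
  res <- switch(bit,
    apolar = list(resname = "ALA",
      names = c("CB"), el = c("C"),
      xyz = rbind(c(0, 0, 4.4)), bbz = 6.5),
    aromatic_f2f = local({
      h <- hex(0, 0, 3.6, "xy")
      list(resname = "PHE",
           names = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB"),
           el = rep("C", 7), xyz = rbind(h, c(0, 0, 5.2)), bbz = 7.5)
    }),
    aromatic_e2f = local({
      h <- hex(0, 0, -3.9, "yz")
      list(resname = "PHE",
           names = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CB"),
           el = rep("C", 7), xyz = rbind(h, c(0, 2.9, -3.9)), bbz = -8.5)
    }),
    hbond_protein_donor = list(resname = "THR",
      names = c("OG1", "CB", "CG2"), el = c("O", "C", "C"),
      xyz = rbind(c(0, 0, 2.9), c(0, 0, 4.4), c(0, 1.4, 4.9)), bbz = 6.5),
    hbond_protein_acceptor = list(resname = "ASN",
      names = c("OD1", "CG", "ND2", "CB"), el = c("O", "C", "N", "C"),
      xyz = rbind(c(0, 0, 2.9), c(0, 0, 4.4), c(0, 1.3, 5.0),
                  c(0, 0, 5.9)), bbz = 8),
    electrostatic_protein_positive = list(resname = "ARG",
      names = c("NH1", "CZ", "NH2", "NE", "CD"), el = c("N", "C", "N", "N",
                                                        "C"),
      xyz = rbind(c(0, 0, 3.8), c(0, 0, 5.1), c(0, 1.2, 5.7),
                  c(0, -1.2, 5.7), c(0, -1.3, 7.1)), bbz = 9),
    electrostatic_protein_negative = list(resname = "GLU",
      names = c("OE2", "CD", "OE1", "CG", "CB"), el = c("O", "C", "O", "C",
                                                        "C"),
      xyz = rbind(c(0, 0, 3.8), c(0, 0, 5.05), c(0, 1.1, 5.6),
                  c(0, -1.1, 6.1), c(0, -1.1, 7.6)), bbz = 9.5),
    water_bridge_1 = list(resname = "THR",
      names = c("OG1", "CB", "CG2"), el = c("O", "C", "C"),
      xyz = rbind(c(0, 0, 5.6), c(0, 0, 7.1), c(0, 1.4, 7.6)), bbz = 9),
    water_bridge_2 = list(resname = "GLU",
      names = c("OE1", "CD", "OE2", "CG", "CB"), el = c("O", "C", "O", "C",
                                                        "C"),
      xyz = rbind(c(0, 0, 8.4), c(0, 0, 9.65), c(0, 1.1, 10.2),
                  c(0, -1.1, 10.7), c(0, -1.1, 12.2)), bbz = 13.5),
    stop("no planted geometry for bit '", bit, "'"))
  res
}

#' Build a complex with one planted instance of each interaction type
#'
#' Emits a multi-chain model: a synthetic ligand (chain L) whose sites are
#' spaced 15 Angstrom apart so interactions cannot cross-talk, one protein
#' residue (chain A) per requested bit placed to satisfy exactly that
#' detector, and water chains (chain W) for the bridge bits. The truth
#' table is the identity pattern over the requested bits.
#'
#' @param interactions bit names to plant (default: all nine, see
#'   [fp_bit_names()]).
#' @param seed RNG seed (reserved for jittered variants; the default
#'   geometry is deterministic).
#' @param dir optional directory; when given, `complex.pdb` and `truth.tsv`
#'   are written there and the paths returned.
#' @return list with `model` (`structure_model`), `topology`
#'   (`ligand_topology` with the fixture's polar/charge template applied),
#'   `truth` (residues x 9 integer matrix) and, with `dir`, `pdb_path` /
#'   `truth_path`.
#' @export
make_planted_complex <- function(interactions = fp_bit_names(), seed = 1,
                                 dir = NULL) {
  bad <- setdiff(interactions, fp_bit_names())
  if (length(bad)) stop("unknown interaction bit(s): ",
                        paste(bad, collapse = ", "))
  site_x <- (match(interactions, fp_bit_names()) - 1) * 15

  # ligand atoms: per-site contact atoms on one hetero residue
  lig <- list()
  lig_polar <- list()
  lig_charges <- c()
  add_lig <- function(name, element, x, y, z, donor = NA, acceptor = NA,
                      charge = 0) {
    lig[[length(lig) + 1]] <<- list(name = name, element = element,
                                    x = x, y = y, z = z)
    if (!is.na(donor))
      lig_polar[[length(lig_polar) + 1]] <<- data.frame(
        name = name, donor = donor, acceptor = acceptor)
    if (charge != 0) lig_charges[name] <<- charge
  }
  for (k in seq_along(interactions)) {
    b <- interactions[k]; x0 <- site_x[k]
    switch(b,
      apolar = {
        add_lig("C1", "C", x0, 0, 0)
        add_lig("C2", "C", x0 + 1.5, 0, 0)
      },
      aromatic_f2f = ,
      aromatic_e2f = {
        if (!any(vapply(lig, function(a) a$name == "N3", logical(1)))) {
          ang <- seq(0, 300, by = 60) * pi / 180
          for (j in seq_along(ang))
            add_lig(paste0("N", j + 2), "N", x0 + 1.4 * cos(ang[j]),
                    1.4 * sin(ang[j]), 0, donor = FALSE, acceptor = FALSE)
        }
      },
      hbond_protein_donor =
        add_lig("O9", "O", x0, 0, 0, donor = FALSE, acceptor = TRUE),
      hbond_protein_acceptor =
        add_lig("N10", "N", x0, 0, 0, donor = TRUE, acceptor = FALSE),
      electrostatic_protein_positive =
        add_lig("O11", "O", x0, 0, 0, donor = FALSE, acceptor = TRUE,
                charge = -1L),
      electrostatic_protein_negative =
        add_lig("N12", "N", x0, 0, 0, donor = TRUE, acceptor = FALSE,
                charge = 1L),
      water_bridge_1 =
        add_lig("N13", "N", x0, 0, 0, donor = TRUE, acceptor = TRUE),
      water_bridge_2 =
        add_lig("N14", "N", x0, 0, 0, donor = TRUE, acceptor = FALSE,
                charge = 1L))
  }
  # aromatic sites share one ring; anchor it at the first aromatic site
  if (any(interactions %in% c("aromatic_f2f", "aromatic_e2f"))) {
    first_ar <- min(site_x[interactions %in% c("aromatic_f2f",
                                               "aromatic_e2f")])
    ring_names <- paste0("N", 3:8)
    for (i in seq_along(lig))
      if (lig[[i]]$name %in% ring_names) {
        j <- match(lig[[i]]$name, ring_names)
        ang <- (j - 1) * 60 * pi / 180
        lig[[i]]$x <- first_ar + 1.4 * cos(ang)
      }
  }

  rows <- list(); serial <- 0L
  for (l in lig) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- new_atom(serial, l$name, l$element, "LIG",
                                         "L", 901L, l$x, l$y, l$z,
                                         het = TRUE)
  }
  n_lig <- serial
  conect <- NULL
  nm <- vapply(lig, `[[`, "", "name")
  if (all(c("C1", "C2") %in% nm))
    conect <- rbind(conect, c(match("C1", nm), match("C2", nm)))
  if (all(paste0("N", 3:8) %in% nm)) {
    ring_i <- match(paste0("N", 3:8), nm)
    conect <- rbind(conect, cbind(ring_i, ring_i[c(2:6, 1)]))
  }

  # protein residues, one per bit, chain A
  for (k in seq_along(interactions)) {
    b <- interactions[k]; x0 <- site_x[k]
    g <- planted_residue_atoms(b)
    # aromatic residues anchor to the shared ring site
    if (b %in% c("aromatic_f2f", "aromatic_e2f"))
      x0 <- min(site_x[interactions %in% c("aromatic_f2f", "aromatic_e2f")])
    for (j in seq_along(g$names)) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- new_atom(
        serial, g$names[j], g$el[j], g$resname, "A", k,
        x0 + g$xyz[j, 1], g$xyz[j, 2], g$xyz[j, 3])
    }
    # minimal backbone stub stacked beyond the side chain
    zb <- g$bbz
    bb <- rbind(c(0, 0, zb), c(1.3, 0.8, zb), c(-1.3, 0.8, zb),
                c(-1.5, 2.0, zb))
    bn <- c("CA", "N", "C", "O"); be <- c("C", "N", "C", "O")
    for (j in 1:4) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- new_atom(
        serial, bn[j], be[j], g$resname, "A", k,
        x0 + bb[j, 1], bb[j, 2], bb[j, 3])
    }
  }

  # waters for bridge sites, chain W
  wat_no <- 500L
  add_water <- function(x, y, z) {
    serial <<- serial + 1L; wat_no <<- wat_no + 1L
    rows[[length(rows) + 1]] <<- new_atom(serial, "O", "O", "HOH", "W",
                                          wat_no, x, y, z, het = TRUE)
  }
  if ("water_bridge_1" %in% interactions)
    add_water(site_x[match("water_bridge_1", interactions)], 0, 2.8)
  if ("water_bridge_2" %in% interactions) {
    x0 <- site_x[match("water_bridge_2", interactions)]
    add_water(x0, 0, 2.8)
    add_water(x0, 0, 5.6)
  }

  atoms <- do.call(rbind, rows)
  model <- structure_model(atoms, conect = if (!is.null(conect))
    cbind(atoms$serial[conect[, 1]], atoms$serial[conect[, 2]]) else NULL)

  polar <- if (length(lig_polar)) do.call(rbind, lig_polar) else NULL
  topology <- suppressWarnings(infer_ligand_topology(
    model, "L", 901L,
    charges = if (length(lig_charges)) lig_charges else NULL,
    polar = polar))

  truth <- matrix(0L, length(interactions), 9,
                  dimnames = list(NULL, fp_bit_names()))
  resnames <- vapply(interactions, function(b)
    planted_residue_atoms(b)$resname, "")
  rownames(truth) <- paste("A", seq_along(interactions), resnames,
                           sep = ":")
  for (k in seq_along(interactions)) truth[k, interactions[k]] <- 1L

  out <- list(model = model, topology = topology, truth = truth,
              polar = polar,
              charges = if (length(lig_charges)) lig_charges else NULL)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$pdb_path <- file.path(dir, "complex.pdb")
    write_structure(model, out$pdb_path)
    out$truth_path <- file.path(dir, "truth.tsv")
    utils::write.table(cbind(residue = rownames(truth),
                             as.data.frame(truth)),
                       out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Simulate a two-state Markov chain
#'
#' @param p01,p10 transition probabilities 0->1 and 1->0, in (0, 1).
#' @param length series length.
#' @param seed RNG seed.
#' @return list with `values` (0/1 integer vector) and `truth`, the
#'   stationary probability p01 / (p01 + p10). The chain starts from its
#'   stationary law.
#' @export
make_markov_series <- function(p01, p10, length = 1000L, seed = 1) {
  stopifnot(p01 > 0, p01 < 1, p10 > 0, p10 < 1, length >= 2)
  set.seed(as.integer(seed))
  pi1 <- p01 / (p01 + p10)
  x <- integer(length)
  u <- stats::runif(length)
  x[1] <- as.integer(u[1] < pi1)
  for (t in 2:length) {
    p_up <- if (x[t - 1] == 0L) p01 else 1 - p10
    x[t] <- as.integer(u[t] < p_up)
  }
  list(values = x, truth = pi1)
}

#' Generate synthetic metadynamics hill sets with planted wells
#'
#' Each pose gets `n_replicates` HILLS files whose reconstructed
#' free-energy profile has its dominant well at the pose's stated centre:
#' hill centres are drawn around the well (spread `center_spread`), with a
#' small replicate-to-replicate jitter of the well position emulating
#' independent runs. Defaults mirror a 10 ns deposition at 4 ps stride:
#' 2500 hills of height 0.21 kJ/mol and width 0.2 Angstrom (0.02 nm).
#'
#' @param well_centers named numeric vector: pose id -> well centre
#'   (Angstrom).
#' @param n_replicates replicates per pose.
#' @param n_hills hills per replicate.
#' @param height hill height, kJ/mol.
#' @param sigma hill width, Angstrom.
#' @param stride_ps deposition stride, ps.
#' @param center_spread sd of hill centres around the well, Angstrom.
#' @param replicate_jitter sd of the per-replicate well shift, Angstrom.
#' @param seed RNG seed (same seed -> byte-identical files).
#' @param dir optional output directory for HILLS files.
#' @return list with `hills` (pose -> list of hill data.frames), `truth`
#'   (well centres) and, with `dir`, `paths` (pose -> file vector).
#' @export
make_hills_set <- function(well_centers, n_replicates = 10L,
                           n_hills = 2500L, height = 0.21, sigma = 0.2,
                           stride_ps = 4, center_spread = 0.05,
                           replicate_jitter = 0.01, seed = 1, dir = NULL) {
  stopifnot(!is.null(names(well_centers)), all(nzchar(names(well_centers))))
  set.seed(as.integer(seed))
  hills <- list(); paths <- list()
  for (pose in names(well_centers)) {
    hills[[pose]] <- vector("list", n_replicates)
    pp <- character(n_replicates)
    for (rep in seq_len(n_replicates)) {
      centre <- well_centers[[pose]] +
        if (replicate_jitter > 0) stats::rnorm(1, 0, replicate_jitter) else 0
      cv <- stats::rnorm(n_hills, centre, center_spread)
      h <- data.frame(time = seq_len(n_hills) * stride_ps, center = cv,
                      sigma = sigma, height = height)
      class(h) <- c("hills", "data.frame")
      hills[[pose]][[rep]] <- h
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        p <- file.path(dir, sprintf("hills_%s_rep%02d.dat", pose, rep))
        writeLines(c("#! FIELDS time cv sigma_cv height",
                     sprintf("%12.3f %14.9f %10.6f %10.6f", h$time,
                             h$center, h$sigma, h$height)), p)
        pp[rep] <- p
      }
    }
    if (!is.null(dir)) paths[[pose]] <- pp
  }
  out <- list(hills = hills, truth = well_centers)
  if (!is.null(dir)) out$paths <- paths
  out
}

#' Generate a pore geometry with an analytically known radius profile
#'
#' Stacks rings of carbon atoms along z realizing a requested ring-radius
#' function; the true pore radius at each ring plane is
#' `ring_radius(z) - vdw`.
#'
#' @param kind `"cylinder"`, `"hourglass"`, or `"custom"` (supply
#'   `radius_fun`).
#' @param length extent along z, Angstrom (centred on 0).
#' @param ring_radius cylinder radius / hourglass mouth radius, Angstrom.
#' @param waist_radius hourglass waist radius.
#' @param ring_spacing z distance between rings.
#' @param atoms_per_ring atoms per ring.
#' @param radius_fun optional function(z) -> ring radius, for
#'   `kind = "custom"`.
#' @param dir optional directory to write `pore.pdb`.
#' @return list with `model`, `truth` (data.frame `z`, `radius`) and, with
#'   `dir`, `pdb_path`.
#' @export
make_pore_shape <- function(kind = c("cylinder", "hourglass", "custom"),
                            length = 30, ring_radius = 6, waist_radius = 4,
                            ring_spacing = 0.5, atoms_per_ring = 12L,
                            radius_fun = NULL, dir = NULL) {
  kind <- match.arg(kind)
  half <- length / 2
  zs <- seq(-half, half, by = ring_spacing)
  rf <- switch(kind,
    cylinder = function(z) rep(ring_radius, base::length(z)),
    hourglass = function(z)
      waist_radius + (ring_radius - waist_radius) * (z / half)^2,
    custom = {
      if (is.null(radius_fun)) stop("kind 'custom' needs radius_fun")
      radius_fun
    })
  rr <- rf(zs)
  vdw <- vdw_radius("C")
  if (any(rr <= vdw)) stop("ring radius must exceed the atom vdW radius")
  rows <- list(); serial <- 0L
  ang0 <- seq(0, 2 * pi, length.out = atoms_per_ring + 1)[-(atoms_per_ring +
                                                              1)]
  for (i in seq_along(zs)) {
    # stagger alternate rings to avoid axial grooves
    ang <- ang0 + (i %% 2) * pi / atoms_per_ring
    for (j in seq_len(atoms_per_ring)) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- new_atom(
        serial, "CA", "C", "GLY", "M", serial,
        rr[i] * cos(ang[j]), rr[i] * sin(ang[j]), zs[i])
    }
  }
  model <- structure_model(do.call(rbind, rows))
  # Exact on-axis pore radius of the stacked-ring geometry: the probe at
  # height z touches whichever ring minimizes sqrt(r_k^2 + (z - z_k)^2)
  # (equals ring_radius(z) - vdw wherever the wall is locally cylindrical,
  # e.g. everywhere for the cylinder and at the hourglass waist).
  truth_r <- vapply(zs, function(z)
    min(sqrt(rr^2 + (z - zs)^2)) - vdw, numeric(1))
  out <- list(model = model,
              truth = data.frame(z = zs, radius = truth_r,
                                 ring_radius = rr))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$pdb_path <- file.path(dir, "pore.pdb")
    write_structure(model, out$pdb_path)
  }
  out
}

helix_xyz <- function(n, radius = 2.3, rise = 1.5, twist = 100) {
  t <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(t), radius * sin(t), (seq_len(n) - 1) * rise)
}

#' Generate a two-chain interface at controlled separation
#'
#' Two identical Calpha-trace helices (chains A and B) offset along x.
#' Large separations give zero burial; touching helices give a finite
#' buried area to be checked against a fine-sampling oracle.
#'
#' @param separation x offset between the chains, Angstrom.
#' @param n_res residues per helix.
#' @param dir optional directory to write `interface.pdb`.
#' @return list with `model` and, with `dir`, `pdb_path`.
#' @export
make_interface_pair <- function(separation = 6, n_res = 12L, dir = NULL) {
  h <- helix_xyz(n_res)
  rows <- list(); serial <- 0L
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else separation
    for (i in seq_len(n_res)) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- new_atom(
        serial, "CA", "C", "GLY", ch, i,
        h[i, 1] + off, h[i, 2], h[i, 3])
    }
  }
  model <- structure_model(do.call(rbind, rows))
  out <- list(model = model)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$pdb_path <- file.path(dir, "interface.pdb")
    write_structure(model, out$pdb_path)
  }
  out
}
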