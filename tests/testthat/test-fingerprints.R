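# builds a one-residue ligand topology from (name, element, x, y, z) rows
toy_ligand <- function(df, charges = NULL, polar = NULL) {
  rows <- lapply(seq_len(nrow(df)), function(i)
    atom_row(i, df$name[i], df$element[i], "LIG", "L", 9,
             df$x[i], df$y[i], df$z[i], het = TRUE))
  m <- structure_model(do.call(rbind, rows))
  suppressWarnings(infer_ligand_topology(m, "L", 9, charges = charges,
                                         polar = polar))
}

lig_df <- function(...) {
  v <- list(...)
  data.frame(name = vapply(v, `[[`, "", 1),
             element = vapply(v, `[[`, "", 2),
             x = as.numeric(vapply(v, `[[`, "", 3)),
             y = as.numeric(vapply(v, `[[`, "", 4)),
             z = as.numeric(vapply(v, `[[`, "", 5)),
             stringsAsFactors = FALSE)
}

test_that("apolar detector honours the 4.5 A carbon-carbon cutoff", {
  lig <- toy_ligand(lig_df(c("C1", "C", 0, 0, 0)))
  res_in <- atom_row(1, "CB", "C", "ALA", "A", 1, 4.4, 0, 0)
  res_out <- atom_row(1, "CB", "C", "ALA", "A", 1, 4.6, 0, 0)
  expect_equal(detect_apolar(res_in, lig), 1L)
  expect_equal(detect_apolar(res_out, lig), 0L)
  # a nitrogen at contact distance is not an apolar partner
  res_n <- atom_row(1, "ND2", "N", "ASN", "A", 1, 3.0, 0, 0)
  expect_equal(detect_apolar(res_n, lig), 0L)
})

test_that("apolar detector equals the all-pairs oracle on random systems", {
  set.seed(11)
  for (rep in 1:20) {
    nl <- sample(5:25, 1); nr <- sample(5:25, 1)
    ldf <- data.frame(name = paste0("X", seq_len(nl)),
                      element = sample(c("C", "N", "O"), nl, replace = TRUE),
                      x = runif(nl, 0, 8), y = runif(nl, 0, 8),
                      z = runif(nl, 0, 8))
    lig <- toy_ligand(ldf)
    res <- do.call(rbind, lapply(seq_len(nr), function(i)
      atom_row(i, paste0("CB", i),
               sample(c("C", "N", "O"), 1), "ALA", "A", 1,
               runif(1, 0, 12), runif(1, 0, 12), runif(1, 0, 12))))
    expect_equal(detect_apolar(res, lig), oracle_apolar(res, lig$atoms))
  }
})

phe_ring <- function(centroid, normal = c(0, 0, 1)) {
  # hexagon of CG..CD2 about `centroid`, plane orthogonal to `normal`
  b <- lgicsa:::plane_basis(normal)
  ang <- seq(0, 300, by = 60) * pi / 180
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  do.call(rbind, lapply(seq_along(ang), function(i) {
    p <- centroid + 1.4 * (cos(ang[i]) * b$e1 + sin(ang[i]) * b$e2)
    atom_row(i, nm[i], "C", "PHE", "A", 1, p[1], p[2], p[3])
  }))
}

test_that("aromatic detector separates stacked, T-shaped and distant rings", {
  ang <- seq(0, 300, by = 60) * pi / 180
  lig <- toy_ligand(lig_df(
    c("N1", "N", 1.4 * cos(ang[1]), 1.4 * sin(ang[1]), 0),
    c("N2", "N", 1.4 * cos(ang[2]), 1.4 * sin(ang[2]), 0),
    c("N3", "N", 1.4 * cos(ang[3]), 1.4 * sin(ang[3]), 0),
    c("N4", "N", 1.4 * cos(ang[4]), 1.4 * sin(ang[4]), 0),
    c("N5", "N", 1.4 * cos(ang[5]), 1.4 * sin(ang[5]), 0),
    c("N6", "N", 1.4 * cos(ang[6]), 1.4 * sin(ang[6]), 0)))
  expect_true(any(lig$aromatic))
  # parallel stack 3.6 A above: face-to-face
  expect_equal(detect_aromatic(phe_ring(c(0, 0, 3.6)), lig), c(1L, 0L))
  # perpendicular ring, centroid 3.9 A away: edge-to-face
  expect_equal(detect_aromatic(phe_ring(c(0, 0, -3.9), normal = c(1, 0, 0)),
                               lig), c(0L, 1L))
  # parallel but centroids at 4.3 A: outside the cutoff
  expect_equal(detect_aromatic(phe_ring(c(0, 0, 4.3)), lig), c(0L, 0L))
  # 45-degree tilt: neither window
  tilt <- c(sin(pi / 4), 0, cos(pi / 4))
  expect_equal(detect_aromatic(phe_ring(c(0, 0, 3.6), normal = tilt), lig),
               c(0L, 0L))
})

test_that("hydrogen-bond detector applies distance, angle and direction", {
  # ligand carbonyl-like O, acceptor only
  lig_acc <- toy_ligand(lig_df(c("O1", "O", 0, 0, 0)),
                        polar = data.frame(name = "O1", donor = FALSE,
                                           acceptor = TRUE))
  thr <- function(og1_z, cb_z) rbind(
    atom_row(1, "OG1", "O", "THR", "A", 1, 0, 0, og1_z),
    atom_row(2, "CB", "C", "THR", "A", 1, 0, 0, cb_z),
    atom_row(3, "CG2", "C", "THR", "A", 1, 0, 1.4, cb_z + 0.5))
  expect_equal(detect_hbond(thr(2.9, 4.4), lig_acc), c(1L, 0L))
  expect_equal(detect_hbond(thr(3.7, 5.2), lig_acc), c(0L, 0L))
  # antecedent on the ligand side of the donor: angle < 90, no bond
  bad <- rbind(atom_row(1, "OG1", "O", "THR", "A", 1, 0, 0, 2.9),
               atom_row(2, "CB", "C", "THR", "A", 1, 0, 0.9, 1.7))
  expect_equal(detect_hbond(bad, lig_acc), c(0L, 0L))
  # ligand protonated N donating to Glu OE1: protein is the acceptor
  lig_don <- toy_ligand(lig_df(c("N1", "N", 0, 0, 0)),
                        polar = data.frame(name = "N1", donor = TRUE,
                                           acceptor = FALSE),
                        charges = c(N1 = 1L))
  glu <- rbind(atom_row(1, "OE1", "O", "GLU", "A", 1, 0, 0, 2.9),
               atom_row(2, "CD", "C", "GLU", "A", 1, 0, 0, 4.15),
               atom_row(3, "OE2", "O", "GLU", "A", 1, 0, 1.1, 4.7))
  expect_equal(detect_hbond(glu, lig_don), c(0L, 1L))
})

test_that("electrostatic detector needs opposite charges within 4 A", {
  lig_pos <- toy_ligand(lig_df(c("N1", "N", 0, 0, 0)), charges = c(N1 = 1L))
  glu <- function(z) rbind(
    atom_row(1, "OE2", "O", "GLU", "A", 1, 0, 0, z),
    atom_row(2, "CD", "C", "GLU", "A", 1, 0, 0, z + 1.25),
    atom_row(3, "OE1", "O", "GLU", "A", 1, 0, 1.1, z + 1.8))
  expect_equal(detect_electrostatic(glu(3.5), lig_pos), c(0L, 1L))
  expect_equal(detect_electrostatic(glu(4.2), lig_pos), c(0L, 0L))
  # arginine near a neutral ligand atom: nothing fires
  lig_neutral <- toy_ligand(lig_df(c("N1", "N", 0, 0, 0)),
                            charges = c(N1 = 0L))
  arg <- rbind(atom_row(1, "NH1", "N", "ARG", "A", 1, 0, 0, 3.5),
               atom_row(2, "CZ", "C", "ARG", "A", 1, 0, 0, 4.8))
  expect_equal(detect_electrostatic(arg, lig_neutral), c(0L, 0L))
  # arginine near a negative ligand atom: protein-positive bit
  lig_neg <- toy_ligand(lig_df(c("O1", "O", 0, 0, 0)), charges = c(O1 = -1L))
  expect_equal(detect_electrostatic(arg, lig_neg), c(1L, 0L))
})

test_that("water bridges match the exhaustive path-search oracle", {
  thr <- rbind(atom_row(1, "OG1", "O", "THR", "A", 1, 0, 0, 5.6),
               atom_row(2, "CB", "C", "THR", "A", 1, 0, 0, 7.1))
  lig <- toy_ligand(lig_df(c("N1", "N", 0, 0, 0)))
  water_rows <- function(xyz) do.call(rbind, lapply(seq_len(nrow(xyz)),
    function(i) atom_row(i, "O", "O", "HOH", "W", 500 + i,
                         xyz[i, 1], xyz[i, 2], xyz[i, 3], het = TRUE)))
  # planted single bridge
  expect_equal(detect_water_bridges(thr, lig, water_rows(rbind(c(0, 0, 2.8)))),
               c(1L, 0L))
  # planted two-water chain, no single-water path
  thr2 <- rbind(atom_row(1, "OG1", "O", "THR", "A", 1, 0, 0, 8.4),
                atom_row(2, "CB", "C", "THR", "A", 1, 0, 0, 9.9))
  expect_equal(detect_water_bridges(
    thr2, lig, water_rows(rbind(c(0, 0, 2.8), c(0, 0, 5.6)))), c(0L, 1L))
  # random 30-water boxes against the brute-force enumeration
  set.seed(23)
  for (rep in 1:15) {
    w <- cbind(runif(30, -3, 3), runif(30, -3, 3), runif(30, 0, 9))
    got <- detect_water_bridges(thr, lig, water_rows(w))
    want <- oracle_water_bridges(og1 = c(0, 0, 5.6), cb = c(0, 0, 7.1),
                                 lig_polar_xyz = rbind(c(0, 0, 0)),
                                 water_xyz = w)
    expect_equal(got, want)
  }
})

test_that("the planted nine-interaction complex yields the identity matrix", {
  pc <- make_planted_complex()
  fpm <- compute_fingerprint_matrix(pc$model, "L", 901,
                                    topology = pc$topology)
  expect_equal(dim(fpm), c(9L, 1L, 9L))
  got <- fpm[, 1, ]
  expect_identical(unname(got), unname(pc$truth))
  expect_equal(rownames(got), rownames(pc$truth))
})

test_that("identical frames give identical fingerprint columns", {
  pc <- make_planted_complex()
  fs <- frame_series(list(pc$model, pc$model, pc$model))
  fpm <- compute_fingerprint_matrix(fs, "L", 901, topology = pc$topology)
  expect_equal(fpm[, 1, ], fpm[, 2, ])
  expect_equal(fpm[, 1, ], fpm[, 3, ])
})

test_that("the pre-screen is a pure optimization", {
  pc <- make_planted_complex()
  on <- compute_fingerprint_matrix(pc$model, "L", 901,
                                   topology = pc$topology,
                                   config = fp_config(prescreen = TRUE))
  off <- compute_fingerprint_matrix(pc$model, "L", 901,
                                    topology = pc$topology,
                                    config = fp_config(prescreen = FALSE))
  expect_identical(unclass(on)[, , ], unclass(off)[, , ])
  # jittered variants
  set.seed(5)
  for (rep in 1:3) {
    m <- pc$model
    jit <- matrix(rnorm(3, 0, 0.05), 1)
    m$atoms$x <- m$atoms$x + jit[1]
    m$atoms$y <- m$atoms$y + jit[2]
    m$atoms$z <- m$atoms$z + jit[3]
    a <- compute_fingerprint_matrix(m, "L", 901, topology = pc$topology,
                                    config = fp_config(prescreen = TRUE))
    b <- compute_fingerprint_matrix(m, "L", 901, topology = pc$topology,
                                    config = fp_config(prescreen = FALSE))
    expect_identical(unclass(a)[, , ], unclass(b)[, , ])
  }
})

test_that("fingerprints are invariant under global rigid motion", {
  pc <- make_planted_complex()
  ref <- compute_fingerprint_matrix(pc$model, "L", 901,
                                    topology = pc$topology)
  set.seed(7)
  for (rep in 1:3) {
    m <- transform_model(pc$model, random_rotation(), rnorm(3, 0, 20))
    got <- compute_fingerprint_matrix(m, "L", 901, topology = pc$topology)
    expect_identical(unclass(got)[, , ], unclass(ref)[, , ])
  }
})

test_that("enlarging cutoffs can only turn bits on", {
  pc <- make_planted_complex()
  base <- compute_fingerprint_matrix(pc$model, "L", 901,
                                     topology = pc$topology)
  wide <- compute_fingerprint_matrix(
    pc$model, "L", 901, topology = pc$topology,
    config = fp_config(apolar_cutoff = 5.5, aromatic_cutoff = 5,
                       hbond_cutoff = 4.5, elec_cutoff = 5,
                       f2f_max_angle = 40, e2f_min_angle = 50))
  expect_true(all(unclass(wide)[, , ] >= unclass(base)[, , ]))
})

test_that("fingerprint TSV serialization round-trips", {
  pc <- make_planted_complex()
  fs <- frame_series(list(pc$model, pc$model))
  fpm <- compute_fingerprint_matrix(fs, "L", 901, topology = pc$topology)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fpm, p)
  back <- read_fingerprints(p)
  expect_equal(unclass(back)[, , ], unclass(fpm)[, , ],
               ignore_attr = TRUE)
  expect_equal(dimnames(back)[[1]], dimnames(fpm)[[1]])
  expect_equal(dimnames(back)[[3]], fp_bit_names())
})

test_that("frames without waters report zero bridge bits with a notice", {
  pc <- make_planted_complex(c("apolar", "water_bridge_1"))
  m <- pc$model
  keep <- m$atoms$resname != "HOH"
  m2 <- structure_model(m$atoms[keep, , drop = FALSE], conect = m$conect)
  expect_message(
    fpm <- compute_fingerprint_matrix(m2, "L", 901, topology = pc$topology),
    "no waters")
  expect_equal(sum(fpm[, , c("water_bridge_1", "water_bridge_2")]), 0)
})
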