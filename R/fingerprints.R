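## Per-residue, per-frame 9-bit protein-ligand interaction fingerprints.
##
## Bit order (fixed; serialization preserves it):
##   1 apolar                         carbon-carbon contact <= 4.5 A
##   2 aromatic_f2f                   ring stacking, centroids <= 4 A,
##                                    inter-normal angle <= 30 deg
##   3 aromatic_e2f                   T-shaped rings, angle >= 60 deg
##   4 hbond_protein_donor            heavy-atom H-bond, protein donates
##   5 hbond_protein_acceptor         heavy-atom H-bond, protein accepts
##   6 electrostatic_protein_positive protein + group near ligand - charge
##   7 electrostatic_protein_negative protein - group near ligand + charge
##   8 water_bridge_1                 one-water-mediated H-bond bridge
##   9 water_bridge_2                 two-water-mediated H-bond bridge
##
## All criteria are heavy-atom-only (cryo-EM models carry no hydrogens);
## distances compare with <= at the cutoff so boundary cases are
## reproducible. Protein side is restricted to side-chain atoms.

#' Canonical fingerprint bit names, in order
#' @export
fp_bit_names <- function() c(
  "apolar", "aromatic_f2f", "aromatic_e2f",
  "hbond_protein_donor", "hbond_protein_acceptor",
  "electrostatic_protein_positive", "electrostatic_protein_negative",
  "water_bridge_1", "water_bridge_2")

#' Fingerprint configuration
#'
#' All cutoffs in Angstrom, angles in degrees. Defaults: 4.5 A apolar, 4 A
#' aromatic and electrostatic, heavy-atom H-bond 3.5 A with a >= 90 degree
#' antecedent-donor-acceptor angle when the antecedent is known;
#' face-to-face <= 30 deg, edge-to-face >= 60 deg (inter-normal angle folded
#' to \[0, 90\]). Pre-screen radii: 6.5 A for direct bits, 9.5 A for
#' water-bridge bits (H-bond cutoff + maximum two-water span).
#'
#' @param apolar_cutoff,aromatic_cutoff,hbond_cutoff,elec_cutoff distance
#'   cutoffs, Angstrom.
#' @param f2f_max_angle,e2f_min_angle aromatic angle windows, degrees.
#' @param hbond_min_angle minimum antecedent-donor-acceptor angle, degrees.
#' @param prescreen logical; skip residues far from the ligand (pure
#'   optimization, result-identical by construction).
#' @param prescreen_direct,prescreen_bridge pre-screen radii, Angstrom.
#' @param his_protonated treat histidine as positively charged.
#' @return named list of settings.
#' @export
fp_config <- function(apolar_cutoff = 4.5, aromatic_cutoff = 4.0,
                      f2f_max_angle = 30, e2f_min_angle = 60,
                      hbond_cutoff = 3.5, hbond_min_angle = 90,
                      elec_cutoff = 4.0, prescreen = TRUE,
                      prescreen_direct = 6.5, prescreen_bridge = 9.5,
                      his_protonated = FALSE) {
  as.list(environment())
}

min_dist <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

xyz_of <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

# angle at `at` between directions to `a` and `b`, degrees
atom_angle <- function(a, at, b) {
  u <- a - at; v <- b - at
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Apolar-contact detector
#'
#' Fires when any side-chain carbon lies within the apolar cutoff of any
#' ligand carbon ("non-polar atoms" are carbons; sulfur is excluded).
#'
#' @param res_atoms data.frame of side-chain heavy atoms.
#' @param ligand a `ligand_topology`.
#' @param config a [fp_config()] list.
#' @return 0 or 1.
#' @export
detect_apolar <- function(res_atoms, ligand, config = fp_config()) {
  rc <- res_atoms[res_atoms$element == "C", , drop = FALSE]
  lc <- ligand$atoms[ligand$atoms$element == "C", , drop = FALSE]
  as.integer(min_dist(xyz_of(rc), xyz_of(lc)) <= config$apolar_cutoff)
}

ring_geometry <- function(xyz) {
  cen <- colMeans(xyz)
  sv <- svd(scale(xyz, scale = FALSE))
  list(centroid = cen, normal = sv$v[, 3])
}

# Side-chain aromatic rings of one residue, as coordinate matrices.
residue_ring_xyz <- function(res_atoms) {
  tpl <- .protein_rings[[toupper(res_atoms$resname[1])]]
  if (is.null(tpl)) return(list())
  out <- list()
  for (names_i in tpl) {
    pos <- match(names_i, res_atoms$name)
    if (!anyNA(pos)) out[[length(out) + 1]] <- xyz_of(res_atoms[pos, ,
                                                                drop = FALSE])
  }
  out
}

#' Aromatic interaction detector
#'
#' For every protein-ring/ligand-aromatic-ring pair whose centroids are
#' within the aromatic cutoff, the inter-normal angle (folded to
#' \[0, 90\] degrees) classifies the geometry: face-to-face when at most
#' `f2f_max_angle`, edge-to-face when at least `e2f_min_angle`; in-between
#' angles set neither bit.
#'
#' @inheritParams detect_apolar
#' @return integer vector `c(f2f, e2f)`.
#' @export
detect_aromatic <- function(res_atoms, ligand, config = fp_config()) {
  pr <- residue_ring_xyz(res_atoms)
  lr <- ligand$rings[ligand$aromatic]
  f2f <- e2f <- 0L
  if (length(pr) && length(lr)) {
    lxyz <- xyz_of(ligand$atoms)
    for (p in pr) {
      gp <- ring_geometry(p)
      for (r in lr) {
        gl <- ring_geometry(lxyz[r, , drop = FALSE])
        if (sqrt(sum((gp$centroid - gl$centroid)^2)) <=
              config$aromatic_cutoff) {
          ang <- acos(pmin(1, abs(sum(gp$normal * gl$normal)))) * 180 / pi
          if (ang <= config$f2f_max_angle) f2f <- 1L
          if (ang >= config$e2f_min_angle) e2f <- 1L
        }
      }
    }
  }
  c(f2f, e2f)
}

# protein side-chain H-bond chemistry rows for one residue
residue_polar <- function(res_atoms) {
  tpl <- .hbond_templates
  hit <- tpl[tpl$resname == toupper(res_atoms$resname[1]), , drop = FALSE]
  hit[hit$atom %in% res_atoms$name, , drop = FALSE]
}

# Heavy-atom H-bond predicate between a protein polar atom (row of the
# template join) and a partner position. Direction-aware: when the protein
# atom donates, its antecedent-donor-acceptor angle must be >= min_angle;
# when the ligand donates, each of the ligand atom's bonded neighbors is
# tried as antecedent (no neighbors -> distance-only).
hbond_geom_ok <- function(d_xyz, a_xyz, ante_xyz, min_angle) {
  if (is.null(ante_xyz)) return(TRUE)
  any(apply(ante_xyz, 1, function(an) atom_angle(an, d_xyz, a_xyz) >=
              min_angle))
}

ligand_antecedents <- function(ligand, i) {
  nb <- c(ligand$bonds[ligand$bonds[, 1] == i, 2],
          ligand$bonds[ligand$bonds[, 2] == i, 1])
  if (!length(nb)) return(NULL)
  xyz_of(ligand$atoms[nb, , drop = FALSE])
}

#' Hydrogen-bond detector (heavy-atom criterion)
#'
#' Donor-heavy to acceptor-heavy distance at most `hbond_cutoff`, plus the
#' antecedent-donor-acceptor angle test when the donor's antecedent heavy
#' atom is known. The direction (protein donates vs accepts) decides which
#' bit fires.
#'
#' @inheritParams detect_apolar
#' @return integer vector `c(protein_donor, protein_acceptor)`.
#' @export
detect_hbond <- function(res_atoms, ligand, config = fp_config()) {
  pol <- residue_polar(res_atoms)
  don <- acc <- 0L
  if (!nrow(pol)) return(c(don, acc))
  lig <- ligand$atoms
  for (k in seq_len(nrow(pol))) {
    p_i <- match(pol$atom[k], res_atoms$name)
    p_xyz <- as.numeric(xyz_of(res_atoms[p_i, , drop = FALSE]))
    a_i <- match(pol$antecedent[k], res_atoms$name)
    ante <- if (is.na(a_i)) NULL else
      xyz_of(res_atoms[a_i, , drop = FALSE])
    for (j in seq_len(nrow(lig))) {
      l_xyz <- as.numeric(xyz_of(lig[j, , drop = FALSE]))
      if (sqrt(sum((p_xyz - l_xyz)^2)) > config$hbond_cutoff) next
      if (pol$donor[k] && ligand$acceptor[j] &&
            hbond_geom_ok(p_xyz, l_xyz, ante, config$hbond_min_angle))
        don <- 1L
      if (pol$acceptor[k] && ligand$donor[j] &&
            hbond_geom_ok(l_xyz, p_xyz, ligand_antecedents(ligand, j),
                          config$hbond_min_angle))
        acc <- 1L
      if (don && acc) return(c(don, acc))
    }
  }
  c(don, acc)
}

charged_atoms <- function(res_atoms, sign, his_protonated = FALSE) {
  rn <- toupper(res_atoms$resname[1])
  tpl <- .charged_templates[[sign]][[rn]]
  if (sign == "positive" && his_protonated)
    tpl <- c(tpl, .charged_templates$positive_his[[rn]])
  if (is.null(tpl)) return(res_atoms[0, , drop = FALSE])
  res_atoms[res_atoms$name %in% tpl, , drop = FALSE]
}

#' Electrostatic interaction detector
#'
#' A bit fires when any formally charged protein side-chain atom lies within
#' the electrostatic cutoff of an oppositely charged ligand atom.
#'
#' @inheritParams detect_apolar
#' @return integer vector `c(protein_positive, protein_negative)`.
#' @export
detect_electrostatic <- function(res_atoms, ligand, config = fp_config()) {
  lig <- ligand$atoms
  lpos <- xyz_of(lig[ligand$formal_charges > 0, , drop = FALSE])
  lneg <- xyz_of(lig[ligand$formal_charges < 0, , drop = FALSE])
  ppos <- xyz_of(charged_atoms(res_atoms, "positive", config$his_protonated))
  pneg <- xyz_of(charged_atoms(res_atoms, "negative"))
  c(as.integer(min_dist(ppos, lneg) <= config$elec_cutoff),
    as.integer(min_dist(pneg, lpos) <= config$elec_cutoff))
}

# H-bond test between a water oxygen and a polar atom row; the polar side's
# antecedent geometry is honoured when known, waters are antecedent-free.
water_polar_hb <- function(w_xyz, p_xyz, ante, config) {
  if (sqrt(sum((w_xyz - p_xyz)^2)) > config$hbond_cutoff) return(FALSE)
  hbond_geom_ok(p_xyz, w_xyz, ante, config$hbond_min_angle)
}

#' Water-mediated bridge detector
#'
#' `water_bridge_1` fires when a single water oxygen is hydrogen-bonded
#' (same heavy-atom rule as [detect_hbond()]) to at least one ligand polar
#' atom and at least one residue side-chain polar atom. `water_bridge_2`
#' fires when a chain ligand - w1 - w2 - residue of consecutive hydrogen
#' bonds exists with two distinct waters.
#'
#' @inheritParams detect_apolar
#' @param waters data.frame of water oxygen atoms in the frame.
#' @return integer vector `c(one_water, two_water)`.
#' @export
detect_water_bridges <- function(res_atoms, ligand, waters,
                                 config = fp_config()) {
  if (is.null(waters) || !nrow(waters)) return(c(0L, 0L))
  pol <- residue_polar(res_atoms)
  lsel <- which(ligand$donor | ligand$acceptor)
  if (!nrow(pol) || !length(lsel)) return(c(0L, 0L))
  wxyz <- xyz_of(waters)
  lxyz <- xyz_of(ligand$atoms)

  lig_ok <- vapply(seq_len(nrow(wxyz)), function(w) {
    any(vapply(lsel, function(j)
      water_polar_hb(wxyz[w, ], lxyz[j, ], ligand_antecedents(ligand, j),
                     config), logical(1)))
  }, logical(1))
  res_ok <- vapply(seq_len(nrow(wxyz)), function(w) {
    any(vapply(seq_len(nrow(pol)), function(k) {
      p_i <- match(pol$atom[k], res_atoms$name)
      a_i <- match(pol$antecedent[k], res_atoms$name)
      ante <- if (is.na(a_i)) NULL else xyz_of(res_atoms[a_i, , drop = FALSE])
      water_polar_hb(wxyz[w, ], as.numeric(xyz_of(res_atoms[p_i, ,
                                                            drop = FALSE])),
                     ante, config)
    }, logical(1)))
  }, logical(1))

  one <- as.integer(any(lig_ok & res_ok))
  two <- 0L
  w1s <- which(lig_ok); w2s <- which(res_ok)
  if (length(w1s) && length(w2s)) {
    for (w1 in w1s) {
      dd <- sqrt(rowSums((wxyz[w2s, , drop = FALSE] -
                            matrix(wxyz[w1, ], length(w2s), 3,
                                   byrow = TRUE))^2))
      if (any(dd <= config$hbond_cutoff & w2s != w1)) { two <- 1L; break }
    }
  }
  c(one, two)
}

residue_fingerprint <- function(res_atoms, ligand, waters, config,
                                lig_xyz = NULL) {
  bits <- integer(9)
  if (!nrow(res_atoms)) return(bits)
  if (is.null(lig_xyz)) lig_xyz <- xyz_of(ligand$atoms)
  dmin <- min_dist(xyz_of(res_atoms), lig_xyz)
  do_direct <- !config$prescreen || dmin <= config$prescreen_direct
  do_bridge <- !config$prescreen || dmin <= config$prescreen_bridge
  if (do_direct) {
    bits[1] <- detect_apolar(res_atoms, ligand, config)
    bits[2:3] <- detect_aromatic(res_atoms, ligand, config)
    bits[4:5] <- detect_hbond(res_atoms, ligand, config)
    bits[6:7] <- detect_electrostatic(res_atoms, ligand, config)
  }
  if (do_bridge)
    bits[8:9] <- detect_water_bridges(res_atoms, ligand, waters, config)
  bits
}

#' Compute the fingerprint matrix of a frame series
#'
#' Applies all five detector families to every protein residue in every
#' frame, using side-chain atoms only. Residues whose nearest heavy atom is
#' beyond the pre-screen radius are skipped (all-zero row) -- a pure
#' optimization whose soundness is property-tested.
#'
#' @param frames a `frame_series` (or single `structure_model`).
#' @param ligand_chain,ligand_resno ligand residue selector.
#' @param topology optional pre-computed [infer_ligand_topology()] result
#'   (perceived on frame 1 otherwise); geometry is re-bound per frame.
#' @param config a [fp_config()] list.
#' @param residues optional data.frame (`chain`, `resno`, `insert`) limiting
#'   the residues scanned.
#' @return object of class `fingerprint_matrix`: a residues x frames x 9
#'   binary array with dimnames, residue table in `attr(,"residues")`.
#' @export
compute_fingerprint_matrix <- function(frames, ligand_chain, ligand_resno,
                                       topology = NULL,
                                       config = fp_config(),
                                       residues = NULL) {
  if (inherits(frames, "structure_model"))
    frames <- frame_series(list(frames))
  if (is.null(topology))
    topology <- infer_ligand_topology(frames$frames[[1]], ligand_chain,
                                      ligand_resno)
  rt <- residue_table(frames$frames[[1]])
  prot <- rt[!rt$is_water & !rt$is_het &
               toupper(rt$resname) %in% .amino3, , drop = FALSE]
  if (!is.null(residues)) {
    key <- paste(prot$chain, prot$resno, prot$insert)
    prot <- prot[key %in% paste(residues$chain, residues$resno,
                                if (is.null(residues$insert)) "" else
                                  residues$insert), , drop = FALSE]
  }
  if (!nrow(prot)) stop("no protein residues to scan")
  nres <- nrow(prot); nfr <- length(frames$frames)
  vals <- array(0L, dim = c(nres, nfr, 9),
                dimnames = list(
                  paste(prot$chain, prot$resno, prot$resname, sep = ":"),
                  seq_len(nfr), fp_bit_names()))
  warned_nowater <- FALSE
  for (f in seq_len(nfr)) {
    model <- frames$frames[[f]]
    top_f <- rebind_topology(topology, model)
    wat_idx <- atom_select(model, resname = .water_resnames)
    waters <- model$atoms[wat_idx, , drop = FALSE]
    waters <- waters[waters$element == "O", , drop = FALSE]
    if (!nrow(waters) && !warned_nowater) {
      message("no waters in frame ", f,
              "; water-bridge bits will be 0 (reported once)")
      warned_nowater <- TRUE
    }
    lig_xyz <- xyz_of(top_f$atoms)
    res <- withCallingHandlers(
      lapply(seq_len(nres), function(r) {
        sc <- side_chain_atoms(model, prot$chain[r], prot$resno[r],
                               prot$insert[r])
        residue_fingerprint(model$atoms[sc, , drop = FALSE], top_f, waters,
                            config, lig_xyz)
      }),
      error = function(e) stop("fingerprint failed at frame ", f, ": ",
                               conditionMessage(e)))
    vals[, f, ] <- do.call(rbind, res)
  }
  structure(vals, class = "fingerprint_matrix", residues = prot,
            config = config)
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  d <- dim(x)
  cat("fingerprint_matrix: ", d[1], " residues x ", d[2], " frames x 9 bits; ",
      sum(x), " set bits\n", sep = "")
  on <- apply(x, c(1, 3), max)
  act <- rowSums(on) > 0
  if (any(act))
    cat("  interacting residues: ",
        paste(rownames(on)[act], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one residue/bit binary time series
#'
#' @param x a `fingerprint_matrix`.
#' @param residue residue key (`"chain:resno:resname"`) or row index.
#' @param bit bit name (see [fp_bit_names()]) or index.
#' @return integer vector of length `n_frames`.
#' @export
fp_series <- function(x, residue, bit) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  as.integer(x[residue, , bit])
}

#' Long-format data.frame of a fingerprint matrix
#'
#' @param x a `fingerprint_matrix`.
#' @param ... unused.
#' @return data.frame with frame, chain, resno, resname and one named column
#'   per bit.
#' @export
as.data.frame.fingerprint_matrix <- function(x, ...) {
  res <- attr(x, "residues")
  d <- dim(x)
  out <- data.frame(
    frame = rep(seq_len(d[2]), each = d[1]),
    chain = rep(res$chain, d[2]),
    resno = rep(res$resno, d[2]),
    resname = rep(res$resname, d[2]))
  m <- matrix(aperm(unclass(x), c(1, 2, 3)), nrow = d[1] * d[2])
  colnames(m) <- fp_bit_names()
  cbind(out, as.data.frame(m))
}

#' Write / read a fingerprint matrix as TSV
#'
#' Long format: frame, chain, resno, resname, then the nine named bit
#' columns in canonical order.
#'
#' @param x a `fingerprint_matrix`.
#' @param path file path.
#' @return `path` invisibly (write); a `fingerprint_matrix` (read).
#' @export
write_fingerprints <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("frame", "chain", "resno", "resname", fp_bit_names())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fingerprint TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  fr1 <- df[df$frame == df$frame[1], , drop = FALSE]
  res <- data.frame(chain = fr1$chain, resno = fr1$resno, insert = "",
                    resname = fr1$resname, stringsAsFactors = FALSE)
  nfr <- length(unique(df$frame)); nres <- nrow(fr1)
  vals <- array(0L, dim = c(nres, nfr, 9),
                dimnames = list(paste(res$chain, res$resno, res$resname,
                                      sep = ":"),
                                sort(unique(df$frame)), fp_bit_names()))
  for (b in fp_bit_names())
    vals[, , b] <- matrix(as.integer(df[[b]]), nrow = nres)
  structure(vals, class = "fingerprint_matrix", residues = res,
            config = NULL)
}

#' Report close charged-atom-to-ring-centroid contacts
#'
#' The 9-bit scheme has no cation-pi bit; this report lists, for
#' interpretation only, charged atoms within `cutoff` of an aromatic ring
#' centroid (protein cations vs ligand rings and ligand cations vs protein
#' rings).
#'
#' @param model a `structure_model`.
#' @param ligand a `ligand_topology`.
#' @param cutoff Angstrom (default 4).
#' @param config a [fp_config()] list (histidine protonation flag).
#' @return data.frame with `kind`, `residue`, `atom` and `distance` columns.
#' @export
cation_pi_report <- function(model, ligand, cutoff = 4.0,
                             config = fp_config()) {
  rt <- residue_table(model)
  prot <- rt[!rt$is_water & !rt$is_het, , drop = FALSE]
  lxyz <- xyz_of(ligand$atoms)
  lig_rings <- lapply(ligand$rings[ligand$aromatic], function(r)
    colMeans(lxyz[r, , drop = FALSE]))
  lig_cat <- which(ligand$formal_charges > 0)
  rows <- list()
  for (r in seq_len(nrow(prot))) {
    sc <- side_chain_atoms(model, prot$chain[r], prot$resno[r],
                           prot$insert[r])
    res_atoms <- model$atoms[sc, , drop = FALSE]
    if (!nrow(res_atoms)) next
    key <- paste(prot$chain[r], prot$resno[r], prot$resname[r], sep = ":")
    pos <- charged_atoms(res_atoms, "positive", config$his_protonated)
    for (cen in lig_rings) for (k in seq_len(nrow(pos))) {
      d <- sqrt(sum((c(pos$x[k], pos$y[k], pos$z[k]) - cen)^2))
      if (d <= cutoff)
        rows[[length(rows) + 1]] <- data.frame(
          kind = "protein_cation_ligand_ring", residue = key,
          atom = pos$name[k], distance = d)
    }
    for (ring in residue_ring_xyz(res_atoms)) {
      cen <- colMeans(ring)
      for (j in lig_cat) {
        d <- sqrt(sum((lxyz[j, ] - cen)^2))
        if (d <= cutoff)
          rows[[length(rows) + 1]] <- data.frame(
            kind = "ligand_cation_protein_ring", residue = key,
            atom = ligand$atoms$name[j], distance = d)
      }
    }
  }
  if (!length(rows))
    return(data.frame(kind = character(), residue = character(),
                      atom = character(), distance = numeric()))
  do.call(rbind, rows)
}
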