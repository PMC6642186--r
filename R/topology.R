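## Ligand topology perception: bonds, rings, aromaticity, formal charges.
##
## Bonds come from CONECT records when the file has them; otherwise a
## covalent-radius heuristic is used (heavy atoms bonded when closer than
## the sum of covalent radii + 0.45 A). Rings are chordless simple cycles
## of length 3-8 found by exhaustive bounded search on the bond graph; a
## ring is
## flagged aromatic when all members are C/N/O/S and the RMS out-of-plane
## deviation from the best-fit plane is below the planarity tolerance.

# Bundled formal-charge templates, keyed by residue name then atom name.
# GRN: granisetron; the tertiary ammonium of the azabicyclic cage carries +1
# (pKa ~9.6, protonated at physiological pH).
.ligand_charge_templates <- list(
  GRN = c(N2 = 1L)
)

bond_perception <- function(atoms, margin = 0.45) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rc <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(rc, rc, "+") + margin
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  unname(hit[, c(1, 2), drop = FALSE])
}

# All chordless simple cycles of length min_len..max_len -- the chemical
# ring census: a cycle with a chord is the envelope of two fused smaller
# rings, not a ring itself, while bridged-bicycle envelopes (chord-free)
# are kept. Each cycle is anchored at its smallest vertex and oriented so
# the second vertex is smaller than the last, de-duplicating rotations and
# reflections.
find_rings <- function(n_atoms, bonds, min_len = 3, max_len = 8) {
  if (nrow(bonds) == 0) return(list())
  amat <- matrix(FALSE, n_atoms, n_atoms)
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
    amat[i, j] <- amat[j, i] <- TRUE
  }
  chordless <- function(path) {
    n <- length(path)
    for (a in seq_len(n - 2)) for (b in (a + 2):n) {
      if (a == 1 && b == n) next   # closing edge, not a chord
      if (amat[path[a], path[b]]) return(FALSE)
    }
    TRUE
  }
  rings <- list()
  walk <- function(path) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == path[1] && length(path) >= min_len) {
        if (path[2] < path[length(path)] && chordless(path))
          rings[[length(rings) + 1]] <<- path
      } else if (w > path[1] && !(w %in% path) && length(path) < max_len) {
        walk(c(path, w))
      }
    }
  }
  for (v in seq_len(n_atoms)) if (length(adj[[v]]) >= 2) walk(v)
  rings
}

ring_planarity_rms <- function(xyz) {
  c0 <- scale(xyz, scale = FALSE)
  sv <- svd(c0)
  # residuals along the smallest principal direction
  sqrt(mean((c0 %*% sv$v[, 3])^2))
}

#' Perceive the topology of a bound ligand
#'
#' Extracts one hetero residue and derives its bond graph, ring census,
#' aromatic flags and formal charges -- the inputs the fingerprint engine
#' needs for the aromatic and electrostatic bits.
#'
#' @param model a `structure_model`.
#' @param chain,resno selector for exactly one hetero residue.
#' @param charges optional named integer vector of formal charges keyed by
#'   atom name; overrides the bundled per-residue template.
#' @param polar optional data.frame with columns `name`, `donor`, `acceptor`
#'   overriding the default polar-atom classification (every N/O both donor
#'   and acceptor under the heavy-atom-only convention).
#' @param planarity_tol RMS out-of-plane tolerance (Angstrom) for the
#'   aromatic flag.
#' @param bond_margin slack added to the covalent-radius sum in
#'   distance-based bond perception.
#' @return object of class `ligand_topology`: `atoms` (atom table),
#'   `bonds` (2-column local-index matrix), `rings` (list of index cycles),
#'   `aromatic` (logical per ring), `formal_charges` (integer per atom),
#'   `donor`/`acceptor` (logical per atom), `heavy` (logical per atom).
#' @export
infer_ligand_topology <- function(model, chain, resno, charges = NULL,
                                  polar = NULL, planarity_tol = 0.1,
                                  bond_margin = 0.45) {
  rt <- residue_table(model)
  hit <- which(rt$chain == chain & rt$resno == resno & rt$is_het &
                 !rt$is_water)
  if (length(hit) != 1)
    stop("ligand selector ", chain, ":", resno, " matches ", length(hit),
         " hetero residues (need exactly 1)")
  idx <- atom_select(model, chain = chain, resno = resno,
                     insert = rt$insert[hit])
  atoms <- model$atoms[idx, , drop = FALSE]
  heavy <- atoms$element != "H"
  atoms <- atoms[heavy, , drop = FALSE]
  rownames(atoms) <- NULL
  n <- nrow(atoms)

  bonds <- NULL
  if (!is.null(model$conect)) {
    inlig <- matrix(match(model$conect, atoms$serial), ncol = 2)
    keep <- stats::complete.cases(inlig)
    if (any(keep)) bonds <- inlig[keep, , drop = FALSE]
  }
  if (is.null(bonds) || nrow(bonds) == 0) bonds <- bond_perception(atoms,
                                                                   bond_margin)

  # connected-component check on the heavy-atom graph
  if (n > 1) {
    comp <- seq_len(n)
    repeat {
      new <- comp
      for (k in seq_len(nrow(bonds))) {
        m <- min(comp[bonds[k, ]])
        new[bonds[k, ]] <- pmin(new[bonds[k, ]], m)
      }
      if (identical(new, comp)) break
      comp <- new
    }
    if (length(unique(comp)) > 1)
      warning("ligand heavy-atom bond graph is disconnected (",
              length(unique(comp)), " components)")
  }

  rings <- find_rings(n, bonds)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  aromatic <- vapply(rings, function(r) {
    all(atoms$element[r] %in% c("C", "N", "O", "S")) &&
      ring_planarity_rms(xyz[r, , drop = FALSE]) < planarity_tol
  }, logical(1))

  fc <- integer(n)
  tmpl <- charges
  if (is.null(tmpl)) tmpl <- .ligand_charge_templates[[toupper(
    atoms$resname[1])]]
  if (!is.null(tmpl)) {
    pos <- match(names(tmpl), atoms$name)
    if (anyNA(pos))
      stop("charge template names not in ligand: ",
           paste(names(tmpl)[is.na(pos)], collapse = ", "))
    fc[pos] <- as.integer(tmpl)
  }

  donor <- acceptor <- atoms$element %in% c("N", "O")
  if (!is.null(polar)) {
    pos <- match(polar$name, atoms$name)
    if (anyNA(pos))
      stop("polar override names not in ligand: ",
           paste(polar$name[is.na(pos)], collapse = ", "))
    donor[pos] <- polar$donor
    acceptor[pos] <- polar$acceptor
  }

  out <- list(atoms = atoms, bonds = bonds, rings = rings,
              aromatic = aromatic, formal_charges = fc, donor = donor,
              acceptor = acceptor, heavy = rep(TRUE, n),
              chain = chain, resno = resno)
  class(out) <- "ligand_topology"
  out
}

#' @export
print.ligand_topology <- function(x, ...) {
  cat("ligand_topology: ", x$atoms$resname[1], " ", x$chain, ":", x$resno,
      " -- ", nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds, ",
      length(x$rings), " ring(s) (", sum(x$aromatic), " aromatic)\n",
      sep = "")
  chg <- which(x$formal_charges != 0)
  if (length(chg))
    cat("  formal charges: ",
        paste0(x$atoms$name[chg], " ", sprintf("%+d", x$formal_charges[chg]),
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Re-binds a perceived topology to the same residue in another frame
# (identical atom names required); geometry-independent fields carry over.
rebind_topology <- function(topology, model) {
  idx <- atom_select(model, chain = topology$chain, resno = topology$resno)
  atoms <- model$atoms[idx, , drop = FALSE]
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  pos <- match(topology$atoms$name, atoms$name)
  if (anyNA(pos))
    stop("ligand atoms missing in frame: ",
         paste(topology$atoms$name[is.na(pos)], collapse = ", "))
  topology$atoms <- atoms[pos, , drop = FALSE]
  rownames(topology$atoms) <- NULL
  topology
}
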