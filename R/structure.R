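## Coordinate model and I/O.
##
## A `structure_model` is a thin, explicit container over an atom table:
## one row per atom with PDB-style identity (chain, residue number,
## insertion code, atom name, alt-loc), element, coordinates in Angstrom and
## a bundled van der Waals radius. Parsing of PDB/mmCIF is delegated to
## bio3d; CONECT connectivity (which bio3d does not retain) is recovered by
## a supplementary scan of the file.

#' Build a structure model from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `alt`,
#'   `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occupancy`, `b`,
#'   `het`. A `vdw` column is added from the bundled radius table when
#'   absent.
#' @param frame_id integer frame label.
#' @param conect optional 2-column matrix of bonded atom serial pairs.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, frame_id = 1L, conect = NULL) {
  needed <- c("serial", "name", "element", "alt", "resname", "chain",
              "resno", "insert", "x", "y", "z", "occupancy", "b", "het")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$alt)
  if (anyDuplicated(key))
    warning("duplicate atom identity: ", key[duplicated(key)][1])
  rownames(atoms) <- NULL
  m <- list(atoms = atoms, frame_id = as.integer(frame_id), conect = conect)
  class(m) <- "structure_model"
  rebuild_indices(m)
}

# Derived indices (chain -> residues, water rows). Rebuilding is idempotent
# by construction: indices are pure functions of the atom table.
rebuild_indices <- function(model) {
  a <- model$atoms
  rk <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(rk)
  model$chains <- split(paste(a$resno[first], a$insert[first], sep = "|"),
                        a$chain[first])
  model$waters <- which(first & toupper(a$resname) %in% .water_resnames)
  model
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  nres <- length(unique(paste(a$chain, a$resno, a$insert)))
  cat("structure_model: ", nrow(a), " atoms, ", nres, " residues, ",
      length(unique(a$chain)), " chain(s) [",
      paste(sort(unique(a$chain)), collapse = " "), "], frame ",
      x$frame_id, "\n", sep = "")
  het <- a[a$het & !(toupper(a$resname) %in% .water_resnames), , drop = FALSE]
  if (nrow(het)) {
    hr <- unique(paste0(het$resname, " ", het$chain, ":", het$resno))
    cat("  hetero residues: ", paste(hr, collapse = ", "), "\n", sep = "")
  }
  nw <- length(x$waters)
  if (nw) cat("  waters: ", nw, "\n", sep = "")
  invisible(x)
}

coords <- function(model, idx = NULL) {
  a <- model$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  el <- ifelse(two %in% c("CL", "BR", "SE", "ZN", "FE", "MG", "MN", "NA",
                          "CU"), two, one)
  el[!nzchar(el)] <- "C"
  el
}

bio3d_to_atoms <- function(pdb) {
  at <- pdb$atom
  el <- toupper(trimws(at$elesy))
  bad <- is.na(el) | !nzchar(el)
  el[bad] <- guess_element(at$elety[bad])
  data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = el,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
}

# Alt-loc policy: keep the highest-occupancy conformer of each atom;
# ties resolve to conformer 'A' (then alphabetically).
collapse_altloc <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$alt != "A", atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

read_conect <- function(path) {
  ln <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  out <- lapply(ln, function(l) {
    f <- suppressWarnings(as.integer(
      substring(l, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  })
  m <- do.call(rbind, out)
  if (is.null(m)) return(NULL)
  m <- t(apply(m, 1, sort))
  unique(m)
}

#' Read a coordinate file into a structure model
#'
#' Parses PDB or mmCIF (via bio3d) and returns a [structure_model()] holding
#' every atom, waters and hetero groups included. For multi-model PDB files
#' the first model is returned unless `model` says otherwise. Alternate
#' locations are collapsed to the highest-occupancy conformer (ties go to
#' 'A'). Unknown elements get a default van der Waals radius with a warning.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model 1-based model index for multi-model files.
#' @return a `structure_model`; PDB CONECT records, if any, are kept in
#'   `$conect` as a 2-column serial-pair matrix.
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                           model = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  pdb <- tryCatch(
    if (dialect == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("cannot parse ", dialect, " file '", path,
                             "': ", conditionMessage(e)))
  atoms <- bio3d_to_atoms(pdb)
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod) stop("model ", model, " requested but file has ", nmod)
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  atoms <- collapse_altloc(atoms)
  conect <- if (dialect == "pdb") read_conect(path) else NULL
  structure_model(atoms, frame_id = as.integer(model), conect = conect)
}

#' Write a structure model as PDB
#'
#' Coordinates are written at PDB precision (3 decimals); CONECT records are
#' emitted when the model carries connectivity.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(model))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = ifelse(a$chain == "", " ", a$chain),
                   insert = ifelse(a$insert == "", "", a$insert),
                   alt = ifelse(a$alt == "", "", a$alt),
                   o = a$occupancy, b = a$b, elesy = a$element)
  if (!is.null(model$conect)) {
    ln <- readLines(path, warn = FALSE)
    endi <- grep("^END", ln)
    con <- sprintf("CONECT%5d%5d", model$conect[, 1], model$conect[, 2])
    body <- if (length(endi)) append(ln[-endi], c(con, "END")) else c(ln, con)
    writeLines(body, path)
  }
  invisible(path)
}

#' Select atom rows of a structure model
#'
#' @param model a `structure_model`.
#' @param chain,resno,name,resname,element optional filters (vectors allowed).
#' @param insert insertion-code filter.
#' @param het `TRUE`/`FALSE` to restrict to hetero / non-hetero atoms.
#' @return integer row indices into `model$atoms`.
#' @export
atom_select <- function(model, chain = NULL, resno = NULL, name = NULL,
                        resname = NULL, element = NULL, insert = NULL,
                        het = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(insert)) keep <- keep & a$insert %in% insert
  if (!is.null(het)) keep <- keep & a$het == het
  which(keep)
}

#' Side-chain atom indices of one residue
#'
#' Excludes the backbone names N, CA, C, O and OXT, so glycine yields an
#' empty selection. Hydrogens are excluded as well: all interaction criteria
#' in this package are defined on heavy atoms.
#'
#' @inheritParams atom_select
#' @return integer row indices.
#' @export
side_chain_atoms <- function(model, chain, resno, insert = "") {
  idx <- atom_select(model, chain = chain, resno = resno, insert = insert)
  a <- model$atoms[idx, , drop = FALSE]
  idx[!(a$name %in% .backbone_names) & a$element != "H"]
}

backbone_atoms <- function(model, chain, resno, insert = "") {
  idx <- atom_select(model, chain = chain, resno = resno, insert = insert)
  idx[model$atoms$name[idx] %in% .backbone_names]
}

#' Residue table of a structure model
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resname`, `is_water`, `is_het` and `n_atoms`.
#' @export
residue_table <- function(model) {
  a <- model$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- which(!duplicated(key))
  data.frame(
    chain = a$chain[first], resno = a$resno[first], insert = a$insert[first],
    resname = a$resname[first],
    is_water = toupper(a$resname[first]) %in% .water_resnames,
    is_het = a$het[first],
    n_atoms = as.integer(table(key)[key[first]]),
    stringsAsFactors = FALSE
  )
}

atom_identity <- function(model)
  paste(model$atoms$chain, model$atoms$resno, model$atoms$insert,
        model$atoms$name, sep = "|")

#' Read a series of coordinate frames
#'
#' Accepts either one multi-model PDB or a vector of single-model files. All
#' frames must share the same atom identity sequence (chain, residue, atom
#' name); the first mismatching atom is reported otherwise.
#'
#' @param paths character vector of file paths (length 1 for a multi-model
#'   file).
#' @param times optional numeric time stamps (ns), one per frame.
#' @return object of class `frame_series`: list with `frames` (list of
#'   `structure_model`) and `times`.
#' @export
read_frames <- function(paths, times = NULL) {
  stopifnot(length(paths) >= 1)
  frames <- list()
  if (length(paths) == 1) {
    pdb <- bio3d::read.pdb(paths, multi = TRUE, verbose = FALSE)
    nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    atoms0 <- collapse_altloc(bio3d_to_atoms(pdb))
    conect <- read_conect(paths)
    for (m in seq_len(nmod)) {
      atoms <- atoms0
      if (is.matrix(pdb$xyz)) {
        xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
        # multi-model xyz follows the raw atom order; re-collapse alt locs
        full <- bio3d_to_atoms(pdb)
        full$x <- xyz[, 1]; full$y <- xyz[, 2]; full$z <- xyz[, 3]
        atoms <- collapse_altloc(full)
      }
      frames[[m]] <- structure_model(atoms, frame_id = m, conect = conect)
    }
  } else {
    frames <- lapply(seq_along(paths), function(i) {
      f <- read_structure(paths[i])
      f$frame_id <- i
      f
    })
  }
  id0 <- atom_identity(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    idi <- atom_identity(frames[[i]])
    if (length(idi) != length(id0))
      stop("frame ", i, " has ", length(idi), " atoms; frame 1 has ",
           length(id0))
    bad <- which(idi != id0)
    if (length(bad))
      stop("atom identity mismatch at frame ", i, ", atom ", bad[1], ": '",
           idi[bad[1]], "' vs '", id0[bad[1]], "'")
  }
  if (!is.null(times) && length(times) != length(frames))
    stop("times length must equal number of frames")
  out <- list(frames = frames, times = times)
  class(out) <- "frame_series"
  out
}

#' Build a frame series from in-memory models
#'
#' @param models list of `structure_model` sharing one atom identity.
#' @param times optional per-frame time stamps (ns).
#' @return a `frame_series`.
#' @export
frame_series <- function(models, times = NULL) {
  stopifnot(length(models) >= 1)
  id0 <- atom_identity(models[[1]])
  for (i in seq_along(models)[-1]) {
    idi <- atom_identity(models[[i]])
    bad <- which(idi != id0)
    if (length(idi) != length(id0) || length(bad))
      stop("atom identity mismatch at frame ", i)
    models[[i]]$frame_id <- i
  }
  out <- list(frames = models, times = times)
  class(out) <- "frame_series"
  out
}

#' @export
print.frame_series <- function(x, ...) {
  cat("frame_series: ", length(x$frames), " frame(s), ",
      nrow(x$frames[[1]]$atoms), " atoms each\n", sep = "")
  if (!is.null(x$times))
    cat("  time range: ", min(x$times), " - ", max(x$times), " ns\n",
        sep = "")
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)
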