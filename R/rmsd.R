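## RMSD with least-squares superposition.
##
## Two conventions are provided, matching how antagonist-complex
## trajectories are analyzed:
##  - anchored_rmsd: the metadynamics collective variable -- superpose the
##    combined set of ligand heavy atoms and the backbone "anchor" atoms of
##    a stable receptor stretch onto the reference, then report the RMSD of
##    that same combined set.
##  - ecd_rmsd_series: per-frame RMSD of a measured selection after fitting
##    on a (possibly different) selection, e.g. protein Calpha measured
##    after fitting on secondary-structure Calpha of the ECD.

# Kabsch optimal rotation: returns P (n x 3) superposed onto Q (n x 3).
kabsch_superpose <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(P0 %*% t(R), 2, cq, "+")
}

rmsd_of <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

resolve_selection <- function(model, selection) {
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.list(selection)) return(do.call(atom_select, c(list(model),
                                                        selection)))
  stop("selection must be atom indices or an atom_select() argument list")
}

#' Anchored RMSD of a ligand pose (metadynamics collective variable)
#'
#' Rigid-body least-squares superposition of the combined ligand + anchor
#' selection onto the same atoms of the reference, followed by the RMSD of
#' that combined set. Anchors are typically the backbone heavy atoms of a
#' stable receptor stretch far from the binding site (e.g. residues
#' 209-212 of one subunit), so ligand displacement relative to the receptor
#' is not absorbed by the fit.
#'
#' @param frame,reference `structure_model`s with identical selections.
#' @param ligand_atoms,anchor_atoms atom row indices, or argument lists for
#'   [atom_select()] (e.g. `list(chain = "L", resno = 401)`).
#' @return RMSD in Angstrom.
#' @export
anchored_rmsd <- function(frame, reference, ligand_atoms, anchor_atoms) {
  li_f <- resolve_selection(frame, ligand_atoms)
  an_f <- resolve_selection(frame, anchor_atoms)
  li_r <- resolve_selection(reference, ligand_atoms)
  an_r <- resolve_selection(reference, anchor_atoms)
  if (length(li_f) != length(li_r) || length(an_f) != length(an_r))
    stop("ligand/anchor selections resolve differently in frame (",
         length(li_f), "+", length(an_f), ") and reference (",
         length(li_r), "+", length(an_r), ")")
  idf <- atom_identity(frame)[c(li_f, an_f)]
  idr <- atom_identity(reference)[c(li_r, an_r)]
  if (!identical(idf, idr))
    stop("selection identity mismatch at atom '",
         idf[which(idf != idr)[1]], "'")
  P <- coords(frame, c(li_f, an_f))
  Q <- coords(reference, c(li_r, an_r))
  rmsd_of(kabsch_superpose(P, Q), Q)
}

#' Per-frame RMSD after fitting on a separate selection
#'
#' For each frame: superpose the fit selection onto the reference's fit
#' selection, apply that transform to the measured selection, report its
#' RMSD. Fit and measure sets may differ (fitting on secondary-structure
#' Calpha while measuring all Calpha or ligand heavy atoms).
#'
#' @param frames a `frame_series`.
#' @param reference a `structure_model`.
#' @param fit_selection,measure_selection atom indices or [atom_select()]
#'   argument lists, resolved identically across frames.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
ecd_rmsd_series <- function(frames, reference, fit_selection,
                            measure_selection) {
  fit_r <- resolve_selection(reference, fit_selection)
  mea_r <- resolve_selection(reference, measure_selection)
  Qf <- coords(reference, fit_r)
  Qm <- coords(reference, mea_r)
  vapply(frames$frames, function(fr) {
    fit_f <- resolve_selection(fr, fit_selection)
    mea_f <- resolve_selection(fr, measure_selection)
    if (length(fit_f) != length(fit_r) || length(mea_f) != length(mea_r))
      stop("selection resolves differently in frame ", fr$frame_id)
    P <- coords(fr, fit_f)
    # fit on the fit set, carry the transform to the measured set
    cp <- colMeans(P); cq <- colMeans(Qf)
    P0 <- sweep(P, 2, cp); Q0 <- sweep(Qf, 2, cq)
    sv <- svd(crossprod(P0, Q0))
    D <- diag(c(1, 1, sign(det(tcrossprod(sv$v, sv$u)))))
    R <- sv$v %*% D %*% t(sv$u)
    M <- sweep(sweep(coords(fr, mea_f), 2, cp) %*% t(R), 2, cq, "+")
    rmsd_of(M, Qm)
  }, numeric(1))
}
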