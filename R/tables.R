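#' @keywords internal
"_PACKAGE"

## Bundled element and residue chemistry tables.
##
## Radii are versioned in-package so every geometric result is reproducible
## bit-for-bit; no external dictionary is consulted at run time.

# Bondi van der Waals radii (Angstrom); common biomolecular elements.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.63,
  MN = 1.73, CU = 1.40, B = 1.92
)
.default_vdw <- 1.70

# Covalent radii (Angstrom), used by distance-based bond perception.
.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84
)
.default_cov <- 0.77

#' Look up van der Waals radii for element symbols
#'
#' Returns the bundled Bondi radius for each element; unknown elements get a
#' carbon-like default of 1.70 Angstrom with a warning.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .vdw_radii[el]
  bad <- is.na(r) & !is.na(el) & nzchar(el)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(el[bad]), collapse = ", "),
            "; using default vdW radius ", .default_vdw, " A")
  }
  r[is.na(r)] <- .default_vdw
  unname(r)
}

covalent_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- .cov_radii[el]
  r[is.na(r)] <- .default_cov
  unname(r)
}

# Backbone atom names excluded by side-chain selection (glycine side chain
# is consequently empty).
.backbone_names <- c("N", "CA", "C", "O", "OXT")

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "H2O")

.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "MSE", "HSD", "HSE", "HSP")

# Aromatic side-chain rings of Phe/Tyr/Trp/His by atom name.
.protein_rings <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  HSD = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  HSE = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  HSP = list(c("CG", "ND1", "CE1", "NE2", "CD2"))
)

# Side-chain hydrogen-bond chemistry: donor/acceptor class per heavy atom,
# with the antecedent heavy atom used for the >= 90 degree angle check.
# Heavy-atom-only criteria: experimental models rarely carry hydrogens.
.hbond_templates <- local({
  row <- function(res, atom, donor, acceptor, antecedent)
    data.frame(resname = res, atom = atom, donor = donor, acceptor = acceptor,
               antecedent = antecedent, stringsAsFactors = FALSE)
  rbind(
    row("SER", "OG",  TRUE,  TRUE,  "CB"),
    row("THR", "OG1", TRUE,  TRUE,  "CB"),
    row("TYR", "OH",  TRUE,  TRUE,  "CZ"),
    row("CYS", "SG",  TRUE,  TRUE,  "CB"),
    row("ASN", "OD1", FALSE, TRUE,  "CG"),
    row("ASN", "ND2", TRUE,  FALSE, "CG"),
    row("GLN", "OE1", FALSE, TRUE,  "CD"),
    row("GLN", "NE2", TRUE,  FALSE, "CD"),
    row("ASP", "OD1", FALSE, TRUE,  "CG"),
    row("ASP", "OD2", FALSE, TRUE,  "CG"),
    row("GLU", "OE1", FALSE, TRUE,  "CD"),
    row("GLU", "OE2", FALSE, TRUE,  "CD"),
    row("HIS", "ND1", TRUE,  TRUE,  "CG"),
    row("HIS", "NE2", TRUE,  TRUE,  "CD2"),
    row("LYS", "NZ",  TRUE,  FALSE, "CE"),
    row("ARG", "NE",  TRUE,  FALSE, "CD"),
    row("ARG", "NH1", TRUE,  FALSE, "CZ"),
    row("ARG", "NH2", TRUE,  FALSE, "CZ"),
    row("TRP", "NE1", TRUE,  FALSE, "CE2")
  )
})

# Formally charged side-chain groups used by the electrostatic detector.
# Histidine counts as positive only when `his_protonated = TRUE`.
.charged_templates <- list(
  positive = list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                  HSP = c("ND1", "NE2")),
  positive_his = list(HIS = c("ND1", "NE2")),
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
)

#' Prime-notation annotation for the 5-HT3A receptor M2 helix
#'
#' Maps the pore-lining M2 prime indices used in the channel literature to
#' 5-HT3A residue numbers (9' = Leu260; the -1' ring is Glu250, implicated in
#' charge selectivity). Editable: pass your own table to annotation consumers.
#'
#' @return data.frame with columns `prime` (integer index), `resno` and
#'   `resname`.
#' @export
m2_prime_table <- function() {
  prime <- -1:20
  resno <- prime + 251
  resname <- rep(NA_character_, length(prime))
  known <- c("-1" = "GLU", "2" = "SER", "6" = "SER", "9" = "LEU",
             "13" = "VAL", "16" = "ILE")
  resname[match(as.integer(names(known)), prime)] <- unname(known)
  data.frame(prime = prime, resno = resno, resname = resname,
             stringsAsFactors = FALSE)
}

# Boltzmann constant in kJ/mol/K, bundled so free-energy weighting is exact
# and reproducible.
.kB <- 0.0083145
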