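## Metadynamics post-processing: hills -> free-energy profile -> the
## Boltzmann-averaged collective variable used to rank binding poses.
##
## With fixed-height Gaussian hills the negated bias sum estimates the
## free-energy profile: F(s) = -sum_i h_i exp(-(s - c_i)^2 / (2 sigma_i^2)),
## shifted so min F = 0. The pose statistic is
##   <s> = Int ds s exp(-F(s)/kB T) / Int ds exp(-F(s)/kB T),
## which is invariant under F -> F + c; a lower <s> (anchored ligand RMSD)
## marks the thermodynamically favored pose.

#' Read a PLUMED-style HILLS file
#'
#' Whitespace-delimited text with a header naming the columns, either a
#' PLUMED `#! FIELDS time <cv> sigma_<cv> height ...` comment or a plain
#' header line containing `time`, a collective-variable column, `sigma` and
#' `height`.
#'
#' @param path file path.
#' @param units units of the CV columns in the file: `"A"` (Angstrom,
#'   default) or `"nm"`; nm values are converted to Angstrom at parse time.
#' @return data.frame of class `hills` with columns `time` (ps), `center`,
#'   `sigma` (Angstrom) and `height` (kJ/mol).
#' @export
read_hills <- function(path, units = c("A", "nm")) {
  units <- match.arg(units)
  ln <- readLines(path, warn = FALSE)
  fields <- NULL
  fl <- grep("^#!\\s*FIELDS", ln, value = TRUE)
  if (length(fl)) {
    fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fl[1])), "\\s+")[[1]]
  } else {
    body0 <- ln[!grepl("^\\s*(#|$)", ln)]
    if (length(body0) && grepl("[A-Za-z]", body0[1])) {
      fields <- strsplit(trimws(body0[1]), "\\s+")[[1]]
      ln <- body0[-1]
    }
  }
  if (is.null(fields)) stop("hills file '", path, "' has no column header")
  # unit declaration may ride in a header comment, e.g. "# UNITS nm"
  un <- grep("^#\\s*UNITS?\\b", ln, value = TRUE, ignore.case = TRUE)
  if (length(un) && grepl("nm", un[1], ignore.case = TRUE)) units <- "nm"
  body <- ln[!grepl("^\\s*(#|$)", ln)]
  body <- body[!grepl("[A-Za-z]", substr(trimws(body), 1, 1))]
  if (!length(body)) {
    out <- data.frame(time = numeric(), center = numeric(),
                      sigma = numeric(), height = numeric())
    class(out) <- c("hills", "data.frame")
    return(out)
  }
  m <- utils::read.table(text = body, col.names = fields,
                         check.names = FALSE)
  pick <- function(patterns, what) {
    for (p in patterns) {
      hit <- grep(p, fields, ignore.case = TRUE)
      if (length(hit)) return(hit[1])
    }
    stop("hills file '", path, "' lacks a ", what, " column (header: ",
         paste(fields, collapse = " "), ")")
  }
  t_i <- pick("^time$", "time")
  s_i <- pick(c("^sigma"), "sigma")
  h_i <- pick(c("^height$"), "height")
  c_i <- setdiff(seq_along(fields), c(t_i, s_i, h_i,
                                      grep("^biasf", fields,
                                           ignore.case = TRUE)))[1]
  if (is.na(c_i)) stop("hills file '", path, "' lacks a CV column")
  out <- data.frame(time = m[[t_i]], center = m[[c_i]], sigma = m[[s_i]],
                    height = m[[h_i]])
  if (units == "nm") {
    out$center <- out$center * 10
    out$sigma <- out$sigma * 10
  }
  if (any(out$sigma <= 0)) stop("non-positive hill width in '", path, "'")
  if (is.unsorted(out$time)) warning("non-monotone time in '", path, "'")
  class(out) <- c("hills", "data.frame")
  out
}

#' Reconstruct a free-energy profile from deposited hills
#'
#' @param hills data.frame with `center`, `sigma`, `height` columns
#'   (Angstrom / kJ/mol), e.g. from [read_hills()].
#' @param grid strictly increasing CV grid; default covers the hill centers
#'   +/- 3 widths at `n_grid` points.
#' @param n_grid default grid size.
#' @param temperature Kelvin.
#' @return object of class `fe_profile`: list with `grid`, `F` (kJ/mol,
#'   min 0), `temperature`, `kB`.
#' @export
reconstruct_free_energy <- function(hills, grid = NULL, n_grid = 501L,
                                    temperature = 300) {
  if (is.null(grid)) {
    if (!nrow(hills)) grid <- seq(0, 1, length.out = n_grid)
    else grid <- seq(min(hills$center - 3 * hills$sigma),
                     max(hills$center + 3 * hills$sigma),
                     length.out = n_grid)
  }
  if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing with >= 2 points")
  Fv <- numeric(length(grid))
  if (nrow(hills)) {
    lo <- min(hills$center - 3 * hills$sigma)
    hi <- max(hills$center + 3 * hills$sigma)
    if (min(grid) > lo || max(grid) < hi) {
      # fraction of deposited Gaussian mass outside the grid
      clip <- vapply(seq_len(nrow(hills)), function(i) {
        p <- stats::pnorm(c(min(grid), max(grid)), hills$center[i],
                          hills$sigma[i])
        1 - (p[2] - p[1])
      }, numeric(1))
      warning(sprintf(
        "grid does not cover hills +/- 3 sigma; ~%.1f%% of hill mass clipped",
        100 * sum(clip * hills$height) / sum(hills$height)))
    }
    for (i in seq_len(nrow(hills)))
      Fv <- Fv - hills$height[i] *
        exp(-(grid - hills$center[i])^2 / (2 * hills$sigma[i]^2))
  }
  Fv <- Fv - min(Fv)
  out <- list(grid = grid, F = Fv, temperature = temperature, kB = .kB)
  class(out) <- "fe_profile"
  out
}

#' Build a free-energy profile from tabulated values
#'
#' @param grid strictly increasing CV values.
#' @param F free energy, kJ/mol.
#' @param temperature Kelvin.
#' @return a `fe_profile` (F is used as given, not re-shifted).
#' @export
fe_profile <- function(grid, F, temperature = 300) {
  if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing with >= 2 points")
  stopifnot(length(F) == length(grid), all(is.finite(F)))
  out <- list(grid = grid, F = F, temperature = temperature, kB = .kB)
  class(out) <- "fe_profile"
  out
}

#' @export
print.fe_profile <- function(x, ...) {
  imin <- which.min(x$F)
  cat("fe_profile: ", length(x$grid), " points on [",
      format(min(x$grid)), ", ", format(max(x$grid)), "], T = ",
      x$temperature, " K, minimum at s = ", format(x$grid[imin]),
      " (F = ", format(min(x$F), digits = 4), " kJ/mol)\n", sep = "")
  invisible(x)
}

#' @export
plot.fe_profile <- function(x, xlab = "s (collective variable)",
                            ylab = "F(s) [kJ/mol]", type = "l", ...) {
  graphics::plot(x$grid, x$F, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Boltzmann-averaged collective variable of a free-energy profile
#'
#' Computes `<s> = Int ds s exp(-F/kBT) / Int ds exp(-F/kBT)` by
#' trapezoidal quadrature on the profile's own grid. The weight is
#' internally rescaled by min(F) (the average is invariant under constant
#' shifts of F), so deep profiles never underflow.
#'
#' @param profile a `fe_profile`.
#' @return the Boltzmann-averaged s, in grid units.
#' @export
boltzmann_average <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  if (profile$temperature <= 0) stop("temperature must be positive")
  kT <- profile$kB * profile$temperature
  w <- exp(-(profile$F - min(profile$F)) / kT)
  num <- pracma::trapz(profile$grid, profile$grid * w)
  den <- pracma::trapz(profile$grid, w)
  num / den
}

#' Rank binding poses by replicate-averaged Boltzmann RMSD
#'
#' For each pose, every replicate free-energy profile yields one `<s>` via
#' [boltzmann_average()]; the pose statistic is the replicate mean with its
#' standard error (sd/sqrt(n)). Ranks ascend with the mean (a lower average
#' anchored RMSD is more favorable); ties break by smaller SEM, then
#' lexicographic pose id.
#'
#' @param profiles named list: pose id -> list of `fe_profile` replicates
#'   (>= 2 each).
#' @return object of class `pose_ranking`: data.frame with `pose`, `mean`,
#'   `sem`, `n_replicates`, `rank`; per-replicate values in
#'   `attr(,"replicates")`.
#' @export
rank_poses <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1,
            !is.null(names(profiles)))
  reps <- lapply(profiles, function(pr) {
    if (length(pr) < 2)
      stop("each pose needs >= 2 replicates for a SEM")
    vapply(pr, boltzmann_average, numeric(1))
  })
  means <- vapply(reps, mean, numeric(1))
  sems <- vapply(reps, function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1))
  ord <- order(means, sems, names(profiles))
  out <- data.frame(pose = names(profiles), mean = means, sem = sems,
                    n_replicates = lengths(reps), stringsAsFactors = FALSE)
  out$rank <- match(seq_len(nrow(out)), ord)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pose_ranking", "data.frame")
  attr(out, "replicates") <- reps
  out
}

#' @export
print.pose_ranking <- function(x, digits = 4, ...) {
  cat("pose_ranking (lower mean anchored RMSD = more favorable):\n")
  df <- data.frame(rank = x$rank, pose = x$pose,
                   mean = signif(x$mean, digits),
                   sem = signif(x$sem, digits), n = x$n_replicates)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
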