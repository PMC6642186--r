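## Two-state Markov estimation of interaction probabilities.
##
## Each fingerprint bit traced over frames is a binary series; its long-run
## occurrence probability is the stationary probability of a two-state
## Markov chain, pi1 = p01/(p01 + p10). Uncertainty comes from sampling the
## transition-matrix posterior under independent per-row Dirichlet priors
## (flat pseudo-count 1 per cell by default): with two states each row
## posterior is a Beta distribution.

#' Count transitions of a binary series
#'
#' @param series integer/logical vector of 0/1 values, length >= 2.
#' @return 2x2 integer matrix `counts` with `counts[i, j]` = number of
#'   consecutive pairs (i-1) -> (j-1); entries sum to `length(series) - 1`.
#' @export
count_transitions <- function(series) {
  series <- as.integer(series)
  if (length(series) < 2) stop("series must have length >= 2")
  if (!all(series %in% c(0L, 1L))) stop("series values must be 0/1")
  from <- series[-length(series)]
  to <- series[-1]
  counts <- matrix(0L, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
  for (i in 0:1) for (j in 0:1)
    counts[i + 1, j + 1] <- sum(from == i & to == j)
  counts
}

#' Posterior of the stationary probability of a two-state chain
#'
#' Draws `n_samples` transition matrices from the posterior (each row
#' independently Dirichlet with the observed counts plus `prior`
#' pseudo-counts), computes the stationary probability
#' `pi1 = p01 / (p01 + p10)` of each draw, and reports the sample mean and
#' standard deviation. Samples in which both p01 and p10 are numerically
#' zero (degenerate, non-mixing chain) fall back to the empirical state-1
#' frequency and are counted in `n_degenerate`.
#'
#' @param counts 2x2 transition-count matrix from [count_transitions()].
#' @param n_samples number of posterior draws (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param prior Dirichlet pseudo-count per transition cell (default 1,
#'   a flat prior).
#' @return object of class `markov_estimate`: `mean_probability`, `error`
#'   (posterior sd), `empirical` (state-1 frequency), `n_samples`,
#'   `transition_counts`, `n_degenerate`.
#' @export
posterior_probability <- function(counts, n_samples = 10000L, seed,
                                  prior = 1) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2), all(counts >= 0))
  if (n_samples < 100) stop("n_samples must be >= 100")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  a0 <- counts[1, ] + prior   # row of state 0: (c00, c01) + prior
  a1 <- counts[2, ] + prior   # row of state 1: (c10, c11) + prior
  p01 <- stats::rbeta(n_samples, a0[2], a0[1])
  p10 <- stats::rbeta(n_samples, a1[1], a1[2])
  denom <- p01 + p10
  pi1 <- ifelse(denom > 0, p01 / denom, NA_real_)
  # empirical state-1 frequency, reconstructed from the counts
  emp <- (counts[2, 1] + counts[2, 2]) / sum(counts)
  degen <- is.na(pi1)
  if (any(degen)) {
    pi1[degen] <- emp
    message(sum(degen), " degenerate posterior sample(s) set to the ",
            "empirical frequency")
  }
  out <- list(mean_probability = mean(pi1), error = stats::sd(pi1),
              empirical = emp, n_samples = as.integer(n_samples),
              transition_counts = counts, n_degenerate = sum(degen),
              prior = prior)
  class(out) <- "markov_estimate"
  out
}

#' @export
print.markov_estimate <- function(x, digits = 4, ...) {
  cat("markov_estimate: stationary probability ",
      format(x$mean_probability, digits = digits), " +/- ",
      format(x$error, digits = digits), "  (empirical ",
      format(x$empirical, digits = digits), ", ", x$n_samples,
      " posterior samples)\n", sep = "")
  invisible(x)
}

#' Markov estimates for every residue/bit series of a fingerprint matrix
#'
#' All-zero series are reported with probability 0 and error 0 without
#' sampling; by default all-one series are likewise not informative about
#' transitions and are sampled like any other series.
#'
#' @param matrix a `fingerprint_matrix`.
#' @param n_samples posterior draws per series.
#' @param seed base RNG seed; each series uses a distinct deterministic
#'   offset so results do not depend on evaluation order.
#' @param prior Dirichlet pseudo-count per cell.
#' @param drop_zero drop all-zero series from the output (default TRUE).
#' @return data.frame with one row per (residue, bit): chain, resno,
#'   resname, bit, probability, error, empirical and the four transition
#'   counts.
#' @export
summarize_matrix <- function(matrix, n_samples = 10000L, seed, prior = 1,
                             drop_zero = TRUE) {
  stopifnot(inherits(matrix, "fingerprint_matrix"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  res <- attr(matrix, "residues")
  bits <- fp_bit_names()
  rows <- list()
  for (r in seq_len(dim(matrix)[1])) for (b in seq_along(bits)) {
    series <- as.integer(matrix[r, , b])
    if (all(series == 0L)) {
      if (drop_zero) next
      est <- list(mean_probability = 0, error = 0, empirical = 0)
      counts <- matrix(c(length(series) - 1L, 0L, 0L, 0L), 2, 2)
    } else {
      counts <- count_transitions(series)
      est <- posterior_probability(counts, n_samples = n_samples,
                                   seed = (as.integer(seed) +
                                             997L * r + 13L * b) %% .Machine$integer.max,
                                   prior = prior)
    }
    rows[[length(rows) + 1]] <- data.frame(
      chain = res$chain[r], resno = res$resno[r], resname = res$resname[r],
      bit = bits[b], probability = est$mean_probability, error = est$error,
      empirical = est$empirical,
      c00 = counts[1, 1], c01 = counts[1, 2],
      c10 = counts[2, 1], c11 = counts[2, 2],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), bit = character(),
                      probability = numeric(), error = numeric(),
                      empirical = numeric(), c00 = integer(),
                      c01 = integer(), c10 = integer(), c11 = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
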