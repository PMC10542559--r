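#' Effective-size trajectory objects
#'
#' An `ne_traj` holds the per-generation effective population size N_g for
#' generations `gmin..gmax` before present, optionally with bootstrap
#' replicate trajectories. It prints and plots like a tibble with columns
#' `generation` and `Ne`; replicates live in a `boot` attribute (a
#' generations-by-replicates matrix) so the point trajectory stays tidy.
#'
#' @param generation Integer vector `gmin:gmax` (consecutive, `gmin >= 1`).
#' @param Ne Positive effective sizes, one per generation.
#' @param boot Optional matrix of bootstrap replicates,
#'   `length(generation)` rows by B columns.
#' @return A tibble of class `ne_traj`.
#' @examples
#' ne_traj(1:10, rep(1e4, 10))
#' @export
ne_traj <- function(generation, Ne, boot = NULL) {
  generation <- as.integer(generation)
  if (length(generation) == 0L || generation[1L] < 1L ||
      !all(diff(generation) == 1L)) {
    stop("`generation` must be consecutive integers starting at gmin >= 1",
         call. = FALSE)
  }
  if (length(Ne) != length(generation) || any(!is.finite(Ne)) || any(Ne <= 0)) {
    stop("`Ne` must be positive and match `generation` in length", call. = FALSE)
  }
  if (!is.null(boot)) {
    boot <- as.matrix(boot)
    if (nrow(boot) != length(generation)) {
      stop("bootstrap replicates must share the trajectory's generation range",
           call. = FALSE)
    }
  }
  structure(tibble::tibble(generation = generation, Ne = as.numeric(Ne)),
            boot = boot,
            class = c("ne_traj", class(tibble::tibble())))
}

#' @export
print.ne_traj <- function(x, ...) {
  b <- attr(x, "boot")
  cat(sprintf("<ne_traj> generations %d..%d%s\n",
              x$generation[1L], x$generation[nrow(x)],
              if (is.null(b)) "" else sprintf(", %d bootstrap replicates", ncol(b))))
  NextMethod()
}

#' Number of bootstrap replicates carried by a trajectory
#' @param traj An `ne_traj`.
#' @return Integer count (0 when none).
#' @export
n_boot <- function(traj) {
  b <- attr(traj, "boot")
  if (is.null(b)) 0L else ncol(b)
}

#' Probability that an ancestral X haplotype is carried by a female
#'
#' A haplotype carried by a female has probability 1/2 that its parent
#' haplotype is carried by a female; a haplotype carried by a male inherited
#' its X from its mother, so its parent haplotype is always female-borne.
#' Iterating p_{g+1} = 1 - p_g / 2 from the sampled generation gives the
#' closed form
#' \deqn{p_g = \frac{2}{3}\left(1 - (-\tfrac12)^g\right) + (-\tfrac12)^g p_0,}
#' which converges to 2/3 and is exactly 2/3 at every generation when the
#' sample has equal numbers of females and males (p_0 = 2/3).
#'
#' @param g Generation(s) before present, non-negative integers.
#' @param p0 Probability the sampled haplotype is female-borne (default 2/3,
#'   the balanced-sample value).
#' @return Vector of probabilities p_g.
#' @export
female_carrier_prob <- function(g, p0 = 2 / 3) {
  if (any(g < 0) || any(g != round(g))) {
    stop("`g` must be non-negative integers", call. = FALSE)
  }
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must be a probability", call. = FALSE)
  (2 / 3) * (1 - (-1 / 2)^g) + (-1 / 2)^g * p0
}

# Unconditioned binomial(2g, 2/3) pmf over f = 0..2g female meioses.
female_meiosis_pmf <- function(g) {
  stats::dbinom(0:(2L * g), size = 2L * g, prob = 2 / 3)
}

#' Exact X-linked IBD segment length density
#'
#' For a coalescence g generations back, the inheritance path holds 2g
#' meioses, of which F are female with F ~ binomial(2g, 2/3). Only female
#' meioses recombine on the X, at rate 3/2 per sex-averaged Morgan, so given
#' F the segment length is exponential with rate 3F/2. The marginal density
#' is the binomial mixture, conditioned on F >= 1: a path with no female
#' meiosis undergoes no recombination and spans the whole chromosome, so it
#' contributes no finite-length segment. That conditioning is the one place
#' the F = 0 corner is handled.
#'
#' @param l Segment length(s) in Morgans, positive.
#' @param g Generation of coalescence, integer >= 1.
#' @return Density values.
#' @seealso [x_length_pdf_approx()] for the exponential(2g) approximation.
#' @export
x_length_pdf_exact <- function(l, g) {
  stopifnot(length(g) == 1L)
  if (g < 1 || g != round(g)) stop("`g` must be an integer >= 1", call. = FALSE)
  if (any(l <= 0)) stop("lengths must be positive", call. = FALSE)
  g <- as.integer(g)
  pf <- female_meiosis_pmf(g)
  f <- seq_along(pf) - 1L
  keep <- f >= 1L
  w <- pf[keep] / sum(pf[keep])
  rate <- 3 * f[keep] / 2
  # density: sum_f w_f * rate_f * exp(-rate_f * l)
  vapply(l, function(x) sum(w * rate * exp(-rate * x)), numeric(1))
}

#' Approximate X-linked IBD segment length density
#'
#' The exponential(2g) model used for autosomal IBD lengths, applied to the
#' X on the sex-averaged scale. It replaces the binomial-mixture rate 3F/2
#' (mean 2g) by its mean and is a close approximation for g > 1.
#'
#' @param l Segment length(s) in Morgans, non-negative.
#' @param g Generation of coalescence, >= 1.
#' @return Density `2g * exp(-2g * l)`.
#' @export
x_length_pdf_approx <- function(l, g) {
  stopifnot(length(g) == 1L, g >= 1)
  if (any(l < 0)) stop("lengths must be non-negative", call. = FALSE)
  2 * g * exp(-2 * g * l)
}

#' Sample IBD segment lengths from the exact X model
#' @param n Number of draws.
#' @param g Coalescence generation, integer >= 1.
#' @return Lengths in Morgans.
#' @export
r_x_length_exact <- function(n, g) {
  stopifnot(g >= 1, g == round(g))
  g <- as.integer(g)
  pf <- female_meiosis_pmf(g)
  f <- seq_along(pf) - 1L
  keep <- f >= 1L
  fs <- sample(f[keep], n, replace = TRUE, prob = pf[keep])
  stats::rexp(n, rate = 3 * fs / 2)
}

#' Sample IBD segment lengths from the exponential(2g) approximation
#' @inheritParams r_x_length_exact
#' @return Lengths in Morgans.
#' @export
r_x_length_approx <- function(n, g) {
  stopifnot(g >= 1)
  stats::rexp(n, rate = 2 * g)
}

#' Per-generation coalescence probabilities under a size trajectory
#'
#' In a Wright-Fisher population of (haploid-equivalent) size N_g, a pair of
#' uncoalesced lineages coalesces at generation g with conditional
#' probability 1/(2 N_g). The unconditional mass is
#' \deqn{q_g = \frac{1}{2N_g} \prod_{i=g_{min}}^{g-1}\left(1-\frac{1}{2N_i}\right).}
#' The trajectory can be extended beyond its last generation with a constant
#' tail (`g_tail`) so that nearly all coalescent mass is accounted for when
#' computing expected IBD spectra.
#'
#' @param traj An `ne_traj`.
#' @param g_tail Final generation of the constant-size tail extension
#'   (default 500); use `max(traj$generation)` for no extension.
#' @return Tibble with columns `generation`, `Ne`, `q` (coalescence mass).
#' @export
coalescence_distribution <- function(traj, g_tail = 500L) {
  stopifnot(inherits(traj, "ne_traj"))
  gmax <- traj$generation[nrow(traj)]
  g_tail <- max(as.integer(g_tail), gmax)
  gens <- c(traj$generation, if (g_tail > gmax) (gmax + 1L):g_tail)
  Ne <- c(traj$Ne, rep(traj$Ne[nrow(traj)], g_tail - gmax))
  if (any(Ne <= 0.5)) {
    stop("all N_g must exceed 1/2 for valid conditional probabilities",
         call. = FALSE)
  }
  cond <- 1 / (2 * Ne)
  surv <- cumprod(1 - cond)
  q <- cond * c(1, surv[-length(surv)])
  tibble::tibble(generation = gens, Ne = Ne, q = q)
}

#' Expected IBD length spectrum for a size trajectory
#'
#' Under the exponential(2g) length model, haplotype pairs coalescing at
#' generation g carry segments of mean length 1/(2g) Morgans tiling the
#' chromosome, about `2gL` segments across a map of length L, each exceeding
#' a length `x` with probability `exp(-2gx)`. The expected count in bin
#' `[a, b)` is therefore
#' \deqn{E = n_{pairs} \sum_g q_g \, 2gL \, (e^{-2ga} - e^{-2gb}),}
#' with the last bin open (`b = Inf`). Chromosome-end effects are ignored.
#'
#' @param traj An `ne_traj` (its constant tail is extended to `g_tail`).
#' @param L Total analysed map length in Morgans.
#' @param npairs Number of analysed haplotype pairs.
#' @param bin_edges Increasing vector of bin left edges in Morgans; bin i is
#'   `[edge_i, edge_{i+1})`, the last bin `[edge_m, Inf)`.
#' @param g_tail Constant-tail depth passed to [coalescence_distribution()].
#' @return Tibble with columns `bin_lo`, `bin_hi`, `expected`.
#' @export
expected_spectrum <- function(traj, L, npairs, bin_edges, g_tail = 500L) {
  stopifnot(L > 0, npairs >= 1)
  if (length(bin_edges) < 1L || any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be increasing", call. = FALSE)
  }
  cd <- coalescence_distribution(traj, g_tail = g_tail)
  w <- spectrum_weights(cd$generation, L, bin_edges)
  tibble::tibble(
    bin_lo = bin_edges,
    bin_hi = c(bin_edges[-1L], Inf),
    expected = as.numeric(npairs * (t(w) %*% cd$q))
  )
}

# Weight matrix w[g, b] = 2gL (exp(-2g a_b) - exp(-2g b_b)); last bin open.
# Factored out so the estimator can precompute it once per spectrum.
spectrum_weights <- function(gens, L, bin_edges) {
  a <- bin_edges
  b <- c(bin_edges[-1L], Inf)
  ea <- exp(-2 * outer(gens, a))
  eb <- exp(-2 * outer(gens, b))
  eb[, length(b)] <- 0
  (2 * gens * L) * (ea - eb)
}
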