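#' Configuration for the spectrum-matching Ne estimator
#'
#' @param threshold_u Minimum IBD length analysed, in Morgans (default 0.02,
#'   i.e. 2 cM on the sex-averaged scale).
#' @param gmin First modelled generation. Use 1 for simulated data where
#'   chromosomes are independent and sibling-like sharing one generation
#'   back is legitimate; 2 for real data where close relatives have been
#'   removed explicitly.
#' @param gmax Last estimated generation (default 100).
#' @param smooth_window Spacing of the piecewise-linear knots of log N in
#'   generations (default 8); wider windows smooth more.
#' @param bin_width Width of the length-spectrum bins in Morgans (default
#'   5e-4, i.e. 0.05 cM).
#' @param g_tail Depth of the constant-size coalescent tail appended beyond
#'   `gmax` when computing expected spectra (default 500), deep enough that
#'   essentially all coalescent mass contributing segments above the length
#'   threshold is covered.
#' @param smooth_penalty Weight of the quadratic curvature penalty applied to
#'   the knot values of log N, per squared slope-change across an
#'   8-generation span and per 1,000 observed segments (default 3). The IBD
#'   length spectrum is a mixture of near-identical exponential kernels, so
#'   the deviance surface has long flat valleys along which oscillating
#'   trajectories trade off against each other; the penalty selects the
#'   smooth representative. It is scaled by the observed segment count so
#'   that the penalty-to-deviance ratio — and hence the effective smoothing
#'   bandwidth — is stable across data sizes. Zero disables it.
#' @param max_iter Optimiser iteration cap.
#' @param rel_tol Relative convergence tolerance of the optimiser.
#' @param n_boot Bootstrap replicate count (default 80).
#' @param seed Root seed; per-replicate seeds are derived by fixed offsets.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(threshold_u = 0.02, gmin = 2L, gmax = 100L,
                       smooth_window = 8L, bin_width = 5e-4, g_tail = 500L,
                       smooth_penalty = 3, max_iter = 2000L, rel_tol = 2e-11,
                       n_boot = 80L, seed = 1L) {
  stopifnot(threshold_u > 0, gmin >= 1, gmax > gmin, smooth_window >= 1,
            bin_width > 0, smooth_penalty >= 0, n_boot >= 0)
  structure(list(threshold_u = threshold_u, gmin = as.integer(gmin),
                 gmax = as.integer(gmax),
                 smooth_window = as.integer(smooth_window),
                 bin_width = bin_width, g_tail = as.integer(g_tail),
                 smooth_penalty = smooth_penalty,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "fit_config")
}

#' Bin observed IBD segment lengths into a spectrum
#'
#' Counts segments at or above the length threshold into contiguous
#' equal-width bins (plus an implicit open tail starting at the last edge).
#' Lengths must already be on the sex-averaged scale for X data.
#'
#' @param segments Segment tibble with `length_cm` on the analysis scale.
#' @param npairs Analysed haplotype-pair count (after balancing and
#'   relative removal).
#' @param total_length_cm Total analysed map length in cM (summed over
#'   chromosomes or pieces).
#' @param config A [fit_config()].
#' @return A tibble of class `ibd_spectrum` with columns `bin_lo`, `bin_hi`
#'   (Morgans) and `count`, and attributes `npairs`, `L` (Morgans), `u`.
#' @export
observed_spectrum <- function(segments, npairs, total_length_cm, config = fit_config()) {
  if (npairs <= 0) stop("`npairs` must be positive", call. = FALSE)
  if (total_length_cm <= 0) stop("map length must be positive", call. = FALSE)
  u <- config$threshold_u
  len <- segments$length_cm / 100
  len <- len[len >= u]
  if (length(len) == 0L) {
    warning("no segments at or above the length threshold")
    edges <- c(u, u + config$bin_width)
  } else {
    n_bins <- max(1L, ceiling((max(len) - u) / config$bin_width + 1e-12))
    edges <- u + config$bin_width * (0:n_bins)
  }
  counts <- if (length(len)) {
    tabulate(pmin(findInterval(len, edges, rightmost.closed = FALSE),
                  length(edges) - 1L),
             nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  structure(tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1L],
    count = counts
  ), npairs = npairs, L = total_length_cm / 100, u = u,
     class = c("ibd_spectrum", class(tibble::tibble())))
}

# Piecewise-linear interpolation of log N over knot generations.
knot_generations <- function(config) {
  kn <- seq(config$gmin, config$gmax, by = config$smooth_window)
  if (kn[length(kn)] != config$gmax) kn <- c(kn, config$gmax)
  as.integer(kn)
}

interp_log_ne <- function(knots, log_ne, gens) {
  stats::approx(knots, log_ne, xout = gens, method = "linear", rule = 2)$y
}

# Poisson deviance between observed counts and expected counts.
poisson_deviance <- function(obs, exp_) {
  exp_ <- pmax(exp_, 1e-12)
  ll <- ifelse(obs > 0, obs * log(obs / exp_), 0)
  2 * sum(ll - (obs - exp_))
}

#' Fit an effective-size trajectory to an observed IBD length spectrum
#'
#' Finds the per-generation effective size history whose expected IBD
#' length spectrum (see [expected_spectrum()]) matches the observed one,
#' by minimising the Poisson deviance of the binned counts. To avoid
#' overfitting, log N is constrained piecewise-linear over knots spaced
#' `smooth_window` generations apart (default 8), and slope changes across
#' knots carry a quadratic penalty (`smooth_penalty`): adjacent coalescence
#' generations produce nearly identical length kernels, so without the
#' penalty the deviance admits wildly oscillating trajectories at
#' essentially the same fit quality. Optimisation is quasi-Newton
#' (L-BFGS-B) over the knot values, initialised from a constant-size moment
#' match of the total segment count; the fit is deterministic given the
#' configuration.
#'
#' For generations more recent than `gmin`, the trajectory reports an
#' extrapolation continuing the growth rate of the first estimable window
#' toward generation 0 (attribute `extrapolated_recent`); these values are
#' not constrained by data.
#'
#' @param spectrum An `ibd_spectrum` from [observed_spectrum()], or any
#'   tibble with `bin_lo`/`count` plus `npairs`/`L` attributes.
#' @param config A [fit_config()].
#' @return An [ne_traj()] for generations `gmin..gmax`, with attributes
#'   `converged` (logical), `deviance`, `config`, and `extrapolated_recent`
#'   (a tibble for generations `0..gmin-1`, present when `gmin > 1`).
#' @export
fit_ne <- function(spectrum, config = fit_config()) {
  obs <- spectrum$count
  if (all(obs == 0)) stop("spectrum is empty: nothing to fit", call. = FALSE)
  npairs <- attr(spectrum, "npairs")
  L <- attr(spectrum, "L")
  edges <- spectrum$bin_lo
  u <- edges[1L]
  gens <- seq(config$gmin, config$g_tail)
  w <- spectrum_weights(gens, L, edges)   # |gens| x |bins|
  single_bin <- sum(obs > 0) == 1L
  knots <- knot_generations(config)

  expected_counts <- function(log_ne_knots) {
    log_ne <- interp_log_ne(knots, log_ne_knots, pmin(gens, config$gmax))
    Ne <- exp(log_ne)
    cond <- 1 / (2 * Ne)
    q <- cond * c(1, cumprod(1 - cond)[-length(cond)])
    npairs * as.numeric(q %*% w)
  }

  # slope changes of log N across knots, expressed per smooth_window span so
  # the penalty is invariant to the (possibly uneven) final knot spacing
  curvature <- function(p) {
    diff(diff(p) / diff(knots)) * config$smooth_window
  }

  # constant-N moment match on the total count: monotone in N, bracket and
  # bisect on log N
  total_obs <- sum(obs)
  nk <- length(knots)
  tot_at <- function(logn) sum(expected_counts(rep(logn, nk)))
  lo <- log(1); hi <- log(1e9)
  f_lo <- tot_at(lo) - total_obs; f_hi <- tot_at(hi) - total_obs
  log_n0 <- if (f_lo < 0) lo else if (f_hi > 0) hi else {
    stats::uniroot(function(x) tot_at(x) - total_obs, c(lo, hi),
                   tol = 1e-10)$root
  }

  if (single_bin) {
    warning("single nonzero bin: returning constant-size moment match only")
    fit_par <- rep(log_n0, nk); conv <- TRUE
  } else {
    lambda <- config$smooth_penalty * total_obs / 1e3
    opt <- stats::optim(
      par = rep(log_n0, nk),
      fn = function(p) {
        poisson_deviance(obs, expected_counts(p)) +
          lambda * sum(curvature(p)^2)
      },
      method = "L-BFGS-B",
      lower = log(1), upper = log(1e12),
      control = list(maxit = config$max_iter,
                     factr = config$rel_tol / .Machine$double.eps)
    )
    fit_par <- opt$par
    conv <- opt$convergence == 0L
    if (!conv) {
      warning("optimiser did not report convergence; returning last iterate")
    }
  }

  g_out <- config$gmin:config$gmax
  Ne <- exp(interp_log_ne(knots, fit_par, g_out))
  traj <- ne_traj(g_out, Ne)
  attr(traj, "converged") <- conv
  attr(traj, "deviance") <- poisson_deviance(obs, expected_counts(fit_par))
  attr(traj, "config") <- config
  if (config$gmin > 1L) {
    # continue the growth rate of the first estimable window toward g = 0
    w1 <- min(config$smooth_window, length(g_out) - 1L)
    rate <- (log(Ne[1L + w1]) - log(Ne[1L])) / w1
    g_recent <- 0:(config$gmin - 1L)
    attr(traj, "extrapolated_recent") <- tibble::tibble(
      generation = g_recent,
      Ne = exp(log(Ne[1L]) - rate * (config$gmin - g_recent)),
      extrapolated = TRUE
    )
  }
  traj
}

#' Bootstrap the Ne fit over chromosomes or chromosome pieces
#'
#' Resamples whole chromosomes (for the X: the equal-cM pieces produced by
#' [split_into_pieces()]) with replacement, recomputing the analysed map
#' length per replicate and refitting. Requires at least two groups.
#' Reproducible: replicate r uses seed `config$seed + r`.
#'
#' @param segments Segment tibble whose `chrom` column defines the groups.
#' @param npairs Analysed haplotype-pair count.
#' @param group_lengths_cm Named numeric vector: analysed cM length of each
#'   chromosome/piece (names matching `chrom` values).
#' @param config A [fit_config()]; `n_boot` replicates are drawn.
#' @return An [ne_traj()] whose point estimate uses all groups, with a
#'   `boot` attribute holding the replicate trajectories (when
#'   `n_boot > 0`).
#' @export
bootstrap_ne <- function(segments, npairs, group_lengths_cm,
                         config = fit_config()) {
  groups <- names(group_lengths_cm)
  if (is.null(groups) || length(groups) < 2L) {
    stop("bootstrap needs at least 2 named chromosome groups", call. = FALSE)
  }
  missing_groups <- setdiff(unique(segments$chrom), groups)
  if (length(missing_groups)) {
    stop("segments reference unknown groups: ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  point <- fit_ne(
    observed_spectrum(segments, npairs, sum(group_lengths_cm), config),
    config
  )
  if (config$n_boot == 0L) return(point)

  by_group <- split(seq_len(nrow(segments)), segments$chrom)
  boot <- matrix(NA_real_, nrow = nrow(point), ncol = config$n_boot)
  for (r in seq_len(config$n_boot)) {
    picks <- withr::with_seed(config$seed + r,
                              sample(groups, length(groups), replace = TRUE))
    idx <- unlist(by_group[picks], use.names = FALSE)
    seg_r <- segments[idx, , drop = FALSE]
    L_r <- sum(group_lengths_cm[picks])
    fit_r <- fit_ne(observed_spectrum(seg_r, npairs, L_r, config), config)
    boot[, r] <- fit_r$Ne
  }
  out <- ne_traj(point$generation, point$Ne, boot = boot)
  for (a in c("converged", "deviance", "config", "extrapolated_recent")) {
    attr(out, a) <- attr(point, a)
  }
  out
}

#' Write an Ne trajectory (with replicates) to TSV
#'
#' Columns: `generation`, `Ne`, `lo2.5`, `hi97.5` (percentile interval over
#' replicates, `NA` without bootstrap), then one `boot<r>` column per
#' replicate — the replicate columns are what the paired sex-specific
#' transformation consumes.
#'
#' @param traj An [ne_traj()].
#' @param path Output path; `.gz` honoured.
#' @param header_lines Optional provenance comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_ne_traj <- function(traj, path, header_lines = character()) {
  stopifnot(inherits(traj, "ne_traj"))
  b <- attr(traj, "boot")
  out <- tibble::tibble(generation = traj$generation, Ne = traj$Ne)
  if (!is.null(b)) {
    qs <- t(apply(b, 1L, stats::quantile, probs = c(0.025, 0.975), names = FALSE))
    out$lo2.5 <- qs[, 1L]; out$hi97.5 <- qs[, 2L]
    colnames(b) <- paste0("boot", seq_len(ncol(b)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(b))
  } else {
    out$lo2.5 <- NA_real_; out$hi97.5 <- NA_real_
  }
  write_tsv_with_header(out, path, header_lines)
}

#' Read an Ne trajectory written by [write_ne_traj()]
#' @param path Path to the TSV.
#' @return An [ne_traj()] with any replicate columns restored as bootstrap.
#' @export
read_ne_traj <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  bcols <- grep("^boot[0-9]+$", names(tab), value = TRUE)
  boot <- if (length(bcols)) as.matrix(tab[, bcols]) else NULL
  ne_traj(tab$generation, tab$Ne, boot = boot)
}
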