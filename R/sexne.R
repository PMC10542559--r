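#' X-chromosome effective size implied by sex-specific sizes
#'
#' On the X, 2/3 of transmitting meioses are from females and 1/3 from males,
#' and males are haploid, so a pair of uncoalesced lineages coalesces with
#' conditional probability \eqn{(2/3)^2/(2N_f) + (1/3)^2/N_m}. The X
#' effective size is half the inverse of that probability:
#' \deqn{N_X = \frac{9 N_f N_m}{2 N_f + 4 N_m}.}
#'
#' @param Nf,Nm Positive female and male effective sizes (vectorised).
#' @return X-chromosome effective size(s).
#' @export
nx_from_sexes <- function(Nf, Nm) {
  check_positive(Nf, Nm)
  9 * Nf * Nm / (2 * Nf + 4 * Nm)
}

#' Autosomal effective size implied by sex-specific sizes
#'
#' With half of meioses from each sex and diploid males, the autosomal
#' conditional coalescence probability is \eqn{(1/2)^2/(2N_f) +
#' (1/2)^2/(2N_m)}, giving the familiar harmonic form
#' \deqn{N_A = \frac{4 N_f N_m}{N_f + N_m},} symmetric in its arguments.
#'
#' @inheritParams nx_from_sexes
#' @return Autosomal effective size(s).
#' @export
na_from_sexes <- function(Nf, Nm) {
  check_positive(Nf, Nm)
  4 * Nf * Nm / (Nf + Nm)
}

#' Ratio of X to autosomal effective population size
#'
#' \deqn{\alpha = \frac{N_X}{N_A} = \frac{9 (N_f + N_m)}{8 (N_f + 2 N_m)}.}
#' Alpha is strictly decreasing in the ratio Nm/Nf and is confined to the
#' open interval (9/16, 9/8); equal sex-specific sizes give exactly 3/4,
#' which is why an X trajectory is conventionally compared with 75% of the
#' autosomal trajectory.
#'
#' @inheritParams nx_from_sexes
#' @return Alpha value(s), strictly inside (9/16, 9/8).
#' @export
alpha_ratio <- function(Nf, Nm) {
  check_positive(Nf, Nm)
  9 * (Nf + Nm) / (8 * (Nf + 2 * Nm))
}

#' Sex-specific effective sizes from X and autosomal effective sizes
#'
#' Inverts the forward relations of [nx_from_sexes()] and [na_from_sexes()]:
#' \deqn{N_f = \frac{2 N_X N_A}{9 N_A - 8 N_X}, \qquad
#'       N_m = \frac{2 N_X N_A}{16 N_X - 9 N_A}.}
#' A consistent pair satisfies 9/16 < N_X/N_A < 9/8. Estimation error can
#' push the ratio outside that band, making a denominator non-positive; the
#' affected estimate is then not scientifically meaningful and is returned
#' as `NA` rather than as a negative size. N_X too high (or N_A too low)
#' invalidates the female estimate; N_X too low invalidates the male one.
#'
#' @param NX,NA_ Positive X-chromosome and autosomal effective sizes
#'   (vectorised; the autosomal argument carries a trailing underscore since
#'   `NA` is reserved in R).
#' @return Tibble with columns `Nf` and `Nm`; undefined values are `NA`.
#' @examples
#' sexes_from_nx_na(150, 200)   # recovers Nf = Nm = 100
#' @export
sexes_from_nx_na <- function(NX, NA_) {
  check_positive(NX, NA_)
  num <- 2 * NX * NA_
  Nf <- num / (9 * NA_ - 8 * NX)
  Nm <- num / (16 * NX - 9 * NA_)
  Nf[!is.finite(Nf) | Nf <= 0] <- NA_real_
  Nm[!is.finite(Nm) | Nm <= 0] <- NA_real_
  tibble::tibble(Nf = Nf, Nm = Nm)
}

check_positive <- function(...) {
  args <- list(...)
  nm <- vapply(substitute(list(...))[-1L], deparse, character(1))
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]])) || any(args[[i]] <= 0)) {
      stop("`", nm[i], "` must be positive and finite", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Sex-specific trajectories with paired-bootstrap confidence intervals
#'
#' Transforms an X-chromosome and an autosomal effective-size trajectory into
#' female and male trajectories via [sexes_from_nx_na()]. Uncertainty is
#' propagated by the paired bootstrap: the n-th bootstrap replicate of the X
#' trajectory is combined with the n-th replicate of the autosomal trajectory
#' at each generation, and the 2.5th and 97.5th percentiles of the
#' transformed replicates give an approximate 95% interval. Replicates whose
#' transform is undefined at a generation (the X/autosome ratio fell outside
#' (9/16, 9/8)) are excluded from the percentiles; their count is reported
#' per generation so the interval's reliability can be judged.
#'
#' @param x_traj,a_traj `ne_traj` objects sharing the same generation range
#'   and the same number of bootstrap replicates (at least 1 each).
#' @return A tibble of class `sex_ne` with columns `generation`, `Nf`,
#'   `Nf_lo`, `Nf_hi`, `Nm`, `Nm_lo`, `Nm_hi`, `alpha`,
#'   `n_undefined_boot_f`, `n_undefined_boot_m`. Undefined values are `NA`;
#'   no negative size is ever emitted.
#' @export
sexne_with_ci <- function(x_traj, a_traj) {
  stopifnot(inherits(x_traj, "ne_traj"), inherits(a_traj, "ne_traj"))
  if (!identical(x_traj$generation, a_traj$generation)) {
    stop("trajectories must share the same generation range", call. = FALSE)
  }
  bx <- attr(x_traj, "boot"); ba <- attr(a_traj, "boot")
  if (is.null(bx) || is.null(ba) || ncol(bx) != ncol(ba)) {
    stop("both trajectories need equal numbers of bootstrap replicates",
         call. = FALSE)
  }
  point <- sexes_from_nx_na(x_traj$Ne, a_traj$Ne)

  pct <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) c(NA_real_, NA_real_)
    else stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  }
  G <- nrow(x_traj)
  lo_f <- hi_f <- lo_m <- hi_m <- numeric(G)
  nun_f <- nun_m <- integer(G)
  for (i in seq_len(G)) {
    rep_i <- sexes_from_nx_na(bx[i, ], ba[i, ])
    qf <- pct(rep_i$Nf); qm <- pct(rep_i$Nm)
    lo_f[i] <- qf[1L]; hi_f[i] <- qf[2L]
    lo_m[i] <- qm[1L]; hi_m[i] <- qm[2L]
    nun_f[i] <- sum(is.na(rep_i$Nf))
    nun_m[i] <- sum(is.na(rep_i$Nm))
  }
  structure(tibble::tibble(
    generation = x_traj$generation,
    Nf = point$Nf, Nf_lo = lo_f, Nf_hi = hi_f,
    Nm = point$Nm, Nm_lo = lo_m, Nm_hi = hi_m,
    alpha = x_traj$Ne / a_traj$Ne,
    n_undefined_boot_f = nun_f,
    n_undefined_boot_m = nun_m
  ), class = c("sex_ne", class(tibble::tibble())))
}

#' Write a sex-specific trajectory table to TSV
#' @param x A `sex_ne` tibble from [sexne_with_ci()].
#' @param path Output path; `.gz` honoured.
#' @param header_lines Optional provenance comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_sex_ne <- function(x, path, header_lines = character()) {
  stopifnot(inherits(x, "sex_ne"))
  write_tsv_with_header(x, path, header_lines)
}
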