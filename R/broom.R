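#' Tidy an effective-size trajectory
#'
#' Returns one row per generation (and per bootstrap replicate when
#' `replicates = TRUE`), pipe-friendly for dplyr/ggplot2 work.
#'
#' @param x An [ne_traj()].
#' @param replicates Include bootstrap replicates as extra rows with a
#'   `replicate` column (`NA` for the point estimate)?
#' @param ... Unused.
#' @return A tibble with columns `generation`, `Ne`, `replicate`, and, when
#'   a bootstrap is present, `lo2.5`/`hi97.5` on the point rows.
#' @export
tidy.ne_traj <- function(x, replicates = FALSE, ...) {
  b <- attr(x, "boot")
  out <- tibble::tibble(generation = x$generation, Ne = x$Ne,
                        replicate = NA_integer_)
  if (!is.null(b)) {
    qs <- t(apply(b, 1L, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
    out$lo2.5 <- qs[, 1L]
    out$hi97.5 <- qs[, 2L]
    if (replicates) {
      reps <- purrr::map_dfr(seq_len(ncol(b)), function(r) {
        tibble::tibble(generation = x$generation, Ne = b[, r],
                       replicate = r, lo2.5 = NA_real_, hi97.5 = NA_real_)
      })
      out <- dplyr::bind_rows(out, reps)
    }
  }
  out
}

#' One-row summary of an effective-size trajectory
#' @param x An [ne_traj()].
#' @param ... Unused.
#' @return Tibble with `gmin`, `gmax`, `n_boot`, `Ne_recent` (first
#'   generation), `Ne_oldest`, `converged`, `deviance`.
#' @export
glance.ne_traj <- function(x, ...) {
  tibble::tibble(
    gmin = x$generation[1L],
    gmax = x$generation[nrow(x)],
    n_boot = n_boot(x),
    Ne_recent = x$Ne[1L],
    Ne_oldest = x$Ne[nrow(x)],
    converged = attr(x, "converged") %||% NA,
    deviance = attr(x, "deviance") %||% NA_real_
  )
}

#' Tidy a sex-specific trajectory into long format
#' @param x A `sex_ne` from [sexne_with_ci()].
#' @param ... Unused.
#' @return Long tibble with columns `generation`, `sex` (`"female"` /
#'   `"male"`), `Ne`, `lo`, `hi`, `alpha`, `n_undefined_boot`.
#' @export
tidy.sex_ne <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(generation = x$generation, sex = "female", Ne = x$Nf,
                   lo = x$Nf_lo, hi = x$Nf_hi, alpha = x$alpha,
                   n_undefined_boot = x$n_undefined_boot_f),
    tibble::tibble(generation = x$generation, sex = "male", Ne = x$Nm,
                   lo = x$Nm_lo, hi = x$Nm_hi, alpha = x$alpha,
                   n_undefined_boot = x$n_undefined_boot_m)
  )
}

#' One-row summary of a sex-specific trajectory
#' @param x A `sex_ne`.
#' @param ... Unused.
#' @return Tibble with generation range, counts of undefined female/male
#'   generations, and the median alpha.
#' @export
glance.sex_ne <- function(x, ...) {
  tibble::tibble(
    gmin = x$generation[1L],
    gmax = x$generation[nrow(x)],
    n_undefined_f = sum(is.na(x$Nf)),
    n_undefined_m = sum(is.na(x$Nm)),
    alpha_median = stats::median(x$alpha, na.rm = TRUE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot an effective-size trajectory
#'
#' Ne against generations before present on a log scale, with the 2.5-97.5
#' percentile bootstrap ribbon when replicates are present.
#'
#' @param object An [ne_traj()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ne_traj <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$Ne))
  if (!is.null(attr(object, "boot"))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo2.5, ymax = .data$hi97.5),
      fill = "grey70", alpha = 0.5)
  }
  p + ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "effective size (Ne)")
}

#' Plot female and male effective-size trajectories
#'
#' Both sexes on one log-scale panel with their percentile ribbons;
#' generations with undefined (out-of-band) estimates are simply not drawn.
#'
#' @param object A `sex_ne` from [sexne_with_ci()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_ne <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$Ne,
                                  colour = .data$sex, fill = .data$sex)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "effective size (Ne)")
}
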