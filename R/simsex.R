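#' Two-sex demographic models
#'
#' A `sex_demography` is a function-backed object giving the female and male
#' population sizes at any generation before present, built from contiguous
#' epochs of continuous exponential growth: within an epoch starting (going
#' forward in time) from size `N_start` at generation `g_start`, the total
#' size at generation `g` is `N_start * exp(r * (g_start - g))`.
#'
#' @param epochs Tibble with columns `g_start` (older bound), `g_end`
#'   (younger bound, `g_end < g_start`), `rate` (per-generation continuous
#'   growth rate going forward in time). Epochs must be contiguous from the
#'   history depth down to generation 0.
#' @param n_base Total size at the oldest epoch boundary.
#' @param female_fraction Proportion of the total size that is female
#'   (default 0.5).
#' @return A list of class `sex_demography` with a `$size(g)` function
#'   returning a tibble (`Nf`, `Nm`, `N`) for a vector of generations.
#' @export
sex_demography <- function(epochs, n_base, female_fraction = 0.5) {
  if (female_fraction <= 0 || female_fraction >= 1) {
    stop("`female_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  epochs <- dplyr::arrange(tibble::as_tibble(epochs), dplyr::desc(.data$g_start))
  if (any(epochs$g_end >= epochs$g_start)) {
    stop("each epoch needs g_end < g_start", call. = FALSE)
  }
  if (any(utils::head(epochs$g_end, -1L) != utils::tail(epochs$g_start, -1L)) ||
      epochs$g_end[nrow(epochs)] != 0) {
    stop("epochs must be contiguous down to generation 0", call. = FALSE)
  }
  # precompute total size at each epoch start
  n_at_start <- numeric(nrow(epochs))
  n_at_start[1L] <- n_base
  for (i in seq_len(nrow(epochs))[-1L]) {
    e <- epochs[i - 1L, ]
    n_at_start[i] <- n_at_start[i - 1L] * exp(e$rate * (e$g_start - e$g_end))
  }
  total_size <- function(g) {
    vapply(g, function(gg) {
      if (gg >= epochs$g_start[1L]) return(n_base)
      i <- which(gg < epochs$g_start & gg >= epochs$g_end)[1L]
      n_at_start[i] * exp(epochs$rate[i] * (epochs$g_start[i] - gg))
    }, numeric(1))
  }
  size <- function(g) {
    n <- total_size(g)
    tibble::tibble(Nf = n * female_fraction, Nm = n * (1 - female_fraction),
                   N = n)
  }
  structure(list(epochs = epochs, n_base = n_base,
                 female_fraction = female_fraction, size = size,
                 depth = epochs$g_start[1L]),
            class = "sex_demography")
}

#' @export
print.sex_demography <- function(x, ...) {
  cat(sprintf("<sex_demography> depth %d generations, %d epochs, %.0f%% female\n",
              x$depth, nrow(x$epochs), 100 * x$female_fraction))
  print(x$epochs, ...)
  invisible(x)
}

#' UK-like four-stage growth demography
#'
#' A population of constant total size 3,000 until 300 generations ago,
#' then continuous exponential growth at 1.4% per generation to 60
#' generations ago, 6% to 10 generations ago, and 25% in the most recent
#' 10 generations, reaching roughly 21 million at sampling time.
#'
#' @param female_fraction Female share of the total size (default 0.5).
#' @param depth History depth in generations (default 5000; constant size
#'   beyond 300 regardless).
#' @return A [sex_demography()].
#' @examples
#' demog <- uk_like_model()
#' demog$size(c(300, 60, 10, 0))
#' @export
uk_like_model <- function(female_fraction = 0.5, depth = 5000L) {
  stopifnot(depth > 300)
  sex_demography(
    epochs = tibble::tibble(
      g_start = c(depth, 300L, 60L, 10L),
      g_end = c(300L, 60L, 10L, 0L),
      rate = c(0, 0.014, 0.06, 0.25)
    ),
    n_base = 3000,
    female_fraction = female_fraction
  )
}

#' Constant-size two-sex demography
#' @param Nf,Nm Constant female and male sizes.
#' @param depth History depth in generations.
#' @return A [sex_demography()].
#' @export
constant_model <- function(Nf, Nm, depth = 1000L) {
  sex_demography(
    epochs = tibble::tibble(g_start = depth, g_end = 0L, rate = 0),
    n_base = Nf + Nm,
    female_fraction = Nf / (Nf + Nm)
  )
}

#' True X or autosomal Ne trajectory implied by a demography
#'
#' Applies the forward relations ([nx_from_sexes()], [na_from_sexes()]) to
#' the per-generation sex-specific sizes.
#'
#' @param demog A [sex_demography()].
#' @param chrom_type `"X"` or `"autosome"`.
#' @param gmin,gmax Generation range of the returned trajectory.
#' @return An [ne_traj()].
#' @export
demog_to_traj <- function(demog, chrom_type = c("X", "autosome"),
                          gmin = 1L, gmax = 100L) {
  chrom_type <- match.arg(chrom_type)
  stopifnot(inherits(demog, "sex_demography"))
  g <- gmin:gmax
  s <- demog$size(g)
  Ne <- if (chrom_type == "X") nx_from_sexes(s$Nf, s$Nm)
        else na_from_sexes(s$Nf, s$Nm)
  ne_traj(g, Ne)
}

#' Single-locus two-sex Wright-Fisher coalescence simulation
#'
#' Simulates pairs of haplotype lineages backwards through a two-sex
#' Wright-Fisher population and records when they first coalesce, as an
#' independent check of the conditional coalescence probabilities
#' \eqn{1/(2 N_{gX})} and \eqn{1/(2 N_{gA})}. On the X, a lineage currently
#' carried by a female picks a female parent with probability 1/2 and a
#' male parent otherwise, while a lineage carried by a male always picks a
#' female parent (males inherit their X maternally); the parent individual
#' is uniform within the chosen sex and the parent haplotype uniform among
#' that individual's X copies (2 for a female, 1 for a male). Lineages start
#' female-borne with probability `p0` (default 2/3, the balanced-sample
#' equilibrium). On autosomes both parent sexes are equally likely and every
#' individual carries 2 copies. Two lineages coalesce when they pick the
#' identical parent haplotype.
#'
#' @param demog A [sex_demography()].
#' @param chrom_type `"X"` or `"autosome"`.
#' @param n_pairs Number of independent lineage pairs.
#' @param max_gen Generations to simulate; pairs still distinct at the end
#'   are right-censored (reported in the output).
#' @param seed Integer seed.
#' @param p0 Probability a sampled lineage is female-borne (X only).
#' @return Tibble with per-generation columns `generation`, `n_at_risk`,
#'   `n_coal`, `p_hat` (conditional coalescence frequency), `se`
#'   (binomial Monte-Carlo standard error), plus attributes `pooled`
#'   (list: `p`, `se`, valid for constant demographies), `n_censored`, and
#'   `carrier_female_frac` (per-generation female-carrier frequency among
#'   active lineages, X only).
#' @export
single_locus_coalescence <- function(demog, chrom_type = c("X", "autosome"),
                                     n_pairs = 1e5, max_gen = 50L, seed = 1L,
                                     p0 = 2 / 3) {
  chrom_type <- match.arg(chrom_type)
  stopifnot(inherits(demog, "sex_demography"))
  is_x <- chrom_type == "X"

  withr::local_seed(as.integer(seed))
  n <- as.integer(n_pairs)
  # carrier sex of each lineage (TRUE = female-borne); X only
  f1 <- if (is_x) stats::runif(n) < p0 else rep(NA, n)
  f2 <- if (is_x) stats::runif(n) < p0 else rep(NA, n)
  active <- rep(TRUE, n)
  res <- vector("list", max_gen)
  carrier_frac <- rep(NA_real_, max_gen)

  for (g in seq_len(max_gen)) {
    idx <- which(active)
    n_risk <- length(idx)
    if (n_risk == 0L) {
      res[[g]] <- c(n_risk = 0L, n_coal = 0L)
      next
    }
    s <- demog$size(g)
    nf <- max(2L, round(s$Nf)); nm <- max(2L, round(s$Nm))
    # haplotype identity encoded numerically: sex block + individual index
    # interleaved with copy; exact in doubles for any desk-scale size
    if (is_x) {
      # parent sex: female carrier -> female parent w.p. 1/2; male carrier ->
      # female parent always
      pf1 <- ifelse(f1[idx], stats::runif(n_risk) < 0.5, TRUE)
      pf2 <- ifelse(f2[idx], stats::runif(n_risk) < 0.5, TRUE)
      pick <- function(parent_female) {
        nind <- ifelse(parent_female, nf, nm)
        ind <- floor(stats::runif(n_risk) * nind)
        copy <- ifelse(parent_female, floor(stats::runif(n_risk) * 2), 0)
        parent_female * 2^40 + ind * 2 + copy
      }
      coal <- pick(pf1) == pick(pf2)
      f1[idx] <- pf1; f2[idx] <- pf2
      carrier_frac[g] <- mean(c(pf1, pf2))
    } else {
      pf1 <- stats::runif(n_risk) < 0.5
      pf2 <- stats::runif(n_risk) < 0.5
      pick <- function(parent_female) {
        nind <- ifelse(parent_female, nf, nm)
        ind <- floor(stats::runif(n_risk) * nind)
        copy <- floor(stats::runif(n_risk) * 2)
        parent_female * 2^40 + ind * 2 + copy
      }
      coal <- pick(pf1) == pick(pf2)
    }
    active[idx[coal]] <- FALSE
    res[[g]] <- c(n_risk = n_risk, n_coal = sum(coal))
  }
  tab <- do.call(rbind, res)
  out <- tibble::tibble(
    generation = seq_len(max_gen),
    n_at_risk = as.integer(tab[, "n_risk"]),
    n_coal = as.integer(tab[, "n_coal"])
  )
  out$p_hat <- ifelse(out$n_at_risk > 0, out$n_coal / out$n_at_risk, NA_real_)
  out$se <- sqrt(out$p_hat * (1 - out$p_hat) / pmax(out$n_at_risk, 1L))
  pooled_p <- sum(out$n_coal) / sum(out$n_at_risk)
  attr(out, "pooled") <- list(
    p = pooled_p,
    se = sqrt(pooled_p * (1 - pooled_p) / sum(out$n_at_risk))
  )
  attr(out, "n_censored") <- sum(active)
  attr(out, "carrier_female_frac") <- carrier_frac
  out
}

#' Sample a synthetic IBD segment set from the coalescent length model
#'
#' Generative twin of [expected_spectrum()]: for each generation g the
#' number of segments longer than the threshold is Poisson with mean
#' `npairs * q_g * 2gL * exp(-2gu)`, and lengths are `u` plus an
#' exponential(2g) excess, truncated at the map length. Segments get
#' uniform positions (on a nominal 1 cM/Mb map) and synthetic sample ids.
#'
#' @param traj An [ne_traj()] for the chromosome type being simulated.
#' @param L Map length in Morgans.
#' @param u Length threshold in Morgans (default 0.02).
#' @param npairs Haplotype-pair count driving the segment rate.
#' @param seed Integer seed.
#' @param chrom Chromosome label written on the segments.
#' @param g_tail Coalescent tail depth (see [coalescence_distribution()]).
#' @return Segment tibble in the standard 8-column layout.
#' @export
sample_ibd_spectrum <- function(traj, L, npairs, u = 0.02, seed = 1L,
                                chrom = "1", g_tail = 500L) {
  stopifnot(inherits(traj, "ne_traj"), L > 0, npairs >= 1)
  cd <- coalescence_distribution(traj, g_tail = g_tail)
  # a segment of length >= u cannot fit on a map shorter than u
  mu <- if (u >= L) rep(0, nrow(cd)) else {
    npairs * cd$q * 2 * cd$generation * L * exp(-2 * cd$generation * u)
  }
  withr::local_seed(as.integer(seed))
  counts <- stats::rpois(length(mu), mu)
  total <- sum(counts)
  if (total == 0L) {
    return(tibble::tibble(id1 = character(), hap1 = integer(),
                          id2 = character(), hap2 = integer(),
                          chrom = character(), start_bp = double(),
                          end_bp = double(), length_cm = double()))
  }
  g_of <- rep(cd$generation, counts)
  len <- pmin(u + stats::rexp(total, rate = 2 * g_of), L)
  start_m <- stats::runif(total, 0, pmax(L - len, 0))
  # nominal physical scale: 1 Mb per cM
  tibble::tibble(
    id1 = sprintf("sim%06d", seq_len(total) * 2L - 1L), hap1 = 1L,
    id2 = sprintf("sim%06d", seq_len(total) * 2L), hap2 = 1L,
    chrom = chrom,
    start_bp = round(start_m * 1e8) + 1,
    end_bp = round((start_m + len) * 1e8) + 1,
    length_cm = len * 100
  )
}

#' Forward two-sex Wright-Fisher simulation with X-specific recombination
#'
#' Desk-scale haplotype-dropping simulator for a constant-size two-sex
#' population. Chromosomes are painted by founder ancestry: each founder
#' haplotype is a distinct colour, and descendants carry mosaics of founder
#' colours. On the X, female meioses place Poisson(3L/2) crossovers per
#' transmission (the female rate on the sex-averaged scale), while male
#' meioses transmit the X intact — sons additionally receive no paternal X.
#' On autosomes both sexes recombine at Poisson(L). IBD segments between two
#' sampled haplotypes are the maximal intervals on which they carry the same
#' founder colour; segments reaching back to the founder generation are
#' truncated by construction, so run the simulation for clearly more
#' generations than the typical pair TMRCA (about `2 * nx_from_sexes(Nf, Nm)`
#' would be full lookback; constant-size tests need far less for the short
#' segments analysed here).
#'
#' @param Nf,Nm Constant female and male population sizes (total at most
#'   2000).
#' @param L Chromosome length in sex-averaged Morgans.
#' @param n_generations Generations to evolve (at most 200).
#' @param sample_nf,sample_nm Females and males sampled at the end.
#' @param u Minimum reported segment length in Morgans (default 0.02).
#' @param chrom_type `"X"` or `"autosome"`.
#' @param seed Integer seed.
#' @return List with `segments` (standard 8-column tibble, positions on a
#'   nominal 1 cM/Mb scale), `events` (tibble of per-transmission crossover
#'   counts with the transmitting parent's sex), and `truth` (the constant
#'   [ne_traj()] implied by the sizes).
#' @export
forward_wf_ibd <- function(Nf, Nm, L, n_generations, sample_nf, sample_nm,
                           u = 0.02, chrom_type = c("X", "autosome"),
                           seed = 1L) {
  chrom_type <- match.arg(chrom_type)
  if (Nf + Nm > 2000 || n_generations > 200) {
    stop("desk-scale limits: total size <= 2000, generations <= 200",
         call. = FALSE)
  }
  stopifnot(sample_nf <= Nf, sample_nm <= Nm, L > 0)
  is_x <- chrom_type == "X"
  withr::local_seed(as.integer(seed))

  # a haplotype is list(pos = segment start positions, src = founder colours)
  new_hap <- function(col) list(pos = 0, src = col)
  col_counter <- 0L
  next_col <- function() { col_counter <<- col_counter + 1L; col_counter }

  recombine <- function(hapA, hapB, rate_per_morgan) {
    k <- stats::rpois(1L, rate_per_morgan * L)
    n_cross <- k
    if (stats::runif(1) < 0.5) { tmp <- hapA; hapA <- hapB; hapB <- tmp }
    if (k == 0L) return(list(hap = hapA, n_crossovers = 0L))
    xs <- sort(stats::runif(k, 0, L))
    cur <- list(hapA, hapB); take <- 1L; left <- 0
    pos <- numeric(0); src <- integer(0)
    for (x in c(xs, L)) {
      h <- cur[[take]]
      i0 <- findInterval(left, h$pos)
      i1 <- findInterval(x, h$pos, left.open = TRUE)
      seg_pos <- pmax(h$pos[i0:i1], left)
      pos <- c(pos, seg_pos)
      src <- c(src, h$src[i0:i1])
      take <- 3L - take; left <- x
    }
    keep <- c(TRUE, diff(src) != 0)
    list(hap = list(pos = pos[keep], src = src[keep]), n_crossovers = n_cross)
  }

  # founders
  females <- replicate(Nf, list(h1 = new_hap(next_col()), h2 = new_hap(next_col())),
                       simplify = FALSE)
  males <- if (is_x) {
    replicate(Nm, list(h1 = new_hap(next_col())), simplify = FALSE)
  } else {
    replicate(Nm, list(h1 = new_hap(next_col()), h2 = new_hap(next_col())),
              simplify = FALSE)
  }

  fem_rate <- if (is_x) 3 / 2 else 1
  events <- list()
  for (gen in seq_len(n_generations)) {
    moms <- sample.int(Nf, Nf + Nm, replace = TRUE)
    dads <- sample.int(Nm, Nf + Nm, replace = TRUE)
    new_f <- vector("list", Nf); new_m <- vector("list", Nm)
    ev_sex <- character(Nf + Nm + ifelse(is_x, Nf, Nf + Nm))
    ev_k <- integer(length(ev_sex)); ei <- 0L
    for (child in seq_len(Nf + Nm)) {
      mom <- females[[moms[child]]]
      dad <- males[[dads[child]]]
      mr <- recombine(mom$h1, mom$h2, fem_rate)
      ei <- ei + 1L; ev_sex[ei] <- "F"; ev_k[ei] <- mr$n_crossovers
      if (child <= Nf) {   # daughter
        if (is_x) {
          # father's single X transmitted intact: zero crossovers
          ei <- ei + 1L; ev_sex[ei] <- "M"; ev_k[ei] <- 0L
          new_f[[child]] <- list(h1 = mr$hap, h2 = dad$h1)
        } else {
          dr <- recombine(dad$h1, dad$h2, 1)
          ei <- ei + 1L; ev_sex[ei] <- "M"; ev_k[ei] <- dr$n_crossovers
          new_f[[child]] <- list(h1 = mr$hap, h2 = dr$hap)
        }
      } else {             # son
        if (is_x) {
          new_m[[child - Nf]] <- list(h1 = mr$hap)
        } else {
          dr <- recombine(dad$h1, dad$h2, 1)
          ei <- ei + 1L; ev_sex[ei] <- "M"; ev_k[ei] <- dr$n_crossovers
          new_m[[child - Nf]] <- list(h1 = mr$hap, h2 = dr$hap)
        }
      }
    }
    females <- new_f; males <- new_m
    events[[gen]] <- tibble::tibble(generation = gen,
                                    parent_sex = ev_sex[seq_len(ei)],
                                    n_crossovers = ev_k[seq_len(ei)])
  }

  # sample haplotypes
  fs <- sample.int(Nf, sample_nf)
  ms <- sample.int(Nm, sample_nm)
  haps <- list(); ids <- character(0); hap_idx <- integer(0)
  for (i in seq_along(fs)) {
    haps <- c(haps, list(females[[fs[i]]]$h1, females[[fs[i]]]$h2))
    ids <- c(ids, rep(sprintf("F%03d", i), 2L)); hap_idx <- c(hap_idx, 1L, 2L)
  }
  for (i in seq_along(ms)) {
    if (is_x) {
      haps <- c(haps, list(males[[ms[i]]]$h1))
      ids <- c(ids, sprintf("M%03d", i)); hap_idx <- c(hap_idx, 1L)
    } else {
      haps <- c(haps, list(males[[ms[i]]]$h1, males[[ms[i]]]$h2))
      ids <- c(ids, rep(sprintf("M%03d", i), 2L)); hap_idx <- c(hap_idx, 1L, 2L)
    }
  }

  shared_runs <- function(a, b) {
    pos <- sort(unique(c(a$pos, b$pos)))
    sa <- a$src[findInterval(pos, a$pos)]
    sb <- b$src[findInterval(pos, b$pos)]
    same <- sa == sb
    ends <- c(pos[-1L], L)
    runs <- rle(paste0(same, "|", ifelse(same, sa, -1)))
    starts <- pos[c(1L, utils::head(cumsum(runs$lengths), -1L) + 1L)]
    stops <- ends[cumsum(runs$lengths)]
    ok <- startsWith(runs$values, "TRUE")
    tibble::tibble(start = starts[ok], end = stops[ok])
  }

  segs <- list()
  nh <- length(haps)
  for (i in seq_len(nh - 1L)) {
    for (j in (i + 1L):nh) {
      if (ids[i] == ids[j]) next
      runs <- shared_runs(haps[[i]], haps[[j]])
      runs <- runs[runs$end - runs$start >= u, , drop = FALSE]
      if (nrow(runs)) {
        segs[[length(segs) + 1L]] <- tibble::tibble(
          id1 = ids[i], hap1 = hap_idx[i], id2 = ids[j], hap2 = hap_idx[j],
          chrom = "X", start_bp = round(runs$start * 1e8) + 1,
          end_bp = round(runs$end * 1e8) + 1,
          length_cm = (runs$end - runs$start) * 100
        )
      }
    }
  }
  segments <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(id1 = character(), hap1 = integer(), id2 = character(),
                   hap2 = integer(), chrom = character(), start_bp = double(),
                   end_bp = double(), length_cm = double())
  truth <- if (is_x) {
    ne_traj(1:n_generations, rep(nx_from_sexes(Nf, Nm), n_generations))
  } else {
    ne_traj(1:n_generations, rep(na_from_sexes(Nf, Nm), n_generations))
  }
  list(segments = segments, events = dplyr::bind_rows(events), truth = truth)
}

#' Compare the exact and approximate X length models
#'
#' Draws `n_samples` segment lengths from the binomial-mixture model and
#' from the exponential(2g) approximation and returns the two-sample
#' Kolmogorov-Smirnov distance. The approximation is close for g > 1 and
#' visibly worse at g = 1.
#'
#' @param g Coalescence generation, integer >= 1.
#' @param n_samples Draws per model (at least 100).
#' @param seed Integer seed.
#' @return The KS statistic (numeric scalar).
#' @export
compare_length_models <- function(g, n_samples = 1e5, seed = 1L) {
  if (n_samples < 100) stop("need at least 100 samples", call. = FALSE)
  withr::local_seed(as.integer(seed))
  x <- r_x_length_exact(n_samples, g)
  y <- r_x_length_approx(n_samples, g)
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}
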