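test_that("the UK-like growth model hits its stated sizes", {
  demog <- uk_like_model()
  expect_equal(demog$size(300)$N, 3000)
  expect_equal(demog$size(1000)$N, 3000)
  # closed-form epoch products
  expect_equal(demog$size(60)$N, 3000 * exp(0.014 * 240), tolerance = 1e-9)
  expect_equal(demog$size(10)$N, 3000 * exp(0.014 * 240) * exp(0.06 * 50),
               tolerance = 1e-9)
  # roughly 21 million at sampling
  expect_equal(demog$size(0)$N, 21e6, tolerance = 0.05)
  # sex split follows female_fraction
  d2 <- uk_like_model(female_fraction = 0.2)
  expect_equal(d2$size(300)$Nf, 600)
  expect_equal(d2$size(300)$Nm, 2400)
  expect_error(uk_like_model(female_fraction = 1), "between 0 and 1")
})

test_that("demography-implied trajectories use the X and autosome relations", {
  demog <- constant_model(100, 300)
  tx <- demog_to_traj(demog, "X", 1, 10)
  ta <- demog_to_traj(demog, "autosome", 1, 10)
  expect_equal(tx$Ne, rep(nx_from_sexes(100, 300), 10))
  expect_equal(ta$Ne, rep(300, 10))
})

test_that("two-sex WF coalescence matches the X and autosome theory", {
  # one constant scenario exercised tightly here; the full grid runs in the
  # acceptance suite
  demog <- constant_model(100, 300, depth = 100)
  r <- single_locus_coalescence(demog, "X", n_pairs = 4e4, max_gen = 40,
                                seed = 2)
  p <- attr(r, "pooled")
  expect_lt(abs(p$p - 1 / (2 * nx_from_sexes(100, 300))), 3 * p$se)
  ra <- single_locus_coalescence(demog, "autosome", n_pairs = 4e4,
                                 max_gen = 40, seed = 3)
  pa <- attr(ra, "pooled")
  expect_lt(abs(pa$p - 1 / (2 * na_from_sexes(100, 300))), 3 * pa$se)
})

test_that("the carrier-sex chain converges to 2/3 from any start", {
  demog <- constant_model(500, 500, depth = 60)
  for (p0 in c(0, 1)) {
    r <- single_locus_coalescence(demog, "X", n_pairs = 2e4, max_gen = 30,
                                  seed = 8, p0 = p0)
    cf <- attr(r, "carrier_female_frac")
    late <- cf[10:30]
    se <- sqrt((2 / 3) * (1 / 3) / (2 * 2e4))
    expect_true(all(abs(late - 2 / 3) < 3 * se + 0.01))
  }
})

test_that("the model-based IBD sampler is seeded and Poisson-consistent", {
  traj <- ne_traj(1:60, rep(2000, 60))
  a <- sample_ibd_spectrum(traj, L = 1, npairs = 5e4, u = 0.02, seed = 4)
  b <- sample_ibd_spectrum(traj, L = 1, npairs = 5e4, u = 0.02, seed = 4)
  expect_equal(a, b)
  expect_true(all(a$length_cm >= 2))
  expect_true(all(a$end_bp > a$start_bp))
  # mean count over repeated draws within 3 SE of the analytic total
  cd <- coalescence_distribution(traj, g_tail = 500)
  mu <- 5e4 * sum(cd$q * 2 * cd$generation * exp(-2 * cd$generation * 0.02))
  counts <- vapply(1:200, function(s)
    nrow(sample_ibd_spectrum(traj, L = 1, npairs = 5e4, u = 0.02,
                             seed = 1000 + s)),
    numeric(1))
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # threshold at or above the map length leaves nearly nothing
  none <- sample_ibd_spectrum(traj, L = 0.02, npairs = 5e4, u = 0.02, seed = 5)
  expect_lt(nrow(none), 5)
})

test_that("forward simulation respects X inheritance rules", {
  sim <- forward_wf_ibd(Nf = 40, Nm = 40, L = 1, n_generations = 25,
                        sample_nf = 12, sample_nm = 12, u = 0.02, seed = 6)
  ev <- sim$events
  # male X transmissions never recombine
  expect_equal(sum(ev$n_crossovers[ev$parent_sex == "M"]), 0L)
  # female meioses place crossovers at rate 3L/2 on the sex-averaged scale
  fem <- ev$n_crossovers[ev$parent_sex == "F"]
  expect_lt(abs(mean(fem) - 1.5), 3 * stats::sd(fem) / sqrt(length(fem)))
  # output segments are well-formed and at or above the threshold
  expect_true(all(sim$segments$length_cm >= 2))
  expect_equal(sim$truth$Ne[1], nx_from_sexes(40, 40))
  # autosomal mode recombines in both sexes at rate L
  sima <- forward_wf_ibd(Nf = 30, Nm = 30, L = 1, n_generations = 10,
                         sample_nf = 8, sample_nm = 8, u = 0.02,
                         chrom_type = "autosome", seed = 7)
  eva <- sima$events
  expect_gt(sum(eva$n_crossovers[eva$parent_sex == "M"]), 0L)
  expect_error(forward_wf_ibd(2000, 2000, 1, 10, 5, 5), "desk-scale")
})

test_that("smaller populations show more IBD in the forward simulation", {
  rate <- function(Nf, Nm, seed) {
    sim <- forward_wf_ibd(Nf, Nm, L = 1, n_generations = 30,
                          sample_nf = 10, sample_nm = 10, u = 0.02,
                          seed = seed)
    nh <- 2 * 10 + 10
    nrow(sim$segments) / (nh * (nh - 1) / 2)
  }
  expect_gt(rate(25, 25, seed = 9), rate(100, 100, seed = 9))
})

test_that("exponential(2g) approximates the mixture for g > 1 but not g = 1", {
  ks10 <- compare_length_models(10, n_samples = 4e4, seed = 12)
  expect_lt(ks10, 0.05)
  ks1 <- compare_length_models(1, n_samples = 4e4, seed = 12)
  expect_gt(ks1, ks10)
  expect_error(compare_length_models(5, n_samples = 50), "at least 100")
})

test_that("spectra sampled from a constant demography recover both sexes end to end", {
  demog <- constant_model(5000, 5000, depth = 200)
  cfg <- fit_config(gmin = 2, gmax = 60, n_boot = 0)
  tx <- demog_to_traj(demog, "X", 2, 60)
  ta <- demog_to_traj(demog, "autosome", 2, 60)
  segx <- sample_ibd_spectrum(tx, L = 1.2, npairs = 1e6, u = 0.02, seed = 21)
  sega <- sample_ibd_spectrum(ta, L = 5, npairs = 1e6, u = 0.02, seed = 22)
  fx <- fit_ne(observed_spectrum(segx, 1e6, 120, cfg), cfg)
  fa <- fit_ne(observed_spectrum(sega, 1e6, 500, cfg), cfg)
  s <- sexes_from_nx_na(fx$Ne, fa$Ne)
  central <- fx$generation >= 10 & fx$generation <= 50
  expect_true(all(abs(s$Nf[central] / 5000 - 1) < 0.25, na.rm = FALSE))
  expect_true(all(abs(s$Nm[central] / 5000 - 1) < 0.25))
})
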