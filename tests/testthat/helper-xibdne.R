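# Fixture builders shared across test files. Everything is generated in
# code; no stored data files.

# Uniform-rate map: `len_cm` over `len_cm` Mb (1 cM per Mb), n_markers rows.
toy_map <- function(len_cm = 120, n_markers = 13, chrom = "X",
                    scale = "sex_averaged") {
  bp <- round(seq(1, len_cm * 1e6, length.out = n_markers))
  cm <- seq(0, len_cm, length.out = n_markers)
  xibdne:::new_genetic_map(tibble::tibble(bp = bp, cm = cm),
                           chrom = chrom, scale = scale)
}

write_toy_map_file <- function(path, chrom = "X", len_cm = 120,
                               n_markers = 13) {
  bp <- round(seq(1, len_cm * 1e6, length.out = n_markers))
  cm <- seq(0, len_cm, length.out = n_markers)
  writeLines(sprintf("%s m%d %.6f %d", chrom, seq_along(bp), cm, bp), path)
  path
}

make_segment <- function(id1 = "a", hap1 = 1L, id2 = "b", hap2 = 1L,
                         chrom = "X", start_bp = 1e6, end_bp = 5e6,
                         length_cm = 4) {
  tibble::tibble(id1 = id1, hap1 = as.integer(hap1), id2 = id2,
                 hap2 = as.integer(hap2), chrom = chrom,
                 start_bp = start_bp, end_bp = end_bp,
                 length_cm = length_cm)
}

# Spectrum whose counts are exactly the model expectation for `traj`.
exact_spectrum <- function(traj, L, npairs, config) {
  edges <- seq(config$threshold_u, 0.5, by = config$bin_width)
  es <- expected_spectrum(traj, L = L, npairs = npairs, bin_edges = edges,
                          g_tail = config$g_tail)
  structure(
    tibble::tibble(bin_lo = es$bin_lo, bin_hi = es$bin_hi, count = es$expected),
    npairs = npairs, L = L, u = config$threshold_u,
    class = c("ibd_spectrum", class(tibble::tibble()))
  )
}

# Independent enumeration of cross-individual haplotype pairs: females carry
# 2 haplotypes, males 1 (X chromosome coding).
enumerate_x_pairs <- function(nf, nm) {
  owner <- c(rep(seq_len(nf), each = 2L), nf + seq_len(nm))
  n <- length(owner)
  if (n < 2L) return(0L)
  total <- 0L
  for (i in seq_len(n - 1L)) {
    total <- total + sum(owner[(i + 1L):n] != owner[i])
  }
  total
}
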