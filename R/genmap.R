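#' Read a PLINK-format genetic map
#'
#' Reads a 4-column PLINK map (chromosome, marker id, cM position, bp
#' position), optionally restricted to one chromosome, and returns a
#' `genetic_map` object: a tibble of markers ordered by physical position,
#' carrying the chromosome label and the map scale as attributes.
#'
#' X-chromosome maps published by HapMap and deCODE report female-specific
#' genetic distances (males do not recombine on the X outside the
#' pseudoautosomal regions). Record that with `scale = "female_specific"` and
#' convert with [to_sex_averaged()] before any IBD analysis. The map supplied
#' here must already exclude the pseudoautosomal regions.
#'
#' @param path Path to a whitespace-delimited map file, plain or gzipped.
#' @param chrom Optional chromosome label to filter on. Required when the
#'   file holds more than one chromosome.
#' @param scale Scale of the cM coordinates: `"sex_averaged"` (autosomes,
#'   or an already-converted X map) or `"female_specific"`.
#' @return A `genetic_map`: tibble with columns `bp` (integer, strictly
#'   increasing) and `cm` (non-decreasing), attributes `chrom` and `scale`.
#' @examples
#' f <- tempfile(fileext = ".map")
#' writeLines(c("X rs1 0.0 1000", "X rs2 1.0 2000", "X rs3 2.0 3000"), f)
#' gmap <- read_genetic_map(f, chrom = "X", scale = "female_specific")
#' map_length_cm(gmap)
#' @export
read_genetic_map <- function(path, chrom = NULL,
                             scale = c("sex_averaged", "female_specific")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) {
    stop("map file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = FALSE, col.names = c("chrom", "id", "cm", "bp"),
                           colClasses = c("character", "character", "numeric", "numeric"))
  raw <- tibble::as_tibble(raw)
  if (!is.null(chrom)) {
    raw <- dplyr::filter(raw, .data$chrom == !!as.character(chrom))
  } else if (dplyr::n_distinct(raw$chrom) > 1L) {
    stop("map file holds multiple chromosomes; supply `chrom`", call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    stop("no map rows for chromosome ", chrom, call. = FALSE)
  }
  chrom_label <- raw$chrom[[1L]]
  markers <- dplyr::arrange(dplyr::select(raw, "bp", "cm"), .data$bp)
  new_genetic_map(markers, chrom = chrom_label, scale = scale)
}

#' @keywords internal
new_genetic_map <- function(markers, chrom, scale) {
  markers <- tibble::as_tibble(markers)[, c("bp", "cm")]
  if (nrow(markers) < 2L) {
    stop("a genetic map needs at least 2 markers", call. = FALSE)
  }
  if (any(diff(markers$bp) <= 0)) {
    stop("bp positions must be strictly increasing", call. = FALSE)
  }
  if (any(diff(markers$cm) < 0)) {
    stop("cM positions must be non-decreasing", call. = FALSE)
  }
  if (any(markers$cm < 0)) {
    stop("cM positions must be non-negative", call. = FALSE)
  }
  if (markers$cm[nrow(markers)] - markers$cm[1L] <= 0) {
    stop("map must have positive total cM length", call. = FALSE)
  }
  structure(markers,
            chrom = as.character(chrom),
            scale = scale,
            class = c("genetic_map", class(markers)))
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> chrom %s, %d markers, %.3f cM (%s scale)\n",
              attr(x, "chrom"), nrow(x), map_length_cm(x), attr(x, "scale")))
  NextMethod()
}

#' Total genetic length of a map in cM
#' @param map A `genetic_map`.
#' @return Length in cM between the first and last marker.
#' @export
map_length_cm <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  map$cm[nrow(map)] - map$cm[1L]
}

#' Convert a female-specific X map to the sex-averaged scale
#'
#' On the X chromosome only female meioses recombine, and on average 2/3 of
#' the meioses that transmit an X are female. The sex-averaged map — the scale
#' on which one Morgan means one expected crossover per transmitted X — is
#' therefore the female-specific map with all genetic distances multiplied by
#' 2/3. A 3 cM female-specific interval becomes 2 cM sex-averaged; likewise a
#' female-specific rate of 3e-8 per bp per generation becomes 2e-8.
#'
#' @param map A `genetic_map` with `scale = "female_specific"`.
#' @return The map with every cM coordinate multiplied by 2/3 and
#'   `scale = "sex_averaged"`. Refuses to convert twice.
#' @export
to_sex_averaged <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  if (identical(attr(map, "scale"), "sex_averaged")) {
    stop("map is already on the sex-averaged scale", call. = FALSE)
  }
  out <- tibble::as_tibble(map)
  out$cm <- out$cm * (2 / 3)
  new_genetic_map(out, chrom = attr(map, "chrom"), scale = "sex_averaged")
}

#' Interpolate genetic position at physical positions
#'
#' Piecewise-linear interpolation of cM position between flanking markers;
#' exact at markers. Positions outside the map span are an error — segments
#' extending beyond the map must be excluded upstream, as regions outside the
#' genetic map are not analysed.
#'
#' @param map A `genetic_map`.
#' @param bp Vector of physical positions (1-based bp).
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(bp) == 0L) return(numeric(0))
  lo <- map$bp[1L]; hi <- map$bp[nrow(map)]
  if (any(bp < lo | bp > hi)) {
    stop(sprintf("position outside map span [%d, %d]", lo, hi), call. = FALSE)
  }
  stats::approx(map$bp, map$cm, xout = bp, method = "linear", ties = "ordered")$y
}

#' Interpolate physical position at genetic positions
#'
#' Inverse of [interpolate_cm()]. Where the map has zero-recombination
#' stretches (equal cM at several markers) the left-most bp is returned.
#'
#' @param map A `genetic_map`.
#' @param cm Vector of genetic positions in cM, within the map's cM span.
#' @return Numeric vector of bp positions (possibly fractional).
#' @export
interpolate_bp <- function(map, cm) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(cm) == 0L) return(numeric(0))
  lo <- map$cm[1L]; hi <- map$cm[nrow(map)]
  if (any(cm < lo - 1e-9 | cm > hi + 1e-9)) {
    stop(sprintf("genetic position outside map span [%g, %g] cM", lo, hi),
         call. = FALSE)
  }
  cm <- pmin(pmax(cm, lo), hi)
  stats::approx(map$cm, map$bp, xout = cm, method = "linear", ties = min)$y
}

#' Boundaries dividing a map into equal-cM pieces
#'
#' Used to split the X chromosome into `k` pseudo-chromosomes of equal genetic
#' length so that a bootstrap over "chromosomes" is possible (the analysis
#' default is 6 pieces).
#'
#' @param map A `genetic_map`.
#' @param k Number of pieces, at least 1.
#' @return Numeric vector of `k + 1` cM boundaries spanning the map; adjacent
#'   differences are all `map_length_cm(map) / k`.
#' @export
equal_cm_breakpoints <- function(map, k) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  seq(map$cm[1L], map$cm[nrow(map)], length.out = k + 1L)
}

#' Write a genetic map in PLINK 4-column format
#' @param map A `genetic_map`.
#' @param path Output path; `.gz` suffix gzips.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  out <- tibble::tibble(
    chrom = attr(map, "chrom"),
    id = paste0("m", seq_len(nrow(map))),
    cm = map$cm,
    bp = map$bp
  )
  readr::write_delim(out, path, delim = " ", col_names = FALSE)
  invisible(path)
}
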