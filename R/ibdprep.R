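ibd_cols <- c("id1", "hap1", "id2", "hap2", "chrom", "start_bp", "end_bp",
              "length_cm")

#' Read an IBD segment file (hap-ibd output format)
#'
#' Eight tab-delimited columns: first sample id, its haplotype index (1 or
#' 2), second sample id, its haplotype index, chromosome, segment start bp,
#' end bp (1-based, closed interval), and segment length in cM on the map
#' used for detection. Gzipped input is handled transparently.
#'
#' @param path Path to a tab-delimited segment file, plain or `.gz`.
#' @return Tibble with columns `id1`, `hap1`, `id2`, `hap2`, `chrom`,
#'   `start_bp`, `end_bp`, `length_cm`.
#' @export
read_ibd <- function(path) {
  if (!file.exists(path)) stop("IBD file not found: ", path, call. = FALSE)
  seg <- readr::read_tsv(
    path, col_names = ibd_cols, comment = "#", progress = FALSE,
    col_types = readr::cols(
      id1 = readr::col_character(), hap1 = readr::col_integer(),
      id2 = readr::col_character(), hap2 = readr::col_integer(),
      chrom = readr::col_character(), start_bp = readr::col_double(),
      end_bp = readr::col_double(), length_cm = readr::col_double()
    )
  )
  validate_ibd(seg)
}

validate_ibd <- function(seg) {
  seg <- tibble::as_tibble(seg)[, ibd_cols]
  if (any(!seg$hap1 %in% c(1L, 2L)) || any(!seg$hap2 %in% c(1L, 2L))) {
    stop("haplotype indices must be 1 or 2", call. = FALSE)
  }
  if (any(seg$start_bp >= seg$end_bp)) {
    stop("segments must have start_bp < end_bp", call. = FALSE)
  }
  if (any(seg$length_cm <= 0)) {
    stop("segment cM lengths must be positive", call. = FALSE)
  }
  if (any(seg$id1 == seg$id2)) {
    stop("within-individual segment pairs are not analysable", call. = FALSE)
  }
  seg
}

#' Write IBD segments in hap-ibd output format
#' @param segments Segment tibble as returned by [read_ibd()].
#' @param path Output path; `.gz` honoured.
#' @return `path`, invisibly.
#' @export
write_ibd <- function(segments, path) {
  readr::write_tsv(segments[, ibd_cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a sample-sex table
#'
#' Two tab- or whitespace-delimited columns: sample id and sex coded
#' `F`/`M` (or `female`/`male`, case-insensitive).
#'
#' @param path Path to the table.
#' @return Tibble with columns `id`, `sex` (values `"F"`/`"M"`).
#' @export
read_sex_table <- function(path) {
  raw <- utils::read.table(path, header = FALSE,
                           col.names = c("id", "sex"),
                           colClasses = "character")
  sex <- toupper(substr(raw$sex, 1L, 1L))
  if (any(!sex %in% c("F", "M"))) {
    stop("sex must be coded female/male (F/M)", call. = FALSE)
  }
  if (anyDuplicated(raw$id)) stop("duplicate sample ids in sex table", call. = FALSE)
  tibble::tibble(id = raw$id, sex = sex)
}

lookup_sex <- function(ids, sexes) {
  m <- sexes$sex[match(ids, sexes$id)]
  if (anyNA(m)) {
    stop("samples missing from sex table: ",
         paste(utils::head(unique(ids[is.na(m)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Drop duplicate X segments from diploid-coded males
#'
#' Males carry one X chromosome; when their X genotypes are coded as
#' homozygous diploid, IBD detection reports each male-involved segment once
#' per phantom haplotype. Keeping only haplotype 1 of every male removes the
#' duplicates: a male-male segment reported four ways (haps 1/1, 1/2, 2/1,
#' 2/2) keeps only the 1/1 record. Female haplotypes are untouched.
#' Idempotent.
#'
#' @param segments Segment tibble (X chromosome).
#' @param sexes Sex table from [read_sex_table()]; every sample appearing in
#'   `segments` must be listed.
#' @return Filtered segment tibble.
#' @export
dedup_diploid_males <- function(segments, sexes) {
  s1 <- lookup_sex(segments$id1, sexes)
  s2 <- lookup_sex(segments$id2, sexes)
  keep <- !(s1 == "M" & segments$hap1 == 2L) &
          !(s2 == "M" & segments$hap2 == 2L)
  segments[keep, , drop = FALSE]
}

#' Balance the numbers of sampled females and males
#'
#' The X analysis assumes the sampled haplotypes are drawn from equal
#' numbers of females and males, so that the proportion of sampled X
#' haplotypes carried by females is p0 = 2/3 and stays 2/3 in every
#' ancestral generation. Randomly selected individuals of the
#' overrepresented sex are removed to equalise the counts.
#'
#' @param sexes Sex table.
#' @param seed Integer seed making the removal reproducible.
#' @return The balanced sex table, with the removed sample ids in attribute
#'   `removed`.
#' @examples
#' sexes <- tibble::tibble(id = paste0("s", 1:5),
#'                         sex = c("F", "F", "F", "M", "M"))
#' balanced <- balance_sexes(sexes, seed = 1)
#' attr(balanced, "removed")
#' @export
balance_sexes <- function(sexes, seed) {
  nf <- sum(sexes$sex == "F"); nm <- sum(sexes$sex == "M")
  if (nf < 1L || nm < 1L) {
    stop("both sexes must be present to balance", call. = FALSE)
  }
  excess <- abs(nf - nm)
  removed <- character(0)
  if (excess > 0L) {
    over <- sexes$id[sexes$sex == if (nf > nm) "F" else "M"]
    removed <- withr::with_seed(as.integer(seed),
                                sample(over, excess, replace = FALSE))
  }
  out <- sexes[!sexes$id %in% removed, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Drop segments involving given samples
#' @param segments Segment tibble.
#' @param ids Sample ids to drop (e.g. the `removed` attribute of
#'   [balance_sexes()]).
#' @return Filtered segment tibble.
#' @export
drop_samples <- function(segments, ids) {
  segments[!(segments$id1 %in% ids | segments$id2 %in% ids), , drop = FALSE]
}

#' Number of analysable X-chromosome haplotype pairs
#'
#' With `nf` females (2 X haplotypes each) and `nm` males (1 each), the
#' cross-individual haplotype pairs number
#' \deqn{2 n_f (2 n_f - 2)/2 + n_m (n_m - 1)/2 + 2 n_f n_m.}
#' The three terms count female-female, male-male, and female-male pairs.
#' Within-individual pairs are never analysed.
#'
#' @param nf,nm Non-negative female and male counts.
#' @return Haplotype-pair count.
#' @export
npairs_x <- function(nf, nm) {
  if (any(nf < 0) || any(nm < 0)) stop("counts must be non-negative", call. = FALSE)
  2 * nf * (2 * nf - 2) / 2 + nm * (nm - 1) / 2 + 2 * nf * nm
}

#' Remove close-relative IBD segments and adjust the haplotype-pair count
#'
#' Close relatives (parent-offspring and sibling pairs, identified from
#' pedigree data or an autosomal analysis — the X alone cannot detect them)
#' share long IBD segments that would bias the recent Ne upward. Their
#' segments are removed rather than whole individuals, and the analysed
#' haplotype-pair count is decremented by the number of cross-pairs the
#' removed pair contributed: 1 for a male-male pair, 2 for a male-female
#' pair, 4 for a female-female pair.
#'
#' @param segments Segment tibble.
#' @param relatives Two-column data frame (`id1`, `id2`) of related sample
#'   pairs; order within a pair is ignored, duplicates are an error.
#' @param sexes Sex table used to classify each pair (sexes are looked up,
#'   never trusted from the pair list).
#' @param npairs Haplotype-pair count before removal (from [npairs_x()]).
#' @return List with `segments` (filtered), `npairs` (decremented),
#'   `n_removed_segments`, and `decrement`.
#' @export
remove_relatives <- function(segments, relatives, sexes, npairs) {
  relatives <- tibble::as_tibble(relatives)
  names(relatives)[1:2] <- c("id1", "id2")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  rk <- key(relatives$id1, relatives$id2)
  if (anyDuplicated(rk)) {
    stop("relative pair listed more than once; npairs would be ",
         "decremented twice", call. = FALSE)
  }
  s1 <- lookup_sex(relatives$id1, sexes)
  s2 <- lookup_sex(relatives$id2, sexes)
  dec_per_pair <- ifelse(s1 == "F", 2L, 1L) * ifelse(s2 == "F", 2L, 1L)
  decrement <- sum(dec_per_pair)
  drop <- key(segments$id1, segments$id2) %in% rk
  list(
    segments = segments[!drop, , drop = FALSE],
    npairs = npairs - decrement,
    n_removed_segments = sum(drop),
    decrement = decrement
  )
}

#' Split segments into equal-cM pseudo-chromosome pieces
#'
#' Recodes the chromosome field of X-linked segments with integer labels
#' `1..k` according to the equal-cM pieces of the map, splitting any segment
#' that crosses a piece boundary into subsegments at the boundary. Segment
#' cM lengths are recomputed from the map, so the subsegment lengths of a
#' split segment sum exactly to the original map length of the segment.
#' This lets a bootstrap treat the pieces as separate chromosomes.
#'
#' @param segments Segment tibble, all within the map's bp span.
#' @param map A `genetic_map` on the scale the analysis uses
#'   (sex-averaged for the X).
#' @param k Number of pieces (analysis default 6).
#' @return Segment tibble with `chrom` relabelled `"1"..."k"`, bp endpoints
#'   of split points interpolated from the map, and `length_cm` recomputed.
#'   Subsegments shorter than the detection threshold are retained; the
#'   spectrum builder applies its length threshold uniformly.
#' @export
split_into_pieces <- function(segments, map, k) {
  stopifnot(inherits(map, "genetic_map"))
  edges <- equal_cm_breakpoints(map, k)
  cm_s <- interpolate_cm(map, segments$start_bp)
  cm_e <- interpolate_cm(map, segments$end_bp)
  piece_of <- function(cm) {
    pmin(pmax(findInterval(cm, edges, rightmost.closed = TRUE), 1L), k)
  }
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(segments)), cm_s, cm_e),
    function(i, a, b) {
      row <- segments[i, , drop = FALSE]
      cuts <- edges[edges > a & edges < b]
      lo <- c(a, cuts); hi <- c(cuts, b)
      keep <- hi > lo
      lo <- lo[keep]; hi <- hi[keep]
      bp_lo <- c(row$start_bp, round(interpolate_bp(map, lo[-1L])))
      bp_hi <- c(round(interpolate_bp(map, hi[-length(hi)])), row$end_bp)
      tibble::tibble(
        id1 = row$id1, hap1 = row$hap1, id2 = row$id2, hap2 = row$hap2,
        chrom = as.character(piece_of((lo + hi) / 2)),
        start_bp = bp_lo, end_bp = bp_hi,
        length_cm = hi - lo
      )
    }
  )
  out
}
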