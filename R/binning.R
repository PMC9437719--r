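#' Five-step bin-marker construction
#'
#' Collapses retained SNPs of one segregation set into recombination-defined
#' bin markers: (i) majority-rule calls in fixed physical windows
#' ([window_bin()]); (ii) fill missing calls from nearby windows;
#' (iii) fill missing runs flanked by identical calls; (iv) correct
#' singleton miscalls ([impute_and_correct()]); (v) merge adjacent windows
#' with identical genotype vectors ([merge_identical()]). Sets are binned
#' independently, per chromosome.
#'
#' @param cp a `cp_sites` object (typically the `sites` element of
#'   [filter_sites()] output).
#' @param window_bp physical window (tile) size in bp. Tiles are fixed
#'   physical-coordinate intervals `[k*W + 1, (k+1)*W]`.
#' @param k_side number of nearest non-missing window calls collected on
#'   each side in step (ii); `k_side = 0` disables step (ii).
#' @param radius neighborhood radius (windows per side) for steps
#'   (iii)-(iv).
#' @param na_matches_na in step (v), whether missing matches missing when
#'   testing vector identity (the default reproduces long merged bins);
#'   if `FALSE`, only fully observed identical vectors merge.
#' @return an object of class `cp_geno`: `codes` (bins x progeny integer
#'   matrix), `info` (id, seg_type, chrom, start, end, snp_count,
#'   n_windows) and `progeny`.
#' @export
bin_markers <- function(cp, window_bp = 500000, k_side = 2, radius = 1,
                        na_matches_na = TRUE) {
  stopifnot(inherits(cp, "cp_sites"))
  info_l <- list(); codes_l <- list()
  counter <- c(lmxll = 0L, nnxnp = 0L, hkxhk = 0L)
  prefix <- c(lmxll = "lm", nnxnp = "np", hkxhk = "hk")
  for (st in SEG_TYPES) {
    for (ch in unique(cp$info$chrom[cp$info$seg_type == st])) {
      i <- which(cp$info$seg_type == st & cp$info$chrom == ch)
      i <- i[order(cp$info$pos[i])]
      wb <- window_bin(cp$codes[i, , drop = FALSE], cp$info$pos[i],
                       seg_type = st, window_bp = window_bp)
      wb$codes <- impute_and_correct(wb$codes, k_side = k_side, radius = radius)
      mg <- merge_identical(wb$codes, wb$info, na_matches_na = na_matches_na)
      nb <- nrow(mg$info)
      if (!nb) next
      ids <- sprintf("%s%04d", prefix[[st]], counter[[st]] + seq_len(nb))
      counter[[st]] <- counter[[st]] + nb
      info_l[[length(info_l) + 1L]] <- data.frame(
        id = ids, seg_type = st, chrom = ch,
        start = mg$info$start, end = mg$info$end,
        snp_count = mg$info$snp_count, n_windows = mg$info$n_windows,
        stringsAsFactors = FALSE)
      rownames(mg$codes) <- ids
      codes_l[[length(codes_l) + 1L]] <- mg$codes
    }
  }
  if (!length(info_l)) stop_input("no informative sites to bin")
  out <- list(codes = do.call(rbind, codes_l),
              info = do.call(rbind, info_l),
              progeny = cp$progeny)
  colnames(out$codes) <- cp$progeny
  class(out) <- "cp_geno"
  out
}

#' @export
print.cp_geno <- function(x, ...) {
  cat("Bin markers:", nrow(x$codes), "bins x", length(x$progeny),
      "progeny;", sum(x$info$snp_count), "member SNPs\n")
  print(table(x$info$seg_type))
  invisible(x)
}

#' Step (i): majority-rule window calls
#'
#' Assigns each SNP to the fixed tile containing its position and calls
#' each (window, progeny) cell as the majority CP code over non-missing
#' member SNPs; ties and all-missing cells are missing. Empty windows are
#' omitted.
#'
#' @param codes integer code matrix (sites x progeny) of one segregation
#'   set on one chromosome, position-sorted.
#' @param pos 1-based bp positions aligned with `codes` rows.
#' @param seg_type the segregation set of the sites.
#' @param window_bp tile size in bp.
#' @return list with `codes` (windows x progeny) and `info`
#'   (window index, tile_start, tile_end, start, end, snp_count) where
#'   start/end span the member SNPs.
#' @export
window_bin <- function(codes, pos, seg_type, window_bp = 500000) {
  if (is.unsorted(pos)) stop_input("sites must be position-sorted")
  nc <- n_codes(seg_type)
  win <- (pos - 1) %/% window_bp
  uw <- sort(unique(win))
  n <- ncol(codes)
  out <- matrix(NA_integer_, length(uw), n)
  info <- data.frame(window = uw,
                     tile_start = uw * window_bp + 1,
                     tile_end = (uw + 1) * window_bp,
                     start = NA_integer_, end = NA_integer_,
                     snp_count = NA_integer_)
  for (w in seq_along(uw)) {
    rows <- which(win == uw[w])
    sub <- codes[rows, , drop = FALSE]
    cnt <- vapply(seq_len(nc) - 1L,
                  function(cd) colSums(sub == cd, na.rm = TRUE),
                  numeric(n))
    cnt <- matrix(cnt, nrow = n)
    top <- max.col(cnt, ties.method = "first")
    mx <- cnt[cbind(seq_len(n), top)]
    tie <- rowSums(cnt == mx) > 1L | mx == 0
    call <- top - 1L
    call[tie] <- NA_integer_
    out[w, ] <- call
    info$start[w] <- min(pos[rows]); info$end[w] <- max(pos[rows])
    info$snp_count[w] <- length(rows)
  }
  colnames(out) <- colnames(codes)
  list(codes = out, info = info)
}

#' Steps (ii)-(iv): impute missing window calls and correct singletons
#'
#' Applied per progeny along window order, one pass per step, in order:
#' (ii) a missing call is filled with the strict majority among the
#' `k_side` nearest non-missing calls on each side, if such a majority
#' exists; (iii) a maximal missing run whose two flanking calls (within
#' `radius` steps) are non-missing and identical is filled with that call;
#' (iv) a call differing from both its immediate neighbors is replaced
#' when those neighbors are non-missing and identical.
#'
#' @param mat windows x progeny integer code matrix, position-sorted.
#' @param k_side non-missing neighbors per side collected in step (ii);
#'   0 disables the step.
#' @param radius neighbor offset used in steps (iii)-(iv).
#' @return the corrected matrix.
#' @export
impute_and_correct <- function(mat, k_side = 2, radius = 1) {
  m <- nrow(mat)
  if (m == 0) return(mat)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    # (ii) nearest-neighbor strict-majority fill
    if (k_side > 0 && anyNA(x) && !all(is.na(x))) {
      filled <- x
      obs <- which(!is.na(x))
      for (i in which(is.na(x))) {
        lo <- rev(obs[obs < i]); hi <- obs[obs > i]
        nb <- x[c(head(lo, k_side), head(hi, k_side))]
        if (!length(nb)) next
        tab <- tabulate(nb + 1L)
        if (sum(tab == max(tab)) == 1L && max(tab) > length(nb) / 2)
          filled[i] <- which.max(tab) - 1L
      }
      x <- filled
    }
    # (iii) fill missing runs between identical flanks
    if (anyNA(x)) {
      r <- rle(is.na(x))
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        lo <- starts[k] - radius; hi <- ends[k] + radius
        if (lo >= 1 && hi <= m && !is.na(x[lo]) && !is.na(x[hi]) &&
            x[lo] == x[hi])
          x[starts[k]:ends[k]] <- x[lo]
      }
    }
    # (iv) correct singletons surrounded by identical non-missing calls
    if (m > 2 * radius) {
      i <- (radius + 1):(m - radius)
      a <- x[i - radius]; b <- x[i + radius]
      fix <- !is.na(x[i]) & !is.na(a) & !is.na(b) & a == b & x[i] != a
      x[i[fix]] <- a[fix]
    }
    mat[, j] <- x
  }
  mat
}

#' Step (v): merge adjacent windows with identical genotype vectors
#'
#' Maximal runs of adjacent window bins whose genotype vectors are
#' element-wise identical are merged into one bin; the merged span is the
#' union of member windows clipped to the member-SNP extremes, and SNP
#' counts are summed.
#'
#' @param mat windows x progeny code matrix (after correction).
#' @param info window info from [window_bin()].
#' @param na_matches_na whether a missing call matches a missing call; if
#'   `FALSE`, rows containing missing data never merge.
#' @return list with merged `codes` and `info` (start, end, snp_count,
#'   n_windows).
#' @export
merge_identical <- function(mat, info, na_matches_na = TRUE) {
  m <- nrow(mat)
  if (m == 0)
    return(list(codes = mat,
                info = data.frame(start = integer(), end = integer(),
                                  snp_count = integer(), n_windows = integer())))
  same_as_prev <- vapply(seq_len(m - 1) + 1L, function(k) {
    a <- mat[k - 1L, ]; b <- mat[k, ]
    if (na_matches_na) all((a == b) | (is.na(a) & is.na(b)), na.rm = TRUE) &&
      all(is.na(a) == is.na(b))
    else !anyNA(a) && !anyNA(b) && all(a == b)
  }, logical(1))
  grp <- cumsum(c(TRUE, !same_as_prev))
  idx <- split(seq_len(m), grp)
  codes <- mat[vapply(idx, `[`, 0L, 1L), , drop = FALSE]
  out_info <- data.frame(
    start = vapply(idx, function(i) min(info$start[i]), 0),
    end = vapply(idx, function(i) max(info$end[i]), 0),
    snp_count = vapply(idx, function(i) sum(info$snp_count[i]), 0),
    n_windows = lengths(idx))
  list(codes = codes, info = out_info)
}

#' Write bin markers as BED (0-based half-open)
#'
#' @param bins a `cp_geno` object.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  stopifnot(inherits(bins, "cp_geno"))
  bed <- data.frame(chrom = bins$info$chrom, start = bins$info$start - 1L,
                    end = bins$info$end, name = bins$info$id,
                    score = bins$info$snp_count,
                    strand = ".")
  write.table(bed[order(bed$chrom, bed$start), ], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
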