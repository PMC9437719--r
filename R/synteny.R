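# Collinearity between maps and a reference layout, marker-class
# accounting, and genetic-map-guided scaffold re-anchoring.

# flat marker table from a genetic_map: id, lg, cM (+ physical columns)
map_marker_table <- function(map) {
  do.call(rbind, c(lapply(names(map$groups), function(nm) {
    g <- map$groups[[nm]]
    cbind(data.frame(lg = nm), g)
  }), make.row.names = FALSE))
}

# majority physical chromosome per linkage group
lg_chrom_pairing <- function(tab) {
  vapply(split(tab$chrom, tab$lg),
         function(ch) names(sort(table(ch), decreasing = TRUE))[1], "")
}

#' Find SNP-bin pairs (SBPs) between two maps
#'
#' Pairs each SNP marker of `snp_map` with a bin of `bin_map`: by
#' physical containment in the bin span (`within_bin`; nearest bin on
#' ties) or, failing that, by co-residence on the same scaffold
#' (`same_scaffold`, nearest bin). SNPs without coordinates or without
#' any candidate bin remain unpaired (counted in `attr(,"n_unpaired")`).
#'
#' @param snp_map a `genetic_map` whose markers carry `chrom` and
#'   `start` (= position) columns.
#' @param bin_map a `genetic_map` whose markers carry `chrom`, `start`,
#'   `end` spans.
#' @param layout scaffold layout data frame (scaffold, chrom, start, end)
#'   used for the same-scaffold relation.
#' @return data frame of class `sbp`: snp_id, bin_id, relation, lg_snp,
#'   lg_bin, chrom, concordant (linkage groups pair by shared majority
#'   chromosome).
#' @export
find_sbps <- function(snp_map, bin_map, layout) {
  A <- map_marker_table(snp_map)
  B <- map_marker_table(bin_map)
  A$pos <- A$start
  skipped <- sum(is.na(A$pos) | is.na(A$chrom))
  A <- A[!is.na(A$pos) & !is.na(A$chrom), ]
  A_sc <- locate_on_scaffolds(layout, A$chrom, A$pos)$scaffold
  B_sc <- locate_on_scaffolds(layout, B$chrom,
                              as.integer((B$start + B$end) / 2))$scaffold
  out <- list()
  for (i in seq_len(nrow(A))) {
    cand <- which(B$chrom == A$chrom[i] & B$start <= A$pos[i] &
                    B$end >= A$pos[i])
    rel <- "within_bin"
    if (!length(cand)) {
      cand <- which(B_sc == A_sc[i] & !is.na(B_sc) & !is.na(A_sc[i]))
      rel <- "same_scaffold"
    }
    if (!length(cand)) next
    mid <- (B$start[cand] + B$end[cand]) / 2
    j <- cand[which.min(abs(mid - A$pos[i]))]
    out[[length(out) + 1L]] <- data.frame(
      snp_id = A$id[i], bin_id = B$id[j], relation = rel,
      lg_snp = A$lg[i], lg_bin = B$lg[j], chrom = A$chrom[i],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
         else data.frame(snp_id = character(), bin_id = character(),
                         relation = character(), lg_snp = character(),
                         lg_bin = character(), chrom = character())
  pa <- lg_chrom_pairing(A); pb <- lg_chrom_pairing(B)
  res$concordant <- pa[res$lg_snp] == pb[res$lg_bin]
  attr(res, "n_unpaired") <- nrow(A) - nrow(res)
  attr(res, "n_skipped") <- skipped
  class(res) <- c("sbp", "data.frame")
  res
}

#' Fraction of SBPs mapped to corresponding linkage groups
#'
#' @param sbps an `sbp` data frame from [find_sbps()] (any data frame
#'   with a logical `concordant` column works).
#' @return percentage of concordant pairs.
#' @export
sbp_concordance <- function(sbps) {
  if (!nrow(sbps)) return(NA_real_)
  100 * mean(sbps$concordant)
}

#' Build a collinearity table from per-group marker-class counts
#'
#' Collinearity is the percentage of markers co-anchored on the
#' corresponding chromosome among those anchored at all:
#' `100 * co / (co + mis)`; the new-anchored percentage is
#' `100 * new / (co + mis + new)`. A `Total` row aggregates the counts.
#'
#' @param counts data frame with columns `lg`, `co_anchored`,
#'   `misaligned`, `new_anchored`.
#' @return data frame of class `collinearity_table` with percentage
#'   columns and a totals row.
#' @export
collinearity_table <- function(counts) {
  stopifnot(all(c("lg", "co_anchored", "misaligned", "new_anchored") %in%
                  names(counts)))
  tot <- data.frame(lg = "Total",
                    co_anchored = sum(counts$co_anchored),
                    misaligned = sum(counts$misaligned),
                    new_anchored = sum(counts$new_anchored))
  tab <- rbind(counts, tot)
  tab$collinearity_pct <-
    100 * tab$co_anchored / (tab$co_anchored + tab$misaligned)
  tab$new_anchored_pct <- 100 * tab$new_anchored /
    (tab$co_anchored + tab$misaligned + tab$new_anchored)
  class(tab) <- c("collinearity_table", "data.frame")
  tab
}

#' Classify mapped markers against a reference anchoring
#'
#' Each marker's scaffold of origin is looked up in the reference
#' anchoring: markers whose scaffold is unanchored are `new_anchored`;
#' anchored markers are `co_anchored` when the reference chromosome
#' matches their linkage group's corresponding chromosome (majority vote
#' over member markers) and `misaligned` otherwise.
#'
#' @param map a `genetic_map` whose markers carry physical spans.
#' @param reference reference anchoring data frame (`scaffold`,
#'   `ref_chrom` with NA = unanchored), e.g. from [fragment_genome()].
#' @param layout scaffold layout (true physical origin of coordinates).
#' @return a `collinearity_table` with one row per linkage group.
#' @export
classify_vs_reference <- function(map, reference, layout) {
  tab <- map_marker_table(map)
  mid <- as.integer((tab$start + tab$end) / 2)
  tab$scaffold <- locate_on_scaffolds(layout, tab$chrom, mid)$scaffold
  tab$ref_chrom <- reference$ref_chrom[match(tab$scaffold,
                                             reference$scaffold)]
  # LG <-> chromosome correspondence from the reference-anchored markers
  anch <- tab[!is.na(tab$ref_chrom), ]
  corr <- vapply(split(anch$ref_chrom, anch$lg), function(ch)
    names(sort(table(ch), decreasing = TRUE))[1], "")
  rows <- lapply(names(map$groups), function(nm) {
    sub <- tab[tab$lg == nm, ]
    newa <- sum(is.na(sub$ref_chrom))
    co <- sum(!is.na(sub$ref_chrom) & sub$ref_chrom == corr[nm])
    mis <- sum(!is.na(sub$ref_chrom) & sub$ref_chrom != corr[nm])
    data.frame(lg = nm, co_anchored = co, misaligned = mis,
               new_anchored = newa)
  })
  collinearity_table(do.call(rbind, rows))
}

#' Re-anchor scaffolds from one or more genetic maps
#'
#' Assigns each scaffold to the marker-count-weighted majority linkage
#' group across the supplied maps, splits a scaffold at a bin-span edge
#' when two runs of at least `split_run` markers each support different
#' groups, orders scaffolds within a group by weighted mean cM, and
#' orients each by the sign of the rank correlation between marker cM
#' and scaffold-local bp (`"?"` with fewer than 2 distinct positions or a
#' zero correlation; placed as `"+"` in the AGP with a flag). Scaffolds
#' without markers are left unplaced.
#'
#' @param maps a `genetic_map` or list of them.
#' @param layout scaffold layout data frame (scaffold, chrom, start, end,
#'   length).
#' @param map_weights per-map weights (default equal).
#' @param split_run minimum run length of same-group markers on both
#'   sides to cut a scaffold.
#' @param gap_size AGP gap length between consecutive scaffolds.
#' @return list of class `scaffold_anchors`: `anchors` data frame
#'   (scaffold, part, group, order_cM, orientation, n_markers, start,
#'   end, length), `agp` data frame, `unplaced` scaffold ids.
#' @export
anchor_scaffolds <- function(maps, layout, map_weights = NULL,
                             split_run = 2, gap_size = 100) {
  if (inherits(maps, "genetic_map")) maps <- list(maps)
  if (is.null(map_weights)) map_weights <- rep(1, length(maps))
  mk <- list()
  for (k in seq_along(maps)) {
    t <- map_marker_table(maps[[k]])
    mid <- as.integer((t$start + t$end) / 2)
    loc <- locate_on_scaffolds(layout, t$chrom, mid)
    mk[[k]] <- data.frame(id = t$id, scaffold = loc$scaffold,
                          offset = loc$offset,
                          span_lo = t$start, span_hi = t$end,
                          lg = t$lg, cM = t$cM, w = map_weights[k],
                          stringsAsFactors = FALSE)
  }
  mk <- do.call(rbind, mk)
  mk <- mk[!is.na(mk$scaffold), ]
  anchors <- list()
  for (sc in unique(mk$scaffold)) {
    sub <- mk[mk$scaffold == sc, ]
    sub <- sub[order(sub$offset), ]
    slen <- layout$length[match(sc, layout$scaffold)]
    # candidate split: two runs of >= split_run markers for different LGs
    rl <- rle(sub$lg)
    parts <- list(seq_len(nrow(sub)))
    if (length(rl$values) >= 2) {
      big <- rl$lengths >= split_run
      # split between consecutive big runs with different groups
      ends <- cumsum(rl$lengths)
      cutpts <- integer()
      for (q in seq_len(length(rl$values) - 1)) {
        nxt_big <- which(big & seq_along(big) > q)
        if (big[q] && length(nxt_big) &&
            rl$values[head(nxt_big, 1)] != rl$values[q])
          cutpts <- c(cutpts, ends[q])
      }
      cutpts <- unique(cutpts)
      if (length(cutpts)) {
        bounds <- c(0, cutpts, nrow(sub))
        parts <- lapply(seq_len(length(bounds) - 1), function(q)
          (bounds[q] + 1):bounds[q + 1])
      }
    }
    for (pi in seq_along(parts)) {
      rows <- sub[parts[[pi]], ]
      grp_w <- tapply(rows$w, rows$lg, sum)
      grp <- names(grp_w)[which.max(grp_w)]
      rows_g <- rows[rows$lg == grp, ]
      ori <- if (length(unique(rows_g$offset)) < 2 ||
                 length(unique(rows_g$cM)) < 2) "?"
      else {
        rho <- suppressWarnings(cor(rows_g$cM, rows_g$offset,
                                    method = "spearman"))
        if (is.na(rho) || rho == 0) "?" else if (rho > 0) "+" else "-"
      }
      # physical extent of this part: cut at bin-span edges
      lo <- if (pi == 1) 1L else
        min(rows$offset - (rows$span_hi - rows$span_lo), na.rm = TRUE)
      lo <- max(1L, as.integer(lo))
      hi <- if (pi == length(parts)) as.integer(slen) else
        as.integer(max(rows$offset, na.rm = TRUE))
      anchors[[length(anchors) + 1L]] <- data.frame(
        scaffold = sc, part = pi,
        part_id = if (length(parts) > 1) paste0(sc, ".", pi) else sc,
        group = grp,
        order_cM = sum(rows_g$cM * rows_g$w) / sum(rows_g$w),
        orientation = ori, n_markers = nrow(rows_g),
        start = lo, end = hi, length = hi - lo + 1L,
        stringsAsFactors = FALSE)
    }
  }
  anchors <- do.call(rbind, c(anchors, make.row.names = FALSE))
  unplaced <- setdiff(layout$scaffold, anchors$scaffold)
  agp <- agp_from_anchors(anchors, gap_size = gap_size)
  structure(list(anchors = anchors, agp = agp, unplaced = unplaced),
            class = "scaffold_anchors")
}

#' @export
print.scaffold_anchors <- function(x, ...) {
  cat("Scaffold anchoring:", nrow(x$anchors), "placed parts over",
      length(unique(x$anchors$group)), "groups;",
      length(x$unplaced), "scaffolds unplaced\n")
  invisible(x)
}

#' Total anchored length and fraction of the genome
#'
#' @param anchors a `scaffold_anchors` object (or its `anchors` data
#'   frame).
#' @param genome_size total genome length in bp.
#' @return list with `anchored_bp` and `anchored_pct`.
#' @export
assembly_stats <- function(anchors, genome_size) {
  a <- if (inherits(anchors, "scaffold_anchors")) anchors$anchors else anchors
  bp <- sum(as.numeric(a$length))
  list(anchored_bp = bp, anchored_pct = 100 * bp / genome_size)
}
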