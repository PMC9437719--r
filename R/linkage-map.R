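#' Group markers by independence LOD
#'
#' Markers with more than `max_missing` missing calls are excluded first;
#' remaining markers are grouped as connected components of the graph with
#' an edge wherever the pairwise independence LOD reaches
#' `ind_lod_min`. A threshold-ladder report (number of groups at each
#' threshold from 2 to 30) is included for diagnostics.
#'
#' @param geno a `cp_geno` object of bin markers.
#' @param ind_lod_min independence-LOD threshold for an edge.
#' @param max_missing maximum missing calls per marker (strictly more are
#'   excluded).
#' @param parent which meioses the map will target: `"maternal"` uses
#'   lmxll + hkxhk markers, `"paternal"` nnxnp + hkxhk, `"all"` every set.
#' @param min_joint floor on jointly observed progeny per pair.
#' @param rfm optionally, a precomputed [rf_matrix()] over the same
#'   markers.
#' @return an object of class `linkage_groups`: `groups` (list of marker
#'   id vectors, largest first), `rf` (the `rf_matrix`), `excluded`
#'   (ids dropped by the missing-call rule) and `ladder` (data frame
#'   threshold / n_groups).
#' @export
group_markers <- function(geno, ind_lod_min = 9, max_missing = 9,
                          parent = c("all", "maternal", "paternal"),
                          min_joint = 20, rfm = NULL) {
  parent <- match.arg(parent)
  keep_types <- switch(parent,
                       maternal = c("lmxll", "hkxhk"),
                       paternal = c("nnxnp", "hkxhk"),
                       all = SEG_TYPES)
  sel <- geno$info$seg_type %in% keep_types
  n_miss <- rowSums(is.na(geno$codes))
  excluded <- geno$info$id[sel & n_miss > max_missing]
  ids <- geno$info$id[sel & n_miss <= max_missing]
  if (!length(ids)) stop_input("no markers left after the missing-call filter")
  if (is.null(rfm)) rfm <- rf_matrix(geno, markers = ids, min_joint = min_joint)
  il <- rfm$ind_lod
  comp_at <- function(th) {
    adj <- !is.na(il) & il >= th
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  }
  membership <- comp_at(ind_lod_min)
  groups <- split(ids, membership)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- NULL
  ladder <- data.frame(
    threshold = 2:30,
    n_groups = vapply(2:30, function(th) max(comp_at(th)), 0))
  structure(list(groups = groups, rf = rfm, excluded = excluded,
                 ladder = ladder, ind_lod_min = ind_lod_min,
                 parent = parent), class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  cat("Linkage grouping (", x$parent, " markers, ind LOD >= ",
      x$ind_lod_min, "): ", length(x$groups), " groups of sizes ",
      paste(lengths(x$groups), collapse = ", "), "\n", sep = "")
  if (length(x$excluded))
    cat("  excluded for missing calls:", length(x$excluded), "markers\n")
  invisible(x)
}

# 2-opt segment reversals plus or-opt relocation of short segments,
# first-improvement, repeated until a full sweep finds nothing better
polish_order <- function(ord, D, W, max_passes = 12) {
  cur <- order_objective(ord, D, W)
  n <- length(ord)
  if (n < 3) return(ord)
  improved <- TRUE; pass <- 0
  while (improved && pass < max_passes) {
    improved <- FALSE; pass <- pass + 1
    for (i in 1:(n - 1)) for (jj in (i + 1):n) {
      cand <- ord
      cand[i:jj] <- rev(cand[i:jj])
      o <- order_objective(cand, D, W)
      if (o < cur - 1e-12) { ord <- cand; cur <- o; improved <- TRUE }
    }
    for (seg_len in 1:2) {
      if (n <= seg_len + 1) next
      for (i in 1:(n - seg_len + 1)) {
        seg <- ord[i:(i + seg_len - 1)]
        rest <- ord[-(i:(i + seg_len - 1))]
        for (s in 0:length(rest)) {
          if (s == i - 1) next
          cand <- append(rest, seg, after = s)
          o <- order_objective(cand, D, W)
          if (o < cur - 1e-12) {
            ord <- cand; cur <- o; improved <- TRUE
            break
          }
        }
      }
    }
  }
  ord
}

# Regression-mapping objective: given a candidate order, inter-marker
# gaps are fitted by weighted least squares against all pairwise
# two-point distances (normal equations built from cumulative sums of
# the rank-permuted weight matrix), and the objective is the weighted
# residual sum of squares. Returns the fitted gaps on request so the
# final map positions come from the same fit.
order_objective <- function(ord, D, W, gaps = FALSE) {
  m <- length(ord)
  if (m < 2) return(if (gaps) list(obj = 0, gaps = numeric()) else 0)
  S <- W[ord, ord]
  Dm <- D[ord, ord]
  S[lower.tri(S, diag = TRUE)] <- 0
  SD <- S * Dm
  # F[k, j] = sum_{i <= k} S[i, j]; M[k, l<=k treated by symmetry] =
  # sum over pairs spanning both gaps = sum_{i <= min, j > max} S[i, j]
  F <- apply(S, 2, cumsum)[-m, , drop = FALSE]
  FD <- apply(SD, 2, cumsum)[-m, , drop = FALSE]
  H <- t(apply(F[, m:1, drop = FALSE], 1, cumsum))[, m:1, drop = FALSE]
  HD <- t(apply(FD[, m:1, drop = FALSE], 1, cumsum))[, m:1, drop = FALSE]
  Mupper <- H[, -1, drop = FALSE]              # M[k, l] for l >= k
  Mfull <- Mupper
  Mfull[lower.tri(Mfull)] <- t(Mupper)[lower.tri(Mfull)]
  b <- HD[cbind(seq_len(m - 1), seq_len(m - 1) + 1)]
  g <- tryCatch(solve(Mfull + diag(1e-8, m - 1), b),
                error = function(e) rep(NA_real_, m - 1))
  if (anyNA(g)) {
    g <- Dm[cbind(seq_len(m - 1), seq_len(m - 1) + 1)]
  }
  g <- pmax(g, 0)
  pos <- c(0, cumsum(g))
  Dist <- abs(outer(pos, pos, "-"))
  obj <- sum(W[ord, ord] * (Dist - D[ord, ord])^2, na.rm = TRUE) / 2
  if (gaps) list(obj = obj, gaps = g) else obj
}

# sum of adjacent two-point distances (seriation criterion used as one
# of the initial candidates)
path_objective <- function(ord, D) {
  sum(D[cbind(ord[-length(ord)], ord[-1])])
}

polish_path <- function(ord, D, max_passes = 12) {
  cur <- path_objective(ord, D)
  n <- length(ord)
  improved <- TRUE; pass <- 0
  while (improved && pass < max_passes) {
    improved <- FALSE; pass <- pass + 1
    for (i in 1:(n - 1)) for (jj in (i + 1):n) {
      cand <- ord
      cand[i:jj] <- rev(cand[i:jj])
      o <- path_objective(cand, D)
      if (o < cur - 1e-12) { ord <- cand; cur <- o; improved <- TRUE }
    }
  }
  ord
}

#' Order the markers of one linkage group
#'
#' Greedy insertion seeded from the most informative linked pair: each
#' next marker (chosen by total linkage LOD to the placed set) is
#' inserted at the position minimizing the LOD-weighted least-squares
#' conflict between map distances and pairwise two-point Kosambi
#' distances; the order is then polished by 2-opt segment reversals of
#' the same objective. Positions are cumulative adjacent Kosambi
#' distances starting at 0.
#'
#' @param group character vector of marker ids (one group).
#' @param rfm an [rf_matrix()] covering them.
#' @param min_lod_edge pairs below this linkage LOD get zero weight in the
#'   objective (exclusion of weak linkages).
#' @param r_cap recombination fractions are capped here before the
#'   Kosambi transform (r = 0.5 maps to infinity).
#' @param max_passes 2-opt pass limit.
#' @param resid_drop markers whose mean weighted residual in the fitted
#'   map exceeds `resid_drop` times the group median (and an absolute
#'   floor) are excluded as poorly fitting and the order re-polished;
#'   their ids are recorded in `attr(, "dropped")`. `Inf` disables the
#'   clean-up.
#' @return a data frame (`id`, `cM`, `lod_sum`) in map order, with the
#'   final objective value in `attr(, "objective")`. Markers without any
#'   usable linkage to the rest are appended at the end with a warning.
#' @export
order_group <- function(group, rfm, min_lod_edge = 3, r_cap = 0.4999,
                        max_passes = 12, resid_drop = 4) {
  idx <- match(group, rownames(rfm$r))
  if (anyNA(idx)) stop_input("group markers missing from rf matrix")
  k <- length(idx)
  lod_sum_all <- rowSums(rfm$lod[idx, idx, drop = FALSE], na.rm = TRUE)
  if (k == 1) {
    out <- data.frame(id = group, cM = 0, lod_sum = 0)
    attr(out, "objective") <- 0
    return(out)
  }
  R <- rfm$r[idx, idx, drop = FALSE]
  L <- rfm$lod[idx, idx, drop = FALSE]
  D <- kosambi(pmin(R, r_cap))
  D[is.na(D)] <- kosambi(r_cap)
  diag(D) <- 0
  # weights: lod-supported pairs, scaled by the inverse variance of the
  # Kosambi distance estimate (delta method), so near-independent pairs
  # with unstable distances cannot dominate the fit
  n_med <- median(rfm$n_joint[idx, idx], na.rm = TRUE)
  rc <- pmin(pmax(R, 1 / (2 * max(n_med, 2))), 0.49)
  rc[is.na(rc)] <- 0.49
  W <- (1 - 4 * rc^2)^2 / (rc * (1 - rc))
  W[is.na(L) | L < min_lod_edge] <- 0
  diag(W) <- 0
  linked <- rowSums(W) > 0
  un <- which(!linked)
  if (length(un))
    warning(sum(!linked), " marker(s) without usable linkage appended at the group end")
  core <- which(linked)
  if (length(core) < 2) {
    ord <- seq_len(k)
  } else {
    # greedy insertion seeded from the strongest pair
    seedpair <- arrayInd(which.max(W), dim(W))
    ord <- as.integer(seedpair)
    remaining <- setdiff(core, ord)
    while (length(remaining)) {
      link_tot <- colSums(W[ord, remaining, drop = FALSE])
      nxt <- remaining[which.max(link_tot)]
      best <- Inf; best_ord <- NULL
      for (s in 0:length(ord)) {
        cand <- append(ord, nxt, after = s)
        o <- order_objective(cand, D, W)
        if (o < best) { best <- o; best_ord <- cand }
      }
      ord <- best_ord
      remaining <- setdiff(remaining, nxt)
    }
    # alternative initializations: principal-coordinate seriation and a
    # shortest-path (sum of adjacent distances) polish of it
    if (length(core) > 3) {
      mds <- tryCatch(cmdscale(D[core, core], k = 1), error = function(e) NULL)
      if (!is.null(mds)) {
        cands <- list(ord, core[order(mds[, 1])])
        cands[[3]] <- polish_path(cands[[2]], D)
        ord <- cands[[which.min(vapply(cands, order_objective, 0,
                                       D = D, W = W))]]
      }
    }
    ord <- polish_order(ord, D, W, max_passes)
    # clean-up: exclude markers with outlying stress and re-polish
    dropped <- integer()
    for (iter in 1:3) {
      if (!is.finite(resid_drop) || length(ord) < 8) break
      fit <- order_objective(ord, D, W, gaps = TRUE)
      pos <- c(0, cumsum(fit$gaps))
      Dist <- abs(outer(pos, pos, "-"))
      R2 <- W[ord, ord] * (Dist - D[ord, ord])^2
      res <- rowSums(R2, na.rm = TRUE) / pmax(rowSums(W[ord, ord]), 1e-9)
      med <- median(res)
      bad <- which(res > resid_drop * med & res > 1)
      if (!length(bad) || length(bad) > length(ord) %/% 5) break
      dropped <- c(dropped, ord[bad])
      ord <- polish_order(ord[-bad], D, W, max_passes)
    }
    ord <- c(ord, un)
  }
  fit <- order_objective(ord, D, W, gaps = TRUE)
  pos <- c(0, cumsum(fit$gaps))
  out <- data.frame(id = group[ord], cM = pos, lod_sum = lod_sum_all[ord])
  attr(out, "objective") <- fit$obj
  attr(out, "dropped") <- group[dropped]
  out
}

make_genetic_map <- function(kind, group_frames, info) {
  groups <- list()
  for (g in group_frames) {
    meta <- info[match(g$id, info$id), c("seg_type", "chrom", "start", "end",
                                         "snp_count")]
    groups[[length(groups) + 1L]] <- cbind(g, meta, row.names = NULL)
  }
  # name linkage groups after the majority physical chromosome of members
  maj <- vapply(groups, function(g)
    names(sort(table(g$chrom), decreasing = TRUE))[1], "")
  lg_num <- as.integer(sub("\\D*", "", maj))
  ord <- order(lg_num, -vapply(groups, nrow, 0L))
  groups <- groups[ord]; lg_num <- lg_num[ord]
  nm <- paste0("LG", lg_num)
  while (any(duplicated(nm))) {
    d <- which(duplicated(nm))[1]
    nm[d] <- paste0(nm[d], "b")
  }
  names(groups) <- nm
  structure(list(kind = kind, groups = groups), class = "genetic_map")
}

#' Build maternal and paternal framework maps
#'
#' The maternal map is built from lmxll + hkxhk markers (hkxhk markers
#' contribute their maternal-meiosis information through the two-locus
#' EM), the paternal map from nnxnp + hkxhk, each via [group_markers()]
#' and [order_group()]. Linkage groups are named after the majority
#' physical chromosome of their member bins.
#'
#' @param bins a `cp_geno` object of bin markers.
#' @param ind_lod_min,max_missing,min_joint passed to [group_markers()].
#' @param min_lod_edge passed to [order_group()].
#' @param min_group_size groups with fewer markers are dropped (singleton
#'   and doubleton fragments).
#' @param nn_r_max weak-linkage exclusion: a marker whose nearest
#'   neighbor within its group has two-point r above this is left out of
#'   the ordered map (ids recorded in `attr(map, "weakly_linked")`).
#' @return list with `maternal` and `paternal` `genetic_map` objects.
#' @export
build_parental_maps <- function(bins, ind_lod_min = 9, max_missing = 9,
                                min_joint = 20, min_lod_edge = 3,
                                min_group_size = 3, nn_r_max = 0.15) {
  out <- list()
  for (parent in c("maternal", "paternal")) {
    keep_types <- if (parent == "maternal") c("lmxll", "hkxhk")
                  else c("nnxnp", "hkxhk")
    if (!any(bins$info$seg_type %in% keep_types)) {
      out[[parent]] <- structure(list(kind = parent, groups = list()),
                                 class = "genetic_map")
      next
    }
    gr <- group_markers(bins, ind_lod_min = ind_lod_min,
                        max_missing = max_missing, parent = parent,
                        min_joint = min_joint)
    weak <- character()
    frames <- lapply(gr$groups[lengths(gr$groups) >= min_group_size],
                     function(g) {
                       R <- gr$rf$r[g, g, drop = FALSE]
                       nn_r <- apply(R, 1, min, na.rm = TRUE)
                       drop <- g[!is.finite(nn_r) | nn_r > nn_r_max]
                       weak <<- c(weak, drop)
                       keep <- setdiff(g, drop)
                       if (length(keep) < 2) return(NULL)
                       order_group(keep, gr$rf, min_lod_edge = min_lod_edge)
                     })
    frames <- frames[!vapply(frames, is.null, TRUE)]
    out[[parent]] <- make_genetic_map(parent, frames, bins$info)
    attr(out[[parent]], "weakly_linked") <- weak
  }
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(x$kind, "genetic map:", length(x$groups), "linkage groups,",
      sum(vapply(x$groups, nrow, 0L)), "markers\n")
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) map_summary(object)

#' Per-linkage-group map summary
#'
#' Reports marker counts, map length (position of the last marker),
#' average adjacent interval (`length / (n - 1)`; empty for single-marker
#' groups) and member-SNP totals, plus average and total rows. The total
#' average interval is `sum(length) / (sum(n) - n_groups)`.
#'
#' @param map a `genetic_map` object.
#' @return a data frame with one row per linkage group plus
#'   `"Average"` and `"Total"` rows.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(names(map$groups), function(nm) {
    g <- map$groups[[nm]]
    n <- nrow(g); len <- max(g$cM)
    data.frame(linkage_group = nm, n_markers = n, length_cM = len,
               avg_interval_cM = if (n > 1) len / (n - 1) else NA_real_,
               n_snps = sum(g$snp_count, na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  total_n <- sum(tab$n_markers); total_len <- sum(tab$length_cM)
  avg <- data.frame(linkage_group = "Average",
                    n_markers = mean(tab$n_markers),
                    length_cM = mean(tab$length_cM),
                    avg_interval_cM = mean(tab$avg_interval_cM, na.rm = TRUE),
                    n_snps = mean(tab$n_snps))
  tot <- data.frame(linkage_group = "Total", n_markers = total_n,
                    length_cM = total_len,
                    avg_interval_cM = total_len / (total_n - nrow(tab)),
                    n_snps = sum(tab$n_snps))
  rbind(tab, avg, tot)
}

# piecewise-linear projection through bridge anchor pairs, linear
# extrapolation beyond the end anchors
pwl_project <- function(x, xb, yb) {
  o <- order(xb); xb <- xb[o]; yb <- yb[o]
  keep <- !duplicated(xb)
  xb <- xb[keep]; yb <- yb[keep]
  if (length(xb) == 1) return(x - xb + yb)
  y <- stats::approx(xb, yb, xout = x, rule = 2)$y
  lo <- x < xb[1]; hi <- x > xb[length(xb)]
  s1 <- (yb[2] - yb[1]) / (xb[2] - xb[1])
  s2 <- (yb[length(yb)] - yb[length(yb) - 1]) / (xb[length(xb)] - xb[length(xb) - 1])
  y[lo] <- yb[1] + (x[lo] - xb[1]) * s1
  y[hi] <- yb[length(yb)] + (x[hi] - xb[length(xb)]) * s2
  y
}

#' Merge parental maps into a consensus map via hkxhk bridge markers
#'
#' Linkage groups are paired by their shared (bridge) markers. For each
#' pair, a monotone piecewise-linear alignment is fitted through the
#' bridge position pairs (isotonic regression); the group whose bridge
#' span is larger provides the consensus axis and the other group's
#' markers are projected through the alignment. Order conflicts at equal
#' consensus positions are resolved by the lod-weighted mean rank across
#' the two parental orders. When fewer than `min_bridges` bridges are
#' shared, the fallback re-groups and re-orders the union of both groups'
#' markers jointly (requires `bins`). Unpaired groups are carried through
#' unchanged with a warning. Consensus positions are rescaled to start at
#' 0.
#'
#' @param maternal,paternal `genetic_map` objects sharing bridge marker
#'   ids.
#' @param bins the `cp_geno` bin genotypes (needed only for the fallback
#'   path).
#' @param min_bridges minimum shared markers for the alignment path.
#' @param ind_lod_min,min_lod_edge parameters for the fallback re-grouping.
#' @return a consensus `genetic_map`.
#' @export
merge_consensus <- function(maternal, paternal, bins = NULL, min_bridges = 2,
                            ind_lod_min = 9, min_lod_edge = 3) {
  stopifnot(inherits(maternal, "genetic_map"), inherits(paternal, "genetic_map"))
  pat_used <- character()
  frames <- list()
  for (nm in names(maternal$groups)) {
    gm <- maternal$groups[[nm]]
    shared_n <- vapply(paternal$groups, function(gp)
      length(intersect(gm$id, gp$id)), 0L)
    if (!length(shared_n) || max(shared_n) == 0) {
      frames[[length(frames) + 1L]] <- gm
      warning("maternal group ", nm, " has no paternal counterpart; carried through")
      next
    }
    pnm <- names(paternal$groups)[which.max(shared_n)]
    gp <- paternal$groups[[pnm]]
    pat_used <- c(pat_used, pnm)
    bridges <- intersect(gm$id, gp$id)
    if (length(bridges) >= min_bridges) {
      frames[[length(frames) + 1L]] <- align_pair(gm, gp, bridges)
    } else {
      if (is.null(bins))
        stop_input("fallback merge for group ", nm,
                   " needs the bin genotypes (bins =)")
      ids <- union(gm$id, gp$id)
      gr <- group_markers(subset_geno(bins, ids), ind_lod_min = ind_lod_min,
                          parent = "all", max_missing = ncol(bins$codes),
                          min_joint = 20)
      sub <- gr$groups[lengths(gr$groups) >= 2]
      for (s in sub)
        frames[[length(frames) + 1L]] <- order_group(s, gr$rf,
                                                     min_lod_edge = min_lod_edge)
    }
  }
  for (pnm in setdiff(names(paternal$groups), pat_used)) {
    frames[[length(frames) + 1L]] <- paternal$groups[[pnm]]
    warning("paternal group ", pnm, " has no maternal counterpart; carried through")
  }
  info_cols <- c("id", "seg_type", "chrom", "start", "end", "snp_count")
  info <- unique(rbind(
    do.call(rbind, lapply(maternal$groups, function(g) g[intersect(info_cols, names(g))])),
    do.call(rbind, lapply(paternal$groups, function(g) g[intersect(info_cols, names(g))]))))
  frames <- lapply(frames, function(f) {
    f$cM <- f$cM - min(f$cM)
    f[c("id", "cM", "lod_sum")]
  })
  make_genetic_map("consensus", frames, info)
}

align_pair <- function(gm, gp, bridges) {
  a <- gm$cM[match(bridges, gm$id)]
  b <- gp$cM[match(bridges, gp$id)]
  # orient the paternal group along the maternal one if needed
  flip <- length(bridges) >= 2 && cor(a, b) < 0
  gp_pos <- if (flip) max(gp$cM) - gp$cM else gp$cM
  b <- gp_pos[match(bridges, gp$id)]
  o <- order(a)
  iso <- isoreg(a[o], b[o])
  b_fit <- iso$yf[order(o)]
  span_a <- diff(range(a)); span_b <- diff(range(b_fit))
  if (span_b >= span_a) { # paternal axis is the consensus scale
    pos_bridge <- b_fit
    pos_m_only <- pwl_project(gm$cM, a, b_fit)
    pos_p_only <- gp_pos
  } else {
    pos_bridge <- a
    pos_m_only <- gm$cM
    pos_p_only <- pwl_project(gp_pos, b_fit, a)
  }
  m_only <- setdiff(gm$id, bridges); p_only <- setdiff(gp$id, bridges)
  ids <- c(bridges, m_only, p_only)
  pos <- c(pos_bridge,
           pos_m_only[match(m_only, gm$id)],
           pos_p_only[match(p_only, gp$id)])
  lod_m <- gm$lod_sum[match(ids, gm$id)]
  lod_p <- gp$lod_sum[match(ids, gp$id)]
  w_lod <- rowSums(cbind(lod_m, lod_p), na.rm = TRUE)
  # lod-weighted mean rank across the parental orders breaks position ties
  rank_m <- match(ids, gm$id); rank_p <- match(ids, gp$id)
  wm <- ifelse(is.na(rank_m), 0, ifelse(is.na(lod_m), 1, lod_m))
  wp <- ifelse(is.na(rank_p), 0, ifelse(is.na(lod_p), 1, lod_p))
  mean_rank <- (ifelse(is.na(rank_m), 0, rank_m) * wm +
                ifelse(is.na(rank_p), 0, rank_p) * wp) / pmax(wm + wp, 1e-9)
  ord <- order(pos, mean_rank)
  data.frame(id = ids[ord], cM = pos[ord] - min(pos), lod_sum = w_lod[ord])
}

#' Export a genetic map as TSV
#'
#' @param map a `genetic_map` object.
#' @param path output path.
#' @return the exported data frame, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(names(map$groups), function(nm)
    cbind(linkage_group = nm, map$groups[[nm]]))
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
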