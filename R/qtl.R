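# Transmission-probability grids and QTL scans for CP populations.

# emission matrix P(obs | chain state) for one marker on one parent chain
# rows = progeny, cols = states (0, 1)
emission_probs <- function(code, seg_type, phase, eps) {
  n <- length(code)
  E <- matrix(1, n, 2)
  obs <- !is.na(code)
  if (seg_type %in% c("lmxll", "nnxnp")) {
    for (s in 0:1) {
      correct <- bitwXor(s, phase)
      E[obs, s + 1] <- ifelse(code[obs] == correct, 1 - eps, eps)
    }
  } else { # hkxhk: other parent's transmission marginalized uniformly
    for (s in 0:1) {
      am <- bitwXor(s, phase)
      p_true <- numeric(3)
      for (ap in 0:1) p_true[am + ap + 1] <- p_true[am + ap + 1] + 0.5
      p_obs <- p_true * (1 - eps) + (1 - p_true) * eps / 2
      E[obs, s + 1] <- p_obs[code[obs] + 1]
    }
  }
  E
}

# forward-backward along one linkage group for one parent
# returns P(state = 0) at every eval position (n_pos x n_progeny)
parent_chain_posterior <- function(pos_eval, marker_pos, emis_list, n) {
  np <- length(pos_eval)
  is_marker <- match(round(pos_eval, 9), round(marker_pos, 9))
  r_step <- kosambi_inverse(diff(pos_eval))
  alpha <- vector("list", np); beta <- vector("list", np)
  a <- matrix(0.5, n, 2)
  for (t in seq_len(np)) {
    if (t > 1) {
      r <- r_step[t - 1]
      a <- cbind(a[, 1] * (1 - r) + a[, 2] * r,
                 a[, 1] * r + a[, 2] * (1 - r))
    }
    if (!is.na(is_marker[t])) a <- a * emis_list[[is_marker[t]]]
    a <- a / pmax(rowSums(a), 1e-300)
    alpha[[t]] <- a
  }
  b <- matrix(1, n, 2)
  for (t in rev(seq_len(np))) {
    beta[[t]] <- b
    if (!is.na(is_marker[t])) b <- b * emis_list[[is_marker[t]]]
    if (t > 1) {
      r <- r_step[t - 1]
      b <- cbind(b[, 1] * (1 - r) + b[, 2] * r,
                 b[, 1] * r + b[, 2] * (1 - r))
      b <- b / pmax(rowSums(b), 1e-300)
    }
  }
  P0 <- matrix(NA_real_, np, n)
  for (t in seq_len(np)) {
    g <- alpha[[t]] * beta[[t]]
    P0[t, ] <- g[, 1] / pmax(rowSums(g), 1e-300)
  }
  P0
}

#' Per-progeny transmission probabilities along a genetic map
#'
#' For each parent a two-state hidden Markov chain runs along every
#' linkage group: states are the two parental haplotypes, transitions are
#' the inverse-Kosambi recombination fractions of the inter-position
#' distances, and emissions match the parent's informative markers with
#' miscall rate `eps`. Marker phases along each chain are inferred from
#' adjacent-pair maximum-likelihood phase estimates. The maternal and
#' paternal chains combine into the four transmitted-class probabilities
#' AC, AD, BC, BD, which sum to 1 at every grid point.
#'
#' @param map a `genetic_map`.
#' @param bins the `cp_geno` genotypes for its markers.
#' @param step_cM evaluation grid step (marker positions are always
#'   included).
#' @param eps per-call miscall rate assumed by the emissions.
#' @return an object of class `cp_probs`: per linkage group a list with
#'   `grid` (cM) and `pm`, `pp` (grid x progeny probabilities of the
#'   first maternal / paternal haplotype).
#' @export
transmission_probs <- function(map, bins, step_cM = 1, eps = 0.01) {
  stopifnot(inherits(map, "genetic_map"), inherits(bins, "cp_geno"))
  n <- length(bins$progeny)
  out <- list()
  for (nm in names(map$groups)) {
    g <- map$groups[[nm]]
    miss <- setdiff(g$id, bins$info$id)
    if (length(miss)) stop_input("map markers absent from genotypes: ",
                                 paste(head(miss, 3), collapse = ", "))
    grid <- sort(unique(c(seq(0, max(g$cM), by = step_cM), g$cM)))
    chains <- list()
    for (parent in c("m", "p")) {
      types <- if (parent == "m") c("lmxll", "hkxhk") else c("nnxnp", "hkxhk")
      sel <- which(g$seg_type %in% types)
      if (!length(sel)) {
        chains[[parent]] <- matrix(0.5, length(grid), n)
        next
      }
      ids <- g$id[sel]
      mpos <- g$cM[sel]
      # phase chain via adjacent-pair ML phase
      ph <- integer(length(ids))
      if (length(ids) > 1) {
        for (k in 2:length(ids)) {
          est <- estimate_rf(bins, ids[k - 1], ids[k], min_joint = 10)
          step <- if (parent == "m") est$phase[["maternal"]]
                  else est$phase[["paternal"]]
          rel <- if (is.na(step) || !est$usable) 0L
                 else as.integer(step == "repulsion")
          ph[k] <- bitwXor(ph[k - 1], rel)
        }
      }
      rows <- match(ids, bins$info$id)
      emis <- lapply(seq_along(ids), function(k)
        emission_probs(bins$codes[rows[k], ], g$seg_type[sel][k],
                       ph[k], eps))
      chains[[parent]] <- parent_chain_posterior(grid, mpos, emis, n)
    }
    out[[nm]] <- list(grid = grid, pm = chains$m, pp = chains$p)
  }
  structure(list(groups = out, progeny = bins$progeny, eps = eps,
                 step_cM = step_cM), class = "cp_probs")
}

class_probs <- function(pm_row, pp_row) {
  cbind(AC = pm_row * pp_row, AD = pm_row * (1 - pp_row),
        BC = (1 - pm_row) * pp_row, BD = (1 - pm_row) * (1 - pp_row))
}

#' Interval mapping by regression on expected class probabilities
#'
#' At each grid position the (possibly transformed) trait is regressed on
#' the expected transmitted-class indicators (four classes, three
#' contrasts; Haley-Knott style), giving
#' `LOD = (n/2) * log10(RSS0 / RSS1)`. Peaks are grid positions with LOD
#' at or above the threshold, at least `peak_sep` cM apart; the
#' percentage of variance explained is `100 * (1 - RSS1/RSS0)` at the
#' peak, and 1-LOD and 2-LOD support intervals are found by walking down
#' the curve on both sides.
#'
#' @param trait numeric values in progeny order.
#' @param probs a `cp_probs` object from [transmission_probs()].
#' @param lod_threshold genome-wide significance threshold (LOD).
#' @param peak_sep minimum separation between reported peaks, cM.
#' @return an object of class `qtl_scan`: `curve` data frame
#'   (lg, cM, lod), `peaks` data frame (lg, cM, lod, pve and the
#'   1-/2-LOD interval bounds), `n`, `threshold`.
#' @export
interval_mapping <- function(trait, probs, lod_threshold = 2.5,
                             peak_sep = 10) {
  stopifnot(inherits(probs, "cp_probs"))
  y <- as.numeric(trait)
  ok <- !is.na(y)
  if (sum(ok) < 10) stop_input("too few phenotyped progeny")
  yv <- y[ok]
  n <- length(yv)
  rss0 <- sum((yv - mean(yv))^2)
  curve <- list()
  for (nm in names(probs$groups)) {
    gp <- probs$groups[[nm]]
    lod <- numeric(length(gp$grid))
    for (t in seq_along(gp$grid)) {
      X <- class_probs(gp$pm[t, ok], gp$pp[t, ok])[, 1:3, drop = FALSE]
      fit <- lm.fit(cbind(1, X), yv)
      rss1 <- sum(fit$residuals^2)
      lod[t] <- n / 2 * log10(rss0 / max(rss1, 1e-300))
    }
    curve[[nm]] <- data.frame(lg = nm, cM = gp$grid, lod = lod)
  }
  curve <- do.call(rbind, c(curve, make.row.names = FALSE))
  peaks <- find_peaks(curve, lod_threshold, peak_sep, rss0_n = c(rss0, n))
  structure(list(curve = curve, peaks = peaks, n = n,
                 threshold = lod_threshold), class = "qtl_scan")
}

find_peaks <- function(curve, threshold, peak_sep, rss0_n) {
  peaks <- list()
  for (nm in unique(curve$lg)) {
    sub <- curve[curve$lg == nm, ]
    nloc <- nrow(sub)
    is_max <- sub$lod >= c(-Inf, sub$lod[-nloc]) &
      sub$lod >= c(sub$lod[-1], -Inf)
    cand <- order(-sub$lod)
    cand <- cand[is_max[cand]]
    kept <- integer()
    for (i in cand) {
      if (sub$lod[i] < threshold) break
      if (!length(kept) || all(abs(sub$cM[kept] - sub$cM[i]) >= peak_sep))
        kept <- c(kept, i)
    }
    for (i in kept) {
      ci <- lapply(c(1, 2), function(drop) {
        lim <- sub$lod[i] - drop
        lo <- i; while (lo > 1 && sub$lod[lo - 1] >= lim) lo <- lo - 1
        hi <- i; while (hi < nrow(sub) && sub$lod[hi + 1] >= lim) hi <- hi + 1
        c(sub$cM[lo], sub$cM[hi])
      })
      pve <- 100 * (1 - 10^(-2 * sub$lod[i] / rss0_n[2]))
      peaks[[length(peaks) + 1L]] <- data.frame(
        lg = nm, cM = sub$cM[i], lod = sub$lod[i], pve = pve,
        ci1_lo = ci[[1]][1], ci1_hi = ci[[1]][2],
        ci2_lo = ci[[2]][1], ci2_hi = ci[[2]][2])
    }
  }
  if (!length(peaks))
    return(data.frame(lg = character(), cM = numeric(), lod = numeric(),
                      pve = numeric(), ci1_lo = numeric(), ci1_hi = numeric(),
                      ci2_lo = numeric(), ci2_hi = numeric()))
  do.call(rbind, c(peaks, make.row.names = FALSE))
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("QTL scan over", length(unique(x$curve$lg)), "linkage groups,",
      nrow(x$curve), "positions; threshold LOD", x$threshold, "\n")
  if (nrow(x$peaks)) print(x$peaks, digits = 3) else cat("  no peaks\n")
  invisible(x)
}

#' @export
plot.qtl_scan <- function(x, ...) {
  lgs <- unique(x$curve$lg)
  off <- 0; at <- numeric(); labs <- character()
  graphics::plot(NA, xlim = c(0, sum(tapply(x$curve$cM, x$curve$lg, max)) +
                                5 * length(lgs)),
                 ylim = c(0, max(x$curve$lod, x$threshold) * 1.05),
                 xlab = "", ylab = "LOD", ...)
  for (nm in lgs) {
    sub <- x$curve[x$curve$lg == nm, ]
    graphics::lines(off + sub$cM, sub$lod)
    at <- c(at, off + max(sub$cM) / 2); labs <- c(labs, nm)
    off <- off + max(sub$cM) + 5
  }
  graphics::axis(1, at = at, labels = labs, tick = FALSE)
  graphics::abline(h = x$threshold, lty = 2, col = 2)
  invisible(x)
}

#' Kruskal-Wallis marker-trait association scan
#'
#' A tie-corrected Kruskal-Wallis test of the trait over each marker's
#' genotype classes; markers with fewer than two classes holding at least
#' two observations are skipped.
#'
#' @param trait numeric values in progeny order.
#' @param bins a `cp_geno` object.
#' @param alpha significance level on P (the conventional stringent
#'   threshold for this scan is 0.005).
#' @param map optional `genetic_map` used to annotate lg / cM.
#' @return data frame (id, H, df, P, significant, and lg/cM when a map is
#'   given) of class `kw_scan`.
#' @export
kw_scan <- function(trait, bins, alpha = 0.005, map = NULL) {
  stopifnot(inherits(bins, "cp_geno"))
  y <- as.numeric(trait)
  m <- nrow(bins$codes)
  H <- rep(NA_real_, m); df <- rep(NA_integer_, m); P <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    cls <- bins$codes[i, ]
    ok <- !is.na(y) & !is.na(cls)
    tb <- table(cls[ok])
    tb <- tb[tb >= 2]
    if (length(tb) < 2) next
    use <- ok & cls %in% as.integer(names(tb))
    if (sd(y[use]) < .Machine$double.eps) { # all values equal
      H[i] <- 0; df[i] <- length(tb) - 1L; P[i] <- 1
      next
    }
    kt <- kruskal.test(y[use], factor(cls[use]))
    H[i] <- unname(kt$statistic); df[i] <- unname(kt$parameter)
    P[i] <- kt$p.value
  }
  out <- data.frame(id = bins$info$id, H = H, df = df, P = P,
                    significant = !is.na(P) & P < alpha)
  if (!is.null(map)) {
    pos <- do.call(rbind, lapply(names(map$groups), function(nm)
      data.frame(id = map$groups[[nm]]$id, lg = nm,
                 cM = map$groups[[nm]]$cM)))
    out <- merge(out, pos, by = "id", all.x = TRUE, sort = FALSE)
  }
  class(out) <- c("kw_scan", "data.frame")
  out
}

#' Match QTL peaks between two environments
#'
#' Peaks on the same linkage group closer than `tol_cM` (strict) are
#' matched by greedy nearest pairing.
#'
#' @param scan1,scan2 `qtl_scan` objects on the same map.
#' @param tol_cM strict matching tolerance in cM.
#' @return data frame of matched pairs (lg, cM_1, cM_2, delta_cM,
#'   lod_1, lod_2).
#' @export
qtl_stability <- function(scan1, scan2, tol_cM = 10) {
  p1 <- scan1$peaks; p2 <- scan2$peaks
  out <- list()
  for (nm in intersect(unique(p1$lg), unique(p2$lg))) {
    a <- p1[p1$lg == nm, ]; b <- p2[p2$lg == nm, ]
    cand <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    cand$delta <- abs(a$cM[cand$i] - b$cM[cand$j])
    cand <- cand[cand$delta < tol_cM, ]
    cand <- cand[order(cand$delta), ]
    used_i <- used_j <- integer()
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (i %in% used_i || j %in% used_j) next
      used_i <- c(used_i, i); used_j <- c(used_j, j)
      out[[length(out) + 1L]] <- data.frame(
        lg = nm, cM_1 = a$cM[i], cM_2 = b$cM[j], delta_cM = cand$delta[k],
        lod_1 = a$lod[i], lod_2 = b$lod[j])
    }
  }
  if (!length(out))
    return(data.frame(lg = character(), cM_1 = numeric(), cM_2 = numeric(),
                      delta_cM = numeric(), lod_1 = numeric(),
                      lod_2 = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Project QTL support intervals to physical coordinates
#'
#' Bins whose map position falls inside a peak's LOD-drop support
#' interval are mapped to their physical spans; overlapping spans are
#' merged per chromosome. With a gene annotation (data frame with chrom,
#' start, end, gene_id columns, e.g. from [read_gff3_genes()]), genes
#' intersecting the merged intervals are listed.
#'
#' @param scan a `qtl_scan`.
#' @param map the `genetic_map` the scan used.
#' @param bins the `cp_geno` bin markers (physical spans).
#' @param drop 1 or 2: which LOD-drop interval to project.
#' @param annotation optional gene table.
#' @return data frame of merged physical intervals per peak
#'   (peak, lg, peak_cM, chrom, start, end, n_bins[, genes]).
#' @export
qtl_to_physical <- function(scan, map, bins, drop = 1, annotation = NULL) {
  stopifnot(inherits(scan, "qtl_scan"), inherits(map, "genetic_map"))
  lo_col <- if (drop == 1) "ci1_lo" else "ci2_lo"
  hi_col <- if (drop == 1) "ci1_hi" else "ci2_hi"
  out <- list()
  pk <- scan$peaks
  for (k in seq_len(nrow(pk))) {
    g <- map$groups[[pk$lg[k]]]
    inside <- g$id[g$cM >= pk[[lo_col]][k] & g$cM <= pk[[hi_col]][k]]
    rows <- bins$info[match(inside, bins$info$id), ]
    rows <- rows[!is.na(rows$start) & !is.na(rows$chrom), ]
    if (!nrow(rows)) next
    for (ch in unique(rows$chrom)) {
      iv <- rows[rows$chrom == ch, c("start", "end")]
      iv <- iv[order(iv$start), , drop = FALSE]
      merged <- list(c(iv$start[1], iv$end[1]))
      nb <- 1L
      if (nrow(iv) > 1) for (q in 2:nrow(iv)) {
        last <- merged[[length(merged)]]
        if (iv$start[q] <= last[2] + 1) {
          merged[[length(merged)]][2] <- max(last[2], iv$end[q])
        } else merged[[length(merged) + 1L]] <- c(iv$start[q], iv$end[q])
      }
      for (mv in merged)
        out[[length(out) + 1L]] <- data.frame(
          peak = k, lg = pk$lg[k], peak_cM = pk$cM[k], chrom = ch,
          start = mv[1], end = mv[2], n_bins = nrow(iv))
    }
  }
  if (!length(out))
    return(data.frame(peak = integer(), lg = character(),
                      peak_cM = numeric(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_bins = integer()))
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (!is.null(annotation)) {
    res$genes <- vapply(seq_len(nrow(res)), function(i) {
      hit <- annotation$chrom == res$chrom[i] &
        annotation$end >= res$start[i] & annotation$start <= res$end[i]
      paste(annotation$gene_id[hit], collapse = ",")
    }, "")
  }
  res
}

#' Read gene features from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return data frame with chrom, start, end, strand, gene_id.
#' @export
read_gff3_genes <- function(path, feature = "gene") {
  if (!requireNamespace("ape", quietly = TRUE))
    stop_input("reading GFF3 requires the 'ape' package")
  g <- ape::read.gff(path)
  g <- g[g$type == feature, ]
  id <- sub(".*ID=([^;]+).*", "\\1", g$attributes)
  data.frame(chrom = as.character(g$seqid), start = g$start, end = g$end,
             strand = as.character(g$strand), gene_id = id,
             stringsAsFactors = FALSE)
}
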