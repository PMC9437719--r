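# Two-point recombination-fraction estimation for CP (full-sib) marker
# pairs. Each parental meiosis is a latent two-state transmission; the
# joint two-locus genotype table is a mixture over the <=16 transmission
# configurations, with recombination fraction r shared by the meioses a
# pair can see. Tables of mixture coefficients are enumerated once per
# (type pair, phase configuration) and cached; EM then runs vectorized
# over many pairs at once.

mother_het_type <- function(t) t %in% c("lmxll", "hkxhk")
father_het_type <- function(t) t %in% c("nnxnp", "hkxhk")

code_of <- function(type, am, ap) {
  switch(type, lmxll = am, nnxnp = ap, hkxhk = am + ap)
}

rf_table_cache <- new.env(parent = emptyenv())

# coefficient tables C[c1, c2, k+1] with cell prob = sum_k C * r^k (1-r)^(j-k)
rf_tables <- function(t1, t2) {
  key <- paste(t1, t2, sep = "|")
  if (!is.null(rf_table_cache[[key]])) return(rf_table_cache[[key]])
  jm <- mother_het_type(t1) && mother_het_type(t2)
  jp <- father_het_type(t1) && father_het_type(t2)
  j <- jm + jp
  nc1 <- n_codes(t1); nc2 <- n_codes(t2)
  cfgs <- list()
  for (phm in (if (jm) 0:1 else 0)) for (php in (if (jp) 0:1 else 0)) {
    C <- array(0, c(nc1, nc2, j + 1))
    for (m1 in 0:1) for (m2 in 0:1) for (p1 in 0:1) for (p2 in 0:1) {
      k <- (if (jm) as.integer(m1 != m2) else 0L) +
           (if (jp) as.integer(p1 != p2) else 0L)
      w <- (if (jm) 0.5 else 0.25) * (if (jp) 0.5 else 0.25)
      c1 <- code_of(t1, m1, p1)
      c2 <- code_of(t2, if (jm) bitwXor(m2, phm) else m2,
                        if (jp) bitwXor(p2, php) else p2)
      C[c1 + 1, c2 + 1, k + 1] <- C[c1 + 1, c2 + 1, k + 1] + w
    }
    cfgs[[length(cfgs) + 1L]] <- list(
      A = matrix(C, nc1 * nc2, j + 1), j = j,
      phase_m = if (jm) phm else NA_integer_,
      phase_p = if (jp) php else NA_integer_)
  }
  out <- list(cfgs = cfgs, j = j, nc1 = nc1, nc2 = nc2)
  rf_table_cache[[key]] <- out
  out
}

# counts: npairs x (nc1*nc2) cell-count matrix, cell index = c1 + nc1*c2
# returns r, lod, loglik, phase indices; r is NA where j == 0
em_rf_batch <- function(counts, tabs, maxit = 200, tol = 1e-10) {
  np <- nrow(counts)
  N <- rowSums(counts)
  j <- tabs$j
  if (j == 0)
    return(list(r = rep(NA_real_, np), lod = rep(0, np),
                phase_m = rep(NA_integer_, np), phase_p = rep(NA_integer_, np)))
  kvec <- 0:j
  basis <- function(r) {
    B <- vapply(kvec, function(k) r^k * (1 - r)^(j - k), numeric(length(r)))
    matrix(B, ncol = j + 1)
  }
  best_ll <- rep(-Inf, np); best_r <- rep(NA_real_, np)
  best_pm <- rep(NA_integer_, np); best_pp <- rep(NA_integer_, np)
  ll0 <- NULL
  for (cfg in tabs$cfgs) {
    A <- cfg$A
    r <- rep(0.25, np)
    for (it in seq_len(maxit)) {
      B <- basis(r)
      cellp <- B %*% t(A)
      Ek <- (B %*% t(A * rep(kvec, each = nrow(A)))) / pmax(cellp, 1e-300)
      rn <- rowSums(counts * Ek) / pmax(j * N, 1)
      rn <- pmin(pmax(rn, 1e-9), 0.5)
      dif <- max(abs(rn - r))
      r <- rn
      if (dif < tol) break
    }
    cellp <- basis(r) %*% t(A)
    ll <- rowSums(counts * log(pmax(cellp, 1e-300)))
    if (is.null(ll0)) {
      cp0 <- basis(rep(0.5, np)) %*% t(A) # phase-independent at r = 0.5
      ll0 <- rowSums(counts * log(pmax(cp0, 1e-300)))
    }
    upd <- ll > best_ll + 1e-12
    best_ll[upd] <- ll[upd]; best_r[upd] <- r[upd]
    best_pm[upd] <- cfg$phase_m; best_pp[upd] <- cfg$phase_p
  }
  list(r = best_r, lod = pmax((best_ll - ll0) / log(10), 0),
       phase_m = best_pm, phase_p = best_pp)
}

# likelihood-ratio independence statistic, LOD-scaled (G^2 / (2 ln 10))
ind_lod_batch <- function(counts, nc1, nc2) {
  N <- rowSums(counts)
  idx1 <- rep(seq_len(nc1), nc2); idx2 <- rep(seq_len(nc2), each = nc1)
  R <- vapply(seq_len(nc1), function(a)
    rowSums(counts[, idx1 == a, drop = FALSE]), numeric(nrow(counts)))
  Cc <- vapply(seq_len(nc2), function(b)
    rowSums(counts[, idx2 == b, drop = FALSE]), numeric(nrow(counts)))
  R <- matrix(R, ncol = nc1); Cc <- matrix(Cc, ncol = nc2)
  E <- R[, idx1, drop = FALSE] * Cc[, idx2, drop = FALSE] / pmax(N, 1)
  term <- counts * log(counts / pmax(E, 1e-300))
  term[counts == 0] <- 0
  G2 <- 2 * rowSums(term)
  pmax(G2, 0) / (2 * log(10))
}

code_indicators <- function(codes, seg_types) {
  # list over code values 0..2 of n x p indicator matrices (NA -> 0)
  lapply(0:2, function(cd) {
    M <- t(codes) == cd
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
}

pair_counts <- function(ind, i1, i2, nc1, nc2) {
  # npairs x (nc1*nc2) counts, pair index column-major over (i1, i2)
  cols <- matrix(0, length(i1) * length(i2), nc1 * nc2)
  for (b in seq_len(nc2) - 1L) for (a in seq_len(nc1) - 1L) {
    Nab <- crossprod(ind[[a + 1L]][, i1, drop = FALSE],
                     ind[[b + 1L]][, i2, drop = FALSE])
    cols[, a + nc1 * b + 1L] <- as.vector(Nab)
  }
  cols
}

#' Pairwise recombination-fraction estimation over a marker set
#'
#' Estimates r, linkage LOD, independence LOD and phase for every marker
#' pair by maximum likelihood over the CP two-locus class probabilities
#' (EM, maximized over admissible phase configurations). Marker pairs
#' sharing no informative meiosis (lmxll x nnxnp) have inestimable r and,
#' their meioses being independent, an independence LOD near zero.
#'
#' @param geno a `cp_geno` (or `cp_sites`) object.
#' @param markers optional character vector restricting to these marker ids.
#' @param min_joint minimum jointly non-missing progeny for an estimate to
#'   be usable (below it, `r`, `lod` and `ind_lod` are set NA).
#' @return an object of class `rf_matrix`: list of p x p matrices `r`,
#'   `lod`, `ind_lod`, `n_joint`, `phase_m`, `phase_p` plus `info` rows for
#'   the markers used.
#' @export
rf_matrix <- function(geno, markers = NULL, min_joint = 20) {
  info <- geno$info
  sel <- if (is.null(markers)) seq_len(nrow(info)) else match(markers, info$id)
  if (anyNA(sel)) stop_input("unknown marker ids")
  info <- info[sel, , drop = FALSE]
  codes <- geno$codes[sel, , drop = FALSE]
  p <- nrow(codes)
  ids <- info$id
  mk_mat <- function() matrix(NA_real_, p, p, dimnames = list(ids, ids))
  out <- list(r = mk_mat(), lod = mk_mat(), ind_lod = mk_mat(),
              n_joint = mk_mat(), phase_m = mk_mat(), phase_p = mk_mat())
  ind <- code_indicators(codes, info$seg_type)
  types <- info$seg_type
  type_sets <- split(seq_len(p), types)
  tn <- names(type_sets)
  for (u in seq_along(tn)) for (v in u:length(tn)) {
    t1 <- tn[u]; t2 <- tn[v]
    i1 <- type_sets[[u]]; i2 <- type_sets[[v]]
    tabs <- rf_tables(t1, t2)
    counts <- pair_counts(ind, i1, i2, tabs$nc1, tabs$nc2)
    est <- em_rf_batch(counts, tabs)
    il <- ind_lod_batch(counts, tabs$nc1, tabs$nc2)
    N <- rowSums(counts)
    low <- N < min_joint
    est$r[low] <- NA; est$lod[low] <- NA; il[low] <- NA
    dimv <- c(length(i1), length(i2))
    out$r[i1, i2] <- est$r; out$r[i2, i1] <- t(matrix(est$r, dimv[1]))
    out$lod[i1, i2] <- est$lod; out$lod[i2, i1] <- t(matrix(est$lod, dimv[1]))
    out$ind_lod[i1, i2] <- il; out$ind_lod[i2, i1] <- t(matrix(il, dimv[1]))
    out$n_joint[i1, i2] <- N; out$n_joint[i2, i1] <- t(matrix(N, dimv[1]))
    out$phase_m[i1, i2] <- est$phase_m
    out$phase_m[i2, i1] <- t(matrix(est$phase_m, dimv[1]))
    out$phase_p[i1, i2] <- est$phase_p
    out$phase_p[i2, i1] <- t(matrix(est$phase_p, dimv[1]))
  }
  diag(out$r) <- NA; diag(out$lod) <- NA; diag(out$ind_lod) <- NA
  out$info <- info
  class(out) <- "rf_matrix"
  out
}

#' Two-point recombination fraction for one marker pair
#'
#' @param geno a `cp_geno`/`cp_sites` object.
#' @param m1,m2 marker ids (or row indices).
#' @param min_joint minimum jointly non-missing progeny; below it the
#'   estimate is flagged unusable.
#' @return an object of class `rf_estimate` with elements `r`, `lod`,
#'   `ind_lod`, `n_joint`, `phase` (named "coupling"/"repulsion" per
#'   heterozygous parent, NA where a parent carries no joint information)
#'   and `usable`.
#' @export
estimate_rf <- function(geno, m1, m2, min_joint = 20) {
  info <- geno$info
  i1 <- if (is.character(m1)) match(m1, info$id) else m1
  i2 <- if (is.character(m2)) match(m2, info$id) else m2
  if (anyNA(c(i1, i2))) stop_input("unknown marker id")
  t1 <- info$seg_type[i1]; t2 <- info$seg_type[i2]
  x <- geno$codes[i1, ]; y <- geno$codes[i2, ]
  ok <- !is.na(x) & !is.na(y)
  tabs <- rf_tables(t1, t2)
  counts <- matrix(0, 1, tabs$nc1 * tabs$nc2)
  if (any(ok)) {
    tb <- tabulate(1L + x[ok] + tabs$nc1 * y[ok], nbins = ncol(counts))
    counts[1, ] <- tb
  }
  est <- em_rf_batch(counts, tabs)
  il <- ind_lod_batch(counts, tabs$nc1, tabs$nc2)
  phase_lab <- function(ph) if (is.na(ph)) NA_character_ else
    c("coupling", "repulsion")[ph + 1L]
  structure(list(
    r = est$r[1], lod = est$lod[1], ind_lod = il[1], n_joint = sum(ok),
    phase = c(maternal = phase_lab(est$phase_m[1]),
              paternal = phase_lab(est$phase_p[1])),
    usable = sum(ok) >= min_joint && !is.na(est$r[1]),
    markers = c(info$id[i1], info$id[i2]),
    types = c(t1, t2)), class = "rf_estimate")
}

#' @export
print.rf_estimate <- function(x, ...) {
  cat(sprintf("rf %s (%s) x %s (%s): r = %s, LOD = %.2f, ind LOD = %.2f, n = %d%s\n",
              x$markers[1], x$types[1], x$markers[2], x$types[2],
              ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)),
              x$lod, x$ind_lod, x$n_joint,
              if (x$usable) "" else " [unusable]"))
  invisible(x)
}

#' Plot a pairwise recombination-fraction heat map
#'
#' Markers are shown in the given order (typically final map order); low
#' recombination fractions concentrate on the diagonal blocks of a sound
#' map.
#'
#' @param rfm an `rf_matrix` object.
#' @param order optional character vector of marker ids giving plot order.
#' @param ... passed to [graphics::image()].
#' @export
plot_rf_heatmap <- function(rfm, order = NULL, ...) {
  stopifnot(inherits(rfm, "rf_matrix"))
  M <- rfm$r
  if (!is.null(order)) M <- M[order, order]
  p <- nrow(M)
  graphics::image(seq_len(p), seq_len(p), t(M[p:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "marker index", ylab = "marker index",
                  main = "pairwise recombination fraction", ...)
  invisible(M)
}
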