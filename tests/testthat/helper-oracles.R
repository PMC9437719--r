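# Independent brute-force implementations used as oracles. These are
# deliberately naive (plain loops, no shared code with the package
# internals beyond the rule statements).

# five-step bin construction on a raw code matrix (sites x progeny)
oracle_bin <- function(codes, pos, seg_type, window_bp = 500000,
                       k_side = 2) {
  nc <- if (seg_type == "hkxhk") 3L else 2L
  win <- (pos - 1) %/% window_bp
  uw <- sort(unique(win))
  # (i) majority vote per window and progeny
  wmat <- matrix(NA_integer_, length(uw), ncol(codes))
  span <- matrix(NA_integer_, length(uw), 2)
  nsnp <- integer(length(uw))
  for (w in seq_along(uw)) {
    rows <- which(win == uw[w])
    span[w, ] <- range(pos[rows]); nsnp[w] <- length(rows)
    for (j in seq_len(ncol(codes))) {
      v <- codes[rows, j]; v <- v[!is.na(v)]
      if (!length(v)) next
      cnt <- sapply(0:(nc - 1), function(cd) sum(v == cd))
      if (sum(cnt == max(cnt)) == 1) wmat[w, j] <- which.max(cnt) - 1L
    }
  }
  m <- nrow(wmat)
  # (ii) fill missing from <=k_side nearest non-missing calls per side
  out <- wmat
  for (j in seq_len(ncol(wmat))) for (w in seq_len(m)) {
    if (!is.na(wmat[w, j])) next
    below <- wmat[seq_len(w - 1), j]; below <- rev(below[!is.na(below)])
    above <- wmat[setdiff(seq_len(m), seq_len(w)), j]
    above <- above[!is.na(above)]
    nb <- c(below[seq_len(min(k_side, length(below)))],
            above[seq_len(min(k_side, length(above)))])
    nb <- nb[!is.na(nb)]
    if (!length(nb)) next
    cnt <- sapply(0:(nc - 1), function(cd) sum(nb == cd))
    if (sum(cnt == max(cnt)) == 1 && max(cnt) > length(nb) / 2)
      out[w, j] <- which.max(cnt) - 1L
  }
  wmat <- out
  # (iii) fill missing runs with identical non-missing flanks
  for (j in seq_len(ncol(wmat))) {
    w <- 1
    while (w <= m) {
      if (is.na(wmat[w, j])) {
        e <- w
        while (e < m && is.na(wmat[e + 1, j])) e <- e + 1
        if (w > 1 && e < m && !is.na(wmat[w - 1, j]) &&
            !is.na(wmat[e + 1, j]) && wmat[w - 1, j] == wmat[e + 1, j])
          wmat[w:e, j] <- wmat[w - 1, j]
        w <- e + 1
      } else w <- w + 1
    }
  }
  # (iv) replace singletons flanked by identical non-missing calls
  if (m > 2) {
    fixed <- wmat
    for (j in seq_len(ncol(wmat))) for (w in 2:(m - 1)) {
      a <- wmat[w - 1, j]; b <- wmat[w + 1, j]
      if (!is.na(wmat[w, j]) && !is.na(a) && !is.na(b) && a == b &&
          wmat[w, j] != a)
        fixed[w, j] <- a
    }
    wmat <- fixed
  }
  # (v) merge adjacent identical rows (missing matches missing)
  groups <- list(1L)
  if (m > 1) for (w in 2:m) {
    prev <- wmat[w - 1, ]; cur <- wmat[w, ]
    same <- all(ifelse(is.na(prev) & is.na(cur), TRUE,
                       ifelse(is.na(prev) != is.na(cur), FALSE,
                              prev == cur)))
    if (isTRUE(same)) groups[[length(groups)]] <- c(groups[[length(groups)]], w)
    else groups[[length(groups) + 1L]] <- w
  }
  list(codes = do.call(rbind, lapply(groups, function(g) wmat[g[1], ])),
       start = sapply(groups, function(g) min(span[g, 1])),
       end = sapply(groups, function(g) max(span[g, 2])),
       snp_count = sapply(groups, function(g) sum(nsnp[g])))
}

# exhaustive best order of <= 7 markers under the package's fitted-gap
# least-squares objective
oracle_best_order <- function(D, W) {
  m <- nrow(D)
  perms <- gtools_permutations(m)
  objs <- apply(perms, 1, function(p) sibmap:::order_objective(p, D, W))
  list(order = perms[which.min(objs), ], obj = min(objs))
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))
  }))
}
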