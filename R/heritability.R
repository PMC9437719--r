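#' Narrow-sense heritability from a genomic relationship matrix
#'
#' Codes each marker's maternal- and paternal-allele transmissions as
#' indicator columns (lmxll informs the maternal column, nnxnp the
#' paternal; hkxhk informs both, with the ambiguous hk class at its
#' expectation 0.5), centers them, and forms the genomic relationship
#' matrix G scaled to mean diagonal 1. Variance components of
#' `y = mu + g + e`, `g ~ N(0, sigma_g^2 G)`, are estimated by REML via
#' the spectral decomposition of G and a one-dimensional likelihood
#' search over the variance ratio; the narrow-sense heritability is
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
#'
#' @param bins a `cp_geno` object (at least 50 markers).
#' @param trait numeric values in progeny order (at least 50 phenotyped
#'   progeny).
#' @param ridge added to G's diagonal if it is numerically singular
#'   (applied with a warning).
#' @return an object of class `heritability_fit` with `h2`, `sigma_g2`,
#'   `sigma_e2`, `loglik`, `n`, `n_markers`.
#' @export
heritability <- function(bins, trait, ridge = 1e-6) {
  stopifnot(inherits(bins, "cp_geno"))
  y <- as.numeric(trait)
  ok <- !is.na(y)
  if (sum(ok) < 50) stop_input("heritability needs at least 50 phenotyped progeny")
  if (nrow(bins$codes) < 50) stop_input("heritability needs at least 50 markers")
  G <- grm_cp(bins)[ok, ok]
  y <- y[ok]
  n <- length(y)
  ev <- eigen(G, symmetric = TRUE)
  # rank deficiency is routine (2p haplotype indicators, p < n); only an
  # indefinite matrix needs regularization
  if (min(ev$values) < -1e-6 * max(ev$values)) {
    warning("relationship matrix numerically indefinite; ridge added")
    G <- G + diag(ridge * mean(diag(G)), n)
    ev <- eigen(G, symmetric = TRUE)
  }
  d <- pmax(ev$values, 0)
  ys <- crossprod(ev$vectors, y)
  xs <- crossprod(ev$vectors, rep(1, n))
  reml_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    w <- lam * d + 1
    xtwx <- sum(xs^2 / w)
    beta <- sum(xs * ys / w) / xtwx
    rs <- ys - xs * beta
    s2 <- sum(rs^2 / w) / (n - 1)
    -0.5 * (sum(log(w)) + (n - 1) * log(s2) + log(xtwx))
  }
  opt <- optimize(reml_ll, interval = c(-12, 12), maximum = TRUE)
  lam <- exp(opt$maximum)
  w <- lam * d + 1
  beta <- sum(xs * ys / w) / sum(xs^2 / w)
  s2e <- sum((ys - xs * beta)^2 / w) / (n - 1)
  structure(list(h2 = lam / (1 + lam), sigma_g2 = lam * s2e, sigma_e2 = s2e,
                 loglik = opt$objective, n = n, n_markers = nrow(bins$codes)),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  cat(sprintf("h2 = %.3f (sigma_g2 = %.3f, sigma_e2 = %.3f; n = %d, %d markers)\n",
              x$h2, x$sigma_g2, x$sigma_e2, x$n, x$n_markers))
  invisible(x)
}

# genomic relationship matrix from CP-coded transmissions
grm_cp <- function(bins) {
  codes <- bins$codes
  seg <- bins$info$seg_type
  cols <- list()
  for (i in seq_len(nrow(codes))) {
    x <- codes[i, ]
    if (seg[i] == "lmxll") {
      cols[[length(cols) + 1L]] <- as.numeric(x)
    } else if (seg[i] == "nnxnp") {
      cols[[length(cols) + 1L]] <- as.numeric(x)
    } else {
      cols[[length(cols) + 1L]] <- x / 2       # maternal k-dose expectation
      cols[[length(cols) + 1L]] <- x / 2       # paternal k-dose expectation
    }
  }
  Z <- do.call(cbind, cols)
  for (j in seq_len(ncol(Z))) {
    mj <- mean(Z[, j], na.rm = TRUE)
    Z[is.na(Z[, j]), j] <- mj
    Z[, j] <- Z[, j] - mj
  }
  K <- tcrossprod(Z)
  K / mean(diag(K))
}
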