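adj_skewness <- function(x) {
  x <- x[!is.na(x)]; n <- length(x)
  z <- (x - mean(x)) / sd(x)
  n / ((n - 1) * (n - 2)) * sum(z^3)
}

adj_kurtosis <- function(x) {
  x <- x[!is.na(x)]; n <- length(x)
  z <- (x - mean(x)) / sd(x)
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Descriptive statistics and normality assessment for one trait
#'
#' Computes the usual moments with the small-sample adjusted (SPSS-style)
#' skewness and kurtosis estimators, the Shapiro-Wilk normality test, and
#' -- when a paired measurement of the same trait from another
#' environment/year is supplied -- the Pearson correlation on
#' pairwise-complete observations and a one-way ANOVA between the two
#' environments.
#'
#' @param values numeric trait values per progeny (missing allowed).
#' @param paired optional second vector (same progeny order).
#' @param name trait name.
#' @param environment environment/year label.
#' @return an object of class `trait_stats`.
#' @export
trait_stats <- function(values, paired = NULL, name = "trait",
                        environment = NA) {
  x <- as.numeric(values)
  n <- sum(!is.na(x))
  if (n < 3) stop_input("need at least 3 non-missing values")
  constant <- sd(x, na.rm = TRUE) < .Machine$double.eps
  sh <- if (constant) list(statistic = NA_real_, p.value = NA_real_)
        else shapiro.test(x[!is.na(x)])
  out <- list(
    name = name, environment = environment, n = n,
    mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
    min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
    skewness = if (constant) NA_real_ else adj_skewness(x),
    kurtosis = if (constant) NA_real_ else adj_kurtosis(x),
    shapiro_W = unname(sh$statistic), shapiro_P = sh$p.value,
    normal = !constant && sh$p.value > 0.05,
    constant = constant)
  if (!is.null(paired)) {
    y <- as.numeric(paired)
    ok <- !is.na(x) & !is.na(y)
    ct <- cor.test(x[ok], y[ok])
    stacked <- data.frame(v = c(x, y),
                          env = rep(c("a", "b"), c(length(x), length(y))))
    ow <- oneway.test(v ~ env, data = stacked[!is.na(stacked$v), ],
                      var.equal = TRUE)
    out$pearson_r <- unname(ct$estimate); out$pearson_P <- ct$p.value
    out$anova_F <- unname(ow$statistic); out$anova_P <- ow$p.value
  }
  class(out) <- "trait_stats"
  out
}

#' @export
print.trait_stats <- function(x, ...) {
  cat(sprintf("%s%s: n=%d mean=%.3f sd=%.3f skew=%.2f kurt=%.2f Shapiro P=%.3g (%s)\n",
              x$name, if (is.na(x$environment)) "" else paste0(" [", x$environment, "]"),
              x$n, x$mean, x$sd, x$skewness, x$kurtosis, x$shapiro_P,
              if (isTRUE(x$normal)) "normal" else "non-normal"))
  if (!is.null(x$pearson_r))
    cat(sprintf("  vs paired: Pearson r=%.2f (P=%.3g), ANOVA F=%.2f (P=%.3g)\n",
                x$pearson_r, x$pearson_P, x$anova_F, x$anova_P))
  invisible(x)
}

#' Normalizing transformations for trait values
#'
#' `ln`, `sqrt` and `curt` (signed cube root) transforms, plus a Tukey
#' ladder-of-powers search over lambda in \{-2, -1, -0.5, 0, 0.5, 1, 2\}
#' choosing the lambda that maximizes the Shapiro-Wilk W. Where `ln` (or a
#' non-positive lambda) requires positive support, values are shifted by
#' `|min| + epsilon`; the shift and selected lambda are recorded as
#' attributes.
#'
#' @param values numeric vector.
#' @param method one of `"none"`, `"ln"`, `"sqrt"`, `"curt"`, `"tukey"`.
#' @param epsilon positivity margin used when shifting.
#' @return transformed values with attributes `method`, `shift` and (for
#'   tukey) `lambda`.
#' @export
transform_trait <- function(values, method = c("none", "ln", "sqrt", "curt",
                                               "tukey"),
                            epsilon = 1e-6) {
  method <- match.arg(method)
  x <- as.numeric(values)
  if (all(is.na(x))) stop_input("all values missing")
  shift_to <- function(x, lower) {
    mn <- min(x, na.rm = TRUE)
    s <- if (mn < lower) abs(mn) + epsilon else 0
    list(x = x + s, shift = s)
  }
  ladder <- function(x, lam) {
    if (lam == 0) log(x) else if (lam > 0) x^lam else -(x^lam)
  }
  out <- switch(method,
    none = list(x = x, shift = 0),
    ln = { s <- shift_to(x, epsilon); s$x <- log(s$x); s },
    sqrt = { s <- shift_to(x, 0); s$x <- sqrt(s$x); s },
    curt = list(x = sign(x) * abs(x)^(1 / 3), shift = 0),
    tukey = {
      s <- shift_to(x, epsilon)
      lams <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
      W <- vapply(lams, function(l) {
        z <- ladder(s$x, l)
        z <- z[is.finite(z)]
        if (length(unique(z)) < 3) return(-Inf)
        tryCatch(shapiro.test(z)$statistic, error = function(e) -Inf)
      }, 0)
      lam <- lams[which.max(W)]
      s$x <- ladder(s$x, lam)
      s$lambda <- lam
      s
    })
  structure(out$x, method = method, shift = out$shift,
            lambda = out$lambda %||% NULL,
            names = names(values))
}
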