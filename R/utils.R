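#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov chisq.test cmdscale cor cor.test dnbinom ecdf isoreg
#'   kruskal.test lm.fit median optimize oneway.test pchisq pf pnorm
#'   quantile rbinom rnbinom rnorm runif sd setNames shapiro.test var
#' @importFrom utils head read.table tail write.table
NULL

SEG_TYPES <- c("lmxll", "nnxnp", "hkxhk")

# CP genotype symbols, indexed by integer code + 1 within each segregation set
CP_SYMBOLS <- list(
  lmxll = c("ll", "lm"),
  nnxnp = c("nn", "np"),
  hkxhk = c("hh", "hk", "kk")
)
MISSING_SYMBOL <- "--"

n_codes <- function(seg_type) {
  if (seg_type == "hkxhk") 3L else 2L
}

cp_decode <- function(codes, seg_type) {
  sym <- CP_SYMBOLS[[seg_type]]
  out <- sym[codes + 1L]
  out[is.na(codes)] <- MISSING_SYMBOL
  out
}

cp_encode <- function(symbols, seg_type) {
  sym <- CP_SYMBOLS[[seg_type]]
  out <- match(symbols, sym) - 1L
  out
}

# deterministic per-stage seed derived from a master seed; kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

subset_geno <- function(geno, ids) {
  sel <- match(ids, geno$info$id)
  if (anyNA(sel)) stop_input("unknown marker ids")
  out <- list(codes = geno$codes[sel, , drop = FALSE],
              info = geno$info[sel, , drop = FALSE],
              progeny = geno$progeny)
  class(out) <- class(geno)
  out
}
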