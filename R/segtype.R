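#' Mask low-confidence genotype calls by read support
#'
#' Progeny calls whose supporting read count is below `min_support` or
#' above `max_support` are set to missing; the bounds themselves are
#' retained (a call supported by exactly 4 or exactly 200 reads passes).
#'
#' @param snp a `snp_data` object.
#' @param min_support,max_support inclusive retention bounds on per-call
#'   read support.
#' @return the `snp_data` object with masked calls; the number of masked
#'   calls is recorded in `attr(, "n_masked")`.
#' @export
mask_low_confidence <- function(snp, min_support = 4, max_support = 200) {
  stopifnot(inherits(snp, "snp_data"))
  if (any(snp$support < 0, na.rm = TRUE))
    stop_input("negative read support")
  bad <- !is.na(snp$support) &
    (snp$support < min_support | snp$support > max_support)
  n_masked <- sum(bad & !is.na(snp$geno))
  snp$geno[bad] <- NA_integer_
  attr(snp, "n_masked") <- n_masked
  snp
}

#' Classify sites into CP segregation types and recode progeny calls
#'
#' From the two parental genotypes each bi-allelic site is typed as
#' lmxll (maternal parent heterozygous, paternal homozygous; progeny
#' segregate lm:ll = 1:1), nnxnp (paternal heterozygous; nn:np = 1:1),
#' hkxhk (both heterozygous; hh:hk:kk = 1:2:1) or uninformative (both
#' homozygous). Progeny calls are recoded to CP symbols; calls impossible
#' under the parental genotypes (e.g. the opposite homozygote under
#' het x hom) are set missing and counted per site. Sites with a missing
#' parental call are flagged unclassifiable.
#'
#' @param snp a `snp_data` object (maternal parent in row 1 of
#'   `parent_gt` by default).
#' @param swap_parents treat the second sample as the maternal parent.
#' @return an object of class `cp_sites`: `info` data frame (adds
#'   `seg_type`, `n_impossible`), `codes` integer matrix (0-based code
#'   within each segregation set; see `CP` symbols ll/lm, nn/np, hh/hk/kk)
#'   and `progeny`.
#' @export
classify_segregation <- function(snp, swap_parents = FALSE) {
  stopifnot(inherits(snp, "snp_data"))
  gm <- snp$parent_gt[if (swap_parents) 2L else 1L, ]
  gp <- snp$parent_gt[if (swap_parents) 1L else 2L, ]
  m_het <- gm == 1L; p_het <- gp == 1L
  seg <- rep("uninformative", length(gm))
  seg[which(m_het & !p_het)] <- "lmxll"
  seg[which(!m_het & p_het)] <- "nnxnp"
  seg[which(m_het & p_het)] <- "hkxhk"
  seg[is.na(gm) | is.na(gp)] <- "unclassifiable"
  seg[!snp$info$biallelic] <- "multiallelic"

  g <- snp$geno
  codes <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  n_imp <- integer(nrow(g))
  lm_i <- which(seg == "lmxll"); nn_i <- which(seg == "nnxnp")
  hk_i <- which(seg == "hkxhk")
  if (length(lm_i)) {
    hom <- gp[lm_i] # 0 or 2; het progeny -> lm (1), parental homozygote -> ll (0)
    sub <- g[lm_i, , drop = FALSE]
    imp <- sub == (2L - hom) & sub != 1L
    out <- ifelse(sub == 1L, 1L, ifelse(sub == hom, 0L, NA_integer_))
    out[which(imp)] <- NA_integer_
    codes[lm_i, ] <- out
    n_imp[lm_i] <- rowSums(imp, na.rm = TRUE)
  }
  if (length(nn_i)) {
    hom <- gm[nn_i]
    sub <- g[nn_i, , drop = FALSE]
    imp <- sub == (2L - hom) & sub != 1L
    out <- ifelse(sub == 1L, 1L, ifelse(sub == hom, 0L, NA_integer_))
    out[which(imp)] <- NA_integer_
    codes[nn_i, ] <- out
    n_imp[nn_i] <- rowSums(imp, na.rm = TRUE)
  }
  if (length(hk_i)) codes[hk_i, ] <- g[hk_i, , drop = FALSE]

  info <- snp$info
  info$seg_type <- seg
  info$n_impossible <- n_imp
  structure(list(info = info, codes = codes, progeny = snp$progeny),
            class = "cp_sites")
}

#' @export
print.cp_sites <- function(x, ...) {
  cat("CP-typed sites:", nrow(x$codes), "sites x", length(x$progeny), "progeny\n")
  print(table(x$info$seg_type))
  invisible(x)
}

#' Chi-square test of Mendelian segregation per site
#'
#' Pearson chi-square of the observed CP genotype counts against 1:1
#' (lmxll, nnxnp; df = 1) or 1:2:1 (hkxhk; df = 2), missing calls
#' excluded; the p-value is the upper tail of the chi-square distribution.
#' Sites that are uninformative or have zero non-missing calls get NA and
#' are flagged.
#'
#' @param cp a `cp_sites` object.
#' @return the `cp_sites` object with `chi2`, `df`, `pvalue` columns added
#'   to `info`.
#' @export
segregation_chi2 <- function(cp) {
  stopifnot(inherits(cp, "cp_sites"))
  m <- nrow(cp$codes)
  chi2 <- rep(NA_real_, m); df <- rep(NA_integer_, m); pv <- rep(NA_real_, m)
  for (st in SEG_TYPES) {
    i <- which(cp$info$seg_type == st)
    if (!length(i)) next
    nc <- n_codes(st)
    counts <- vapply(seq_len(nc) - 1L, function(cd)
      rowSums(cp$codes[i, , drop = FALSE] == cd, na.rm = TRUE),
      numeric(length(i)))
    counts <- matrix(counts, ncol = nc)
    tot <- rowSums(counts)
    p_exp <- if (st == "hkxhk") c(1, 2, 1) / 4 else c(1, 1) / 2
    expd <- tot %o% p_exp
    x2 <- rowSums((counts - expd)^2 / expd)
    x2[tot == 0] <- NA_real_
    chi2[i] <- x2
    df[i] <- nc - 1L
    pv[i] <- pchisq(x2, df = nc - 1L, lower.tail = FALSE)
  }
  cp$info$chi2 <- chi2; cp$info$df <- df; cp$info$pvalue <- pv
  cp
}

#' Filter sites on bi-allelism, informativeness and segregation distortion
#'
#' Retains sites that are bi-allelic, informative (lmxll / nnxnp / hkxhk),
#' have an impossible-genotype rate at or below `impossible_max`, and show
#' no segregation distortion at `pvalue >= p_min` (strict `P < p_min`
#' rejection, so a site at exactly `p_min` is retained).
#'
#' @param cp a `cp_sites` object with chi-square results (computed here if
#'   absent).
#' @param p_min distortion threshold; sites with `P < p_min` are discarded.
#' @param require_biallelic reject multi-allelic sites.
#' @param impossible_max maximum tolerated fraction of impossible progeny
#'   calls per site.
#' @return list with `sites` (the retained `cp_sites`) and `log`, a data
#'   frame of rejected site ids and the first rule each one failed.
#' @export
filter_sites <- function(cp, p_min = 0.05, require_biallelic = TRUE,
                         impossible_max = 0.05) {
  stopifnot(inherits(cp, "cp_sites"))
  if (is.null(cp$info$pvalue)) cp <- segregation_chi2(cp)
  info <- cp$info
  n <- length(cp$progeny)
  reason <- rep(NA_character_, nrow(info))
  reason[is.na(reason) & require_biallelic & !info$biallelic] <- "multiallelic"
  reason[is.na(reason) & info$seg_type == "unclassifiable"] <- "missing_parent_call"
  reason[is.na(reason) & !info$seg_type %in% SEG_TYPES] <- "uninformative"
  reason[is.na(reason) & info$n_impossible / n > impossible_max] <- "impossible_rate"
  reason[is.na(reason) & is.na(info$pvalue)] <- "no_calls"
  reason[is.na(reason) & info$pvalue < p_min] <- "distorted_segregation"
  keep <- is.na(reason)
  out <- cp
  out$info <- info[keep, , drop = FALSE]
  out$codes <- cp$codes[keep, , drop = FALSE]
  list(sites = out,
       log = data.frame(id = info$id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

#' Export a CP genotype matrix and site metadata as TSV
#'
#' @param cp a `cp_sites` or binned `cp_geno` object.
#' @param geno_path,meta_path output paths (either may be `NULL` to skip).
#' @return invisibly, the symbol matrix written.
#' @export
write_cp_geno <- function(cp, geno_path = NULL, meta_path = NULL) {
  info <- cp$info
  sym <- matrix(MISSING_SYMBOL, nrow(cp$codes), ncol(cp$codes),
                dimnames = list(info$id, cp$progeny))
  for (st in intersect(unique(info$seg_type), SEG_TYPES)) {
    i <- info$seg_type == st
    sym[i, ] <- matrix(cp_decode(cp$codes[i, , drop = FALSE], st), sum(i))
  }
  if (!is.null(geno_path))
    write.table(data.frame(id = info$id, seg_type = info$seg_type, sym,
                           check.names = FALSE),
                geno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(info, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sym)
}
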