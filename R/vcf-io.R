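#' Write a simulated population as multi-sample VCF 4.2
#'
#' Emits parents (P1 = maternal, P2 = paternal) followed by the progeny,
#' with GT and DP fields; the simulation configuration and seed are echoed
#' into the header.
#'
#' @param pop a `sim_pop` object.
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(pop, path) {
  stopifnot(inherits(pop, "sim_pop"))
  cfg <- pop$cfg
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sibmap.simulate_population",
    sprintf("##sibmap_config=n_progeny=%d;n_chrom=%d;error_rate=%g;missing_rate=%g;map_function=%s;seed=%d",
            cfg$n_progeny, cfg$n_chrom, cfg$error_rate, cfg$missing_rate,
            cfg$map_function, cfg$seed),
    sprintf("##contig=<ID=%s,length=%d>",
            sprintf("chr%02d", seq_len(cfg$n_chrom)),
            as.integer(cfg$chrom_len_bp)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", pop$progeny), collapse = "\t"))
  gt_str <- function(g) c("0/0", "0/1", "1/1")[g + 1L]
  m <- nrow(pop$geno)
  parent_cells <- cbind(paste0(gt_str(pop$parent_gt[1, ]), ":99"),
                        paste0(gt_str(pop$parent_gt[2, ]), ":99"))
  prog <- matrix("./.", m, ncol(pop$geno))
  ok <- !is.na(pop$geno)
  prog[ok] <- gt_str(pop$geno[ok])
  prog <- matrix(paste0(prog, ":", pop$support), m)
  body <- paste(pop$info$chrom, pop$info$pos, pop$info$id, pop$info$ref,
                pop$info$alt, ".", "PASS", ".", "GT:DP",
                parent_cells[, 1], parent_cells[, 2],
                apply(prog, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into site data for segregation typing
#'
#' Uses `vcfR` to parse the file; genotypes are reduced to diploid dosage
#' codes (0 = hom ref, 1 = het, 2 = hom alt, NA = missing) and per-call
#' read support is taken from the DP format field when present.
#' Multi-allelic sites are retained here and rejected later by
#' [filter_sites()] unless `drop_multiallelic = TRUE`.
#'
#' @param path VCF file (plain or bgzipped).
#' @param parents names (or indices) of the two parental samples; defaults
#'   to the first two sample columns, maternal first.
#' @param drop_multiallelic drop non-bi-allelic sites on read.
#' @return an object of class `snp_data` with elements `info` (chrom, pos,
#'   id, ref, alt, biallelic), `parent_gt` (2 x sites), `geno`
#'   (sites x progeny), `support`, `progeny`.
#' @export
read_vcf <- function(path, parents = NULL, drop_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  fix <- vcfR::getFIX(v)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  code[clean %in% c("0/0")] <- 0L
  code[clean %in% c("0/1", "1/0")] <- 1L
  code[clean %in% c("1/1")] <- 2L
  samples <- colnames(gt)
  if (is.null(parents)) parents <- samples[1:2]
  if (is.numeric(parents)) parents <- samples[parents]
  if (!all(parents %in% samples)) stop_input("parent samples not found in VCF")
  prog <- setdiff(samples, parents)
  alt <- fix[, "ALT"]
  info <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    biallelic = !grepl(",", alt) & nchar(fix[, "REF"]) == 1 & nchar(alt) == 1,
    stringsAsFactors = FALSE)
  keep <- if (drop_multiallelic) info$biallelic else rep(TRUE, nrow(info))
  sup <- if (is.null(dp)) matrix(NA_real_, nrow(gt), length(prog))
         else dp[, prog, drop = FALSE]
  out <- list(info = info[keep, , drop = FALSE],
              parent_gt = t(code[keep, parents, drop = FALSE]),
              geno = code[keep, prog, drop = FALSE],
              support = sup[keep, , drop = FALSE],
              progeny = prog)
  rownames(out$geno) <- rownames(out$support) <- out$info$id
  class(out) <- "snp_data"
  out
}

#' Convert a simulated population to site data without a file round trip
#'
#' @param pop a `sim_pop` object.
#' @return a `snp_data` object equivalent to writing with [write_vcf()]
#'   and reading back with [read_vcf()].
#' @export
as_snp_data <- function(pop) {
  stopifnot(inherits(pop, "sim_pop"))
  info <- pop$info
  info$biallelic <- TRUE
  out <- list(info = info[c("id", "chrom", "pos", "ref", "alt", "biallelic")],
              parent_gt = pop$parent_gt,
              geno = pop$geno, support = pop$support, progeny = pop$progeny)
  rownames(out$geno) <- rownames(out$support) <- info$id
  class(out) <- "snp_data"
  out
}

#' @export
print.snp_data <- function(x, ...) {
  cat("SNP site data:", nrow(x$geno), "sites x", length(x$progeny),
      "progeny (+2 parents)\n")
  invisible(x)
}
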