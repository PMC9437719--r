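# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# minimal cp_geno / cp_sites object from explicit code vectors
mk_geno <- function(..., seg_type, chrom = "chr01", pos = NULL,
                    start = NULL, end = NULL, cls = "cp_geno") {
  rows <- list(...)
  m <- length(rows)
  codes <- do.call(rbind, rows)
  ids <- names(rows) %||% paste0("m", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  info <- data.frame(id = ids, seg_type = rep_len(seg_type, m),
                     chrom = rep_len(chrom, m), pos = pos,
                     start = start %||% pos, end = end %||% pos,
                     snp_count = 1L, biallelic = TRUE,
                     stringsAsFactors = FALSE)
  rownames(codes) <- ids
  out <- list(codes = codes, info = info,
              progeny = sprintf("F%03d", seq_len(ncol(codes))))
  colnames(out$codes) <- out$progeny
  class(out) <- cls
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# snp_data object built from explicit parent and progeny genotypes
mk_snp_data <- function(parent_gt, geno, support = NULL, pos = NULL,
                        biallelic = TRUE) {
  m <- nrow(geno)
  if (is.null(support)) support <- matrix(50, m, ncol(geno))
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  info <- data.frame(id = paste0("s", seq_len(m)), chrom = "chr01",
                     pos = pos, ref = "A", alt = "G",
                     biallelic = rep_len(biallelic, m),
                     stringsAsFactors = FALSE)
  out <- list(info = info, parent_gt = parent_gt, geno = geno,
              support = support,
              progeny = sprintf("F%03d", seq_len(ncol(geno))))
  rownames(out$geno) <- rownames(out$support) <- info$id
  class(out) <- "snp_data"
  out
}

# small simulated population shared by several tests
small_pop <- function(seed = 42, n = 80, error = 0, missing = 0,
                      n_chrom = 2, snps = 450, len_bp = 5e6, cM = 60) {
  cfg <- sim_config(n_progeny = n, n_chrom = n_chrom,
                    snps_per_chrom = snps, chrom_len_bp = len_bp,
                    chrom_len_cM = cM, error_rate = error,
                    missing_rate = missing, seed = seed)
  simulate_population(cfg)
}

subset_geno_pub <- function(geno, ids) sibmap:::subset_geno(geno, ids)
validate_agp_pub <- function(agp) sibmap:::validate_agp(agp)

# fabricated genetic_map from a list of data.frames with id/cM columns
mk_map <- function(frames, kind = "consensus") {
  structure(list(kind = kind, groups = frames), class = "genetic_map")
}
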