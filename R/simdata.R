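#' Configuration for the synthetic F1 population generator
#'
#' Builds a validated configuration for [simulate_population()]. Defaults
#' describe a study-scale resequenced pear-type F1 family: 176 progeny, 17
#' chromosomes of roughly 30 Mb / 80 cM each, and a segregation-type mix in
#' which roughly 43% of informative SNPs are lmxll, 42% nnxnp and 15% hkxhk.
#'
#' @param n_progeny number of F1 individuals.
#' @param n_chrom number of chromosomes (use 2-3 for unit-scale runs).
#' @param chrom_len_bp physical chromosome length(s) in bp (scalar recycled).
#' @param chrom_len_cM genetic chromosome length(s) in cM (scalar recycled).
#' @param snps_per_chrom number of SNP markers per chromosome.
#' @param seg_type_mix named proportions over lmxll / nnxnp / hkxhk; must sum to 1.
#' @param error_rate per-call probability that a genotype is miscalled
#'   (replaced by one of the two other states, uniformly).
#' @param missing_rate per-call probability that a genotype is missing.
#' @param phase_coherence probability that a heterozygous parent carries
#'   the alternate allele on its second (non-reference-like) haplotype.
#'   Resequenced crosses are typically aligned to a reference closely
#'   related to the parents, so alternate alleles concentrate on one
#'   haplotype; 0.5 gives fully random phase.
#' @param support_mean,support_size mean and dispersion of the
#'   negative-binomial per-call read support (depth-like; only used to
#'   exercise support masking).
#' @param map_function `"kosambi"` or `"haldane"`; inter-marker recombination
#'   fractions are the inverse map function of the cM spacing.
#' @param seed RNG seed recorded in the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_progeny = 176, n_chrom = 17,
                       chrom_len_bp = 30e6, chrom_len_cM = 80,
                       snps_per_chrom = 600,
                       seg_type_mix = c(lmxll = 0.43, nnxnp = 0.42, hkxhk = 0.15),
                       error_rate = 0.01, missing_rate = 0.05,
                       phase_coherence = 0.85,
                       support_mean = 14, support_size = 5,
                       map_function = c("kosambi", "haldane"),
                       seed = 1L) {
  map_function <- match.arg(map_function)
  if (n_progeny < 1 || n_chrom < 1 || any(snps_per_chrom < 1))
    stop_input("need at least one progeny, one chromosome and one marker")
  if (abs(sum(seg_type_mix) - 1) > 1e-8)
    stop_input("seg_type_mix proportions must sum to 1")
  if (is.null(names(seg_type_mix))) names(seg_type_mix) <- SEG_TYPES
  if (!setequal(names(seg_type_mix), SEG_TYPES))
    stop_input("seg_type_mix must be named over ", paste(SEG_TYPES, collapse = ", "))
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop_input("rates must lie in [0, 1]")
  if (phase_coherence < 0 || phase_coherence > 1)
    stop_input("phase_coherence must lie in [0, 1]")
  if (any(chrom_len_bp <= 0) || any(chrom_len_cM <= 0))
    stop_input("chromosome lengths must be positive")
  cfg <- list(
    n_progeny = as.integer(n_progeny), n_chrom = as.integer(n_chrom),
    chrom_len_bp = rep_len(chrom_len_bp, n_chrom),
    chrom_len_cM = rep_len(chrom_len_cM, n_chrom),
    snps_per_chrom = rep_len(as.integer(snps_per_chrom), n_chrom),
    seg_type_mix = seg_type_mix[SEG_TYPES],
    error_rate = error_rate, missing_rate = missing_rate,
    phase_coherence = phase_coherence,
    support_mean = support_mean, support_size = support_size,
    map_function = map_function, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("F1 simulation config:", x$n_progeny, "progeny,", x$n_chrom,
      "chromosomes,", sum(x$snps_per_chrom), "SNPs\n")
  cat("  error", x$error_rate, "/ missing", x$missing_rate,
      "/ map function", x$map_function, "/ seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an F1 pseudo-testcross population
#'
#' Generates a two-parent full-sib family. Each parental meiosis is a
#' two-state Markov chain along the true map (no crossover interference);
#' the transition probability between adjacent markers is the inverse map
#' function of their cM spacing. Observed genotypes derive from the
#' transmitted alleles, then per-call miscalls (rate `error_rate`), then
#' missing data (rate `missing_rate`); per-call read support is drawn from
#' a negative-binomial distribution. Parental phase is recorded in the
#' truth object but withheld from the observable genotype table, so
#' downstream linkage analysis must infer it.
#'
#' @param cfg a [sim_config()] object.
#' @param seed optional override of `cfg$seed`.
#' @return an object of class `sim_pop`: observable genotype data
#'   (`$geno` coded 0/1/2/NA over markers x progeny, `$support`,
#'   `$parent_gt`, `$info`) plus `$truth`, a `sim_truth` object holding
#'   parental haplotypes, per-progeny transmissions (hence crossover
#'   locations), the true map, and slots for planted QTLs and the genome
#'   layout.
#' @export
simulate_population <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed %||% cfg$seed)
  inv <- map_fun_inverse(cfg$map_function)
  n <- cfg$n_progeny
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chrom))

  info_l <- list(); Sm_l <- list(); Sp_l <- list()
  for (c in seq_len(cfg$n_chrom)) {
    m <- cfg$snps_per_chrom[c]
    pos <- sort(sample.int(cfg$chrom_len_bp[c], m))
    cM <- (pos - 1) / (cfg$chrom_len_bp[c] - 1) * cfg$chrom_len_cM[c]
    seg <- sample(SEG_TYPES, m, replace = TRUE, prob = cfg$seg_type_mix)
    # haplotype alleles (0 = ref, 1 = alt). At heterozygous parents the
    # alternate allele sits on haplotype 2 with probability
    # phase_coherence (haplotype 1 is the reference-like one); the
    # homozygous parent carries the reference allele with the same
    # probability, as variants at sites heterozygous in one parent of a
    # reference-aligned cross are rarely fixed in the other.
    m_het <- seg %in% c("lmxll", "hkxhk")
    p_het <- seg %in% c("nnxnp", "hkxhk")
    hm1 <- rbinom(m, 1, 1 - cfg$phase_coherence)
    hm2 <- ifelse(m_het, 1L - hm1, hm1)
    hp1 <- rbinom(m, 1, 1 - cfg$phase_coherence)
    hp2 <- ifelse(p_het, 1L - hp1, hp1)
    r_adj <- inv(diff(cM))
    Sm <- sim_meiosis(m, n, r_adj)
    Sp <- sim_meiosis(m, n, r_adj)
    info_l[[c]] <- data.frame(
      id = sprintf("%s_%08d", chroms[c], pos), chrom = chroms[c],
      pos = pos, cM = cM, seg_type = seg,
      hm1 = hm1, hm2 = hm2, hp1 = hp1, hp2 = hp2,
      stringsAsFactors = FALSE)
    Sm_l[[c]] <- Sm; Sp_l[[c]] <- Sp
  }
  info <- do.call(rbind, info_l)
  Sm <- do.call(rbind, Sm_l); Sp <- do.call(rbind, Sp_l)
  rownames(Sm) <- rownames(Sp) <- info$id
  progeny <- sprintf("F%03d", seq_len(n))
  colnames(Sm) <- colnames(Sp) <- progeny

  allele_m <- info$hm1 * (1 - Sm) + info$hm2 * Sm
  allele_p <- info$hp1 * (1 - Sp) + info$hp2 * Sp
  g <- allele_m + allele_p
  nm <- length(g)
  err <- runif(nm) < cfg$error_rate
  g[err] <- (g[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
  g[runif(nm) < cfg$missing_rate] <- NA_integer_
  support <- matrix(rnbinom(nm, mu = cfg$support_mean, size = cfg$support_size),
                    nrow = nrow(Sm), dimnames = dimnames(Sm))
  storage.mode(g) <- "integer"

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(info), replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  info$ref <- ref; info$alt <- unname(alt)

  truth <- structure(list(
    marker = info, trans_m = Sm, trans_p = Sp,
    n_xo_m = crossover_counts(Sm, info$chrom),
    n_xo_p = crossover_counts(Sp, info$chrom),
    qtl = NULL, layout = NULL, cfg = cfg), class = "sim_truth")

  structure(list(
    geno = g, support = support,
    parent_gt = rbind(P1 = info$hm1 + info$hm2, P2 = info$hp1 + info$hp2),
    info = info[c("id", "chrom", "pos", "ref", "alt", "seg_type")],
    progeny = progeny, truth = truth, cfg = cfg), class = "sim_pop")
}

# two-state Markov chain per progeny; returns m x n 0/1 matrix
sim_meiosis <- function(m, n, r_adj) {
  S <- matrix(0L, m, n)
  S[1, ] <- rbinom(n, 1, 0.5)
  if (m > 1) {
    flips <- matrix(rbinom((m - 1) * n, 1, rep(r_adj, n)), m - 1, n)
    for (k in 2:m) S[k, ] <- (S[k - 1, ] + flips[k - 1, ]) %% 2L
  }
  S
}

crossover_counts <- function(S, chrom) {
  split_idx <- split(seq_len(nrow(S)), chrom)
  Reduce(`+`, lapply(split_idx, function(i) {
    if (length(i) < 2) return(rep(0L, ncol(S)))
    colSums(abs(diff(S[i, , drop = FALSE])))
  }))
}

#' @export
print.sim_pop <- function(x, ...) {
  cat("Simulated F1 population:", ncol(x$geno), "progeny,",
      nrow(x$geno), "SNPs on", length(unique(x$info$chrom)), "chromosomes\n")
  print(table(x$info$seg_type))
  invisible(x)
}

#' Simulate traits with planted QTLs and a polygenic background
#'
#' The trait is a sum of QTL class effects (one effect per transmitted
#' parental-haplotype class AC/AD/BC/BD at each planted position), a
#' polygenic term built from small random effects on every marker's
#' transmissions, and Gaussian noise. Each component is rescaled so the
#' realized variance fractions equal the requested PVE / polygenic
#' heritability; total phenotypic variance is 1 in expectation.
#'
#' @param truth a `sim_truth` object from [simulate_population()].
#' @param qtl_spec list of QTLs, each a list with `chrom`, `pos_cM`,
#'   `effects` (length-4 class-effect vector for AC, AD, BC, BD) and `pve`
#'   (fraction of phenotypic variance in `[0, 1]`).
#' @param h2_polygenic fraction of variance assigned to the polygenic term.
#' @param seed RNG seed.
#' @return a numeric trait vector (named by progeny) of class `sim_trait`
#'   with attributes `genetic` (per-progeny total genetic value), `qtl`
#'   (annotated spec including the marker used per QTL) and
#'   `h2_target`.
#' @export
simulate_traits <- function(truth, qtl_spec = list(), h2_polygenic = 0,
                            seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  pve <- vapply(qtl_spec, function(q) q$pve, 0)
  if (any(pve < 0) || any(pve > 1)) stop_input("PVE values must lie in [0, 1]")
  if (sum(pve) + h2_polygenic > 1)
    stop_input("PVE plus polygenic heritability exceeds 1")
  n <- ncol(truth$trans_m)
  mk <- truth$marker
  genetic <- rep(0, n)
  for (qi in seq_along(qtl_spec)) {
    q <- qtl_spec[[qi]]
    on_chr <- which(mk$chrom == q$chrom)
    if (!length(on_chr)) stop_input("QTL chromosome not in the simulated map")
    k <- on_chr[which.min(abs(mk$cM[on_chr] - q$pos_cM))]
    cls <- truth$trans_m[k, ] * 2L + truth$trans_p[k, ] + 1L
    v <- q$effects[cls]
    sv <- var(v)
    if (q$pve > 0) {
      if (sv < .Machine$double.eps)
        stop_input("QTL effects are constant across realized classes")
      v <- (v - mean(v)) * sqrt(q$pve / sv)
    } else v <- rep(0, n)
    qtl_spec[[qi]]$marker <- mk$id[k]
    qtl_spec[[qi]]$pos_realized <- mk$cM[k]
    genetic <- genetic + v
  }
  if (h2_polygenic > 0) {
    um <- rnorm(nrow(mk)); up <- rnorm(nrow(mk))
    gp <- drop(crossprod(truth$trans_m, um) + crossprod(truth$trans_p, up))
    gp <- (gp - mean(gp)) * sqrt(h2_polygenic / var(gp))
    genetic <- genetic + gp
  }
  ve <- 1 - sum(pve) - h2_polygenic
  y <- genetic + rnorm(n, 0, sqrt(max(ve, 0)))
  names(y) <- colnames(truth$trans_m)
  structure(y, genetic = genetic, qtl = qtl_spec,
            h2_target = sum(pve) + h2_polygenic, class = "sim_trait")
}

#' Fragment the simulated genome into scaffolds and inject anchoring errors
#'
#' Partitions each chromosome into contiguous scaffolds at random
#' positions, records the true layout (and its AGP), and derives a
#' "reference anchoring" in which a fraction of scaffolds are deliberately
#' misplaced -- assigned to a wrong chromosome, flipped in orientation, or
#' both -- and a further fraction left unanchored, emulating a fragmented
#' draft assembly.
#'
#' @param truth a `sim_truth` object.
#' @param n_scaffolds total number of scaffolds (`>= n_chrom`).
#' @param misassign_rate fraction of scaffolds misplaced in the reference.
#' @param unplaced_rate fraction of scaffolds left unanchored in the
#'   reference (the source of "new anchored" markers downstream).
#' @param seed RNG seed.
#' @return list with `layout` (true scaffold placements: scaffold, chrom,
#'   start, end, length, orientation), `reference` (the error-injected
#'   anchoring with `ref_chrom` NA for unanchored scaffolds) and `agp`
#'   (the true AGP as a data frame).
#' @export
fragment_genome <- function(truth, n_scaffolds, misassign_rate = 0,
                            unplaced_rate = 0.25, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (misassign_rate < 0 || misassign_rate > 1)
    stop_input("misassign_rate must lie in [0, 1]")
  if (unplaced_rate < 0 || unplaced_rate > 1)
    stop_input("unplaced_rate must lie in [0, 1]")
  cfg <- truth$cfg
  if (n_scaffolds < cfg$n_chrom) stop_input("need at least one scaffold per chromosome")
  set.seed(seed)
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  extra <- table(factor(
    sample(chroms, n_scaffolds - cfg$n_chrom, replace = TRUE,
           prob = cfg$chrom_len_bp), levels = chroms))
  rows <- list()
  for (c in seq_along(chroms)) {
    len <- cfg$chrom_len_bp[c]
    k <- 1L + as.integer(extra[c])
    cuts <- if (k > 1) sort(sample.int(len - 1, k - 1)) else integer()
    start <- c(1L, cuts + 1L); end <- c(cuts, len)
    rows[[c]] <- data.frame(chrom = chroms[c], start = start, end = end,
                            stringsAsFactors = FALSE)
  }
  layout <- do.call(rbind, rows)
  layout$length <- layout$end - layout$start + 1L
  layout$scaffold <- sprintf("scaffold_%04d", seq_len(nrow(layout)))
  layout$orientation <- "+"
  layout <- layout[c("scaffold", "chrom", "start", "end", "length", "orientation")]

  reference <- layout
  names(reference)[names(reference) == "chrom"] <- "ref_chrom"
  names(reference)[names(reference) == "orientation"] <- "ref_orient"
  ns <- nrow(reference)
  bad <- which(runif(ns) < misassign_rate)
  if (length(bad)) {
    mode <- sample(c("chrom", "flip", "both"), length(bad), replace = TRUE)
    swap <- mode != "flip"
    reference$ref_chrom[bad[swap]] <- vapply(
      reference$ref_chrom[bad[swap]],
      function(ch) sample(setdiff(chroms, ch), 1), "")
    reference$ref_orient[bad[mode != "chrom"]] <- "-"
  }
  unpl <- setdiff(which(runif(ns) < unplaced_rate), bad)
  reference$ref_chrom[unpl] <- NA_character_
  reference$misassigned <- seq_len(ns) %in% bad
  structure(list(layout = layout, reference = reference,
                 agp = agp_from_layout(layout)), class = "sim_layout")
}

#' Locate physical positions on the scaffold layout
#'
#' @param layout the `layout` data frame from [fragment_genome()].
#' @param chrom,pos vectors of chromosome ids and 1-based bp positions.
#' @return data frame with `scaffold` and 1-based `offset` within it.
#' @export
locate_on_scaffolds <- function(layout, chrom, pos) {
  scaffold <- character(length(pos)); offset <- integer(length(pos))
  for (ch in unique(chrom)) {
    li <- layout[layout$chrom == ch, ]
    sel <- chrom == ch
    k <- findInterval(pos[sel], li$start)
    ok <- k >= 1 & pos[sel] <= li$end[pmax(k, 1)]
    scaffold[sel] <- ifelse(ok, li$scaffold[k], NA_character_)
    offset[sel] <- ifelse(ok, pos[sel] - li$start[k] + 1L, NA_integer_)
  }
  data.frame(scaffold = scaffold, offset = offset, stringsAsFactors = FALSE)
}

#' Serialize / restore simulation ground truth
#'
#' Writes the truth tables (marker map with parental haplotypes,
#' transmission matrices) as TSV plus a JSON manifest holding the
#' configuration, and reads them back losslessly.
#'
#' @param truth a `sim_truth` object.
#' @param dir output directory (created if needed).
#' @return `write_sim_truth()` returns `dir` invisibly;
#'   `read_sim_truth()` returns a `sim_truth` object.
#' @export
write_sim_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- truth$marker
  mk$cM <- sprintf("%.17g", mk$cM)
  write.table(mk, file.path(dir, "truth_markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$trans_m, file.path(dir, "truth_trans_maternal.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(truth$trans_p, file.path(dir, "truth_trans_paternal.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  cfg <- truth$cfg; class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "truth_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(dir) {
  mk <- read.table(file.path(dir, "truth_markers.tsv"), sep = "\t",
                   header = TRUE, colClasses = c(cM = "character"),
                   stringsAsFactors = FALSE)
  mk$cM <- as.numeric(mk$cM)
  rd <- function(f) {
    x <- read.table(file.path(dir, f), sep = "\t", header = TRUE,
                    row.names = 1, check.names = FALSE)
    as.matrix(x)
  }
  Sm <- rd("truth_trans_maternal.tsv"); Sp <- rd("truth_trans_paternal.tsv")
  storage.mode(Sm) <- storage.mode(Sp) <- "integer"
  cfgl <- jsonlite::read_json(file.path(dir, "truth_config.json"),
                              simplifyVector = TRUE)
  cfg <- sim_config(
    n_progeny = cfgl$n_progeny, n_chrom = cfgl$n_chrom,
    chrom_len_bp = cfgl$chrom_len_bp, chrom_len_cM = cfgl$chrom_len_cM,
    snps_per_chrom = cfgl$snps_per_chrom,
    seg_type_mix = unlist(cfgl$seg_type_mix),
    error_rate = cfgl$error_rate, missing_rate = cfgl$missing_rate,
    phase_coherence = cfgl$phase_coherence,
    support_mean = cfgl$support_mean, support_size = cfgl$support_size,
    map_function = cfgl$map_function, seed = cfgl$seed)
  structure(list(marker = mk, trans_m = Sm, trans_p = Sp,
                 n_xo_m = crossover_counts(Sm, mk$chrom),
                 n_xo_p = crossover_counts(Sp, mk$chrom),
                 qtl = NULL, layout = NULL, cfg = cfg), class = "sim_truth")
}
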