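#' Simulation configuration for a ZW dioecious GBS population
#'
#' Bundles and validates the free parameters of the population simulator.
#' Defaults emulate the design of a wild dioecious association panel:
#' 265 accessions with a 61/39 female/male split, a few thousand biallelic
#' GBS markers, a small female-heterogametic (ZW) sex-determining region,
#' and collapsed-paralog tags where females carry extra hemizygous W-linked
#' copies of an autosomal fragment.
#'
#' @param n_accessions Number of accessions (>= 2).
#' @param female_fraction Expected proportion of females, in (0, 1).
#' @param n_autosomal Number of autosomal markers segregating under
#'   Hardy-Weinberg equilibrium within subpopulations.
#' @param n_w_strict Markers whose rare allele rides every W haplotype:
#'   all females are heterozygous, no male carries it.
#' @param n_w_partial Markers whose rare allele is carried by a fraction
#'   (`w_partial_fraction`) of W haplotypes.
#' @param n_z_poly Z-polymorphic markers: the rare allele segregates on Z
#'   haplotypes only, so males can be homozygous rare while females carry
#'   at most one copy.
#' @param n_paralog_tags Collapsed-paralog tags: everyone carries one
#'   autosomal locus monomorphic for the common allele; females
#'   additionally carry `extra_w_copies` hemizygous W-linked loci whose
#'   reads carry the rare allele. The emitted marker is the superposition
#'   of reads from all copies.
#' @param extra_w_copies Integer >= 1; number of extra female-specific
#'   copies at paralog tags.
#' @param w_partial_fraction Fraction of W haplotypes carrying the rare
#'   allele at `w_partial` markers.
#' @param mean_depth Mean reads per locus per site (negative binomial).
#' @param depth_dispersion Negative-binomial size parameter; smaller is
#'   more overdispersed, `Inf` recovers a Poisson depth law.
#' @param error_rate Per-read allele miscall probability, in (0, 0.5).
#' @param missing_rate Proportion of (accession, marker) cells dropped
#'   to (0, 0) depth, in \[0, 1).
#' @param n_subpops Number of discrete subpopulations.
#' @param fst_like_divergence Balding-Nichols-style divergence of
#'   subpopulation allele frequencies, in \[0, 1).
#' @param maf_range Interval from which autosomal (and Z-polymorphic)
#'   base allele frequencies are drawn.
#' @param n_unknown_sex Number of accessions whose phenotype record is
#'   masked to `"unknown"` (for filter testing); their genetic sex is
#'   still simulated.
#' @param seed Integer seed; identical configurations produce identical
#'   output.
#' @return Validated list of class `sim_config`.
#' @seealso [simulate_population]
#' @export
sim_config <- function(n_accessions = 265,
                       female_fraction = 162 / 265,
                       n_autosomal = 2000,
                       n_w_strict = 5,
                       n_w_partial = 3,
                       n_z_poly = 2,
                       n_paralog_tags = 2,
                       extra_w_copies = 2,
                       w_partial_fraction = 0.7,
                       mean_depth = 20,
                       depth_dispersion = 12,
                       error_rate = 0.01,
                       missing_rate = 0.03,
                       n_subpops = 1,
                       fst_like_divergence = 0,
                       maf_range = c(0.05, 0.5),
                       n_unknown_sex = 0,
                       seed = 1L) {
  cfg <- list(n_accessions = n_accessions, female_fraction = female_fraction,
              n_autosomal = n_autosomal, n_w_strict = n_w_strict,
              n_w_partial = n_w_partial, n_z_poly = n_z_poly,
              n_paralog_tags = n_paralog_tags, extra_w_copies = extra_w_copies,
              w_partial_fraction = w_partial_fraction, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion, error_rate = error_rate,
              missing_rate = missing_rate, n_subpops = n_subpops,
              fst_like_divergence = fst_like_divergence, maf_range = maf_range,
              n_unknown_sex = n_unknown_sex, seed = seed)
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v))
      stop(sprintf("invalid sim_config field '%s': must be an integer >= %d",
                   field, min), call. = FALSE)
  }
  chk_prob <- function(field, lo, hi, lo_open = TRUE, hi_open = TRUE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1L && !is.na(v) &&
      (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok)
      stop(sprintf("invalid sim_config field '%s': must lie in %s%g, %g%s",
                   field, if (lo_open) "(" else "[", lo, hi,
                   if (hi_open) ")" else "]"), call. = FALSE)
  }
  chk_count("n_accessions", 2)
  for (f in c("n_autosomal", "n_w_strict", "n_w_partial", "n_z_poly",
              "n_paralog_tags", "n_unknown_sex"))
    chk_count(f, 0)
  chk_count("extra_w_copies", 1)
  chk_count("n_subpops", 1)
  chk_count("seed", 0)
  chk_prob("female_fraction", 0, 1)
  chk_prob("w_partial_fraction", 0, 1, lo_open = TRUE, hi_open = FALSE)
  chk_prob("error_rate", 0, 0.5, lo_open = FALSE)
  chk_prob("missing_rate", 0, 1, lo_open = FALSE)
  chk_prob("fst_like_divergence", 0, 1, lo_open = FALSE)
  if (!is.numeric(cfg$mean_depth) || length(cfg$mean_depth) != 1L ||
      cfg$mean_depth <= 0)
    stop("invalid sim_config field 'mean_depth': must be > 0", call. = FALSE)
  if (!is.numeric(cfg$depth_dispersion) || length(cfg$depth_dispersion) != 1L ||
      cfg$depth_dispersion <= 0)
    stop("invalid sim_config field 'depth_dispersion': must be > 0",
         call. = FALSE)
  if (!is.numeric(cfg$maf_range) || length(cfg$maf_range) != 2L ||
      any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid sim_config field 'maf_range': must be an interval within (0, 0.5]",
         call. = FALSE)
  if (cfg$female_fraction * cfg$n_accessions < 1)
    stop("invalid sim_config field 'female_fraction': expected females < 1",
         call. = FALSE)
  if (cfg$n_unknown_sex >= cfg$n_accessions)
    stop("invalid sim_config field 'n_unknown_sex': must leave sexed accessions",
         call. = FALSE)
  if (sum(cfg$n_autosomal, cfg$n_w_strict, cfg$n_w_partial, cfg$n_z_poly,
          cfg$n_paralog_tags) < 1)
    stop("invalid sim_config field 'n_autosomal': at least one marker required",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

# draw per-locus read depths; Inf dispersion -> Poisson
.rdepth <- function(n, mu, size) {
  if (is.finite(size)) stats::rnbinom(n, size = size, mu = mu)
  else stats::rpois(n, lambda = mu)
}

#' Simulate a ZW dioecious population with GBS-like allele depths
#'
#' Generates a population of sexed accessions and biallelic markers in
#' five classes (autosomal HWE, strictly W-linked, partially W-linked,
#' Z-polymorphic, collapsed paralog), emits per-allele read counts per
#' cell, and returns the ground truth needed to score recovery.
#'
#' Read counts per diploid locus are negative binomial with mean
#' `mean_depth`; reads split between the two haplotypes' alleles
#' binomially. Collapsed-paralog tags superimpose reads from the shared
#' autosomal locus (common allele) and, in females, `extra_w_copies`
#' hemizygous W-linked loci (rare allele), so female total depth is
#' `(1 + extra_w_copies) * mean_depth` in expectation versus `mean_depth`
#' in males. Each read's allele is miscalled with probability
#' `error_rate`; cells are masked to zero depth at `missing_rate`.
#'
#' @param config A [sim_config] object.
#' @return List with elements:
#'   \describe{
#'     \item{depths}{[allele_depths] for all accessions and markers.}
#'     \item{phenotypes}{`data.frame(accession, sex, subpop)` with sex in
#'       `F`/`M`/`unknown`.}
#'     \item{truth}{`data.frame(marker_id, class_label, w_allele,
#'       true_extra_copies, base_freq, subpop_freqs)`; `class_label` is one
#'       of `autosomal`, `w_strict`, `w_partial`, `z_poly`,
#'       `paralog_collapsed`.}
#'     \item{true_geno}{Integer matrix of simulated alt-allele dosages
#'       (`NA` for paralog tags, whose diploid dosage is undefined).}
#'     \item{true_sex}{Simulated sex of every accession (before any
#'       unknown masking).}
#'   }
#' @examples
#' pop <- simulate_population(sim_config(n_accessions = 20, n_autosomal = 10,
#'                                       n_w_strict = 1, n_w_partial = 0,
#'                                       n_z_poly = 0, n_paralog_tags = 1,
#'                                       seed = 7))
#' pop$truth$class_label
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_accessions
  acc <- sprintf("acc%04d", seq_len(n))
  sex <- ifelse(stats::rbinom(n, 1, config$female_fraction) == 1, "F", "M")
  # the population must contain both sexes
  if (all(sex == "F")) sex[n] <- "M"
  if (all(sex == "M")) sex[1] <- "F"
  is_f <- sex == "F"
  subpop <- sprintf("pop%d", ((seq_len(n) - 1L) %% config$n_subpops) + 1L)

  counts <- c(autosomal = config$n_autosomal, w_strict = config$n_w_strict,
              w_partial = config$n_w_partial, z_poly = config$n_z_poly,
              paralog_collapsed = config$n_paralog_tags)
  m <- sum(counts)
  class_label <- rep(names(counts), counts)

  # marker placement: sex-linked classes on chromosome 15, paralog tags
  # reported at their shared autosomal location (chromosome 9), the rest
  # spread over the remaining autosomes
  chrom <- character(m)
  auto_chroms <- sprintf("%02d", setdiff(1:19, c(9, 15)))
  chrom[class_label == "autosomal"] <-
    sample(auto_chroms, counts[["autosomal"]], replace = TRUE)
  chrom[class_label %in% c("w_strict", "w_partial", "z_poly")] <- "15"
  chrom[class_label == "paralog_collapsed"] <- "09"
  pos <- sample.int(2e8L, m)
  id <- sprintf("S%s_%d", chrom, pos)
  bases <- c("A", "C", "G", "T")
  ref_al <- sample(bases, m, replace = TRUE)
  alt_al <- vapply(ref_al, function(b) sample(setdiff(bases, b), 1),
                   character(1))
  markers <- data.frame(id = id, chrom = chrom, pos = pos,
                        ref = ref_al, alt = alt_al, stringsAsFactors = FALSE)

  base_freq <- rep(NA_real_, m)
  subpop_freqs <- rep(NA_character_, m)
  G <- matrix(NA_integer_, n, m)

  if (counts[["autosomal"]] > 0) {
    j <- which(class_label == "autosomal")
    p0 <- stats::runif(length(j), config$maf_range[1], config$maf_range[2])
    base_freq[j] <- p0
    fst <- config$fst_like_divergence
    if (config$n_subpops > 1 && fst > 0) {
      a <- p0 * (1 - fst) / fst
      b <- (1 - p0) * (1 - fst) / fst
      P <- matrix(stats::rbeta(config$n_subpops * length(j),
                               rep(a, each = config$n_subpops),
                               rep(b, each = config$n_subpops)),
                  nrow = config$n_subpops)
    } else {
      P <- matrix(p0, nrow = config$n_subpops, ncol = length(j), byrow = TRUE)
    }
    subpop_freqs[j] <- apply(P, 2, function(p)
      paste(sprintf("%.4f", p), collapse = ";"))
    sp_idx <- as.integer(factor(subpop, levels = unique(subpop)))
    Pacc <- P[sp_idx, , drop = FALSE]
    G[, j] <- stats::rbinom(n * length(j), 2L, Pacc)
  }
  if (counts[["w_strict"]] > 0) {
    j <- which(class_label == "w_strict")
    G[, j] <- matrix(as.integer(is_f), n, length(j))
  }
  if (counts[["w_partial"]] > 0) {
    j <- which(class_label == "w_partial")
    carry <- matrix(stats::rbinom(n * length(j), 1L,
                                  config$w_partial_fraction), n, length(j))
    G[, j] <- carry * as.integer(is_f)
  }
  if (counts[["z_poly"]] > 0) {
    # Z-polymorphic markers emulate loci where both alleles are common on
    # Z (males frequently homozygous rare): a near-balanced Z frequency,
    # so the male hom-rare fraction (q^2) stays well clear of zero even
    # after binomial sampling across a few hundred males
    j <- which(class_label == "z_poly")
    q <- stats::runif(length(j), 0.4, 0.5)
    base_freq[j] <- q
    n_z <- ifelse(is_f, 1L, 2L)  # females carry one Z, males two
    G[, j] <- stats::rbinom(n * length(j), rep(n_z, length(j)),
                            rep(q, each = n))
  }
  # paralog tags: diploid dosage undefined (superposition of loci)

  # read depths: one diploid locus per standard marker
  std <- which(class_label != "paralog_collapsed")
  REF <- matrix(0L, n, m)
  ALT <- matrix(0L, n, m)
  if (length(std)) {
    d <- .rdepth(n * length(std), config$mean_depth, config$depth_dispersion)
    a <- stats::rbinom(n * length(std), d, as.vector(G[, std, drop = FALSE]) / 2)
    ALT[, std] <- a
    REF[, std] <- d - a
  }
  par <- which(class_label == "paralog_collapsed")
  if (length(par)) {
    k <- config$extra_w_copies
    d0 <- .rdepth(n * length(par), config$mean_depth, config$depth_dispersion)
    REF[, par] <- d0                       # shared locus, common allele
    nw <- sum(is_f) * length(par)
    dw <- .rdepth(nw, k * config$mean_depth,
                  if (is.finite(config$depth_dispersion))
                    k * config$depth_dispersion else Inf)
    AW <- matrix(0L, n, length(par))
    AW[is_f, ] <- dw                       # W copies, rare allele
    ALT[, par] <- AW
  }

  # per-read miscalls
  e <- config$error_rate
  if (e > 0) {
    flip_ra <- stats::rbinom(length(REF), REF, e)
    flip_ar <- stats::rbinom(length(ALT), ALT, e)
    REF2 <- REF - flip_ra + flip_ar
    ALT2 <- ALT - flip_ar + flip_ra
    REF <- matrix(REF2, n, m); ALT <- matrix(ALT2, n, m)
  }

  # missingness: cells masked independently at missing_rate
  if (config$missing_rate > 0) {
    drop <- matrix(stats::rbinom(n * m, 1L, config$missing_rate) == 1L, n, m)
    REF[drop] <- 0L
    ALT[drop] <- 0L
  }

  # mask phenotype sex for filter testing
  sex_pheno <- sex
  if (config$n_unknown_sex > 0) {
    unk <- sample.int(n, config$n_unknown_sex)
    sex_pheno[unk] <- "unknown"
  }

  depths <- allele_depths(REF, ALT, markers, accessions = acc)
  phen <- data.frame(accession = acc, sex = sex_pheno, subpop = subpop,
                     stringsAsFactors = FALSE)
  truth <- data.frame(marker_id = markers$id,
                      class_label = class_label,
                      w_allele = ifelse(class_label %in%
                                          c("w_strict", "w_partial",
                                            "paralog_collapsed"),
                                        "alt", NA_character_),
                      true_extra_copies = ifelse(
                        class_label == "paralog_collapsed",
                        config$extra_w_copies, 0L),
                      base_freq = base_freq,
                      subpop_freqs = subpop_freqs,
                      stringsAsFactors = FALSE)
  dimnames(G) <- list(acc, markers$id)
  list(depths = depths, phenotypes = phen, truth = truth,
       true_geno = G, true_sex = sex)
}
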