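#' Segregation-class thresholds
#'
#' Numeric cutoffs turning verbal segregation patterns ("entirely /
#' almost entirely female-exclusive") into deterministic rules. All are
#' exposed because the underlying biology offers no canonical values.
#'
#' @param tau_m Maximum male b-carrier (or female hom-b) fraction still
#'   treated as "(almost) never".
#' @param tau_delta Minimum excess of female over male b-carrier fraction
#'   for the loose W-linked class.
#' @param tau_z Minimum male hom-b fraction for the Z-polymorphic class.
#' @param min_female_carrier Minimum female b-carrier fraction for the
#'   strict W-linked class.
#' @return Named list of thresholds.
#' @export
seg_thresholds <- function(tau_m = 0.05, tau_delta = 0.3, tau_z = 0.1,
                           min_female_carrier = 0.5) {
  list(tau_m = tau_m, tau_delta = tau_delta, tau_z = tau_z,
       min_female_carrier = min_female_carrier)
}

#' Segregation profile of a marker
#'
#' Per-sex genotype counts in the rare-allele (b) orientation, carrier
#' and heterozygote frequencies, and the segregation class label.
#'
#' @inheritParams sex_genotype_table
#' @param thresholds See [seg_thresholds].
#' @return List of class `segregation_profile`: `marker_id`, `counts`
#'   (2 x 3 matrix, columns `hom_a`/`het`/`hom_b`), per-sex carrier /
#'   het / hom-b frequencies, and `class_label`.
#' @export
segregation_profile <- function(g, phenotypes, marker,
                                thresholds = seg_thresholds()) {
  stopifnot(inherits(g, "genotype_calls"))
  j <- match(marker, g$markers$id)
  if (is.na(j)) stop("unknown marker id: ", marker)
  sex <- phenotypes$sex[match(rownames(g$geno), phenotypes$accession)]
  b <- marker_b_allele(subset_markers(g, j))[[1]]
  geno <- g$geno[, j]
  dose_b <- if (b == "alt") geno else 2L - geno
  counts <- rbind(
    F = tabulate(dose_b[sex == "F" & !is.na(sex)] + 1L, nbins = 3L),
    M = tabulate(dose_b[sex == "M" & !is.na(sex)] + 1L, nbins = 3L))
  colnames(counts) <- c("hom_a", "het", "hom_b")
  prof <- list(marker_id = marker, b_allele = b, counts = counts)
  prof <- c(prof, .seg_freqs(counts))
  prof$class_label <- classify_segregation(prof, thresholds)
  structure(prof, class = "segregation_profile")
}

.seg_freqs <- function(counts) {
  nF <- sum(counts["F", ]); nM <- sum(counts["M", ])
  safe <- function(x, n) if (n > 0) x / n else NA_real_
  list(n_F = nF, n_M = nM,
       b_carrier_freq_F = safe(counts["F", "het"] + counts["F", "hom_b"], nF),
       b_carrier_freq_M = safe(counts["M", "het"] + counts["M", "hom_b"], nM),
       het_freq_F = safe(counts["F", "het"], nF),
       het_freq_M = safe(counts["M", "het"], nM),
       homb_freq_F = safe(counts["F", "hom_b"], nF),
       homb_freq_M = safe(counts["M", "hom_b"], nM))
}

#' Classify a marker's segregation pattern
#'
#' Deterministic rules over per-sex genotype counts (b = rare allele):
#' \describe{
#'   \item{w_strict}{no male carries b and at least
#'     `min_female_carrier` of females do — the pattern of a fully
#'     W-linked allele under female heterogamety;}
#'   \item{w_loose}{male b-carrier fraction at most `tau_m` and female
#'     carrier fraction exceeding the male one by at least `tau_delta`;}
#'   \item{z_poly}{males hom-b at a fraction of at least `tau_z` while
#'     females are (almost) never hom-b — two alleles segregating on Z
#'     with a monomorphic W;}
#'   \item{ambiguous}{anything else, including markers where one sex has
#'     no calls (flagged with a warning).}
#' }
#'
#' @param profile A `segregation_profile` or any list with a `counts`
#'   matrix as produced by [segregation_profile].
#' @param thresholds See [seg_thresholds].
#' @return Class label string.
#' @export
classify_segregation <- function(profile, thresholds = seg_thresholds()) {
  counts <- profile$counts
  f <- .seg_freqs(counts)
  if (f$n_F == 0L || f$n_M == 0L) {
    warning("one sex has no called genotypes; class is ambiguous",
            call. = FALSE)
    return("ambiguous")
  }
  th <- thresholds
  carriers_M <- counts["M", "het"] + counts["M", "hom_b"]
  if (carriers_M == 0L && f$b_carrier_freq_F >= th$min_female_carrier)
    return("w_strict")
  if (f$b_carrier_freq_M <= th$tau_m &&
      (f$b_carrier_freq_F - f$b_carrier_freq_M) >= th$tau_delta)
    return("w_loose")
  if (f$homb_freq_M >= th$tau_z && f$homb_freq_F <= th$tau_m)
    return("z_poly")
  "ambiguous"
}

#' Infer the heterogametic sex from significant markers
#'
#' Majority vote over classified markers. Each marker is classified both
#' as observed (supporting female heterogamety when W-linked or
#' Z-polymorphic patterns emerge) and with the sexes swapped (the mirror
#' image, supporting male heterogamety). The verdict goes to the
#' orientation with more votes; support is the winning vote fraction over
#' all markers considered.
#'
#' @param g A [genotype_calls] object.
#' @param phenotypes Phenotype table.
#' @param marker_ids Markers to vote over (typically the Bonferroni-
#'   significant ones).
#' @param thresholds See [seg_thresholds].
#' @return List `verdict` (`"female_heterogametic"`,
#'   `"male_heterogametic"` or `"undetermined"`), `support` (winning
#'   fraction), `votes_female`, `votes_male`, `n_markers`, and the
#'   per-marker class labels under both orientations.
#' @export
infer_heterogamety <- function(g, phenotypes, marker_ids,
                               thresholds = seg_thresholds()) {
  if (length(marker_ids) == 0L)
    return(list(verdict = "undetermined", support = NA_real_,
                votes_female = 0L, votes_male = 0L, n_markers = 0L,
                classes = character(0), classes_swapped = character(0)))
  swapped <- phenotypes
  swapped$sex <- c(F = "M", M = "F", unknown = "unknown")[phenotypes$sex]
  cls <- vapply(marker_ids, function(m)
    segregation_profile(g, phenotypes, m, thresholds)$class_label, "")
  cls_sw <- vapply(marker_ids, function(m)
    suppressWarnings(
      segregation_profile(g, swapped, m, thresholds)$class_label), "")
  informative <- c("w_strict", "w_loose", "z_poly")
  vf <- sum(cls %in% informative)
  vm <- sum(cls_sw %in% informative)
  verdict <- if (vf == 0L && vm == 0L) "undetermined"
  else if (vf > vm) "female_heterogametic"
  else if (vm > vf) "male_heterogametic"
  else "undetermined"
  support <- if (verdict == "undetermined") NA_real_
  else max(vf, vm) / length(marker_ids)
  list(verdict = verdict, support = support, votes_female = vf,
       votes_male = vm, n_markers = length(marker_ids),
       classes = cls, classes_swapped = cls_sw)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom chi-square of observed genotype counts against
#' the expectation from the observed allele frequency.
#'
#' @param counts Integer vector `c(hom_ref, het, hom_alt)` (orientation
#'   irrelevant; the statistic is invariant under allele relabelling).
#' @return List `statistic`, `p`. Monomorphic markers give
#'   `statistic = 0`, `p = 1`.
#' @examples
#' hwe_chisq(c(25, 50, 25))  # chi-square 0, p 1
#' hwe_chisq(c(30, 40, 30))  # chi-square 4
#' @export
hwe_chisq <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be c(hom_ref, het, hom_alt)")
  n <- sum(counts)
  if (n == 0) stop("no genotyped accessions")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(list(statistic = 0, p = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Identify "textbook" reference markers
#'
#' Well-behaved markers whose calls plausibly reflect a single biallelic
#' locus: complete genotyping (call rate exactly 1), MAF > `maf_min`, and
#' a pooled-sex segregation pattern consistent with Hardy-Weinberg
#' equilibrium (chi-square p > `hwe_alpha`). These serve as the reference
#' set for read-depth dosage diagnostics.
#'
#' @param g A [genotype_calls] object.
#' @param maf_min MAF threshold (strict).
#' @param hwe_alpha HWE test level; markers with p > `hwe_alpha` pass.
#' @return Character vector of marker ids (may be empty, with a warning).
#' @export
identify_textbook_markers <- function(g, maf_min = 0.05, hwe_alpha = 0.05) {
  stopifnot(inherits(g, "genotype_calls"))
  st <- marker_stats(g)
  cand <- which(st$call_rate == 1 & !is.na(st$maf) & st$maf > maf_min)
  keep <- cand[vapply(cand, function(j) {
    cnt <- tabulate(g$geno[, j] + 1L, nbins = 3L)
    hwe_chisq(cnt)$p > hwe_alpha
  }, TRUE)]
  if (!length(keep))
    warning("no textbook markers found; dosage comparisons will need fallback thresholds",
            call. = FALSE)
  st$id[keep]
}
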