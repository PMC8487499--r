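#' Read-depth summary for one marker
#'
#' Collects the per-accession total depths by sex (over *all* accessions,
#' whether or not they obtained a genotype call — uncalled accessions
#' still carry reads) and the allele-specific mean depths conditional on
#' called genotype class.
#'
#' @param depths An [allele_depths] object.
#' @param g Matching [genotype_calls].
#' @param phenotypes Phenotype table.
#' @param marker Marker id.
#' @return List of class `dosage_summary`: `marker_id`, `by_sex`
#'   (`data.frame(sex, n, mean_total, sd_total)`), `depth_F` / `depth_M`
#'   (per-accession total-depth vectors), and `allele_by_class`
#'   (`data.frame(genotype, allele, n, mean_depth)` over called
#'   accessions only).
#' @export
depth_summary <- function(depths, g, phenotypes, marker) {
  stopifnot(inherits(depths, "allele_depths"), inherits(g, "genotype_calls"))
  j <- match(marker, depths$markers$id)
  if (is.na(j)) stop("unknown marker id: ", marker)
  acc <- rownames(depths$ref)
  sex <- phenotypes$sex[match(acc, phenotypes$accession)]
  r <- depths$ref[, j]; a <- depths$alt[, j]
  tot <- r + a
  jg <- match(marker, g$markers$id)
  geno <- if (is.na(jg)) rep(NA_integer_, length(acc)) else g$geno[, jg]

  by_sex <- do.call(rbind, lapply(c("F", "M"), function(s) {
    idx <- which(sex == s)
    if (!length(idx)) {
      message("depth_summary: no accessions of sex ", s, " for ", marker)
      return(NULL)
    }
    data.frame(sex = s, n = length(idx), mean_total = mean(tot[idx]),
               sd_total = stats::sd(tot[idx]), stringsAsFactors = FALSE)
  }))

  classes <- c(`0` = "hom_ref", `1` = "het", `2` = "hom_alt")
  abc <- do.call(rbind, lapply(0:2, function(gc) {
    idx <- which(!is.na(geno) & geno == gc)
    if (!length(idx)) return(NULL)
    data.frame(genotype = classes[[as.character(gc)]],
               allele = c("ref", "alt"), n = length(idx),
               mean_depth = c(mean(r[idx]), mean(a[idx])),
               stringsAsFactors = FALSE)
  }))

  structure(list(marker_id = marker,
                 by_sex = by_sex,
                 depth_F = tot[which(sex == "F")],
                 depth_M = tot[which(sex == "M")],
                 allele_by_class = abc),
            class = "dosage_summary")
}

#' Dose-compensation test on allele-specific depths
#'
#' At a well-behaved single locus the mean depth of an allele in
#' heterozygotes is about half its mean depth in the corresponding
#' homozygotes (each het carries one dose of the allele, each homozygote
#' two). The ratio `het mean / hom mean` is computed per allele over
#' classes with at least `n_min` called accessions; the marker is dose
#' compensated when every testable ratio lies within
#' `[0.5 - delta, 0.5 + delta]`.
#'
#' @param summary A `dosage_summary` from [depth_summary].
#' @param delta Half-width of the acceptance band around 0.5.
#' @param n_min Minimum accessions per compared class. The default (12)
#'   keeps the sampling error of a mean-depth ratio (about
#'   `0.5 * cv * sqrt(2/n)` with GBS depth coefficients of variation
#'   around 0.5) well inside `delta`, so class-size noise is not mistaken
#'   for a compensation violation.
#' @return List `ratios` (named `ref` / `alt`, `NA` when untestable),
#'   `dose_compensated` (`TRUE` / `FALSE`, or `NA` when no allele is
#'   testable), `testable`.
#' @export
compensation_test <- function(summary, delta = 0.15, n_min = 12) {
  abc <- summary$allele_by_class
  get <- function(genotype, allele) {
    row <- abc[abc$genotype == genotype & abc$allele == allele, ]
    if (nrow(row) == 0L || row$n < n_min) NULL else row$mean_depth
  }
  ratio_for <- function(allele, hom_class) {
    het <- get("het", allele); hom <- get(hom_class, allele)
    if (is.null(het) || is.null(hom) || hom <= 0) NA_real_ else het / hom
  }
  ratios <- c(ref = ratio_for("ref", "hom_ref"),
              alt = ratio_for("alt", "hom_alt"))
  testable <- !is.na(ratios)
  compensated <- if (!any(testable)) NA
  else all(abs(ratios[testable] - 0.5) <= delta)
  list(ratios = ratios, dose_compensated = compensated,
       testable = any(testable))
}

#' Female-to-male total-depth ratio
#'
#' Ratio of mean total read depth in females to that in males, over all
#' accessions. The elevation flag additionally requires a Welch
#' two-sample test at `p < p_cut`, guarding against small-sample noise in
#' overdispersed depth data.
#'
#' @param summary A `dosage_summary`.
#' @param ratio_threshold Minimum ratio to flag elevation.
#' @param p_cut Welch-test p-value cutoff.
#' @return List `ratio` (`NA` when the male mean is 0), `ratio_elevated`,
#'   `p_welch`, `male_null` (male mean depth is zero).
#' @export
sex_depth_ratio <- function(summary, ratio_threshold = 2, p_cut = 0.01) {
  dF <- summary$depth_F; dM <- summary$depth_M
  if (!length(dF) || !length(dM))
    return(list(ratio = NA_real_, ratio_elevated = NA, p_welch = NA_real_,
                male_null = NA))
  mM <- mean(dM)
  if (mM == 0)
    return(list(ratio = NA_real_, ratio_elevated = NA, p_welch = NA_real_,
                male_null = TRUE))
  ratio <- mean(dF) / mM
  p <- if (length(dF) > 1L && length(dM) > 1L &&
           (stats::sd(dF) > 0 || stats::sd(dM) > 0))
    stats::t.test(dF, dM)$p.value else 0
  list(ratio = ratio, ratio_elevated = ratio >= ratio_threshold && p < p_cut,
       p_welch = p, male_null = FALSE)
}

#' Estimate female-specific extra copy number from the depth ratio
#'
#' Under the model that males carry one locus and females carry
#' `1 + k` loci of the sequence tag, the female:male depth ratio
#' estimates `1 + k`, so `k = ratio - 1` (floored at 0). A bootstrap over
#' accessions (resampled within sex) yields a percentile interval.
#'
#' @param summary A `dosage_summary`.
#' @param n_boot Bootstrap resamples.
#' @param conf Interval coverage.
#' @param seed Integer seed for the bootstrap (the global RNG state is
#'   restored afterwards).
#' @return List `estimate`, `ci` (length-2 vector), `note`.
#' @export
estimate_extra_copies <- function(summary, n_boot = 200, conf = 0.95,
                                  seed = 1L) {
  sr <- sex_depth_ratio(summary, ratio_threshold = -Inf, p_cut = 1.1)
  if (is.na(sr$ratio))
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                note = "male mean depth is zero; ratio undefined"))
  est <- max(sr$ratio - 1, 0)
  note <- if (sr$ratio < 1) "ratio below 1; estimate floored at 0" else ""
  dF <- summary$depth_F; dM <- summary$depth_M
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  boots <- replicate(n_boot, {
    mF <- mean(sample(dF, replace = TRUE))
    mM <- mean(sample(dM, replace = TRUE))
    if (mM == 0) NA_real_ else max(mF / mM - 1, 0)
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = est, ci = qs, note = note)
}

#' Full dosage report for one marker
#'
#' Combines [depth_summary], [compensation_test], [sex_depth_ratio] and
#' [estimate_extra_copies] into one record.
#'
#' @inheritParams depth_summary
#' @param delta,n_min See [compensation_test].
#' @param ratio_threshold,p_cut See [sex_depth_ratio].
#' @param n_boot,seed See [estimate_extra_copies].
#' @return List of class `dosage_report` with components `summary`,
#'   `compensation`, `sex_ratio`, `extra_copies`.
#' @export
dosage_report <- function(depths, g, phenotypes, marker, delta = 0.15,
                          n_min = 12, ratio_threshold = 2, p_cut = 0.01,
                          n_boot = 200, seed = 1L) {
  s <- depth_summary(depths, g, phenotypes, marker)
  structure(list(marker_id = marker,
                 summary = s,
                 compensation = compensation_test(s, delta, n_min),
                 sex_ratio = sex_depth_ratio(s, ratio_threshold, p_cut),
                 extra_copies = estimate_extra_copies(s, n_boot = n_boot,
                                                      seed = seed)),
            class = "dosage_report")
}

#' Flag collapsed-paralog suspects
#'
#' A marker is suspect when its read-depth behaviour is incompatible with
#' a single biallelic locus: the dose-compensation test is violated, the
#' female:male depth ratio is elevated, or its mean total depth is an
#' outlier (z-score above `z_cut`) against the depth distribution of the
#' textbook reference markers. The reasons are recorded per marker.
#'
#' @param depths An [allele_depths] object.
#' @param g Matching [genotype_calls].
#' @param phenotypes Phenotype table.
#' @param markers Marker ids to screen (default: all in `depths`).
#' @param textbook Ids of reference markers (see
#'   [identify_textbook_markers]); when empty, the depth-outlier rule
#'   falls back to the screened markers' own median/MAD.
#' @param delta,n_min,ratio_threshold,p_cut,z_cut Thresholds.
#' @return `data.frame(marker_id, paralog_suspect, compensation_violated,
#'   ratio_elevated, depth_outlier, sex_depth_ratio, extra_copy_estimate,
#'   reasons)`.
#' @export
flag_paralog_suspects <- function(depths, g, phenotypes,
                                  markers = depths$markers$id,
                                  textbook = character(0),
                                  delta = 0.15, n_min = 12,
                                  ratio_threshold = 2, p_cut = 0.01,
                                  z_cut = 3) {
  tot <- total_depth(depths)
  mean_depths <- colMeans(tot)
  if (length(textbook)) {
    ref_mu <- mean(mean_depths[textbook])
    ref_sd <- stats::sd(mean_depths[textbook])
  } else {
    warning("empty textbook reference; using median/MAD of screened markers",
            call. = FALSE)
    ref_mu <- stats::median(mean_depths[markers])
    ref_sd <- stats::mad(mean_depths[markers])
  }
  if (!is.finite(ref_sd) || ref_sd == 0) ref_sd <- Inf

  rows <- lapply(markers, function(mk) {
    s <- depth_summary(depths, g, phenotypes, mk)
    comp <- compensation_test(s, delta, n_min)
    sr <- sex_depth_ratio(s, ratio_threshold, p_cut)
    zs <- (mean_depths[[mk]] - ref_mu) / ref_sd
    comp_viol <- isTRUE(comp$testable) && identical(comp$dose_compensated, FALSE)
    ratio_up <- isTRUE(sr$ratio_elevated)
    outlier <- zs > z_cut
    reasons <- c(if (comp_viol) "compensation_violated",
                 if (ratio_up) "ratio_elevated",
                 if (outlier) "depth_outlier")
    data.frame(marker_id = mk,
               paralog_suspect = length(reasons) > 0L,
               compensation_violated = comp_viol,
               ratio_elevated = ratio_up,
               depth_outlier = outlier,
               sex_depth_ratio = if (is.na(sr$ratio)) NA_real_ else sr$ratio,
               extra_copy_estimate = if (is.na(sr$ratio)) NA_real_
                                     else max(sr$ratio - 1, 0),
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a depth histogram by genotype or sex
#'
#' Bins per-accession allele-specific read depths into classes of
#' `bin_width` reads, for plotting read-coverage distributions of a
#' marker.
#'
#' @inheritParams depth_summary
#' @param allele `"ref"` or `"alt"`.
#' @param by Group accessions by called `"genotype"` or by `"sex"`.
#' @param bin_width Width of a depth class in reads.
#' @return `data.frame(group, depth_bin, n)` where `depth_bin` is the
#'   lower edge of the class.
#' @export
depth_histogram <- function(depths, g, phenotypes, marker,
                            allele = c("ref", "alt"),
                            by = c("genotype", "sex"), bin_width = 10) {
  allele <- match.arg(allele)
  by <- match.arg(by)
  j <- match(marker, depths$markers$id)
  if (is.na(j)) stop("unknown marker id: ", marker)
  x <- depths[[allele]][, j]
  grp <- if (by == "sex") {
    phenotypes$sex[match(rownames(depths$ref), phenotypes$accession)]
  } else {
    jg <- match(marker, g$markers$id)
    c("hom_ref", "het", "hom_alt", NA)[ifelse(is.na(g$geno[, jg]), 4L,
                                              g$geno[, jg] + 1L)]
  }
  keep <- !is.na(grp)
  bin <- (x[keep] %/% bin_width) * bin_width
  agg <- stats::aggregate(list(n = bin), by = list(group = grp[keep],
                                                   depth_bin = bin), length)
  agg[order(agg$group, agg$depth_bin), ]
}
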