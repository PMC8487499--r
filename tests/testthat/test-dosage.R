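# deterministic depth fixture: one marker, explicit per-accession depths
depth_case <- function(ref_f, alt_f, ref_m, alt_m, geno_f = NULL,
                       geno_m = NULL) {
  nf <- length(ref_f); nm <- length(ref_m)
  mk <- data.frame(id = "mk001", chrom = "01", pos = 100L, ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  acc <- paste0("a", seq_len(nf + nm))
  d <- allele_depths(matrix(c(ref_f, ref_m), ncol = 1),
                     matrix(c(alt_f, alt_m), ncol = 1), mk, accessions = acc)
  geno <- if (is.null(geno_f)) call_genotypes(d, min_depth = 1)
          else genotype_calls(matrix(c(geno_f, geno_m), ncol = 1), mk)
  if (!is.null(geno_f)) rownames(geno$geno) <- acc
  list(d = d, g = geno, ph = make_phen(acc, nf))
}

test_that("uniform depth yields flat summaries and conserved totals", {
  cs <- depth_case(rep(30L, 6), rep(30L, 6), rep(30L, 5), rep(30L, 5))
  s <- depth_summary(cs$d, cs$g, cs$ph, "mk001")
  expect_equal(s$by_sex$mean_total, c(60, 60))
  expect_equal(s$by_sex$sd_total, c(0, 0))
  expect_identical(unname(total_depth(cs$d)[, 1]),
                   unname(cs$d$ref[, 1] + cs$d$alt[, 1]))
})

test_that("exact halving of het allele depth is dose compensated", {
  # 15 het females (30+30), 15 hom_ref males (60+0): ref ratio 30/60 = 0.5
  cs <- depth_case(rep(30L, 15), rep(30L, 15), rep(60L, 15), rep(0L, 15),
                   geno_f = rep(1L, 15), geno_m = rep(0L, 15))
  ct <- compensation_test(depth_summary(cs$d, cs$g, cs$ph, "mk001"))
  expect_equal(unname(ct$ratios["ref"]), 0.5)
  expect_true(ct$dose_compensated)
})

test_that("paralog-like allele depths violate compensation", {
  # common-allele depth equal in het females and hom males (ratio ~1),
  # the printed pattern of a collapsed paralog
  cs <- depth_case(rep(10L, 15), rep(22L, 15), rep(9L, 15), rep(0L, 15),
                   geno_f = rep(1L, 15), geno_m = rep(0L, 15))
  s <- depth_summary(cs$d, cs$g, cs$ph, "mk001")
  ct <- compensation_test(s)
  expect_false(ct$dose_compensated)
  expect_gt(ct$ratios["ref"], 0.85)
})

test_that("classes below n_min are untestable rather than misjudged", {
  cs <- depth_case(rep(30L, 3), rep(30L, 3), rep(60L, 3), rep(0L, 3),
                   geno_f = rep(1L, 3), geno_m = rep(0L, 3))
  s <- depth_summary(cs$d, cs$g, cs$ph, "mk001")
  ct <- compensation_test(s, n_min = 5)
  expect_true(all(is.na(ct$ratios)))
  expect_identical(ct$dose_compensated, NA)
  expect_false(ct$testable)
})

test_that("sex depth ratio flags the printed female excess but not flat markers", {
  set.seed(71)
  dF <- as.integer(pmax(round(rnorm(162, 31.9, 14.1)), 0))
  dM <- as.integer(pmax(round(rnorm(103, 9.0, 5.3)), 0))
  cs <- depth_case(dF, rep(0L, 162), dM, rep(0L, 103))
  s <- depth_summary(cs$d, cs$g, cs$ph, "mk001")
  sr <- sex_depth_ratio(s)
  expect_gt(sr$ratio, 3)
  expect_true(sr$ratio_elevated)
  # textbook-like marker: near-equal means
  cs2 <- depth_case(rep(60L, 20), rep(0L, 20), rep(61L, 20), rep(0L, 20))
  s2 <- depth_summary(cs2$d, cs2$g, cs2$ph, "mk001")
  sr2 <- sex_depth_ratio(s2)
  expect_lt(abs(sr2$ratio - 1), 0.05)
  expect_false(sr2$ratio_elevated)
  # all-zero males: undefined ratio, flagged male-null
  cs3 <- depth_case(rep(10L, 6), rep(0L, 6), rep(0L, 6), rep(0L, 6))
  sr3 <- sex_depth_ratio(depth_summary(cs3$d, cs3$g, cs3$ph, "mk001"))
  expect_true(is.na(sr3$ratio))
  expect_true(sr3$male_null)
})

test_that("extra-copy estimate is ratio - 1, floored, with a seeded bootstrap", {
  cs <- depth_case(rep(319L, 30), rep(0L, 30), rep(90L, 30), rep(0L, 30))
  s <- depth_summary(cs$d, cs$g, cs$ph, "mk001")
  ec <- estimate_extra_copies(s, seed = 9)
  expect_equal(ec$estimate, 319 / 90 - 1, tolerance = 1e-12)
  ec2 <- estimate_extra_copies(s, seed = 9)
  expect_identical(ec$ci, ec2$ci)  # reproducible bootstrap
  # equal depths: estimate 0
  cs2 <- depth_case(rep(10L, 10), rep(0L, 10), rep(10L, 10), rep(0L, 10))
  s2 <- depth_summary(cs2$d, cs2$g, cs2$ph, "mk001")
  expect_equal(estimate_extra_copies(s2, seed = 1)$estimate, 0)
})

test_that("simulated extra copies are recovered and estimates are depth-scale-free", {
  ests <- vapply(c(10, 20), function(mu) {
    pop <- small_pop(seed = 73, n_accessions = 265, n_autosomal = 5,
                     n_w_strict = 0, n_w_partial = 0, n_z_poly = 0,
                     n_paralog_tags = 3, extra_w_copies = 2, mean_depth = mu)
    g <- call_genotypes(pop$depths)
    par <- pop$truth$marker_id[pop$truth$class_label == "paralog_collapsed"]
    mean(vapply(par, function(mk)
      dosage_report(pop$depths, g, pop$phenotypes, mk)$extra_copies$estimate,
      0))
  }, 0)
  expect_true(all(abs(ests - 2) < 0.5))
  expect_lt(abs(ests[1] - ests[2]), 0.3)
})

test_that("paralog flagging separates simulated paralog tags from textbook markers", {
  pop <- small_pop(seed = 79, n_accessions = 265, n_autosomal = 200,
                   n_w_strict = 0, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 3, extra_w_copies = 2, mean_depth = 20,
                   missing_rate = 0)
  g <- call_genotypes(pop$depths)
  tb <- suppressWarnings(identify_textbook_markers(g))
  expect_gt(length(tb), 20)
  par <- pop$truth$marker_id[pop$truth$class_label == "paralog_collapsed"]
  fl <- flag_paralog_suspects(pop$depths, g, pop$phenotypes,
                              markers = c(par, tb), textbook = tb)
  expect_true(all(fl$paralog_suspect[fl$marker_id %in% par]))
  expect_true(all(grepl("ratio_elevated",
                        fl$reasons[fl$marker_id %in% par])))
  expect_false(any(fl$paralog_suspect[fl$marker_id %in% tb]))
})

test_that("a compensation-only violation is flagged with that single reason", {
  # similar totals between sexes, but the hets' common-allele depth is
  # nowhere near half the homozygotes' (partial null allele)
  n <- 12
  cs <- depth_case(rep(55L, n), rep(25L, n), rep(60L, n), rep(0L, n),
                   geno_f = rep(1L, n), geno_m = rep(0L, n))
  fl <- flag_paralog_suspects(cs$d, cs$g, cs$ph, markers = "mk001",
                              textbook = character(0)) |> suppressWarnings()
  expect_true(fl$paralog_suspect)
  expect_identical(fl$reasons, "compensation_violated")
})

test_that("depth histograms bin accessions into 10-read classes", {
  cs <- depth_case(c(5L, 15L, 25L, 25L), rep(0L, 4), c(5L, 35L), rep(0L, 2))
  h <- depth_histogram(cs$d, cs$g, cs$ph, "mk001", allele = "ref", by = "sex",
                       bin_width = 10)
  expect_identical(h$n[h$group == "F" & h$depth_bin == 20], 2L)
  expect_equal(sort(unique(h$depth_bin)), c(0, 10, 20, 30))
})
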