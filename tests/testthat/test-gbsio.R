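test_that("genotype calling follows the depth threshold and the ML rule", {
  d <- allele_depths(
    ref = matrix(c(4L, 10L, 5L, 0L, 3L), 1),
    alt = matrix(c(0L, 0L, 5L, 12L, 3L), 1),
    markers = data.frame(id = paste0("m", 1:5), chrom = "01",
                         pos = 1:5 * 10L, ref = "A", alt = "G"),
    accessions = "s1")
  g <- call_genotypes(d, error_rate = 0.01, min_depth = 5)$geno
  expect_identical(g[1, ], c(m1 = NA_integer_,  # depth 4 < 5
                             m2 = 0L,           # 10 ref reads
                             m3 = 1L,           # balanced
                             m4 = 2L,           # 12 alt reads
                             m5 = 1L))          # 3+3 passes min, balanced
})

test_that("the called genotype maximises the hand-computed binomial likelihood", {
  e <- 0.05
  lik <- function(r, a) c(hom_ref = (1 - e)^r * e^a,
                          het = 0.5^(r + a),
                          hom_alt = e^r * (1 - e)^a)
  grid <- expand.grid(r = 0:12, a = 0:12)
  grid <- grid[grid$r + grid$a >= 5, ]
  d <- allele_depths(
    ref = matrix(grid$r, 1), alt = matrix(grid$a, 1),
    markers = data.frame(id = sprintf("m%03d", seq_len(nrow(grid))),
                         chrom = "01", pos = seq_len(nrow(grid)),
                         ref = "A", alt = "G"),
    accessions = "s1")
  called <- call_genotypes(d, error_rate = e, min_depth = 5)$geno[1, ]
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    l <- lik(grid$r[i], grid$a[i])
    # ties go to the heterozygote
    if (l["het"] >= max(l)) 1L else c(0L, 1L, 2L)[which.max(l)]
  }, 0L)
  expect_identical(unname(called), expected)
})

test_that("calling is monotone in the added allele's reads", {
  for (e in c(0.01, 0.1)) {
    for (r in 0:10) for (a in 0:10) {
      if (r + a < 5 || r + a + 1 < 5) next
      d2 <- allele_depths(
        ref = matrix(c(r, r + 1L), 1), alt = matrix(c(a, a), 1),
        markers = data.frame(id = c("x", "y"), chrom = "01", pos = 1:2,
                             ref = "A", alt = "G"),
        accessions = "s1")
      g <- call_genotypes(d2, error_rate = e, min_depth = 0)$geno
      # one more ref read can only move the call toward hom_ref
      expect_lte(g[1, "y"], g[1, "x"])
    }
  }
})

test_that("error-free deep data recovers the simulated genotypes exactly", {
  pop <- small_pop(seed = 17, error_rate = 0, missing_rate = 0,
                   mean_depth = 40)
  g <- call_genotypes(pop$depths, error_rate = 0.01)
  std <- pop$truth$class_label != "paralog_collapsed"
  called <- g$geno[, std]
  truth <- pop$true_geno[, std]
  deep <- total_depth(pop$depths)[, std] >= 5
  expect_true(all(called[deep] == truth[deep]))
})

test_that("association filter enforces its call-rate and MAF cutoffs strictly", {
  # 100 accessions; columns designed around the 75% / 5% boundaries
  g <- matrix(NA_integer_, 100, 4)
  g[1:74, 1] <- 1L                     # call rate 0.74 -> removed
  g[1:75, 2] <- rep(c(0L, 1L), c(30, 45))  # call rate 0.75, MAF 0.3 -> kept
  g[, 3] <- rep(c(1L, 0L), c(10, 90))  # MAF exactly 0.05 -> removed (strict >)
  g[, 4] <- 0L                         # monomorphic -> removed
  gc <- make_geno(g)
  out <- filter_assoc_markers(gc)
  expect_identical(out$markers$id, "mk002")
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_removed_call_rate, 1)
  expect_equal(rep$n_removed_maf, 2)
  expect_equal(rep$n_out, 1)
})

test_that("kinship filter uses 95% completeness and MAF >= 1%", {
  g <- matrix(0L, 100, 3)
  g[1:94, 1] <- 1L; g[95:100, 1] <- NA_integer_   # call rate 0.94 -> removed
  g[, 2] <- rep(c(1L, 0L), c(2, 98))              # MAF exactly 0.01 -> kept
  g[, 3] <- rep(c(0L, 1L, 2L), c(25, 50, 25))     # common, complete -> kept
  out <- filter_kinship_markers(make_geno(g))
  expect_identical(out$markers$id, c("mk002", "mk003"))
})

test_that("filters are idempotent", {
  pop <- small_pop(seed = 19)
  g <- call_genotypes(pop$depths)
  once <- filter_assoc_markers(g)
  twice <- filter_assoc_markers(once)
  expect_identical(once$geno, twice$geno)
  expect_identical(once$markers, twice$markers)
  k1 <- filter_kinship_markers(g)
  k2 <- filter_kinship_markers(k1)
  expect_identical(k1$geno, k2$geno)
})

test_that("VCF writing and reading round-trips the simulator output", {
  pop <- small_pop(seed = 23, n_accessions = 10, n_autosomal = 8,
                   n_w_strict = 1, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 1)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pop$depths, f, genotypes = call_genotypes(pop$depths))
  back <- read_vcf_depths(f)
  expect_identical(pop$depths$ref, back$ref)
  expect_identical(pop$depths$alt, back$alt)
  expect_identical(pop$depths$markers$id, back$markers$id)
  expect_identical(as.integer(pop$depths$markers$pos),
                   as.integer(back$markers$pos))
})

test_that("missing AD entries become (0,0) and multi-allelic records are skipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT:AD\t0/0:9,1\t./.:.\t0/1:5,6",
    "1\t200\tm2\tA\tG,T\t.\tPASS\t.\tGT:AD\t0/0:9,1,0\t0/1:5,5,1\t./.:.",
    "1\t300\tm3\tC\tT\t.\tPASS\t.\tGT:AD\t1/1:0,12\t0/0:7,0\t0/1:4,4"), f)
  d <- suppressMessages(read_vcf_depths(f))
  expect_identical(d$markers$id, c("m1", "m3"))
  expect_identical(attr(d, "n_multiallelic_skipped"), 1L)
  expect_identical(unname(d$ref[, "m1"]), c(9L, 0L, 5L))
  expect_identical(unname(d$alt[, "m1"]), c(1L, 0L, 6L))
  d2 <- read_vcf_depths(f, split_multiallelic = TRUE)
  expect_equal(ncol(d2$ref), 4)
})

test_that("phenotype IO validates sexes and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ph <- make_phen(c("a1", "a2", "a3"), 2)
  write_phenotypes(ph, f)
  back <- read_phenotypes(f)
  expect_identical(back$accession, ph$accession)
  expect_identical(back$sex, ph$sex)
  writeLines("accession\tsex\na1\tfemale", f)
  expect_error(read_phenotypes(f), "F/M/unknown")
})
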