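test_that("sex-genotype tables count sexed, called accessions per class", {
  g <- make_geno(matrix(c(1L, 1L, 0L, 0L), 4, 1))
  rownames(g$geno) <- paste0("a", 1:4)
  ph <- make_phen(paste0("a", 1:4), 2)
  tab <- sex_genotype_table(g, ph, "mk001")
  expect_identical(tab, rbind(F = c(hom_a = 0L, het = 2L),
                              M = c(hom_a = 2L, het = 0L)))
  ph$sex[] <- "unknown"
  expect_null(suppressMessages(sex_genotype_table(g, ph, "mk001")))
})

test_that("the exact test returns 1 for independent or degenerate tables", {
  expect_equal(fisher_exact_rc(matrix(c(10, 10, 10, 10), 2, 2)), 1)
  expect_equal(fisher_exact_rc(matrix(c(0, 0, 3, 4), 2, 2)), 1)  # zero column
  expect_equal(fisher_exact_rc(matrix(c(0, 5, 0, 7), 2, 2, byrow = TRUE)), 1)
})

test_that("the exact test matches enumeration oracles on random and extreme tables", {
  set.seed(42)
  for (i in 1:300) {
    nc <- sample(2:3, 1)
    tab <- matrix(rpois(2 * nc, sample(1:8, 1)), 2, nc)
    expect_equal(fisher_exact_rc(tab), oracle_fisher(tab), tolerance = 1e-10)
  }
  # 2x2 against stats::dhyper tail summation
  dhyper_oracle <- function(tab) {
    m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
    xs <- max(0, k - n):min(k, m)
    d <- dhyper(xs, m, n, k)
    sum(d[d <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-9)])
  }
  set.seed(7)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 8), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rc(tab), dhyper_oracle(tab), tolerance = 1e-10)
  }
  # near-perfect sex segregation at study scale: p far below 1e-50,
  # still matching the oracle in log space
  big <- rbind(F = c(3, 159), M = c(101, 2))
  p <- fisher_exact_rc(big)
  expect_lt(p, 1e-50)
  expect_equal(p, dhyper_oracle(big), tolerance = 1e-9)
})

test_that("full sweep of small 2x3 tables agrees with the enumeration oracle", {
  for (n in 3:12) {
    for (r1 in 0:n) for (c1 in 1:(n - 2)) for (c2 in 1:(n - 1 - c1)) {
      c3 <- n - c1 - c2
      for (x1 in 0:min(r1, c1)) {
        lo <- max(0, r1 - x1 - c3); hi <- min(r1 - x1, c2)
        if (hi < lo) next
        for (x2 in lo:hi) {
          row1 <- c(x1, x2, r1 - x1 - x2)
          tab <- rbind(row1, c(c1, c2, c3) - row1)
          expect_equal(fisher_exact_rc(tab), oracle_fisher(tab),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("Bonferroni threshold and flags behave", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(19592), 0.05 / 19592)
  p <- c(1e-8, 2e-6, 0.01)
  sig_strict <- p < bonferroni_threshold(1000, 0.05)
  sig_looser <- p < bonferroni_threshold(1000, 0.01)
  expect_true(all(which(sig_looser) %in% which(sig_strict)))
})

test_that("kinship matrix is symmetric, PSD, unit mean diagonal, and groups duplicates", {
  pop <- small_pop(seed = 31, n_accessions = 100, n_autosomal = 400,
                   n_w_strict = 0, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 0)
  g <- suppressWarnings(filter_kinship_markers(call_genotypes(pop$depths)))
  K <- compute_kinship(g)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 1e-8)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # unrelated accessions: off-diagonal mean near 0
  expect_lt(abs(mean(K[upper.tri(K)])), 0.05)
  # duplicated genotype rows are maximally related
  gd <- make_geno(rbind(g$geno[1, ], g$geno[1, ], g$geno[2:10, ]))
  rownames(gd$geno) <- paste0("a", 1:11)
  Kd <- compute_kinship(gd, bend = FALSE)
  expect_equal(Kd[1, 2], Kd[1, 1], tolerance = 1e-12)
})

test_that("structure components separate simulated subpopulations and are orthogonal", {
  pop <- small_pop(seed = 37, n_accessions = 120, n_autosomal = 300,
                   n_w_strict = 0, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 0, n_subpops = 2,
                   fst_like_divergence = 0.25)
  g <- call_genotypes(pop$depths)
  Q <- structure_components(g, q = 2)
  expect_identical(colnames(Q), c("intercept", "PC1", "PC2"))
  grp <- as.numeric(factor(pop$phenotypes$subpop))
  expect_gt(abs(cor(Q[, "PC1"], grp)), 0.9)
  cp <- crossprod(Q)
  expect_equal(cp[1, 2], 0, tolerance = 1e-6)
  expect_equal(cp[2, 3], 0, tolerance = 1e-6)
  # q = 0 gives the intercept only; q too large errors
  expect_identical(ncol(structure_components(g, q = 0)), 1L)
  expect_error(structure_components(g, q = 120), "smaller")
})

test_that("with identity kinship the MLM reduces to single-marker OLS", {
  set.seed(5)
  n <- 40
  g <- make_geno(matrix(rbinom(n * 12, 2, 0.3), n))
  rownames(g$geno) <- paste0("a", 1:n)
  ph <- make_phen(paste0("a", 1:n), 22)
  K <- diag(n); dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  ms <- mlm_scan(g, ph, K)
  y <- as.numeric(ph$sex == "F")
  p_ols <- vapply(seq_len(12), function(j) {
    x <- g$geno[, j]
    if (var(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients["x", 4]
  }, 0)
  expect_equal(ms$p_mlm, p_ols, tolerance = 1e-9)
})

test_that("per-marker REML optimum matches a dense grid-search oracle", {
  # two clonal-like families whose membership partly predicts sex, so the
  # polygenic variance ratio has a genuine interior optimum
  n <- 8
  K <- kronecker(diag(2), matrix(0.8, 4, 4)); diag(K) <- 1
  dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  y01 <- c(1, 1, 1, 0, 0, 0, 0, 1)
  x <- c(0, 1, 2, 1, 0, 2, 1, 0)
  ph <- data.frame(accession = paste0("a", 1:n),
                   sex = ifelse(y01 == 1, "F", "M"), subpop = NA)
  g <- make_geno(matrix(x, n)); rownames(g$geno) <- paste0("a", 1:n)
  ms <- mlm_scan(g, ph, K)
  # independent oracle: profile the REML criterion on a dense grid using
  # direct dense-matrix algebra (solve/determinant), no eigen shortcut
  y <- as.numeric(ph$sex == "F")
  X <- cbind(1, x)
  crit <- function(lambda) {
    V <- lambda * K + diag(n)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    (n - 2) * log(rss) + determinant(V)$modulus + determinant(XtVX)$modulus
  }
  grid <- exp(seq(log(1e-5), log(1e5), length.out = 8001))
  vals <- vapply(grid, crit, 0)
  lam_star <- grid[which.min(vals)]
  expect_gt(lam_star, grid[2]); expect_lt(lam_star, grid[8000])
  # 3 significant figures on the variance ratio
  expect_equal(ms$lambda, lam_star, tolerance = 5e-3)
})

test_that("MLM type-I error is calibrated on a null simulation", {
  pop <- small_pop(seed = 41, n_accessions = 120, n_autosomal = 250,
                   n_w_strict = 0, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 0)
  g <- suppressWarnings(filter_assoc_markers(call_genotypes(pop$depths)))
  K <- compute_kinship(g)
  ms <- suppressMessages(mlm_scan(g, pop$phenotypes, K))
  rate <- mean(ms$p_mlm < 0.05, na.rm = TRUE)
  m <- sum(!is.na(ms$p_mlm))
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / m) + 0.01)
})

test_that("gwas_sex recovers simulated W-linked markers at the top ranks", {
  pop <- small_pop(seed = 43, n_accessions = 150, n_autosomal = 300,
                   n_w_strict = 5, n_w_partial = 0, n_z_poly = 0,
                   n_paralog_tags = 0)
  g <- suppressWarnings(filter_assoc_markers(call_genotypes(pop$depths)))
  gw <- suppressMessages(gwas_sex(g, pop$phenotypes, mlm = TRUE))
  w <- pop$truth$marker_id[pop$truth$class_label == "w_strict"]
  expect_setequal(gw$results$marker_id[1:5], w)
  expect_true(all(gw$results$significant_fisher[1:5]))
  expect_lte(gw$n_agree, min(gw$n_sig_fisher, gw$n_sig_mlm))
})

test_that("Fisher and MLM rank sex-linked markers concordantly", {
  # kinship needs enough autosomal markers that the sex-linked minority
  # does not contaminate the polygenic term (see the methods vignette)
  ps_f <- c(); ps_m <- c()
  for (s in 1:10) {
    pop <- small_pop(seed = 310 + s, n_accessions = 265, n_autosomal = 1200)
    g <- suppressWarnings(filter_assoc_markers(call_genotypes(pop$depths)))
    sd_ids <- intersect(
      pop$truth$marker_id[pop$truth$class_label != "autosomal"],
      g$markers$id)
    gw <- suppressMessages(gwas_sex(g, pop$phenotypes, mlm = TRUE))
    r <- gw$results[match(sd_ids, gw$results$marker_id), ]
    ps_f <- c(ps_f, r$p_fisher); ps_m <- c(ps_m, r$p_mlm)
  }
  ok <- !is.na(ps_m)
  expect_gt(cor(ps_f[ok], ps_m[ok], method = "spearman"), 0.8)
})

test_that("permuting sex labels destroys the top association", {
  pop <- small_pop(seed = 47, n_accessions = 100, n_autosomal = 150)
  g <- suppressWarnings(filter_assoc_markers(call_genotypes(pop$depths)))
  gw <- gwas_sex(g, pop$phenotypes, mlm = FALSE)
  top <- gw$results$marker_id[1]
  set.seed(123)
  perm_p <- replicate(20, {
    ph <- pop$phenotypes
    ph$sex <- sample(ph$sex)
    fisher_exact_rc(sex_genotype_table(g, ph, top))
  })
  expect_gt(median(perm_p), 0.01)
})
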