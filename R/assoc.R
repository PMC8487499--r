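#' Sex-by-genotype contingency table for one marker
#'
#' Counts sexed, genotyped accessions per genotype class. Genotype
#' columns are labelled in the rare-allele (b) orientation — `hom_a`,
#' `het`, `hom_b` — with b determined per marker by [marker_b_allele].
#' Unknown-sex and uncalled accessions are excluded and empty genotype
#' columns dropped.
#'
#' @param g A [genotype_calls] object.
#' @param phenotypes Phenotype `data.frame` (see [read_phenotypes]).
#' @param marker Marker id.
#' @return Integer matrix with rows `F`, `M`, or `NULL` (with a message)
#'   if no sexed accession has a call.
#' @export
sex_genotype_table <- function(g, phenotypes, marker) {
  stopifnot(inherits(g, "genotype_calls"))
  j <- match(marker, g$markers$id)
  if (is.na(j)) stop("unknown marker id: ", marker)
  sex <- phenotypes$sex[match(rownames(g$geno), phenotypes$accession)]
  geno <- g$geno[, j]
  use <- sex %in% c("F", "M") & !is.na(geno)
  if (!any(use)) {
    message("sex_genotype_table: no sexed, genotyped accessions for ", marker)
    return(NULL)
  }
  b <- marker_b_allele(subset_markers(g, j))[[1]]
  dose_b <- if (b == "alt") geno[use] else 2L - geno[use]
  tab <- table(factor(sex[use], levels = c("F", "M")),
               factor(dose_b, levels = 0:2))
  tab <- unclass(tab)
  dimnames(tab) <- list(c("F", "M"), c("hom_a", "het", "hom_b"))
  tab[, colSums(tab) > 0L, drop = FALSE]
}

#' Freeman-Halton exact test for a 2 x c contingency table
#'
#' Exact p-value for independence of the row and column classifications:
#' the sum, over all tables with the observed margins, of the
#' (multivariate hypergeometric) point probabilities not exceeding that of
#' the observed table. All point probabilities are handled in log space
#' (log-gamma factorials), so p-values far below double underflow of
#' intermediate factorials (e.g. 1e-70) are computed accurately. A
#' relative tolerance guards the "as or more extreme" comparison against
#' floating-point exclusion of tied tables.
#'
#' @param tab Integer matrix with 2 rows and 2 or 3 columns of
#'   non-negative counts.
#' @param rel_tol Relative tolerance when comparing point probabilities.
#' @return The exact p-value. Degenerate tables (a zero row or column
#'   margin after dropping empty columns) return 1 by convention.
#' @examples
#' fisher_exact_rc(matrix(c(10, 10, 10, 10), 2, 2))  # 1
#' fisher_exact_rc(rbind(F = c(3, 159), M = c(101, 2)))
#' @export
fisher_exact_rc <- function(tab, rel_tol = 1e-12) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || !(ncol(tab) %in% c(2L, 3L)))
    stop("fisher_exact_rc expects a 2 x 2 or 2 x 3 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers")
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || ncol(tab) < 2L || n == 0) return(1)
  r1 <- rs[1]
  lp_obs <- sum(lchoose(cs, tab[1, ])) - lchoose(n, r1)
  slack <- rel_tol * max(1, abs(lp_obs))
  if (ncol(tab) == 2L) {
    k <- max(0, r1 - cs[2]):min(r1, cs[1])
    lp <- lchoose(cs[1], k) + lchoose(cs[2], r1 - k) - lchoose(n, r1)
    keep <- lp <= lp_obs + slack
    lpk <- lp[keep]
  } else {
    lpk <- numeric(0)
    lc_n <- lchoose(n, r1)
    for (x1 in max(0, r1 - cs[2] - cs[3]):min(r1, cs[1])) {
      rem <- r1 - x1
      x2 <- max(0, rem - cs[3]):min(rem, cs[2])
      if (length(x2) == 0L || x2[1] > x2[length(x2)]) next
      lp <- lchoose(cs[1], x1) + lchoose(cs[2], x2) +
        lchoose(cs[3], rem - x2) - lc_n
      lpk <- c(lpk, lp[lp <= lp_obs + slack])
    }
  }
  mx <- max(lpk)
  p <- exp(mx + log(sum(exp(lpk - mx))))
  min(p, 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param m Number of tests (markers).
#' @param alpha Experiment-wise error rate.
#' @return The per-test threshold `alpha / m`; a p-value is declared
#'   significant when strictly below it.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

# mean-imputed alt-dosage matrix (used by kinship, PCA and the MLM)
.imputed_dosage <- function(g) {
  X <- g$geno
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[(idx - 1L) %/% nrow(X) + 1L]
  X
}

#' Realized-relationship (kinship) matrix from genotype dosages
#'
#' VanRaden-style centered cross-product of allele dosages,
#' `Z Z' / (2 * sum p (1 - p))` with `Z` the dosage matrix centred at
#' `2p`, rescaled so that the mean diagonal equals 1. Missing dosages are
#' mean-imputed for this computation only. The result is symmetric and,
#' after bending (flooring tiny negative eigenvalues), positive
#' semidefinite.
#'
#' @param g A [genotype_calls] object, typically pre-filtered with
#'   [filter_kinship_markers].
#' @param bend Floor negative eigenvalues at zero and reconstruct.
#' @return Square symmetric numeric matrix over accessions.
#' @export
compute_kinship <- function(g, bend = TRUE) {
  stopifnot(inherits(g, "genotype_calls"))
  if (ncol(g$geno) < 2L) stop("kinship needs at least 2 markers")
  X <- .imputed_dosage(g)
  p <- colMeans(X) / 2
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("kinship markers are monomorphic")
  K <- tcrossprod(Z) / denom
  K <- K / mean(diag(K))
  K <- (K + t(K)) / 2
  if (bend) {
    ev <- eigen(K, symmetric = TRUE)
    if (min(ev$values) < 0) {
      vals <- pmax(ev$values, 0)
      K <- ev$vectors %*% (vals * t(ev$vectors))
      K <- (K + t(K)) / 2
      K <- K / mean(diag(K))
    }
  }
  dimnames(K) <- list(rownames(g$geno), rownames(g$geno))
  K
}

#' Population-structure covariates from genotype principal components
#'
#' Top principal components of the centred, mean-imputed dosage matrix,
#' returned together with an intercept column; `q = 0` yields the
#' intercept only.
#'
#' @param g A [genotype_calls] object.
#' @param q Number of components (0 <= q < number of accessions).
#' @return Numeric matrix with `q + 1` columns (`intercept`, `PC1`, ...).
#' @export
structure_components <- function(g, q = 2) {
  stopifnot(inherits(g, "genotype_calls"))
  n <- nrow(g$geno)
  if (q < 0 || q != round(q)) stop("q must be a non-negative integer")
  if (q >= n) stop("q must be smaller than the number of accessions")
  out <- matrix(1, n, 1, dimnames = list(rownames(g$geno), "intercept"))
  if (q > 0) {
    X <- .imputed_dosage(g)
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    sc <- pc$x[, seq_len(min(q, ncol(pc$x))), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
    out <- cbind(out, sc)
  }
  out
}

# REML criterion (-2 * restricted log-likelihood up to a constant) for a
# variance ratio lambda = sigma2_g / sigma2_e, on eigen-rotated data.
.reml_crit <- function(log_lambda, ty, tX, d) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- tX * sw
  yw <- ty * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(tX)) return(Inf)
  rss <- sum(qr.resid(qrX, yw)^2)
  n <- length(ty); p <- ncol(tX)
  R <- qr.R(qrX)
  (n - p) * log(rss) - sum(log(w)) + 2 * sum(log(abs(diag(R))))
}

.mlm_fit_marker <- function(ty, tQ, tx, d, grid) {
  tX <- cbind(tQ, tx)
  crit <- vapply(grid, .reml_crit, 0, ty = ty, tX = tX, d = d)
  if (all(!is.finite(crit))) return(NULL)
  i <- which.min(crit)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- if (hi > lo)
    stats::optimize(.reml_crit, c(lo, hi), ty = ty, tX = tX, d = d,
                    tol = 1e-8)
  else list(minimum = grid[i])
  lambda <- exp(opt$minimum)
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  Xw <- tX * sw; yw <- ty * sw
  qrX <- qr(Xw)
  if (qrX$rank < ncol(tX)) return(NULL)
  n <- length(ty); p <- ncol(tX)
  beta <- qr.coef(qrX, yw)
  rss <- sum(qr.resid(qrX, yw)^2)
  sigma2e <- rss / (n - p)
  XtX_inv <- solve(crossprod(Xw))
  se <- sqrt(sigma2e * XtX_inv[p, p])
  Fstat <- (beta[p] / se)^2
  list(beta = unname(beta[p]), se = se, lambda = lambda,
       p = stats::pf(Fstat, 1, n - p, lower.tail = FALSE))
}

#' Single-marker mixed-linear-model association scan
#'
#' Fits, for each marker, `y = Q gamma + x beta + u + e` with
#' `u ~ N(0, sigma2_g K)` and `e ~ N(0, sigma2_e I)`, where `y` is sex
#' coded 0/1 (F = 1) treated as Gaussian (matching the behaviour of
#' standard MLM GWAS tools for binary traits), `Q` holds the structure
#' covariates and `K` the kinship matrix. One spectral decomposition of
#' `K` is shared across markers; the variance ratio
#' `lambda = sigma2_g / sigma2_e` is re-estimated for every marker by
#' REML (profiled over a bracketed log-scale grid, then refined by
#' golden-section/parabolic search). The reported p-value is a Wald
#' F-test on the marker effect. Missing dosages are mean-imputed per
#' marker; markers with a singular fixed-effect design are skipped.
#'
#' @param g A [genotype_calls] object (the markers to test).
#' @param phenotypes Phenotype `data.frame`; unknown-sex accessions are
#'   dropped from the model.
#' @param K Kinship matrix over (at least) the sexed accessions.
#' @param Q Covariate matrix incl. intercept (see
#'   [structure_components]); default intercept only.
#' @param grid_log_lambda Log-scale grid bracketing the REML optimum.
#' @return `data.frame(marker_id, beta, lambda, p_mlm)`; skipped markers
#'   carry `NA`.
#' @export
mlm_scan <- function(g, phenotypes, K, Q = NULL,
                     grid_log_lambda = log(10) * seq(-5, 5, by = 0.5)) {
  stopifnot(inherits(g, "genotype_calls"))
  acc <- rownames(g$geno)
  sex <- phenotypes$sex[match(acc, phenotypes$accession)]
  use <- sex %in% c("F", "M")
  if (sum(use) < 3L) stop("mlm_scan needs at least 3 sexed accessions")
  y <- as.numeric(sex[use] == "F")
  if (is.null(Q)) Q <- matrix(1, length(acc), 1,
                              dimnames = list(acc, "intercept"))
  if (!is.null(rownames(K))) K <- K[acc, acc, drop = FALSE]
  Ku <- K[use, use, drop = FALSE]
  Qu <- Q[use, , drop = FALSE]
  ev <- eigen((Ku + t(Ku)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  Ut <- t(ev$vectors)
  ty <- drop(Ut %*% y)
  tQ <- Ut %*% Qu
  X <- .imputed_dosage(g)[use, , drop = FALSE]
  tXall <- Ut %*% X
  res <- lapply(seq_len(ncol(X)), function(j) {
    if (stats::var(X[, j]) == 0) return(NULL)
    .mlm_fit_marker(ty, tQ, tXall[, j], d, grid_log_lambda)
  })
  skipped <- vapply(res, is.null, TRUE)
  if (any(skipped))
    message(sprintf("mlm_scan: skipped %d marker(s) with singular design",
                    sum(skipped)))
  data.frame(marker_id = g$markers$id,
             beta = vapply(res, function(r) if (is.null(r)) NA_real_ else r$beta, 0),
             lambda = vapply(res, function(r) if (is.null(r)) NA_real_ else r$lambda, 0),
             p_mlm = vapply(res, function(r) if (is.null(r)) NA_real_ else r$p, 0),
             stringsAsFactors = FALSE)
}

#' Fisher-test association scan
#'
#' Applies [fisher_exact_rc] to the sex-by-genotype table of every
#' marker.
#'
#' @inheritParams mlm_scan
#' @return `data.frame(marker_id, p_fisher)` plus the per-class counts
#'   (`nF_hom_a`, `nF_het`, `nF_hom_b`, `nM_hom_a`, ...).
#' @export
fisher_scan <- function(g, phenotypes) {
  stopifnot(inherits(g, "genotype_calls"))
  sex <- phenotypes$sex[match(rownames(g$geno), phenotypes$accession)]
  fem <- sex == "F" & !is.na(sex)
  mal <- sex == "M" & !is.na(sex)
  b <- marker_b_allele(g)
  count_geno <- function(rows, j) {
    geno <- g$geno[rows, j]
    dose <- if (b[[j]] == "alt") geno else 2L - geno
    tabulate(dose + 1L, nbins = 3L)
  }
  m <- ncol(g$geno)
  out <- data.frame(marker_id = g$markers$id,
                    nF_hom_a = 0L, nF_het = 0L, nF_hom_b = 0L,
                    nM_hom_a = 0L, nM_het = 0L, nM_hom_b = 0L,
                    p_fisher = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    cf <- count_geno(fem, j)
    cm <- count_geno(mal, j)
    out[j, 2:7] <- c(cf, cm)
    tab <- rbind(cf, cm)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (sum(cf) + sum(cm) == 0L || ncol(tab) < 2L) {
      out$p_fisher[j] <- 1
      next
    }
    out$p_fisher[j] <- fisher_exact_rc(tab)
  }
  out
}

#' Genome-wide association of sex
#'
#' Runs the Fisher exact-test scan and (optionally) the mixed-linear-model
#' scan on pre-filtered genotypes, flags Bonferroni significance for
#' each, and reports the agreement between methods.
#'
#' @param g [genotype_calls], typically from [filter_assoc_markers].
#' @param phenotypes Phenotype table.
#' @param alpha Experiment-wise error rate for the Bonferroni threshold.
#' @param mlm Run the MLM scan as well.
#' @param q_pcs Number of structure principal components for the MLM.
#' @param kinship_g Genotypes used to estimate kinship and structure;
#'   defaults to `filter_kinship_markers(g)`.
#' @return List with elements `results` (per-marker `data.frame` ranked
#'   by Fisher p, including chromosome/position, counts, p-values,
#'   significance flags and `rank`), `bonferroni` (threshold),
#'   `n_sig_fisher`, `n_sig_mlm`, `n_agree`.
#' @export
gwas_sex <- function(g, phenotypes, alpha = 0.05, mlm = TRUE, q_pcs = 2,
                     kinship_g = NULL) {
  stopifnot(inherits(g, "genotype_calls"))
  m <- ncol(g$geno)
  if (m < 1L) stop("no markers to test")
  thr <- bonferroni_threshold(m, alpha)
  fs <- fisher_scan(g, phenotypes)
  res <- cbind(fs[, "marker_id", drop = FALSE],
               chrom = g$markers$chrom, pos = g$markers$pos,
               fs[, -1])
  res$significant_fisher <- res$p_fisher < thr
  if (mlm) {
    if (is.null(kinship_g)) {
      kinship_g <- suppressWarnings(filter_kinship_markers(g))
      if (ncol(kinship_g$geno) < 2L) {
        message("gwas_sex: <2 markers pass the kinship filter; ",
                "estimating kinship from the association-filtered set")
        kinship_g <- g
      }
    }
    K <- compute_kinship(kinship_g)
    Q <- structure_components(kinship_g, q = q_pcs)
    ms <- mlm_scan(g, phenotypes, K, Q)
    res$p_mlm <- ms$p_mlm[match(res$marker_id, ms$marker_id)]
    res$significant_mlm <- !is.na(res$p_mlm) & res$p_mlm < thr
  } else {
    res$p_mlm <- NA_real_
    res$significant_mlm <- NA
  }
  ord <- order(res$p_fisher, res$marker_id)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  n_sig_f <- sum(res$significant_fisher)
  n_sig_m <- if (mlm) sum(res$significant_mlm) else NA_integer_
  n_agree <- if (mlm) sum(res$significant_fisher & res$significant_mlm)
             else NA_integer_
  list(results = res, bonferroni = thr, n_sig_fisher = n_sig_f,
       n_sig_mlm = n_sig_m, n_agree = n_agree)
}
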