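# Independent oracles and small builders shared across tests.

# Freeman-Halton p-value by direct enumeration in probability space
# (choose() products), independent of the package's log-space path.
oracle_fisher <- function(tab, tol = 1e-9) {
  tab <- as.matrix(tab)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || ncol(tab) < 2L || n == 0) return(1)
  r1 <- rs[1]
  if (ncol(tab) == 2L) {
    k <- max(0, r1 - cs[2]):min(r1, cs[1])
    xs <- cbind(k, r1 - k)
  } else {
    g <- expand.grid(x1 = 0:min(r1, cs[1]), x2 = 0:min(r1, cs[2]))
    x3 <- r1 - g$x1 - g$x2
    ok <- x3 >= 0 & x3 <= cs[3]
    xs <- cbind(g$x1[ok], g$x2[ok], x3[ok])
  }
  probs <- apply(xs, 1, function(x) prod(choose(cs, x)) / choose(n, r1))
  p0 <- prod(choose(cs, tab[1, ])) / choose(n, r1)
  min(sum(probs[probs <= p0 * (1 + tol)]), 1)
}

# genotype_calls object from a plain dosage matrix
make_geno <- function(geno, chrom = "01") {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  genotype_calls(geno, data.frame(id = sprintf("mk%03d", seq_len(m)),
                                  chrom = chrom, pos = seq_len(m) * 100L,
                                  ref = "A", alt = "G",
                                  stringsAsFactors = FALSE))
}

# phenotype table with the first n_f accessions female
make_phen <- function(accessions, n_f) {
  data.frame(accession = accessions,
             sex = rep(c("F", "M"), c(n_f, length(accessions) - n_f)),
             subpop = NA_character_, stringsAsFactors = FALSE)
}

# small default simulation for module tests
small_pop <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_accessions = 120, female_fraction = 0.6, n_autosomal = 150,
         n_w_strict = 3, n_w_partial = 2, n_z_poly = 2, n_paralog_tags = 2,
         mean_depth = 20, seed = seed), list(...))
  simulate_population(do.call(sim_config, args))
}
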