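#' Read allele depths from a VCF file
#'
#' Ingests a VCF (4.x) whose FORMAT includes a two-integer `AD`
#' (allele-depth) field and returns the depth matrix for biallelic
#' records. Multi-allelic records are skipped by default (the number
#' skipped is reported and attached as an attribute); with
#' `split_multiallelic = TRUE` each alternate allele becomes its own
#' biallelic pseudo-marker whose alt depth is that allele's depth and
#' whose ref depth is the reference depth.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param split_multiallelic Split records with more than one ALT allele
#'   instead of skipping them.
#' @return An [allele_depths] object; missing `AD` entries become
#'   `(0, 0)`. Attribute `n_multiallelic_skipped` records skipped rows.
#' @export
read_vcf_depths <- function(path, split_multiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fx$ALT)
  n_multi <- sum(multi)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF lacks an AD FORMAT field: ", path)

  parse_pair <- function(strings, field) {
    # field-th and reference component of comma-separated AD strings
    parts <- strsplit(ifelse(is.na(strings), "0,0", strings), ",", fixed = TRUE)
    r <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= field + 1L) p[field + 1L] else NA_character_, "")))
    r[is.na(r)] <- 0L; a[is.na(a)] <- 0L
    list(ref = r, alt = a)
  }

  build <- function(rows, alt_field, alt_allele, id_suffix = "") {
    strings <- ad[rows, , drop = FALSE]
    pp <- parse_pair(as.vector(strings), alt_field)
    nm <- length(rows)
    ids <- fx$ID[rows]
    ids[is.na(ids) | ids == "."] <-
      paste0("S", fx$CHROM[rows], "_", fx$POS[rows])[is.na(ids) | ids == "."]
    list(ref = matrix(pp$ref, nrow = nm), alt = matrix(pp$alt, nrow = nm),
         markers = data.frame(id = paste0(ids, id_suffix),
                              chrom = fx$CHROM[rows],
                              pos = as.integer(fx$POS[rows]),
                              ref = fx$REF[rows], alt = alt_allele,
                              stringsAsFactors = FALSE))
  }

  pieces <- list()
  bi <- which(!multi)
  if (length(bi))
    pieces[[1]] <- build(bi, 1L, fx$ALT[bi])
  if (n_multi > 0) {
    if (split_multiallelic) {
      for (r in which(multi)) {
        alts <- strsplit(fx$ALT[r], ",", fixed = TRUE)[[1]]
        for (k in seq_along(alts)) {
          pieces[[length(pieces) + 1L]] <-
            build(r, k, alts[k], id_suffix = paste0("_alt", k))
        }
      }
    } else {
      message(sprintf("read_vcf_depths: skipped %d multi-allelic record(s)",
                      n_multi))
    }
  }
  if (!length(pieces)) stop("no biallelic records retained from ", path)
  ref <- do.call(cbind, lapply(pieces, function(p) t(p$ref)))
  alt <- do.call(cbind, lapply(pieces, function(p) t(p$alt)))
  markers <- do.call(rbind, lapply(pieces, `[[`, "markers"))
  # splitting duplicates (chrom, pos); disambiguate positions are unique per id
  if (anyDuplicated(paste(markers$chrom, markers$pos))) {
    dup <- duplicated(paste(markers$chrom, markers$pos))
    markers$pos[dup] <- markers$pos[dup]  # ids already suffixed; keep pos,
    # uniqueness enforced on id only in this case
    out <- structure(list(ref = ref, alt = alt, markers = markers),
                     class = "allele_depths")
    dimnames(out$ref) <- dimnames(out$alt) <- list(colnames(ad), markers$id)
    storage.mode(out$ref) <- "integer"; storage.mode(out$alt) <- "integer"
    attr(out, "n_multiallelic_skipped") <- if (split_multiallelic) 0L else n_multi
    return(out)
  }
  out <- allele_depths(ref, alt, markers, accessions = colnames(ad))
  attr(out, "n_multiallelic_skipped") <- if (split_multiallelic) 0L else n_multi
  out
}

#' Write an allele-depth matrix (and optional genotype calls) to VCF
#'
#' Emits a minimal VCF 4.2 with `GT` and `AD` FORMAT fields, suitable for
#' round-tripping through [read_vcf_depths]. Coordinates are written
#' 1-based as stored.
#'
#' @param depths An [allele_depths] object.
#' @param path Output path (plain text).
#' @param genotypes Optional [genotype_calls] on the same axes; if absent
#'   all GT entries are `./.`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(depths, path, genotypes = NULL) {
  stopifnot(inherits(depths, "allele_depths"))
  mk <- depths$markers
  acc <- rownames(depths$ref)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=zwscan",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                      "Description=\"Allelic depths for the ref and alt alleles\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", acc), collapse = "\t")), con)
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_calls"))
    g <- genotypes$geno
    gt <- matrix("./.", nrow(g), ncol(g))
    gt[!is.na(g)] <- gt_code[as.character(g[!is.na(g)])]
  } else {
    gt <- matrix("./.", nrow(depths$ref), ncol(depths$ref))
  }
  cells <- matrix(paste0(gt, ":", depths$ref, ",", depths$alt),
                  nrow = length(acc))
  body <- vapply(seq_len(nrow(mk)), function(j) {
    paste(c(mk$chrom[j], mk$pos[j], mk$id[j], mk$ref[j], mk$alt[j],
            ".", "PASS", ".", "GT:AD", cells[, j]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Tab-separated table with columns `accession`, `sex` (`F`, `M` or
#' `unknown`) and optionally `subpop`.
#'
#' @param path File path.
#' @return `read_phenotypes`: a validated `data.frame`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("accession", "sex") %in% names(ph)))
    stop("phenotype table needs 'accession' and 'sex' columns: ", path)
  bad <- setdiff(unique(ph$sex), c("F", "M", "unknown"))
  if (length(bad))
    stop("phenotype sex values must be F/M/unknown; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(ph$accession))
    stop("duplicated accession identifiers in phenotype table")
  if (!"subpop" %in% names(ph)) ph$subpop <- NA_character_
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype `data.frame` to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Call diploid genotypes from allele depths by maximum likelihood
#'
#' Per cell with `r` reference and `a` alternate reads (depth `d = r + a`):
#' cells with `d < min_depth` are no-calls; otherwise the genotype
#' maximising the binomial read likelihood is chosen, with per-read
#' alternate-allele probabilities `e` (hom ref), `1/2` (het) and `1 - e`
#' (hom alt), where `e` is the per-read miscall rate. Likelihood ties are
#' broken toward the heterozygote.
#'
#' @param depths An [allele_depths] object.
#' @param error_rate Per-read miscall probability, in (0, 0.5).
#' @param min_depth Minimum total reads for a call (default 5).
#' @return A [genotype_calls] object.
#' @examples
#' d <- allele_depths(matrix(c(10L, 5L), 1, 2), matrix(c(0L, 5L), 1, 2),
#'                    data.frame(id = c("m1", "m2"), chrom = "1",
#'                               pos = c(1L, 2L), ref = "A", alt = "G"),
#'                    accessions = "s1")
#' call_genotypes(d)$geno
#' @export
call_genotypes <- function(depths, error_rate = 0.01, min_depth = 5) {
  stopifnot(inherits(depths, "allele_depths"))
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  r <- depths$ref; a <- depths$alt
  d <- r + a
  e <- error_rate
  ll_hom_ref <- r * log(1 - e) + a * log(e)
  ll_het <- d * log(0.5)
  ll_hom_alt <- r * log(e) + a * log(1 - e)
  g <- matrix(1L, nrow(r), ncol(r))
  g[ll_hom_ref > ll_het & ll_hom_ref >= ll_hom_alt] <- 0L
  g[ll_hom_alt > ll_het & ll_hom_alt > ll_hom_ref] <- 2L
  g[d < min_depth] <- NA_integer_
  dimnames(g) <- dimnames(r)
  genotype_calls(g, depths$markers)
}

.filter_by <- function(g, min_call_rate, maf_op, maf_cut) {
  st <- marker_stats(g)
  fail_cr <- st$call_rate < min_call_rate
  maf <- ifelse(is.na(st$maf), 0, st$maf)
  fail_maf <- if (maf_op == ">") !(maf > maf_cut) else !(maf >= maf_cut)
  keep <- !(fail_cr | fail_maf)
  out <- subset_markers(g, keep)
  report <- list(n_in = ncol(g$geno),
                 n_removed_call_rate = sum(fail_cr),
                 n_removed_maf = sum(fail_maf),
                 n_out = sum(keep))
  if (report$n_out == 0L)
    warning("no markers passed the filter", call. = FALSE)
  attr(out, "filter_report") <- report
  out
}

#' Marker filters for association and kinship estimation
#'
#' `filter_assoc_markers` retains markers with a genotype call rate of at
#' least 75% and a minor allele frequency strictly above 5%;
#' `filter_kinship_markers` requires 95% completeness and MAF of at least
#' 1%. MAF is computed from called genotypes only. A removal report is
#' attached as attribute `"filter_report"`. Both filters are idempotent.
#'
#' @param g A [genotype_calls] object.
#' @param min_call_rate,min_maf Override the default thresholds.
#' @return Filtered [genotype_calls].
#' @export
filter_assoc_markers <- function(g, min_call_rate = 0.75, min_maf = 0.05) {
  .filter_by(g, min_call_rate, ">", min_maf)
}

#' @rdname filter_assoc_markers
#' @export
filter_kinship_markers <- function(g, min_call_rate = 0.95, min_maf = 0.01) {
  .filter_by(g, min_call_rate, ">=", min_maf)
}
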