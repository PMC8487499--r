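#' Allele-depth matrix
#'
#' Container for per-(accession, marker) allele-specific read counts at
#' biallelic markers, the raw observable of a GBS experiment. Rows are
#' accessions, columns markers; each cell holds a (ref reads, alt reads)
#' pair stored as two integer matrices.
#'
#' @param ref,alt Integer matrices of reference / alternate allele read
#'   counts, accessions in rows, markers in columns.
#' @param markers `data.frame` with one row per marker and columns
#'   `id`, `chrom`, `pos`, `ref`, `alt` (allele strings).
#' @param accessions Character vector of accession identifiers; defaults
#'   to `rownames(ref)`.
#' @return An object of class `allele_depths` with elements `ref`, `alt`
#'   (integer matrices) and `markers`.
#' @examples
#' d <- allele_depths(matrix(5L, 2, 1), matrix(3L, 2, 1),
#'                    data.frame(id = "m1", chrom = "1", pos = 100L,
#'                               ref = "A", alt = "G"),
#'                    accessions = c("s1", "s2"))
#' total_depth(d)
#' @export
allele_depths <- function(ref, alt, markers, accessions = rownames(ref)) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (!identical(dim(ref), dim(alt)))
    stop("ref and alt depth matrices must have identical dimensions")
  if (nrow(markers) != ncol(ref))
    stop("markers table must have one row per depth-matrix column")
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("markers table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(accessions)) accessions <- paste0("acc", seq_len(nrow(ref)))
  if (anyNA(ref) || anyNA(alt) || any(ref < 0L) || any(alt < 0L))
    stop("allele depths must be non-negative integers")
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique")
  if (anyDuplicated(paste(markers$chrom, markers$pos)))
    stop("marker (chromosome, position) pairs must be unique")
  dimnames(ref) <- dimnames(alt) <- list(accessions, markers$id)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(list(ref = ref, alt = alt, markers = markers),
            class = "allele_depths")
}

#' @export
print.allele_depths <- function(x, ...) {
  cat(sprintf("<allele_depths> %d accessions x %d markers, mean depth %.1f\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' Total read depth per cell
#'
#' @param x An [allele_depths] object.
#' @return Integer matrix `ref + alt`.
#' @export
total_depth <- function(x) {
  stopifnot(inherits(x, "allele_depths"))
  x$ref + x$alt
}

#' Called-genotype matrix
#'
#' Diploid genotype calls on the same axes as an [allele_depths] object.
#' Genotypes are coded as the dosage of the alternate allele: 0 (hom ref),
#' 1 (het), 2 (hom alt), `NA` (no call). The rarer "b" allele used in
#' segregation summaries is derived per marker from the calls themselves
#' (see [marker_b_allele]).
#'
#' @param geno Integer matrix of alt-allele dosages (0/1/2/`NA`),
#'   accessions in rows, markers in columns.
#' @param markers Marker table as in [allele_depths].
#' @return Object of class `genotype_calls` with elements `geno`, `markers`.
#' @export
genotype_calls <- function(geno, markers) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(markers) != ncol(geno))
    stop("markers table must have one row per genotype-matrix column")
  if (any(geno < 0L | geno > 2L, na.rm = TRUE))
    stop("genotypes must be alt-allele dosages in {0, 1, 2} or NA")
  dimnames(geno) <- list(rownames(geno), markers$id)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(list(geno = geno, markers = markers), class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cr <- mean(!is.na(x$geno))
  cat(sprintf("<genotype_calls> %d accessions x %d markers, call rate %.1f%%\n",
              nrow(x$geno), ncol(x$geno), 100 * cr))
  invisible(x)
}

#' Subset markers of a depth or genotype container
#'
#' @param x An [allele_depths] or [genotype_calls] object.
#' @param keep Marker ids (character) or a logical/integer index over
#'   columns.
#' @return Object of the same class restricted to the selected markers,
#'   in the order given.
#' @export
subset_markers <- function(x, keep) {
  UseMethod("subset_markers")
}

.marker_index <- function(ids, keep) {
  if (is.character(keep)) {
    idx <- match(keep, ids)
    if (anyNA(idx)) stop("unknown marker id(s): ",
                         paste(keep[is.na(idx)], collapse = ", "))
    idx
  } else if (is.logical(keep)) {
    which(keep)
  } else as.integer(keep)
}

#' @export
subset_markers.allele_depths <- function(x, keep) {
  idx <- .marker_index(x$markers$id, keep)
  allele_depths(x$ref[, idx, drop = FALSE], x$alt[, idx, drop = FALSE],
                x$markers[idx, , drop = FALSE])
}

#' @export
subset_markers.genotype_calls <- function(x, keep) {
  idx <- .marker_index(x$markers$id, keep)
  genotype_calls(x$geno[, idx, drop = FALSE], x$markers[idx, , drop = FALSE])
}

#' Per-marker call rate and minor allele frequency
#'
#' Call rate is the fraction of accessions with a non-missing call; the
#' minor allele frequency is computed from called genotypes only, counting
#' two alleles per called diploid accession.
#'
#' @param g A [genotype_calls] object.
#' @return `data.frame` with columns `id`, `call_rate`, `maf`,
#'   `alt_freq`, `n_called`.
#' @export
marker_stats <- function(g) {
  stopifnot(inherits(g, "genotype_calls"))
  n_called <- colSums(!is.na(g$geno))
  alt_freq <- colMeans(g$geno, na.rm = TRUE) / 2
  alt_freq[n_called == 0L] <- NA_real_
  data.frame(id = g$markers$id,
             call_rate = n_called / nrow(g$geno),
             maf = pmin(alt_freq, 1 - alt_freq),
             alt_freq = alt_freq,
             n_called = n_called,
             stringsAsFactors = FALSE)
}

#' Rare-allele (b) designation per marker
#'
#' The rarer of the two alleles among called genotypes; ties and
#' all-missing markers default to the alternate allele so that the
#' designation is deterministic.
#'
#' @param g A [genotype_calls] object.
#' @return Character vector over markers, `"ref"` or `"alt"`.
#' @export
marker_b_allele <- function(g) {
  st <- marker_stats(g)
  out <- ifelse(!is.na(st$alt_freq) & st$alt_freq > 0.5, "ref", "alt")
  names(out) <- st$id
  out
}
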