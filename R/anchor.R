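#' Read a map-marker hit table
#'
#' Tab-separated table of linkage-map markers located within assembly
#' scaffolds, with columns `map_marker_id`, `scaffold`, `chromosome`,
#' `position_cM`, `evalue`.
#'
#' @param path File path.
#' @return `data.frame` of hits.
#' @export
read_map_hits <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("map_marker_id", "scaffold", "chromosome", "position_cM", "evalue")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("map-hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(h$evalue <= 0, na.rm = TRUE)) stop("e-values must be positive")
  h
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12-column BLAST tabular output: `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`. A header
#' line is optional.
#'
#' @param path File path.
#' @return `data.frame` with the 12 standard columns.
#' @export
read_blast_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- readLines(path, n = 1L)
  has_header <- grepl("qseqid", first, fixed = TRUE)
  h <- utils::read.table(path, header = has_header, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(h) != 12L)
    stop("expected 12 tab-separated columns (BLAST outfmt 6): ", path)
  names(h) <- cols
  if (any(h$evalue <= 0)) stop("e-values must be positive")
  h
}

# "Chr15W", "15Z", "chr05" -> "15", "15", "05"; used for conflict
# detection only — sub-labels are retained verbatim in reports.
.normalize_chrom <- function(x) {
  out <- toupper(as.character(x))
  out <- sub("^CHR", "", out)
  out <- sub("[WZ]$", "", out)
  out <- sub("^0+(?=[0-9])", "", out, perl = TRUE)
  out[out == ""] <- NA_character_
  out
}

#' Anchor one scaffold to a chromosome by map-marker majority vote
#'
#' Retains hits with `evalue < e_threshold`; the scaffold is assigned the
#' chromosome carrying a strict majority (> 50%) of retained hits, with
#' ties or no majority yielding `NA`. The centre position is the median
#' linkage-map position (cM) of the supporting hits.
#'
#' @param hits `data.frame` of map-marker hits for a single scaffold
#'   (see [read_map_hits]).
#' @param e_threshold Maximum e-value (strict) for a hit to count.
#' @return One-row `data.frame(scaffold, chromosome, center_cM,
#'   n_supporting, n_conflicting)`; all-`NA` assignment when no hit
#'   survives.
#' @export
anchor_scaffold <- function(hits, e_threshold = 1e-10) {
  scaffold <- if (nrow(hits)) as.character(hits$scaffold[1]) else NA_character_
  if (nrow(hits) && length(unique(hits$scaffold)) > 1L)
    stop("anchor_scaffold expects hits for a single scaffold")
  keep <- hits[!is.na(hits$evalue) & hits$evalue < e_threshold &
                 !is.na(hits$chromosome), , drop = FALSE]
  empty <- data.frame(scaffold = scaffold, chromosome = NA_character_,
                      center_cM = NA_real_, n_supporting = 0L,
                      n_conflicting = 0L, stringsAsFactors = FALSE)
  if (nrow(keep) == 0L) return(empty)
  tal <- sort(table(keep$chromosome), decreasing = TRUE)
  if (tal[1] * 2L <= nrow(keep)) {  # no strict majority (incl. ties)
    empty$n_conflicting <- nrow(keep)
    return(empty)
  }
  chr <- names(tal)[1]
  sup <- keep$chromosome == chr
  data.frame(scaffold = scaffold, chromosome = chr,
             center_cM = stats::median(keep$position_cM[sup], na.rm = TRUE),
             n_supporting = sum(sup), n_conflicting = sum(!sup),
             stringsAsFactors = FALSE)
}

#' Anchor many scaffolds at once
#'
#' @param hits Map-marker hits for any number of scaffolds.
#' @param e_threshold See [anchor_scaffold].
#' @return `data.frame` with one row per scaffold present in `hits`.
#' @export
anchor_scaffolds <- function(hits, e_threshold = 1e-10) {
  out <- do.call(rbind, lapply(split(hits, hits$scaffold), anchor_scaffold,
                               e_threshold = e_threshold))
  rownames(out) <- NULL
  out
}

#' Detect conflicts between linkage-map and external chromosome
#' assignments
#'
#' Compares each scaffold's linkage-map chromosome with an assignment
#' from a second reference (e.g. alignment to another species' genome).
#' W/Z sub-labels are collapsed to the chromosome number before
#' comparison ("Chr15W" agrees with "15"), but reported verbatim.
#'
#' @param anchors `data.frame` with columns `scaffold`, `chromosome`
#'   (linkage map) and `external_chromosome`.
#' @return Subset of rows where both assignments are present and
#'   disagree.
#' @export
detect_anchor_conflicts <- function(anchors) {
  a <- .normalize_chrom(anchors$chromosome)
  b <- .normalize_chrom(anchors$external_chromosome)
  conflict <- !is.na(a) & !is.na(b) & a != b
  out <- anchors[conflict, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reference copies of a sequence tag from alignment hits
#'
#' Counts alignment hits passing an e-value threshold for one query tag
#' and summarises them per target scaffold; more than one passing hit
#' indicates multiple genomic copies of the tag in the reference.
#'
#' @param hits BLAST-style hits for a single query (see
#'   [read_blast_hits]).
#' @param e_threshold Hits with `evalue < e_threshold` are counted
#'   (strict, matching the usual "e-value < x" reporting convention).
#'   A "high-confidence" count keeping only hits whose e-value exponent
#'   is at most -17 corresponds to `e_threshold = 1e-16`.
#' @return List `n_copies`, `multi_copy`, `by_scaffold`
#'   (`data.frame(scaffold, n_hits)`), `tandem_scaffolds` (scaffolds with
#'   more than one hit).
#' @export
count_tag_copies <- function(hits, e_threshold = 0.05) {
  if (nrow(hits) && length(unique(hits$qseqid)) > 1L)
    stop("count_tag_copies expects hits for a single query tag")
  keep <- hits[hits$evalue < e_threshold, , drop = FALSE]
  n <- nrow(keep)
  by_sc <- if (n) {
    tt <- table(keep$sseqid)
    data.frame(scaffold = names(tt), n_hits = as.integer(tt),
               stringsAsFactors = FALSE)
  } else data.frame(scaffold = character(0), n_hits = integer(0))
  list(n_copies = n, multi_copy = n > 1L, by_scaffold = by_sc,
       tandem_scaffolds = by_sc$scaffold[by_sc$n_hits > 1L])
}

#' Combine copy counts, dosage evidence and anchoring into a
#' sex-specific copy-number verdict
#'
#' Decides whether a sequence tag behaves as a single locus shared by the
#' sexes or as a female-specific multicopy (hemizygous W-linked) element.
#' The female-specific verdict requires (i) more than one reference copy
#' in a female-derived assembly, (ii) an elevated female:male depth
#' ratio, and (iii) agreement (within `tol`) between the depth-based
#' extra-copy estimate and the number of reference copies on scaffolds
#' anchored to the sex-determining chromosome by the linkage map —
#' external-only (unanchored) copies are treated as supporting but not
#' decisive.
#'
#' @param copies Output of [count_tag_copies].
#' @param dosage A `dosage_report` (or a list with `sex_ratio` and
#'   `extra_copies` components) for the tag's marker.
#' @param anchors Scaffold anchor table with columns `scaffold`,
#'   `chromosome` (linkage map).
#' @param sd_chromosome Chromosome label of the sex-determining region
#'   (compared after W/Z collapse).
#' @param tol Tolerance for the copy-count agreement.
#' @return List `verdict` (`"female_specific_multicopy"`,
#'   `"shared_single_locus"` or `"unresolved"`), `n_copies`,
#'   `n_sd_copies` (copies on linkage-anchored SD-chromosome scaffolds),
#'   `extra_copy_estimate`, `reasons`.
#' @export
sex_specific_copy_model <- function(copies, dosage, anchors,
                                    sd_chromosome = "15", tol = 1) {
  est <- if (!is.null(dosage$extra_copies)) dosage$extra_copies$estimate
         else NA_real_
  elevated <- isTRUE(dosage$sex_ratio$ratio_elevated)
  sd_norm <- .normalize_chrom(sd_chromosome)
  anch_chr <- .normalize_chrom(anchors$chromosome)
  sd_scaffolds <- anchors$scaffold[!is.na(anch_chr) & anch_chr == sd_norm]
  n_sd <- sum(copies$by_scaffold$n_hits[
    copies$by_scaffold$scaffold %in% sd_scaffolds])
  reasons <- character(0)
  verdict <- "unresolved"
  if (copies$n_copies > 1L && elevated && !is.na(est) &&
      abs(est - n_sd) <= tol) {
    verdict <- "female_specific_multicopy"
  } else if (copies$n_copies == 1L && !elevated &&
             !isTRUE(dosage$compensation$dose_compensated == FALSE)) {
    verdict <- "shared_single_locus"
  } else {
    if (copies$n_copies > 1L && !elevated)
      reasons <- c(reasons, "multiple reference copies without depth elevation")
    if (copies$n_copies == 1L && elevated)
      reasons <- c(reasons, "depth elevation without extra reference copies")
    if (copies$n_copies > 1L && elevated && (is.na(est) ||
                                             abs(est - n_sd) > tol))
      reasons <- c(reasons,
                   "extra-copy estimate disagrees with anchored copy count")
  }
  list(verdict = verdict, n_copies = copies$n_copies, n_sd_copies = n_sd,
       extra_copy_estimate = est, reasons = reasons)
}
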