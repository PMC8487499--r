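#' Published scaffold anchoring table for the S. viminalis
#' sex-determination study region
#'
#' The published characteristics of the 20 *Salix viminalis* genome
#' scaffolds relevant to sex association: the 19 scaffolds carrying
#' Bonferroni-significant sex-associated markers plus scaffold 1112,
#' which harbours the secondary alignment hit of the top-ranking marker
#' tag. Columns give the chromosome assigned by linkage-map markers
#' (majority vote), the centre linkage-map position for chromosome-15
#' scaffolds, the chromosome assigned by alignment to the *S. purpurea*
#' v5.1 genome, and the number of sex-associated markers per scaffold
#' (summing to 48).
#'
#' @return `data.frame(scaffold, length_bp, chromosome, center_cM,
#'   external_chromosome, n_sa_markers)`.
#' @export
sdlocus_scaffold_table <- function() {
  data.frame(
    scaffold = c("0702", "0535", "1391", "1541", "1658", "0302", "0724",
                 "1236", "0779", "1114", "1491", "1649", "1730", "1839",
                 "2018", "2040", "2041", "1732", "2218", "1112"),
    length_bp = c(768110L, 622702L, 539124L, 2553872L, 116437L, 814410L,
                  541616L, 355459L, 3309791L, 392477L, 291271L, 120404L,
                  2005520L, 54690L, 1314944L, 3822569L, 1625512L, 6877L,
                  1126343L, 7166859L),
    chromosome = c("Chr15", "Chr15", "Chr15", "Chr15", NA, "Chr15", NA,
                   "Chr15", "Chr05", NA, NA, NA, "Chr14", NA, "Chr11",
                   "Chr02", "Chr17", NA, "Chr14", "Chr09"),
    center_cM = c(69.0, 57.2, 70.4, 68.0, NA, 58.0, NA, 67.6, NA, NA, NA,
                  NA, NA, NA, NA, NA, NA, NA, NA, NA),
    external_chromosome = c("Chr15W", "Chr15W", "Chr15W", "Chr15W", NA,
                            "Chr15W", "Chr15W", "Chr15W", "Chr15W",
                            "Chr15W", "Chr16", NA, "Chr14", NA, "Chr11",
                            "Chr02", "Chr17", NA, "Chr14", "Chr09"),
    n_sa_markers = c(10L, 9L, 5L, 4L, 3L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L,
                     1L, 1L, 1L, 1L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
}

#' Published alignment hits of the top sex-associated sequence tag
#'
#' The five reference-assembly alignment hits (e-value < 0.05) of the
#' GBS sequence tag harbouring the two most significant sex-associated
#' markers, in BLAST outfmt-6-style columns: three hits on scaffold 0535
#' (chromosome 15), one on 1114 (unanchored by the linkage map) and one
#' on 1112 (chromosome 9).
#'
#' @return 12-column `data.frame` in `qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore` order.
#' @export
sdlocus_tag_hits <- function() {
  data.frame(
    qseqid = "SA_tag_1",
    sseqid = c("1114", "0535", "0535", "0535", "1112"),
    pident = c(100, 100, 100, 98.08, 96.23),
    length = c(53L, 53L, 52L, 52L, 53L),
    mismatch = c(0L, 0L, 0L, 0L, 2L),
    gapopen = 0L,
    qstart = 1L,
    qend = c(53L, 53L, 52L, 52L, 53L),
    sstart = c(185301L, 171930L, 78761L, 190880L, 3895886L),
    send = c(185249L, 171982L, 78710L, 190830L, 3895938L),
    evalue = c(7e-20, 7e-20, 2e-19, 1e-16, 3e-17),
    bitscore = c(96.9, 96.9, 95.1, 86.0, 87.8),
    stringsAsFactors = FALSE)
}

#' Synthetic map-marker hits consistent with the published anchors
#'
#' Constructs a synthetic per-scaffold map-marker hit table whose
#' majority-vote anchoring reproduces a given scaffold table (such as
#' [sdlocus_scaffold_table]): scaffolds with an assigned chromosome get
#' three supporting hits (at `center_cM` - 1, `center_cM`, `center_cM` +
#' 1 when a centre is known, at arbitrary positions otherwise) and, when
#' `with_noise`, one discordant hit; unassigned scaffolds get two hits
#' tied between different chromosomes so that no strict majority exists.
#' All hits carry e-values passing the default threshold. This is a
#' stand-in constructed from the published assignments, not the original
#' (unpublished per-hit) data.
#'
#' @param anchors Scaffold table with columns `scaffold`, `chromosome`,
#'   `center_cM`.
#' @param with_noise Add one discordant hit per assigned scaffold.
#' @return `data.frame` as read by [read_map_hits].
#' @export
synthetic_map_hits <- function(anchors = sdlocus_scaffold_table(),
                               with_noise = TRUE) {
  rows <- lapply(seq_len(nrow(anchors)), function(i) {
    sc <- anchors$scaffold[i]
    chr <- anchors$chromosome[i]
    cm <- anchors$center_cM[i]
    if (is.na(chr)) {
      data.frame(map_marker_id = paste0("mm_", sc, "_", 1:2),
                 scaffold = sc, chromosome = c("Chr01", "Chr03"),
                 position_cM = c(10, 20), evalue = 1e-20,
                 stringsAsFactors = FALSE)
    } else {
      if (is.na(cm)) cm <- 50
      sup <- data.frame(map_marker_id = paste0("mm_", sc, "_", 1:3),
                        scaffold = sc, chromosome = chr,
                        position_cM = c(cm - 1, cm, cm + 1), evalue = 1e-20,
                        stringsAsFactors = FALSE)
      if (with_noise) {
        other <- if (chr == "Chr01") "Chr02" else "Chr01"
        sup <- rbind(sup, data.frame(map_marker_id = paste0("mm_", sc, "_x"),
                                     scaffold = sc, chromosome = other,
                                     position_cM = 5, evalue = 1e-15,
                                     stringsAsFactors = FALSE))
      }
      sup
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published phenotype counts as a fixture table
#'
#' A phenotype table reproducing the published sex tally of the
#' association panel: 265 sexed accessions, 162 female and 103 male.
#' Accession identifiers are synthetic.
#'
#' @return `data.frame(accession, sex, subpop)`.
#' @export
sdlocus_phenotypes <- function() {
  data.frame(accession = sprintf("acc%04d", 1:265),
             sex = rep(c("F", "M"), c(162, 103)),
             subpop = NA_character_, stringsAsFactors = FALSE)
}

#' Write the bundled fixture files
#'
#' Materialises the published-table fixtures and a small simulated toy
#' VCF into a directory: scaffold anchors (TSV), tag alignment hits
#' (TSV), synthetic map-marker hits (TSV), the published sex-count
#' phenotype table (TSV) and a 12-accession toy VCF with AD fields.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(anchors = file.path(out_dir, "scaffold_anchors.tsv"),
         tag_hits = file.path(out_dir, "tag_blast_hits.tsv"),
         map_hits = file.path(out_dir, "map_marker_hits.tsv"),
         phenotypes = file.path(out_dir, "phenotypes.tsv"),
         toy_vcf = file.path(out_dir, "toy.vcf"))
  wt <- function(d, f) utils::write.table(d, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(sdlocus_scaffold_table(), p[["anchors"]])
  wt(sdlocus_tag_hits(), p[["tag_hits"]])
  wt(synthetic_map_hits(), p[["map_hits"]])
  wt(sdlocus_phenotypes(), p[["phenotypes"]])
  toy <- simulate_population(sim_config(
    n_accessions = 12, female_fraction = 0.5, n_autosomal = 8,
    n_w_strict = 1, n_w_partial = 0, n_z_poly = 0, n_paralog_tags = 1,
    mean_depth = 20, missing_rate = 0, seed = 42))
  write_vcf(toy$depths, p[["toy_vcf"]],
            genotypes = call_genotypes(toy$depths))
  p
}
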