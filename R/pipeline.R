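#' Pipeline run configuration
#'
#' Collects inputs, stage toggles, thresholds and the seed for a full
#' analysis run. Either a VCF + phenotype-table pair or a simulation
#' configuration must be supplied.
#'
#' @param vcf,phenotypes Paths to the input VCF (with AD fields) and the
#'   phenotype TSV; ignored when `sim` is given.
#' @param sim A [sim_config]; when supplied the run starts from a
#'   simulated population (whose ground truth is carried into the
#'   report).
#' @param out_dir Directory for intermediates and reports.
#' @param do_assoc,do_mlm,do_segregation,do_dosage,do_anchor Stage
#'   toggles.
#' @param map_hits,blast_hits Optional paths to map-marker and tag
#'   alignment hit tables for the anchoring stage.
#' @param alpha Experiment-wise error rate.
#' @param q_pcs Structure principal components for the MLM.
#' @param error_rate,min_depth Genotype-calling parameters.
#' @param seg Segregation thresholds ([seg_thresholds]).
#' @param seed Integer seed governing all stochastic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf = NULL, phenotypes = NULL, sim = NULL,
                       out_dir = tempfile("zwscan_run_"),
                       do_assoc = TRUE, do_mlm = TRUE, do_segregation = TRUE,
                       do_dosage = TRUE, do_anchor = FALSE,
                       map_hits = NULL, blast_hits = NULL,
                       alpha = 0.05, q_pcs = 2,
                       error_rate = 0.01, min_depth = 5,
                       seg = seg_thresholds(), seed = 1L) {
  if (is.null(sim) && (is.null(vcf) || is.null(phenotypes)))
    stop("run_config needs either a sim config or vcf + phenotypes paths")
  structure(list(vcf = vcf, phenotypes = phenotypes, sim = sim,
                 out_dir = out_dir, do_assoc = do_assoc, do_mlm = do_mlm,
                 do_segregation = do_segregation, do_dosage = do_dosage,
                 do_anchor = do_anchor, map_hits = map_hits,
                 blast_hits = blast_hits, alpha = alpha, q_pcs = q_pcs,
                 error_rate = error_rate, min_depth = min_depth,
                 seg = seg, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate/ingest, genotype
#' calling, marker filtering, sex association (Fisher and optionally
#' MLM), segregation classification and heterogamety inference, dosage /
#' paralog screening, scaffold anchoring — writing every intermediate as
#' TSV/VCF under `config$out_dir` and returning (and writing, as JSON
#' and plain text) a run report. A fixed seed makes the whole run
#' reproducible.
#'
#' @param config A [run_config].
#' @param verbose Emit per-stage messages.
#' @return The run report (list), invisibly also written to
#'   `report.json` / `report.txt` in `out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[zwscan] ", sprintf(...))
  out <- function(f) file.path(config$out_dir, f)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("zwscan")),
                 stages = character(0), counts = list(), notes = character(0))

  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulating population (seed %d)", config$sim$seed)
    pop <- simulate_population(config$sim)
    depths <- pop$depths
    phen <- pop$phenotypes
    truth <- pop$truth
    write_vcf(depths, out("simulated.vcf"))
    write_phenotypes(phen, out("phenotypes.tsv"))
    utils::write.table(truth, out("sim_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages <- c(report$stages, "simulate")
  } else {
    say("reading %s", config$vcf)
    depths <- read_vcf_depths(config$vcf)
    phen <- read_phenotypes(config$phenotypes)
    report$stages <- c(report$stages, "ingest")
  }
  report$counts$n_accessions <- nrow(depths$ref)
  report$counts$n_markers_raw <- ncol(depths$ref)

  say("calling genotypes (min depth %d, error %.3g)", config$min_depth,
      config$error_rate)
  g <- call_genotypes(depths, error_rate = config$error_rate,
                      min_depth = config$min_depth)
  report$stages <- c(report$stages, "call_genotypes")

  gf <- suppressWarnings(filter_assoc_markers(g))
  fr <- attr(gf, "filter_report")
  report$counts$n_markers_assoc_filtered <- fr$n_out
  report$counts$filter_removed_call_rate <- fr$n_removed_call_rate
  report$counts$filter_removed_maf <- fr$n_removed_maf
  say("assoc filter kept %d of %d markers", fr$n_out, fr$n_in)
  report$stages <- c(report$stages, "filter")

  sig_ids <- gf$markers$id
  if (config$do_assoc && ncol(gf$geno) > 0L) {
    say("association scan (%d markers, mlm = %s)", ncol(gf$geno),
        config$do_mlm)
    gw <- gwas_sex(gf, phen, alpha = config$alpha, mlm = config$do_mlm,
                   q_pcs = config$q_pcs)
    utils::write.table(gw$results, out("association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$counts$n_sig_fisher <- gw$n_sig_fisher
    report$counts$n_sig_mlm <- gw$n_sig_mlm
    report$counts$n_sig_agree <- gw$n_agree
    report$bonferroni <- gw$bonferroni
    sig_ids <- gw$results$marker_id[gw$results$significant_fisher]
    report$stages <- c(report$stages, "assoc")
  } else if (!config$do_assoc) {
    report$notes <- c(report$notes,
                      "association stage disabled; downstream stages use all filtered markers")
  }

  if (config$do_segregation && ncol(gf$geno) > 0L) {
    say("segregation classification over %d marker(s)", length(sig_ids))
    het <- infer_heterogamety(gf, phen, sig_ids, thresholds = config$seg)
    report$heterogamety <- het[c("verdict", "support", "votes_female",
                                 "votes_male", "n_markers")]
    if (length(sig_ids)) {
      seg_tab <- data.frame(marker_id = sig_ids, class = het$classes,
                            class_sex_swapped = het$classes_swapped,
                            stringsAsFactors = FALSE)
      utils::write.table(seg_tab, out("segregation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$stages <- c(report$stages, "segregation")
  }

  if (config$do_dosage && ncol(gf$geno) > 0L) {
    textbook <- suppressWarnings(identify_textbook_markers(gf))
    say("dosage screen (%d textbook reference markers)", length(textbook))
    screen <- if (length(sig_ids)) sig_ids else gf$markers$id
    flags <- suppressWarnings(
      flag_paralog_suspects(depths, g, phen, markers = screen,
                            textbook = textbook))
    utils::write.table(flags, out("dosage_flags.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$counts$n_textbook <- length(textbook)
    report$counts$n_paralog_suspects <- sum(flags$paralog_suspect)
    report$paralog_suspects <- flags$marker_id[flags$paralog_suspect]
    report$stages <- c(report$stages, "dosage")
  }

  if (config$do_anchor && !is.null(config$map_hits)) {
    say("anchoring scaffolds")
    hits <- read_map_hits(config$map_hits)
    anchors <- anchor_scaffolds(hits)
    utils::write.table(anchors, out("anchors.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$counts$n_scaffolds_anchored <- sum(!is.na(anchors$chromosome))
    if (!is.null(config$blast_hits)) {
      bh <- read_blast_hits(config$blast_hits)
      copies <- count_tag_copies(bh)
      report$tag_copies <- copies[c("n_copies", "multi_copy")]
    }
    report$stages <- c(report$stages, "anchor")
  }

  if (!is.null(truth)) {
    truth_sig <- truth$marker_id[truth$class_label != "autosomal"]
    report$truth_eval <- list(
      n_truth_sex_linked = length(truth_sig),
      n_recovered_significant = length(intersect(sig_ids, truth_sig)),
      true_paralogs_flagged = length(intersect(
        report$paralog_suspects,
        truth$marker_id[truth$class_label == "paralog_collapsed"])))
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  txt <- c(sprintf("zwscan run (seed %d)", config$seed),
           sprintf("stages: %s", paste(report$stages, collapse = " -> ")),
           vapply(names(report$counts), function(k)
             sprintf("  %s: %s", k, report$counts[[k]]), ""),
           if (!is.null(report$heterogamety))
             sprintf("heterogamety verdict: %s (support %.2f)",
                     report$heterogamety$verdict,
                     ifelse(is.na(report$heterogamety$support), 0,
                            report$heterogamety$support)),
           report$notes)
  writeLines(txt, out("report.txt"))
  say("done; report at %s", out("report.json"))
  invisible(report)
}
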