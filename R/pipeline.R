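#' Pipeline configuration
#'
#' Paths and policies for a full marker-development run:
#' scan -> design -> e-PCR uniqueness filter -> GTM cross-reference ->
#' transferability -> diversity. Stages whose inputs are `NULL` are
#' skipped.
#'
#' @param genome Path to the assembly FASTA (required for scan/design/epcr).
#' @param transcriptome Optional path to transcript contig FASTA (GTM
#'   stage).
#' @param annotations Optional path to a transcript annotation TSV
#'   (`transcript_id`, `gene`).
#' @param foreign Optional named character vector of foreign genome FASTA
#'   paths (transferability stage).
#' @param genotypes Optional path to a genotype TSV (diversity stage).
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run.
#' @param design A [design_config()].
#' @param policy_genomic [match_policy()] for the uniqueness filter.
#' @param policy_tx [match_policy()] for transcript cross-referencing.
#' @param scan_min_unit,scan_max_unit,scan_min_repeats SSR scan thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome = NULL, transcriptome = NULL,
                            annotations = NULL, foreign = NULL,
                            genotypes = NULL, out_dir = "floramark_run",
                            stages = c("scan", "design", "epcr", "gtm",
                                       "transfer", "diversity"),
                            design = design_config(),
                            policy_genomic = match_policy(),
                            policy_tx = match_policy(
                              reverse_5prime_mismatch_allowed = TRUE),
                            scan_min_unit = 2, scan_max_unit = 6,
                            scan_min_repeats = 5) {
  if (length(stages)) stages <- match.arg(stages, several.ok = TRUE)
  needs_genome <- intersect(stages, c("scan", "design", "epcr", "gtm",
                                      "transfer"))
  for (p in c(genome[length(needs_genome) > 0], transcriptome, annotations,
              foreign, genotypes)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(genome = genome, transcriptome = transcriptome,
                 annotations = annotations, foreign = foreign,
                 genotypes = genotypes, out_dir = out_dir, stages = stages,
                 design = design, policy_genomic = policy_genomic,
                 policy_tx = policy_tx, scan_min_unit = scan_min_unit,
                 scan_max_unit = scan_max_unit,
                 scan_min_repeats = scan_min_repeats),
            class = "pipeline_config")
}

.manifest_row <- function(stage, file, n_rows, secs) {
  data.frame(stage = stage, output = file, n_rows = n_rows,
             seconds = round(secs, 3), stringsAsFactors = FALSE)
}

#' Run the marker-development pipeline
#'
#' Executes the enabled stages in dependency order, writing one TSV per
#' stage product plus a manifest listing every emitted file with its row
#' count, parameters and timing. The marker counts funnel monotonically:
#' designed pairs >= retained unique pairs >= gene-targeted pairs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest data frame (class `run_manifest`), invisibly also
#'   carrying the stage results in attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  emit <- function(stage, name, df, t0) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[length(manifest) + 1L]] <<-
      .manifest_row(stage, name, nrow(df),
                    as.numeric(proc.time()[3] - t0))
    path
  }
  fail <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  genome <- NULL; loci <- NULL; pairs <- NULL; retained <- NULL

  if ("scan" %in% config$stages) {
    t0 <- proc.time()[3]
    tryCatch({
      genome <- read_fasta(config$genome)
      loci <- scan_ssrs(genome, config$scan_min_unit, config$scan_max_unit,
                        config$scan_min_repeats)
      emit("scan", "loci.tsv", loci, t0)
      emit("scan", "motif_summary.tsv", summarize_motifs(loci), t0)
      results$loci <- loci
    }, error = function(e) fail("scan", e))
  }
  if ("design" %in% config$stages) {
    t0 <- proc.time()[3]
    tryCatch({
      if (is.null(loci)) stop("design needs the scan stage")
      pairs <- design_primers(genome, loci, config$design)
      emit("design", "primers.tsv", pairs, t0)
      results$pairs <- pairs
    }, error = function(e) fail("design", e))
  }
  if ("epcr" %in% config$stages) {
    t0 <- proc.time()[3]
    tryCatch({
      if (is.null(pairs)) stop("epcr needs the design stage")
      ep <- classify_pairs(pairs, genome, config$policy_genomic)
      retained <- pairs[pairs$pair_id %in% ep$retained, , drop = FALSE]
      emit("epcr", "classification.tsv", ep$classification, t0)
      emit("epcr", "amplicons.tsv", ep$amplicons, t0)
      emit("epcr", "retained_primers.tsv", retained, t0)
      results$epcr <- ep
      results$retained <- retained
    }, error = function(e) fail("epcr", e))
  }
  if ("gtm" %in% config$stages && !is.null(config$transcriptome)) {
    t0 <- proc.time()[3]
    tryCatch({
      if (is.null(retained)) stop("gtm needs the epcr stage")
      tx <- read_fasta(config$transcriptome)
      ann <- if (is.null(config$annotations)) NULL else
        utils::read.table(config$annotations, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
      g <- gtm_cross_reference(retained, tx, config$policy_tx, ann)
      emit("gtm", "gtm.tsv", g$records, t0)
      results$gtm <- g
    }, error = function(e) fail("gtm", e))
  }
  if ("transfer" %in% config$stages && length(config$foreign)) {
    t0 <- proc.time()[3]
    tryCatch({
      if (is.null(retained)) stop("transfer needs the epcr stage")
      fdb <- lapply(config$foreign, read_fasta)
      tr <- transferability_screen(retained, fdb, config$policy_genomic)
      emit("transfer", "transfer_summary.tsv", tr$summary, t0)
      emit("transfer", "transfer_pairs.tsv", tr$mapped, t0)
      results$transfer <- tr
    }, error = function(e) fail("transfer", e))
  }
  if ("diversity" %in% config$stages && !is.null(config$genotypes)) {
    t0 <- proc.time()[3]
    tryCatch({
      gm <- read_genotypes(config$genotypes)
      pr <- pic_report(gm)
      emit("diversity", "pic.tsv", pr, t0)
      d <- nei72_matrix(gm, infinite_policy = "cap")
      dd <- data.frame(accession = rownames(d), d, check.names = FALSE)
      emit("diversity", "nei72.tsv", dd, t0)
      tree <- upgma(d)
      write_newick(tree, file.path(config$out_dir, "upgma.nwk"))
      manifest[[length(manifest) + 1L]] <-
        .manifest_row("diversity", "upgma.nwk", length(tree$labels),
                      as.numeric(proc.time()[3] - t0))
      results$diversity <- list(pic = pr, distances = d, tree = tree,
                                h_t = total_gene_diversity(gm))
    }, error = function(e) fail("diversity", e))
  }
  mf <- if (length(manifest))
    do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  else .manifest_row(character(0), character(0), integer(0), numeric(0))
  utils::write.table(mf, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  class(mf) <- c("run_manifest", class(mf))
  attr(mf, "results") <- results
  invisible(mf)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
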