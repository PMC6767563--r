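# End-to-end orchestration: peaks -> flanks -> motif -> candidates ->
# validated-promoter PWMs -> genome scan -> expression classes ->
# conservation. Stages write their outputs before the next starts and are
# skippable when inputs are supplied pre-computed.

#' Extract peak summit flank sequences, oriented by the downstream gene
#'
#' Each summit window is extended by \code{flank_bp} per side and the
#' sequence extracted. When a gene table is supplied, each flank is oriented
#' to the sense strand of the nearest gene for which the summit lies
#' upstream, so that a single forward-strand motif search applies to all
#' flanks regardless of the target gene's genomic strand.
#'
#' @param peaks Peak table from \code{call_peaks}.
#' @param contigs Named \code{DNAStringSet}.
#' @param genes Optional gene table used for orientation.
#' @param flank_bp Flank per side of the summit window.
#' @return Character vector of sequences, one per peak.
#' @export
peak_flank_sequences <- function(peaks, contigs, genes = NULL, flank_bp = 100L) {
  vapply(seq_len(nrow(peaks)), function(p) {
    clen <- Biostrings::width(contigs)[match(peaks$contig_id[p], names(contigs))]
    s0 <- max(peaks$summit_start[p] - flank_bp, 0L)
    s1 <- min(peaks$summit_end[p] + flank_bp, clen)
    seq <- as.character(Biostrings::subseq(contigs[[peaks$contig_id[p]]],
                                           s0 + 1L, s1))
    if (!is.null(genes)) {
      centre <- (peaks$summit_start[p] + peaks$summit_end[p]) / 2
      g <- genes[genes$contig_id == peaks$contig_id[p], , drop = FALSE]
      upstream_of <- ifelse(g$strand == "+", g$start_codon_pos >= centre,
                            g$start_codon_pos <= centre)
      cand <- g[upstream_of, , drop = FALSE]
      if (nrow(cand) > 0L) {
        best <- which.min(abs(cand$start_codon_pos - centre))
        if (cand$strand[best] == "-") seq <- revcomp(seq)
      }
    }
    seq
  }, character(1))
}

write_stage <- function(obj, writer, out_dir, file) {
  path <- file.path(out_dir, file)
  writer(obj, path)
  path
}

#' Run the full regulon-inference pipeline
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{contigs, genes}{Genome (DNAStringSet or FASTA path) and gene
#'       table (data.frame or GFF3 path).}
#'     \item{chip, control}{\code{coverage_track}s or coverage file paths
#'       (omit both to skip peak calling; then supply \code{peaks} or
#'       \code{candidates}).}
#'     \item{peaks}{Optional precomputed peak table.}
#'     \item{candidates}{Optional promoter table (data.frame or TSV path);
#'       skips the peaks/motif/candidate stages.}
#'     \item{validated_promoters}{Promoter table used to build the scanning
#'       PWMs; default the packaged validated set.}
#'     \item{expression, n_promoters}{Optional expression matrix (or path)
#'       and promoter-count annotation for dependence classification.}
#'     \item{panel}{Optional named species list for the conservation stage
#'       (see \code{conservation_matrix}).}
#'     \item{peak_params, gibbs_params, rule, scan_params, thresholds,
#'       conservation_params}{Optional parameter objects.}
#'     \item{out_dir}{Output directory (created).}
#'     \item{seed}{Root seed; stage seeds derive from it.}
#'   }
#' @return A report bundle: list of stage outputs plus the paths written.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stopf("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("ecfmap pipeline run, seed %d\n%s\n", seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  bundle <- list(paths = character(0))
  add_path <- function(p) bundle$paths <<- c(bundle$paths, p)

  contigs <- config$contigs
  if (is.character(contigs)) contigs <- read_genome_fasta(contigs)
  if (is.null(contigs)) stopf("config$contigs (genome) is required")
  genes <- config$genes
  if (is.character(genes)) genes <- read_gff_genes(genes, contigs = contigs)
  if (is.null(genes)) stopf("config$genes (annotation) is required")
  logf("genome: %d contig(s), %d genes", length(contigs), nrow(genes))

  pp <- config$peak_params %||% peak_params()
  gp <- config$gibbs_params %||% gibbs_params(seed = seed + 10L)
  rule <- config$rule %||% candidate_rule()
  sp <- config$scan_params %||% scan_params()
  thr <- config$thresholds %||% class_thresholds()
  cp <- config$conservation_params %||% conservation_params()
  for (nm in c("pp", "gp", "rule", "sp", "thr", "cp"))
    logf("%s: %s", nm, paste(deparse(unclass(get(nm))), collapse = " "))

  candidates <- config$candidates
  if (is.character(candidates)) candidates <- read_promoter_table(candidates)
  motif <- NULL; peaks <- config$peaks
  if (is.null(candidates)) {
    if (is.null(peaks)) {
      chip <- config$chip; control <- config$control
      if (is.character(chip)) chip <- read_coverage_track(chip)
      if (is.character(control)) control <- read_coverage_track(control)
      peaks <- stage("peaks", call_peaks(chip, control, pp))
      logf("peaks: %d called (window %d bp, P < %g)", nrow(peaks),
           pp$window_bp, pp$p_threshold)
    }
    add_path(write_stage(peaks, write_peaks_bed, out_dir, "peaks.bed"))
    flanks <- stage("flanks", peak_flank_sequences(peaks, contigs, genes))
    writeLines(paste0(">peak_", seq_along(flanks), "\n", flanks),
               file.path(out_dir, "peak_flanks.fa"))
    add_path(file.path(out_dir, "peak_flanks.fa"))
    motif <- stage("motif", gibbs_two_block(flanks, gp))
    logf("motif: score %.2f bits, consensus %s/%s", motif$score,
         motif_consensus(motif)$minus35, motif_consensus(motif)$minus10)
    candidates <- stage("candidates",
                        candidate_promoters(peaks, contigs, genes, rule, motif))
    logf("candidates: %d (orphan peaks: %d)", nrow(candidates),
         length(attr(candidates, "orphans")))
  } else {
    logf("candidates: supplied (%d rows); peak/motif stages skipped",
         nrow(candidates))
  }
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add_path(file.path(out_dir, "candidates.tsv"))

  validated <- config$validated_promoters %||% sigE_validated_promoters()
  if (is.character(validated)) validated <- read_promoter_table(validated)
  pwms <- stage("pwm", build_pwm_pair(validated))
  for (pw in pwms)
    add_path(write_stage(pw, write_pwm, out_dir, sprintf("%s.tsv", pw$name)))
  logf("PWMs: %s from %d promoters",
       paste(vapply(pwms, `[[`, character(1), "name"), collapse = ", "),
       nrow(validated))

  hits <- stage("scan", scan_upstream(contigs, genes, pwms, sp))
  utils::write.table(hits, file.path(out_dir, "scan_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add_path(file.path(out_dir, "scan_hits.tsv"))
  logf("scan: %d genes with an upstream site", length(unique(hits$gene_id)))

  if (!is.null(config$expression)) {
    expr <- config$expression
    if (is.character(expr)) expr <- read_expression_matrix(expr)
    cls <- stage("classify", classify_targets(expr, config$n_promoters, thr))
    add_path(write_stage(cls, dependence_report, out_dir, "classification.tsv"))
    bundle$classification <- cls
    logf("classification: %s",
         paste(sprintf("%s=%d", names(table(cls$promoter_class)),
                       table(cls$promoter_class)), collapse = " "))
  }

  if (!is.null(config$panel)) {
    targets <- config$conservation_targets %||%
      unique(candidates$gene_id %||% candidates$target_id)
    reference <- list(contigs = contigs, genes = genes,
                      proteins = config$reference_proteins)
    cm <- stage("conserve", conservation_matrix(targets, reference,
                                                config$panel, pwms, cp))
    add_path(write_stage(cm, write_conservation_matrix, out_dir,
                         "conservation_matrix.tsv"))
    bundle$conservation <- cm
    bundle$conserved <- conserved_targets(cm)
    logf("conservation: %d/%d targets conserved in >= %d genomes",
         length(bundle$conserved), length(targets), cp$min_genomes)
  }

  bundle$peaks <- peaks
  bundle$motif <- motif
  bundle$candidates <- candidates
  bundle$pwms <- pwms
  bundle$scan_hits <- hits
  bundle$log <- log_path
  bundle
}

#' Run the pipeline on a freshly simulated demo dataset
#'
#' Simulates a genome with planted promoter sites, ChIP/control coverage and
#' an induction experiment at the configured study conditions, then runs the
#' full pipeline on them.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param cfg Optional \code{sim_config} override.
#' @return List with the pipeline \code{bundle}, the simulated \code{genome}
#'   (with its truth table) and the simulated \code{expression}.
#' @export
run_synthetic_demo <- function(seed, out_dir = tempfile("ecfmap_demo_"),
                               cfg = NULL) {
  cfg <- cfg %||% sim_config(seed = seed)
  genome <- simulate_genome_with_sites(cfg)
  chip <- simulate_chip(cfg, genome)
  expr <- simulate_expression(cfg, genome)
  bundle <- run_pipeline(list(
    contigs = genome$contigs, genes = genome$genes,
    chip = chip$chip, control = chip$control,
    expression = expr$matrix, n_promoters = expr$n_promoters,
    out_dir = out_dir, seed = cfg$seed))
  list(bundle = bundle, genome = genome, expression = expr, config = cfg)
}
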