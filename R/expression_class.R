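# Promoter-dependence classification from WT vs deletion-mutant induction
# time courses (log2 expression, per-gene median-normalized).

EXPR_STRAINS <- c("WT", "dsigE")
EXPR_TIMES <- c(0L, 30L, 60L, 90L)

expr_colnames <- function() {
  paste(rep(EXPR_STRAINS, each = length(EXPR_TIMES)), EXPR_TIMES, sep = "_")
}

#' Read a log2 expression matrix
#'
#' TSV with a gene-id first column and condition columns named
#' \code{WT_0 ... dsigE_90} (strain_time in minutes).
#' @param path File path.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!all(expr_colnames() %in% colnames(m)))
    stopf("expression matrix lacks column(s): %s",
          paste(setdiff(expr_colnames(), colnames(m)), collapse = ", "))
  if (any(!is.finite(m))) stopf("non-finite expression values")
  m
}

#' Write a log2 expression matrix
#' @param m Matrix from \code{read_expression_matrix}.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene normalization to the median
#'
#' Subtracts each gene's own median (log2 scale); idempotent.
#' @param m Expression matrix (genes in rows).
#' @return Matrix of the same shape.
#' @export
normalize_per_gene_median <- function(m) {
  m - apply(m, 1, stats::median)
}

#' Induction of one strain's time course
#'
#' Maximum rise over the time-zero value: max over t > 0 of x(t) - x(0).
#' @param series Named numeric vector; names are times in minutes and must
#'   include 0.
#' @return log2 fold induction.
#' @export
induction <- function(series) {
  times <- as.numeric(names(series))
  if (!0 %in% times) stopf("time course lacks the t = 0 point")
  x0 <- series[match(0, times)]
  later <- series[times > 0]
  if (length(later) == 0L) return(0)
  max(later - x0)
}

#' Classification thresholds
#'
#' Operationalise the qualitative dependence scheme: a gene counts as
#' vancomycin-induced when the WT rises by at least
#' \code{induction_min_log2} (default 1, i.e. two-fold); its promoter is
#' completely sigma-E-dependent when the mutant stays below
#' \code{full_dependence_max_mutant_log2}; dependence is absent when the
#' mutant induction comes within \code{epsilon_log2} of the WT induction;
#' everything between is partial dependence.
#'
#' @param induction_min_log2 Minimum WT induction to classify at all.
#' @param full_dependence_max_mutant_log2 Mutant induction ceiling for
#'   complete dependence.
#' @param epsilon_log2 Band below the WT induction within which the mutant
#'   is considered uninfluenced.
#' @return A list of class \code{class_thresholds}.
#' @export
class_thresholds <- function(induction_min_log2 = 1,
                             full_dependence_max_mutant_log2 = 0.5,
                             epsilon_log2 = 0.1) {
  stopifnot(induction_min_log2 > full_dependence_max_mutant_log2)
  structure(list(induction_min_log2 = induction_min_log2,
                 full_dependence_max_mutant_log2 = full_dependence_max_mutant_log2,
                 epsilon_log2 = epsilon_log2),
            class = "class_thresholds")
}

#' Classify one target gene
#'
#' Class I: one promoter, completely sigma-E-dependent; Class II: one
#' promoter, partially dependent; Class III: multiple promoters, at least
#' partial dependence. Genes whose WT induction falls below the induction
#' threshold, or whose expression shows no dependence, are unclassified.
#'
#' @param gene_id Gene identifier.
#' @param n_promoters Number of promoters (external annotation, >= 1).
#' @param wt_series,mut_series Named time courses (see \code{induction});
#'   both on the same time grid, already per-gene normalized.
#' @param thresholds A \code{class_thresholds}.
#' @return One-row data.frame: gene_id, n_promoters, wt_induction,
#'   mut_induction, dependence, promoter_class.
#' @export
classify_target <- function(gene_id, n_promoters, wt_series, mut_series,
                            thresholds = class_thresholds()) {
  if (n_promoters < 1L) stopf("gene %s: n_promoters must be >= 1", gene_id)
  wt_ind <- induction(wt_series)
  mut_ind <- induction(mut_series)
  if (wt_ind < thresholds$induction_min_log2) {
    dep <- "none"; cls <- "unclassified"
  } else {
    dep <- if (mut_ind <= thresholds$full_dependence_max_mutant_log2) "complete"
           else if (mut_ind >= wt_ind - thresholds$epsilon_log2) "none"
           else "partial"
    cls <- if (dep == "complete" && n_promoters == 1L) "I"
           else if (dep == "partial" && n_promoters == 1L) "II"
           else if (dep %in% c("partial", "complete") && n_promoters > 1L) "III"
           else "unclassified"
  }
  data.frame(gene_id = gene_id, n_promoters = n_promoters,
             wt_induction = wt_ind, mut_induction = mut_ind,
             dependence = dep, promoter_class = cls,
             stringsAsFactors = FALSE)
}

#' Classify all genes of an expression matrix
#'
#' @param m Expression matrix with \code{WT_*} and \code{dsigE_*} columns.
#' @param n_promoters Named integer vector (or data.frame with gene_id /
#'   n_promoters columns); genes absent from it default to 1 promoter.
#' @param thresholds A \code{class_thresholds}.
#' @param normalize Apply per-gene median normalization first (default).
#' @return Data.frame, one row per gene.
#' @export
classify_targets <- function(m, n_promoters = NULL,
                             thresholds = class_thresholds(), normalize = TRUE) {
  if (is.data.frame(n_promoters))
    n_promoters <- stats::setNames(n_promoters$n_promoters, n_promoters$gene_id)
  if (normalize) m <- normalize_per_gene_median(m)
  res <- lapply(rownames(m), function(g) {
    np <- if (!is.null(n_promoters) && g %in% names(n_promoters))
      as.integer(n_promoters[[g]]) else 1L
    wt <- stats::setNames(m[g, paste0("WT_", EXPR_TIMES)], EXPR_TIMES)
    mu <- stats::setNames(m[g, paste0("dsigE_", EXPR_TIMES)], EXPR_TIMES)
    classify_target(g, np, wt, mu, thresholds)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write (and read back) a dependence report
#'
#' One row per gene with all classification fields; an empty classification
#' yields a header-only file.
#' @param classifications Data.frame from \code{classify_targets}.
#' @param path Output TSV path.
#' @export
dependence_report <- function(classifications, path) {
  cols <- c("gene_id", "n_promoters", "wt_induction", "mut_induction",
            "dependence", "promoter_class")
  utils::write.table(classifications[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dependence_report
#' @export
read_dependence_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
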