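# Cross-genome conservation of target promoters: reciprocal-best-hit
# ortholog mapping and assembly of the targets x species conservation
# matrix (site with score / ortholog without site / no ortholog).

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
                 "S","T","W","Y","V","X")

#' Protein alignment parameters
#'
#' @param min_identity Minimum percent identity for an ortholog pair.
#' @param min_coverage Minimum percent of the shorter sequence covered by
#'   the local alignment.
#' @param near_bp,far_bp Upstream scan window for site detection.
#' @param min_genomes Conservation threshold (site present in at least this
#'   many panel genomes).
#' @param gap_opening,gap_extension Affine gap penalties (BLOSUM62 scoring).
#' @return A list of class \code{conservation_params}.
#' @export
conservation_params <- function(min_identity = 30, min_coverage = 50,
                                near_bp = 10L, far_bp = 200L, min_genomes = 9L,
                                gap_opening = 11, gap_extension = 1) {
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 near_bp = as.integer(near_bp), far_bp = as.integer(far_bp),
                 min_genomes = as.integer(min_genomes),
                 gap_opening = gap_opening, gap_extension = gap_extension),
            class = "conservation_params")
}

check_protein <- function(x, what = "protein") {
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), toupper(x))
  if (any(bad)) stopf("non-amino-acid character in %s sequence(s)", what)
  if (any(nchar(x) == 0L)) stopf("empty %s sequence", what)
  toupper(x)
}

#' Align two proteins locally
#'
#' Smith-Waterman local alignment with BLOSUM62 scoring and affine gaps.
#' Identity is identical residues over aligned columns (gaps included);
#' coverage is the aligned span of the shorter sequence over its length.
#'
#' @param a,b Amino-acid strings (20-letter alphabet, X allowed).
#' @param params A \code{conservation_params} (gap penalties).
#' @return List with \code{identity} and \code{coverage} (percent) and the
#'   alignment \code{score}.
#' @export
align_protein <- function(a, b, params = conservation_params()) {
  a <- check_protein(a); b <- check_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  span_a <- Biostrings::nchar(Biostrings::pattern(aln)) -
    sum(Biostrings::width(Biostrings::indel(Biostrings::pattern(aln))[[1]]))
  span_b <- Biostrings::nchar(Biostrings::subject(aln)) -
    sum(Biostrings::width(Biostrings::indel(Biostrings::subject(aln))[[1]]))
  shorter <- min(nchar(a), nchar(b))
  cov <- 100 * min(span_a, span_b) / shorter
  list(identity = Biostrings::pid(aln, type = "PID1"),
       coverage = cov, score = Biostrings::score(aln))
}

# Align one query against a set of subjects; returns score/identity/coverage
# vectors. Vectorised over subjects for speed.
align_one_vs_set <- function(query, subjects, params) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(query, length(subjects))),
    Biostrings::AAStringSet(subjects), type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = params$gap_opening, gapExtension = params$gap_extension)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  gaps_pat <- vapply(Biostrings::width(Biostrings::indel(pat)), sum, numeric(1))
  gaps_sub <- vapply(Biostrings::width(Biostrings::indel(sub)), sum, numeric(1))
  span_pat <- Biostrings::nchar(pat) - gaps_pat
  span_sub <- Biostrings::nchar(sub) - gaps_sub
  shorter <- pmin(nchar(query), nchar(subjects))
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1"),
       coverage = 100 * pmin(span_pat, span_sub) / shorter)
}

best_hits <- function(from, to, params) {
  # best subject for every query, ties by higher identity then lexicographic id
  res <- lapply(names(from), function(q) {
    al <- align_one_vs_set(from[[q]], unlist(to), params)
    ord <- order(-al$score, -al$identity, names(to))
    k <- ord[1L]
    data.frame(query = q, hit = names(to)[k], score = al$score[k],
               identity = al$identity[k], coverage = al$coverage[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Reciprocal-best-hit orthologs between two proteomes
#'
#' A pair is recorded when each protein is the other's best local-alignment
#' hit and the identity/coverage thresholds are met. Absence is a value,
#' not an error.
#'
#' @param reference,other Named character vectors of protein sequences.
#' @param params A \code{conservation_params}.
#' @return Data.frame with \code{ref_id}, \code{other_id},
#'   \code{identity}, \code{coverage}, \code{score}.
#' @export
rbh_orthologs <- function(reference, other, params = conservation_params()) {
  if (length(reference) == 0L || length(other) == 0L)
    stopf("empty proteome")
  reference <- vapply(reference, check_protein, character(1))
  other <- vapply(other, check_protein, character(1))
  fwd <- best_hits(as.list(reference), as.list(other), params)
  rev <- best_hits(as.list(other), as.list(reference), params)
  rev_best <- stats::setNames(rev$hit, rev$query)
  keep <- rev_best[fwd$hit] == fwd$query &
    fwd$identity >= params$min_identity & fwd$coverage >= params$min_coverage
  out <- fwd[keep, , drop = FALSE]
  names(out)[1:2] <- c("ref_id", "other_id")
  rownames(out) <- NULL
  out
}

#' Assemble a conservation matrix over a genome panel
#'
#' For each target gene and panel species: if no ortholog is found the cell
#' is \code{no_ortholog}; otherwise the ortholog's upstream window
#' ([near, far] bp of the start codon, sense strand) is scanned with the
#' promoter PWMs and the best hit's normalized score recorded
#' (\code{site}), or \code{no_site} when nothing passes.
#'
#' @param targets Character vector of reference gene ids.
#' @param reference List with \code{contigs} (DNAStringSet), \code{genes}
#'   (gene table) and \code{proteins} (named character vector).
#' @param panel Named list of species, each a list like \code{reference}.
#' @param pwms List of \code{two_block_pwm}s.
#' @param params A \code{conservation_params}.
#' @param scan A \code{scan_params}; defaults to the window in
#'   \code{params}.
#' @param orthologs Optional precomputed ortholog table (data.frame with
#'   columns species, ref_id, other_id) replacing the internal RBH search.
#' @return An object of class \code{conservation_matrix}: \code{state}
#'   (character matrix targets x species with values no_ortholog / no_site /
#'   site), \code{score} (normalized best-site scores, NA off-site) and
#'   \code{ortholog} (ortholog ids).
#' @export
conservation_matrix <- function(targets, reference, panel, pwms,
                                params = conservation_params(), scan = NULL,
                                orthologs = NULL) {
  scan <- scan %||% scan_params(near_bp = params$near_bp, far_bp = params$far_bp)
  species <- names(panel)
  state <- matrix("no_ortholog", length(targets), length(species),
                  dimnames = list(targets, species))
  score <- matrix(NA_real_, length(targets), length(species),
                  dimnames = list(targets, species))
  orth <- matrix(NA_character_, length(targets), length(species),
                 dimnames = list(targets, species))
  if (length(targets) == 0L)
    return(structure(list(state = state, score = score, ortholog = orth,
                          params = params),
                     class = "conservation_matrix"))
  for (sp in species) {
    spec <- panel[[sp]]
    if (is.null(spec$contigs) || is.null(spec$genes) || is.null(spec$proteins))
      stopf("species %s lacks genome, annotation or proteome", sp)
    if (!all(spec$genes$contig_id %in% names(spec$contigs)))
      stopf("annotation/genome mismatch for species %s", sp)
    if (length(spec$proteins) == 0L) next  # every gene lost: all no_ortholog
    if (is.null(orthologs)) {
      omap <- rbh_orthologs(reference$proteins[targets], spec$proteins, params)
    } else {
      omap <- orthologs[orthologs$species == sp & orthologs$ref_id %in% targets, ,
                        drop = FALSE]
    }
    for (t in targets) {
      row <- omap[omap$ref_id == t, , drop = FALSE]
      if (nrow(row) == 0L) next
      og <- row$other_id[1L]
      orth[t, sp] <- og
      gi <- which(spec$genes$gene_id == og)
      if (length(gi) == 0L)
        stopf("ortholog %s of %s not in the %s annotation", og, t, sp)
      region <- suppressWarnings(
        extract_upstream(spec$contigs, spec$genes[gi[1L], ],
                         scan$near_bp, scan$far_bp))
      hits <- scan_region(pwms, region, scan)
      if (nrow(hits) == 0L) {
        state[t, sp] <- "no_site"
      } else {
        state[t, sp] <- "site"
        score[t, sp] <- hits$normalized[1L]
      }
    }
  }
  structure(list(state = state, score = score, ortholog = orth, params = params),
            class = "conservation_matrix")
}

#' Targets conserved in at least min_genomes panel genomes
#'
#' @param cm A \code{conservation_matrix}.
#' @param min_genomes Threshold on the number of \code{site} cells.
#' @return Character vector of target ids, sorted by site count
#'   (descending) then id.
#' @export
conserved_targets <- function(cm, min_genomes = cm$params$min_genomes) {
  n_site <- rowSums(cm$state == "site")
  keep <- which(n_site >= min_genomes)
  if (length(keep) == 0L) return(character(0))
  ids <- rownames(cm$state)[keep]
  ids[order(-n_site[keep], ids)]
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat(sprintf("conservation matrix: %d targets x %d species (%d site cells)\n",
              nrow(x$state), ncol(x$state), sum(x$state == "site")))
  invisible(x)
}

#' Write / read a conservation matrix as TSV
#'
#' Cells are written as \code{absent} (no ortholog), \code{no_site}, or the
#' normalized site score as a decimal.
#' @param cm A \code{conservation_matrix}.
#' @param path File path.
#' @export
write_conservation_matrix <- function(cm, path) {
  cells <- cm$state
  cells[cells == "no_ortholog"] <- "absent"
  idx <- cells == "site"
  cells[idx] <- sprintf("%.6f", cm$score[idx])
  utils::write.table(data.frame(target = rownames(cells), cells,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conservation_matrix
#' @export
read_conservation_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cells <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cells) <- tab$target
  state <- ifelse(cells == "absent", "no_ortholog",
                  ifelse(cells == "no_site", "no_site", "site"))
  score <- suppressWarnings(matrix(as.numeric(cells), nrow(cells),
                                   dimnames = dimnames(cells)))
  structure(list(state = state, score = score,
                 ortholog = matrix(NA_character_, nrow(cells), ncol(cells),
                                   dimnames = dimnames(cells)),
                 params = conservation_params()),
            class = "conservation_matrix")
}
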