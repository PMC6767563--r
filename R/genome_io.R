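#' Read a genome FASTA file
#'
#' Reads contigs into a \code{DNAStringSet}, uppercasing sequences and
#' validating the alphabet. Only A, C, G, T and N are accepted; other IUPAC
#' ambiguity codes are rejected by default or masked to N.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Either \code{"reject"} (error on non-ACGTN letters) or
#'   \code{"mask"} (replace them with N).
#' @return A named \code{DNAStringSet}, one element per record, in file order.
#' @export
read_genome_fasta <- function(path, ambiguity = c("reject", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  contigs <- Biostrings::readDNAStringSet(path)
  if (length(contigs) == 0L) stopf("empty FASTA file: %s", path)
  # keep only the first whitespace-delimited token of each header
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  dup <- names(contigs)[duplicated(names(contigs))]
  if (length(dup) > 0L)
    stopf("duplicate contig id(s) in %s: %s", path, paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(contigs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguity == "reject")
      stopf("non-ACGTN characters in contig(s): %s",
            paste(names(contigs)[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(contigs)
  out
}

#' Write contigs to FASTA
#' @param contigs A named \code{DNAStringSet} or named character vector.
#' @param path Output path.
#' @export
write_genome_fasta <- function(contigs, path) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts features of the requested types and converts them to the internal
#' 0-based half-open convention. The start-codon position is the span start on
#' the + strand and span end − 1 on the − strand.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep (default gene and CDS; if both
#'   are present for the same ID the gene record wins).
#' @param contigs Optional \code{DNAStringSet}; when given, features beyond
#'   contig bounds raise an error.
#' @return A data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open) and
#'   \code{start_codon_pos}.
#' @export
read_gff_genes <- function(path, feature_types = c("gene", "CDS"), contigs = NULL) {
  if (!file.exists(path)) stopf("GFF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) stopf("no %s features in %s",
                              paste(feature_types, collapse = "/"), path)
  ids <- as.character(gr$ID)
  if (length(ids) != length(gr) || any(is.na(ids) | ids == ""))
    stopf("feature(s) without an ID attribute in %s", path)
  # prefer the first listed feature type for duplicated IDs
  ord <- order(match(as.character(gr$type), feature_types))
  gr <- gr[ord][!duplicated(ids[ord])]
  genes <- data.frame(
    gene_id   = as.character(gr$ID),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    strand    = as.character(BiocGenerics::strand(gr)),
    start     = BiocGenerics::start(gr) - 1L,  # GFF 1-based inclusive -> 0-based half-open
    end       = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(!genes$strand %in% c("+", "-")))
    stopf("gene(s) without +/- strand in %s", path)
  genes$start_codon_pos <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (!is.null(contigs)) {
    len <- stats::setNames(Biostrings::width(contigs), names(contigs))
    bad <- is.na(len[genes$contig_id]) | genes$end > len[genes$contig_id] | genes$start < 0L
    if (any(bad))
      stopf("feature(s) beyond contig bounds: %s",
            paste(genes$gene_id[bad], collapse = ", "))
  }
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#' @param genes A gene table as returned by \code{read_gff_genes}.
#' @param path Output path.
#' @param feature_type Feature type to emit (default \code{"gene"}).
#' @export
write_gff_genes <- function(genes, path, feature_type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges   = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand   = genes$strand
  )
  gr$type <- feature_type
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the upstream region of a gene
#'
#' Returns the sequence between \code{near} and \code{far} bp upstream of the
#' start codon, on the gene's sense strand (5'->3' toward the start codon).
#' Reverse-strand genes yield the reverse complement of the mirror interval.
#' The window is clipped at contig ends with a warning; a window entirely off
#' the contig yields an empty region, not an error.
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param gene A single-row gene table (see \code{read_gff_genes}).
#' @param near,far Window bounds in bp upstream of the start codon
#'   (\code{near < far}); the extracted genomic interval has length
#'   \code{far - near} when unclipped.
#' @return An object of class \code{upstream_region}: a list with
#'   \code{gene_id}, \code{sequence}, \code{strand}, \code{contig_id},
#'   \code{genomic_start}/\code{genomic_end} (0-based half-open interval on
#'   the reference strand), \code{near} and \code{far}. Region position j
#'   (1-based, sense strand) maps to upstream distance \code{far - j + 1}
#'   when unclipped; \code{region_to_genomic} gives genomic coordinates.
#' @export
extract_upstream <- function(contigs, gene, near = 10L, far = 200L) {
  stopifnot(near < far, nrow(gene) == 1L)
  if (!gene$contig_id %in% names(contigs))
    stopf("unknown contig for gene %s: %s", gene$gene_id, gene$contig_id)
  clen <- length(contigs[[gene$contig_id]])
  if (gene$strand == "+") {
    g0 <- gene$start_codon_pos - far
    g1 <- gene$start_codon_pos - near
  } else {
    g0 <- gene$start_codon_pos + 1L + near
    g1 <- gene$start_codon_pos + 1L + far
  }
  c0 <- max(g0, 0L); c1 <- min(g1, clen)
  if (c0 >= c1) {
    seq <- ""
    c0 <- c1 <- max(min(c0, clen), 0L)
  } else {
    if (c0 > g0 || c1 < g1)
      warnf("upstream window of %s clipped at contig end (%d of %d bp kept)",
            gene$gene_id, c1 - c0, far - near)
    seq <- as.character(Biostrings::subseq(contigs[[gene$contig_id]],
                                           start = c0 + 1L, end = c1))
    if (gene$strand == "-") seq <- revcomp(seq)
  }
  structure(list(gene_id = gene$gene_id, sequence = seq, strand = gene$strand,
                 contig_id = gene$contig_id, genomic_start = c0, genomic_end = c1,
                 near = near, far = far),
            class = "upstream_region")
}

#' Map a region position to a genomic coordinate
#' @param region An \code{upstream_region}.
#' @param pos 1-based position(s) within the region sequence.
#' @return 0-based genomic coordinate(s) of the base on the reference strand.
#' @export
region_to_genomic <- function(region, pos) {
  n <- nchar(region$sequence)
  stopifnot(all(pos >= 1L & pos <= n))
  if (region$strand == "+") region$genomic_start + pos - 1L
  else region$genomic_end - pos
}

#' @export
print.upstream_region <- function(x, ...) {
  cat(sprintf("upstream region of %s (%s strand): %d bp, %s:[%d,%d)\n",
              x$gene_id, x$strand, nchar(x$sequence), x$contig_id,
              x$genomic_start, x$genomic_end))
  invisible(x)
}

PROMOTER_COLUMNS <- c("target_id", "minus35", "spacer", "minus10",
                      "distance_bp", "validated", "promoter_class")

#' Validate promoter entries
#'
#' Checks the two-block promoter invariants: 4-bp -35 element, 5-bp -10
#' element, spacer length 16 or 17, non-negative distance, and a known
#' promoter class.
#'
#' @param entries A promoter table (data.frame).
#' @return The table, invisibly; errors name the offending row.
#' @export
validate_promoter_entries <- function(entries) {
  missing_cols <- setdiff(PROMOTER_COLUMNS, names(entries))
  if (length(missing_cols) > 0L)
    stopf("promoter table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  check <- function(ok, what) {
    if (any(!ok))
      stopf("invalid %s in promoter row(s): %s", what,
            paste(entries$target_id[!ok], collapse = ", "))
  }
  check(nchar(entries$minus35) == 4L & grepl("^[ACGT]+$", entries$minus35), "-35 element")
  check(nchar(entries$minus10) == 5L & grepl("^[ACGT]+$", entries$minus10), "-10 element")
  check(nchar(entries$spacer) %in% c(16L, 17L) & grepl("^[ACGT]+$", entries$spacer),
        "spacer (length must be 16 or 17)")
  check(entries$distance_bp >= 0L, "distance to start codon")
  check(entries$promoter_class %in% c("I", "II", "III", "unassigned"), "promoter class")
  invisible(entries)
}

#' Read a promoter table
#'
#' TSV with header columns target_id, minus35, spacer, minus10, distance_bp,
#' validated, promoter_class. Row order is preserved and every row is checked
#' against the promoter invariants.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of promoter entries.
#' @export
read_promoter_table <- function(path) {
  if (!file.exists(path)) stopf("promoter table not found: %s", path)
  entries <- utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(distance_bp = "integer",
                                              validated = "logical"))
  validate_promoter_entries(entries)
  entries
}

#' Write a promoter table
#' @param entries Promoter table.
#' @param path Output path.
#' @export
write_promoter_table <- function(entries, path) {
  validate_promoter_entries(entries)
  utils::write.table(entries[, PROMOTER_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full promoter sequence of each entry
#'
#' Concatenates the -35 element, spacer and -10 element (25 bp for a 16-bp
#' spacer, 26 bp for a 17-bp spacer).
#' @param entries Promoter table.
#' @return Character vector named by target id.
#' @export
promoter_sequence <- function(entries) {
  stats::setNames(paste0(entries$minus35, entries$spacer, entries$minus10),
                  entries$target_id)
}

#' Packaged sigma-E promoter tables
#'
#' \code{sigE_table1()} returns the 91 predicted sigma-E target promoters of
#' the S. coelicolor regulon screen; \code{sigE_validated_promoters()} the 19
#' promoters validated by transcript mapping / in vitro transcription, with
#' their Class I/II/III dependence labels.
#' @return A promoter table (data.frame).
#' @export
sigE_table1 <- function() {
  read_promoter_table(system.file("extdata", "table1_promoters.tsv",
                                  package = "ecfmap", mustWork = TRUE))
}

#' @rdname sigE_table1
#' @export
sigE_validated_promoters <- function() {
  read_promoter_table(system.file("extdata", "validated_promoters.tsv",
                                  package = "ecfmap", mustWork = TRUE))
}
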