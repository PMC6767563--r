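# Windowed enrichment peak calling of ChIP coverage against an input control.

#' Peak-calling parameters
#'
#' @param window_bp Tiling window width in bp (the screen used 25-bp windows).
#' @param p_threshold Per-window significance threshold (default 1e-4, the
#'   raw threshold used in the original screen; no multiple-testing
#'   correction unless \code{fdr = TRUE}).
#' @param min_enrichment Minimum library-size-normalised ChIP/control ratio.
#' @param merge_gap_bp Significant windows at most this far apart are merged
#'   into one peak.
#' @param fdr Apply Benjamini-Hochberg correction and threshold the adjusted
#'   p-values instead.
#' @return A list of class \code{peak_params}.
#' @export
peak_params <- function(window_bp = 25L, p_threshold = 1e-4,
                        min_enrichment = 2, merge_gap_bp = 25L, fdr = FALSE) {
  stopifnot(window_bp >= 1L, p_threshold > 0, p_threshold < 1,
            min_enrichment >= 0, merge_gap_bp >= 0L)
  structure(list(window_bp = as.integer(window_bp), p_threshold = p_threshold,
                 min_enrichment = min_enrichment,
                 merge_gap_bp = as.integer(merge_gap_bp), fdr = fdr),
            class = "peak_params")
}

#' Construct a coverage track
#'
#' @param contig_id Contig the track covers.
#' @param counts Non-negative integer vector of per-base read counts, one
#'   entry per contig base.
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(contig_id, counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  structure(list(contig_id = contig_id, counts = as.numeric(counts),
                 library_size = sum(counts)),
            class = "coverage_track")
}

#' Read a coverage track from TSV or bedGraph
#'
#' Accepts a 4-column table (contig, start0, end0, count) covering one
#' contig; intervals may be sparse, uncovered bases get count 0.
#'
#' @param path File path (plain TSV or bedGraph; both are 0-based half-open).
#' @param length Optional contig length; defaults to the largest end seen.
#' @return A \code{coverage_track}.
#' @export
read_coverage_track <- function(path, length = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("contig", "start", "end", "count"),
                           comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[!grepl("^track", tab$contig), , drop = FALSE]
  if (nrow(tab) == 0L) stopf("empty coverage file: %s", path)
  cid <- unique(tab$contig)
  if (length(cid) != 1L)
    stopf("coverage file %s spans multiple contigs: %s", path,
          paste(cid, collapse = ", "))
  L <- as.integer(length %||% max(tab$end))
  counts <- numeric(L)
  for (i in seq_len(nrow(tab)))
    counts[(tab$start[i] + 1L):tab$end[i]] <- tab$count[i]
  coverage_track(cid, counts)
}

#' Write a coverage track as bedGraph
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @export
write_coverage_track <- function(track, path) {
  r <- rle(track$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  utils::write.table(
    data.frame(track$contig_id, starts, ends, r$values)[keep, , drop = FALSE],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Sum of counts per tiling window; the trailing partial window is kept.
window_sums <- function(counts, window_bp) {
  n <- length(counts)
  idx <- (seq_len(n) - 1L) %/% window_bp
  as.numeric(tapply(counts, idx, sum))
}

#' Call enrichment peaks against an input control
#'
#' The contig is tiled in \code{window_bp} windows and each window's ChIP
#' count is compared with the control count by the exact conditional test for
#' the ratio of two Poisson rates: given the window total n = chip + control,
#' the ChIP count is Binomial(n, r/(1+r)) under the null, with r the
#' chip/control library-size ratio. Windows passing both the p-value and
#' enrichment thresholds are merged when at most \code{merge_gap_bp} apart;
#' each merged peak is annotated with its best window as the summit (lowest
#' p-value, ties by higher enrichment, then leftmost).
#'
#' @param chip,control \code{coverage_track}s over the same contig.
#' @param params A \code{peak_params} object.
#' @return A data.frame of peak calls with 0-based half-open \code{start} /
#'   \code{end}, the 25-bp \code{summit_start}/\code{summit_end}, the summit
#'   \code{enrichment} and \code{p_value}.
#' @export
call_peaks <- function(chip, control, params = peak_params()) {
  if (!identical(chip$contig_id, control$contig_id))
    stopf("chip and control tracks cover different contigs (%s vs %s)",
          chip$contig_id, control$contig_id)
  if (length(chip$counts) != length(control$counts))
    stopf("chip and control tracks have different lengths")
  if (control$library_size == 0)
    stopf("all-zero control track; supply a pseudo-flat control (e.g. constant expected depth)")
  if (chip$library_size == 0) stopf("all-zero ChIP track")
  w <- params$window_bp
  cw <- window_sums(chip$counts, w)
  tw <- window_sums(control$counts, w)
  ratio <- chip$library_size / control$library_size
  pr <- ratio / (1 + ratio)
  p <- stats::pbinom(cw - 1, size = cw + tw, prob = pr, lower.tail = FALSE)
  # library-size-normalised ratio; 0.5 pseudocount guards empty control windows
  enr <- (cw / chip$library_size) / (pmax(tw, 0.5) / control$library_size)
  pcrit <- if (params$fdr) stats::p.adjust(p, "BH") else p
  sig <- which(pcrit <= params$p_threshold & enr >= params$min_enrichment)
  if (length(sig) == 0L)
    return(data.frame(contig_id = character(), start = integer(), end = integer(),
                      summit_start = integer(), summit_end = integer(),
                      enrichment = numeric(), p_value = numeric()))
  n <- length(cw)
  win_start <- (sig - 1L) * w
  win_end <- pmin(sig * w, length(chip$counts))
  grp <- cumsum(c(1L, as.integer((win_start[-1] - win_end[-length(sig)]) > params$merge_gap_bp)))
  out <- do.call(rbind, lapply(split(seq_along(sig), grp), function(ii) {
    wi <- sig[ii]
    best <- ii[order(p[wi], -enr[wi], wi)][1L]
    data.frame(contig_id = chip$contig_id,
               start = win_start[ii[1L]], end = win_end[ii[length(ii)]],
               summit_start = win_start[best], summit_end = win_end[best],
               enrichment = enr[sig[best]], p_value = p[sig[best]])
  }))
  rownames(out) <- NULL
  out
}

#' Per-window p-values without peak assembly
#'
#' Exposes the per-window test used by \code{call_peaks}, e.g. for
#' calibration checks.
#' @inheritParams call_peaks
#' @return Numeric vector of one-sided p-values, one per tiling window.
#' @export
window_pvalues <- function(chip, control, params = peak_params()) {
  cw <- window_sums(chip$counts, params$window_bp)
  tw <- window_sums(control$counts, params$window_bp)
  ratio <- chip$library_size / control$library_size
  stats::pbinom(cw - 1, size = cw + tw, prob = ratio / (1 + ratio),
                lower.tail = FALSE)
}

#' Flank a peak summit
#'
#' Extends the summit window by \code{flank_bp} on each side (>= 200 bp total
#' at the defaults), clipped at contig ends.
#'
#' @param peaks Peak table from \code{call_peaks}.
#' @param flank_bp Flank width per side.
#' @param contig_length Length of the contig, for clipping.
#' @return Data.frame with 0-based half-open \code{start}/\code{end}.
#' @export
summit_flank <- function(peaks, flank_bp = 100L, contig_length = Inf) {
  start <- peaks$summit_start - flank_bp
  end <- peaks$summit_end + flank_bp
  clipped <- start < 0L | end > contig_length
  if (any(clipped))
    warnf("%d summit flank(s) clipped at contig ends", sum(clipped))
  data.frame(contig_id = peaks$contig_id,
             start = pmax(start, 0L),
             end = pmin(end, contig_length),
             summit_start = peaks$summit_start,
             summit_end = peaks$summit_end)
}

#' Write peaks as BED6 plus enrichment and p-value columns
#' @param peaks Peak table from \code{call_peaks}.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$contig_id, peaks$start, peaks$end,
                    sprintf("peak_%d", seq_len(nrow(peaks))),
                    round(-10 * log10(pmax(peaks$p_value, 1e-300))), ".",
                    peaks$enrichment, peaks$p_value)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
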