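# Two-block promoter PWMs and upstream-window scanning.
#
# A two-block PWM carries probabilities only for the -35 (4 columns) and -10
# (5 columns) blocks; spacer columns are score-neutral. This makes spacer
# normalization exact: the same 19 validated promoters yield both the 16-bp
# and 17-bp spacer models, differing only in the gap the scanner uses, with
# no arbitrary choice of which spacer base to drop or duplicate.

#' Build a two-block PWM from promoter entries
#'
#' Count matrices are accumulated over all entries (spacer columns carry no
#' probabilities, so 16- and 17-bp-spacer promoters contribute alike);
#' probabilities are (count + pseudocount) / (N + 4 pseudocount). The core is
#' the \code{core_size} columns of highest information content
#' (Kullback-Leibler divergence from the background), ties broken 5'-first.
#' The per-source-site scores stored in the object define the detection
#' thresholds used by the scanner (see \code{scan_params}).
#'
#' @param promoters Promoter table (see \code{read_promoter_table}).
#' @param spacer_len Gap length this model scans with (16 or 17).
#' @param pseudocount Per-cell pseudocount.
#' @param background Mononucleotide background frequencies.
#' @param core_size Number of core columns.
#' @param name Model name; default \code{PWM_<N>_<spacer>}.
#' @return An object of class \code{two_block_pwm}.
#' @export
build_pwm <- function(promoters, spacer_len, pseudocount = 0.5,
                      background = default_background(), core_size = 6L,
                      name = NULL) {
  if (nrow(promoters) == 0L) stopf("empty promoter list")
  if (!spacer_len %in% c(16L, 17L)) stopf("spacer_len must be 16 or 17")
  if (any(grepl("[^ACGT]", c(promoters$minus35, promoters$minus10))))
    stopf("promoter blocks must be plain ACGT")
  n <- nrow(promoters)
  count_block <- function(seqs, width) {
    m <- matrix(0, 4L, width, dimnames = list(DNA_BASES, NULL))
    for (s in seqs) {
      v <- encode_dna(s)
      for (k in seq_len(width)) m[v[k], k] <- m[v[k], k] + 1
    }
    m
  }
  c35 <- count_block(promoters$minus35, 4L)
  c10 <- count_block(promoters$minus10, 5L)
  bg <- background[DNA_BASES] / sum(background[DNA_BASES])
  to_prob <- function(m) sweep(m + pseudocount, 2, colSums(m) + 4 * pseudocount, "/")
  p35 <- to_prob(c35); p10 <- to_prob(c10)
  lo35 <- log2(p35 / bg); lo10 <- log2(p10 / bg)
  ic <- c(colSums(p35 * log2(p35 / bg)), colSums(p10 * log2(p10 / bg)))
  core <- sort(order(-ic, seq_along(ic))[seq_len(core_size)])
  pwm <- structure(list(
    name = name %||% sprintf("PWM_%d_%d", n, spacer_len),
    counts35 = c35, counts10 = c10, prob35 = p35, prob10 = p10,
    logodds35 = lo35, logodds10 = lo10, spacer_len = as.integer(spacer_len),
    pseudocount = pseudocount, background = bg,
    core_positions = core, information = ic,
    n_promoters = n), class = "two_block_pwm")
  sc <- score_site(pwm, promoters$minus35, promoters$minus10)
  pwm$training_full <- sc$raw
  pwm$training_core <- sc$core_raw
  pwm
}

#' Build both spacer variants of the promoter PWM
#' @inheritParams build_pwm
#' @return List of two \code{two_block_pwm}s (spacer 16 and 17).
#' @export
build_pwm_pair <- function(promoters, pseudocount = 0.5,
                           background = default_background(), core_size = 6L) {
  list(build_pwm(promoters, 16L, pseudocount, background, core_size),
       build_pwm(promoters, 17L, pseudocount, background, core_size))
}

pwm_score_range <- function(pwm, core_only = FALSE) {
  lo <- cbind(pwm$logodds35, pwm$logodds10)
  if (core_only) lo <- lo[, pwm$core_positions, drop = FALSE]
  lo[!is.finite(lo)] <- -Inf
  c(min = sum(apply(lo, 2, min)), max = sum(apply(lo, 2, max)))
}

normalize_score <- function(raw, rng) {
  # zero-pseudocount models have -Inf minima: only the consensus is finite
  if (!is.finite(rng["min"])) return(as.numeric(raw >= rng["max"] - 1e-9))
  pmax(0, pmin(1, (raw - rng["min"]) / (rng["max"] - rng["min"])))
}

#' Score a candidate site under a two-block PWM
#'
#' Raw score is the summed log2 odds of each block base versus the
#' background over the -35 and -10 columns (spacer excluded); N bases score
#' at background (contribution 0). Normalized score is
#' (raw - min possible) / (max possible - min possible), and likewise over
#' the core columns only.
#'
#' @param pwm A \code{two_block_pwm}.
#' @param minus35,minus10 Character vectors of 4-mers and 5-mers.
#' @return List with \code{raw}, \code{normalized}, \code{core_raw},
#'   \code{core_normalized} (vectorised over sites).
#' @export
score_site <- function(pwm, minus35, minus10) {
  stopifnot(length(minus35) == length(minus10))
  if (any(nchar(minus35) != 4L) || any(nchar(minus10) != 5L))
    stopf("block lengths must match the PWM widths (4 and 5)")
  core35 <- pwm$core_positions[pwm$core_positions <= 4L]
  core10 <- pwm$core_positions[pwm$core_positions > 4L] - 4L
  raw <- core_raw <- numeric(length(minus35))
  for (i in seq_along(minus35)) {
    v35 <- encode_dna(minus35[i]); v10 <- encode_dna(minus10[i])
    s35 <- pwm$logodds35[cbind(v35, 1:4)]
    s10 <- pwm$logodds10[cbind(v10, 1:5)]
    s35[is.na(s35)] <- 0; s10[is.na(s10)] <- 0
    raw[i] <- sum(s35) + sum(s10)
    core_raw[i] <- sum(s35[core35]) + sum(s10[core10])
  }
  rng <- pwm_score_range(pwm)
  crng <- pwm_score_range(pwm, core_only = TRUE)
  list(raw = raw, normalized = normalize_score(raw, rng),
       core_raw = core_raw, core_normalized = normalize_score(core_raw, crng))
}

#' Scan parameters
#'
#' \code{sensitivity} and \code{core_sensitivity} are guaranteed recall
#' levels on the PWM's source promoters: the detection threshold is the
#' empirical (1 - sensitivity) quantile of the source-site scores, so at the
#' default of 1 the threshold is the weakest source promoter and every
#' promoter the PWM was built from is detectable by construction. The full
#' score and the core (6 most informative columns) score must both pass.
#'
#' @param sensitivity,core_sensitivity Guaranteed source-site recall in
#'   [0, 1] for the full and core scores.
#' @param core_size Number of core columns (set when the PWM is built).
#' @param near_bp,far_bp Upstream scan window in bp from the start codon.
#' @return A list of class \code{scan_params}.
#' @export
scan_params <- function(sensitivity = 1, core_sensitivity = 1, core_size = 6L,
                        near_bp = 10L, far_bp = 200L) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            core_sensitivity >= 0, core_sensitivity <= 1, near_bp < far_bp)
  structure(list(sensitivity = sensitivity, core_sensitivity = core_sensitivity,
                 core_size = as.integer(core_size),
                 near_bp = as.integer(near_bp), far_bp = as.integer(far_bp)),
            class = "scan_params")
}

pwm_thresholds <- function(pwm, params) {
  list(full = stats::quantile(pwm$training_full, probs = 1 - params$sensitivity,
                              type = 1, names = FALSE),
       core = stats::quantile(pwm$training_core,
                              probs = 1 - params$core_sensitivity,
                              type = 1, names = FALSE))
}

#' Scan a bare sequence with two-block PWMs
#'
#' Evaluates every start offset of every supplied PWM (i.e. both spacer
#' lengths) and emits hits passing both detection thresholds.
#'
#' @param pwms A \code{two_block_pwm} or list of them.
#' @param seq A DNA string.
#' @param params A \code{scan_params}.
#' @return Data.frame of hits: \code{pwm}, \code{offset} (1-based site
#'   start), \code{gap}, \code{raw}, \code{normalized}, \code{core_raw},
#'   \code{core_normalized}, sorted by normalized score (descending), then
#'   offset.
#' @export
scan_sequence <- function(pwms, seq, params = scan_params()) {
  if (inherits(pwms, "two_block_pwm")) pwms <- list(pwms)
  out <- list()
  s <- encode_dna(seq)
  for (pwm in pwms) {
    span <- 4L + pwm$spacer_len + 5L
    if (length(s) < span) next
    thr <- pwm_thresholds(pwm, params)
    core35 <- pwm$core_positions[pwm$core_positions <= 4L]
    core10 <- pwm$core_positions[pwm$core_positions > 4L] - 4L
    zero_noncore <- function(M, keep) { M[, setdiff(seq_len(ncol(M)), keep)] <- 0; M }
    s35 <- block_scores(s, pwm$logodds35)
    s10 <- block_scores(s, pwm$logodds10)
    s35c <- block_scores(s, zero_noncore(pwm$logodds35, core35))
    s10c <- block_scores(s, zero_noncore(pwm$logodds10, core10))
    off <- seq_len(length(s) - span + 1L)
    raw <- s35[off] + s10[off + 4L + pwm$spacer_len]
    core_raw <- s35c[off] + s10c[off + 4L + pwm$spacer_len]
    keep <- raw >= thr$full - 1e-9 & core_raw >= thr$core - 1e-9
    if (!any(keep)) next
    rng <- pwm_score_range(pwm); crng <- pwm_score_range(pwm, TRUE)
    out[[length(out) + 1L]] <- data.frame(
      pwm = pwm$name, offset = off[keep], gap = pwm$spacer_len,
      raw = raw[keep], normalized = normalize_score(raw[keep], rng),
      core_raw = core_raw[keep],
      core_normalized = normalize_score(core_raw[keep], crng))
  }
  if (length(out) == 0L)
    return(data.frame(pwm = character(), offset = integer(), gap = integer(),
                      raw = numeric(), normalized = numeric(),
                      core_raw = numeric(), core_normalized = numeric()))
  hits <- do.call(rbind, out)
  hits <- hits[order(-hits$normalized, hits$offset, hits$gap), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan an upstream region for promoter sites
#'
#' As \code{scan_sequence}, on the sense-strand sequence of an upstream
#' region, with hits annotated with the gene, genomic coordinates and the
#' distance from the 3' end of the -10 element to the start codon. Hits are
#' sorted by normalized score (descending), ties by smaller distance, then
#' leftmost genomic coordinate.
#'
#' @param pwms A \code{two_block_pwm} or list of them.
#' @param region An \code{upstream_region}.
#' @param params A \code{scan_params}.
#' @return Data.frame of site hits (possibly empty).
#' @export
scan_region <- function(pwms, region, params = scan_params()) {
  hits <- scan_sequence(pwms, region$sequence, params)
  n <- nchar(region$sequence)
  if (nrow(hits) == 0L) {
    hits$gene_id <- character(0); hits$distance_bp <- integer(0)
    hits$genomic_start <- integer(0); hits$genomic_end <- integer(0)
    return(hits)
  }
  span <- 4L + hits$gap + 5L
  site_end_pos <- hits$offset + span - 1L             # region pos of last -10 base
  hits$gene_id <- region$gene_id
  hits$distance_bp <- region$near + (n - site_end_pos)
  if (region$strand == "+") {
    hits$genomic_start <- region$genomic_start + hits$offset - 1L
    hits$genomic_end <- hits$genomic_start + span
  } else {
    hits$genomic_end <- region$genomic_end - (hits$offset - 1L)
    hits$genomic_start <- hits$genomic_end - span
  }
  hits <- hits[order(-hits$normalized, hits$distance_bp, hits$genomic_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan the upstream windows of many genes
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param genes Gene table.
#' @param pwms PWM or list of PWMs.
#' @param params \code{scan_params}; the window is
#'   [\code{near_bp}, \code{far_bp}] upstream of each start codon.
#' @param best_only Keep only the best hit per gene.
#' @return Data.frame of site hits across genes.
#' @export
scan_upstream <- function(contigs, genes, pwms, params = scan_params(),
                          best_only = TRUE) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    region <- suppressWarnings(
      extract_upstream(contigs, genes[i, ], params$near_bp, params$far_bp))
    hits <- scan_region(pwms, region, params)
    if (best_only && nrow(hits) > 1L) hits <- hits[1L, , drop = FALSE]
    hits
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Candidate-promoter screening rule
#'
#' Formalises the conservation screen that produced the original candidate
#' list: an AAC-like -35 and a TC-bearing -10 within 400 bp of a start
#' codon. The -35 must match \code{minus35_pattern} at block positions
#' 1..nchar(pattern) with at most \code{minus35_max_mismatch} mismatches; the
#' -10 must contain \code{minus10_pattern} starting at one of
#' \code{minus10_offsets} with at most \code{minus10_max_mismatch}
#' mismatches.
#'
#' @param minus35_pattern,minus35_max_mismatch -35 pattern and tolerance.
#' @param minus10_pattern,minus10_offsets,minus10_max_mismatch -10 pattern,
#'   allowed 1-based start positions within the 5-mer, and tolerance.
#' @param max_distance_bp Maximum distance from the -10 to the start codon.
#' @param spacer_range Allowed spacer lengths.
#' @return A list of class \code{candidate_rule}.
#' @export
candidate_rule <- function(minus35_pattern = "AAC", minus35_max_mismatch = 1L,
                           minus10_pattern = "TC", minus10_offsets = c(3L, 4L),
                           minus10_max_mismatch = 1L, max_distance_bp = 400L,
                           spacer_range = c(16L, 17L)) {
  structure(list(minus35_pattern = minus35_pattern,
                 minus35_max_mismatch = as.integer(minus35_max_mismatch),
                 minus10_pattern = minus10_pattern,
                 minus10_offsets = as.integer(minus10_offsets),
                 minus10_max_mismatch = as.integer(minus10_max_mismatch),
                 max_distance_bp = as.integer(max_distance_bp),
                 spacer_range = as.integer(spacer_range)),
            class = "candidate_rule")
}

mismatches <- function(x, pattern, at = 1L) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  xs <- strsplit(x, "", fixed = TRUE)
  vapply(xs, function(v) sum(v[at + seq_along(p) - 1L] != p), integer(1))
}

rule_matches <- function(rule, minus35, minus10) {
  ok35 <- mismatches(minus35, rule$minus35_pattern) <= rule$minus35_max_mismatch
  ok10 <- rep(FALSE, length(minus10))
  for (o in rule$minus10_offsets)
    ok10 <- ok10 | mismatches(minus10, rule$minus10_pattern, o) <= rule$minus10_max_mismatch
  ok35 & ok10
}

#' Screen peaks for candidate target promoters
#'
#' Stage 1 applies the pattern rule at every offset and spacer length on the
#' sense-strand upstream window (within \code{max_distance_bp} of the start
#' codon) of every gene whose window overlaps a peak's summit flank. Stage 2
#' (when a discovered motif is supplied) rescores the stage-1 candidates
#' with the motif log-odds and keeps the best per peak-gene pair. Peaks with
#' no gene window in reach are reported as orphans.
#'
#' @param peaks Peak table from \code{call_peaks}.
#' @param contigs Named \code{DNAStringSet}.
#' @param genes Gene table.
#' @param rule A \code{candidate_rule}.
#' @param motif Optional \code{two_block_motif} from \code{gibbs_two_block}.
#' @param flank_bp Summit flank used to associate peaks with genes.
#' @return A promoter table of candidates with extra columns \code{peak},
#'   \code{gene_id}, \code{genomic_start}, \code{motif_score}; orphan peak
#'   indices in attribute \code{"orphans"}.
#' @export
candidate_promoters <- function(peaks, contigs, genes, rule = candidate_rule(),
                                motif = NULL, flank_bp = 100L) {
  clen <- Biostrings::width(contigs)[match(peaks$contig_id, names(contigs))]
  flanks <- data.frame(start = pmax(peaks$summit_start - flank_bp, 0L),
                       end = pmin(peaks$summit_end + flank_bp, clen))
  if (!is.null(motif)) {
    mlo35 <- counts_to_logodds(motif$counts35, 0, motif$params$pseudocount,
                               motif$background)
    mlo10 <- counts_to_logodds(motif$counts10, 0, motif$params$pseudocount,
                               motif$background)
  }
  # search window reaches one full site span past the distance bound so a
  # -10 element at exactly max_distance_bp is still found intact
  span_max <- 4L + max(rule$spacer_range) + 5L
  reach <- rule$max_distance_bp + span_max
  rows <- list(); orphans <- integer(0)
  for (p in seq_len(nrow(peaks))) {
    fs <- flanks$start[p]; fe <- flanks$end[p]
    found <- FALSE
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$contig_id != peaks$contig_id[p]) next
      if (g$strand == "+") {
        u0 <- g$start_codon_pos - reach; u1 <- g$start_codon_pos
      } else {
        u0 <- g$start_codon_pos + 1L; u1 <- g$start_codon_pos + 1L + reach
      }
      if (fe <= u0 || fs >= u1) next
      region <- suppressWarnings(extract_upstream(contigs, g, 0L, reach))
      n <- nchar(region$sequence)
      cand <- list()
      for (gap in rule$spacer_range) {
        span <- 4L + gap + 5L
        if (n < span) next
        off <- seq_len(n - span + 1L)
        m35 <- substring(region$sequence, off, off + 3L)
        m10 <- substring(region$sequence, off + 4L + gap, off + span - 1L)
        ok <- rule_matches(rule, m35, m10)
        if (!any(ok)) next
        cand[[length(cand) + 1L]] <- data.frame(
          target_id = g$gene_id, minus35 = m35[ok],
          spacer = substring(region$sequence, off[ok] + 4L, off[ok] + 3L + gap),
          minus10 = m10[ok], distance_bp = n - (off[ok] + span - 1L),
          validated = FALSE, promoter_class = "unassigned",
          peak = p, gene_id = g$gene_id,
          genomic_start = if (g$strand == "+") region$genomic_start + off[ok] - 1L
                          else region$genomic_end - (off[ok] - 1L) - span,
          stringsAsFactors = FALSE)
      }
      if (length(cand) == 0L) next
      cand <- do.call(rbind, cand)
      cand <- cand[cand$distance_bp <= rule$max_distance_bp, , drop = FALSE]
      if (nrow(cand) == 0L) next
      if (!is.null(motif)) {
        sc <- vapply(seq_len(nrow(cand)), function(k) {
          v35 <- encode_dna(cand$minus35[k]); v10 <- encode_dna(cand$minus10[k])
          sum(mlo35[cbind(v35, 1:4)], na.rm = TRUE) +
            sum(mlo10[cbind(v10, 1:5)], na.rm = TRUE)
        }, numeric(1))
        cand$motif_score <- sc
        cand <- cand[order(-sc, cand$distance_bp, cand$genomic_start), , drop = FALSE]
        cand <- cand[1L, , drop = FALSE]
      } else {
        cand$motif_score <- NA_real_
      }
      rows[[length(rows) + 1L]] <- cand
      found <- TRUE
    }
    if (!found) orphans <- c(orphans, p)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(target_id = character(), minus35 = character(), spacer = character(),
               minus10 = character(), distance_bp = integer(), validated = logical(),
               promoter_class = character(), peak = integer(), gene_id = character(),
               genomic_start = integer(), motif_score = numeric())
  rownames(out) <- NULL
  attr(out, "orphans") <- orphans
  out
}

#' Export a PWM's count matrices as a logo table
#'
#' Lossless position-by-base count export (pseudocount excluded); spacer
#' columns are marked as gap rows with zero counts, so standard logo tools
#' can draw the full two-block layout.
#'
#' @param pwm A \code{two_block_pwm}.
#' @return Data.frame with columns \code{position}, \code{block},
#'   \code{gap}, and counts \code{A}, \code{C}, \code{G}, \code{T}.
#' @export
export_logo_counts <- function(pwm) {
  blocks <- c(rep("minus35", 4L), rep("spacer", pwm$spacer_len), rep("minus10", 5L))
  counts <- matrix(0, length(blocks), 4L, dimnames = list(NULL, DNA_BASES))
  counts[blocks == "minus35", ] <- t(pwm$counts35)
  counts[blocks == "minus10", ] <- t(pwm$counts10)
  data.frame(position = seq_along(blocks), block = blocks,
             gap = blocks == "spacer", counts)
}

#' Write / read a two-block PWM as TSV with metadata headers
#'
#' The file stores the count matrices plus \code{#}-prefixed metadata lines
#' (name, spacer length, pseudocount, background, source-site scores), which
#' is sufficient to reconstruct the model exactly.
#' @param pwm A \code{two_block_pwm}.
#' @param path File path.
#' @export
write_pwm <- function(pwm, path) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- c(sprintf("#name\t%s", pwm$name),
            sprintf("#spacer_len\t%d", pwm$spacer_len),
            sprintf("#pseudocount\t%.10g", pwm$pseudocount),
            sprintf("#background\t%s", paste(sprintf("%.10g", pwm$background), collapse = ",")),
            sprintf("#core_size\t%d", length(pwm$core_positions)),
            sprintf("#training_full\t%s", paste(sprintf("%.10g", pwm$training_full), collapse = ",")),
            sprintf("#training_core\t%s", paste(sprintf("%.10g", pwm$training_core), collapse = ",")))
  writeLines(meta, con)
  tab <- export_logo_counts(pwm)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- stats::setNames(sub("^#\\S+\t", "", meta_lines),
                          sub("^#(\\S+)\t.*$", "\\1", meta_lines))
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  bg <- stats::setNames(as.numeric(strsplit(meta[["background"]], ",")[[1]]), DNA_BASES)
  c35 <- t(as.matrix(tab[tab$block == "minus35", DNA_BASES]))
  c10 <- t(as.matrix(tab[tab$block == "minus10", DNA_BASES]))
  rownames(c35) <- rownames(c10) <- DNA_BASES
  colnames(c35) <- colnames(c10) <- NULL
  # rebuild from counts; fake a promoter table with the right column sums
  pc <- as.numeric(meta[["pseudocount"]])
  to_prob <- function(m) sweep(m + pc, 2, colSums(m) + 4 * pc, "/")
  p35 <- to_prob(c35); p10 <- to_prob(c10)
  ic <- c(colSums(p35 * log2(p35 / bg)), colSums(p10 * log2(p10 / bg)))
  core <- sort(order(-ic, seq_along(ic))[seq_len(as.integer(meta[["core_size"]]))])
  structure(list(name = meta[["name"]], counts35 = c35, counts10 = c10,
                 prob35 = p35, prob10 = p10,
                 logodds35 = log2(p35 / bg), logodds10 = log2(p10 / bg),
                 spacer_len = as.integer(meta[["spacer_len"]]),
                 pseudocount = pc, background = bg, core_positions = core,
                 information = ic, n_promoters = sum(c35[, 1]),
                 training_full = as.numeric(strsplit(meta[["training_full"]], ",")[[1]]),
                 training_core = as.numeric(strsplit(meta[["training_core"]], ",")[[1]])),
            class = "two_block_pwm")
}

#' @export
print.two_block_pwm <- function(x, ...) {
  cons35 <- paste(DNA_BASES[apply(x$prob35, 2, which.max)], collapse = "")
  cons10 <- paste(DNA_BASES[apply(x$prob10, 2, which.max)], collapse = "")
  cat(sprintf("%s: %s <%d bp spacer> %s (n=%d, core columns %s)\n",
              x$name, cons35, x$spacer_len, cons10, x$n_promoters,
              paste(x$core_positions, collapse = ",")))
  invisible(x)
}
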