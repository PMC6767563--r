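# Two-block Gibbs motif sampler for gapped promoter motifs.
#
# One-occurrence-per-sequence (OOPS) model: each input sequence carries
# exactly one site, a W-mer and a w-mer separated by a gap in [g_min, g_max],
# searched on the forward strand only. Sampling follows the classic
# leave-one-out scheme: the withheld sequence's (start, gap) is drawn from
# the posterior proportional to the product of position-specific odds versus
# the background, times the gap-length frequencies of the remaining
# sequences. After the stochastic phase a deterministic argmax sweep is run
# to a fixed point so the reported optimum is reproducible.

#' Gibbs sampler parameters
#'
#' Defaults mirror the promoter search that defined the sigma-E consensus:
#' a 4-bp upstream block, a 5-bp downstream block, gap 16-17 bp, and 40
#' random reinitialisations.
#'
#' @param W,w Widths of the upstream (-35) and downstream (-10) blocks.
#' @param g_min,g_max Allowed gap lengths (inclusive).
#' @param restarts Number of random reinitialisations; the best-scoring
#'   restart is returned.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param max_iters Cap on sampling sweeps per restart.
#' @param pseudocount Added per count-matrix cell when building sampling
#'   matrices.
#' @param background Mononucleotide background; \code{NULL} uses the
#'   empirical frequencies of the input set (GC-rich genomes would otherwise
#'   inflate GC-rich spurious motifs).
#' @return A list of class \code{gibbs_params}.
#' @export
gibbs_params <- function(W = 4L, w = 5L, g_min = 16L, g_max = 17L,
                         restarts = 40L, seed = 1L, max_iters = 500L,
                         pseudocount = 0.5, background = NULL) {
  stopifnot(W >= 1L, w >= 1L, g_max >= g_min, restarts >= 1L, max_iters >= 1L,
            pseudocount > 0)
  structure(list(W = as.integer(W), w = as.integer(w),
                 g_min = as.integer(g_min), g_max = as.integer(g_max),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 max_iters = as.integer(max_iters), pseudocount = pseudocount,
                 background = background),
            class = "gibbs_params")
}

# Per-position block score of one encoded sequence under a log-odds matrix:
# out[i] = sum_k M[s[i+k-1], k]; NA bases (N) contribute 0.
block_scores <- function(s, M) {
  width <- ncol(M)
  n <- length(s) - width + 1L
  out <- numeric(n)
  for (k in seq_len(width)) {
    v <- M[s[k:(k + n - 1L)], k]
    v[is.na(v)] <- 0
    out <- out + v
  }
  out
}

# Count matrices (4 x width) from encoded sequences and their assignments.
site_counts <- function(enc, starts, gaps, W, w) {
  c35 <- matrix(0, 4L, W, dimnames = list(DNA_BASES, NULL))
  c10 <- matrix(0, 4L, w, dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(enc)) {
    b35 <- enc[[i]][starts[i]:(starts[i] + W - 1L)]
    b10 <- enc[[i]][(starts[i] + W + gaps[i]):(starts[i] + W + gaps[i] + w - 1L)]
    for (k in seq_len(W)) if (!is.na(b35[k])) c35[b35[k], k] <- c35[b35[k], k] + 1
    for (k in seq_len(w)) if (!is.na(b10[k])) c10[b10[k], k] <- c10[b10[k], k] + 1
  }
  list(c35 = c35, c10 = c10)
}

counts_to_logodds <- function(counts, n, pseudocount, background) {
  probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
  log2(probs / background[DNA_BASES])
}

#' Discover a gapped two-block motif by Gibbs sampling
#'
#' @param seqs Character vector of DNA sequences (forward strand). Each must
#'   be at least \code{W + g_max + w} long; non-ACGT bases are treated as
#'   background.
#' @param params A \code{gibbs_params} object.
#' @return An object of class \code{two_block_motif}: count matrices
#'   \code{counts35} / \code{counts10}, the gap-length table, per-sequence
#'   \code{assignments} (1-based site start and gap), the relative-entropy
#'   \code{score} in bits, the background used, and the parameters.
#' @export
gibbs_two_block <- function(seqs, params = gibbs_params()) {
  W <- params$W; w <- params$w
  span_max <- W + params$g_max + w
  if (length(seqs) < 2L) stopf("need at least 2 sequences")
  short <- nchar(seqs) < span_max
  if (any(short))
    stopf("sequence(s) shorter than the motif span (%d bp): %s", span_max,
          paste(which(short), collapse = ", "))
  enc <- lapply(seqs, encode_dna)
  bg <- params$background %||% mono_frequencies(seqs)
  bg <- bg[DNA_BASES] / sum(bg[DNA_BASES])
  gaps_allowed <- params$g_min:params$g_max
  n <- length(enc)

  # one sequence's contribution to the count matrices (added or removed)
  site_contrib <- function(c35, c10, gap_tab, s, start, gap, sign) {
    b35 <- s[start:(start + W - 1L)]
    b10 <- s[(start + W + gap):(start + W + gap + w - 1L)]
    for (k in seq_len(W)) if (!is.na(b35[k]))
      c35[b35[k], k] <- c35[b35[k], k] + sign
    for (k in seq_len(w)) if (!is.na(b10[k]))
      c10[b10[k], k] <- c10[b10[k], k] + sign
    gi <- gap - params$g_min + 1L
    gap_tab[gi] <- gap_tab[gi] + sign
    list(c35 = c35, c10 = c10, gap_tab = gap_tab)
  }

  run_restart <- function() {
    starts <- vapply(enc, function(s)
      sample.int(length(s) - span_max + 1L, 1L), integer(1))
    gaps <- sample(gaps_allowed, n, replace = TRUE)
    cts <- site_counts(enc, starts, gaps, W, w)
    c35 <- cts$c35; c10 <- cts$c10
    gap_tab <- tabulate(gaps - params$g_min + 1L, length(gaps_allowed))
    sample_sweep <- function(deterministic) {
      changed <- FALSE
      for (i in seq_len(n)) {
        held <- site_contrib(c35, c10, gap_tab, enc[[i]], starts[i], gaps[i], -1)
        M35 <- counts_to_logodds(held$c35, n - 1L, params$pseudocount, bg)
        M10 <- counts_to_logodds(held$c10, n - 1L, params$pseudocount, bg)
        s35 <- block_scores(enc[[i]], M35)
        s10 <- block_scores(enc[[i]], M10)
        gap_lw <- log2((held$gap_tab + 0.5) / sum(held$gap_tab + 0.5))
        n_start <- length(enc[[i]]) - span_max + 1L
        cand_start <- integer(0); cand_gap <- integer(0); cand_lw <- numeric(0)
        for (gi in seq_along(gaps_allowed)) {
          g <- gaps_allowed[gi]
          st <- seq_len(length(enc[[i]]) - (W + g + w) + 1L)
          cand_start <- c(cand_start, st)
          cand_gap <- c(cand_gap, rep.int(g, length(st)))
          cand_lw <- c(cand_lw, s35[st] + s10[st + W + g] + gap_lw[gi])
        }
        pick <- if (deterministic) {
          order(-cand_lw, cand_start, cand_gap)[1L]
        } else {
          p <- 2^(cand_lw - max(cand_lw))
          sample.int(length(cand_lw), 1L, prob = p)
        }
        if (cand_start[pick] != starts[i] || cand_gap[pick] != gaps[i]) changed <- TRUE
        starts[i] <<- cand_start[pick]
        gaps[i] <<- cand_gap[pick]
        back <- site_contrib(held$c35, held$c10, held$gap_tab, enc[[i]],
                             starts[i], gaps[i], +1)
        c35 <<- back$c35; c10 <<- back$c10; gap_tab <<- back$gap_tab
      }
      changed
    }
    score_now <- function()
      two_block_relative_entropy(c35, c10, params$pseudocount, bg)
    # global phase-shift move: slide every site (and/or its gap) together,
    # escaping the shift-locked optima single-sequence updates cannot leave
    try_phase_shift <- function() {
      cur <- score_now()
      best_sc <- cur; best_starts <- starts; best_gaps <- gaps
      for (ds in -2:2) for (dg in -1:1) {
        if (ds == 0L && dg == 0L) next
        ng <- gaps + dg
        bad <- ng < params$g_min | ng > params$g_max
        ng[bad] <- gaps[bad]
        ns <- starts + ds
        lim <- vapply(seq_len(n), function(i)
          length(enc[[i]]) - (W + ng[i] + w) + 1L, integer(1))
        ns <- pmin(pmax(ns, 1L), lim)
        cts <- site_counts(enc, ns, ng, W, w)
        sc <- two_block_relative_entropy(cts$c35, cts$c10, params$pseudocount, bg)
        if (sc > best_sc + 1e-9) {
          best_sc <- sc; best_starts <- ns; best_gaps <- ng
        }
      }
      if (best_sc > cur + 1e-9) {
        starts <<- best_starts; gaps <<- best_gaps
        cts <- site_counts(enc, starts, gaps, W, w)
        c35 <<- cts$c35; c10 <<- cts$c10
        gap_tab <<- tabulate(gaps - params$g_min + 1L, length(gaps_allowed))
        TRUE
      } else FALSE
    }
    best <- -Inf; stale <- 0L
    for (it in seq_len(params$max_iters)) {
      sample_sweep(deterministic = FALSE)
      sc <- score_now()
      if (sc > best + 1e-9) { best <- sc; stale <- 0L } else stale <- stale + 1L
      if (stale >= 10L) break
    }
    # deterministic polish to an assignment fixed point, interleaved with
    # phase shifts until neither improves
    repeat {
      for (it in seq_len(params$max_iters))
        if (!sample_sweep(deterministic = TRUE)) break
      if (!try_phase_shift()) break
    }
    list(starts = starts, gaps = gaps, score = score_now())
  }

  set.seed(params$seed)
  best <- NULL
  for (r in seq_len(params$restarts)) {
    res <- run_restart()
    if (is.null(best) || res$score > best$score) best <- res
  }
  cts <- site_counts(enc, best$starts, best$gaps, W, w)
  structure(list(counts35 = cts$c35, counts10 = cts$c10,
                 gap_table = table(factor(best$gaps, levels = gaps_allowed)),
                 assignments = data.frame(seq = seq_len(n), start = best$starts,
                                          gap = best$gaps),
                 score = best$score, background = bg, params = params),
            class = "two_block_motif")
}

two_block_relative_entropy <- function(c35, c10, pseudocount, background) {
  kl <- function(counts) {
    probs <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
    term <- probs * log2(probs / background[DNA_BASES])
    sum(term[probs > 0])
  }
  kl(c35) + kl(c10)
}

#' Relative entropy of a two-block motif
#'
#' Sum over the informative (-35 and -10) columns of the Kullback-Leibler
#' divergence of the pseudocounted column frequencies from the background;
#' gap columns contribute nothing.
#'
#' @param motif A \code{two_block_motif}.
#' @param background Optional background override.
#' @return Score in bits.
#' @export
motif_relative_entropy <- function(motif, background = NULL) {
  bg <- background %||% motif$background
  two_block_relative_entropy(motif$counts35, motif$counts10,
                             motif$params$pseudocount, bg)
}

#' Consensus blocks of a motif
#' @param motif A \code{two_block_motif}.
#' @return List with \code{minus35} and \code{minus10} consensus strings
#'   (ties broken alphabetically).
#' @export
motif_consensus <- function(motif) {
  cons <- function(m) paste(DNA_BASES[apply(m, 2, which.max)], collapse = "")
  list(minus35 = cons(motif$counts35), minus10 = cons(motif$counts10))
}

#' @export
print.two_block_motif <- function(x, ...) {
  cons <- motif_consensus(x)
  cat(sprintf("two-block motif: %s <gap %s-%s> %s, score %.2f bits, %d sequences\n",
              cons$minus35, x$params$g_min, x$params$g_max, cons$minus10,
              x$score, nrow(x$assignments)))
  invisible(x)
}

#' Export motif assignments as BED relative to the input sequences
#' @param motif A \code{two_block_motif}.
#' @param seq_names Optional names for the input sequences.
#' @return Data.frame in BED-like layout (0-based half-open, whole site span).
#' @export
motif_assignments_bed <- function(motif, seq_names = NULL) {
  a <- motif$assignments
  nm <- seq_names %||% sprintf("seq_%d", a$seq)
  span <- motif$params$W + a$gap + motif$params$w
  data.frame(name = nm[a$seq], start = a$start - 1L, end = a$start - 1L + span,
             gap = a$gap)
}
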