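# Shared helpers: tiny genomes, planted sequences, independent oracles.

# A sequence set with the same two-block site embedded at known positions in
# otherwise random GC-rich flanks. site_blocks = list(minus35=, minus10=);
# the spacer is drawn fresh per sequence (length `gap`).
planted_set <- function(n = 30, len = 250, site_blocks = NULL, gap = 16,
                        positions = NULL, pwm = NULL) {
  positions <- positions %||% sample(20:(len - 30), n, replace = TRUE)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- ecfmap:::random_dna(len)
    if (is.null(pwm)) {
      site <- paste0(site_blocks$minus35, ecfmap:::random_dna(gap),
                     site_blocks$minus10)
    } else {
      em <- ecfmap:::emit_site(pwm, ecfmap:::default_background(0.72))
      site <- paste0(em$minus35, em$spacer, em$minus10)
    }
    substr(s, positions[i], positions[i] + nchar(site) - 1L) <- site
    seqs[i] <- s
  }
  list(seqs = seqs, positions = positions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One + strand gene 1 kb into a contig, with a given promoter planted at a
# given distance upstream of the start codon.
planted_gene_contig <- function(entry, distance, strand = "+",
                                contig_len = 3000L, start_codon = 1000L) {
  site <- unname(promoter_sequence(entry))
  span <- nchar(site)
  seq <- ecfmap:::random_dna(contig_len)
  if (strand == "+") {
    site_start <- start_codon - distance - span   # 0-based
    substr(seq, site_start + 1L, site_start + span) <- site
    gene <- data.frame(gene_id = entry$target_id, contig_id = "chr1",
                       strand = "+", start = start_codon,
                       end = start_codon + 900L, start_codon_pos = start_codon)
  } else {
    site_start <- start_codon + 1L + distance
    substr(seq, site_start + 1L, site_start + span) <- ecfmap:::revcomp(site)
    gene <- data.frame(gene_id = entry$target_id, contig_id = "chr1",
                       strand = "-", start = start_codon - 900L,
                       end = start_codon + 1L, start_codon_pos = start_codon)
  }
  list(contigs = Biostrings::DNAStringSet(c(chr1 = seq)), genes = gene,
       site_start = site_start)
}

# Independent affine-gap Smith-Waterman (BLOSUM62), the brute-force oracle
# for align_protein. O(nm) three-matrix DP written without reference to the
# implementation.
sw_affine_oracle <- function(a, b, open = 11, ext = 1) {
  sm <- get_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- E <- F <- matrix(-Inf, n + 1L, m + 1L)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    E[i, j] <- max(M[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
    F[i, j] <- max(M[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
    M[i, j] <- max(0, max(M[i - 1L, j - 1L], E[i - 1L, j - 1L],
                          F[i - 1L, j - 1L]) + sm[A[i - 1L], B[j - 1L]])
    best <- max(best, M[i, j], E[i, j], F[i, j])
  }
  best
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

random_protein <- function(n) {
  paste(sample(ecfmap:::AA_ALPHABET[1:20], n, replace = TRUE), collapse = "")
}

# point-mutate a protein string at the given per-residue rate
mutate_str <- function(x, rate) {
  v <- strsplit(x, "")[[1]]
  hit <- stats::runif(length(v)) < rate
  v[hit] <- sample(ecfmap:::AA_ALPHABET[1:20], sum(hit), replace = TRUE)
  paste(v, collapse = "")
}
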