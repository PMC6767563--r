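test_that("PWM probabilities follow hand counts at zero pseudocount", {
  one <- data.frame(target_id = "x", minus35 = "AACC",
                    spacer = strrep("G", 16), minus10 = "CGTCT",
                    distance_bp = 50L, validated = TRUE, promoter_class = "I")
  pwm <- build_pwm(one, 16L, pseudocount = 0)
  expect_equal(unname(pwm$prob35["A", 1]), 1)
  expect_equal(unname(pwm$prob35["C", 3]), 1)
  expect_equal(unname(pwm$prob10["T", 5]), 1)
  expect_equal(sum(pwm$prob35[, 1]), 1)

  two <- rbind(one, one)
  two$target_id <- c("x", "y")
  two$minus10[2] <- "CGTCC"   # differs at -10 position 5 only
  pwm2 <- build_pwm(two, 16L, pseudocount = 0)
  expect_equal(unname(pwm2$prob10[c("T", "C"), 5]), c(0.5, 0.5))
  expect_equal(max(abs(pwm2$prob35 - pwm$prob35)), 0)
  expect_error(build_pwm(one[0, ], 16L), "empty")
})

test_that("consensus scores maximal and anti-consensus minimal, exhaustively", {
  v <- sigE_validated_promoters()
  pwm <- build_pwm(v, 16L)
  bases <- c("A", "C", "G", "T")
  # independent oracle: per-column log-odds computed directly from the
  # probability matrices, enumerated over all 4^4 x 4^5 block pairs
  lo <- function(m) log2(m / pwm$background[bases])
  lo35 <- lo(pwm$prob35); lo10 <- lo(pwm$prob10)
  all35 <- expand.grid(rep(list(bases), 4), stringsAsFactors = FALSE)
  all10 <- expand.grid(rep(list(bases), 5), stringsAsFactors = FALSE)
  s35 <- rowSums(mapply(function(col, j) lo35[col, j], all35, seq_len(4)))
  s10 <- rowSums(mapply(function(col, j) lo10[col, j], all10, seq_len(5)))
  # enumeration oracle extrema over the full 262144-pair space
  omax <- max(s35) + max(s10)
  omin <- min(s35) + min(s10)
  # consensus/anti-consensus by column log-odds (background-aware)
  cons35 <- paste(bases[apply(lo35, 2, which.max)], collapse = "")
  cons10 <- paste(bases[apply(lo10, 2, which.max)], collapse = "")
  anti35 <- paste(bases[apply(lo35, 2, which.min)], collapse = "")
  anti10 <- paste(bases[apply(lo10, 2, which.min)], collapse = "")
  sc_cons <- score_site(pwm, cons35, cons10)
  sc_anti <- score_site(pwm, anti35, anti10)
  expect_equal(sc_cons$raw, omax)
  expect_equal(sc_anti$raw, omin)
  expect_equal(sc_cons$normalized, 1)
  expect_equal(sc_anti$normalized, 0)
  # random block pairs agree exactly with the enumeration oracle
  set.seed(30)
  for (k in 1:50) {
    i <- sample(nrow(all35), 1); j <- sample(nrow(all10), 1)
    got <- score_site(pwm, paste(unlist(all35[i, ]), collapse = ""),
                      paste(unlist(all10[j, ]), collapse = ""))
    expect_equal(got$raw, unname(s35[i] + s10[j]))
  }
  # N bases score at background: contribution 0 for that column
  base_sc <- score_site(pwm, "AACC", "CGTCT")$raw
  n_sc <- score_site(pwm, "NACC", "CGTCT")$raw
  expect_equal(n_sc, unname(base_sc - lo35["A", 1]))
})

test_that("the validated-set PWMs match the published consensus layout", {
  v <- sigE_validated_promoters()
  expect_equal(nrow(v), 19L)
  expect_setequal(v$target_id[nchar(v$spacer) == 17L], c("sco3194", "sco4934"))
  pwms <- build_pwm_pair(v)
  expect_equal(pwms[[1]]$name, "PWM_19_16")
  expect_equal(pwms[[2]]$name, "PWM_19_17")
  # spacer normalization: both models share identical block matrices
  expect_equal(pwms[[1]]$prob35, pwms[[2]]$prob35)
  expect_equal(pwms[[1]]$prob10, pwms[[2]]$prob10)
  # -35 column 2 dominated by A, -10 column 4 dominated by C
  expect_equal(rownames(pwms[[1]]$prob35)[which.max(pwms[[1]]$prob35[, 2])], "A")
  expect_equal(rownames(pwms[[1]]$prob10)[which.max(pwms[[1]]$prob10[, 4])], "C")
  expect_length(pwms[[1]]$core_positions, 6L)
})

test_that("logo count export is lossless and sums to the promoter count", {
  pwm <- build_pwm(sigE_validated_promoters(), 16L)
  tab <- export_logo_counts(pwm)
  expect_equal(sum(!tab$gap), 9L)
  counts <- as.matrix(tab[!tab$gap, c("A", "C", "G", "T")])
  expect_true(all(rowSums(counts) == 19))
  expect_equal(t(counts[tab$block[!tab$gap] == "minus35", ]), pwm$counts35,
               ignore_attr = TRUE)
  expect_equal(t(counts[tab$block[!tab$gap] == "minus10", ]), pwm$counts10,
               ignore_attr = TRUE)
})

test_that("PWMs round-trip through their TSV representation", {
  pwm <- build_pwm(sigE_validated_promoters(), 17L)
  path <- tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  back <- read_pwm(path)
  for (f in c("name", "spacer_len", "pseudocount", "core_positions"))
    expect_equal(back[[f]], pwm[[f]])
  expect_equal(back$prob35, pwm$prob35, tolerance = 1e-9)
  expect_equal(back$training_full, pwm$training_full, tolerance = 1e-8)
  # a scan through the reread model behaves identically
  s <- promoter_sequence(sigE_validated_promoters())[1]
  expect_equal(scan_sequence(back, s)$raw, scan_sequence(pwm, s)$raw,
               tolerance = 1e-8)
})

test_that("a planted promoter is found at its distance and gap on both strands", {
  t1 <- sigE_table1()
  p736 <- t1[t1$target_id == "sco0736", ]
  pwms <- build_pwm_pair(sigE_validated_promoters())
  for (strand in c("+", "-")) {
    set.seed(31)
    g <- planted_gene_contig(p736, distance = 70L, strand = strand)
    hits <- scan_region(pwms, extract_upstream(g$contigs, g$genes, 10L, 200L))
    expect_gte(nrow(hits), 1L)
    expect_equal(hits$distance_bp[1], 70L)
    expect_equal(hits$gap[1], 16L)
    expect_equal(hits$gene_id[1], "sco0736")
    expect_equal(hits$genomic_start[1], g$site_start)
  }
})

test_that("scanning is specific on random GC-rich regions and empty input", {
  pwms <- build_pwm_pair(sigE_validated_promoters())
  set.seed(32)
  zero_hits <- vapply(1:1000, function(i)
    nrow(scan_sequence(pwms, ecfmap:::random_dna(190))) == 0L, logical(1))
  expect_gte(mean(zero_hits), 0.95)
  expect_equal(nrow(scan_sequence(pwms, "")), 0L)
  expect_equal(nrow(scan_sequence(pwms, "ACGT")), 0L)
})

test_that("no scan hit falls outside the near/far window", {
  set.seed(33)
  pwms <- build_pwm_pair(sigE_validated_promoters())
  cfg <- sim_config(seed = 33, n_genes = 12, n_targets = 8,
                    distance_range = c(10L, 160L))
  g <- simulate_genome_with_sites(cfg)
  hits <- scan_upstream(g$contigs, g$genes, pwms, scan_params(), best_only = FALSE)
  expect_true(all(hits$distance_bp >= 10L & hits$distance_bp <= 200L))
})

test_that("candidate screening finds planted promoters and reports orphans", {
  t1 <- sigE_table1()
  p736 <- t1[t1$target_id == "sco0736", ]
  set.seed(34)
  g <- planted_gene_contig(p736, distance = 70L)
  peaks <- data.frame(contig_id = "chr1",
                      start = g$site_start - 20L, end = g$site_start + 30L,
                      summit_start = g$site_start - 10L,
                      summit_end = g$site_start + 15L,
                      enrichment = 10, p_value = 1e-8)
  cand <- candidate_promoters(peaks, g$contigs, g$genes)
  best <- cand[which.min(abs(cand$genomic_start - g$site_start)), ]
  expect_equal(best$minus35, "AACC")
  expect_equal(best$minus10, "GGTCT")
  expect_equal(best$distance_bp, 70L)
  expect_true(all(cand$distance_bp <= 400L))

  # a gene too far away leaves the peak an orphan
  far_gene <- g$genes
  far_gene$start <- far_gene$start + 1500L
  far_gene$end <- far_gene$end + 1500L
  far_gene$start_codon_pos <- far_gene$start_codon_pos + 1500L
  orphaned <- candidate_promoters(peaks, g$contigs, far_gene)
  expect_equal(nrow(orphaned), 0L)
  expect_equal(attr(orphaned, "orphans"), 1L)
})

test_that("a peak between divergent genes yields one candidate per gene", {
  v <- sigE_validated_promoters()
  set.seed(35)
  seq <- ecfmap:::random_dna(3000)
  # divergent pair: minus-strand gene ends at 1000, plus-strand gene starts
  # at 2000; both promoters live in the shared intergenic region
  site <- promoter_sequence(v[v$target_id == "sco5030", ])      # 25 bp
  substr(seq, 1101, 1100 + nchar(site)) <- ecfmap:::revcomp(site) # d=100 for minus gene
  substr(seq, 1876, 1875 + nchar(site)) <- site                   # d=100 for plus gene
  contigs <- Biostrings::DNAStringSet(c(chr1 = seq))
  genes <- data.frame(gene_id = c("left", "right"), contig_id = "chr1",
                      strand = c("-", "+"), start = c(200L, 2000L),
                      end = c(1000L, 2800L), start_codon_pos = c(999L, 2000L))
  peaks <- data.frame(contig_id = "chr1", start = 1400L, end = 1600L,
                      summit_start = 1450L, summit_end = 1475L,
                      enrichment = 8, p_value = 1e-7)
  motif <- list(counts35 = build_pwm(v, 16L)$counts35,
                counts10 = build_pwm(v, 16L)$counts10,
                background = ecfmap:::default_background(),
                params = list(pseudocount = 0.5))
  class(motif) <- "two_block_motif"
  cand <- candidate_promoters(peaks, contigs, genes, motif = motif,
                              flank_bp = 400L)
  expect_equal(sort(cand$gene_id), c("left", "right"))
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$distance_bp, c(100L, 100L))
})
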