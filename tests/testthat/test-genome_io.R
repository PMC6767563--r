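test_that("FASTA reading normalises case, keeps record order, rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt", ">c2 some description", "GGGCCC"), fa)
  contigs <- read_genome_fasta(fa)
  expect_equal(names(contigs), c("c1", "c2"))
  expect_equal(as.character(contigs[["c1"]]), "ACGT")
  expect_equal(as.character(contigs[["c2"]]), "GGGCCC")

  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), fa)
  expect_error(read_genome_fasta(fa), "duplicate contig id")

  writeLines(c(">c1", "ACRT"), fa)
  expect_error(read_genome_fasta(fa), "non-ACGTN")
  expect_equal(as.character(read_genome_fasta(fa, ambiguity = "mask")[["c1"]]),
               "ACNT")

  file.create(empty <- tempfile(fileext = ".fa"))
  expect_error(read_genome_fasta(empty), "empty")
})

test_that("contig and gene tables round-trip through FASTA/GFF3", {
  set.seed(1)
  contigs <- Biostrings::DNAStringSet(c(c1 = ecfmap:::random_dna(500),
                                        c2 = ecfmap:::random_dna(300)))
  fa <- tempfile(fileext = ".fa")
  write_genome_fasta(contigs, fa)
  expect_equal(as.character(read_genome_fasta(fa)), as.character(contigs))

  genes <- data.frame(gene_id = c("gA", "gB"), contig_id = c("c1", "c2"),
                      strand = c("+", "-"), start = c(100L, 9L),
                      end = c(190L, 250L), start_codon_pos = c(100L, 249L))
  gff <- tempfile(fileext = ".gff3")
  write_gff_genes(genes, gff)
  back <- read_gff_genes(gff, contigs = contigs)
  expect_equal(back[order(back$gene_id), names(genes)],
               genes[order(genes$gene_id), ], ignore_attr = TRUE)
})

test_that("GFF coordinates convert to 0-based half-open with strand-aware start codon", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t190\t.\t+\t.\tID=plus_gene",
               "c1\tsrc\tgene\t101\t190\t.\t-\t.\tID=minus_gene",
               "c1\tsrc\tCDS\t11\t40\t.\t+\t.\tID=sco0736"), gff)
  genes <- read_gff_genes(gff)
  plus <- genes[genes$gene_id == "plus_gene", ]
  minus <- genes[genes$gene_id == "minus_gene", ]
  expect_equal(c(plus$start, plus$end, plus$start_codon_pos), c(100L, 190L, 100L))
  expect_equal(minus$start_codon_pos, 189L)
  expect_true("sco0736" %in% genes$gene_id)

  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t190\t.\t+\t.\tName=anon"), gff)
  expect_error(read_gff_genes(gff), "ID")

  writeLines(c("##gff-version 3",
               "c1\tsrc\tgene\t101\t900\t.\t+\t.\tID=off_end"), gff)
  contigs <- Biostrings::DNAStringSet(c(c1 = strrep("A", 200)))
  expect_error(read_gff_genes(gff, contigs = contigs), "beyond contig bounds")
})

test_that("upstream extraction is strand-aware, clipped, and length far - near", {
  set.seed(2)
  seq <- ecfmap:::random_dna(2000)
  contigs <- Biostrings::DNAStringSet(c(chr = seq))
  plus <- data.frame(gene_id = "p", contig_id = "chr", strand = "+",
                     start = 1000L, end = 1900L, start_codon_pos = 1000L)
  r <- extract_upstream(contigs, plus, 10L, 200L)
  expect_equal(c(r$genomic_start, r$genomic_end), c(800L, 990L))
  expect_equal(r$sequence, substr(seq, 801, 990))
  expect_equal(nchar(r$sequence), 190L)

  minus <- data.frame(gene_id = "m", contig_id = "chr", strand = "-",
                      start = 100L, end = 1000L, start_codon_pos = 999L)
  r2 <- extract_upstream(contigs, minus, 10L, 200L)
  expect_equal(c(r2$genomic_start, r2$genomic_end), c(1010L, 1200L))
  expect_equal(r2$sequence, ecfmap:::revcomp(substr(seq, 1011, 1200)))

  # region position maps back to the genomic coordinate on either strand
  expect_equal(region_to_genomic(r, 1L), 800L)
  expect_equal(region_to_genomic(r, 190L), 989L)
  expect_equal(region_to_genomic(r2, 1L), 1199L)
  expect_equal(region_to_genomic(r2, 190L), 1010L)

  near_edge <- data.frame(gene_id = "e", contig_id = "chr", strand = "+",
                          start = 50L, end = 500L, start_codon_pos = 50L)
  expect_warning(re <- extract_upstream(contigs, near_edge, 10L, 200L), "clipped")
  expect_equal(nchar(re$sequence), 40L)

  off <- data.frame(gene_id = "o", contig_id = "chr", strand = "+",
                    start = 5L, end = 100L, start_codon_pos = 5L)
  expect_equal(nchar(extract_upstream(contigs, off, 10L, 200L)$sequence), 0L)
})

test_that("unclipped upstream windows have length far - near for random genes", {
  set.seed(3)
  contigs <- Biostrings::DNAStringSet(c(chr = ecfmap:::random_dna(5000)))
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    sc <- sample(1000:4000, 1)
    g <- data.frame(gene_id = "g", contig_id = "chr", strand = strand,
                    start = if (strand == "+") sc else sc - 500L,
                    end = if (strand == "+") sc + 500L else sc + 1L,
                    start_codon_pos = sc)
    near <- sample(0:50, 1); far <- near + sample(50:400, 1)
    r <- extract_upstream(contigs, g, near, far)
    expect_equal(nchar(r$sequence), far - near)
  }
})

test_that("the packaged promoter tables pass all entry invariants", {
  t1 <- sigE_table1()
  expect_equal(nrow(t1), 91L)
  expect_true(all(nchar(t1$minus35) == 4L))
  expect_true(all(nchar(t1$minus10) == 5L))
  expect_true(all(nchar(t1$spacer) %in% c(16L, 17L)))
  expect_true(all(t1$distance_bp >= 0L))

  p736 <- t1[t1$target_id == "sco0736", ]
  expect_equal(p736$minus35, "AACC")
  expect_equal(p736$spacer, "AAAGCCGCCGGACGGC")
  expect_equal(p736$minus10, "GGTCT")
  expect_equal(p736$distance_bp, 70L)

  expect_equal(nchar(t1$spacer[t1$target_id == "sco1875"]), 17L)

  hrdD <- t1[t1$target_id == "hrdD", ]
  expect_equal(hrdD$minus35, "AACC")
  expect_equal(nchar(hrdD$spacer), 16L)
  expect_equal(hrdD$minus10, "CGTCT")
  expect_equal(hrdD$distance_bp, 375L)
})

test_that("promoter tables round-trip and invalid spacers are rejected by row", {
  v <- sigE_validated_promoters()
  path <- tempfile(fileext = ".tsv")
  write_promoter_table(v, path)
  expect_equal(read_promoter_table(path), v)

  bad <- v
  bad$spacer[3] <- substr(bad$spacer[3], 1, 10)
  expect_error(validate_promoter_entries(bad), bad$target_id[3])
})
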