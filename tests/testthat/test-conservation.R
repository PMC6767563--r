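test_that("protein alignment matches identity/coverage expectations", {
  set.seed(50)
  a <- random_protein(100)
  al <- align_protein(a, a)
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 100)
  rev_a <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  expect_lt(align_protein(a, rev_a)$identity, 60)
  expect_error(align_protein("ARND", "AR1D"), "non-amino-acid")
})

test_that("alignment scores equal an independent affine-gap DP oracle", {
  set.seed(51)
  for (k in 1:25) {
    a <- random_protein(8)
    b <- random_protein(8)
    expect_equal(align_protein(a, b)$score, sw_affine_oracle(a, b))
  }
  # longer pair with a shared core, where a gapped alignment can win
  core <- random_protein(30)
  a <- paste0(random_protein(5), core, random_protein(5))
  b <- paste0(core, random_protein(12))
  expect_equal(align_protein(a, b)$score, sw_affine_oracle(a, b))
})

test_that("reciprocal best hits map copied proteomes onto themselves", {
  set.seed(52)
  ref <- stats::setNames(vapply(1:6, function(i) random_protein(80),
                                character(1)), paste0("p", 1:6))
  hits <- rbh_orthologs(ref, ref)
  expect_equal(nrow(hits), 6L)
  expect_equal(hits$ref_id, hits$other_id)
  expect_true(all(hits$identity == 100))
})

test_that("a lost gene is absent and non-mutual paralogs are not recorded", {
  set.seed(53)
  ref <- stats::setNames(vapply(1:5, function(i) random_protein(80),
                                character(1)), paste0("p", 1:5))
  other <- ref[-3]                      # species lost gene p3
  hits <- rbh_orthologs(ref, other)
  expect_false("p3" %in% hits$ref_id)
  expect_equal(nrow(hits), 4L)

  # paralog pair: a1 and a2 both resemble b1, but only a1 is mutual-best
  base <- random_protein(80)
  a1 <- base
  a2 <- paste0(substr(base, 1, 60), random_protein(20))
  b1 <- base
  hits2 <- rbh_orthologs(c(a1 = a1, a2 = a2), c(b1 = b1))
  expect_equal(hits2$ref_id, "a1")
  expect_equal(nrow(hits2), 1L)
})

test_that("RBH is symmetric under swapping the two proteomes", {
  set.seed(54)
  pa <- stats::setNames(vapply(1:5, function(i) random_protein(60),
                               character(1)), paste0("a", 1:5))
  pb <- stats::setNames(vapply(1:5, function(i)
    mutate_str(pa[i], 0.1), character(1)), paste0("b", 1:5))
  f <- rbh_orthologs(pa, pb)
  r <- rbh_orthologs(pb, pa)
  expect_setequal(paste(f$ref_id, f$other_id), paste(r$other_id, r$ref_id))
})

test_that("the self-panel reproduces the reference scan exactly", {
  set.seed(55)
  cfg <- sim_config(seed = 55, n_genes = 8, n_targets = 5,
                    distance_range = c(10L, 160L), n_species = 1L,
                    substitution_rate = 0, site_loss_prob = 0,
                    gene_loss_prob = 0)
  g <- simulate_genome_with_sites(cfg)
  fam <- simulate_species_family(cfg, g)
  pwms <- build_pwm_pair(sigE_validated_promoters())
  self_panel <- list(self = fam$reference)
  cm <- conservation_matrix(g$truth$gene_id, fam$reference, self_panel, pwms)
  expect_true(all(cm$state != "no_ortholog"))
  ref_hits <- scan_upstream(g$contigs, g$genes[g$genes$gene_id %in% g$truth$gene_id, ],
                            pwms, scan_params())
  expect_setequal(ref_hits$gene_id, rownames(cm$state)[cm$state[, 1] == "site"])
  expect_equal(unname(cm$score[ref_hits$gene_id, 1]), ref_hits$normalized)
})

test_that("a constructed 7 site / 2 grey / 1 black row is read back exactly", {
  set.seed(56)
  cfg <- sim_config(seed = 56, n_genes = 4, n_targets = 1,
                    distance_range = c(30L, 120L), n_species = 10L,
                    substitution_rate = 0, site_loss_prob = 0,
                    gene_loss_prob = 0)
  g <- simulate_genome_with_sites(cfg)
  fam <- simulate_species_family(cfg, g)
  target <- g$truth$gene_id[1]
  # species 8 and 9 lose the site (replaced by a neutral G-run, which the
  # A/T-anchored core cannot match); species 10 loses the gene
  for (sp in c("sp08", "sp09")) {
    v <- as.character(fam$panel[[sp]]$contigs[[1]])
    substr(v, g$truth$site_start + 1L, g$truth$site_end) <-
      strrep("G", g$truth$site_end - g$truth$site_start)
    fam$panel[[sp]]$contigs <- Biostrings::DNAStringSet(c(chr1 = v))
  }
  keep <- fam$panel$sp10$genes$gene_id != target
  fam$panel$sp10$genes <- fam$panel$sp10$genes[keep, ]
  fam$panel$sp10$proteins <- fam$panel$sp10$proteins[
    names(fam$panel$sp10$proteins) != target]
  pwms <- build_pwm_pair(sigE_validated_promoters())
  cm <- conservation_matrix(target, fam$reference, fam$panel, pwms)
  tab <- table(factor(cm$state[target, ],
                      levels = c("site", "no_site", "no_ortholog")))
  expect_equal(as.vector(tab), c(7L, 2L, 1L))
  # threshold arithmetic on the same matrix
  expect_equal(conserved_targets(cm, 0L), target)
  expect_equal(conserved_targets(cm, 7L), target)
  expect_equal(conserved_targets(cm, 8L), character(0))
  expect_equal(conserved_targets(cm, 11L), character(0))
  # matrix round-trips through its TSV representation
  path <- tempfile(fileext = ".tsv")
  write_conservation_matrix(cm, path)
  back <- read_conservation_matrix(path)
  expect_equal(back$state, cm$state)
  expect_equal(back$score[cm$state == "site"], cm$score[cm$state == "site"],
               tolerance = 1e-5)
})

test_that("an empty target list yields an empty matrix", {
  cm <- conservation_matrix(character(0),
                            list(contigs = NULL, genes = NULL, proteins = NULL),
                            list(), list())
  expect_equal(dim(cm$state), c(0L, 0L))
  expect_equal(conserved_targets(cm, 0L), character(0))
})

test_that("conservation counts are monotone in the identity threshold", {
  set.seed(57)
  cfg <- sim_config(seed = 57, n_genes = 6, n_targets = 4,
                    distance_range = c(10L, 160L), n_species = 3L,
                    substitution_rate = 0.25, site_loss_prob = 0,
                    gene_loss_prob = 0)
  g <- simulate_genome_with_sites(cfg)
  fam <- simulate_species_family(cfg, g)
  pwms <- build_pwm_pair(sigE_validated_promoters())
  loose <- conservation_matrix(g$truth$gene_id, fam$reference, fam$panel, pwms,
                               conservation_params(min_identity = 30))
  strict <- conservation_matrix(g$truth$gene_id, fam$reference, fam$panel, pwms,
                                conservation_params(min_identity = 95))
  expect_true(all(rowSums(strict$state == "site") <=
                  rowSums(loose$state == "site")))
})
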