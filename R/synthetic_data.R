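# Seeded generators that emulate every input the pipeline consumes:
# a GC-rich genome with promoter sites planted upstream of start codons,
# ChIP/control coverage with localized enrichment, WT vs mutant induction
# time courses with planted dependence classes, and a family of related
# genomes that retain or lose orthologs and sites. Each generator draws all
# randomness from the config seed (plus a fixed per-generator offset), so a
# config determines every output byte.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generators emulate: a 72% GC
#' Streptomyces-like chromosome, promoter sites drawn from the validated
#' sigma-E promoter matrix planted 10-400 bp upstream of start codons, ChIP
#' enrichment of 10x over a depth-5 background, induction time courses at
#' 0/30/60/90 min with noise sigma 0.3 log2 units, and a panel of related
#' genomes with per-site substitution, site-loss and gene-loss rates.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genes,n_targets Number of genes and of planted sigma-E targets.
#' @param gc GC content of background sequence.
#' @param gene_length Gene length in bp.
#' @param intergenic_bp Intergenic (upstream) region length per gene.
#' @param distance_range Planting distance (bp, 3' end of -10 to start
#'   codon), drawn uniformly.
#' @param site_pwm \code{two_block_pwm} used for site emission; default the
#'   packaged validated-promoter model.
#' @param functional_only Restrict emitted sites to the detection envelope
#'   of the emission PWM (score at least that of its weakest source
#'   promoter), so planted sites are recognisable functional promoters.
#' @param chip_depth,chip_enrichment Mean per-base coverage and fold
#'   enrichment within 150 bp of a planted site.
#' @param expression_noise_sd Gaussian noise added to every log2 expression
#'   value.
#' @param class_mix Proportions of Class I / II / III / non-target genes.
#' @param n_species,substitution_rate,site_loss_prob,gene_loss_prob
#'   Species-family parameters: panel size, per-site substitution rate
#'   (nucleotide level for genomes, amino-acid level for proteins),
#'   probability that a planted site is randomized, probability that the
#'   gene (with its site) is deleted.
#' @param aa_length Protein length in residues.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed, n_genes = 40L, n_targets = min(20L, n_genes),
                       gc = 0.72,
                       gene_length = 300L, intergenic_bp = 600L,
                       distance_range = c(10L, 400L), site_pwm = NULL,
                       functional_only = TRUE, chip_depth = 5,
                       chip_enrichment = 10, expression_noise_sd = 0.3,
                       class_mix = c(I = 0.05, II = 0.10, III = 0.04, none = 0.81),
                       n_species = 10L, substitution_rate = 0.1,
                       site_loss_prob = 0.2, gene_loss_prob = 0.1,
                       aa_length = 120L) {
  if (missing(seed)) stopf("a seed is mandatory")
  stopifnot(gc > 0, gc < 1, n_targets <= n_genes,
            all(c(substitution_rate, site_loss_prob, gene_loss_prob) >= 0),
            all(c(site_loss_prob, gene_loss_prob) <= 1),
            diff(distance_range) >= 0,
            intergenic_bp >= distance_range[2] + 30L)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets), gc = gc,
                 gene_length = as.integer(gene_length),
                 intergenic_bp = as.integer(intergenic_bp),
                 distance_range = as.integer(distance_range),
                 site_pwm = site_pwm, functional_only = functional_only,
                 chip_depth = chip_depth, chip_enrichment = chip_enrichment,
                 expression_noise_sd = expression_noise_sd,
                 class_mix = class_mix / sum(class_mix),
                 n_species = as.integer(n_species),
                 substitution_rate = substitution_rate,
                 site_loss_prob = site_loss_prob,
                 gene_loss_prob = gene_loss_prob,
                 aa_length = as.integer(aa_length)),
            class = "sim_config")
}

default_site_pwm <- function(cfg) {
  cfg$site_pwm %||% build_pwm(sigE_validated_promoters(), 16L,
                              background = default_background(cfg$gc))
}

# Draw one promoter site from the emission PWM: blocks sampled column-wise
# from the observed (pseudocount-free) column frequencies, spacer from the
# background, gap uniform over 16/17. With functional_only, rejection-sample
# until the site scores at least as well as the weakest source promoter on
# both the full and core scores.
emit_site <- function(pwm, background, functional_only = TRUE) {
  emp35 <- sweep(pwm$counts35, 2, colSums(pwm$counts35), "/")
  emp10 <- sweep(pwm$counts10, 2, colSums(pwm$counts10), "/")
  thr_full <- min(pwm$training_full); thr_core <- min(pwm$training_core)
  for (try in 1:1000) {
    m35 <- paste(vapply(1:4, function(k)
      sample(DNA_BASES, 1L, prob = emp35[, k]), character(1)), collapse = "")
    m10 <- paste(vapply(1:5, function(k)
      sample(DNA_BASES, 1L, prob = emp10[, k]), character(1)), collapse = "")
    if (!functional_only) break
    sc <- score_site(pwm, m35, m10)
    if (sc$raw >= thr_full - 1e-9 && sc$core_raw >= thr_core - 1e-9) break
  }
  gap <- sample(c(16L, 17L), 1L)
  list(minus35 = m35, spacer = random_dna(gap, background), minus10 = m10,
       gap = gap)
}

#' Simulate a genome with planted promoter sites
#'
#' Builds one contig of i.i.d. background sequence at the configured GC
#' content, places genes alternately on the two strands (each with its own
#' upstream intergenic region), and for target genes plants a site sampled
#' from the emission PWM on the gene's sense strand at a distance drawn from
#' \code{distance_range}.
#'
#' @param cfg A \code{sim_config}.
#' @return List with \code{contigs} (DNAStringSet), \code{genes} (gene
#'   table), \code{truth} (one row per planted site: blocks, gap, distance,
#'   genomic coordinates) and \code{config}.
#' @export
simulate_genome_with_sites <- function(cfg) {
  set.seed(cfg$seed)
  bg <- default_background(cfg$gc)
  pwm <- default_site_pwm(cfg)
  targets <- sort(sample.int(cfg$n_genes, cfg$n_targets))
  segs <- character(0)
  pos <- 0L
  genes <- list(); truth <- list()
  buffer <- 50L
  for (i in seq_len(cfg$n_genes)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    up <- random_dna(cfg$intergenic_bp, bg)
    gene_seq <- random_dna(cfg$gene_length, bg)
    gid <- sprintf("g%03d", i)
    if (strand == "+") {
      gstart <- pos + cfg$intergenic_bp
      start_codon <- gstart
    } else {
      gstart <- pos
      start_codon <- gstart + cfg$gene_length - 1L
    }
    site_row <- NULL
    if (i %in% targets) {
      site <- emit_site(pwm, bg, cfg$functional_only)
      span <- 4L + site$gap + 5L
      d <- if (diff(cfg$distance_range) == 0L) cfg$distance_range[1] else
        sample(cfg$distance_range[1]:cfg$distance_range[2], 1L)
      sense <- paste0(site$minus35, site$spacer, site$minus10)
      if (strand == "+") {
        site_end <- start_codon - d          # exclusive, reference strand
        site_start <- site_end - span
        rel <- site_start - pos              # offset within `up`
        substr(up, rel + 1L, rel + span) <- sense
      } else {
        site_start <- start_codon + 1L + d
        site_end <- site_start + span
        rel <- site_start - (pos + cfg$gene_length)
        substr(up, rel + 1L, rel + span) <- revcomp(sense)
      }
      site_row <- data.frame(gene_id = gid, strand = strand,
                             minus35 = site$minus35, spacer = site$spacer,
                             minus10 = site$minus10, gap = site$gap,
                             distance_bp = d, site_start = site_start,
                             site_end = site_end, stringsAsFactors = FALSE)
    }
    if (strand == "+") segs <- c(segs, up, gene_seq)
    else segs <- c(segs, gene_seq, up)
    genes[[i]] <- data.frame(gene_id = gid, contig_id = "chr1", strand = strand,
                             start = gstart, end = gstart + cfg$gene_length,
                             start_codon_pos = start_codon,
                             stringsAsFactors = FALSE)
    if (!is.null(site_row)) truth[[length(truth) + 1L]] <- site_row
    pos <- pos + cfg$intergenic_bp + cfg$gene_length
    segs <- c(segs, random_dna(buffer, bg))
    pos <- pos + buffer
  }
  contigs <- Biostrings::DNAStringSet(c(chr1 = paste(segs, collapse = "")))
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_id = character(), strand = character(), minus35 = character(),
               spacer = character(), minus10 = character(), gap = integer(),
               distance_bp = integer(), site_start = integer(),
               site_end = integer())
  list(contigs = contigs, genes = do.call(rbind, genes), truth = truth,
       config = cfg)
}

#' Simulate ChIP and control coverage
#'
#' Control coverage is Poisson(depth) at every base; ChIP coverage is
#' Poisson(depth x enrichment) within 150 bp of each planted site and
#' Poisson(depth) elsewhere.
#'
#' @param cfg A \code{sim_config}.
#' @param genome Output of \code{simulate_genome_with_sites}.
#' @return List with \code{chip} and \code{control} \code{coverage_track}s.
#' @export
simulate_chip <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  L <- Biostrings::width(genome$contigs)[1]
  lambda <- rep(cfg$chip_depth, L)
  if (nrow(genome$truth) > 0L) {
    centre <- (genome$truth$site_start + genome$truth$site_end) %/% 2L
    for (c0 in centre) {
      i0 <- max(c0 - 150L, 0L) + 1L; i1 <- min(c0 + 150L, L - 1L) + 1L
      lambda[i0:i1] <- cfg$chip_depth * cfg$chip_enrichment
    }
  }
  list(chip = coverage_track("chr1", stats::rpois(L, lambda)),
       control = coverage_track("chr1", stats::rpois(L, cfg$chip_depth)))
}

#' Simulate WT and mutant induction time courses
#'
#' Each gene gets a Normal(0,1) baseline. Targets are induced at 30 min and
#' stay up: Class I gains a WT rise of U(2,4) log2 with no mutant rise;
#' Class II the same WT rise with the mutant scaled by a partial factor
#' U(0.2, 0.7); Class III a WT rise of U(1.5, 3) with the mutant lower by
#' U(0.3, 0.8) and 2-4 promoters. Gaussian noise is added everywhere.
#'
#' @param cfg A \code{sim_config}.
#' @param genome Optional genome (its target genes get the planted
#'   classes); otherwise \code{n_genes} synthetic gene ids are used with
#'   targets drawn from \code{class_mix}.
#' @return List with \code{matrix} (genes x WT_0..dsigE_90),
#'   \code{classes} (gene_id, class, n_promoters, wt_delta, mut_delta) and
#'   \code{n_promoters} table.
#' @export
simulate_expression <- function(cfg, genome = NULL) {
  set.seed(cfg$seed + 2L)
  if (!is.null(genome)) {
    ids <- genome$genes$gene_id
    is_target <- ids %in% genome$truth$gene_id
    mixIII <- cfg$class_mix[c("I", "II", "III")]
    cls <- ifelse(is_target,
                  sample(c("I", "II", "III"), length(ids), replace = TRUE,
                         prob = mixIII / sum(mixIII)),
                  "none")
  } else {
    ids <- sprintf("g%03d", seq_len(cfg$n_genes))
    cls <- sample(names(cfg$class_mix), length(ids), replace = TRUE,
                  prob = cfg$class_mix)
  }
  shape <- c(0, 1, 1, 1)
  m <- matrix(NA_real_, length(ids), 8L,
              dimnames = list(ids, expr_colnames()))
  rows <- list()
  for (i in seq_along(ids)) {
    base <- stats::rnorm(1)
    np <- 1L; wt_d <- 0; mut_d <- 0
    if (cls[i] == "I") {
      wt_d <- stats::runif(1, 2, 4)
    } else if (cls[i] == "II") {
      wt_d <- stats::runif(1, 2, 4); mut_d <- stats::runif(1, 0.2, 0.7) * wt_d
    } else if (cls[i] == "III") {
      wt_d <- stats::runif(1, 1.5, 3); mut_d <- wt_d - stats::runif(1, 0.3, 0.8)
      np <- sample(2:4, 1L)
    }
    noise <- stats::rnorm(8L, 0, cfg$expression_noise_sd)
    m[i, ] <- base + c(wt_d * shape, mut_d * shape) + noise
    rows[[i]] <- data.frame(gene_id = ids[i], class = cls[i], n_promoters = np,
                            wt_delta = wt_d, mut_delta = mut_d,
                            stringsAsFactors = FALSE)
  }
  classes <- do.call(rbind, rows)
  list(matrix = m, classes = classes,
       n_promoters = classes[, c("gene_id", "n_promoters")])
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET[1:20], n, replace = TRUE), collapse = "")
}

mutate_protein <- function(x, rate) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(v)) < rate
  v[hit] <- sample(AA_ALPHABET[1:20], sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

#' Simulate a family of related genomes
#'
#' Derives \code{n_species} genomes from a reference produced by
#' \code{simulate_genome_with_sites}. Each species genome is the reference
#' with per-base substitutions at \code{substitution_rate} (sparing the
#' positions of retained planted sites, which are the object under study);
#' with probability \code{site_loss_prob} a planted site is replaced by
#' background sequence, and with probability \code{gene_loss_prob} the gene
#' is deleted from the annotation and proteome (and its site randomized).
#' Reference proteins are random amino-acid sequences; species proteins
#' carry amino-acid substitutions at the same rate.
#'
#' @param cfg A \code{sim_config}.
#' @param genome Reference from \code{simulate_genome_with_sites}.
#' @return List with \code{reference} (contigs/genes/proteins), \code{panel}
#'   (named list of species, same layout) and \code{truth} (species x gene:
#'   ortholog_retained, site_retained for every target gene).
#' @export
simulate_species_family <- function(cfg, genome) {
  set.seed(cfg$seed + 3L)
  bg <- default_background(cfg$gc)
  ref_seq <- as.character(genome$contigs[[1]])
  ref_proteins <- stats::setNames(
    vapply(genome$genes$gene_id, function(g) random_protein(cfg$aa_length),
           character(1)),
    genome$genes$gene_id)
  reference <- list(contigs = genome$contigs, genes = genome$genes,
                    proteins = ref_proteins)
  site_pos <- function(row) (row$site_start + 1L):row$site_end
  panel <- list(); truth <- list()
  for (s in seq_len(cfg$n_species)) {
    sp <- sprintf("sp%02d", s)
    v <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
    gene_lost <- stats::runif(nrow(genome$genes)) < cfg$gene_loss_prob
    names(gene_lost) <- genome$genes$gene_id
    site_lost <- stats::runif(nrow(genome$truth)) < cfg$site_loss_prob
    protect <- integer(0)
    for (k in seq_len(nrow(genome$truth))) {
      row <- genome$truth[k, ]
      lost <- site_lost[k] || gene_lost[row$gene_id]
      if (lost) {
        v[site_pos(row)] <- sample(DNA_BASES, length(site_pos(row)),
                                   replace = TRUE, prob = bg)
      } else {
        protect <- c(protect, site_pos(row))
      }
    }
    hit <- stats::runif(length(v)) < cfg$substitution_rate
    hit[protect] <- FALSE
    v[hit] <- sample(DNA_BASES, sum(hit), replace = TRUE, prob = bg)
    keep <- !gene_lost
    proteins <- vapply(ref_proteins[keep], mutate_protein, character(1),
                       rate = cfg$substitution_rate)
    panel[[sp]] <- list(
      contigs = Biostrings::DNAStringSet(c(chr1 = paste(v, collapse = ""))),
      genes = genome$genes[keep, , drop = FALSE],
      proteins = proteins)
    if (nrow(genome$truth) > 0L)
      truth[[sp]] <- data.frame(
        species = sp, gene_id = genome$truth$gene_id,
        ortholog_retained = !gene_lost[genome$truth$gene_id],
        site_retained = !site_lost & !gene_lost[genome$truth$gene_id],
        stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(species = character(), gene_id = character(),
               ortholog_retained = logical(), site_retained = logical())
  rownames(truth) <- NULL
  list(reference = reference, panel = panel, truth = truth)
}
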