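# Synthetic study generator ------------------------------------------------
#
# Generates every input the pipeline needs without downloads: a toy
# multi-isoform genome annotation, an 8-array intensity matrix (4 conditions
# x 2 replicates) with log-normal noise and planted drought-responsive and
# memory transcripts, a GO annotation with one planted enriched term, and an
# ortholog alignment table.  Everything is deterministic under the config
# seed; each generator uses a fixed per-stage offset of that seed.

#' Simulation configuration
#'
#' Defaults mirror the study design being emulated: four states
#' (WT1/DR1/WT2/DR2) with two biological replicates, strong planted effects
#' (+/-3 log2 for the first-drought response and a further +/-3 log2 memory
#' increment in the second drought), replicate noise of 0.25 on the log2
#' scale, and a baseline intensity distribution anchored at a median of
#' about 231 raw units.
#'
#' @param seed integer seed driving every generator.
#' @param n_genes number of nuclear genes.
#' @param fraction_alternatively_spliced fraction of genes given a second
#'   isoform that skips one internal exon (the representative then carries a
#'   unique exon).
#' @param n_dit,n_drt planted drought-induced / -repressed transcripts.
#' @param n_dimt,n_drmt planted memory transcripts; nested within the
#'   corresponding response sets (`n_dimt <= n_dit`, `n_drmt <= n_drt`).
#' @param effect_response_log2 log2 effect of the first drought.
#' @param effect_memory_log2 additional log2 increment in the second drought
#'   for memory transcripts.
#' @param noise_sigma_log2 replicate noise standard deviation (log2 scale).
#' @param baseline_log2_mean,baseline_log2_sd baseline log2 intensity
#'   distribution.
#' @param background_level additive raw-scale background.
#' @param n_control_rows organellar/control rows carrying no planted effect.
#' @param utr3_max maximum simulated 3'-UTR length (some transcripts draw
#'   under 60 nt so the probe-frame shift rule is exercised).
#' @param n_go_terms background GO terms.
#' @param go_overlap_fraction fraction of the planted gene set annotated to
#'   the planted term.
#' @param go_term_size two-element range of background term sizes.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 200L,
                              fraction_alternatively_spliced = 0.3,
                              n_dit = 30L, n_drt = 30L,
                              n_dimt = 10L, n_drmt = 10L,
                              effect_response_log2 = 3,
                              effect_memory_log2 = 3,
                              noise_sigma_log2 = 0.25,
                              baseline_log2_mean = log2(231),
                              baseline_log2_sd = 2.5,
                              background_level = 30,
                              n_control_rows = 10L,
                              utr3_max = 200L,
                              n_go_terms = 30L,
                              go_overlap_fraction = 0.8,
                              go_term_size = c(10L, 40L)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              fraction_alternatively_spliced = fraction_alternatively_spliced,
              n_dit = n_dit, n_drt = n_drt, n_dimt = n_dimt, n_drmt = n_drmt,
              effect_response_log2 = effect_response_log2,
              effect_memory_log2 = effect_memory_log2,
              noise_sigma_log2 = noise_sigma_log2,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              background_level = background_level,
              n_control_rows = as.integer(n_control_rows),
              utr3_max = as.integer(utr3_max),
              n_go_terms = as.integer(n_go_terms),
              go_overlap_fraction = go_overlap_fraction,
              go_term_size = as.integer(go_term_size))
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$n_dimt > cfg$n_dit) stop("n_dimt must not exceed n_dit (gating)")
  if (cfg$n_drmt > cfg$n_drt) stop("n_drmt must not exceed n_drt (gating)")
  if (cfg$n_dit + cfg$n_drt > cfg$n_genes) {
    stop("planted counts exceed n_genes")
  }
  if (cfg$noise_sigma_log2 < 0 || cfg$baseline_log2_sd <= 0) {
    stop("noise and baseline standard deviations must be positive")
  }
  if (cfg$utr3_max < 0) stop("utr3_max must be non-negative")
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy multi-isoform genome
#'
#' Generates gene models with 1-4 exons, a valid CDS ending in a TAA stop
#' codon, 3'-UTRs of 0 to `utr3_max` nt (some shorter than 60 nt), and, for
#' the alternatively spliced fraction, a second isoform skipping one
#' internal exon so that the representative isoform carries a unique exon.
#' Genes alternate between strands.
#'
#' @param cfg a [simulation_config()].
#' @return list with `gff3_text`, `fasta_text` (character scalars) and
#'   `truth` (data frame: per gene, ids, strand, alt-splicing flag and the
#'   genomic interval of the skipped exon where present).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  n_alt <- round(cfg$fraction_alternatively_spliced * cfg$n_genes)
  alt_genes <- if (n_alt > 0) sort(sample.int(cfg$n_genes, n_alt))
  else integer(0)

  chrom_seq <- character(0)  # accumulated pieces of chr1
  cursor <- 1L
  gff <- c("##gff-version 3")
  truth <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", i)
    is_alt <- i %in% alt_genes
    strand <- if (i %% 2L == 0L) "-" else "+"
    n_exons <- if (is_alt) sample(3:4, 1L) else sample(1:4, 1L)
    exon_len <- sample(150:350, n_exons, replace = TRUE)
    intron_len <- if (n_exons > 1L) sample(60:200, n_exons - 1L,
                                           replace = TRUE) else integer(0)
    txlen <- sum(exon_len)
    utr5 <- sample(0:60, 1L)
    utr3 <- sample(0:cfg$utr3_max, 1L)
    utr3 <- min(utr3, txlen - utr5 - 90L)
    cds_len <- txlen - utr5 - utr3
    rem <- cds_len %% 3L
    utr5 <- utr5 + rem
    cds_len <- cds_len - rem
    cds_start_tx <- utr5 + 1L
    cds_end_tx <- utr5 + cds_len

    txseq <- rand_dna(txlen)
    substr(txseq, cds_end_tx - 2L, cds_end_tx) <- "TAA"

    # genomic placement: exons left-to-right with introns between
    gstarts <- integer(n_exons); gends <- integer(n_exons)
    pos <- cursor
    for (e in seq_len(n_exons)) {
      gstarts[e] <- pos
      gends[e] <- pos + exon_len[e] - 1L
      pos <- gends[e] + if (e < n_exons) intron_len[e] else 0L
    }
    exons <- cbind(start = gstarts, end = gends)
    # transcript order of exons: genomic order on '+', reversed on '-'
    tx_order <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
    offs <- c(0L, cumsum(exon_len[tx_order]))
    # genomic pieces in genomic order, with intron filler
    gpieces <- character(0)
    for (e in seq_len(n_exons)) {
      j <- which(tx_order == e)
      piece <- substr(txseq, offs[j] + 1L, offs[j + 1L])
      if (strand == "-") {
        piece <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(piece)))
      }
      gpieces <- c(gpieces, piece,
                   if (e < n_exons) rand_dna(intron_len[e]))
    }
    chrom_seq <- c(chrom_seq, gpieces, rand_dna(100L))  # intergenic gap
    cursor <- pos + 100L + 1L

    # CDS genomic intervals: intersect CDS tx span with each exon tx span
    cds_iv <- list()
    for (j in seq_len(n_exons)) {
      a <- offs[j] + 1L; b <- offs[j + 1L]
      lo <- max(a, cds_start_tx); hi <- min(b, cds_end_tx)
      if (lo > hi) next
      e <- tx_order[j]
      g1 <- tx_to_genomic(exons, strand, lo)
      g2 <- tx_to_genomic(exons, strand, hi)
      cds_iv[[length(cds_iv) + 1L]] <- c(min(g1, g2), max(g1, g2), e)
    }
    cds <- do.call(rbind, cds_iv)

    tid1 <- paste0(gid, ".1")
    gff <- c(gff, paste("chr1", "sim", "gene", gstarts[1L],
                        gends[n_exons], ".", strand, ".",
                        paste0("ID=", gid), sep = "\t"))
    gff <- c(gff, gff_mrna_lines(tid1, gid, strand, exons, cds))

    skipped <- NA_integer_
    if (is_alt) {
      skipped <- 2L  # skip the second genomic exon (internal)
      keep <- setdiff(seq_len(n_exons), skipped)
      exons2 <- exons[keep, , drop = FALSE]
      cds2 <- cds[cds[, 3L] != skipped, , drop = FALSE]
      gff <- c(gff, gff_mrna_lines(paste0(gid, ".2"), gid, strand,
                                   exons2, cds2))
    }
    truth[[i]] <- data.frame(
      gene_id = gid, representative = tid1, strand = strand,
      n_exons = n_exons, alternatively_spliced = is_alt,
      skipped_exon_start = if (is_alt) exons[skipped, 1L] else NA_integer_,
      skipped_exon_end = if (is_alt) exons[skipped, 2L] else NA_integer_)
  }
  seq_all <- paste(chrom_seq, collapse = "")
  fasta <- paste0(">chr1\n",
                  paste(substring(seq_all,
                                  seq(1L, nchar(seq_all), 80L),
                                  pmin(seq(1L, nchar(seq_all), 80L) + 79L,
                                       nchar(seq_all))),
                        collapse = "\n"), "\n")
  list(gff3_text = paste(gff, collapse = "\n"),
       fasta_text = fasta,
       truth = do.call(rbind, truth))
}

gff_mrna_lines <- function(tid, gid, strand, exons, cds) {
  out <- paste("chr1", "sim", "mRNA", min(exons[, 1L]), max(exons[, 2L]),
               ".", strand, ".", paste0("ID=", tid, ";Parent=", gid),
               sep = "\t")
  for (i in seq_len(nrow(exons))) {
    out <- c(out, paste("chr1", "sim", "exon", exons[i, 1L], exons[i, 2L],
                        ".", strand, ".", paste0("Parent=", tid), sep = "\t"))
  }
  for (i in seq_len(nrow(cds))) {
    out <- c(out, paste("chr1", "sim", "CDS", cds[i, 1L], cds[i, 2L],
                        ".", strand, "0", paste0("Parent=", tid), sep = "\t"))
  }
  out
}

#' Write simulated genome files
#'
#' @param sim output of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_simulated_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff3 <- file.path(dir, "genome.gff3")
  fasta <- file.path(dir, "genome.fa")
  truth <- file.path(dir, "genome_truth.tsv")
  writeLines(sim$gff3_text, gff3)
  cat(sim$fasta_text, file = fasta)
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  c(gff3 = gff3, fasta = fasta, truth = truth)
}

#' Simulate an 8-array intensity matrix with planted memory structure
#'
#' Baseline log2 intensities are drawn per transcript; planted
#' drought-induced transcripts gain the response effect in DR1 and DR2,
#' memory transcripts an additional increment in DR2 only, repressed classes
#' mirrored negatively; WT2 returns to baseline.  Replicate noise is added
#' on the log2 scale, values are exponentiated and an additive raw-scale
#' background applied.  Control rows carry no planted effect and no labels.
#'
#' @param cfg a [simulation_config()].
#' @param transcript_ids transcripts to simulate (e.g. representative
#'   transcripts of a simulated genome); planted labels are assigned among
#'   them at random under the seed.
#' @return list with `matrix` (raw-scale `expr_matrix` including control
#'   rows) and `truth` (data frame: transcript_id, true_label,
#'   true_memory_label, is_control).
#' @export
simulate_expression <- function(cfg, transcript_ids) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(transcript_ids)
  if (cfg$n_dit + cfg$n_drt > n) {
    stop("planted counts exceed the number of transcripts")
  }
  set.seed(cfg$seed + 202L)
  ids <- sample(transcript_ids)  # random planting positions
  dit <- ids[seq_len(cfg$n_dit)]
  drt <- ids[cfg$n_dit + seq_len(cfg$n_drt)]
  dimt <- dit[seq_len(cfg$n_dimt)]
  drmt <- drt[seq_len(cfg$n_drmt)]

  all_ids <- c(transcript_ids,
               if (cfg$n_control_rows > 0)
                 sprintf("CTRL_ORG_%03d", seq_len(cfg$n_control_rows)))
  is_control <- all_ids %in% setdiff(all_ids, transcript_ids)
  label <- ifelse(all_ids %in% dit, "DIT",
                  ifelse(all_ids %in% drt, "DRT", "non-responsive"))
  memory <- ifelse(all_ids %in% dimt, "DIMT",
                   ifelse(all_ids %in% drmt, "DRMT", "none"))
  label[is_control] <- "non-responsive"
  memory[is_control] <- "none"

  e <- cfg$effect_response_log2
  me <- cfg$effect_memory_log2
  eff <- matrix(0, nrow = length(all_ids), ncol = 4L,
                dimnames = list(all_ids, CONDITIONS))
  eff[label == "DIT", "DR1"] <- e
  eff[label == "DIT", "DR2"] <- e
  eff[label == "DRT", "DR1"] <- -e
  eff[label == "DRT", "DR2"] <- -e
  eff[memory == "DIMT", "DR2"] <- e + me
  eff[memory == "DRMT", "DR2"] <- -e - me

  # Induced stress genes start near basal levels and repressed ones
  # (photosynthesis, primary metabolism) are constitutively high, so planted
  # baselines are offset from the bulk; this also keeps induced peaks inside
  # the bulk dynamic range, where quantile normalization preserves ranks.
  baseline <- rnorm(length(all_ids), cfg$baseline_log2_mean,
                    cfg$baseline_log2_sd)
  n_up <- sum(label == "DIT"); n_dn <- sum(label == "DRT")
  baseline[label == "DIT"] <- rnorm(n_up,
                                    cfg$baseline_log2_mean - e,
                                    cfg$baseline_log2_sd / 2)
  baseline[label == "DRT"] <- rnorm(n_dn,
                                    cfg$baseline_log2_mean + e,
                                    cfg$baseline_log2_sd / 2)
  samples <- expand.grid(replicate = 1:2, condition = CONDITIONS,
                         stringsAsFactors = FALSE)[, 2:1]
  sample_ids <- paste0(samples$condition, "_", samples$replicate)
  v <- vapply(seq_len(nrow(samples)), function(j) {
    mu <- baseline + eff[, samples$condition[j]]
    2^(mu + rnorm(length(all_ids), 0, cfg$noise_sigma_log2)) +
      cfg$background_level
  }, numeric(length(all_ids)))
  dimnames(v) <- list(all_ids, sample_ids)
  meta <- data.frame(sample_id = sample_ids,
                     condition = samples$condition,
                     replicate = samples$replicate,
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(v, meta, "raw"),
       truth = data.frame(transcript_id = all_ids, true_label = label,
                          true_memory_label = memory,
                          is_control = is_control,
                          stringsAsFactors = FALSE))
}

#' Simulate a GO annotation with one planted enriched term
#'
#' Background terms draw members uniformly from the universe; the planted
#' term `GO:PLANTED` contains `go_overlap_fraction` of the supplied planted
#' gene set plus random fillers up to a background-sized membership.
#'
#' @param cfg a [simulation_config()].
#' @param gene_ids the gene universe.
#' @param planted_genes gene set the planted term should be enriched in.
#' @return a [go_annotation()] whose universe is `gene_ids`.
#' @export
simulate_go <- function(cfg, gene_ids, planted_genes = character(0)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(gene_ids) < 20L) stop("need at least 20 genes for a universe")
  set.seed(cfg$seed + 303L)
  rows <- list()
  for (t in seq_len(cfg$n_go_terms)) {
    size <- sample(cfg$go_term_size[1L]:cfg$go_term_size[2L], 1L)
    size <- min(size, length(gene_ids))
    rows[[t]] <- data.frame(term_id = sprintf("GO:%07d", t),
                            gene_id = sample(gene_ids, size))
  }
  if (length(planted_genes)) {
    k <- max(1L, round(cfg$go_overlap_fraction * length(planted_genes)))
    members <- sample(planted_genes, k)
    fill <- max(0L, cfg$go_term_size[1L] - k)
    if (fill > 0) {
      members <- unique(c(members,
                          sample(setdiff(gene_ids, members), fill)))
    }
    rows[[length(rows) + 1L]] <- data.frame(term_id = "GO:PLANTED",
                                            gene_id = members)
  }
  go_annotation(do.call(rbind, rows), universe = gene_ids)
}

#' Simulate an ortholog alignment table
#'
#' Produces a 12-column tabular alignment (outfmt-6-like layout) mapping a
#' fraction of the queries to synthetic subject genes with bit scores
#' straddling the acceptance threshold.
#'
#' @param cfg a [simulation_config()].
#' @param query_ids query transcript ids.
#' @param mapped_fraction fraction of queries given a hit scoring >= 70.
#' @return data frame with 12 unnamed alignment columns.
#' @export
simulate_alignments <- function(cfg, query_ids, mapped_fraction = 0.7) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 404L)
  rows <- lapply(seq_along(query_ids), function(i) {
    good <- runif(1) < mapped_fraction
    score <- if (good) round(runif(1, 70, 400), 1) else round(runif(1, 30, 69.9), 1)
    data.frame(V1 = query_ids[i],
               V2 = sprintf("AT%dG%05d", sample(1:5, 1L),
                            sample.int(99999L, 1L)),
               V3 = round(runif(1, 40, 100), 2), V4 = sample(50:500, 1L),
               V5 = sample(0:30, 1L), V6 = sample(0:5, 1L),
               V7 = 1L, V8 = sample(50:500, 1L),
               V9 = 1L, V10 = sample(50:500, 1L),
               V11 = signif(10^runif(1, -50, -2), 3), V12 = score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
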