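test_that("a toy two-isoform gene parses into one gene model with both transcripts", {
  chrom <- rand_chrom(600)
  body <- c(
    gff_feat("gene", 1, 500, "ID=g1"),
    gff_feat("mRNA", 1, 500, "ID=g1.1;Parent=g1"),
    gff_feat("exon", 1, 200, "Parent=g1.1"),
    gff_feat("exon", 301, 500, "Parent=g1.1"),
    gff_feat("CDS", 51, 200, "Parent=g1.1"),
    gff_feat("CDS", 301, 430, "Parent=g1.1"),
    gff_feat("mRNA", 1, 500, "ID=g1.2;Parent=g1"),
    gff_feat("exon", 1, 200, "Parent=g1.2"),
    gff_feat("exon", 401, 500, "Parent=g1.2"),
    gff_feat("CDS", 51, 200, "Parent=g1.2"))
  p <- write_toy_genome(body, chrom)
  out <- parse_gene_models(p$gff3, p$fasta)
  expect_length(out$genes, 1)
  expect_equal(nrow(out$errors), 0)
  g <- out$genes[["g1"]]
  expect_setequal(names(g$transcripts), c("g1.1", "g1.2"))
  t1 <- g$transcripts[["g1.1"]]
  expect_equal(t1$tx_length, 400L)
  expect_equal(t1$sequence,
               paste0(substr(chrom, 1, 200), substr(chrom, 301, 500)))
  # stop end: genomic 430 -> tx 200 + 130 = 330; 3'-UTR = 70
  expect_equal(t1$stop_end_tx, 330L)
  expect_equal(t1$utr3_length_tx, 70L)
})

test_that("minus-strand spliced sequence is the reverse complement", {
  chrom <- paste0("AAACCC", strrep("G", 94))
  body <- c(
    gff_feat("gene", 1, 6, "ID=g1", "-"),
    gff_feat("mRNA", 1, 6, "ID=g1.1;Parent=g1", "-"),
    gff_feat("exon", 1, 6, "Parent=g1.1", "-"),
    gff_feat("CDS", 1, 6, "Parent=g1.1", "-"))
  p <- write_toy_genome(body, chrom)
  out <- parse_gene_models(p$gff3, p$fasta)
  expect_equal(out$genes[["g1"]]$transcripts[["g1.1"]]$sequence, "GGGTTT")
})

test_that("a CDS extending past its exons yields an error record, not a gene", {
  chrom <- rand_chrom(300)
  body <- c(
    gff_feat("gene", 1, 200, "ID=g1"),
    gff_feat("mRNA", 1, 200, "ID=g1.1;Parent=g1"),
    gff_feat("exon", 1, 200, "Parent=g1.1"),
    gff_feat("CDS", 50, 250, "Parent=g1.1"))
  p <- write_toy_genome(body, chrom)
  out <- parse_gene_models(p$gff3, p$fasta)
  expect_length(out$genes, 0)
  expect_equal(out$errors$reason, "CDS outside exons")
})

test_that("a missing chromosome is fatal and names the feature", {
  body <- c(
    gff_feat("gene", 1, 100, "ID=g1"),
    gff_feat("mRNA", 1, 100, "ID=g1.1;Parent=g1"),
    gff_feat("exon", 1, 100, "Parent=g1.1"),
    gff_feat("CDS", 1, 90, "Parent=g1.1"))
  dir <- tempfile(); dir.create(dir)
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  writeLines(c("##gff-version 3", body), gff)
  writeLines(c(">chrOther", rand_chrom(200)), fa)
  expect_error(parse_gene_models(gff, fa), "g1.1")
})

test_that("representative selection follows longest-CDS with stated tie-breaks", {
  t_short <- make_tx(500, 300, id = "a.2")   # CDS 300
  t_long <- make_tx(600, 450, id = "a.1")    # CDS 450
  g <- structure(list(gene_id = "a", chromosome = "chr1", strand = "+",
                      transcripts = list(a.2 = t_short, a.1 = t_long)),
                 class = "gene_model")
  expect_equal(select_representative(g)$transcript_id, "a.1")

  # equal CDS, longer spliced sequence wins
  t1 <- make_tx(500, 300, id = "b.1")
  t2 <- make_tx(620, 300, id = "b.2")
  g2 <- structure(list(gene_id = "b", chromosome = "chr1", strand = "+",
                       transcripts = list(b.1 = t1, b.2 = t2)),
                  class = "gene_model")
  expect_equal(select_representative(g2)$transcript_id, "b.2")

  # full tie -> lexicographically smallest id
  t3 <- make_tx(500, 300, id = "c.2"); t4 <- make_tx(500, 300, id = "c.1")
  g3 <- structure(list(gene_id = "c", chromosome = "chr1", strand = "+",
                       transcripts = list(c.2 = t3, c.1 = t4)),
                  class = "gene_model")
  expect_equal(select_representative(g3)$transcript_id, "c.1")

  # single transcript is its own representative; no-CDS gene errors
  g4 <- structure(list(gene_id = "d", chromosome = "chr1", strand = "+",
                       transcripts = list(d.1 = t1)), class = "gene_model")
  expect_equal(select_representative(g4)$transcript_id, "b.1")
  t5 <- make_tx(100, 90, id = "e.1"); t5$cds <- t5$cds[0, , drop = FALSE]
  g5 <- structure(list(gene_id = "e", chromosome = "chr1", strand = "+",
                       transcripts = list(e.1 = t5)), class = "gene_model")
  expect_error(select_representative(g5), "non-coding")
})

test_that("unique exons are those absent from every sibling isoform", {
  chrom <- rand_chrom(1500)
  # representative has exons E1 [1,100], E2 [201,300], E3 [401,520]
  exons <- function(tid, which) {
    iv <- list(c(1, 100), c(201, 300), c(401, 520))[which]
    vapply(iv, function(x) gff_feat("exon", x[1], x[2],
                                    paste0("Parent=", tid)), character(1))
  }
  body <- c(
    gff_feat("gene", 1, 520, "ID=g1"),
    gff_feat("mRNA", 1, 520, "ID=g1.1;Parent=g1"),
    exons("g1.1", 1:3),
    gff_feat("CDS", 11, 100, "Parent=g1.1"),
    gff_feat("CDS", 201, 300, "Parent=g1.1"),
    gff_feat("CDS", 401, 430, "Parent=g1.1"),
    gff_feat("mRNA", 1, 520, "ID=g1.2;Parent=g1"),
    exons("g1.2", c(1, 3)),
    gff_feat("CDS", 11, 100, "Parent=g1.2"),
    gff_feat("mRNA", 1, 520, "ID=g1.3;Parent=g1"),
    exons("g1.3", 1:3),
    gff_feat("CDS", 11, 100, "Parent=g1.3"))
  p <- write_toy_genome(body, chrom)
  g <- parse_gene_models(p$gff3, p$fasta)$genes[["g1"]]
  rep_tx <- g$transcripts[["g1.1"]]

  # E2 present in sibling g1.3 -> not unique (must be absent from ALL);
  # brute-force oracle: compare every representative exon against the
  # union of sibling exon interval sets
  sib_ivs <- unique(unlist(lapply(g$transcripts[c("g1.2", "g1.3")],
                                  function(t) apply(t$exons, 1, paste,
                                                    collapse = "-"))))
  rep_ivs <- apply(rep_tx$exons, 1, paste, collapse = "-")
  oracle_unique <- rep_ivs[!rep_ivs %in% sib_ivs]
  ue <- find_unique_exons(g, rep_tx)
  expect_equal(nrow(ue), length(oracle_unique))
  expect_equal(nrow(ue), 0L)  # E2 is in g1.3, E1/E3 in both siblings

  # drop g1.3: now E2 is unique
  g2 <- g; g2$transcripts <- g$transcripts[c("g1.1", "g1.2")]
  ue2 <- find_unique_exons(g2, rep_tx)
  expect_equal(nrow(ue2), 1L)
  expect_equal(ue2$start_tx, 101L)
  expect_equal(ue2$end_tx, 200L)

  # invariance under sibling order permutation
  g3 <- g2; g3$transcripts <- rev(g2$transcripts)
  expect_equal(find_unique_exons(g3, rep_tx), ue2)

  # single-transcript gene -> empty, no error
  g4 <- g; g4$transcripts <- g$transcripts["g1.1"]
  expect_equal(nrow(find_unique_exons(g4, rep_tx)), 0L)
})

test_that("GFF3 round trip preserves coordinates and sequences", {
  cfg <- simulation_config(seed = 11, n_genes = 12, n_dit = 2, n_drt = 2,
                           n_dimt = 1, n_drmt = 1,
                           fraction_alternatively_spliced = 0.5)
  sim <- simulate_genome(cfg)
  p <- write_simulated_genome(sim, tempfile())
  out1 <- parse_gene_models(p[["gff3"]], p[["fasta"]])
  expect_equal(nrow(out1$errors), 0)
  gff2 <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(out1$genes, gff2)
  out2 <- parse_gene_models(gff2, p[["fasta"]])
  expect_equal(names(out2$genes), names(out1$genes))
  for (gid in names(out1$genes)) {
    for (tid in names(out1$genes[[gid]]$transcripts)) {
      a <- out1$genes[[gid]]$transcripts[[tid]]
      b <- out2$genes[[gid]]$transcripts[[tid]]
      expect_equal(a$exons, b$exons)
      expect_equal(a$cds, b$cds)
      expect_equal(a$sequence, b$sequence)
    }
  }
})

test_that("stop_end_tx maps back to the final CDS base under brute-force walking", {
  cfg <- simulation_config(seed = 5, n_genes = 15, n_dit = 2, n_drt = 2,
                           n_dimt = 1, n_drmt = 1,
                           fraction_alternatively_spliced = 0.4)
  sim <- simulate_genome(cfg)
  p <- write_simulated_genome(sim, tempfile())
  genes <- parse_gene_models(p[["gff3"]], p[["fasta"]])$genes
  for (g in genes) {
    for (t in g$transcripts) {
      # oracle: walk the exons base by base in transcript orientation
      gpos_all <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
        seq(t$exons[i, 1L], t$exons[i, 2L])))
      if (t$strand == "-") gpos_all <- rev(gpos_all)
      walked <- gpos_all[t$stop_end_tx]
      expected <- if (t$strand == "+") max(t$cds[, 2L]) else min(t$cds[, 1L])
      expect_identical(walked, expected)
      expect_identical(tx_to_genomic(t$exons, t$strand, t$stop_end_tx),
                       as.integer(expected))
      expect_identical(
        genomic_to_tx(t$exons, t$strand, walked), t$stop_end_tx)
    }
  }
})
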