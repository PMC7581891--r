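# Fixtures are built in code: tiny transcript models, toy GFF3/FASTA files
# and small intensity matrices.

# single-exon plus-strand transcript with CDS [cds_start, cds_end]
make_tx <- function(len, cds_end, cds_start = 1L, id = "tx1", gid = "g1",
                    seq = NULL, seed = 42L) {
  if (is.null(seq)) {
    set.seed(seed)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
  }
  droughtmem:::new_transcript_model(
    id, gid, "chr1", "+",
    exons = cbind(start = 1L, end = as.integer(len)),
    cds = cbind(start = as.integer(cds_start), end = as.integer(cds_end)),
    sequence = seq)
}

# write a toy genome: gff3 lines + one-chromosome fasta
write_toy_genome <- function(gff_body, chrom_seq, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  gff <- file.path(dir, "toy.gff3")
  fa <- file.path(dir, "toy.fa")
  writeLines(c("##gff-version 3", gff_body), gff)
  writeLines(c(">chr1", chrom_seq), fa)
  list(gff3 = gff, fasta = fa)
}

gff_feat <- function(type, start, end, attrs, strand = "+") {
  paste("chr1", "test", type, start, end, ".", strand,
        if (type == "CDS") "0" else ".", attrs, sep = "\t")
}

rand_chrom <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 8-sample expression matrix from per-condition replicate values;
# vals: named list condition -> matrix (rows x 2 replicates)
make_expr <- function(vals, scale = "raw") {
  conds <- names(vals)
  v <- do.call(cbind, vals)
  ids <- as.vector(t(outer(conds, 1:2, paste, sep = "_")))
  colnames(v) <- ids
  if (is.null(rownames(v))) rownames(v) <- paste0("t", seq_len(nrow(v)))
  meta <- data.frame(sample_id = ids,
                     condition = rep(conds, each = 2),
                     replicate = rep(1:2, length(conds)))
  expression_matrix(v, meta, scale)
}

# pooled sensitivity/specificity accumulator
pool_rates <- function(acc, truth, pred, lab) {
  if (is.null(acc)) acc <- c(tp = 0, pos = 0, tn = 0, neg = 0)
  acc + c(tp = sum(truth == lab & pred == lab), pos = sum(truth == lab),
          tn = sum(truth != lab & pred != lab), neg = sum(truth != lab))
}
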