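#' @importFrom stats cor lm coef quantile median rnorm runif setNames sd
#'   p.adjust pt phyper hclust as.dist dist var
#' @importFrom utils read.table write.table head modifyList
NULL

# Transcript and gene model containers -------------------------------------
#
# A transcript model stores genomic exon/CDS intervals (1-based, closed) plus
# the strand-normalized spliced sequence, so that transcript coordinate 1 is
# always the 5' end.  All probe arithmetic downstream is done in transcript
# coordinates anchored on `stop_end_tx`, the last base of the stop codon.

new_transcript_model <- function(transcript_id, gene_id, chromosome, strand,
                                 exons, cds, sequence) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds[, 1L]), , drop = FALSE]
  tx_length <- sum(exons[, 2L] - exons[, 1L] + 1L)
  if (nchar(sequence) != tx_length) {
    stop("spliced sequence length disagrees with exon lengths for ",
         transcript_id)
  }
  stop_end_tx <- NA_integer_
  if (nrow(cds)) {
    # last CDS base in transcript orientation: rightmost end on '+',
    # leftmost start on '-'
    g <- if (strand == "+") max(cds[, 2L]) else min(cds[, 1L])
    stop_end_tx <- genomic_to_tx(exons, strand, g)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chromosome = chromosome, strand = strand,
         exons = exons, cds = cds, sequence = sequence,
         tx_length = tx_length, stop_end_tx = stop_end_tx,
         utr3_length_tx = if (is.na(stop_end_tx)) NA_integer_
                          else tx_length - stop_end_tx),
    class = "transcript_model")
}

#' Map a genomic position into transcript coordinates
#'
#' Transcript coordinates are 1-based with position 1 at the 5' end, so on the
#' minus strand they run towards decreasing genomic position.
#'
#' @param exons two-column matrix of sorted genomic exon intervals
#'   (1-based, closed).
#' @param strand `"+"` or `"-"`.
#' @param gpos genomic position; must fall inside an exon.
#' @return integer transcript coordinate.
#' @export
genomic_to_tx <- function(exons, strand, gpos) {
  widths <- exons[, 2L] - exons[, 1L] + 1L
  hit <- which(gpos >= exons[, 1L] & gpos <= exons[, 2L])
  if (length(hit) != 1L) stop("position ", gpos, " not inside any exon")
  before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
  pos_plus <- before + (gpos - exons[hit, 1L] + 1L)
  if (strand == "+") as.integer(pos_plus)
  else as.integer(sum(widths) - pos_plus + 1L)
}

#' Map a transcript coordinate back to a genomic position
#'
#' Inverse of [genomic_to_tx()].
#'
#' @inheritParams genomic_to_tx
#' @param tpos 1-based transcript coordinate.
#' @return genomic position (integer).
#' @export
tx_to_genomic <- function(exons, strand, tpos) {
  widths <- exons[, 2L] - exons[, 1L] + 1L
  total <- sum(widths)
  if (tpos < 1L || tpos > total) stop("transcript position out of range")
  pos_plus <- if (strand == "+") tpos else total - tpos + 1L
  cum <- cumsum(widths)
  hit <- which(pos_plus <= cum)[1L]
  before <- if (hit > 1L) cum[hit - 1L] else 0L
  as.integer(exons[hit, 1L] + (pos_plus - before) - 1L)
}

#' Parse gene models from GFF3 and FASTA
#'
#' Reads gene/mRNA/exon/CDS features, extracts the strand-normalized spliced
#' sequence of every transcript, and derives the transcript-coordinate
#' position of the stop-codon end (`stop_end_tx`) and the 3'-UTR length.
#' Genes whose transcripts carry no CDS, or whose CDS falls outside the
#' annotated exons, are excluded and reported in the `errors` table.
#'
#' @param gff3_source path to a GFF3 file with gene, mRNA, exon and CDS
#'   features linked by `Parent` attributes.
#' @param fasta_source path to a FASTA file containing every chromosome
#'   referenced by the annotation.
#' @param stop_codon_included logical; if `FALSE` the annotation dialect
#'   excludes the stop codon from the CDS and the CDS end is extended by 3
#'   bases before deriving `stop_end_tx`.
#' @return a list with components `genes` (named list of gene models, each a
#'   list with `gene_id`, `chromosome`, `strand` and `transcripts`) and
#'   `errors` (data frame of per-gene error records).
#' @export
parse_gene_models <- function(gff3_source, fasta_source,
                              stop_codon_included = TRUE) {
  gr <- rtracklayer::import(gff3_source, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_source)
  names(genome) <- sub("\\s.*$", "", names(genome))

  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent
  parent1 <- vapply(as.list(parents), function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))

  mrna_idx <- which(type == "mRNA")
  gene_of_mrna <- parent1[mrna_idx]
  mrna_ids <- ids[mrna_idx]
  if (anyDuplicated(mrna_ids)) stop("duplicate mRNA IDs in annotation")

  seqs <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)

  exon_idx <- which(type == "exon")
  cds_idx <- which(type == "CDS")
  exon_by_tx <- split(exon_idx, parent1[exon_idx])
  cds_by_tx <- split(cds_idx, parent1[cds_idx])

  genes <- list()
  errors <- list()
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tid <- mrna_ids[k]
    gid <- gene_of_mrna[k]
    chrom <- seqs[i]
    strand <- strands[i]
    if (!chrom %in% names(genome)) {
      stop("chromosome '", chrom, "' referenced by ", tid,
           " is missing from the FASTA")
    }
    ei <- exon_by_tx[[tid]]
    if (is.null(ei) || !length(ei)) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene_id = gid, transcript_id = tid, reason = "no exons")
      next
    }
    exons <- cbind(start = starts[ei], end = ends[ei])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    ci <- cds_by_tx[[tid]]
    cds <- if (is.null(ci) || !length(ci))
      matrix(integer(0), ncol = 2L,
             dimnames = list(NULL, c("start", "end")))
    else {
      m <- cbind(start = starts[ci], end = ends[ci])
      m[order(m[, 1L]), , drop = FALSE]
    }
    if (!nrow(cds)) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene_id = gid, transcript_id = tid, reason = "no CDS")
      next
    }
    if (!stop_codon_included) {
      if (strand == "+") cds[nrow(cds), 2L] <- cds[nrow(cds), 2L] + 3L
      else cds[1L, 1L] <- cds[1L, 1L] - 3L
    }
    if (!cds_within_exons(cds, exons)) {
      errors[[length(errors) + 1L]] <-
        data.frame(gene_id = gid, transcript_id = tid,
                   reason = "CDS outside exons")
      next
    }
    chrom_seq <- genome[[chrom]]
    pieces <- Biostrings::DNAStringSet(
      chrom_seq, start = exons[, 1L], end = exons[, 2L])
    spliced <- Biostrings::DNAString(paste(as.character(pieces),
                                           collapse = ""))
    if (strand == "-") spliced <- Biostrings::reverseComplement(spliced)
    tm <- new_transcript_model(tid, gid, chrom, strand, exons, cds,
                               as.character(spliced))
    if (is.null(genes[[gid]])) {
      genes[[gid]] <- list(gene_id = gid, chromosome = chrom,
                           strand = strand, transcripts = list())
      class(genes[[gid]]) <- "gene_model"
    }
    genes[[gid]]$transcripts[[tid]] <- tm
  }
  errors <- if (length(errors)) do.call(rbind, errors)
  else data.frame(gene_id = character(0), transcript_id = character(0),
                  reason = character(0))
  list(genes = genes, errors = errors)
}

cds_within_exons <- function(cds, exons) {
  all(vapply(seq_len(nrow(cds)), function(i) {
    any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
  }, logical(1L)))
}

#' Select the representative transcript of a gene
#'
#' The representative isoform anchors probe design, so it must have a
#' well-defined stop codon.  Selection is deterministic: longest total CDS,
#' ties broken by longest spliced sequence, then by lexicographically
#' smallest transcript id.
#'
#' @param gene a gene model from [parse_gene_models()].
#' @return a transcript model.
#' @export
select_representative <- function(gene) {
  txs <- gene$transcripts
  cds_len <- vapply(txs, function(t)
    if (nrow(t$cds)) sum(t$cds[, 2L] - t$cds[, 1L] + 1L) else 0L, numeric(1L))
  keep <- cds_len > 0
  if (!any(keep)) stop("non-coding gene: ", gene$gene_id,
                       " has no CDS-bearing transcript")
  txs <- txs[keep]; cds_len <- cds_len[keep]
  tx_len <- vapply(txs, function(t) t$tx_length, numeric(1L))
  ids <- vapply(txs, function(t) t$transcript_id, character(1L))
  ord <- order(-cds_len, -tx_len, ids)
  txs[[ord[1L]]]
}

#' Find unique exons of the representative isoform
#'
#' An exon of the representative transcript is unique when its exact genomic
#' interval appears in no sibling isoform of the same gene; such exons can
#' carry an isoform-discriminating probe.  For single-transcript genes the
#' result is empty.
#'
#' @param gene a gene model.
#' @param representative the representative transcript (normally from
#'   [select_representative()]).
#' @return data frame with `transcript_id`, `start_tx`, `end_tx`, `length`,
#'   sorted by transcript coordinate.
#' @export
find_unique_exons <- function(gene, representative) {
  sibs <- gene$transcripts[names(gene$transcripts) !=
                             representative$transcript_id]
  empty <- data.frame(transcript_id = character(0), start_tx = integer(0),
                      end_tx = integer(0), length = integer(0))
  if (!length(sibs)) return(empty)
  rex <- representative$exons
  unique_rows <- vapply(seq_len(nrow(rex)), function(i) {
    all(vapply(sibs, function(s) {
      !any(s$exons[, 1L] == rex[i, 1L] & s$exons[, 2L] == rex[i, 2L])
    }, logical(1L)))
  }, logical(1L))
  if (!any(unique_rows)) return(empty)
  rows <- lapply(which(unique_rows), function(i) {
    a <- genomic_to_tx(rex, representative$strand, rex[i, 1L])
    b <- genomic_to_tx(rex, representative$strand, rex[i, 2L])
    data.frame(transcript_id = representative$transcript_id,
               start_tx = min(a, b), end_tx = max(a, b),
               length = abs(b - a) + 1L)
  })
  out <- do.call(rbind, rows)
  out[order(out$start_tx), , drop = FALSE]
}

#' Write gene models back to GFF3
#'
#' Emits gene/mRNA/exon/CDS features with Parent links; round-tripping
#' through [parse_gene_models()] reproduces coordinates and sequences.
#'
#' @param genes named list of gene models.
#' @param path output file path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    gstart <- min(vapply(g$transcripts, function(t) min(t$exons[, 1L]),
                         numeric(1L)))
    gend <- max(vapply(g$transcripts, function(t) max(t$exons[, 2L]),
                       numeric(1L)))
    lines <- c(lines, paste(g$chromosome, "droughtmem", "gene", gstart, gend,
                            ".", g$strand, ".", paste0("ID=", g$gene_id),
                            sep = "\t"))
    for (t in g$transcripts) {
      lines <- c(lines, paste(
        g$chromosome, "droughtmem", "mRNA", min(t$exons[, 1L]),
        max(t$exons[, 2L]), ".", t$strand, ".",
        paste0("ID=", t$transcript_id, ";Parent=", g$gene_id), sep = "\t"))
      for (i in seq_len(nrow(t$exons))) {
        lines <- c(lines, paste(
          g$chromosome, "droughtmem", "exon", t$exons[i, 1L], t$exons[i, 2L],
          ".", t$strand, ".", paste0("Parent=", t$transcript_id), sep = "\t"))
      }
      for (i in seq_len(nrow(t$cds))) {
        lines <- c(lines, paste(
          g$chromosome, "droughtmem", "CDS", t$cds[i, 1L], t$cds[i, 2L],
          ".", t$strand, "0", paste0("Parent=", t$transcript_id), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a transcript-model summary table
#'
#' @param genes named list of gene models.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
write_transcript_table <- function(genes, path) {
  rows <- list()
  for (g in genes) for (t in g$transcripts) {
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = t$transcript_id, gene_id = t$gene_id,
      strand = t$strand, n_exons = nrow(t$exons),
      cds_len = if (nrow(t$cds)) sum(t$cds[, 2L] - t$cds[, 1L] + 1L) else 0L,
      utr3_len = t$utr3_length_tx)
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript model ", x$transcript_id, " (", x$gene_id, ", strand ",
      x$strand, ")\n", sep = "")
  cat("  exons: ", nrow(x$exons), ", length: ", x$tx_length,
      " nt, stop end at tx position ", x$stop_end_tx,
      ", 3'-UTR: ", x$utr3_length_tx, " nt\n", sep = "")
  invisible(x)
}
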