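# Probe design ------------------------------------------------------------
#
# Each transcript receives three 60-nt probes stepping downstream at 30-bp
# intervals, anchored so that with full flanks the trio covers 120 bases: the
# final 60 bases of CDS and the first 60 bases of 3'-UTR.  When the 3'-UTR is
# shorter than 60 nt the whole frame shifts upstream so the last probe still
# ends on the transcript; probes whose start would fall before position 1 are
# omitted.

PROBE_LEN <- 60L
PROBE_STEP <- 30L

probe_row <- function(probe_id, gene_id, transcript_id, start_tx, sequence,
                      category, dropped = FALSE, reason = NA_character_) {
  n <- length(probe_id)
  data.frame(probe_id = probe_id, gene_id = rep_len(gene_id, n),
             transcript_id = rep_len(transcript_id, n),
             start_tx = as.integer(start_tx),
             length = rep_len(PROBE_LEN, n), sequence = sequence,
             category = category, dropped = rep_len(dropped, n),
             reason = rep_len(reason, n), stringsAsFactors = FALSE)
}

empty_probe_table <- function() {
  probe_row(character(0), character(0), character(0), integer(0),
            character(0), character(0), logical(0), character(0))
}

#' Design the three stop-codon-anchored tiling probes of a transcript
#'
#' With a full 60-bp CDS flank and a 3'-UTR of at least 60 nt, the probes
#' occupy `[stop-59, stop]`, `[stop-29, stop+30]` and `[stop+1, stop+60]`
#' (transcript coordinates, `stop` = last base of the stop codon), jointly
#' spanning 120 bases centred on the CDS/3'-UTR boundary.  A 3'-UTR shorter
#' than 60 nt shifts the frame upstream by the deficit; probes that would
#' start before transcript position 1 are then dropped.
#'
#' @param transcript a transcript model with a defined `stop_end_tx`.
#' @return data frame of up to three probe records (categories
#'   `TILE1`/`TILE2`/`TILE3`); empty with attribute `reason = "too short"`
#'   for transcripts under 60 nt.
#' @export
tile_probes <- function(transcript) {
  L <- transcript$tx_length
  stop_end <- transcript$stop_end_tx
  if (is.na(stop_end)) stop("transcript ", transcript$transcript_id,
                            " has no stop-codon anchor (no CDS)")
  if (L < PROBE_LEN) {
    out <- empty_probe_table()
    attr(out, "reason") <- "too short"
    return(out)
  }
  shift <- max(0L, PROBE_LEN - (L - stop_end))
  starts <- stop_end - (PROBE_LEN - 1L) + (0L:2L) * PROBE_STEP - shift
  keep <- starts >= 1L & (starts + PROBE_LEN - 1L) <= L
  starts <- starts[keep]
  cats <- paste0("TILE", 1:3)[keep]
  if (!length(starts)) return(empty_probe_table())
  seqs <- substring(transcript$sequence, starts, starts + PROBE_LEN - 1L)
  probe_row(paste0(transcript$transcript_id, "_P", which(keep)),
            transcript$gene_id, transcript$transcript_id, starts, seqs, cats)
}

#' Design an isoform-discriminating probe on a unique exon
#'
#' Places a single 60-nt probe centred in the unique exon; exons shorter
#' than 60 nt yield no probe.
#'
#' @param transcript the transcript owning the exon.
#' @param ue one row of [find_unique_exons()] output (transcript-coordinate
#'   interval).
#' @param suffix probe id suffix, default `"_UE"`.
#' @return a one-row probe record, or `NULL` for short exons.
#' @export
design_ue_probe <- function(transcript, ue, suffix = "_UE") {
  len <- ue$end_tx - ue$start_tx + 1L
  if (len < PROBE_LEN) return(NULL)
  start <- ue$start_tx + floor((len - PROBE_LEN) / 2)
  probe_row(paste0(transcript$transcript_id, suffix),
            transcript$gene_id, transcript$transcript_id, start,
            substring(transcript$sequence, start, start + PROBE_LEN - 1L),
            "UE")
}

#' Flag cross-hybridizing probes
#'
#' A probe cross-hybridizes when its exact 60-mer (or its reverse complement)
#' occurs in any transcript belonging to a different gene; matches to
#' isoforms of the probe's own gene are exempt.  To preserve coverage, at
#' most one of a transcript's tiling probes is dropped: the one with the most
#' cross-gene matches (ties drop the higher `start_tx`).  Unique-exon and
#' control probes are dropped on any cross-gene match.
#'
#' @param probes probe table (e.g. from [assemble_chip()]).
#' @param transcriptome_sequences named character vector or
#'   [Biostrings::DNAStringSet] of transcript sequences.
#' @param tx2gene named character vector mapping transcript id to gene id
#'   for the transcriptome; transcripts absent from the map are treated as
#'   foreign to every probe.
#' @return the probe table with `dropped`/`reason` filled in.
#' @export
screen_cross_hybridization <- function(probes, transcriptome_sequences,
                                       tx2gene = NULL) {
  if (!nrow(probes)) return(probes)
  stopifnot(all(nchar(probes$sequence) == PROBE_LEN))
  subject <- if (inherits(transcriptome_sequences, "DNAStringSet"))
    transcriptome_sequences
  else Biostrings::DNAStringSet(transcriptome_sequences)
  if (is.null(tx2gene)) {
    tx2gene <- setNames(rep(NA_character_, length(subject)), names(subject))
  }
  pset <- Biostrings::DNAStringSet(probes$sequence)
  fwd <- Biostrings::vcountPDict(Biostrings::PDict(pset), subject)
  rev <- Biostrings::vcountPDict(
    Biostrings::PDict(Biostrings::reverseComplement(pset)), subject)
  hits <- fwd + rev  # probes x transcripts
  subj_gene <- unname(tx2gene[names(subject)])
  cross <- vapply(seq_len(nrow(probes)), function(i) {
    foreign <- is.na(subj_gene) | subj_gene != probes$gene_id[i]
    sum(hits[i, foreign])
  }, numeric(1L))

  probes$cross_matches <- cross
  is_tile <- grepl("^TILE", probes$category)
  for (tid in unique(probes$transcript_id[is_tile])) {
    idx <- which(probes$transcript_id == tid & is_tile)
    bad <- idx[cross[idx] > 0]
    if (!length(bad)) next
    # drop exactly one: most promiscuous, tie -> higher start_tx
    ord <- bad[order(-cross[bad], -probes$start_tx[bad])]
    drop <- ord[1L]
    probes$dropped[drop] <- TRUE
    probes$reason[drop] <- "cross-hybridization"
  }
  other <- which(!is_tile & cross > 0)
  probes$dropped[other] <- TRUE
  probes$reason[other] <- "cross-hybridization"
  probes
}

#' Assemble the chip probe manifest
#'
#' Tiling probes are designed for the representative transcript of every gene
#' and for each additional annotated isoform; unique exons of the
#' representative (length >= 60 nt) receive an extra isoform-discriminating
#' probe.  Organellar and selection-marker control sequences, which carry no
#' CDS annotation, get three tiling-style probes anchored at the sequence
#' end.
#'
#' @param genes named list of gene models from [parse_gene_models()].
#' @param organellar_fasta,marker_fasta optional FASTA paths with control
#'   sequences.
#' @return an object of class `chip_manifest`: list with `probes` (probe
#'   table), `counts` (by category) and `controls` (control sequence ids).
#' @export
assemble_chip <- function(genes, organellar_fasta = NULL,
                          marker_fasta = NULL) {
  all_tids <- unlist(lapply(genes, function(g) names(g$transcripts)))
  if (anyDuplicated(all_tids)) {
    stop("duplicate transcript ids across input: ",
         paste(unique(all_tids[duplicated(all_tids)]), collapse = ", "))
  }
  tabs <- list()
  for (g in genes) {
    rep_tx <- select_representative(g)
    for (t in g$transcripts) tabs[[length(tabs) + 1L]] <- tile_probes(t)
    ues <- find_unique_exons(g, rep_tx)
    if (nrow(ues)) {
      for (i in seq_len(nrow(ues))) {
        suffix <- if (nrow(ues) == 1L) "_UE" else paste0("_UE", i)
        p <- design_ue_probe(rep_tx, ues[i, ], suffix = suffix)
        if (!is.null(p)) tabs[[length(tabs) + 1L]] <- p
      }
    }
  }
  controls <- character(0)
  for (src in list(c(organellar_fasta, "ORGANELLAR"),
                   c(marker_fasta, "MARKER_CONTROL"))) {
    if (length(src) < 2L || is.null(src[1L]) || is.na(src[1L])) next
    ctl <- Biostrings::readDNAStringSet(src[1L])
    names(ctl) <- sub("\\s.*$", "", names(ctl))
    controls <- c(controls, names(ctl))
    for (j in seq_along(ctl)) {
      tm <- control_pseudo_transcript(names(ctl)[j], as.character(ctl[[j]]))
      p <- tile_probes(tm)
      if (nrow(p)) p$category <- src[2L]
      tabs[[length(tabs) + 1L]] <- p
    }
  }
  probes <- do.call(rbind, c(tabs, list(empty_probe_table())))
  rownames(probes) <- NULL
  if (anyDuplicated(probes$probe_id)) stop("internal: duplicate probe ids")
  structure(list(probes = probes,
                 counts = table(probes$category),
                 controls = controls),
            class = "chip_manifest")
}

# Controls have no CDS annotation: anchor the tiling frame at the sequence
# end by treating the final base as the stop-codon end (zero-length 3'-UTR).
control_pseudo_transcript <- function(id, sequence) {
  L <- nchar(sequence)
  structure(list(transcript_id = id, gene_id = id, chromosome = NA_character_,
                 strand = "+", exons = cbind(start = 1L, end = L),
                 cds = cbind(start = 1L, end = L), sequence = sequence,
                 tx_length = L, stop_end_tx = L, utr3_length_tx = 0L),
            class = "transcript_model")
}

#' Write the chip manifest and probe FASTA
#'
#' @param manifest a `chip_manifest`.
#' @param manifest_path output TSV path (probe_id, gene_id, transcript_id,
#'   start_tx, category, sequence, dropped, reason).
#' @param fasta_path optional probe FASTA output path.
#' @export
write_chip_manifest <- function(manifest, manifest_path, fasta_path = NULL) {
  p <- manifest$probes
  cols <- c("probe_id", "gene_id", "transcript_id", "start_tx", "category",
            "sequence", "dropped", "reason")
  write.table(p[, cols], manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta_path)) {
    keep <- !p$dropped
    writeLines(paste0(">", p$probe_id[keep], "\n", p$sequence[keep]),
               fasta_path)
  }
  invisible(manifest_path)
}

#' @export
print.chip_manifest <- function(x, ...) {
  cat("Chip manifest:", nrow(x$probes), "probes\n")
  print(x$counts)
  if (any(x$probes$dropped)) {
    cat(sum(x$probes$dropped), "probes flagged dropped\n")
  }
  if (length(x$controls)) cat(length(x$controls), "control sequences\n")
  invisible(x)
}
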