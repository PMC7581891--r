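# End-to-end pipeline -------------------------------------------------------

default_run_config <- function() {
  list(seed = 1L, outdir = tempfile("droughtmem_run_"),
       stages = c("simulate", "design", "normalize", "diff", "classify",
                  "enrich", "network"),
       n_genes = 120L, fraction_alternatively_spliced = 0.3,
       n_dit = 20L, n_drt = 20L, n_dimt = 8L, n_drmt = 8L,
       fold = 4, alpha = 0.05, level_cut = 1, abs_r = 0.65,
       score_threshold = 70, randomizations = 100L,
       offset = 1, bg_quantile = 0.05, tolerance_fold = 2,
       matrix_path = NULL, samples_path = NULL, go_path = NULL,
       control_ids = NULL)
}

#' Run the drought-memory pipeline end to end
#'
#' Executes the requested stages in order (simulate or ingest, probe design,
#' normalization, moderated differential statistics, memory classification,
#' GO enrichment, co-expression network), writes per-stage outputs under the
#' configured output directory, and records a JSON manifest listing inputs,
#' thresholds, seeds, per-stage outputs with md5 checksums and headline
#' counts.  One seed fans out to fixed per-stage derivations, so a rerun
#' with the same config is byte-identical.
#'
#' @param config named list overriding the defaults, or a path to a YAML
#'   file of such overrides.  Recognised keys include `seed`, `outdir`,
#'   `stages`, the simulation sizes (`n_genes`, `n_dit`, ...), the analysis
#'   thresholds (`fold`, `alpha`, `level_cut`, `abs_r`, `score_threshold`,
#'   `randomizations`) and, when the `simulate` stage is skipped,
#'   `matrix_path`/`samples_path`/`go_path`.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  bad <- names(config)[!names(config) %in% names(default_run_config())]
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (th in c("fold", "alpha", "level_cut", "abs_r", "score_threshold",
               "randomizations")) {
    if (!is.numeric(cfg[[th]]) || cfg[[th]] <= 0) {
      stop("threshold '", th, "' must be positive")
    }
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "outdir")],
                   stages = list())
  outputs <- character(0)
  genes <- NULL; truth <- NULL; norm <- NULL; cls <- NULL; anno <- NULL

  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      sim_cfg <- simulation_config(
        seed = cfg$seed, n_genes = cfg$n_genes,
        fraction_alternatively_spliced = cfg$fraction_alternatively_spliced,
        n_dit = cfg$n_dit, n_drt = cfg$n_drt,
        n_dimt = cfg$n_dimt, n_drmt = cfg$n_drmt)
      genome <- simulate_genome(sim_cfg)
      paths <- write_simulated_genome(genome, cfg$outdir)
      parsed <- parse_gene_models(paths[["gff3"]], paths[["fasta"]])
      genes <<- parsed$genes
      reps <- vapply(genes, function(g)
        select_representative(g)$transcript_id, character(1L))
      sim <- simulate_expression(sim_cfg, unname(reps))
      mp <- file.path(cfg$outdir, "intensity_raw.tsv")
      sp <- file.path(cfg$outdir, "samples.tsv")
      write_intensity_matrix(sim$matrix, mp, sp)
      tp <- file.path(cfg$outdir, "expression_truth.tsv")
      write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      truth <<- sim$truth
      cfg$matrix_path <<- mp; cfg$samples_path <<- sp
      cfg$control_ids <<- sim$truth$transcript_id[sim$truth$is_control]
      planted <- sim$truth$transcript_id[
        sim$truth$true_memory_label == "DIMT"]
      anno <<- simulate_go(sim_cfg, sim$truth$transcript_id, planted)
      gp <- file.path(cfg$outdir, "go_annotation.tsv")
      ann_tab <- do.call(rbind, lapply(names(anno$terms), function(t)
        data.frame(term_id = t, gene_id = anno$terms[[t]])))
      write.table(ann_tab, gp, sep = "\t", quote = FALSE, row.names = FALSE)
      ap <- file.path(cfg$outdir, "alignments.tsv")
      aln <- simulate_alignments(sim_cfg, sim$truth$transcript_id[
        !sim$truth$is_control])
      write.table(aln, ap, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      manifest$stages$simulate <<- list(
        outputs = unname(c(paths, mp, sp, tp, gp, ap)),
        n_transcripts = nrow(sim$truth))
      outputs <<- c(outputs, unname(c(paths, mp, sp, tp, gp, ap)))
    })
  }

  if ("design" %in% cfg$stages) {
    run_stage("design", function() {
      if (is.null(genes)) stop("probe design needs the simulate stage ",
                               "(or pre-parsed gene models)")
      chip <- assemble_chip(genes)
      seqs <- unlist(lapply(genes, function(g)
        lapply(g$transcripts, function(t) t$sequence)))
      names(seqs) <- unlist(lapply(genes, function(g) names(g$transcripts)))
      tx2gene <- unlist(unname(lapply(genes, function(g)
        setNames(rep(g$gene_id, length(g$transcripts)),
                 names(g$transcripts)))))
      chip$probes <- screen_cross_hybridization(chip$probes, seqs, tx2gene)
      mp <- file.path(cfg$outdir, "chip_manifest.tsv")
      fp <- file.path(cfg$outdir, "probes.fa")
      write_chip_manifest(chip, mp, fp)
      manifest$stages$design <<- list(outputs = c(mp, fp),
                                      n_probes = nrow(chip$probes),
                                      n_dropped = sum(chip$probes$dropped))
      outputs <<- c(outputs, mp, fp)
    })
  }

  if ("normalize" %in% cfg$stages) {
    run_stage("normalize", function() {
      if (is.null(cfg$matrix_path)) stop("no intensity matrix configured")
      raw <- read_intensity_matrix(cfg$matrix_path, cfg$samples_path, "raw")
      norm <<- normalize_expression(raw, offset = cfg$offset,
                                    bg_quantile = cfg$bg_quantile)
      np <- file.path(cfg$outdir, "normalized_log2.tsv")
      write_intensity_matrix(norm, np)
      manifest$stages$normalize <<- list(outputs = np,
                                         offset = cfg$offset,
                                         bg_quantile = cfg$bg_quantile)
      outputs <<- c(outputs, np)
    })
  }

  if ("diff" %in% cfg$stages) {
    run_stage("diff", function() {
      if (is.null(norm)) stop("differential statistics need the ",
                              "normalize stage")
      fit <- moderated_differential(norm)
      dp <- file.path(cfg$outdir, "differential.tsv")
      write.table(fit$table, dp, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      sig <- filter_significant(fit, alpha = cfg$alpha,
                                level_cut = cfg$level_cut)
      sp <- file.path(cfg$outdir, "significant_ids.txt")
      writeLines(sig, sp)
      manifest$stages$diff <<- list(outputs = c(dp, sp),
                                    alpha = cfg$alpha,
                                    level_cut = cfg$level_cut,
                                    n_significant = length(sig),
                                    d0 = fit$d0)
      outputs <<- c(outputs, dp, sp)
    })
  }

  if ("classify" %in% cfg$stages) {
    run_stage("classify", function() {
      if (is.null(norm)) stop("classification needs the normalize stage")
      cls <<- classify_drought_memory(norm, fold = cfg$fold,
                                      control_ids = cfg$control_ids,
                                      tolerance_fold = cfg$tolerance_fold)
      cp <- file.path(cfg$outdir, "classification.tsv")
      write.table(cls, cp, sep = "\t", quote = FALSE, row.names = FALSE)
      counts <- summarize_counts(cls, path = cfg$outdir)
      manifest$stages$classify <<- list(
        outputs = cp, fold = cfg$fold, counts = as.list(counts))
      outputs <<- c(outputs, cp)
    })
  }

  if ("enrich" %in% cfg$stages) {
    run_stage("enrich", function() {
      if (is.null(cls)) stop("enrichment needs the classify stage")
      if (is.null(anno)) {
        if (is.null(cfg$go_path)) stop("no GO annotation configured")
        anno <<- go_annotation(cfg$go_path)
      }
      sets <- list(DIT = cls$transcript_id[cls$label == "DIT"],
                   DRT = cls$transcript_id[cls$label == "DRT"],
                   DIMT = cls$transcript_id[cls$memory_label == "DIMT"],
                   DRMT = cls$transcript_id[cls$memory_label == "DRMT"])
      sets <- sets[vapply(sets, function(s)
        length(intersect(s, anno$universe)) > 0, logical(1L))]
      tabs <- lapply(seq_along(sets), function(i) {
        suppressWarnings(enrich_go(sets[[i]], anno,
                                   R = cfg$randomizations,
                                   seed = cfg$seed + 500L + i))
      })
      names(tabs) <- names(sets)
      paths <- character(0)
      for (nm in names(tabs)) {
        p <- file.path(cfg$outdir, paste0("enrichment_", nm, ".tsv"))
        write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths <- c(paths, p)
      }
      dirs <- c(DIT = "induced", DIMT = "induced",
                DRT = "repressed", DRMT = "repressed")
      sm <- score_matrix(tabs, dirs)
      smp <- file.path(cfg$outdir, "enrichment_scores.tsv")
      write.table(data.frame(term_id = rownames(sm), sm,
                             check.names = FALSE),
                  smp, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$enrich <<- list(
        outputs = c(paths, smp), randomizations = cfg$randomizations,
        n_selected_terms = nrow(sm))
      outputs <<- c(outputs, paths, smp)
    })
  }

  if ("network" %in% cfg$stages) {
    run_stage("network", function() {
      if (is.null(norm) || is.null(cls)) {
        stop("network needs the normalize and classify stages")
      }
      mem <- cls$transcript_id[cls$memory_label != "none"]
      if (length(mem) < 2L) mem <- cls$transcript_id[cls$label !=
                                                       "non-responsive"]
      if (length(mem) < 2L) {
        manifest$stages$network <<- list(outputs = character(0),
                                         note = "fewer than 2 memory genes")
        return(invisible(NULL))
      }
      expr <- norm$values[mem, , drop = FALSE]
      net <- pearson_network(expr, threshold = cfg$abs_r)
      ep <- file.path(cfg$outdir, "network_edges.tsv")
      cp <- file.path(cfg$outdir, "network_components.tsv")
      write_network(net, ep, cp)
      nk <- file.path(cfg$outdir, "network.nwk")
      writeLines(cluster_tree(net), nk)
      manifest$stages$network <<- list(
        outputs = c(ep, cp, nk), abs_r = cfg$abs_r,
        n_edges = nrow(net$edges),
        component_sizes = as.integer(net$component_sizes))
      outputs <<- c(outputs, ep, cp, nk)
    })
  }

  manifest$checksums <- as.list(tools::md5sum(sort(unique(outputs))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  mp <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
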