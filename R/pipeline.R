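# End-to-end orchestration: structure -> markers -> schemes -> trees ->
# ranking, with a run manifest.

#' Run the full plastome survey pipeline
#'
#' Executes every stage on a cohort of annotated genomes (or on a freshly
#' simulated cohort when `sim` is given): quadripartite structure and
#' region/class tables, marker extraction, the six concatenation schemes,
#' the full-scheme reference tree, per-marker bootstrap trees, and the
#' composite marker ranking. All outputs are plain text (TSV, FASTA,
#' Newick) under `outdir`; a manifest records configuration, seeds, input
#' checksums and per-stage outputs and timings. Reruns with the same
#' inputs and seed are identical.
#'
#' @param genomes list of annotated [circular_genome()] objects (>= 4), or
#'   `NULL` to simulate.
#' @param sim a [sim_config()] used when `genomes` is `NULL`.
#' @param outdir output directory.
#' @param min_ir minimum IR length for [detect_inverted_repeats()].
#' @param min_len,max_len spacer PCR-suitability window (bp).
#' @param bootstrap bootstrap replicates per marker.
#' @param seed integer seed for all stochastic stages.
#' @param reference optional reference `phylo` for the ranking; default is
#'   the pipeline's own full-scheme tree.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json` (if jsonlite is installed) or `manifest.txt`.
#' @export
run_all <- function(genomes = NULL, sim = NULL, outdir,
                    min_ir = 10000L, min_len = 400, max_len = 1600,
                    bootstrap = 100L, seed = 1L, reference = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "plastrank",
                   version = as.character(utils::packageVersion("plastrank")),
                   seed = seed,
                   config = list(min_ir = min_ir, min_len = min_len,
                                 max_len = max_len, bootstrap = bootstrap),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = attr(res, "outputs"))
    res
  }
  with_outputs <- function(x, paths) { attr(x, "outputs") <- paths; x }

  if (is.null(genomes)) {
    stopifnot(inherits(sim, "sim_config"))
    cohort <- t_stage("simulate", {
      co <- simulate_cohort(sim)
      paths <- write_cohort(co, file.path(outdir, "genomes"))
      with_outputs(co, unname(paths))
    })
    genomes <- cohort$genomes
    manifest$config$sim_seed <- sim$seed
  }
  stopifnot(length(genomes) >= 4L)
  manifest$inputs <- lapply(genomes, function(g)
    list(id = g$id, length = g$length,
         md5 = unname(tools::md5sum(textConnection_md5(g$seq)))))

  t_stage("structure", {
    co <- summarize_cohort(genomes, min_ir = min_ir)
    p_tab <- file.path(outdir, "regions.tsv")
    utils::write.table(co$table, p_tab, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_sum <- file.path(outdir, "regions_summary.tsv")
    utils::write.table(co$summary, p_sum, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jx <- do.call(rbind, lapply(genomes, function(g) {
      p <- detect_inverted_repeats(g, min_ir = min_ir)
      cbind(id = g$id, report_junctions(g, p))
    }))
    p_jx <- file.path(outdir, "junctions.tsv")
    utils::write.table(jx, p_jx, sep = "\t", quote = FALSE, row.names = FALSE)
    with_outputs(co, c(p_tab, p_sum, p_jx))
  })

  sets <- t_stage("markers", {
    s <- collate_all_markers(genomes, classes = c("intron", "spacer"),
                             min_len = min_len, max_len = max_len)
    mdir <- file.path(outdir, "markers")
    dir.create(mdir, showWarnings = FALSE)
    paths <- vapply(names(s), function(nm) {
      a <- marker_alignment(unlist(s[[nm]]), nm, attr(s[[nm]], "mclass"))
      p <- file.path(mdir, paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".fasta"))
      write_fasta_alignment(a, p)
      p
    }, character(1))
    with_outputs(s, unname(paths))
  })

  schemes <- t_stage("schemes", {
    sch <- cohort_schemes(genomes, min_len = min_len, max_len = max_len)
    sdir <- file.path(outdir, "schemes")
    dir.create(sdir, showWarnings = FALSE)
    paths <- character(0)
    for (nm in names(sch)) {
      pf <- file.path(sdir, paste0(nm, ".fasta"))
      write_fasta_alignment(sch[[nm]]$alignment, pf)
      pp <- file.path(sdir, paste0(nm, ".partitions.tsv"))
      utils::write.table(sch[[nm]]$partition, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, pf, pp)
    }
    with_outputs(sch, paths)
  })

  reference <- t_stage("reference_tree", {
    tr <- if (is.null(reference))
      nj_tree(k80_matrix(schemes$full$alignment)) else reference
    p <- file.path(outdir, "full_scheme_tree.nwk")
    write_newick(tr, p)
    with_outputs(tr, p)
  })

  report <- t_stage("ranking", {
    alignments <- lapply(names(sets), function(nm)
      marker_alignment(unlist(sets[[nm]]), nm, attr(sets[[nm]], "mclass")))
    names(alignments) <- names(sets)
    rep <- survey_alignments(alignments, reference, bootstrap = bootstrap,
                             seed = seed)
    p <- file.path(outdir, "marker_ranking.tsv")
    utils::write.table(rep, p, sep = "\t", quote = FALSE, row.names = FALSE)
    with_outputs(rep, p)
  })

  write_manifest(manifest, outdir)
  invisible(list(manifest = manifest, report = report,
                 reference = reference))
}

# md5 of an in-memory string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(s) {
  tf <- tempfile()
  writeLines(s, tf)
  tf
}

write_manifest <- function(manifest, outdir) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  } else {
    utils::capture.output(utils::str(manifest),
                          file = file.path(outdir, "manifest.txt"))
  }
  invisible(NULL)
}
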