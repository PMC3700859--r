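#' Configure a full phylogeographic pipeline run
#'
#' Validates everything up front — a missing input is a configuration error
#' raised before any stage computes.
#'
#' @param haplotype_table path to a haplotype TSV (see
#'   [read_haplotype_table()]).
#' @param motif_tree path to a motif tree file ([load_motif_tree()]).
#' @param out_dir output directory (created if needed).
#' @param mask a [hotspot_mask()] or path to a mask config file.
#' @param clades character vector of haplogroup names to reconstruct and
#'   date; defaults to none (classification only).
#' @param populations optional path to a population CSV for the frequency
#'   map ([read_population_csv()]).
#' @param target_haplogroup haplogroup mapped in the frequency stage.
#' @param clock_mode `"corrected"` or `"linear"`.
#' @param epsilon median-joining tolerance.
#' @param grid_spec kriging grid, as in [interpolate_surface()].
#' @param stages subset of `c("classify", "phylogeny", "dating", "map")`.
#' @param seed integer seed recorded for provenance (the pipeline stages
#'   are deterministic; the seed matters when simulation inputs are
#'   regenerated from it).
#' @param verbose print stage progress.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(haplotype_table, motif_tree, out_dir,
                            mask = hotspot_mask(), clades = character(),
                            populations = NULL,
                            target_haplogroup = clades[1],
                            clock_mode = "corrected", epsilon = 0L,
                            grid_spec = list(nx = 60, ny = 60),
                            stages = c("classify", "phylogeny", "dating",
                                       "map"),
                            seed = 1L, verbose = FALSE) {
  for (p in c(haplotype_table, motif_tree,
              if (is.character(mask)) mask, populations)) {
    if (!file.exists(p)) stop("configuration error: input file not found: ", p)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(mask)) mask <- read_mask_config(mask)
  stopifnot(inherits(mask, "hotspot_mask"))
  structure(list(haplotype_table = haplotype_table, motif_tree = motif_tree,
                 out_dir = out_dir, mask = mask, clades = clades,
                 populations = populations,
                 target_haplogroup = target_haplogroup,
                 clock_mode = clock_mode, epsilon = as.integer(epsilon),
                 grid_spec = grid_spec, stages = stages,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the pipeline: classify, reconstruct, date, map
#'
#' Stages run in order; each writes its outputs under `out_dir` and the run
#' closes with a manifest (`manifest.tsv`), a log (`pipeline.log`, which
#' records the per-sample masked-variant counts so hotspot exclusions are
#' auditable) and the serialized configuration. If a stage fails, the
#' partial outputs and manifest are kept and the error is re-raised.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (config$verbose) message(msg)
  }
  cat("", file = log_path)
  write_config(config)
  manifest <- data.frame(stage = character(), output = character(),
                         status = character(), stringsAsFactors = FALSE)
  add <- function(stage, output, status = "ok") {
    output <- basename(output)      # manifest is relative to out_dir
    manifest <<- rbind(manifest, data.frame(stage = stage, output = output,
                                            status = status,
                                            stringsAsFactors = FALSE))
  }
  finish <- function() {
    utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results <- list()
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    logf("[%s] starting", name)
    res <- tryCatch(fun(), error = function(e) {
      add(name, "", paste("failed:", conditionMessage(e)))
      finish()
      stop("pipeline stage ", sQuote(name), " failed: ",
           conditionMessage(e), call. = FALSE)
    })
    results[[name]] <<- res
    logf("[%s] done", name)
    res
  }

  motif <- load_motif_tree(config$motif_tree)
  haps <- read_haplotype_table(config$haplotype_table)
  masked <- lapply(haps, apply_mask, mask = config$mask)
  for (i in seq_along(masked)) {
    logf("mask: %s: %d variant(s) excluded", masked[[i]]$sample_id,
         attr(masked[[i]], "n_masked"))
  }

  cls <- run_stage("classify", function() {
    df <- classify_panel(masked, motif)
    df$population <- vapply(masked, `[[`, "", "population")
    out <- file.path(config$out_dir, "classifications.tsv")
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    add("classify", out)
    df
  })

  trees <- run_stage("phylogeny", function() {
    out <- list()
    for (hg in config$clades) {
      members <- masked[vapply(masked, function(h) {
        cls$best_node[match(h$sample_id, cls$haplotype_id)] == hg
      }, TRUE)]
      if (!length(members)) stop("no samples classified to ", hg)
      tr <- build_mp_tree(members, root_motif = full_motif(motif, hg))
      net <- build_mj_network(members, epsilon = config$epsilon)
      agree <- network_matches_tree(net, tr)
      tr <- with_stem(tr, motif$defining[[hg]],
                      parent_name = motif$nodes$parent[
                        match(hg, motif$nodes$name)],
                      clade_name = hg)
      logf("phylogeny: %s: parsimony length %d; MJ verification: %s",
           hg, parsimony_length(tr),
           if (agree) "network matches tree" else "network differs (homoplasy)")
      nwk <- file.path(config$out_dir, paste0("tree_", hg, ".nwk"))
      write_clade_tree_newick(tr, nwk); add("phylogeny", nwk)
      edg <- file.path(config$out_dir, paste0("network_", hg, ".tsv"))
      write_network_edgelist(net, edg); add("phylogeny", edg)
      out[[hg]] <- list(tree = tr, network = net, mj_agrees = agree)
    }
    out
  })

  run_stage("dating", function() {
    rows <- list()
    for (hg in names(trees)) {
      for (mode in c("coalescence", "splitting")) {
        rows[[paste(hg, mode)]] <-
          date_clade(trees[[hg]]$tree, clade_name = hg, mode = mode,
                     clock_mode = config$clock_mode)
      }
    }
    tab <- do.call(rbind, unname(rows))
    out <- file.path(config$out_dir, "dating.tsv")
    utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
    add("dating", out)
    tab
  })

  run_stage("map", function() {
    if (is.null(config$populations)) {
      stop("map stage needs a population CSV")
    }
    pops <- read_population_csv(config$populations)
    freqs <- if ("count" %in% names(pops)) {
      pops
    } else {
      tabulate_frequencies(cls, pops, config$target_haplogroup,
                           total = FALSE)
    }
    surf <- interpolate_surface(freqs, config$grid_spec)
    out <- file.path(config$out_dir, "frequency_surface.asc")
    write_ascii_grid(surf, out)
    add("map", out)
    ftab <- file.path(config$out_dir, "frequencies.tsv")
    utils::write.table(freqs, ftab, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("map", ftab)
    surf
  })

  finish()
  invisible(c(results, list(manifest = manifest)))
}

write_config <- function(config) {
  path <- file.path(config$out_dir, "pipeline_config.json")
  ser <- config
  ser$mask <- list(positions = config$mask$positions,
                   intervals = config$mask$intervals,
                   exclude_length_heteroplasmy =
                     config$mask$exclude_length_heteroplasmy)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(unclass(ser), auto_unbox = TRUE,
                                null = "null"), path)
  } else {
    dput(unclass(ser), file = path)
  }
  invisible(path)
}
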