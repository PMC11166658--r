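# End-to-end orchestration: filter -> spectrum -> sister -> enrichment ->
# coding, from a JSON config, with a manifest that records seed, versions,
# input checksums and record counts in/out of every stage.

#' Load (or pass through) a pipeline configuration
#'
#' A configuration is a plain named list, serializable as JSON; a run is
#' reproducible from config + seed alone. Recognized top-level fields:
#' `seed`, `out_dir`, `stages` (character subset of
#' `c("filter","spectrum","sister","enrichment","coding")`),
#' `filter_params` (arguments to [filter_params()]), and either
#' `simulate` (arguments: `genome_length`, `gc_fraction`,
#' `cpg_observed_expected`, `cpg_ct_fold`, `n_clones`,
#' `n_private_per_clone`, `shared`, `fail_fraction`, ...) or `inputs`
#' (paths: `genome`, `vcfs` (one per clone), `repeats`, `cgi`, `tss`,
#' `dmr`, `simple_repeats`, `cds`, optional `germline_vcf`).
#'
#' @param config Named list or path to a JSON file.
#' @return The configuration list, minimally validated.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% "cpgmutspec-out"
  config$stages <- config$stages %||%
    c("filter", "spectrum", "sister", "enrichment", "coding")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config needs either a 'simulate' or an 'inputs' section")
  }
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages run in order; each can be skipped via `config$stages`. A missing
#' annotation track disables only the statistics that depend on it (with a
#' message); a failing stage aborts with the stage name. All outputs are
#' tab-separated tables under `config$out_dir`, plus `manifest.json`.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cpgmutspec")),
    r_version = R.version.string,
    seed = config$seed,
    stages = config$stages,
    counts = list()
  )
  res <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    genome <- generate_genome(
      length = sim$genome_length %||% 1e6,
      gc_fraction = sim$gc_fraction %||% 0.41,
      cpg_observed_expected = sim$cpg_observed_expected %||% 0.2,
      n_contigs = sim$n_contigs %||% 1L,
      seed = config$seed
    )
    ann <- generate_annotations(genome, seed = config$seed + 1L)
    rates <- rate_table(cpg_ct_fold = sim$cpg_ct_fold %||% 10)
    shared <- lapply(sim$shared %||% list(), function(s) {
      list(clones = as.integer(unlist(s$clones)), n = as.integer(s$n))
    })
    fam <- simulate_clone_family(genome, rates, clone_family_config(
      n_clones = sim$n_clones %||% 3L,
      n_private_per_clone = sim$n_private_per_clone %||% 200L,
      shared = shared,
      n_preexisting = sim$n_preexisting %||% 0L,
      fail_fraction = sim$fail_fraction %||% 0.05,
      metric_noise = sim$metric_noise %||% TRUE,
      seed = config$seed + 2L
    ))
    clones <- fam$clones
    germline <- simulate_mutations(genome, rate_table(cpg_ct_fold = 1),
                                   n_total = sim$n_germline %||% 500L,
                                   seed = config$seed + 3L)
    res$truth <- fam$ledger
    write_tsv(fam$ledger, file.path(config$out_dir, "truth_ledger.tsv"))
  } else {
    paths <- config$inputs
    genome <- run_stage("load", read_genome(paths$genome))
    manifest$input_checksums <- as.list(tools::md5sum(
      unlist(paths[vapply(paths, is.character, logical(1))])))
    ann <- read_annotations(
      repeats = paths$repeats, cgi = paths$cgi, tss = paths$tss,
      dmr = paths$dmr, simple_repeats = paths$simple_repeats,
      cds = paths$cds, genome = genome)
    clones <- lapply(paths$vcfs, read_variants, genome = genome)
    germline <- if (!is.null(paths$germline_vcf)) {
      read_variants(paths$germline_vcf, genome = genome,
                    require_metrics = FALSE)
    } else NULL
  }
  manifest$counts$n_clones <- length(clones)
  manifest$counts$candidates_in <- vapply(clones, nrow, integer(1))

  # ---- filter ----
  params <- do.call(filter_params, config$filter_params %||% list())
  if ("filter" %in% config$stages) {
    filtered <- run_stage("filter", lapply(clones, function(cl) {
      apply_filters(cl, params, genome = genome)
    }))
    calls <- lapply(filtered, `[[`, "accepted")
    rep_tab <- do.call(rbind, lapply(seq_along(filtered), function(i) {
      r <- filtered[[i]]$report
      data.frame(clone = i, n_input = r$n_input, n_accepted = r$n_accepted,
                 t(r$removed))
    }))
    write_tsv(rep_tab, file.path(config$out_dir, "filter_report.tsv"))
    manifest$counts$accepted <- vapply(calls, nrow, integer(1))
  } else {
    calls <- lapply(clones, function(cl) classify_calls(genome, cl))
  }
  res$calls <- calls
  all_calls <- do.call(rbind, lapply(calls, function(d) {
    d$sister_alt <- NULL
    d
  }))

  # ---- spectrum ----
  if ("spectrum" %in% config$stages) {
    res$spectrum <- run_stage("spectrum", build_spectrum(genome, all_calls))
    spec_tab <- data.frame(
      mut_class = rep(rownames(res$spectrum$counts), 4),
      three_prime = rep(colnames(res$spectrum$counts), each = 6),
      count = as.vector(res$spectrum$counts),
      rate_per_1e9 = as.vector(res$spectrum$rate)
    )
    write_tsv(spec_tab, file.path(config$out_dir, "spectrum.tsv"))
    parts <- lapply(calls, cpg_partition)
    part_tab <- do.call(rbind, lapply(parts, as.data.frame))
    part_tab$clone <- seq_along(parts)
    write_tsv(part_tab, file.path(config$out_dir, "cpg_partition.tsv"))
    res$partitions <- parts
    if (length(parts) >= 3) {
      res$correlation <- correlate_partition(parts)
    }
    manifest$counts$spectrum_total <- sum(res$spectrum$counts)
  }

  # ---- sister ----
  if ("sister" %in% config$stages && length(calls) >= 2) {
    # shared-SNV detection needs the sister filter off
    params_shared <- params
    params_shared$exclude_sisters <- FALSE
    calls_ns <- run_stage("sister", lapply(clones, function(cl) {
      apply_filters(cl, params_shared, genome = genome)$accepted
    }))
    res$shared <- shared_snvs(calls_ns)
    write_tsv(as.data.frame(res$shared$pairwise),
              file.path(config$out_dir, "shared_matrix.tsv"))
    write_tsv(res$shared$shared_keys,
              file.path(config$out_dir, "shared_variants.tsv"))
  }

  # ---- enrichment ----
  if ("enrichment" %in% config$stages) {
    enr <- list()
    if (length(ann$repeats) > 0) {
      enr$retro <- retrotransposon_rates(all_calls, ann)
      write_tsv(enr$retro, file.path(config$out_dir, "retrotransposon.tsv"))
      if (!is.null(germline)) {
        germ_cls <- if ("mut_class" %in% names(germline)) germline else
          classify_calls(genome, germline)
        sf <- sine_subfamily_enrichment(all_calls, germ_cls, ann)
        enr$subfamily <- sf
        write_tsv(sf$groups, file.path(config$out_dir, "sine_subfamily.tsv"))
      }
    } else message("no repeat track: skipping retrotransposon statistics")
    if (length(ann$dmr) > 0) {
      enr$dmr <- dmr_ratio(all_calls, ann, genome)
      write_tsv(enr$dmr, file.path(config$out_dir, "dmr_ratio.tsv"))
    } else message("no DMR track: skipping DMR ratio")
    if (length(ann$cgi) > 0) {
      enr$cgi <- cgi_shore_counts(calls, ann, genome)
      write_tsv(enr$cgi, file.path(config$out_dir, "cgi_shore.tsv"))
    } else message("no CGI track: skipping CGI/shore counts")
    if (length(ann$tss) > 0) {
      germ_cls <- if (is.null(germline)) NULL else if
        ("mut_class" %in% names(germline)) germline else
          classify_calls(genome, germline)
      enr$tss <- tss_distance_profile(
        all_calls, ann, germline_calls = germ_cls,
        n_clones = length(calls))
      write_tsv(enr$tss, file.path(config$out_dir, "tss_distance.tsv"))
    } else message("no TSS track: skipping TSS distances")
    res$enrichment <- run_stage("enrichment", enr)
    compart <- table(assign_regions(all_calls, ann, genome)$compartment)
    manifest$counts$compartments <- as.list(compart)
  }

  # ---- coding ----
  if ("coding" %in% config$stages && length(ann$cds) > 0) {
    res$coding <- run_stage("coding",
                            annotate_coding(all_calls, ann$cds, genome))
    write_tsv(res$coding, file.path(config$out_dir, "coding_effects.tsv"))
    smry <- summarize_effects(res$coding)
    manifest$counts$coding_effects <- as.list(smry$counts)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
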