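# Cohort-level orchestration: simulate or load a cohort, build feature
# catalogs, extract signatures, call ploidy/aneuploidy, detect complex
# chromosomes and kataegis, annotate, and record provenance.

#' Run configuration for the full pipeline
#'
#' Collects every stage parameter with its default so the provenance
#' record materializes the complete configuration, not just overrides.
#'
#' @param seed master seed for all stochastic stages.
#' @param genome `"grch37"`, `"mini"` or a `GenomeBuild`.
#' @param simulation a `SimulationConfig`, or `NULL` to read an existing
#'   cohort from `input_dir`.
#' @param input_dir directory holding a cohort manifest (as written by
#'   [simulate_cohort()]); ignored when `simulation` is supplied.
#' @param cluster_distance_d,cluster_min_size breakpoint clustering
#'   parameters (see [cluster_breakpoints()]).
#' @param kataegis_gamma piecewise-constant-fit penalty (see
#'   [detect_kataegis()]).
#' @param nmf_ranks,nmf_runs,nmf_randomized_runs signature-extraction
#'   controls (see [extract_signatures()]).
#' @param exposure_threshold,min_mutations refitting controls (see
#'   [refit_exposures()]).
#' @param run_signatures whether to run de-novo extraction (the slowest
#'   stage).
#' @return a `RunConfig` list.
#' @export
run_config <- function(seed = 1, genome = "mini", simulation = NULL,
                       input_dir = NULL, cluster_distance_d = 1e6,
                       cluster_min_size = 10, kataegis_gamma = 25,
                       nmf_ranks = 2:12, nmf_runs = 100,
                       nmf_randomized_runs = 100,
                       exposure_threshold = 0.15, min_mutations = 50,
                       run_signatures = FALSE) {
  build <- if (inherits(genome, "GenomeBuild")) genome else
    load_genome_build(genome)
  structure(list(seed = seed, genome = genome, build = build,
                 simulation = simulation, input_dir = input_dir,
                 cluster_distance_d = cluster_distance_d,
                 cluster_min_size = cluster_min_size,
                 kataegis_gamma = kataegis_gamma, nmf_ranks = nmf_ranks,
                 nmf_runs = nmf_runs,
                 nmf_randomized_runs = nmf_randomized_runs,
                 exposure_threshold = exposure_threshold,
                 min_mutations = min_mutations,
                 run_signatures = run_signatures),
            class = "RunConfig")
}

#' Run the full cohort analysis
#'
#' Stages: simulate (or load), features (SBS96/SV32/CN40 matrices), ploidy
#' (WGD, arm calls, aneuploidy score, altered fraction), complexity
#' (kataegis and complex chromosomes), annotate (per-sample summaries,
#' breakpoint bins) and optionally signatures (de-novo NMF on the SV32 and
#' CN40 matrices). Each stage's outputs are written under `out_dir`; a
#' `stage_status.tsv` records success or failure per stage and a
#' `provenance.json` records the full configuration and seeds. A failed
#' stage stops the pipeline but retains the outputs of earlier stages.
#'
#' @param config a `RunConfig`.
#' @param out_dir output directory.
#' @return invisibly, a list with the per-sample objects and result tables.
#' @export
run_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- data.frame(stage = character(), status = character())
  note <- function(stage, st) {
    status <<- rbind(status, data.frame(stage = stage, status = st))
    utils::write.table(status, file.path(out_dir, "stage_status.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      note(stage, paste0("failed: ", conditionMessage(res)))
      stop("stage '", stage, "' failed: ", conditionMessage(res))
    }
    note(stage, "ok")
    res
  }
  build <- config$build

  cohort_dir <- run_stage("simulate", {
    if (!is.null(config$simulation)) {
      d <- file.path(out_dir, "cohort")
      simulate_cohort(config$simulation, d)
      d
    } else {
      if (is.null(config$input_dir) ||
          !file.exists(file.path(config$input_dir, "manifest.tsv"))) {
        stop("no simulation config and no manifest in input_dir")
      }
      config$input_dir
    }
  })
  samples <- run_stage("genome_io", {
    manifest <- utils::read.table(file.path(cohort_dir, "manifest.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    lapply(seq_len(nrow(manifest)), function(i) {
      paths <- file.path(cohort_dir,
                         c(manifest$segments[i], manifest$bedpe[i],
                           manifest$vcf[i]))
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0) stop("missing file(s): ",
                                    paste(missing, collapse = ", "))
      read_sample(paths[1], paths[2], paths[3], build = build)
    })
  })
  if (length(samples) == 0) {
    note("features", "skipped: empty cohort")
    write_provenance(config, out_dir)
    return(invisible(list(samples = samples)))
  }
  reference_path <- file.path(cohort_dir, "reference.fa")
  features <- run_stage("features", {
    profiles <- lapply(samples, `[[`, "profile")
    rsets <- lapply(samples, `[[`, "rearrangements")
    snvs <- lapply(samples, `[[`, "snvs")
    out <- list(
      sv32 = build_feature_matrix("SV32", rsets),
      cn40 = build_feature_matrix("CN40", profiles))
    if (file.exists(reference_path)) {
      out$sbs96 <- build_feature_matrix("SBS96", snvs,
                                        reference = reference_path)
    }
    for (nm in names(out)) {
      write_feature_matrix(out[[nm]],
                           file.path(out_dir, paste0("features_", nm, ".tsv")))
    }
    out
  })
  ploidy_tab <- run_stage("ploidy", {
    tab <- do.call(rbind, lapply(samples, function(s)
      ploidy_report(s$profile, build)))
    utils::write.table(tab, file.path(out_dir, "ploidy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    arm_tab <- do.call(rbind, lapply(samples, function(s) {
      calls <- suppressWarnings(call_arm_events(s$profile, build))
      cbind(sample = s$profile$sample_id, calls)
    }))
    utils::write.table(arm_tab, file.path(out_dir, "arm_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })
  complexity_tab <- run_stage("complexity", {
    kat <- do.call(rbind, lapply(samples, function(s) {
      loci <- detect_kataegis(s$snvs, gamma = config$kataegis_gamma)
      if (nrow(loci) > 0) cbind(sample = s$profile$sample_id, loci) else NULL
    }))
    if (is.null(kat)) kat <- data.frame()
    utils::write.table(kat, file.path(out_dir, "kataegis.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cx <- do.call(rbind, lapply(samples, function(s) {
      rep <- complex_chromosome_report(s$profile, s$rearrangements, build)
      cbind(sample = s$profile$sample_id, rep)
    }))
    utils::write.table(cx, file.path(out_dir, "complex_chromosomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(kataegis = kat, complex = cx)
  })
  annotate_tab <- run_stage("annotate", {
    summaries <- do.call(rbind, lapply(samples, function(s)
      sample_summary(s$profile, s$rearrangements, s$snvs, build)))
    utils::write.table(summaries, file.path(out_dir, "sample_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bins <- bin_breakpoints_1mb(lapply(samples, `[[`, "rearrangements"), build)
    utils::write.table(bins, file.path(out_dir, "breakpoint_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summaries
  })
  model <- NULL
  if (config$run_signatures) {
    model <- run_stage("signatures", {
      m <- extract_signatures(features$sv32, ranks = config$nmf_ranks,
                              n_runs = config$nmf_runs,
                              n_randomized_runs = config$nmf_randomized_runs,
                              seed = config$seed)
      utils::write.table(
        data.frame(category = rownames(m$W), m$W, check.names = FALSE),
        file.path(out_dir, "signatures_sv32.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      m
    })
  }
  write_provenance(config, out_dir)
  invisible(list(samples = samples, features = features, ploidy = ploidy_tab,
                 complexity = complexity_tab, summaries = annotate_tab,
                 signature_model = model))
}

write_provenance <- function(config, out_dir) {
  cfg <- config
  cfg$build <- NULL
  cfg$simulation <- if (!is.null(config$simulation)) {
    s <- unclass(config$simulation)
    s$build <- NULL
    s$sbs_signature_matrix <- NULL
    s$true_exposures <- NULL
    s
  } else NULL
  prov <- list(
    package = "genomplexity",
    version = as.character(utils::packageVersion("genomplexity")),
    config = cfg)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(NULL)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()] and [sim_config()]
#' (simulation keys under a `simulation:` block).
#'
#' @param path YAML file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sim <- do.call(sim_config, y$simulation)
    y$simulation <- NULL
  }
  do.call(run_config, c(y, list(simulation = sim)))
}
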