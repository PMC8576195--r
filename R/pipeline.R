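# Run configuration -----------------------------------------------------------

pipeline_stages <- function() c("describe", "popgen", "assoc", "grs", "gxe")

#' Configuration for a full pipeline run
#'
#' @param input A cohort table, a path to a cohort file, or a
#'   [generator_spec()] (in which case a cohort is simulated with `seed`).
#' @param snp_config A [snp_panel()] or path to a YAML SNP config (used
#'   when `input` is a file path).
#' @param stages Stages to run, a prefix-closed subset of
#'   `describe, popgen, assoc, grs, gxe` in pipeline order; the empty
#'   vector produces a manifest only.
#' @param alpha Base significance level for allelic comparisons.
#' @param bonferroni_m Number of tests for the Bonferroni adjustment.
#' @param low_band,high_cut Score bands for GRS-stratified association.
#' @param genetic_coding Genetic binarization for the interaction stratum
#'   odds ratios.
#' @param out_dir Output directory for reports (created if needed).
#' @param seed Integer seed controlling simulation and any resampling.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input, snp_config = default_snp_panel(),
                       stages = pipeline_stages(), alpha = 0.05,
                       bonferroni_m = 6L, low_band = c(0, 1), high_cut = 3,
                       genetic_coding = "dominant", out_dir = tempfile("run"),
                       seed = 1L) {
  stages <- as.character(stages)
  all_stages <- pipeline_stages()
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (length(stages)) {
    idx <- sort(match(stages, all_stages))
    if (!identical(all_stages[idx], all_stages[seq_len(max(idx))])) {
      stop("stages must be a prefix-closed subset of the pipeline order (",
           paste(all_stages, collapse = " -> "), ")", call. = FALSE)
    }
    stages <- all_stages[seq_len(max(idx))]
  }
  structure(list(input = input, snp_config = snp_config, stages = stages,
                 alpha = alpha, bonferroni_m = bonferroni_m,
                 low_band = low_band, high_cut = high_cut,
                 genetic_coding = genetic_coding, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

# rolling 31-bit polynomial hash over the serialized config, for the manifest
config_hash <- function(config) {
  bytes <- serialize(config[setdiff(names(config), "out_dir")],
                     connection = NULL, version = 2L)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order -- descriptive statistics,
#' allele frequencies/HWE/allelic association, genotype-level association,
#' genetic risk scores with stratified association, and the
#' gene-environment interaction scan -- writing one tab-delimited report
#' per stage plus a manifest recording the package version, seed, every
#' effective parameter and per-stage exclusion counts. Reruns with the
#' same configuration are bit-identical for deterministic stages.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths of all written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  results <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- run_stage("ingest", function() {
    inp <- config$input
    if (inherits(inp, "cohort")) inp
    else if (inherits(inp, "generator_spec")) {
      simulate_cohort(inp, seed = config$seed)
    } else if (is.character(inp)) read_cohort(inp, config$snp_config)
    else stop("unsupported input type", call. = FALSE)
  })

  if ("describe" %in% config$stages) {
    s <- run_stage("describe", function() summarize_cohort(cohort))
    results$describe <- s
    paths <- c(paths,
               write_report(s$characteristics,
                            file.path(config$out_dir, "describe.tsv")),
               write_report(s$vte,
                            file.path(config$out_dir, "describe_vte.tsv")))
  }
  if ("popgen" %in% config$stages) {
    r <- run_stage("popgen", function() {
      popgen_report(cohort, alpha = config$alpha)
    })
    results$popgen <- r
    paths <- c(paths, write_report(r, file.path(config$out_dir,
                                                "popgen.tsv")))
  }
  if ("assoc" %in% config$stages) {
    r <- run_stage("assoc", function() {
      association_report(cohort, adjust_age = TRUE)
    })
    results$assoc <- r
    paths <- c(paths, write_report(r, file.path(config$out_dir,
                                                "assoc.tsv")))
  }
  if ("grs" %in% config$stages) {
    r <- run_stage("grs", function() {
      u <- compute_grs(cohort, mode = "unweighted")
      w <- compute_grs(cohort, mode = "weighted")
      scores <- data.frame(subject_id = cohort$subject_id,
                           population = cohort$population,
                           ugrs = u$score, wgrs = w$score,
                           band = as.character(grs_band(
                             u$score, "explicit",
                             low_band = config$low_band,
                             high_cut = config$high_cut)),
                           stringsAsFactors = FALSE)
      list(unweighted = u, weighted = w, scores = scores)
    })
    results$grs <- r
    summ <- rbind(cbind(mode = "unweighted", r$unweighted$summary),
                  cbind(mode = "weighted", r$weighted$summary))
    paths <- c(paths,
               write_report(summ, file.path(config$out_dir, "grs.tsv")),
               write_report(r$scores,
                            file.path(config$out_dir, "grs_scores.tsv")))
  }
  if ("gxe" %in% config$stages) {
    r <- run_stage("gxe", function() {
      gxe_report(cohort, genetic_coding = config$genetic_coding)
    })
    results$gxe <- r
    paths <- c(paths, write_report(r, file.path(config$out_dir, "gxe.tsv")))
  }

  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("vtegxe"))),
    sprintf("seed: %d", config$seed),
    sprintf("stages: %s", paste(config$stages, collapse = ",")),
    sprintf("alpha: %g", config$alpha),
    sprintf("bonferroni_m: %d", config$bonferroni_m),
    sprintf("alpha_adjusted: %g", bonferroni(config$alpha,
                                             config$bonferroni_m)),
    sprintf("grs_low_band: [%g, %g]", config$low_band[1],
            config$low_band[2]),
    sprintf("grs_high_cut: %g", config$high_cut),
    sprintf("gxe_genetic_coding: %s", config$genetic_coding),
    sprintf("n_subjects: %d", nrow(cohort)),
    sprintf("grs_excluded_missing: %s",
            if (!is.null(results$grs)) {
              results$grs$unweighted$n_excluded
            } else "NA"),
    sprintf("config_hash: %s", config_hash(config))
  )
  manifest_path <- file.path(config$out_dir, "manifest.txt")
  writeLines(manifest, manifest_path)
  paths <- c(paths, manifest_path)

  invisible(list(cohort = cohort, results = results, paths = paths,
                 manifest = manifest))
}
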