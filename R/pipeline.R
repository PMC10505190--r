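# End-to-end pipeline wiring and the subcommand CLI. A single JSON config
# drives simulate -> normalize -> call -> order -> fit -> score -> screen
# with every random draw flowing from the config seed, so identical
# configs yield byte-identical text outputs.

#' Default pipeline configuration
#'
#' @param seed global seed.
#' @param ... overrides for any default field.
#' @return a named list (validated by [validate_config()]).
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_targets = 50,
    n_variants = 20,
    c_dist = c(0, 10),
    f_span = c(0, 10),
    cleaved_band = c(0.70, 1.20),
    residual_scale = 0.03,
    softness = 0,
    replicates = 3,
    background_pct = 2,
    wt_raw_pct = 50,
    replicate_sd = 1,
    theta = 0.20,
    boundary_mode = "min_misclass",
    rough_min = 0.20,
    fine_min = 0.50,
    max_block_exhaustive = 8,
    screen_targets = 5
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks presence, types and ranges of every field before any stage runs.
#'
#' @param cfg configuration list (e.g. parsed from JSON).
#' @return the validated config (numeric fields coerced).
#' @export
validate_config <- function(cfg) {
  need <- c("seed", "n_targets", "n_variants", "c_dist", "f_span",
            "cleaved_band", "residual_scale", "softness", "replicates",
            "background_pct", "wt_raw_pct", "replicate_sd", "theta",
            "boundary_mode", "rough_min", "fine_min",
            "max_block_exhaustive", "screen_targets")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("config is missing field(s): %s",
                          paste(miss, collapse = ", "))
  num2 <- function(x, nm) {
    x <- as.numeric(x)
    if (length(x) != 2) stopf("config field '%s' must have length 2", nm)
    x
  }
  cfg$c_dist <- num2(cfg$c_dist, "c_dist")
  cfg$f_span <- num2(cfg$f_span, "f_span")
  cfg$cleaved_band <- num2(cfg$cleaved_band, "cleaved_band")
  if (cfg$theta <= 0 || cfg$theta > 2) stopf("config theta must be in (0, 2]")
  if (!cfg$boundary_mode %in% c("min_misclass", "count_matched")) {
    stopf("config boundary_mode must be 'min_misclass' or 'count_matched'")
  }
  if (cfg$wt_raw_pct <= cfg$background_pct) {
    stopf("config wt_raw_pct must exceed background_pct")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full synthetic pipeline
#'
#' Stages, in order: sample latent parameters; simulate a raw disruption
#' table; normalize to wild type; call cleavage; order variants and
#' targets and fit the staircase boundary; score the fit; per-variant
#' ROC; two-step screens on a subset of targets; parameter-recovery
#' report. Each stage failure aborts with the stage named. When `out_dir`
#' is given, deterministic text artifacts (TSV/JSON, no timestamps) are
#' written, with the config and its MD5 hash as provenance.
#'
#' @param config a validated config (see [pipeline_config()]).
#' @param out_dir optional output directory.
#' @return (invisibly) list with `params`, `raw`, `matrix`, `calls`,
#'   `map`, `fit`, `roc`, `screens`, `recovery`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  params <- stage("sample_model", sample_model(
    n_targets = config$n_targets, n_variants = config$n_variants,
    c_dist = config$c_dist, f_span = config$f_span,
    cleaved_band = config$cleaved_band,
    residual_scale = config$residual_scale,
    softness = config$softness, seed = config$seed))
  raw <- stage("simulate", simulate_disruption_matrix(
    params, replicates = config$replicates,
    background_pct = config$background_pct,
    wt_raw_pct = config$wt_raw_pct,
    replicate_sd = config$replicate_sd))
  mat <- stage("normalize", normalize_to_wt(raw))
  calls <- stage("call", call_cleavage(mat, theta = config$theta))
  map <- stage("fit_rule", suppressWarnings(rank_cleavage_map(
    calls, activities = mat, mode = config$boundary_mode)))
  fit <- stage("score", score_rule_fit(map))
  roc <- stage("roc", variant_roc_all(map))
  panel <- stage("panel", panel_from_params(params))
  screen_tg <- utils::head(names(params$c), config$screen_targets)
  screens <- stage("screen", lapply(stats::setNames(screen_tg, screen_tg),
    function(tg) {
      oracle <- function(v) {
        if (v == "WT") 1 else {
          clv <- params$c[tg] > params$f[v]
          if (clv) mean(params$cleaved_band) else 0
        }
      }
      two_step_screen(panel, oracle, rough_min = config$rough_min,
                      fine_min = config$fine_min)
    }))
  recovery <- stage("recovery", recover_and_compare(params, map))

  bundle <- list(params = params, raw = raw, matrix = mat, calls = calls,
                 map = map, fit = fit, roc = roc, screens = screens,
                 recovery = recovery)
  if (!is.null(out_dir)) write_bundle(bundle, config, out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = config$seed)

  write_activity_matrix(bundle$matrix, file.path(out_dir, "matrix.tsv"))

  map <- bundle$map
  map_df <- data.frame(variant_id = map$variant_order,
                       boundary = unname(map$boundary[map$variant_order]))
  utils::write.table(map_df, file.path(out_dir, "map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(map$target_order, file.path(out_dir, "target_order.txt"))
  utils::write.table(map$outliers, file.path(out_dir, "outliers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fit <- bundle$fit
  jsonlite::write_json(
    c(provenance,
      list(TP = fit$TP, FP = fit$FP, TN = fit$TN, FN = fit$FN,
           sensitivity = fit$sensitivity, specificity = fit$specificity,
           gmean = fit$gmean, n_outliers = fit$n_outliers)),
    file.path(out_dir, "rule_fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  roc_df <- do.call(rbind, lapply(bundle$roc, function(r) {
    cbind(data.frame(variant_id = r$variant_id), r$points,
          data.frame(auc = r$auc))
  }))
  utils::write.table(roc_df, file.path(out_dir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  screens <- lapply(bundle$screens, function(s) {
    list(target_matched = s$target_matched,
         candidates = s$candidates_for_offtarget_confirmation,
         assays_used = s$assays_used,
         flag = s$flag)
  })
  jsonlite::write_json(c(provenance, list(screens = screens)),
                       file.path(out_dir, "screens.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Subcommand command-line interface
#'
#' Subcommands: `simulate`, `normalize`, `call`, `fit-rule`, `roc`,
#' `screen`, `kinetics`, `tally`, `run-all`. Run without arguments for
#' usage. Intended entry point:
#' `Rscript -e 'cleavr::cleavr_cli()' <subcommand> [options]`.
#'
#' @param args command-line arguments (defaults to the process arguments).
#' @return exit status, invisibly.
#' @export
cleavr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cleavr <subcommand> [options]",
    "subcommands:",
    "  simulate   --config cfg.json --out raw.tsv",
    "  normalize  --in raw.tsv --out matrix.tsv",
    "  call       --in matrix.tsv --theta 0.20 --out calls.tsv",
    "  fit-rule   --in matrix.tsv --theta 0.20 --out-dir DIR",
    "  roc        --in matrix.tsv --theta 0.20 --out roc.tsv",
    "  kinetics   --in curves.tsv --plateau fixed0 --out fits.tsv",
    "  tally      --sam reads.sam --ref ref.fa --protospacer SEQ",
    "             [--window 2 --min-match 0.75] --out summary.json",
    "  run-all    --config cfg.json --out-dir DIR",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  opt <- function(spec) optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = rest)
  o <- optparse::make_option

  switch(sub,
    "simulate" = {
      op <- opt(list(o("--config", type = "character"),
                     o("--out", type = "character")))
      cfg <- validate_config(jsonlite::read_json(op$config, simplifyVector = TRUE))
      params <- sample_model(n_targets = cfg$n_targets,
                             n_variants = cfg$n_variants,
                             c_dist = cfg$c_dist, f_span = cfg$f_span,
                             cleaved_band = cfg$cleaved_band,
                             residual_scale = cfg$residual_scale,
                             softness = cfg$softness, seed = cfg$seed)
      raw <- simulate_disruption_matrix(params, replicates = cfg$replicates,
                                        background_pct = cfg$background_pct,
                                        wt_raw_pct = cfg$wt_raw_pct,
                                        replicate_sd = cfg$replicate_sd)
      utils::write.table(raw, op$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    "normalize" = {
      op <- opt(list(o("--in", type = "character", dest = "input"),
                     o("--out", type = "character")))
      write_activity_matrix(normalize_to_wt(read_activity_table(op$input)),
                            op$out)
    },
    "call" = {
      op <- opt(list(o("--in", type = "character", dest = "input"),
                     o("--theta", type = "double", default = 0.20),
                     o("--out", type = "character")))
      calls <- call_cleavage(read_activity_matrix(op$input), theta = op$theta)
      m <- ifelse(calls$calls, "cleaved", "not_cleaved")
      utils::write.table(cbind(variant_id = rownames(m), as.data.frame(m)),
                         op$out, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "fit-rule" = {
      op <- opt(list(o("--in", type = "character", dest = "input"),
                     o("--theta", type = "double", default = 0.20),
                     o("--out-dir", type = "character", dest = "out_dir")))
      mat <- read_activity_matrix(op$input, theta = op$theta)
      calls <- call_cleavage(mat, theta = op$theta)
      map <- suppressWarnings(rank_cleavage_map(calls, activities = mat))
      fit <- score_rule_fit(map)
      dir.create(op$out_dir, recursive = TRUE, showWarnings = FALSE)
      map_df <- data.frame(variant_id = map$variant_order,
                           boundary = unname(map$boundary[map$variant_order]))
      utils::write.table(map_df, file.path(op$out_dir, "map.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(map$target_order, file.path(op$out_dir, "target_order.txt"))
      utils::write.table(map$outliers, file.path(op$out_dir, "outliers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(gmean = fit$gmean,
                                n_outliers = fit$n_outliers),
                           file.path(op$out_dir, "rule_fit.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    "roc" = {
      op <- opt(list(o("--in", type = "character", dest = "input"),
                     o("--theta", type = "double", default = 0.20),
                     o("--out", type = "character")))
      mat <- read_activity_matrix(op$input, theta = op$theta)
      map <- suppressWarnings(rank_cleavage_map(call_cleavage(mat, op$theta),
                                                activities = mat))
      roc_df <- do.call(rbind, lapply(variant_roc_all(map), function(r) {
        cbind(data.frame(variant_id = r$variant_id), r$points,
              data.frame(auc = r$auc))
      }))
      utils::write.table(roc_df, op$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    "kinetics" = {
      op <- opt(list(o("--in", type = "character", dest = "input"),
                     o("--plateau", type = "character", default = "fixed0"),
                     o("--out", type = "character")))
      curves <- utils::read.table(op$input, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      fits <- fit_decay_table(curves, plateau = op$plateau)
      utils::write.table(fits, op$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    "tally" = {
      op <- opt(list(o("--sam", type = "character"),
                     o("--ref", type = "character"),
                     o("--protospacer", type = "character"),
                     o("--window", type = "integer", default = 2L),
                     o("--min-match", type = "double", default = 0.75,
                       dest = "min_match"),
                     o("--out", type = "character")))
      fa <- Biostrings::readDNAStringSet(op$ref)
      spec <- amplicon_spec(as.character(fa[[1]]), op$protospacer,
                            reference_name = names(fa)[1])
      reads <- read_amplicon_sam(op$sam, spec)
      s <- tally_amplicon(reads, spec, window = op$window,
                          min_match = op$min_match)
      jsonlite::write_json(unclass(s), op$out, auto_unbox = TRUE, digits = NA)
    },
    "run-all" = {
      op <- opt(list(o("--config", type = "character"),
                     o("--out-dir", type = "character", dest = "out_dir")))
      cfg <- validate_config(jsonlite::read_json(op$config,
                                                 simplifyVector = TRUE))
      run_pipeline(cfg, out_dir = op$out_dir)
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
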