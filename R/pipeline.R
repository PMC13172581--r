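#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an R list. Unknown keys and
#' constraint violations are collected and reported together. Defaults
#' describe a self-contained synthetic run; supplying real input paths
#' (`inputs:`) and a `scenario:` block at the same time is ambiguous and
#' rejected.
#'
#' @param config path to a YAML or JSON document, or a list. An empty
#'   document yields the all-defaults configuration.
#' @param strict reject unknown keys (default `TRUE`).
#' @return A normalized `PipelineConfig` list.
#' @export
validate_config <- function(config = list(), strict = TRUE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    seed = 1,
    scenario = list(),              # scenario_params() overrides
    noise = list(),                 # noise_params() overrides
    genes = list(n_genes = 200, frac_gained = 0.15, min_gain_distance = 0),
    effect = list(),                # effect_params() overrides
    inputs = NULL,                  # real-data paths (chrom_sizes, beds...)
    caller = list(method = "hmm", self_transition = 0.98,
                  quantile = 0.75, gap_bins = 1, min_bins = 3),
    merge_mode = "union",
    flank_bp = 3000, flank_bins = 60, body_bins = 100,
    promoter_window = c(3000, 3000),
    tile_width = 10000,
    fdr_cut = 0.05, fc_cut = 1.2,
    pca_bin_size = 1e5,
    outdir = NULL)
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) && strict) {
    errors <- c(errors, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  if (!is.null(cfg$inputs) && length(cfg$scenario)) {
    errors <- c(errors, "both real 'inputs' and a 'scenario' block given: ambiguous")
  }
  num_checks <- list(
    c("caller.gap_bins", cfg$caller$gap_bins, 0, Inf),
    c("caller.min_bins", cfg$caller$min_bins, 1, Inf),
    c("flank_bp", cfg$flank_bp, 0, Inf),
    c("flank_bins", cfg$flank_bins, 1, Inf),
    c("body_bins", cfg$body_bins, 1, Inf),
    c("tile_width", cfg$tile_width, 1, Inf),
    c("fdr_cut", cfg$fdr_cut, 1e-12, 1),
    c("fc_cut", cfg$fc_cut, 1, Inf),
    c("pca_bin_size", cfg$pca_bin_size, 1, Inf),
    c("genes.n_genes", cfg$genes$n_genes, 0, Inf))
  for (chk in num_checks) {
    v <- suppressWarnings(as.numeric(chk[2]))
    if (is.na(v) || v < as.numeric(chk[3]) || v > as.numeric(chk[4])) {
      errors <- c(errors, sprintf("key '%s' out of range [%s, %s]: %s",
                                  chk[1], chk[3], chk[4], chk[2]))
    }
  }
  if (!is.null(cfg$caller$quantile) &&
      (cfg$caller$quantile <= 0 || cfg$caller$quantile >= 1)) {
    errors <- c(errors, "key 'caller.quantile' must lie in (0, 1)")
  }
  if (!cfg$merge_mode %in% c("union", "intersection")) {
    errors <- c(errors, "merge_mode must be 'union' or 'intersection'")
  }
  if (!identical(cfg$caller$method, "hmm") &&
      !identical(cfg$caller$method, "quantile")) {
    errors <- c(errors, "caller.method must be 'hmm' or 'quantile'")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full remodeling pipeline on a synthetic scenario
#'
#' Executes simulate -> segmentation -> classification -> metaprofiles ->
#' annotation -> enrichment from one configuration, deterministically
#' given the seed. Intermediates are persisted to `config$outdir` when
#' set. Any stage error aborts with the stage name.
#'
#' @param config a [validate_config()] result, list, or config file path.
#' @return A `PipelineReport`: nested list with per-stage results
#'   (`scenario`, `domains`, `venn`, `changes`, `totals`, `sizes`,
#'   `profiles`, `annotation`, `enrichment`, `expression_by_lad`,
#'   `ordination`), the normalized config and the package version.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "PipelineConfig")) config else validate_config(config)
  if (!is.null(cfg$inputs)) {
    stop("stage 'io': real-data inputs are loaded with the genomic_io ",
         "functions and analysed stage by stage; run_pipeline() drives ",
         "the synthetic end-to-end demonstration")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  report <- list(version = as.character(utils::packageVersion("ladscape")),
                 seed = cfg$seed, config = cfg)

  scenario <- stage("simulate", {
    sp <- do.call(scenario_params, c(cfg$scenario, list(seed = cfg$seed)))
    simulate_scenario(sp)
  })
  noise <- stage("simulate", do.call(noise_params,
                                     c(cfg$noise, list(seed = cfg$seed + 1))))
  tracks <- stage("simulate", simulate_signal_tracks(scenario, noise))
  genes <- stage("simulate", do.call(simulate_genes, c(
    list(scenario = scenario, seed = cfg$seed + 2), cfg$genes)))
  effect <- stage("simulate", do.call(effect_params,
                                      c(cfg$effect, list(seed = cfg$seed + 3))))
  expr_tab <- stage("simulate", simulate_expression(genes, scenario, effect))
  report$scenario <- list(
    wt_mb = coverage_bp(scenario$wt) / 1e6,
    ko_mb = coverage_bp(scenario$ko) / 1e6,
    n_wt_domains = length(scenario$wt),
    n_ko_domains = length(scenario$ko),
    n_genes = length(genes))

  called <- stage("segmentation", {
    if (cfg$caller$method == "hmm") {
      # replicate tracks are averaged (the signal-level analogue of
      # merging replicate alignments), then segmented once
      lapply(tracks, function(reps) {
        call_domains_hmm(average_tracks(reps),
                         self_transition = cfg$caller$self_transition,
                         min_bins = cfg$caller$min_bins)
      })
    } else {
      params <- caller_params(quantile = cfg$caller$quantile,
                              gap_bins = cfg$caller$gap_bins,
                              min_bins = cfg$caller$min_bins)
      lapply(tracks, function(reps) {
        calls <- lapply(reps, call_domains, params = params)
        Reduce(function(a, b) merge_replicates(a, b, mode = cfg$merge_mode),
               calls)
      })
    }
  })
  called$WT$label <- "WT.called"; called$KO$label <- "KO.called"
  constitutive <- stage("segmentation",
                        consensus_intersection(list(called$WT, called$KO)))
  venn <- stage("segmentation",
                venn_coverage(called$WT, called$KO, constitutive))
  report$domains <- list(
    wt_called_mb = coverage_bp(called$WT) / 1e6,
    ko_called_mb = coverage_bp(called$KO) / 1e6,
    constitutive_mb = coverage_bp(constitutive) / 1e6)
  report$venn <- venn

  changes <- stage("classification", classify_changes(called$WT, called$KO))
  totals <- stage("classification", category_totals(changes, mb_digits = 3))
  report$changes <- changes
  report$totals <- totals
  report$truth_accuracy <- stage("classification",
                                 change_map_accuracy(changes, scenario$truth))
  report$sizes <- stage("classification", {
    out <- lapply(change_categories(), function(cat_) {
      suppressWarnings(domain_size_distribution(changes, cat_))
    })
    names(out) <- change_categories()
    out
  })

  report$profiles <- stage("profiles", {
    prof_sets <- list(LAD = called$KO, cLAD = changes$cLAD)
    if (length(changes$GainedLAD$gr) > 0) prof_sets$GainedLAD <- changes$GainedLAD
    out <- lapply(prof_sets, function(set) {
      p <- build_metaprofile(tracks$KO$rep1, set, flank_bp = cfg$flank_bp,
                             flank_bins = cfg$flank_bins,
                             body_bins = cfg$body_bins)
      list(profile = p, summary = summarize_profile(p))
    })
    out
  })

  report$annotation <- stage("annotation", {
    wt_tiles <- tile_domains(called$WT, cfg$tile_width)
    ko_tiles <- tile_domains(called$KO, cfg$tile_width)
    wt_ann <- annotate_intervals(wt_tiles, genes,
                                 promoter_window = cfg$promoter_window)
    ko_ann <- annotate_intervals(ko_tiles, genes,
                                 promoter_window = cfg$promoter_window)
    wt_dist <- feature_distribution(wt_ann)
    ko_dist <- feature_distribution(ko_ann)
    list(wt = wt_dist, ko = ko_dist,
         delta = compare_feature_distributions(wt_dist, ko_dist),
         tss_wt = tss_distance_distribution(wt_tiles, genes),
         tss_ko = tss_distance_distribution(ko_tiles, genes))
  })

  report$enrichment <- stage("enrichment", {
    de <- classify_de(expr_tab, fdr_cut = cfg$fdr_cut, fc_cut = cfg$fc_cut)
    st <- assign_gene_domain_status(genes, changes)
    gain_enrichment_test(de, st)
  })
  report$expression_by_lad <- stage("enrichment",
                                    expression_by_lad(genes, called$WT, expr_tab))
  report$ordination <- stage("enrichment", domain_overlap_pca(
    list(called$WT, called$KO, constitutive), bin_size = cfg$pca_bin_size))

  class(report) <- "PipelineReport"
  if (!is.null(cfg$outdir)) persist_report(report, scenario, tracks, genes,
                                           expr_tab, called, changes)
  report
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat(sprintf("ladscape pipeline report (v%s, seed %s)\n", x$version, x$seed))
  cat(sprintf("  WT %.2f Mb planted / %.2f Mb called; KO %.2f / %.2f Mb\n",
              x$scenario$wt_mb, x$domains$wt_called_mb,
              x$scenario$ko_mb, x$domains$ko_called_mb))
  cat(sprintf("  truth-recovery accuracy %.4f\n", x$truth_accuracy))
  print(x$totals)
  cat(sprintf("  enrichment: OR %s, p = %.4g\n",
              format(round(x$enrichment$odds_ratio_corrected, 2)),
              x$enrichment$p_value))
  invisible(x)
}

# Persist stage outputs as text files under cfg$outdir.
persist_report <- function(report, scenario, tracks, genes, expr_tab,
                           called, changes) {
  dir <- report$config$outdir
  write_scenario(scenario, dir, tracks = tracks, genes = genes,
                 expression = expr_tab)
  save_domains(called$WT, file.path(dir, "WT.called.bed"))
  save_domains(called$KO, file.path(dir, "KO.called.bed"))
  for (cat_ in change_categories()) {
    save_domains(changes[[cat_]], file.path(dir, paste0(cat_, ".bed")))
  }
  utils::write.table(report$totals, file.path(dir, "category_totals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$venn, file.path(dir, "venn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_to_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Flatten the report into JSON-friendly structures.
report_to_json <- function(report) {
  list(
    version = report$version,
    seed = report$seed,
    scenario = report$scenario,
    domains = report$domains,
    truth_accuracy = report$truth_accuracy,
    totals = as.data.frame(report$totals),
    venn = as.data.frame(report$venn),
    profiles = lapply(report$profiles, function(p) p$summary),
    annotation_delta = report$annotation$delta,
    enrichment = list(
      table = as.vector(report$enrichment$table),
      odds_ratio = report$enrichment$odds_ratio,
      odds_ratio_corrected = report$enrichment$odds_ratio_corrected,
      p_value = report$enrichment$p_value,
      corrected = report$enrichment$corrected),
    expression_by_lad = report$expression_by_lad,
    ordination = list(explained = report$ordination$explained,
                      distances = report$ordination$distances))
}
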