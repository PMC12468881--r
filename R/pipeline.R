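#' Pipeline configuration
#'
#' Collects every tunable of a full atlas run: the decision thresholds
#' ([atlas_thresholds()]), the expression filter, the normalization unit,
#' window sizes, the seed, and the synthetic-data generator parameters.
#' Unknown keys are rejected so configuration drift fails loudly.
#'
#' @param ... named overrides of the defaults listed below. `thresholds`
#'   takes a list of [atlas_thresholds()] overrides; `sim` a list of
#'   [simulate_atlas()] arguments.
#' @return a named list of class `atlas_config`.
#' @export
atlas_config <- function(...) {
  cfg <- list(
    seed = 42,
    unit = "cpm",
    min_reads = 10, min_samples = 3,
    context_window = 10000,
    conservation_min_overlap = 1,
    thresholds = list(),
    sim = list()
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  if (!cfg$unit %in% c("cpm", "mor")) {
    stop('`unit` must be "cpm" or "mor"', call. = FALSE)
  }
  sim_known <- names(formals(simulate_atlas))
  unknown <- setdiff(names(cfg$sim), setdiff(sim_known, "..."))
  if (length(unknown)) {
    stop("unknown sim key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg$thresholds <- do.call(atlas_thresholds, as.list(cfg$thresholds))
  structure(cfg, class = "atlas_config")
}

#' Read a pipeline configuration from YAML
#' @param file path to a YAML file whose keys match [atlas_config()].
#' @return an `atlas_config`.
#' @export
read_config <- function(file) {
  do.call(atlas_config, yaml::read_yaml(file))
}

#' Run the full atlas pipeline on synthetic or supplied data
#'
#' Executes, in dependency order: data generation (or intake), the
#' expression filter, normalization, genomic-context description,
#' housekeeping/tissue-specific classification, conservation calling,
#' differential-expression thresholding, and ceRNA assembly. The returned
#' report records per-stage input/output counts and every threshold used,
#' and is JSON-serializable; a rerun with the same config is identical.
#'
#' @param config an [atlas_config()].
#' @param data optional input bundle shaped like [simulate_atlas()]'s
#'   return value; when NULL the bundle is simulated from `config$sim` and
#'   `config$seed`.
#' @return a list of class `atlas_report` with elements `config`, `stages`
#'   (per-stage summaries) and `results` (the stage output tables).
#' @export
run_pipeline <- function(config = atlas_config(), data = NULL) {
  stopifnot(inherits(config, "atlas_config"))
  thr <- config$thresholds
  if (is.null(data)) {
    data <- do.call(simulate_atlas, c(list(seed = config$seed), config$sim))
  }
  stages <- list()

  kept <- filter_expression(data$counts, data$groups,
                            min_reads = config$min_reads,
                            min_samples = config$min_samples)
  stages$filter <- list(n_in = nrow(data$counts), n_kept = nrow(kept),
                        min_reads = config$min_reads,
                        min_samples = config$min_samples)

  expr <- if (config$unit == "cpm") cpm_normalize(kept) else mor_normalize(kept)
  stages$normalize <- list(unit = config$unit, n_samples = ncol(expr) - 1)

  contexts <- classify_context(data$annotation, window_bp = config$context_window)
  split <- strand_split(contexts)
  stages$context <- list(
    n_lncs = nrow(contexts),
    by_category = as.list(table(contexts$category)),
    sense_fraction = split$fraction[split$orientation == "sense"]
  )

  classes <- classify_features(expr, data$groups, thr)
  stages$classify <- c(as.list(glance(classes)),
                       list(cv_max = thr$cv_max, rank_top = thr$rank_top,
                            share_min = thr$share_min, ratio_min = thr$ratio_min))

  calls <- call_conserved(data$lifted, data$annotation,
                          min_overlap_bp = config$conservation_min_overlap,
                          unmapped = data$unmapped)
  report <- conservation_report(calls, n_source = nrow(data$conserved_truth))
  stages$conservation <- as.list(report)

  de <- select_de(data$de, fdr = thr$de_fdr, lfc = thr$de_lfc)
  stages$de <- list(n_records = nrow(de), n_de = sum(de$is_de),
                    fdr = thr$de_fdr, lfc = thr$de_lfc)

  sp <- filter_interactions(data$edges$sponge_mirna,
                            score_min = thr$mirna_score,
                            energy_max = thr$mirna_energy)
  mg <- filter_interactions(data$edges$mirna_mrna,
                            score_min = thr$mirna_score,
                            energy_max = thr$mirna_energy)
  triples <- assemble_cerna(sp, mg)
  stages$cerna <- list(
    n_sponge_mirna = nrow(sp), n_mirna_mrna = nrow(mg),
    n_triples = nrow(triples),
    score_min = thr$mirna_score, energy_max = thr$mirna_energy
  )

  structure(
    list(config = config, stages = stages,
         results = list(classes = classes, contexts = contexts,
                        conservation = calls, de = de, cerna = triples)),
    class = "atlas_report"
  )
}

#' @export
print.atlas_report <- function(x, ...) {
  cat("<atlas_report>\n")
  for (s in names(x$stages)) {
    vals <- x$stages[[s]]
    cat("  ", s, ": ",
        paste(names(vals), vapply(vals, function(v) paste(format(v), collapse = "/"),
                                  character(1)),
              sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
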