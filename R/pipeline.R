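#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()], starting from
#' package defaults (which equal the documented defaults of every stage),
#' optionally overlaid with a YAML file and/or a list of overrides. The
#' configuration round-trips losslessly through
#' [write_run_config()]/[run_config()].
#'
#' @param path Optional YAML file of settings.
#' @param overrides Optional named list merged last (deep merge).
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  ## canonicalize: YAML cannot represent NULL path slots, so restore them
  for (k in names(default_run_config()$inputs))
    if (!k %in% names(cfg$inputs)) cfg$inputs[k] <- list(NULL)
  cfg$inputs <- cfg$inputs[names(default_run_config()$inputs)]
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

default_run_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "screen", "de", "integrate", "enrich"),
    simulate = list(
      n_genes = 100L, shrnas_per_gene = 8L, barcode_length = 18L,
      n_drivers = 10L, n_acute = 5L,
      driver_s = -0.75, acute_s = -0.75, active_fraction = 0.8,
      weeks_selected = 4, depth = 2e6, screen_dispersion = 0.05,
      replicates = 3L,
      rnaseq_replicates = 4L, rnaseq_dispersion = 0.1,
      rnaseq_baseline_meanlog = 5.7, rnaseq_baseline_sdlog = 1,
      driver_de_effect = 2, n_extra_de = 20L, extra_de_effect = 1.5),
    thresholds = list(
      pseudocount = 0.5, lfc_threshold = -1, abundance_floor = 5,
      min_candidate = 2L, min_stringent = 4L,
      p_max = 0.05, min_abs_lfc = 0.58, use_fdr = FALSE,
      enrich_p = 0.05),
    enrich = list(n_random_sets = 10L, set_size = 15L, n_perm = 200L),
    inputs = list(library = NULL, screen_counts = NULL,
                  screen_samples = NULL, rnaseq_counts = NULL,
                  rnaseq_samples = NULL, fastq_dir = NULL, gmt = NULL)
  )
}

merge_config <- function(base, new) {
  for (k in names(new)) {
    if (is.null(new[[k]])) next
    if (is.list(base[[k]]) && is.list(new[[k]]))
      base[[k]] <- merge_config(base[[k]], new[[k]])
    else base[[k]] <- new[[k]]
  }
  base
}

validate_config <- function(cfg) {
  known <- c("simulate", "count", "screen", "de", "integrate", "enrich")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    abort_validation(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (!is_count(cfg$seed)) abort_validation("seed must be a single integer")
  if (!"simulate" %in% cfg$stages) {
    need <- c("library", "screen_counts", "screen_samples")
    if ("de" %in% cfg$stages) need <- c(need, "rnaseq_counts", "rnaseq_samples")
    missing <- need[vapply(cfg$inputs[need], is.null, logical(1))]
    if (length(missing))
      abort_validation(sprintf(
        "without the simulate stage the config must provide input path(s): %s",
        paste(missing, collapse = ", ")))
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the candidate-discovery pipeline
#'
#' Executes the configured stages in order: `simulate` (library, planted
#' screen and RNA-seq), `count` (FASTQ to counts, when FASTQ inputs are
#' configured), `screen` (CPM, depletion, acute subtraction, gene tiers),
#' `de` (NB likelihood-ratio test and significance filter), `integrate`
#' (screen x DE overlay and Venn summary), `enrich` (ORA and GSEA against a
#' gene-set collection). All artifacts are written under `out_dir`, every
#' source of randomness derives from the configured seed, and the run is
#' summarized in a machine-readable `report.json` that regenerates
#' byte-identically from the same config.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(overrides = cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  th <- cfg$thresholds
  report <- list(config = unclass(cfg), stages = list(),
                 outputs = character(0),
                 versions = list(dropscreen =
                   as.character(utils::packageVersion("dropscreen"))))
  emit <- function(path) report$outputs <<- c(report$outputs, basename(path))

  lib <- NULL; screen_cm <- NULL; rnaseq_cm <- NULL
  truth <- NULL; expr_truth <- NULL

  if ("simulate" %in% cfg$stages) {
    say("stage simulate")
    sm <- cfg$simulate
    lib <- generate_library(sm$n_genes, sm$shrnas_per_gene,
                            sm$barcode_length, seed = cfg$seed)
    truth <- random_screen_truth(lib, sm$n_drivers, sm$n_acute,
                                 driver_s = sm$driver_s, acute_s = sm$acute_s,
                                 active_fraction = sm$active_fraction,
                                 seed = cfg$seed + 1L)
    design <- screen_design(weeks = c(reference = 0,
                                      resistant_selected = sm$weeks_selected,
                                      parental_acute = sm$weeks_selected),
                            depth = sm$depth,
                            dispersion = sm$screen_dispersion,
                            replicates = sm$replicates)
    screen_cm <- simulate_screen(lib, truth, design, seed = cfg$seed + 2L)
    expr_truth <- simulate_expression_truth(lib, truth, sm,
                                            seed = cfg$seed + 3L)
    rnaseq_cm <- simulate_rnaseq(expr_truth, sm$rnaseq_replicates,
                                 sm$rnaseq_dispersion, seed = cfg$seed + 4L)
    write_library(lib, file.path(out_dir, "library.tsv"))
    write_screen_truth(truth, file.path(out_dir, "screen_truth.json"))
    write_counts(screen_cm, file.path(out_dir, "screen_counts.tsv"),
                 file.path(out_dir, "screen_samples.tsv"))
    write_counts(rnaseq_cm, file.path(out_dir, "rnaseq_counts.tsv"),
                 file.path(out_dir, "rnaseq_samples.tsv"))
    for (f in c("library.tsv", "screen_truth.json", "screen_counts.tsv",
                "screen_samples.tsv", "rnaseq_counts.tsv",
                "rnaseq_samples.tsv")) emit(f)
    report$stages$simulate <- list(
      n_genes = sm$n_genes, n_shrnas = nrow(lib),
      n_drivers = sm$n_drivers, n_acute = sm$n_acute,
      screen_samples = ncol(screen_cm$counts),
      rnaseq_samples = ncol(rnaseq_cm$counts))
  } else {
    lib <- read_library(cfg$inputs$library)
    screen_cm <- read_counts(cfg$inputs$screen_counts,
                             cfg$inputs$screen_samples)
    screen_cm <- count_matrix(screen_cm$counts, samples = screen_cm$samples,
                              features = data.frame(
                                feature_id = lib$shrna_id, gene = lib$gene,
                                stringsAsFactors = FALSE))
    if (!is.null(cfg$inputs$rnaseq_counts))
      rnaseq_cm <- read_counts(cfg$inputs$rnaseq_counts,
                               cfg$inputs$rnaseq_samples)
  }

  if ("count" %in% cfg$stages) {
    say("stage count")
    if (is.null(cfg$inputs$fastq_dir))
      abort_validation("count stage requires inputs$fastq_dir")
    fq <- list.files(cfg$inputs$fastq_dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                     full.names = TRUE)
    if (!length(fq))
      abort_io(sprintf("no FASTQ files in %s", cfg$inputs$fastq_dir))
    res <- count_barcodes(fq, lib)
    screen_cm <- count_matrix(res$counts$counts, samples = screen_cm$samples,
                              features = res$counts$features)
    write_counts(screen_cm, file.path(out_dir, "barcode_counts.tsv"))
    emit("barcode_counts.tsv")
    report$stages$count <- list(discards = as.list(res$discards),
                                assigned = as.list(colSums(res$counts$counts)))
  }

  gene_summary <- NULL
  if ("screen" %in% cfg$stages) {
    say("stage screen")
    norm <- cpm_normalize(screen_cm)
    arm <- screen_cm$samples$arm
    ids <- screen_cm$samples$sample
    res_calls <- shrna_depletion(norm, ids[arm == "resistant_selected"],
                                 ids[arm == "reference"],
                                 pseudocount = th$pseudocount,
                                 lfc_threshold = th$lfc_threshold,
                                 abundance_floor = th$abundance_floor)
    acute_calls <- shrna_depletion(norm, ids[arm == "parental_acute"],
                                   ids[arm == "reference"],
                                   pseudocount = th$pseudocount,
                                   lfc_threshold = th$lfc_threshold,
                                   abundance_floor = th$abundance_floor)
    surviving <- subtract_acute(res_calls, acute_calls)
    gene_summary <- aggregate_genes(surviving, th$min_candidate,
                                    th$min_stringent)
    utils::write.table(surviving, file.path(out_dir, "shrna_depletion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_summary, file.path(out_dir, "gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("shrna_depletion.tsv"); emit("gene_summary.tsv")
    report$stages$screen <- list(
      n_depleted_shrnas = sum(surviving$depleted),
      n_acute_subtracted = sum(surviving$acute_depleted),
      n_candidate = length(tier_genes(gene_summary, "candidate")),
      n_stringent = length(tier_genes(gene_summary, "stringent")))
  }

  de <- NULL; de_sets <- NULL
  if ("de" %in% cfg$stages) {
    say("stage de")
    if (is.null(rnaseq_cm))
      abort_validation("de stage requires RNA-seq counts")
    if (!"group" %in% names(rnaseq_cm$samples))
      abort_validation("RNA-seq sample sheet needs a 'group' column")
    de <- nb_test(rnaseq_cm, rnaseq_cm$samples$group)
    de_sets <- filter_de(de, th$p_max, th$min_abs_lfc, th$use_fdr)
    utils::write.table(de, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(de_sets$up, file.path(out_dir, "de_up.txt"))
    writeLines(de_sets$down, file.path(out_dir, "de_down.txt"))
    emit("de_results.tsv"); emit("de_up.txt"); emit("de_down.txt")
    report$stages$de <- list(n_tested = nrow(de),
                             n_up = length(de_sets$up),
                             n_down = length(de_sets$down),
                             contrast = attr(de, "groups"))
  }

  candidates <- NULL
  if ("integrate" %in% cfg$stages) {
    say("stage integrate")
    if (is.null(gene_summary) || is.null(de_sets))
      abort_validation("integrate stage needs the screen and de stages")
    candidates <- overlay_screen_de(gene_summary, de_sets, tier = "candidate")
    venn <- venn_summary(list(screen = tier_genes(gene_summary, "candidate"),
                              up = de_sets$up, down = de_sets$down))
    writeLines(candidates, file.path(out_dir, "candidates.txt"))
    emit("candidates.txt")
    report$stages$integrate <- list(
      n_candidates = length(candidates),
      provenance = attr(candidates, "provenance"),
      venn = as.list(venn))
  }

  if ("enrich" %in% cfg$stages) {
    say("stage enrich")
    if (is.null(de) || is.null(candidates))
      abort_validation("enrich stage needs the de and integrate stages")
    universe <- de$gene
    collection <- if (!is.null(cfg$inputs$gmt)) read_gmt(cfg$inputs$gmt)
      else demo_collection(universe, truth, cfg$enrich, seed = cfg$seed + 5L)
    query <- if (length(candidates)) candidates
             else tier_genes(gene_summary, "candidate")
    ora <- enrich_ora(query, collection, universe, p_cutoff = th$enrich_p)
    ranked <- sort(stats::setNames(de$log2fc, de$gene), decreasing = TRUE)
    gsea <- lapply(names(collection), function(nm) {
      s <- intersect(normalize_symbols(collection[[nm]]),
                     normalize_symbols(universe))
      if (!length(s) || length(s) >= length(ranked)) return(NULL)
      g <- gsea_perm_p(ranked, s, n_perm = cfg$enrich$n_perm,
                       seed = cfg$seed + 6L)
      data.frame(set_name = nm, es = g$es, p_perm = g$p_perm,
                 stringsAsFactors = FALSE)
    })
    gsea <- do.call(rbind, gsea)
    utils::write.table(ora, file.path(out_dir, "enrichment_ora.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gsea, file.path(out_dir, "enrichment_gsea.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("enrichment_ora.tsv"); emit("enrichment_gsea.tsv")
    report$stages$enrich <- list(
      n_sets = length(collection),
      n_significant_ora = sum(ora$significant),
      top_set = ora$set_name[1])
  }

  report_path <- file.path(out_dir, "report.json")
  report$outputs <- c(report$outputs, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("wrote %s", report_path)
  invisible(report)
}

## Planted expression truth for the demo/simulated pipeline: drivers are
## up-regulated in the resistant group, plus extra up/down genes private to
## the DE stage.
simulate_expression_truth <- function(lib, truth, sm, seed) {
  genes <- unique(lib$gene)
  with_seed(seed, {
    baseline <- stats::setNames(
      stats::rlnorm(length(genes), sm$rnaseq_baseline_meanlog,
                    sm$rnaseq_baseline_sdlog), genes)
    eff <- matrix(0, nrow = length(genes), ncol = 2,
                  dimnames = list(genes, c("parental", "resistant")))
    drivers <- names(truth$gene_role)[truth$gene_role == "resistance_driver"]
    eff[drivers, "resistant"] <- sm$driver_de_effect
    neutral <- setdiff(genes, names(truth$gene_role)[truth$gene_role != "neutral"])
    n_extra <- min(sm$n_extra_de, length(neutral))
    if (n_extra > 0) {
      extra <- sample(neutral, n_extra)
      half <- seq_len(floor(n_extra / 2))
      eff[extra[half], "resistant"] <- sm$extra_de_effect
      eff[extra[-half], "resistant"] <- -sm$extra_de_effect
    }
    expression_truth(baseline, eff)
  })
}

## Synthetic gene-set collection over the simulated universe: the planted
## driver and acute-essential sets plus seeded random sets.
demo_collection <- function(universe, truth, enr, seed) {
  universe <- normalize_symbols(universe)
  sets <- list()
  if (!is.null(truth)) {
    drivers <- intersect(normalize_symbols(
      names(truth$gene_role)[truth$gene_role == "resistance_driver"]),
      universe)
    acute <- intersect(normalize_symbols(
      names(truth$gene_role)[truth$gene_role == "acute_essential"]),
      universe)
    if (length(drivers)) sets$PLANTED_DRIVERS <- drivers
    if (length(acute)) sets$PLANTED_ACUTE <- acute
  }
  rand <- with_seed(seed, lapply(seq_len(enr$n_random_sets), function(i)
    sample(universe, min(enr$set_size, length(universe)))))
  names(rand) <- sprintf("RANDOM_SET_%02d", seq_along(rand))
  c(sets, rand)
}
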