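#' Configuration for a full synthetic pipeline run
#'
#' Declarative description of the whole cascade: simulation configs for the
#' discovery cohort, the external validation cohort and the single-cell
#' reference; analysis thresholds; the focus disease whose specific gene set
#' is validated and mapped; and the master seed from which all stage seeds
#' are derived.
#'
#' @param bulk a \code{\link{bulk_sim_config}} for the discovery cohort. The
#'   default plants macrophage-early and cholangiocyte-late trajectory
#'   programs in the focus disease.
#' @param sc an \code{\link{sc_sim_config}}; its gene universe and the marker
#'   sets of trajectory cell types are overridden to match the bulk cohort.
#' @param qpcr optional list of arguments for
#'   \code{\link{simulate_qpcr_plate}} (or \code{NULL} to skip the stage).
#' @param focus disease whose specific set is validated and cell-type mapped.
#' @param external_overlap fraction of the focus DEG program shared with the
#'   external validation cohort's planted program.
#' @param external_stage_counts per-stage sample counts of the external
#'   cohort (Ishak 0-6; default 74 samples).
#' @param min_total,alpha,lfc_min,detection_min,specificity_fold analysis
#'   thresholds.
#' @param n_components PCA components computed per disease.
#' @param trajectory_components optional named vector (disease -> component)
#'   overriding the automatic pick (the component whose scores correlate most
#'   strongly, by absolute Spearman rho, with the fibrosis stage).
#' @param outdir output directory (created); \code{NULL} for no file output.
#' @param seed master seed.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(bulk = NULL, sc = NULL, qpcr = NULL,
                            focus = "PSC", external_overlap = 0.6,
                            external_stage_counts = c(6L, 12L, 14L, 12L, 12L, 10L, 8L),
                            min_total = 10, alpha = 0.05, lfc_min = 1,
                            detection_min = 0.005, specificity_fold = 1.5,
                            n_components = 2L, trajectory_components = NULL,
                            outdir = NULL, seed = 1L) {
  if (is.null(bulk))
    bulk <- bulk_sim_config(trajectory_programs = list(
      list(disease = focus, cell_type = "macrophage", polarity = "early",
           n_genes = 30L, slope_log2fc = 0.8),
      list(disease = focus, cell_type = "cholangiocyte", polarity = "late",
           n_genes = 30L, slope_log2fc = 0.8)))
  sc <- sc %||% sc_sim_config()
  if (!focus %in% names(bulk$diseases))
    stop_fib("focus disease '", focus, "' not in the bulk config")
  if (alpha <= 0 || alpha > 1 || lfc_min < 0 || detection_min < 0 ||
      detection_min > 1 || specificity_fold < 1 || min_total < 0 ||
      external_overlap < 0 || external_overlap > 1)
    stop_fib("threshold out of range")
  structure(list(bulk = bulk, sc = sc, qpcr = qpcr, focus = focus,
                 external_overlap = external_overlap,
                 external_stage_counts = external_stage_counts,
                 min_total = min_total, alpha = alpha, lfc_min = lfc_min,
                 detection_min = detection_min,
                 specificity_fold = specificity_fold,
                 n_components = as.integer(n_components),
                 trajectory_components = trajectory_components,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_stage <- function(obj, path, writer) {
  if (is.null(path)) return(invisible(NULL))
  writer(obj, path)
  invisible(path)
}

#' Run the full pro-fibrogenic signature pipeline
#'
#' Orchestrates the cascade on synthetic data with planted ground truth:
#' simulate the discovery cohort, the external validation cohort (focus
#' disease, Ishak staging, controlled program overlap) and the single-cell
#' reference (trajectory-program genes co-planted as markers of their cell
#' type); filter and normalize; per-disease NB Wald differential expression
#' (sex covariate); Venn partition and focus-specific set; external overlap
#' validation; cell-type specificity calls for the validated genes; per-
#' disease oriented PCA and trajectory scoring; optional qPCR report. When
#' \code{config$outdir} is set, every stage output is written as plain text
#' and listed, with its MD5 hash, in \code{manifest.json}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{pipeline_run}: all stage outputs plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) if (is.null(outdir)) NULL else file.path(outdir, ...)

  # --- stage 1: simulation ------------------------------------------------
  bulk_cfg <- config$bulk; bulk_cfg$seed <- seed + 101L
  bulk <- simulate_bulk_cohort(bulk_cfg)

  focus <- config$focus
  focus_genes <- bulk$truth$gene[bulk$truth[[paste0("member_", focus)]]]
  n_shared <- round(config$external_overlap * length(focus_genes))
  ext_cfg <- bulk_sim_config(
    n_genes = bulk_cfg$n_genes,
    diseases = setNames(list(config$external_stage_counts), focus),
    scheme = "ishak",
    program_sizes = setNames(length(focus_genes), focus),
    shared_program_sizes = c(pairwise = 0L, triple = 0L),
    effect_log2fc = bulk_cfg$effect_log2fc,
    sex_effect_log2fc = bulk_cfg$sex_effect_log2fc,
    n_sex_genes = bulk_cfg$n_sex_genes,
    nb_dispersion = bulk_cfg$nb_dispersion,
    size_factor_range = bulk_cfg$size_factor_range,
    seed = seed + 102L)
  with_seed(seed + 103L, {
    shared_genes <- sample(focus_genes, n_shared)
    fresh_pool <- setdiff(bulk$truth$gene, focus_genes)
    fresh <- sample(fresh_pool, length(focus_genes) - n_shared)
    ext_cfg$preset_member_genes <- setNames(list(c(shared_genes, fresh)), focus)
  })
  external <- simulate_bulk_cohort(ext_cfg)

  sc_cfg <- config$sc
  sc_cfg$gene_ids <- rownames(bulk$counts)
  traj <- bulk$truth[!is.na(bulk$truth$trajectory_cell_type), ]
  if (nrow(traj)) {
    mg <- split(traj$gene, traj$trajectory_cell_type)
    missing_types <- setdiff(names(mg), names(sc_cfg$cell_types))
    if (length(missing_types))
      stop_fib("trajectory cell type(s) absent from the sc config: ",
               paste(missing_types, collapse = ", "))
    sc_cfg$marker_genes <- mg
  }
  sc_cfg$seed <- seed + 104L
  scref <- simulate_sc_reference(sc_cfg)

  write_stage(bulk$counts, fp("counts.tsv"), write_counts)
  write_stage(bulk$meta, fp("meta.csv"), write_meta)
  write_stage(bulk$truth, fp("truth.csv"),
              function(o, p) write.csv(o, p, row.names = FALSE))
  write_stage(external$counts, fp("external_counts.tsv"), write_counts)
  write_stage(external$meta, fp("external_meta.csv"), write_meta)
  if (!is.null(outdir)) write_sc_reference(scref$ref, fp("sc_reference"))

  # --- stage 2: preprocessing + per-disease DE ---------------------------
  filtered <- filter_low_counts(bulk$counts, config$min_total)
  diseases <- names(config$bulk$diseases)
  de <- list(); degs <- list(); pcas <- list()
  for (d in diseases) {
    sel <- bulk$meta$disease == d
    cts <- filtered[, bulk$meta$sample[sel], drop = FALSE]
    cts <- cts[rowSums(cts) > 0, , drop = FALSE]
    fit <- nb_fit(cts, bulk$meta[sel, ], covariates = "sex")
    res <- results(fit, config$alpha, config$lfc_min)
    de[[d]] <- res
    degs[[d]] <- call_degs(res, config$alpha, config$lfc_min)$gene
    sf <- size_factors(cts)
    lt <- log_transform(cts, sf)
    pcas[[d]] <- pca_with_orientation(lt, bulk$meta[sel, ],
                                      n_components = config$n_components)
    write_stage(res, fp(paste0("de_", d, ".tsv")),
                function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE))
  }

  # --- stage 3: set algebra + external validation ------------------------
  partition <- venn_partition(degs)
  spec <- specific_set(partition, focus)

  ext_filtered <- filter_low_counts(external$counts, config$min_total)
  ext_fit <- nb_fit(ext_filtered, external$meta, covariates = "sex")
  ext_res <- results(ext_fit, config$alpha, config$lfc_min)
  ext_degs <- call_degs(ext_res, config$alpha, config$lfc_min)$gene
  validation <- validate_against_external(spec, ext_degs)

  if (!is.null(outdir)) {
    venn_df <- data.frame(region = names(partition$regions),
                          count = unname(partition$counts),
                          genes = vapply(partition$regions, paste,
                                         character(1), collapse = ";"))
    write.csv(venn_df, fp("venn.csv"), row.names = FALSE)
    writeLines(spec, fp(paste0("specific_", focus, ".txt")))
    write.table(ext_res, fp("external_de.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(validation$shared, fp("validated_genes.txt"))
  }

  # --- stage 4: cell-type mapping ----------------------------------------
  map_genes <- intersect(tolower_match(validation$shared,
                                       rownames(scref$ref$counts)),
                         rownames(scref$ref$counts))
  calls <- if (length(map_genes))
    assign_specificity(scref$ref, map_genes, config$detection_min,
                       config$specificity_fold)
  else assign_specificity(scref$ref, detection_min = config$detection_min,
                          specificity_fold = config$specificity_fold)[0, ]
  dot <- if (length(map_genes))
    dotplot_table(scref$ref, map_genes, config$detection_min,
                  config$specificity_fold)
  else NULL
  write_stage(as.data.frame(calls), fp("specificity.csv"),
              function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(dot))
    write_stage(dot, fp("dotplot.csv"),
                function(o, p) write.csv(o, p, row.names = FALSE))

  # --- stage 5: trajectory scoring ---------------------------------------
  normref <- normalize_sc_for_projection(scref$ref)
  trajectories <- list()
  for (d in diseases) {
    pc <- config$trajectory_components[[d]] %||% {
      stg <- pcas[[d]]$stage
      rho <- abs(apply(pcas[[d]]$scores, 2L, function(s)
        suppressWarnings(cor(s, stg, method = "spearman"))))
      which.max(replace(rho, is.na(rho), -Inf))
    }
    trajectories[[d]] <- trajectory_scores(scref$ref, pcas[[d]],
                                           component = pc,
                                           normalized = normref)
    write_stage(trajectories[[d]]$densities, fp(paste0("density_", d, ".csv")),
                function(o, p) write.csv(o, p, row.names = FALSE))
    write_stage(trajectories[[d]]$ranking, fp(paste0("ranking_", d, ".tsv")),
                function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE))
  }

  # --- stage 6: qPCR (optional) ------------------------------------------
  qpcr <- NULL
  if (!is.null(config$qpcr)) {
    args <- config$qpcr
    args$seed <- args$seed %||% (seed + 105L)
    plate <- do.call(simulate_qpcr_plate, args)
    qpcr <- qpcr_report(plate)
    write_stage(qpcr$fold_changes, fp("qpcr_fold_changes.csv"),
                function(o, p) write.csv(o, p, row.names = FALSE))
    write_stage(qpcr$tests, fp("qpcr_tests.csv"),
                function(o, p) write.csv(o, p, row.names = FALSE))
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("fibrosig")),
    seed = seed,
    thresholds = list(min_total = config$min_total, alpha = config$alpha,
                      lfc_min = config$lfc_min,
                      detection_min = config$detection_min,
                      specificity_fold = config$specificity_fold),
    stages = list(
      simulate = list(n_genes = nrow(bulk$counts),
                      n_samples = ncol(bulk$counts),
                      n_external_samples = ncol(external$counts),
                      n_cells = ncol(scref$ref$counts)),
      preprocess = list(n_genes_filtered = nrow(filtered)),
      diffexp = lapply(degs, length),
      genesets = list(specific = length(spec),
                      external_degs = length(ext_degs),
                      validated = validation$n_shared,
                      jaccard = validation$jaccard),
      celltype = list(n_mapped = nrow(calls),
                      n_attributed = sum(!calls$label %in%
                                           c("unspecific", "undetected"))),
      trajectory = lapply(trajectories, function(t)
        list(component = t$component, n_genes_used = t$n_genes_used)),
      qpcr = if (!is.null(qpcr)) list(n_genes = nrow(qpcr$tests)) else NULL))
  if (!is.null(outdir)) {
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$files <- lapply(files, function(f)
      list(path = sub(paste0("^", outdir, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  structure(list(bulk = bulk, external = external, sc = scref,
                 filtered = filtered, de = de, degs = degs, pcas = pcas,
                 partition = partition, specific = spec,
                 external_results = ext_res, validation = validation,
                 specificity = calls, dotplot = dot,
                 trajectories = trajectories, qpcr = qpcr,
                 manifest = manifest, config = config),
            class = "pipeline_run")
}

# case-insensitive symbol matching helper: returns elements of `x` mapped to
# the casing used in `target` where a case-insensitive match exists
tolower_match <- function(x, target) {
  hit <- match(toupper(x), toupper(target))
  out <- ifelse(is.na(hit), x, target[hit])
  unique(out)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed", x$manifest$seed, ")\n")
  cat("  DEGs per disease:",
      paste(names(x$degs), vapply(x$degs, length, integer(1)),
            sep = "=", collapse = ", "), "\n")
  cat("  ", x$config$focus, "-specific: ", length(x$specific),
      "; validated externally: ", x$validation$n_shared, "\n", sep = "")
  cat("  cell-type attributed:", x$manifest$stages$celltype$n_attributed,
      "of", x$manifest$stages$celltype$n_mapped, "mapped genes\n")
  invisible(x)
}
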