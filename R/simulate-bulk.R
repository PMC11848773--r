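#' Configuration for a synthetic multi-disease bulk RNA-seq cohort
#'
#' Describes a bulk liver cohort with per-disease fibrosis-stage composition,
#' planted stage-linked gene programs with controlled cross-disease overlap, a
#' sex covariate effect, negative-binomial noise and per-sample size factors.
#' The defaults emulate the study conditions of a three-etiology liver-fibrosis
#' cohort: 16 PSC (12 early / 4 advanced), 15 PBC (12/3) and 16 MASLD (10/6)
#' samples staged 0-4 on the Desmet/Scheuer scale.
#'
#' @param n_genes number of genes in the universe.
#' @param diseases named list; one entry per disease giving the number of
#'   samples at each fibrosis stage (a vector of length 5 for Desmet 0-4, or
#'   7 for Ishak 0-6).
#' @param scheme fibrosis staging scheme: \code{"desmet"} (0-4; early 0-2,
#'   advanced 3-4) or \code{"ishak"} (0-6; early 0-3, advanced 4-6).
#' @param program_sizes named integer vector: number of genes planted as
#'   DEGs specific to each disease (advanced vs. early step effect).
#' @param shared_program_sizes named vector with elements \code{pairwise}
#'   (genes planted in every 2-disease overlap) and \code{triple} (genes
#'   planted in all three diseases). Ignored entries for absent diseases.
#' @param effect_log2fc absolute log2 fold change (advanced vs. early) of
#'   planted DEGs; direction is random per gene (70\% up).
#' @param sex_effect_log2fc log2 effect applied to males for the designated
#'   sex-affected gene subset.
#' @param n_sex_genes number of sex-affected genes (disjoint from DEG programs).
#' @param nb_dispersion negative-binomial dispersion alpha (>0) shared across
#'   genes: Var = mu + alpha * mu^2.
#' @param size_factor_range interval from which per-sample size factors are
#'   drawn uniformly.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline mean expression.
#' @param trajectory_programs optional list of planted trajectory programs,
#'   each a list with elements \code{disease}, \code{cell_type},
#'   \code{polarity} ("early" or "late"), \code{n_genes} and
#'   \code{slope_log2fc} (log2 change per fibrosis stage). Trajectory genes
#'   vary log-linearly with stage within their disease and are disjoint from
#'   the DEG programs.
#' @param preset_member_genes optional named list (disease -> gene ids of the
#'   form \code{"g00001"}) fixing that disease's planted DEG program instead
#'   of drawing it at random; used to build validation cohorts with a
#'   controlled program overlap.
#' @param seed integer seed making generation reproducible.
#'
#' @return an object of class \code{bulk_sim_config}.
#' @export
bulk_sim_config <- function(n_genes = 2000L,
                            diseases = list(
                              PSC   = c(1L, 7L, 4L, 2L, 2L),
                              PBC   = c(2L, 5L, 5L, 0L, 3L),
                              MASLD = c(4L, 5L, 1L, 4L, 2L)),
                            scheme = c("desmet", "ishak"),
                            program_sizes = c(PSC = 120L, PBC = 40L, MASLD = 120L),
                            shared_program_sizes = c(pairwise = 6L, triple = 4L),
                            effect_log2fc = 2,
                            sex_effect_log2fc = 1,
                            n_sex_genes = 50L,
                            nb_dispersion = 0.05,
                            size_factor_range = c(0.5, 2),
                            baseline_meanlog = log(100),
                            baseline_sdlog = 1.5,
                            trajectory_programs = NULL,
                            preset_member_genes = NULL,
                            seed = 1L) {
  scheme <- match.arg(scheme)
  n_stages <- if (scheme == "desmet") 5L else 7L
  if (length(diseases) < 1L || is.null(names(diseases)))
    stop_fib("diseases must be a named list of per-stage sample counts")
  for (d in names(diseases)) {
    v <- diseases[[d]]
    if (length(v) != n_stages || any(v < 0) || any(v != round(v)))
      stop_fib("disease '", d, "': need ", n_stages,
               " non-negative integer stage counts for scheme '", scheme, "'")
  }
  if (nb_dispersion <= 0) stop_fib("nb_dispersion must be > 0")
  if (effect_log2fc < 0) stop_fib("effect_log2fc must be >= 0")
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0)
    stop_fib("size_factor_range must be an increasing positive interval")
  program_sizes <- program_sizes[names(diseases)[names(diseases) %in% names(program_sizes)]]
  n_traj <- 0L
  if (!is.null(trajectory_programs)) {
    for (tp in trajectory_programs) {
      need <- c("disease", "cell_type", "polarity", "n_genes", "slope_log2fc")
      if (!all(need %in% names(tp)))
        stop_fib("each trajectory program needs fields: ", paste(need, collapse = ", "))
      if (!tp$disease %in% names(diseases))
        stop_fib("trajectory program references unknown disease '", tp$disease, "'")
      if (!tp$polarity %in% c("early", "late"))
        stop_fib("trajectory polarity must be 'early' or 'late'")
      n_traj <- n_traj + as.integer(tp$n_genes)
    }
  }
  n_dis <- length(diseases)
  n_pairs <- if (n_dis >= 2L) choose(n_dis, 2L) else 0L
  n_planted <- sum(program_sizes) +
    n_pairs * as.integer(shared_program_sizes[["pairwise"]] %||% 0L) +
    (if (n_dis >= 3L) as.integer(shared_program_sizes[["triple"]] %||% 0L) else 0L) +
    as.integer(n_sex_genes) + n_traj
  if (n_planted > n_genes)
    stop_fib("planted program sizes (", n_planted, ") exceed the gene universe (",
             n_genes, ")")
  structure(list(
    n_genes = as.integer(n_genes), diseases = diseases, scheme = scheme,
    program_sizes = program_sizes, shared_program_sizes = shared_program_sizes,
    effect_log2fc = effect_log2fc, sex_effect_log2fc = sex_effect_log2fc,
    n_sex_genes = as.integer(n_sex_genes), nb_dispersion = nb_dispersion,
    size_factor_range = size_factor_range,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    trajectory_programs = trajectory_programs,
    preset_member_genes = preset_member_genes, seed = as.integer(seed)),
    class = "bulk_sim_config")
}

#' Simulate a bulk RNA-seq cohort with planted ground truth
#'
#' Draws gene-by-sample negative-binomial counts
#' \eqn{y_{gj} \sim NB(\mu = s_j q_{gj}, \alpha)} where \eqn{q_{gj}} combines a
#' log-normal per-gene baseline, planted advanced-vs-early step effects for
#' disease DEG programs, log-linear-in-stage effects for trajectory programs,
#' and a sex effect for a designated gene subset. Per-sample size factors
#' \eqn{s_j} are drawn uniformly from the configured range.
#'
#' @param config a \code{\link{bulk_sim_config}}.
#' @return a list with elements \code{counts} (integer matrix genes x samples),
#'   \code{meta} (data frame: sample, disease, stage, scheme, fibrosis_category,
#'   sex, true_size_factor) and \code{truth} (per-gene data frame recording
#'   planted disease memberships, direction, true log2FC, sex effect and
#'   trajectory program membership).
#' @export
simulate_bulk_cohort <- function(config) {
  if (!inherits(config, "bulk_sim_config"))
    stop_fib("config must be built with bulk_sim_config()")
  with_seed(config$seed, {
    ng <- config$n_genes
    genes <- sprintf("g%05d", seq_len(ng))
    dis <- names(config$diseases)
    n_stages <- if (config$scheme == "desmet") 5L else 7L

    # --- sample sheet -----------------------------------------------------
    meta <- do.call(rbind, lapply(dis, function(d) {
      stages <- rep(seq_len(n_stages) - 1L, times = config$diseases[[d]])
      if (!length(stages)) return(NULL)
      data.frame(sample = NA_character_, disease = d, stage = stages,
                 scheme = config$scheme, stringsAsFactors = FALSE)
    }))
    meta$sample <- sprintf("%s_s%02d", meta$disease,
                           unlist(lapply(dis, function(d) seq_len(sum(config$diseases[[d]])))))
    meta$fibrosis_category <- as.character(stage_category(meta$stage, config$scheme))
    # alternate sexes within disease (ordered by stage) -> balanced, not
    # confounded with the fibrosis category
    meta$sex <- unlist(lapply(dis, function(d) {
      n <- sum(config$diseases[[d]])
      rep_len(c("female", "male"), n)
    }))
    meta$true_size_factor <- runif(nrow(meta), config$size_factor_range[1],
                                   config$size_factor_range[2])

    # --- gene programs ----------------------------------------------------
    pool <- sample.int(ng)          # randomised disjoint allocation
    take <- function(k) {
      if (k == 0L) return(integer(0))
      out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out
    }
    membership <- matrix(FALSE, ng, length(dis), dimnames = list(genes, dis))
    preset <- config$preset_member_genes %||% list()
    for (d in names(preset)) {
      idx <- match(preset[[d]], genes)
      if (anyNA(idx)) stop_fib("preset_member_genes for ", d,
                               " outside the gene universe")
      membership[idx, d] <- TRUE
      pool <- setdiff(pool, idx)
    }
    for (d in setdiff(names(config$program_sizes), names(preset)))
      membership[take(config$program_sizes[[d]]), d] <- TRUE
    if (length(dis) >= 2L) {
      np <- as.integer(config$shared_program_sizes[["pairwise"]] %||% 0L)
      for (pr in utils::combn(dis, 2L, simplify = FALSE))
        membership[take(np), pr] <- TRUE
    }
    if (length(dis) >= 3L) {
      nt <- as.integer(config$shared_program_sizes[["triple"]] %||% 0L)
      membership[take(nt), dis] <- TRUE
    }
    planted <- rowSums(membership) > 0
    direction <- integer(ng)
    direction[planted] <- ifelse(runif(sum(planted)) < 0.7, 1L, -1L)
    true_lfc <- direction * config$effect_log2fc

    sex_idx <- take(config$n_sex_genes)
    sex_affected <- seq_len(ng) %in% sex_idx
    sex_dir <- integer(ng)
    sex_dir[sex_idx] <- ifelse(runif(length(sex_idx)) < 0.5, 1L, -1L)

    traj_type <- rep(NA_character_, ng)
    traj_pol <- rep(NA_character_, ng)
    traj_dis <- rep(NA_character_, ng)
    traj_slope <- rep(0, ng)
    for (tp in config$trajectory_programs %||% list()) {
      idx <- take(as.integer(tp$n_genes))
      traj_type[idx] <- tp$cell_type
      traj_pol[idx] <- tp$polarity
      traj_dis[idx] <- tp$disease
      traj_slope[idx] <- tp$slope_log2fc * if (tp$polarity == "late") 1 else -1
    }

    baseline <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)

    # --- counts -----------------------------------------------------------
    mid_stage <- (n_stages - 1L) / 2
    counts <- matrix(0L, ng, nrow(meta), dimnames = list(genes, meta$sample))
    for (j in seq_len(nrow(meta))) {
      l2 <- numeric(ng)
      d <- meta$disease[j]
      if (meta$fibrosis_category[j] == "advanced")
        l2 <- l2 + true_lfc * membership[, d]
      on_traj <- !is.na(traj_dis) & traj_dis == d
      l2[on_traj] <- l2[on_traj] + traj_slope[on_traj] * (meta$stage[j] - mid_stage)
      if (meta$sex[j] == "male")
        l2 <- l2 + sex_dir * config$sex_effect_log2fc * sex_affected
      mu <- meta$true_size_factor[j] * baseline * 2^l2
      counts[, j] <- rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
    }
    storage.mode(counts) <- "integer"

    truth <- data.frame(gene = genes,
                        planted_deg = planted & config$effect_log2fc > 0,
                        direction = direction,
                        true_log2fc = ifelse(planted, true_lfc, 0),
                        sex_affected = sex_affected,
                        sex_direction = sex_dir,
                        trajectory_disease = traj_dis,
                        trajectory_cell_type = traj_type,
                        trajectory_polarity = traj_pol,
                        trajectory_slope_log2fc = traj_slope,
                        stringsAsFactors = FALSE)
    for (d in dis) truth[[paste0("member_", d)]] <- membership[, d] & config$effect_log2fc > 0

    list(counts = counts, meta = check_sample_meta(meta), truth = truth)
  })
}
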