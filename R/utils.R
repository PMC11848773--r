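# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fib <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_fib(name, " must be TRUE or FALSE")
  x
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_fib("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fib("counts must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fib("duplicate gene identifiers: ",
             paste(unique(rownames(counts)[duplicated(rownames(counts))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_fib("duplicate sample identifiers: ",
             paste(unique(colnames(counts)[duplicated(colnames(counts))])[1:3], collapse = ", "))
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_fib("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop_fib("counts must be integral; offending gene: ",
             rownames(counts)[which(rowSums(counts != round(counts)) > 0)[1]])
  invisible(counts)
}

# Fibrosis staging schemes: Desmet/Scheuer 0-4 (early 0-2, advanced 3-4),
# Ishak 0-6 (early 0-3, advanced 4-6).
stage_category <- function(stage, scheme = c("desmet", "ishak")) {
  scheme <- match.arg(scheme)
  max_stage <- if (scheme == "desmet") 4L else 6L
  cut_adv <- if (scheme == "desmet") 3L else 4L
  if (any(is.na(stage)) || any(stage < 0L | stage > max_stage) ||
      any(stage != round(stage)))
    stop_fib("fibrosis stage out of range for scheme '", scheme, "' (0-", max_stage,
             "); offending stage: ", stage[which(stage < 0 | stage > max_stage | stage != round(stage))[1]])
  factor(ifelse(stage >= cut_adv, "advanced", "early"),
         levels = c("early", "advanced"))
}

check_sample_meta <- function(meta) {
  req <- c("sample", "disease", "stage", "scheme", "sex")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop_fib("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample))
    stop_fib("duplicate sample identifiers in metadata: ",
             meta$sample[duplicated(meta$sample)][1])
  if (!all(meta$scheme %in% c("desmet", "ishak")))
    stop_fib("unknown staging scheme: ",
             paste(setdiff(unique(meta$scheme), c("desmet", "ishak")), collapse = ", "))
  if (!all(meta$sex %in% c("female", "male")))
    stop_fib("sex must be 'female' or 'male'")
  cat_by_scheme <- character(nrow(meta))
  for (sch in unique(meta$scheme)) {
    i <- meta$scheme == sch
    cat_by_scheme[i] <- as.character(stage_category(meta$stage[i], sch))
  }
  if (is.null(meta$fibrosis_category)) {
    meta$fibrosis_category <- cat_by_scheme
  } else if (!identical(as.character(meta$fibrosis_category), cat_by_scheme)) {
    bad <- which(as.character(meta$fibrosis_category) != cat_by_scheme)[1]
    stop_fib("fibrosis_category inconsistent with stage/scheme for sample ",
             meta$sample[bad])
  }
  meta$fibrosis_category <- factor(meta$fibrosis_category,
                                   levels = c("early", "advanced"))
  meta$sex <- factor(meta$sex, levels = c("female", "male"))
  meta
}

align_counts_meta <- function(counts, meta) {
  if (!setequal(colnames(counts), meta$sample))
    stop_fib("sample sets of counts and metadata differ; e.g. ",
             paste(head(c(setdiff(colnames(counts), meta$sample),
                          setdiff(meta$sample, colnames(counts))), 3), collapse = ", "))
  meta[match(colnames(counts), meta$sample), , drop = FALSE]
}
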