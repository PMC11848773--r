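#' Venn partition of labeled gene sets
#'
#' Exact disjoint region decomposition of 2-3 labeled gene sets: every member
#' of the union is assigned to exactly one region named by the sets that
#' contain it (e.g. \code{"PSC"}, \code{"PSC&PBC"}, \code{"PSC&PBC&MASLD"}).
#'
#' @param sets named list of 2-3 character vectors (gene identifiers).
#' @return object of class \code{venn_partition}: \code{labels},
#'   \code{regions} (named list of member vectors), \code{counts}.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop_fib("need 2 or 3 labeled sets")
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets)))
    stop_fib("sets must carry unique non-empty labels")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  labels <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  inset <- vapply(sets, function(s) universe %in% s,
                  logical(length(universe)))
  if (length(universe) == 1L) inset <- matrix(inset, nrow = 1L,
                                              dimnames = list(NULL, labels))
  key <- apply(inset, 1L, function(r) paste(labels[r], collapse = "&"))
  # all 2^n - 1 regions, empty ones included
  combos <- unlist(lapply(seq_along(labels), function(k)
    utils::combn(labels, k, paste, collapse = "&")))
  regions <- setNames(lapply(combos, function(cb) universe[key == cb]), combos)
  structure(list(labels = labels, regions = regions,
                 counts = vapply(regions, length, integer(1))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of", length(x$labels), "sets (",
      sum(x$counts), "genes in union )\n")
  print(x$counts)
  invisible(x)
}

#' Disease-specific gene set
#'
#' The region of a Venn partition belonging to \code{focus} only: the focus
#' set minus the union of all other sets.
#'
#' @param partition a \code{\link{venn_partition}}.
#' @param focus one of the partition labels.
#' @return character vector of genes exclusive to \code{focus}.
#' @export
specific_set <- function(partition, focus) {
  stopifnot(inherits(partition, "venn_partition"))
  if (!focus %in% partition$labels)
    stop_fib("unknown set label '", focus, "'")
  partition$regions[[focus]]
}

#' Reconstruct one input set from its partition regions
#'
#' @param partition a \code{\link{venn_partition}}.
#' @param label set label.
#' @return all genes of that input set (union of every region containing it).
#' @export
set_from_partition <- function(partition, label) {
  stopifnot(inherits(partition, "venn_partition"))
  if (!label %in% partition$labels) stop_fib("unknown set label '", label, "'")
  hit <- vapply(strsplit(names(partition$regions), "&", fixed = TRUE),
                function(p) label %in% p, logical(1))
  sort(unique(unlist(partition$regions[hit], use.names = FALSE)))
}

#' Validate a gene set against an external cohort
#'
#' Intersection of a disease-specific DEG set with the DEGs of an external
#' validation cohort, after case-normalizing the symbols, with the Jaccard
#' index of the two sets.
#'
#' @param specific character vector (e.g. the focus-specific set).
#' @param external_degs character vector of external-cohort DEGs.
#' @return list: \code{shared} (intersection), \code{n_specific},
#'   \code{n_external}, \code{n_shared}, \code{jaccard}.
#' @export
validate_against_external <- function(specific, external_degs) {
  a <- unique(toupper(as.character(specific)))
  b <- unique(toupper(as.character(external_degs)))
  if (!length(a) || !length(b))
    warning("empty input set; returning empty overlap")
  shared <- intersect(a, b)
  uni <- union(a, b)
  list(shared = shared, n_specific = length(a), n_external = length(b),
       n_shared = length(shared),
       jaccard = if (length(uni)) length(shared) / length(uni) else NA_real_)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set and
#' each collection, conditioned on a gene universe, with BH adjustment across
#' collections. Collections reaching outside the universe are clipped with a
#' warning.
#'
#' @param query character vector of genes (clipped to the universe).
#' @param collections named list of gene sets.
#' @param universe character vector of background genes.
#' @return data frame: collection, k (overlap), K (set size), n (query size),
#'   N (universe size), p, padj.
#' @export
hypergeom_ora <- function(query, collections, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop_fib("empty universe")
  if (is.null(names(collections))) stop_fib("collections must be named")
  query <- unique(as.character(query))
  if (!all(query %in% universe)) {
    warning("query clipped to universe (",
            sum(!query %in% universe), " genes dropped)")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collections), function(lbl) {
    s <- unique(as.character(collections[[lbl]]))
    if (!all(s %in% universe)) {
      warning("collection '", lbl, "' clipped to universe (",
              sum(!s %in% universe), " genes dropped)")
      s <- intersect(s, universe)
    }
    K <- length(s)
    k <- length(intersect(s, query))
    # P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(collection = lbl, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
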