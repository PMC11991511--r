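#' Quality Threshold Clustering
#'
#' Iterative clustering under a hard diameter bound. In each round, every
#' remaining point seeds a candidate cluster that is grown greedily: at
#' each step the point whose addition yields the smallest resulting
#' diameter (maximum pairwise distance) is added, provided the diameter
#' stays within `threshold`; ties are broken toward the smallest case id.
#' The largest candidate is accepted (ties toward the seed with the
#' smallest case id), its members are removed, and the process repeats
#' until the largest candidate falls below `min_size`. Points never
#' assigned are reported as outliers. The procedure is fully
#' deterministic and invariant to the input ordering of the matrix.
#'
#' Greedy growth is a heuristic: the accepted cluster is usually, but not
#' provably, a maximum-cardinality subset of diameter within the
#' threshold.
#'
#' @param d symmetric distance matrix with case-id dimnames (a
#'   [distance_matrix()]).
#' @param threshold maximum allowed cluster diameter, in `[0, 1]`.
#' @param min_size smallest acceptable cluster (>= 2); default 5.
#' @return object of class `qt_clustering`: list with `clusters` (list
#'   of character vectors of member ids, sorted), `outliers` (character
#'   vector), `threshold` and `min_size`.
#' @export
qt_cluster <- function(d, threshold, min_size = 5L) {
  if (is.null(dim(d)) || nrow(d) == 0L) {
    stop("empty distance matrix", call. = FALSE)
  }
  stopifnot(threshold >= 0, threshold <= 1, min_size >= 2)
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix needs case-id dimnames",
                         call. = FALSE)
  eps <- 1e-12
  remaining <- sort(ids)
  clusters <- list()
  while (length(remaining) >= min_size) {
    best <- character(0)
    for (seed in remaining) {          # remaining is id-sorted
      members <- seed
      cand <- setdiff(remaining, seed)
      maxd <- d[seed, cand]
      diam <- 0
      while (length(cand)) {
        res_diam <- pmax(diam, maxd)
        ok <- res_diam <= threshold + eps
        if (!any(ok)) break
        pick_i <- which(ok)[order(res_diam[ok], cand[ok])][1L]
        pick <- cand[pick_i]
        diam <- max(diam, maxd[pick_i])
        members <- c(members, pick)
        cand <- cand[-pick_i]
        maxd <- pmax(maxd[-pick_i], d[pick, cand])
      }
      if (length(members) > length(best)) best <- members
      # earliest seed wins ties, so only strict improvements replace
    }
    if (length(best) < min_size) break
    clusters[[length(clusters) + 1L]] <- sort(best)
    remaining <- setdiff(remaining, best)
  }
  structure(list(clusters = clusters, outliers = remaining,
                 threshold = threshold, min_size = as.integer(min_size)),
            class = "qt_clustering")
}

#' @export
print.qt_clustering <- function(x, ...) {
  cat(sprintf("<qt_clustering> %d clusters (sizes %s), %d outliers, threshold %.4g\n",
              length(x$clusters),
              paste(lengths(x$clusters), collapse = ", "),
              length(x$outliers), x$threshold))
  invisible(x)
}

#' Diameter of each cluster
#'
#' @param clustering a [qt_cluster()] result.
#' @param d the distance matrix used for clustering.
#' @return numeric vector of maximum pairwise distances, one per cluster.
#' @export
cluster_diameters <- function(clustering, d) {
  vapply(clustering$clusters, function(m) {
    if (length(m) < 2L) return(0)
    max(d[m, m])
  }, numeric(1))
}

#' Outcome-separation score of a clustering
#'
#' Pearson chi-square statistic of the strata-by-outcome contingency
#' table, where the strata are the clusters plus (if non-empty) one
#' outlier stratum and the outcome is a boolean label per case. Strata
#' with zero row total are dropped; if fewer than two strata or a
#' degenerate outcome margin remain the score is 0.
#'
#' @param clustering a [qt_cluster()] result.
#' @param labels named logical vector (names = case ids) or an
#'   `outcome_labels` data frame plus `outcome` column name.
#' @param outcome when `labels` is an `outcome_labels` data frame, which
#'   column to use (`"vulnerable"` or `"anxiety"`).
#' @return the chi-square statistic (numeric scalar, >= 0).
#' @export
cluster_separation <- function(clustering, labels, outcome = "vulnerable") {
  lab <- as_label_vector(labels, outcome)
  strata <- clustering$clusters
  if (length(clustering$outliers)) {
    strata <- c(strata, list(clustering$outliers))
  }
  missing <- setdiff(unlist(strata), names(lab))
  if (length(missing)) {
    stop("labels missing for case(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  tab <- t(vapply(strata, function(m) {
    c(sum(lab[m]), sum(!lab[m]))
  }, numeric(2)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0)) return(0)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expd)^2 / expd)
}

as_label_vector <- function(labels, outcome) {
  if (inherits(labels, "outcome_labels") || is.data.frame(labels)) {
    stopifnot(outcome %in% names(labels))
    setNames(as.logical(labels[[outcome]]), labels$case_id)
  } else {
    stopifnot(is.logical(labels), !is.null(names(labels)))
    labels
  }
}

#' Select the quality threshold that best separates outcomes
#'
#' Runs [qt_cluster()] over a grid of candidate thresholds and scores
#' each clustering by [cluster_separation()] — the chi-square separation
#' between the behaviour strata and the cases reporting versus not
#' reporting the outcome. The chosen threshold attains the maximal
#' score, with ties broken toward the smallest threshold.
#'
#' @param d a [distance_matrix()].
#' @param labels outcome labels (see [cluster_separation()]).
#' @param outcome outcome column when `labels` is a data frame.
#' @param grid candidate thresholds; default the deciles (10%..90%) of
#'   the off-diagonal distance distribution.
#' @param min_size smallest acceptable cluster; default 5.
#' @return object of class `threshold_selection`: list with `grid`,
#'   `scores`, `chosen` (threshold value) and `clustering` (the
#'   [qt_cluster()] result at the chosen threshold).
#' @export
select_threshold <- function(d, labels, outcome = "vulnerable",
                             grid = NULL, min_size = 5L) {
  if (is.null(grid)) {
    off <- d[lower.tri(d)]
    grid <- unname(quantile(off, probs = seq(0.1, 0.9, by = 0.1)))
  }
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  grid <- sort(unique(grid))
  scores <- vapply(grid, function(t) {
    cluster_separation(qt_cluster(d, t, min_size), labels, outcome)
  }, numeric(1))
  chosen <- grid[which.max(scores)]   # first max = smallest threshold
  structure(list(grid = grid, scores = scores, chosen = chosen,
                 clustering = qt_cluster(d, chosen, min_size)),
            class = "threshold_selection")
}

#' Export a clustering result as JSON
#'
#' @param clustering a [qt_cluster()] result.
#' @param selection optionally, the [select_threshold()] object whose
#'   grid and scores should be embedded.
#' @return JSON text.
#' @export
export_clustering_json <- function(clustering, selection = NULL) {
  obj <- list(threshold = clustering$threshold,
              min_size = clustering$min_size,
              clusters = clustering$clusters,
              outliers = clustering$outliers)
  if (!is.null(selection)) {
    obj$threshold_grid <- selection$grid
    obj$separation_scores <- selection$scores
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}
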