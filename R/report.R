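#' Cohort share table
#'
#' Tabulates group sizes with their percentage of a cohort total, the
#' layout used to report behaviour-group memberships. Percentages are
#' always computed from the counts (one-decimal rounding), never copied
#' from elsewhere. The total defaults to the sum of the counts but can
#' be set explicitly when the groups do not exhaust the cohort (e.g.
#' clustered patients with outliers excluded from the rows).
#'
#' @param counts named integer vector of group sizes.
#' @param total cohort size the percentages refer to; default
#'   `sum(counts)`.
#' @return data frame with columns `group`, `n`, `pct` (one decimal),
#'   with the total stored in `attr(, "total")`.
#' @examples
#' cohort_share_table(c(medium_to_active = 42, active = 24), total = 121)
#' @export
cohort_share_table <- function(counts, total = sum(counts)) {
  stopifnot(!is.null(names(counts)), all(counts >= 0), total > 0)
  out <- data.frame(group = names(counts), n = as.integer(counts),
                    pct = round(100 * as.integer(counts) / total, 1),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  out
}

#' Cluster membership shares of a clustering result
#'
#' @param clustering a [qt_cluster()] result.
#' @param total cohort size; default clustered members plus outliers.
#' @param include_outliers add an `outliers` row; default `TRUE`.
#' @return a [cohort_share_table()] data frame.
#' @export
clustering_share_table <- function(clustering, total = NULL,
                                   include_outliers = TRUE) {
  counts <- setNames(lengths(clustering$clusters),
                     paste0("cluster_", seq_along(clustering$clusters)))
  if (include_outliers) {
    counts <- c(counts, outliers = length(clustering$outliers))
  }
  if (is.null(total)) {
    total <- sum(lengths(clustering$clusters)) +
      length(clustering$outliers)
  }
  cohort_share_table(counts, total)
}

#' Demographic summary per country
#'
#' Counts patients, women and men per country and overall, with mean age
#' and standard deviation, in the usual participant-description layout.
#'
#' @param patients patients data frame with `country`, `sex`, `age`.
#' @return data frame with one row per country plus a `Total` row.
#' @export
demographic_summary <- function(patients) {
  one <- function(p, label) {
    data.frame(country = label, total = nrow(p),
               mean_age = round(mean(p$age), 2),
               sd_age = round(stats::sd(p$age), 2),
               women = sum(p$sex == "F"), men = sum(p$sex == "M"),
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(patients$country)), function(ct) {
    one(patients[patients$country == ct, , drop = FALSE], ct)
  })
  do.call(rbind, c(parts, list(one(patients, "Total"))))
}
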