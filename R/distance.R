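#' Aligned heuristic distance between daily state sequences
#'
#' Dissimilarity between two ordinal behaviour-state sequences based on
#' global sequence alignment: substituting one state for another costs
#' the ordinal gap `|i - j| / (K - 1)` (adjacent states 0.5, extreme
#' states 1 for `K = 3`), an insertion or deletion costs `gap_cost`, and
#' the minimal total alignment cost is normalised by the longer sequence
#' length. The result lies in `[0, 1]`, is symmetric, and is 0 exactly
#' for identical sequences. The default gap cost of 0.75 sits between
#' the adjacent and extreme substitution costs, so gaps are usable but
#' never free.
#'
#' @param a,b non-empty character vectors of state labels drawn from
#'   `categories`.
#' @param categories the ordered category set shared by both sequences;
#'   defaults to the union of states observed in `a` and `b` in the
#'   activity/sleep state orders when recognised.
#' @param gap_cost insertion/deletion cost; default 0.75.
#' @return a single distance in `[0, 1]`.
#' @examples
#' trace_distance(c("sedentary"), c("active"))                # 1
#' trace_distance(c("sedentary", "medium"), c("sedentary"))   # 0.375
#' @export
trace_distance <- function(a, b, categories = NULL, gap_cost = 0.75) {
  if (!length(a) || !length(b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  a <- as.character(a)
  b <- as.character(b)
  if (is.null(categories)) categories <- infer_categories(c(a, b))
  ia <- match(a, categories)
  ib <- match(b, categories)
  if (anyNA(ia) || anyNA(ib)) {
    stop("sequences contain states outside the category set: ",
         paste(setdiff(c(a, b), categories), collapse = ", "),
         call. = FALSE)
  }
  .align_distance_cpp(ia - 1L, ib - 1L, length(categories), gap_cost)
}

infer_categories <- function(states) {
  for (known in list(act_states, slp_states)) {
    if (all(states %in% known)) return(known)
  }
  sort(unique(states))
}

#' Pairwise distance matrix over the traces of a log
#'
#' Computes the aligned heuristic distance between every pair of cases'
#' daily state sequences for one activity. Each pair is computed once,
#' so the matrix is exactly symmetric with a zero diagonal.
#'
#' @param seqs named list of state sequences, as from
#'   [state_sequences()].
#' @param categories ordered category set (default inferred).
#' @param gap_cost insertion/deletion cost; default 0.75.
#' @return symmetric numeric matrix with case ids as dimnames, entries
#'   in `[0, 1]`, of class `dist_matrix`.
#' @export
distance_matrix <- function(seqs, categories = NULL, gap_cost = 0.75) {
  if (length(seqs) < 2L) {
    stop("need at least two traces to compute distances", call. = FALSE)
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must be uniquely named by case id", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- infer_categories(unlist(seqs, use.names = FALSE))
  }
  coded <- lapply(seqs, function(s) {
    i <- match(as.character(s), categories)
    if (anyNA(i) || !length(i)) {
      stop("empty sequence or states outside the category set",
           call. = FALSE)
    }
    i - 1L
  })
  d <- .distance_matrix_cpp(coded, length(categories), gap_cost)
  dimnames(d) <- list(names(seqs), names(seqs))
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Write and read a distance matrix as CSV
#'
#' Plain CSV with case ids as header row and first column.
#'
#' @param d a [distance_matrix()].
#' @param path file path.
#' @export
write_distance_matrix <- function(d, path) {
  out <- data.frame(case_id = rownames(d), unclass(d),
                    check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  class(m) <- c("dist_matrix", class(m))
  m
}
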