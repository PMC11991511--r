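#' Discover a directly-follows process model from visit sequences
#'
#' Each visit sequence contributes one path `@Start -> v1 -> ... -> vk ->
#' @End` to the model. Edge counts are exact tallies of directly-follows
#' transitions across sequences, and each state node records the number
#' of visits and the median visit duration in days (the median of an
#' even-length set is the midpoint of the central pair). Run-length
#' collapsing upstream guarantees no self-loop edges.
#'
#' Flow is conserved by construction: the outflow of `@Start` and the
#' inflow of `@End` both equal the number of sequences, and every state
#' node's inflow equals its outflow.
#'
#' @param visit_seqs list of visit data frames (`state`, `duration`), as
#'   produced by [visit_sequences()].
#' @return object of class `process_model` with elements `nodes` (data
#'   frame `label`, `visit_count`, `median_duration`), `edges` (data
#'   frame `from`, `to`, `count`), `n_traces` and `heat` (empty until
#'   [heatmap_scores()] is applied).
#' @examples
#' v <- data.frame(state = c("sedentary", "medium"), duration = c(2, 1))
#' discover_model(list(v))
#' @export
discover_model <- function(visit_seqs) {
  if (!length(visit_seqs)) stop("no visit sequences given", call. = FALSE)
  states <- character(0)
  durations <- numeric(0)
  from <- character(0)
  to <- character(0)
  for (v in visit_seqs) {
    if (!nrow(v)) stop("empty visit sequence", call. = FALSE)
    s <- as.character(v$state)
    if (any(s[-1L] == s[-length(s)])) {
      stop("self-transition in visit sequence; collapse runs first",
           call. = FALSE)
    }
    states <- c(states, s)
    durations <- c(durations, v$duration)
    path <- c("@Start", s, "@End")
    from <- c(from, path[-length(path)])
    to <- c(to, path[-1L])
  }
  node_labels <- sort(unique(states))
  nodes <- data.frame(
    label = c("@Start", node_labels, "@End"),
    visit_count = c(NA_integer_,
                    as.integer(table(factor(states, node_labels))),
                    NA_integer_),
    median_duration = c(NA_real_,
                        vapply(node_labels, function(l) {
                          median(durations[states == l])
                        }, numeric(1)),
                        NA_real_),
    stringsAsFactors = FALSE
  )
  ek <- paste(from, to, sep = " -> ")
  tab <- table(ek)
  parts <- strsplit(names(tab), " -> ", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  model <- structure(list(nodes = nodes, edges = edges,
                          n_traces = length(visit_seqs),
                          heat = NULL),
                     class = "process_model")
  stopifnot(flow_conserved(model))
  model
}

#' Check flow conservation of a process model
#'
#' @param model a [discover_model()] result.
#' @return `TRUE` if `@Start` outflow and `@End` inflow both equal
#'   `n_traces` and inflow equals outflow at every state node.
#' @export
flow_conserved <- function(model) {
  e <- model$edges
  outflow <- function(l) sum(e$count[e$from == l])
  inflow <- function(l) sum(e$count[e$to == l])
  if (outflow("@Start") != model$n_traces) return(FALSE)
  if (inflow("@End") != model$n_traces) return(FALSE)
  state_labels <- setdiff(model$nodes$label, c("@Start", "@End"))
  all(vapply(state_labels, function(l) inflow(l) == outflow(l), logical(1)))
}

#' Fill heat-map scores of a process model
#'
#' Node scores min-max normalise the median durations over the state
#' nodes (longer median time -> hotter node); edge scores min-max
#' normalise the transition counts (more frequent transition -> hotter
#' arrow). When all values coincide (including a single node or edge)
#' the score falls back to 0.5.
#'
#' @param model a [discover_model()] result.
#' @return the model with `heat` filled: a list with numeric vectors
#'   `nodes` (named by state label, `NA` for `@Start`/`@End`) and
#'   `edges` (named `"from -> to"`), all in `[0, 1]`.
#' @export
heatmap_scores <- function(model) {
  stopifnot(inherits(model, "process_model"))
  minmax <- function(x) {
    if (!length(x)) return(numeric(0))
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  is_state <- !model$nodes$label %in% c("@Start", "@End")
  node_scores <- rep(NA_real_, nrow(model$nodes))
  node_scores[is_state] <- minmax(model$nodes$median_duration[is_state])
  names(node_scores) <- model$nodes$label
  edge_scores <- minmax(model$edges$count)
  names(edge_scores) <- paste(model$edges$from, model$edges$to,
                              sep = " -> ")
  model$heat <- list(nodes = node_scores, edges = edge_scores)
  model
}

heat_colour <- function(score) {
  # green (short / rare) to red (long / frequent)
  s <- pmin(pmax(score, 0), 1)
  sprintf("#%02X%02X40",
          as.integer(round(46 + s * (231 - 46))),
          as.integer(round(204 - s * (204 - 76))))
}

#' Export a process model as Graphviz DOT
#'
#' Renders the heat-mapped directly-follows graph: node fill interpolates
#' green to red with the median-duration score, edge colour with the
#' transition-frequency score, and edges are annotated with their counts.
#' Node statements are emitted in label-sorted order, so identical models
#' yield identical DOT text.
#'
#' @param model a [heatmap_scores()]-filled model.
#' @return a single DOT digraph string.
#' @export
export_dot <- function(model) {
  stopifnot(inherits(model, "process_model"))
  if (is.null(model$heat)) model <- heatmap_scores(model)
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph process_model {",
             "  rankdir=LR;",
             "  node [style=filled, fontname=\"Helvetica\"];")
  nodes <- model$nodes[order(model$nodes$label), , drop = FALSE]
  for (i in seq_len(nrow(nodes))) {
    l <- nodes$label[i]
    if (l %in% c("@Start", "@End")) {
      lines <- c(lines, sprintf("  %s [shape=circle, fillcolor=\"#DDDDDD\"];",
                                q(l)))
    } else {
      lines <- c(lines, sprintf(
        "  %s [shape=box, fillcolor=\"%s\", label=\"%s\\nmedian %g d\"];",
        q(l), heat_colour(model$heat$nodes[[l]]), l,
        nodes$median_duration[i]))
    }
  }
  edges <- model$edges[order(model$edges$from, model$edges$to), ,
                       drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    key <- paste(edges$from[i], edges$to[i], sep = " -> ")
    lines <- c(lines, sprintf(
      "  %s -> %s [color=\"%s\", label=\"%d\"];",
      q(edges$from[i]), q(edges$to[i]),
      heat_colour(model$heat$edges[[key]]), edges$count[i]))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Export and re-import process models as JSON
#'
#' The JSON schema (version 1) is lossless: nodes with visit counts,
#' median durations and heat scores, edges with counts and heat scores,
#' and the trace count. `parse_model_json(export_model_json(m))`
#' reconstructs `m` exactly; models without heat export `null` scores.
#'
#' @param model a `process_model`.
#' @param txt JSON text produced by `export_model_json()`.
#' @return `export_model_json()` a JSON string; `parse_model_json()` a
#'   `process_model`.
#' @export
export_model_json <- function(model) {
  stopifnot(inherits(model, "process_model"))
  nodes <- model$nodes
  node_heat <- if (is.null(model$heat)) {
    rep(NA_real_, nrow(nodes))
  } else {
    unname(model$heat$nodes[nodes$label])
  }
  edge_heat <- if (is.null(model$heat)) {
    rep(NA_real_, nrow(model$edges))
  } else {
    unname(model$heat$edges[paste(model$edges$from, model$edges$to,
                                  sep = " -> ")])
  }
  obj <- list(
    schema_version = 1L,
    n_traces = model$n_traces,
    has_heat = !is.null(model$heat),
    nodes = data.frame(label = nodes$label,
                       visit_count = nodes$visit_count,
                       median_duration = nodes$median_duration,
                       heat = node_heat, stringsAsFactors = FALSE),
    edges = data.frame(from = model$edges$from, to = model$edges$to,
                       count = model$edges$count, heat = edge_heat,
                       stringsAsFactors = FALSE)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname export_model_json
#' @export
parse_model_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  if (!identical(as.integer(obj$schema_version), 1L)) {
    stop("unsupported process-model schema version", call. = FALSE)
  }
  nodes <- obj$nodes
  edges <- obj$edges
  if (!"heat" %in% names(nodes)) nodes$heat <- NA_real_
  if (!"heat" %in% names(edges)) edges$heat <- NA_real_
  if (!"median_duration" %in% names(nodes)) {
    nodes$median_duration <- NA_real_
  }
  nodes$median_duration <- as.numeric(nodes$median_duration)
  nodes$visit_count <- as.integer(nodes$visit_count)
  heat <- NULL
  if (isTRUE(obj$has_heat)) {
    heat <- list(
      nodes = setNames(as.numeric(nodes$heat), nodes$label),
      edges = setNames(as.numeric(edges$heat),
                       paste(edges$from, edges$to, sep = " -> "))
    )
  }
  structure(list(
    nodes = data.frame(label = nodes$label,
                       visit_count = nodes$visit_count,
                       median_duration = nodes$median_duration,
                       stringsAsFactors = FALSE),
    edges = data.frame(from = edges$from, to = edges$to,
                       count = as.integer(edges$count),
                       stringsAsFactors = FALSE),
    n_traces = as.integer(obj$n_traces),
    heat = heat
  ), class = "process_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("<process_model> %d state nodes, %d edges, %d traces\n",
              sum(!x$nodes$label %in% c("@Start", "@End")),
              nrow(x$edges), x$n_traces))
  invisible(x)
}
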