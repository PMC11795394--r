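#' Build an areal adjacency graph from an edge list
#'
#' Constructs the neighbourhood structure used by the intrinsic CAR spatial
#' prior: a symmetric, self-loop-free graph over areal units (districts),
#' together with its connected components. Disconnected maps — e.g. several
#' countries with no shared borders, or islands — are first-class: every
#' component is labelled and downstream priors apply one sum-to-zero
#' constraint per component.
#'
#' @param edges A data frame with two columns (`from`, `to`, any names) whose
#'   values are area identifiers, one row per shared border. Order within a
#'   row is irrelevant; duplicate and mirrored rows are collapsed.
#' @param area_ids Character vector of all area identifiers, in the order that
#'   defines the rows/columns of every structure matrix. Areas absent from
#'   `edges` become isolated singleton components.
#' @return An object of class `areal_graph`: a list with `n_areas`, `area_ids`,
#'   `edges` (two-column integer matrix of area indices, `i < j`),
#'   `component` (integer label per area, `1..n_components`), and
#'   `n_components`.
#' @examples
#' g <- areal_graph(data.frame(from = "a", to = "b"), area_ids = c("a", "b", "c"))
#' g$n_components # 2: {a,b} and the isolate {c}
#' @export
areal_graph <- function(edges, area_ids) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    abort("`area_ids` contains duplicate identifiers.")
  }
  S <- length(area_ids)
  if (S < 1L) abort("At least one area is required.")
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    if (ncol(edges) < 2L) abort("`edges` needs two columns of area ids.")
    a <- match(as.character(edges[[1]]), area_ids)
    b <- match(as.character(edges[[2]]), area_ids)
    bad <- is.na(a) | is.na(b)
    if (any(bad)) {
      unknown <- unique(c(as.character(edges[[1]])[is.na(a)],
                          as.character(edges[[2]])[is.na(b)]))
      abort(sprintf("Unknown area id(s) in edge list: %s",
                    paste(unknown, collapse = ", ")))
    }
    if (any(a == b)) abort("Self-edges are not allowed in an areal graph.")
    em <- cbind(pmin(a, b), pmax(a, b))
    em <- unique(em)
    em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  } else {
    em <- matrix(integer(0), ncol = 2)
  }
  comp <- label_components(S, em)
  structure(
    list(
      n_areas = S,
      area_ids = area_ids,
      edges = em,
      component = comp,
      n_components = max(comp)
    ),
    class = "areal_graph"
  )
}

# Breadth-first connected-component labelling; labels are 1..C in order of
# first appearance so they are stable under the area ordering.
label_components <- function(S, edges) {
  adj <- vector("list", S)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(S)
  label <- 0L
  for (s in seq_len(S)) {
    if (comp[s] != 0L) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue) > 0L) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Connected components of an areal graph
#'
#' @param graph An [areal_graph()].
#' @return A tibble with one row per area: `area_id`, `component` (integer
#'   label, `1..n_components`), and `component_size`.
#' @export
connected_components <- function(graph) {
  check_areal_graph(graph)
  sizes <- tabulate(graph$component)
  tibble::tibble(
    area_id = graph$area_ids,
    component = graph$component,
    component_size = sizes[graph$component]
  )
}

check_areal_graph <- function(graph) {
  if (!inherits(graph, "areal_graph")) {
    abort("Expected an `areal_graph` object; see `areal_graph()`.")
  }
  invisible(graph)
}

#' Number of neighbours of each area
#' @param graph An [areal_graph()].
#' @return Integer vector of neighbour counts in `area_ids` order.
#' @export
neighbour_counts <- function(graph) {
  check_areal_graph(graph)
  d <- integer(graph$n_areas)
  if (nrow(graph$edges) > 0L) {
    tab <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n_areas)
    d <- tab
  }
  d
}

# Dense 0/1 adjacency matrix in area order.
adjacency_matrix <- function(graph) {
  S <- graph$n_areas
  A <- matrix(0, S, S, dimnames = list(graph$area_ids, graph$area_ids))
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' @export
print.areal_graph <- function(x, ...) {
  sizes <- tabulate(x$component)
  cat(sprintf("<areal_graph> %d areas, %d edges, %d component(s)\n",
              x$n_areas, nrow(x$edges), x$n_components))
  cat("  component sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Read an edge list from a delimited text file
#'
#' Accepts comma- or tab-separated files with two id columns (header optional,
#' detected by whether the first row's ids reappear in `area_ids`).
#'
#' @param path Path to the edge-list file.
#' @param area_ids Optional id universe; if omitted, ids are collected from
#'   the file itself.
#' @return An [areal_graph()].
#' @export
read_edges <- function(path, area_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) trimws(p[1:2])))
  # Drop a header row if its entries never occur again as ids.
  if (nrow(m) > 1L) {
    rest <- unique(c(m[-1, 1], m[-1, 2]))
    if (!(m[1, 1] %in% rest) && !(m[1, 2] %in% rest) && is.null(area_ids)) {
      m <- m[-1, , drop = FALSE]
    } else if (!is.null(area_ids) && !(m[1, 1] %in% area_ids)) {
      m <- m[-1, , drop = FALSE]
    }
  }
  ids <- area_ids %||% sort(unique(c(m[, 1], m[, 2])))
  areal_graph(data.frame(from = m[, 1], to = m[, 2]), area_ids = ids)
}

#' Write an edge list as CSV
#' @param graph An [areal_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  check_areal_graph(graph)
  df <- data.frame(
    from = graph$area_ids[graph$edges[, 1]],
    to = graph$area_ids[graph$edges[, 2]]
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' Summarize an areal graph as JSON
#'
#' @param graph An [areal_graph()].
#' @param path Optional path; when given the JSON is written there.
#' @return The summary list (invisibly when writing).
#' @export
graph_summary <- function(graph, path = NULL) {
  check_areal_graph(graph)
  out <- list(
    n_areas = graph$n_areas,
    n_edges = nrow(graph$edges),
    n_components = graph$n_components,
    component_sizes = as.integer(tabulate(graph$component))
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
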