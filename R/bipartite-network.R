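# Two-mode network analysis of the ailment-category x species incidence
# structure: matrix construction, UCINET DL interchange, degree
# centralities, the one-mode category projection, force-directed layout
# and modularity-based grouping of categories.

#' Build the ailment-category by species incidence matrix
#'
#' Rows are ailment categories, columns species, entries deduplicated
#' use-report counts. Row sums equal the per-category `nur` and column
#' sums the per-species `n` of the consensus statistics, so the network
#' and index views of a dataset are conserved by construction.
#'
#' @param reports A categorised use-report tibble.
#' @param mode `"category"` (default) or `"ailment"` to use the raw
#'   free-text ailments as row nodes instead of the resolved categories.
#' @return An integer matrix with row and column dimnames, labels sorted
#'   lexicographically.
#' @export
build_incidence <- function(reports, mode = c("category", "ailment")) {
  mode <- match.arg(mode)
  if (nrow(reports) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = 0,
                  dimnames = list(character(0), character(0))))
  }
  row_var <- if (mode == "category") reports$category else reports$ailment
  if (anyNA(row_var)) {
    stop("reports must be categorised first; see resolve_categories()",
         call. = FALSE)
  }
  tab <- table(factor(row_var), factor(reports$species_id))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(sort(unique(row_var)),
                              sort(unique(reports$species_id))))
  stopifnot(sum(m) == nrow(reports))
  m
}

#' Binary view of an incidence matrix
#'
#' @param matrix An incidence matrix.
#' @return The same matrix with entries replaced by 0/1 presence.
#' @export
binary_incidence <- function(matrix) {
  (matrix > 0) + 0L
}

#' Write a matrix in UCINET DL full-matrix format
#'
#' Emits the plain-text DL dialect consumed by UCINET and NetDraw: a
#' `dl nr=<R> nc=<C> format=fullmatrix` header, quoted row and column
#' label blocks one label per line, and a `data:` block of space-separated
#' integers, with LF line endings.
#'
#' @param matrix A labelled non-empty numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ucinet_dl <- function(matrix, path) {
  if (nrow(matrix) == 0 || ncol(matrix) == 0) {
    stop("cannot write an empty matrix in DL format", call. = FALSE)
  }
  lines <- c(
    sprintf("dl nr=%d nc=%d format=fullmatrix", nrow(matrix), ncol(matrix)),
    "row labels:",
    sprintf('"%s"', rownames(matrix)),
    "col labels:",
    sprintf('"%s"', colnames(matrix)),
    "data:",
    apply(matrix, 1, paste, collapse = " ")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a UCINET DL full-matrix file
#'
#' Parses the dialect written by [write_ucinet_dl()].
#'
#' @param path Path to a DL file.
#' @return An integer matrix with dimnames.
#' @export
read_ucinet_dl <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  m <- regmatches(header,
                  regexec("^dl nr=(\\d+) nc=(\\d+) format=fullmatrix$",
                          header))[[1]]
  if (length(m) != 3) {
    stop("not a DL fullmatrix file: unexpected header '", header, "'",
         call. = FALSE)
  }
  nr <- as.integer(m[2]); nc <- as.integer(m[3])
  unquote <- function(x) gsub('^"|"$', "", x)
  i_row <- which(lines == "row labels:")
  i_col <- which(lines == "col labels:")
  i_dat <- which(lines == "data:")
  if (length(i_row) != 1 || length(i_col) != 1 || length(i_dat) != 1) {
    stop("malformed DL file: missing label or data block", call. = FALSE)
  }
  row_labels <- unquote(lines[(i_row + 1):(i_row + nr)])
  col_labels <- unquote(lines[(i_col + 1):(i_col + nc)])
  data_lines <- lines[(i_dat + 1):(i_dat + nr)]
  values <- lapply(strsplit(trimws(data_lines), "\\s+"), as.integer)
  if (any(lengths(values) != nc)) {
    stop("malformed DL file: data row width differs from nc", call. = FALSE)
  }
  matrix(as.integer(unlist(values)), nrow = nr, byrow = TRUE,
         dimnames = list(row_labels, col_labels))
}

#' Two-mode degree centrality
#'
#' Degree for every node of both modes of the bipartite graph: unweighted
#' degree counts nonzero incident cells, weighted degree is the marginal
#' sum. Normalised degree divides by the size of the opposite mode
#' (unweighted variant only).
#'
#' @param matrix An incidence matrix.
#' @param weighted Use entry weights instead of presence (default FALSE).
#' @param normalised Divide unweighted degree by opposite-mode size.
#' @return A tibble with columns `node`, `mode`
#'   (`"category"`/`"species"`), `degree`.
#' @export
two_mode_degree <- function(matrix, weighted = FALSE, normalised = FALSE) {
  b <- if (weighted) matrix else binary_incidence(matrix)
  deg_rows <- rowSums(b)
  deg_cols <- colSums(b)
  if (normalised) {
    if (weighted) stop("normalisation applies to unweighted degree only",
                       call. = FALSE)
    deg_rows <- deg_rows / ncol(matrix)
    deg_cols <- deg_cols / nrow(matrix)
  }
  tibble::tibble(
    node = c(rownames(matrix), colnames(matrix)),
    mode = rep(c("category", "species"), c(nrow(matrix), ncol(matrix))),
    degree = as.numeric(c(deg_rows, deg_cols))
  )
}

#' Project the two-mode network onto ailment categories
#'
#' One-mode co-membership projection on the binary view: entry (a, b)
#' counts the species cited in both categories a and b; the diagonal holds
#' each category's distinct-species count `nt`. Shared species are a set
#' notion, so weights do not enter the projection.
#'
#' @param matrix An incidence matrix.
#' @return A symmetric integer matrix over categories.
#' @export
project_categories <- function(matrix) {
  b <- binary_incidence(matrix)
  p <- b %*% t(b)
  storage.mode(p) <- "integer"
  p
}

#' Seeded force-directed layout of the bipartite graph
#'
#' Embeds both modes with the Fruchterman-Reingold algorithm (edge weights
#' as attraction strengths), then rescales coordinates to the unit box.
#' Deterministic for a given seed and iteration count.
#'
#' @param matrix A non-empty incidence matrix.
#' @param seed Integer seed (required).
#' @param iterations Iterations of the force simulation (default 500).
#' @return A tibble with columns `node`, `mode`, `x`, `y`.
#' @export
layout_spring <- function(matrix, seed, iterations = 500) {
  if (nrow(matrix) == 0 || ncol(matrix) == 0) {
    stop("cannot lay out an empty graph", call. = FALSE)
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  g <- igraph::graph_from_biadjacency_matrix(matrix, weighted = TRUE)
  coords <- withr::with_seed(seed, {
    igraph::layout_with_fr(
      g, niter = iterations,
      weights = igraph::E(g)$weight)
  })
  rng <- apply(coords, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  scaled <- sweep(sweep(coords, 2, rng[1, ]), 2, span, "/")
  tibble::tibble(
    node = igraph::V(g)$name,
    mode = ifelse(igraph::V(g)$type, "species", "category"),
    x = scaled[, 1],
    y = scaled[, 2]
  )
}

#' Group ailment categories by modularity maximisation
#'
#' Partitions the weighted category projection into groups by greedy
#' modularity maximisation (agglomerative fast-greedy). The diagonal is
#' dropped before clustering. The partition, not any visual layout, is
#' the reproducible contract for grouping.
#'
#' @param projection A symmetric category projection matrix (see
#'   [project_categories()]).
#' @param seed Integer seed; the algorithm is deterministic but the seed
#'   is fixed around it so alternative methods remain reproducible.
#' @param method Currently `"fast_greedy"` only.
#' @return A list with `membership` (tibble: `category`, `group_id`,
#'   group ids contiguous from 1 in order of first appearance),
#'   `modularity` (numeric score) and `n_groups`.
#' @export
detect_groups <- function(projection, seed = 1L, method = "fast_greedy") {
  method <- match.arg(method, "fast_greedy")
  cats <- rownames(projection)
  if (nrow(projection) < 2) {
    return(list(
      membership = tibble::tibble(category = cats,
                                  group_id = rep(1L, length(cats))),
      modularity = NA_real_, n_groups = min(1L, length(cats))))
  }
  adj <- projection
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  comm <- withr::with_seed(seed, igraph::cluster_fast_greedy(g))
  raw <- igraph::membership(comm)
  # a partition with non-positive modularity carries no community
  # structure (it ties the trivial single community at Q = 0)
  if (igraph::modularity(comm) <= 1e-12) raw[] <- 1L
  relabel <- match(raw, unique(raw))  # contiguous ids by first appearance
  list(
    membership = tibble::tibble(category = cats,
                                group_id = as.integer(relabel)),
    modularity = max(igraph::modularity(comm), 0),
    n_groups = length(unique(relabel))
  )
}

#' Export the bipartite network as GraphML
#'
#' @param matrix An incidence matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(matrix, path) {
  g <- igraph::graph_from_biadjacency_matrix(matrix, weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the bipartite network as a weighted edge list
#'
#' Tab-separated columns `source`, `target`, `weight`, one edge per
#' nonzero cell, rows in row-major matrix order.
#'
#' @param matrix An incidence matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(matrix, path) {
  idx <- which(t(matrix) > 0)
  col_i <- (idx - 1L) %% ncol(matrix) + 1L
  row_i <- (idx - 1L) %/% ncol(matrix) + 1L
  df <- tibble::tibble(
    source = rownames(matrix)[row_i],
    target = colnames(matrix)[col_i],
    weight = matrix[cbind(row_i, col_i)]
  )
  readr::write_tsv(df, path)
  invisible(path)
}
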