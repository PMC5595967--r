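# Thresholded chemical-similarity networks over hit compounds, from
# user-supplied bit fingerprints (e.g. FP2). Fingerprints are inputs, not
# computed here: similarity values depend on the fingerprinting
# implementation and structure source, so decoupling keeps this stage
# testable offline.

#' Tanimoto similarity between two bit fingerprints
#'
#' `|A intersect B| / |A union B|` over set-bit positions; defined as 0 when
#' both sets are empty.
#'
#' @param a,b Integer vectors of set-bit positions.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
tanimoto <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  uni <- length(union(a, b))
  if (uni == 0) return(0)
  length(intersect(a, b)) / uni
}

check_bit_fps <- function(fps) {
  stopifnot(is.data.frame(fps),
            all(c("compound", "nbits", "bits") %in% names(fps)))
  if (dplyr::n_distinct(fps$nbits) > 1) {
    stop("fingerprint length (nbits) mismatch across compounds", call. = FALSE)
  }
  ok <- purrr::map2_lgl(fps$bits, fps$nbits,
                        ~ all(.x >= 0 & .x < .y))
  if (!all(ok)) {
    stop("bit positions out of range for: ",
         paste(fps$compound[!ok], collapse = ", "), call. = FALSE)
  }
  invisible(fps)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps Tibble with columns `compound`, `nbits` and `bits`
#'   (list-column of set-bit positions); see [read_bit_fingerprints()].
#' @return Symmetric similarity matrix with unit diagonal, labelled by
#'   compound.
#' @export
tanimoto_matrix <- function(fps) {
  check_bit_fps(fps)
  n <- nrow(fps)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- tanimoto(fps$bits[[i]], fps$bits[[j]])
    }
  }
  dimnames(m) <- list(fps$compound, fps$compound)
  m
}

#' Thresholded chemical-similarity network
#'
#' Undirected simple graph with one node per compound and an edge wherever
#' the pairwise Tanimoto similarity is at least `threshold`; edge weight is
#' the similarity. Isolated nodes are retained.
#'
#' @param fps Bit-fingerprint tibble (see [tanimoto_matrix()]).
#' @param threshold Similarity threshold in \[0, 1\] (default 0.5).
#' @return An [igraph::graph] with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
similarity_network <- function(fps, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (nrow(fps) < 2) stop("need at least 2 fingerprints", call. = FALSE)
  m <- tanimoto_matrix(fps)
  adj <- (m >= threshold) * m
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g
}

#' Read a bit-fingerprint file
#'
#' One line per compound: `name,nbits,pos1,pos2,...` (comma-separated set-bit
#' positions, possibly none).
#'
#' @param path File path.
#' @return Tibble `compound`, `nbits`, `bits` (list-column).
#' @export
read_bit_fingerprints <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::map(lines, function(l) {
    parts <- trimws(strsplit(l, ",")[[1]])
    if (length(parts) < 2) {
      stop("malformed fingerprint line: ", l, call. = FALSE)
    }
    bits <- if (length(parts) > 2) as.integer(parts[-(1:2)]) else integer(0)
    tibble::tibble(compound = parts[1], nbits = as.integer(parts[2]),
                   bits = list(bits))
  })
  fps <- dplyr::bind_rows(parsed)
  check_bit_fps(fps)
  fps
}

#' Write a similarity network as GraphML
#'
#' @param g An igraph network (see [similarity_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a similarity network as SIF (Cytoscape)
#'
#' Lines `source sim target`; isolated nodes are written as bare names so
#' Cytoscape keeps them.
#'
#' @inheritParams write_graphml
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el) > 0) paste(el[, 1], "sim", el[, 2]) else character(0)
  iso <- setdiff(igraph::V(g)$name, unique(as.vector(el)))
  writeLines(c(lines, iso), path)
  invisible(path)
}
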