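#' Construct a gene network
#'
#' Undirected weighted gene graph. Node attributes carry the first prominent
#' phenotype (for succession networks) and a core/variable role (for
#' per-time-point network series).
#'
#' @param nodes character vector of gene ids, or data.frame with columns
#'   `gene` and optionally `first_phenotype`, `role`.
#' @param edges data.frame with columns `from`, `to`, `weight` (positive
#'   integers); no self-loops.
#' @return object of class `gene_network`: list(nodes, edges).
#' @export
gene_network <- function(nodes, edges = NULL) {
  if (is.character(nodes))
    nodes <- data.frame(gene = nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$first_phenotype)) nodes$first_phenotype <- NA_character_
  if (is.null(nodes$role)) nodes$role <- NA_character_
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) abort_value("self-loops are not allowed")
    if (any(edges$weight < 1L)) abort_value("edge weights must be >= 1")
    missing <- setdiff(c(edges$from, edges$to), nodes$gene)
    if (length(missing) > 0L)
      abort_value(sprintf("edge endpoint '%s' is not a node", missing[1L]))
  }
  structure(list(nodes = nodes[, c("gene", "first_phenotype", "role")],
                 edges = edges[, c("from", "to", "weight")]),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Co-phenotype gene network at one time point
#'
#' Nodes are the genes with at least one passing event at time `t`; two
#' genes are linked iff they share at least one passing phenotype at `t`,
#' with edge weight = the number of shared passing phenotypes (for
#' condition-style data: the number of conditions to which both genes
#' respond). The network is recomputed per time point. Networks of 500 or
#' more nodes raise a capacity error (they are impractical to lay out and
#' read) unless `force_large = TRUE`.
#'
#' @param mask logical gene x phenotype x time array from [build_mask()].
#' @param t 1-based time point.
#' @param max_nodes node cap (default 500, exclusive: the node count must
#'   stay below it).
#' @param force_large bypass the cap.
#' @return a [gene_network].
#' @export
cophenotype_network <- function(mask, t, max_nodes = 500L,
                                force_large = FALSE) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (t < 1L || t > dim(mask)[3L]) abort_value("time point out of range")
  M <- matrix(mask[, , t], nrow = dim(mask)[1L],
              dimnames = dimnames(mask)[1:2])
  active <- rowSums(M) > 0L
  n_active <- sum(active)
  if (n_active >= max_nodes && !force_large)
    abort_capacity(sprintf(
      "network has %d nodes; only networks with less than %d nodes are generated",
      n_active, max_nodes))
  M <- M[active, , drop = FALSE]
  genes <- rownames(M)
  shared <- tcrossprod(M * 1L)          # shared passing-phenotype counts
  idx <- which(upper.tri(shared) & shared >= 1L, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
                      weight = as.integer(shared[idx]),
                      stringsAsFactors = FALSE)
  gene_network(genes, edges)
}

#' Synchronous-succession gene network
#'
#' Two genes are linked iff their full prominence profiles are identical —
#' the exact same phenotypic succession over every time point, including
#' agreeing on when no phenotype is prominent. Genes with no partner are
#' dropped, so every connected component is a clique of profile-identical
#' genes. Each node is annotated with its first prominent phenotype.
#'
#' @param profiles a `prominence_profile` from [derive_prominence()].
#' @return a [gene_network] (edge weights all 1).
#' @export
synchronous_network <- function(profiles) {
  stopifnot(inherits(profiles, "prominence_profile"))
  key <- apply(profiles, 1L, function(r)
    paste(ifelse(is.na(r), "\r", r), collapse = "\n"))
  groups <- split(rownames(profiles), key)
  groups <- groups[lengths(groups) >= 2L]
  nodes <- unlist(groups, use.names = FALSE)
  edges <- do.call(rbind, lapply(groups, function(g) {
    cmb <- utils::combn(sort(g), 2L)
    data.frame(from = cmb[1L, ], to = cmb[2L, ], weight = 1L,
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0), stringsAsFactors = FALSE)
  first_phen <- vapply(nodes, function(g) {
    r <- profiles[g, ]
    nz <- which(!is.na(r))
    if (length(nz) == 0L) NA_character_ else r[nz[1L]]
  }, character(1))
  nodes_df <- data.frame(gene = nodes, first_phenotype = unname(first_phen),
                         role = NA_character_, stringsAsFactors = FALSE)
  nodes_df <- nodes_df[order(nodes_df$gene), , drop = FALSE]
  rownames(nodes_df) <- NULL
  gene_network(nodes_df, edges)
}

#' Core/variable classification over a series of per-time networks
#'
#' A gene is `core` iff it is a node in every per-time-point network, and
#' `variable` otherwise (present at some time points only).
#'
#' @param networks list of [gene_network], one per time point (>= 1).
#' @return named character vector gene -> "core"/"variable", covering the
#'   union of all node sets.
#' @export
core_variable_split <- function(networks) {
  if (length(networks) == 0L) abort_value("at least one network required")
  sets <- lapply(networks, function(nw) nw$nodes$gene)
  all_genes <- sort(unique(unlist(sets)))
  core <- Reduce(intersect, sets)
  stats::setNames(ifelse(all_genes %in% core, "core", "variable"), all_genes)
}

#' Annotate a network's nodes with roles from a series
#'
#' @param network a [gene_network] whose nodes are covered by the role map.
#' @param roles named vector from [core_variable_split()].
#' @return the network with `role` filled in.
#' @export
set_node_roles <- function(network, roles) {
  stopifnot(inherits(network, "gene_network"))
  network$nodes$role <- unname(roles[network$nodes$gene])
  network
}

#' Deterministic force-directed layout
#'
#' Fruchterman–Reingold layout (all-pairs repulsion, spring attraction along
#' edges) run for a fixed number of iterations from seeded random start
#' coordinates, then rescaled to the unit square. Identical
#' (network, seed, iterations) always give identical coordinates. A single
#' node is placed at (0.5, 0.5).
#'
#' @param network a non-empty [gene_network].
#' @param seed integer seed for the start coordinates.
#' @param iterations iteration count (default 200).
#' @return data.frame (gene, x, y) with coordinates in `[0, 1]^2`.
#' @export
force_layout <- function(network, seed = 1L, iterations = 200L) {
  stopifnot(inherits(network, "gene_network"))
  n <- nrow(network$nodes)
  if (n == 0L) abort_value("network has no nodes")
  if (n == 1L)
    return(data.frame(gene = network$nodes$gene, x = 0.5, y = 0.5,
                      stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$gene)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  start <- matrix(stats::runif(2L * n, -1, 1), ncol = 2L)
  w <- if (nrow(network$edges) > 0L) network$edges$weight else NULL
  xy <- igraph::layout_with_fr(g, coords = start, niter = as.integer(iterations),
                               weights = w)
  rescale01 <- function(v) {
    r <- range(v)
    if (diff(r) < .Machine$double.eps) rep(0.5, length(v))
    else (v - r[1L]) / diff(r)
  }
  data.frame(gene = network$nodes$gene,
             x = rescale01(xy[, 1L]), y = rescale01(xy[, 2L]),
             stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Highlight and size annotation terms against active genes
#'
#' A term is highlighted iff its member gene set intersects the active set
#' (e.g. the genes behind the connections at the current time point); its
#' size value is the number of members present in the dataset (node size is
#' drawn proportional to it).
#'
#' @param annotation an `annotation_network` from
#'   [parse_annotation_network()].
#' @param active_genes character vector of currently active genes.
#' @param dataset_genes the dataset's gene universe.
#' @return data.frame (id, highlighted, size).
#' @export
go_highlight <- function(annotation, active_genes, dataset_genes) {
  stopifnot(inherits(annotation, "annotation_network"))
  data.frame(
    id = annotation$terms$id,
    highlighted = vapply(annotation$terms$members, function(m)
      length(intersect(m, active_genes)) > 0L, logical(1)),
    size = vapply(annotation$terms$members, function(m)
      length(intersect(m, dataset_genes)), integer(1)),
    stringsAsFactors = FALSE)
}
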