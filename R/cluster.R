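#' MCL parameters
#'
#' Parameters of the Markov clustering stage. The default inflation of 4
#' (rather than MCL's customary 2) deliberately yields finer clusters, so
#' that transcript isoforms resist collapsing into a single orthogroup.
#'
#' @param inflation entrywise-power inflation (> 1); higher = more, smaller
#'   clusters.
#' @param expansion matrix-power expansion (integer >= 2).
#' @param prune_threshold entries below this are dropped after inflation.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the max entry change.
#' @return An `mcl_params` object.
#' @export
mcl_params <- function(inflation = 4, expansion = 2L, prune_threshold = 1e-5,
                       max_iter = 100L, tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2L, max_iter >= 1L)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

#' Canonical k-mer containment similarity between two sequences
#'
#' Max-containment of canonical k-mer sets:
#' `|K(a) n K(b)| / min(|K(a)|, |K(b)|)`. Containment (rather than Jaccard)
#' makes a fragment connect at full strength to its full-length parent, so
#' fragments and parents co-cluster.
#'
#' @param a,b nucleotide sequences (character scalars).
#' @param k k-mer size (>= 11).
#' @return similarity in `[0, 1]`; 0 (with a warning) if either sequence is
#'   shorter than `k`.
#' @export
kmer_similarity <- function(a, b, k = 31L) {
  stopifnot(k >= 11L)
  if (nchar(a) < k || nchar(b) < k) {
    warning("sequence shorter than k; similarity 0")
    return(0)
  }
  ka <- cpp_kmer_hashes(toupper(a), k)
  kb <- cpp_kmer_hashes(toupper(b), k)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Build the transcript similarity graph over a pooled contig set
#'
#' Edges connect contig pairs whose canonical k-mer containment is at least
#' `min_similarity`. Candidate pairs are found through a shared-k-mer
#' inverted index, so the all-vs-all comparison is never materialized;
#' contigs with no qualifying partner remain as isolated nodes.
#'
#' @param pooled a [contig_set] (typically from [pool_assemblies()]).
#' @param k k-mer size.
#' @param min_similarity edge threshold in `(0, 1]`.
#' @return A `similarity_graph`: list with `nodes` (contig ids) and `edges`
#'   (data.frame `from`, `to`, `weight`).
#' @export
build_graph <- function(pooled, k = 31L, min_similarity = 0.1) {
  stopifnot(inherits(pooled, "contig_set"), length(pooled) > 0L)
  e <- cpp_containment_edges(pooled$seq, as.integer(k), min_similarity)
  structure(list(
    nodes = pooled$id,
    edges = data.frame(from = pooled$id[e$i], to = pooled$id[e$j],
                       weight = pmin(e$weight, 1.0),
                       stringsAsFactors = FALSE)
  ), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# MCL on one (dense-ish, small) component given a base sparse column-
# stochastic matrix. Returns a list of integer index vectors (clusters).
mcl_component <- function(A, params) {
  n <- nrow(A)
  if (n == 1L) return(list(1L))
  # self-loops at the max incident edge weight (1.0 for isolated nodes)
  mx <- apply(A, 2L, max)
  diag(A) <- ifelse(mx > 0, mx, 1.0)
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    Mexp <- M
    for (e in seq_len(params$expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ params$inflation
    Minf[Minf < params$prune_threshold] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Mnew <- sweep(Minf, 2L, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    tx_log("cluster", sprintf(
      "MCL did not converge in %d iterations on a %d-node component; using current interpretation",
      params$max_iter, n))
  }
  interpret_mcl(M, params$prune_threshold)
}

# Attractors are nodes with non-negligible self-mass; each node goes to its
# highest-mass attractor (ties to the lowest attractor index); attractors
# sharing support are merged into one cluster.
interpret_mcl <- function(M, thr) {
  n <- nrow(M)
  attractors <- which(diag(M) > thr)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # merge attractors that occur in each other's columns
  parent <- seq_along(attractors)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ai in seq_along(attractors)) {
    for (bi in seq_along(attractors)) {
      if (bi <= ai) next
      a <- attractors[ai]; b <- attractors[bi]
      if (M[a, b] > thr || M[b, a] > thr) {
        ra <- findp(ai); rb <- findp(bi)
        parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  sys_of <- vapply(seq_along(attractors), findp, integer(1))
  systems <- split(attractors, sys_of)
  clusters <- lapply(systems, function(s) integer(0))
  for (j in seq_len(n)) {
    mass <- M[attractors, j]
    if (all(mass <= 0)) {
      # unattracted node: its own singleton
      clusters[[length(clusters) + 1L]] <- j
      next
    }
    best <- attractors[which.max(mass)]  # which.max takes the lowest on ties
    sidx <- which(vapply(systems, function(s) best %in% s, logical(1)))
    clusters[[sidx]] <- c(clusters[[sidx]], j)
  }
  clusters[vapply(clusters, length, integer(1)) > 0L]
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL on the column-stochastic weighted adjacency matrix with
#' self-loops (loop weight = max incident edge weight; 1.0 for isolated
#' nodes): alternate expansion (matrix power) and inflation (entrywise power
#' followed by column renormalization) with pruning, until the largest entry
#' change falls below `tol` or `max_iter` is reached. Because disconnected
#' components can never merge under MCL, the iteration runs per connected
#' component.
#'
#' @param graph a `similarity_graph` from [build_graph()].
#' @param params an [mcl_params] object.
#' @return list of orthogroups, each a list with `group_id` and `members`
#'   (character vector of contig ids); groups partition the node set.
#' @export
markov_cluster <- function(graph, params = mcl_params()) {
  stopifnot(inherits(graph, "similarity_graph"))
  nodes <- graph$nodes
  if (length(nodes) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    members <- nodes[comp$membership == ci]
    if (length(members) == 1L) {
      clusters[[length(clusters) + 1L]] <- members
      next
    }
    sub <- graph$edges[graph$edges$from %in% members &
                         graph$edges$to %in% members, , drop = FALSE]
    A <- matrix(0, length(members), length(members))
    i <- match(sub$from, members); j <- match(sub$to, members)
    A[cbind(i, j)] <- sub$weight
    A[cbind(j, i)] <- sub$weight
    cl <- mcl_component(A, params)
    for (cc in cl) {
      clusters[[length(clusters) + 1L]] <- members[sort(cc)]
    }
  }
  lapply(seq_along(clusters), function(i)
    list(group_id = i, members = clusters[[i]]))
}

#' Hub-damping degree normalization of a similarity graph
#'
#' Rescales every edge weight to `w / sqrt(s_i * s_j)` where `s_i` is the
#' weighted degree of node `i`. Containment makes a chimeric contig a hub:
#' it connects at full strength to the orthogroups of both of its source
#' transcripts, and a hub with uniformly strong edges becomes the attractor
#' of everything it touches under Markov clustering, gluing two orthogroups
#' into one. Degree normalization weakens precisely the hub's edges (its
#' weighted degree is roughly double that of its neighbours) while leaving
#' the relative structure of cliques and fragment-parent stars intact, so
#' the clustering separates bridged orthogroups but still co-clusters
#' fragments with their full-length parents.
#'
#' @param graph a `similarity_graph`.
#' @return a `similarity_graph` with rescaled weights.
#' @export
normalize_graph <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (nrow(graph$edges) == 0L) return(graph)
  deg <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  for (col in c("from", "to")) {
    agg <- tapply(graph$edges$weight, graph$edges[[col]], sum)
    deg[names(agg)] <- deg[names(agg)] + agg
  }
  graph$edges$weight <- graph$edges$weight /
    sqrt(deg[graph$edges$from] * deg[graph$edges$to])
  graph
}

#' Cluster pooled assemblies into orthogroups
#'
#' Composition of [build_graph()], [normalize_graph()] and
#' [markov_cluster()]. Group ids are assigned in decreasing order of member
#' count, ties broken by the lexicographically smallest member id, so output
#' is reproducible.
#'
#' @inheritParams build_graph
#' @param params an [mcl_params] object.
#' @param normalize apply hub-damping degree normalization before
#'   clustering (recommended; see [normalize_graph()]).
#' @return list of orthogroups (`group_id`, `members`).
#' @export
cluster_assemblies <- function(pooled, k = 31L, min_similarity = 0.1,
                               params = mcl_params(), normalize = TRUE) {
  graph <- build_graph(pooled, k = k, min_similarity = min_similarity)
  if (normalize) graph <- normalize_graph(graph)
  tx_log("cluster", sprintf("graph: %d nodes, %d edges", length(graph$nodes),
                            nrow(graph$edges)))
  groups <- markov_cluster(graph, params)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  firsts <- vapply(groups, function(g) min(g$members), character(1))
  ord <- order(-sizes, firsts)
  out <- lapply(seq_along(ord), function(i)
    list(group_id = i, members = groups[[ord[i]]]$members))
  tx_log("cluster", sprintf("%d orthogroups formed", length(out)))
  out
}

#' Write orthogroups to a TSV file
#'
#' @param groups list of orthogroups from [cluster_assemblies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(groups, path) {
  df <- data.frame(
    group_id = vapply(groups, `[[`, integer(1), "group_id"),
    member_count = vapply(groups, function(g) length(g$members), integer(1)),
    members = vapply(groups, function(g)
      paste(g$members, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  write_report(df, path)
}
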