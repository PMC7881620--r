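as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = graph$n_vertices, directed = FALSE)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j))
    igraph::E(g)$weight <- graph$edges$weight
  }
  g
}

#' Partition the protein graph into communities (Louvain)
#'
#' Runs weighted Louvain modularity optimisation at a given resolution.
#' Deterministic for a fixed seed. Disconnected graphs are handled natively;
#' communities never span connected components.
#'
#' @param graph A \code{protein_graph}.
#' @param resolution Resolution parameter of the modularity (> 0); larger
#'   values give more, smaller communities.
#' @param seed Integer RNG seed.
#' @return List of integer vectors, the residue-index communities.
#' @export
louvain_partition <- function(graph, resolution = 1, seed = 1L) {
  if (graph$n_vertices < 1) stop("empty graph")
  if (resolution <= 0) stop("resolution must be positive")
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) {
    return(as.list(seq_len(graph$n_vertices)))
  }
  memb <- local_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  unname(split(seq_len(graph$n_vertices), memb))
}

# evaluate expr with a temporarily fixed RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tune the Louvain resolution toward a target community count
#'
#' Bisection search over the resolution parameter until the number of
#' communities falls inside a band around the target (default
#' target +/- 5), capped at \code{max_iter} iterations; if the band is never
#' hit the partition closest to the target is returned. Around 20
#' medium-sized communities balance two failure modes: communities so large
#' that they swallow hinge regions, and communities so small that the
#' between-community mean-variance signal loses significance.
#'
#' @param graph A \code{protein_graph}.
#' @param target Desired community count (default 20).
#' @param band Integer vector \code{c(lo, hi)}; default \code{target + c(-5, 5)}.
#' @param seed Integer RNG seed.
#' @param max_iter Bisection cap (default 30).
#' @return List with \code{resolution} and \code{partition}.
#' @export
tune_resolution <- function(graph, target = 20, band = target + c(-5, 5),
                            seed = 1L, max_iter = 30) {
  if (target < 2) stop("target must be >= 2")
  band[1] <- max(band[1], 1L)
  best <- NULL; best_gap <- Inf
  consider <- function(res, part) {
    k <- length(part)
    gap <- abs(k - target)
    if (gap < best_gap) { best <<- list(resolution = res, partition = part); best_gap <<- gap }
    k
  }
  lo <- NULL; hi <- NULL
  res <- 1
  for (iter in seq_len(max_iter)) {
    part <- louvain_partition(graph, resolution = res, seed = seed)
    k <- consider(res, part)
    if (k >= band[1] && k <= band[2]) { best <- list(resolution = res, partition = part); break }
    if (k < band[1]) {
      lo <- res
      res <- if (is.null(hi)) res * 2 else (lo + hi) / 2
    } else {
      hi <- res
      res <- if (is.null(lo)) res / 2 else (lo + hi) / 2
    }
  }
  big <- ceiling(graph$n_vertices / 4)
  sizes <- lengths(best$partition)
  if (any(sizes > big)) {
    message("tune_resolution: ", sum(sizes > big), " community(ies) larger than ",
            big, " residues (N/4)")
  }
  best
}

#' Coarse-grain a protein graph over a community partition
#'
#' Two communities are linked iff at least one residue pair spanning them is
#' an edge of the protein graph. For every community pair the mean variance
#' xi is the average, over all cross-community residue pairs (not only graph
#' edges), of the per-pair distance variance across conformations -- the
#' method's motion signal: rigid-body pairs have small xi, pairs moving
#' relative to each other have large xi.
#'
#' @param graph A \code{protein_graph}.
#' @param tensor The \code{distance_tensor} the graph was built from.
#' @param partition List of residue-index communities covering the graph.
#' @return An object of class \code{coarse_graph}: list with
#'   \code{communities}, \code{edges} (data frame \code{c1}, \code{c2},
#'   c1 < c2), \code{xi} (K x K matrix, Angstrom^2; diagonal unused).
#' @export
build_coarse_graph <- function(graph, tensor, partition) {
  N <- graph$n_vertices
  memb <- integer(N)
  for (k in seq_along(partition)) memb[partition[[k]]] <- k
  if (any(memb == 0)) stop("partition does not cover all vertices")
  K <- length(partition)

  # adjacency between communities from protein-graph edges
  edges <- graph$edges
  if (nrow(edges) > 0) {
    ck <- memb[edges$i]; cl <- memb[edges$j]
    cross <- ck != cl
    pair <- cbind(pmin(ck[cross], cl[cross]), pmax(ck[cross], cl[cross]))
    pair <- unique(pair)
  } else {
    pair <- matrix(integer(0), ncol = 2)
  }
  ce <- data.frame(c1 = pair[, 1], c2 = pair[, 2])
  if (nrow(ce) > 0) {
    ce <- ce[order(ce$c1, ce$c2), , drop = FALSE]
    rownames(ce) <- NULL
  }

  # xi over ALL cross pairs via the membership indicator
  V <- variance_matrix(tensor)
  B <- matrix(0, N, K)
  B[cbind(seq_len(N), memb)] <- 1
  S <- t(B) %*% V %*% B
  sizes <- lengths(partition)
  xi <- S / outer(sizes, sizes)
  diag(xi) <- NA_real_

  structure(list(communities = partition, edges = ce, xi = xi,
                 membership = memb),
            class = "coarse_graph")
}

#' @export
print.coarse_graph <- function(x, ...) {
  cat("Coarse-grained graph: ", length(x$communities), " communities, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a community partition as TSV
#'
#' Columns: residue (index), community (id).
#'
#' @param partition List of residue-index sets.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(residue = unlist(partition),
                   community = rep(seq_along(partition), lengths(partition)))
  df <- df[order(df$residue), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
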