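#' Configuration for rigid-domain segmentation
#'
#' Bundles the tunable parameters of the pipeline with their defaults.
#'
#' @param delta Contact cutoff in Angstrom (default 7.5).
#' @param theta Rigidity threshold in Angstrom (default 3.5): a residue set
#'   is rigid iff its ensemble RMSD is strictly below theta.
#' @param target_communities Desired Louvain community count (default 20).
#' @param mad_threshold One-sided MAD outlier cut (default 3).
#' @param outlier_expansion Initial outlier-expansion fraction (default 0).
#' @param max_recursion Recursion-depth cap (default 10).
#' @param min_domain_size Segments smaller than this are absorbed during
#'   merging (default 10 residues).
#' @param seed Integer RNG seed for the Louvain step.
#' @return A list of class \code{rigid_config}.
#' @export
rigid_config <- function(delta = 7.5, theta = 3.5, target_communities = 20,
                         mad_threshold = 3, outlier_expansion = 0,
                         max_recursion = 10, min_domain_size = 10, seed = 1L) {
  stopifnot(delta > 0, theta > 0, target_communities >= 2,
            mad_threshold > 0, outlier_expansion >= 0,
            max_recursion >= 1, min_domain_size >= 1)
  structure(list(delta = delta, theta = theta,
                 target_communities = target_communities,
                 mad_threshold = mad_threshold,
                 outlier_expansion = outlier_expansion,
                 max_recursion = max_recursion,
                 min_domain_size = min_domain_size,
                 seed = as.integer(seed)),
            class = "rigid_config")
}

# induced coarse subgraph on a subset of community indices (residue content
# and xi values are retained; community indices are re-numbered)
induce_coarse <- function(coarse, comm_idx) {
  comm_idx <- sort(comm_idx)
  keep <- coarse$edges$c1 %in% comm_idx & coarse$edges$c2 %in% comm_idx
  ed <- coarse$edges[keep, , drop = FALSE]
  ed$c1 <- match(ed$c1, comm_idx)
  ed$c2 <- match(ed$c2, comm_idx)
  rownames(ed) <- NULL
  structure(list(communities = coarse$communities[comm_idx],
                 edges = ed,
                 xi = coarse$xi[comm_idx, comm_idx, drop = FALSE],
                 membership = NULL),
            class = "coarse_graph")
}

#' Split a coarse graph once via CRF edge labeling
#'
#' Builds the modified line graph, computes outlier indicators from the
#' subgraph's own mean-variance arrays, infers the MAP labeling, deletes
#' every coarse edge whose line vertex is labeled -1, and returns the
#' resulting connected components as induced coarse subgraphs.
#'
#' @param coarse A \code{coarse_graph}.
#' @param mad_threshold MAD cut for the outlier indicators.
#' @param expansion Outlier-expansion fraction.
#' @param backend MAP backend, see \code{\link{map_labeling}}.
#' @return List with \code{components} (list of \code{coarse_graph}),
#'   \code{labeling} (the MAP labels), \code{removed} (removed coarse edges).
#' @export
split_once <- function(coarse, mad_threshold = 3, expansion = 0,
                       backend = "exact") {
  K <- length(coarse$communities)
  if (K == 0) stop("empty coarse graph")
  if (nrow(coarse$edges) == 0) {
    comps <- lapply(seq_len(K), function(k) induce_coarse(coarse, k))
    return(list(components = comps, labeling = integer(0),
                removed = coarse$edges))
  }
  lg <- suppressWarnings(line_graph(coarse))
  lg <- compute_gamma(lg, mad_threshold = mad_threshold, expansion = expansion)
  y <- map_labeling(lg, backend = backend)
  drop <- which(y == -1L)
  keep_edges <- coarse$edges[setdiff(seq_len(nrow(coarse$edges)), drop), ,
                             drop = FALSE]
  g <- igraph::make_empty_graph(n = K, directed = FALSE)
  if (nrow(keep_edges)) g <- igraph::add_edges(g, rbind(keep_edges$c1, keep_edges$c2))
  memb <- igraph::components(g)$membership
  comps <- lapply(sort(unique(memb)), function(cc)
    induce_coarse(coarse, which(memb == cc)))
  list(components = comps, labeling = y,
       removed = coarse$edges[drop, , drop = FALSE])
}

#' Map coarse-graph components back to a per-residue segmentation
#'
#' @param components List of community-index sets partitioning the
#'   communities.
#' @param partition The residue-index communities.
#' @return Integer vector of domain labels (contiguous from 1), one per
#'   residue.
#' @export
backmap <- function(components, partition) {
  N <- max(unlist(partition))
  labels <- integer(N)
  for (d in seq_along(components)) {
    res <- unlist(partition[components[[d]]])
    labels[res] <- d
  }
  labels
}

#' Merge segments into final rigid domains
#'
#' Two-phase post-processing: (1) every segment smaller than
#' \code{min_domain_size} is absorbed into the candidate minimising the
#' merged ensemble RMSD, candidates being the segments adjacent in the
#' protein graph (all segments if none is adjacent); (2) among adjacent
#' segment pairs whose merged RMSD stays below \code{theta}, the pair with
#' the smallest merged RMSD is merged, repeatedly, until no pair qualifies.
#' Compensates for segmentation errors involving small fragments.
#'
#' @param segments List of residue-index sets partitioning the residues.
#' @param ensemble The \code{conformation_ensemble}.
#' @param graph The \code{protein_graph} (for adjacency).
#' @param theta Rigidity threshold (Angstrom).
#' @param min_domain_size Minimum domain size in residues.
#' @return List of merged residue-index sets (deterministic given input
#'   order; ties broken toward the smallest segment index).
#' @export
merge_segments <- function(segments, ensemble, graph, theta = 3.5,
                           min_domain_size = 10) {
  segments <- lapply(segments, sort)
  seg_adjacent <- function(segs) {
    K <- length(segs)
    N <- graph$n_vertices
    memb <- integer(N)
    for (k in seq_len(K)) memb[segs[[k]]] <- k
    adj <- matrix(FALSE, K, K)
    if (nrow(graph$edges)) {
      a <- memb[graph$edges$i]; b <- memb[graph$edges$j]
      ok <- a != b & a > 0 & b > 0
      adj[cbind(a[ok], b[ok])] <- TRUE
      adj[cbind(b[ok], a[ok])] <- TRUE
    }
    adj
  }

  # phase 1: absorb undersized fragments
  repeat {
    if (length(segments) <= 1) break
    sizes <- lengths(segments)
    small <- which(sizes < min_domain_size)
    if (!length(small)) break
    s <- small[order(sizes[small], small)][1]
    adj <- seg_adjacent(segments)
    cand <- which(adj[s, ])
    if (!length(cand)) cand <- setdiff(seq_along(segments), s)
    mr <- vapply(cand, function(k)
      rmsd_or_zero(ensemble, c(segments[[s]], segments[[k]])), numeric(1))
    k <- cand[order(mr, cand)][1]
    tgt <- min(s, k); src <- max(s, k)
    segments[[tgt]] <- sort(c(segments[[s]], segments[[k]]))
    segments[[src]] <- NULL
  }

  # phase 2: greedy RMSD-guided merging of adjacent segments
  repeat {
    if (length(segments) <= 1) break
    adj <- seg_adjacent(segments)
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (!nrow(pairs)) break
    mr <- apply(pairs, 1, function(p)
      rmsd_or_zero(ensemble, c(segments[[p[1]]], segments[[p[2]]])))
    ok <- mr < theta
    if (!any(ok)) break
    pairs <- pairs[ok, , drop = FALSE]; mr <- mr[ok]
    b <- order(mr, pairs[, 1], pairs[, 2])[1]
    i <- pairs[b, 1]; j <- pairs[b, 2]
    segments[[i]] <- sort(c(segments[[i]], segments[[j]]))
    segments[[j]] <- NULL
  }
  segments
}

#' Detect rigid domains in a conformational ensemble
#'
#' The main fitting function. Pipeline: residue contact graph weighted by
#' distance variance -> Louvain coarse-graining (resolution tuned toward
#' \code{target_communities}) -> recursive splitting of non-rigid
#' components, each split inferred by exact MAP labeling of the modified
#' line graph -> merging post-processing -> per-residue domain labels. The
#' number of domains is determined automatically.
#'
#' A component is final when its residues are rigid (ensemble RMSD <
#' \code{theta}), it consists of a single community, or the recursion-depth
#' cap is hit. If a non-rigid component refuses to split, the outlier set
#' is expanded (two steps of 0.1) before it is accepted as a flagged
#' non-rigid leaf.
#'
#' @param ensemble A \code{conformation_ensemble}
#'   (see \code{\link{build_ensemble}}).
#' @param config A \code{\link{rigid_config}}.
#' @param prior Optional integer vector of prior domain labels (one per
#'   residue) used to down-weight cross-boundary contacts.
#' @param alpha Attenuation factor for prior cross-boundary edges
#'   (default 0.75).
#' @param rule Contact-graph construction rule, \code{"all"} (default) or
#'   \code{"any"}; see \code{\link{build_protein_graph}}.
#' @param backend MAP inference backend (\code{"exact"} default).
#' @return An object of class \code{rigid_domains}; see
#'   \code{\link{print.rigid_domains}}, \code{\link{summary.rigid_domains}},
#'   \code{\link{plot.rigid_domains}}.
#' @examples
#' spec <- fixture_spec(domain_sizes = c(40, 40), hinge_angles = 60,
#'                      noise_sd = 0.3, n_conformations = 2, seed = 7)
#' fx <- make_ensemble(spec)
#' fit <- rigid_domains(fx$ensemble)
#' fit
#' @export
rigid_domains <- function(ensemble, config = rigid_config(), prior = NULL,
                          alpha = 0.75, rule = "all", backend = "exact") {
  validate_ensemble(ensemble)
  cl <- match.call()
  tensor <- distance_tensor(ensemble)
  graph <- build_protein_graph(tensor, delta = config$delta, rule = rule)
  if (!is.null(prior)) graph <- apply_prior(graph, prior, alpha)

  tuned <- tune_resolution(graph, target = config$target_communities,
                           seed = config$seed)
  partition <- tuned$partition
  coarse <- build_coarse_graph(graph, tensor, partition)

  tree <- list()
  leaves <- list()        # each: list(residues, communities, non_rigid)
  warn <- character(0)

  recurse <- function(sub, depth) {
    residues <- sort(unlist(sub$communities))
    rmsd <- rmsd_or_zero(ensemble, residues)
    rigid <- rmsd < config$theta
    node <- list(depth = depth, n_communities = length(sub$communities),
                 n_residues = length(residues), rmsd = rmsd, rigid = rigid)
    if (rigid || length(sub$communities) == 1 || depth >= config$max_recursion) {
      node$leaf <- TRUE
      tree[[length(tree) + 1]] <<- node
      if (!rigid) {
        warn <<- c(warn, paste0("non-rigid leaf: ", length(residues),
                                " residues, RMSD ", round(rmsd, 2), " A"))
      }
      leaves[[length(leaves) + 1]] <<- list(residues = residues,
                                            non_rigid = !rigid)
      return(invisible(NULL))
    }
    expansion <- config$outlier_expansion
    res <- NULL
    for (try in 0:2) {
      res <- split_once(sub, mad_threshold = config$mad_threshold,
                        expansion = expansion + 0.1 * try, backend = backend)
      if (length(res$components) > 1) break
    }
    node$leaf <- length(res$components) == 1
    node$n_components <- length(res$components)
    node$removed_edges <- nrow(res$removed)
    tree[[length(tree) + 1]] <<- node
    if (length(res$components) == 1) {
      warn <<- c(warn, paste0("non-rigid leaf (unsplittable): ",
                              length(residues), " residues, RMSD ",
                              round(rmsd, 2), " A"))
      leaves[[length(leaves) + 1]] <<- list(residues = residues,
                                            non_rigid = TRUE)
      return(invisible(NULL))
    }
    for (comp in res$components) recurse(comp, depth + 1)
    invisible(NULL)
  }
  recurse(coarse, 0)

  segs <- lapply(leaves, `[[`, "residues")
  merged <- merge_segments(segs, ensemble, graph, theta = config$theta,
                           min_domain_size = config$min_domain_size)
  # order domains along the chain, ids contiguous from 1
  merged <- merged[order(vapply(merged, min, 1L))]
  N <- n_residues(ensemble)
  labels <- integer(N)
  for (d in seq_along(merged)) labels[merged[[d]]] <- d
  rmsd <- vapply(merged, function(s)
    if (length(s) >= 3) ensemble_rmsd(ensemble, s) else NA_real_, numeric(1))
  non_rigid_flag <- !is.na(rmsd) & rmsd >= config$theta

  structure(list(labels = labels, domains = merged, domain_rmsd = rmsd,
                 non_rigid = non_rigid_flag,
                 residue_ids = ensemble$residue_ids,
                 config = config, rule = rule,
                 n_edges = nrow(graph$edges),
                 resolution = tuned$resolution,
                 n_communities = length(partition),
                 partition = partition,
                 tree = tree, warnings = warn,
                 ensemble = ensemble, call = cl),
            class = "rigid_domains")
}

#' Write a segmentation as TSV
#'
#' Columns: chain, resno, insert, domain.
#'
#' @param x A \code{rigid_domains} fit or a data frame with those columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_segmentation_tsv <- function(x, path) {
  df <- if (inherits(x, "rigid_domains")) as.data.frame(x) else x
  utils::write.table(df[, c("chain", "resno", "insert", "domain")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a segmentation TSV
#'
#' @param path TSV with columns chain, resno, insert, domain.
#' @return Data frame.
#' @export
read_segmentation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chain = "character",
                                         insert = "character"),
                          fill = TRUE)
  df$insert[is.na(df$insert)] <- ""
  df
}
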