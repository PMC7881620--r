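#' Pairwise distance tensor of an ensemble
#'
#' For each conformation m, the symmetric N x N matrix of Euclidean
#' distances between representative atoms.
#'
#' @param ensemble A \code{conformation_ensemble}.
#' @return An object of class \code{distance_tensor}: list with \code{d}
#'   (array M x N x N, Angstrom).
#' @export
distance_tensor <- function(ensemble) {
  validate_ensemble(ensemble)
  M <- n_conformations(ensemble); N <- n_residues(ensemble)
  d <- array(0, dim = c(M, N, N))
  for (m in seq_len(M)) {
    d[m, , ] <- as.matrix(stats::dist(ensemble$coords[m, , ]))
  }
  structure(list(d = d), class = "distance_tensor")
}

# per-pair sample variance (denominator M-1) of distances across conformations
variance_matrix <- function(tensor) {
  d <- tensor$d
  M <- dim(d)[1]; N <- dim(d)[2]
  dm <- matrix(d, nrow = M)            # M x N^2, column-major over (k,l)
  mu <- colMeans(dm)
  v <- (colSums(dm^2) - M * mu^2) / (M - 1)
  v[v < 0] <- 0                        # numerical guard
  matrix(v, N, N)
}

#' Build the residue contact graph from a distance tensor
#'
#' Vertices are residues. Under the default \code{"all"} rule an edge links
#' residues k,l iff their distance stays within \code{delta} in every
#' conformation; the edge weight is \code{exp(-Var)} with Var the sample
#' variance (denominator M-1) of the pair distance across conformations, so
#' conformationally stable contacts weigh close to one. Under the
#' \code{"any"} rule an edge requires proximity in at least one conformation
#' and is weighted by the fraction of conformations within the cutoff.
#'
#' @param tensor A \code{distance_tensor}.
#' @param delta Distance cutoff in Angstrom (default 7.5).
#' @param rule \code{"all"} (default) or \code{"any"}.
#' @return An object of class \code{protein_graph}: list with
#'   \code{n_vertices}, \code{edges} (data frame \code{i}, \code{j} with
#'   i < j, \code{weight}, \code{variance}), \code{delta}, \code{rule}.
#' @export
build_protein_graph <- function(tensor, delta = 7.5, rule = c("all", "any")) {
  rule <- match.arg(rule)
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0)
    stop("delta must be a positive number")
  d <- tensor$d
  M <- dim(d)[1]; N <- dim(d)[2]
  dmax <- apply(d, c(2, 3), max)
  V <- variance_matrix(tensor)
  ut <- upper.tri(dmax)
  if (rule == "all") {
    sel <- ut & dmax <= delta
    w <- exp(-V[sel])
  } else {
    dmin <- apply(d, c(2, 3), min)
    sel <- ut & dmin <= delta
    cnt <- apply(d <= delta, c(2, 3), sum)
    w <- cnt[sel] / M
  }
  ij <- which(sel, arr.ind = TRUE)
  edges <- data.frame(i = ij[, 1], j = ij[, 2],
                      weight = w, variance = V[sel])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(n_vertices = N, edges = edges, delta = delta, rule = rule),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("Protein graph: ", x$n_vertices, " residues, ", nrow(x$edges),
      " edges (delta = ", x$delta, " A, rule = ", x$rule, ")\n", sep = "")
  invisible(x)
}

# Kabsch superposition: optimal-rotation RMSD between two coordinate sets
kabsch_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  H <- crossprod(A0, B0)
  s <- svd(H)
  sgn <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, sgn))
  R <- s$v %*% D %*% t(s$u)
  diffs <- B0 - A0 %*% t(R)
  sqrt(mean(rowSums(diffs^2)))
}

#' Ensemble RMSD of a residue subset
#'
#' Mean over all M(M-1)/2 conformation pairs of the minimal (Kabsch
#' superposed) root-mean-square deviation restricted to the subset. This is
#' the rigidity measure of the method: a subset is called rigid when this
#' value stays below the threshold theta.
#'
#' @param ensemble A \code{conformation_ensemble}.
#' @param subset Integer vector of residue indices (length >= 3).
#' @return RMSD in Angstrom.
#' @export
ensemble_rmsd <- function(ensemble, subset = seq_len(n_residues(ensemble))) {
  validate_ensemble(ensemble)
  subset <- as.integer(subset)
  if (length(subset) < 3)
    stop("subset must contain at least 3 residues (superposition underdetermined)")
  M <- n_conformations(ensemble)
  total <- 0
  for (m in seq_len(M - 1)) {
    for (mp in (m + 1):M) {
      total <- total + kabsch_rmsd(ensemble$coords[m, subset, , drop = FALSE][1, , ],
                                   ensemble$coords[mp, subset, , drop = FALSE][1, , ])
    }
  }
  2 * total / (M * (M - 1))
}

# internal: tolerate tiny subsets during merging (<= 2 points are trivially rigid)
rmsd_or_zero <- function(ensemble, subset) {
  if (length(subset) < 3) return(0)
  ensemble_rmsd(ensemble, subset)
}

#' Test whether a residue subset is rigid
#'
#' Strict comparison: rigid iff ensemble RMSD < theta.
#'
#' @inheritParams ensemble_rmsd
#' @param theta Rigidity threshold in Angstrom (default 3.5).
#' @return Logical.
#' @export
is_rigid <- function(ensemble, subset, theta = 3.5) {
  if (!is.numeric(theta) || theta <= 0) stop("theta must be positive")
  ensemble_rmsd(ensemble, subset) < theta
}

#' Down-weight contacts crossing a prior segmentation
#'
#' Edges whose endpoints carry different labels in a prior segmentation are
#' multiplied by \code{alpha} (0 < alpha < 1), steering the subsequent
#' coarse-graining away from communities that straddle known domain
#' boundaries. Even an imperfect prior (e.g. from another segmentation
#' method) can improve the result.
#'
#' @param graph A \code{protein_graph}.
#' @param prior Integer vector of prior domain labels, one per vertex.
#' @param alpha Attenuation factor in (0, 1); 0.75 is a good default.
#' @return The reweighted \code{protein_graph}.
#' @export
apply_prior <- function(graph, prior, alpha = 0.75) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (length(prior) != graph$n_vertices || anyNA(prior))
    stop("prior must label every vertex of the graph")
  cross <- prior[graph$edges$i] != prior[graph$edges$j]
  graph$edges$weight[cross] <- graph$edges$weight[cross] * alpha
  graph
}

#' Export a protein graph as an edge-list TSV
#'
#' Columns: vertex_k, vertex_l, weight, variance.
#'
#' @param graph A \code{protein_graph}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- graph$edges
  names(df) <- c("vertex_k", "vertex_l", "weight", "variance")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
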