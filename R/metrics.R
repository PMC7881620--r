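# O(n^3) Hungarian method (potentials formulation) for the square
# min-cost assignment problem; returns the column assigned to each row.
# Hand-rolled: no linear-assignment solver among the package's dependencies.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials, col 0 at index 1
  p <- integer(n + 1)        # row matched to column j (index j+1), 0 = none
  way <- integer(n)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      js <- which(!used[2:(n + 1)])
      cur <- cost[i0, js] - u[i0] - v[js + 1]
      upd <- cur < minv[js]
      minv[js[upd]] <- cur[upd]
      way[js[upd]] <- j0
      j1 <- js[which.min(minv[js])]
      delta <- minv[j1]
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1]] <- j
  ans
}

as_labels <- function(x) {
  if (inherits(x, "rigid_domains")) return(x$labels)
  if (is.data.frame(x)) {
    if (!"domain" %in% names(x)) stop("data frame lacks a 'domain' column")
    return(x$domain)
  }
  as.vector(x)
}

check_same_residues <- function(a, b) {
  ra <- if (is.data.frame(a)) paste(a$chain, a$resno, a$insert) else NULL
  rb <- if (is.data.frame(b)) paste(b$chain, b$resno, b$insert) else NULL
  la <- as_labels(a); lb <- as_labels(b)
  if (length(la) != length(lb)) stop("segmentations cover different residue sets")
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
    stop("segmentations cover different residue sets")
  list(a = la, b = lb)
}

#' Overlap between two segmentations
#'
#' Solves the linear assignment between the two sets of domain ids that
#' maximises the number of residues with matched labels (Hungarian method
#' on the contingency table) and returns the matched fraction. Invariant to
#' independent relabeling of either segmentation.
#'
#' @param a,b Segmentations: \code{rigid_domains} fits, label vectors, or
#'   data frames with a \code{domain} column (and residue columns, which
#'   are checked for identity when present in both).
#' @return Overlap in [0, 1].
#' @export
segmentation_overlap <- function(a, b) {
  l <- check_same_residues(a, b)
  ct <- table(l$a, l$b)
  n <- max(dim(ct))
  P <- matrix(0, n, n)
  P[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  assign <- solve_assignment(max(P) - P)
  matched <- sum(P[cbind(seq_len(n), assign)])
  matched / length(l$a)
}

#' Pairwise segmentation error
#'
#' Fraction of the N(N-1)/2 residue pairs on which the two segmentations
#' disagree about co-domain membership.
#'
#' @inheritParams segmentation_overlap
#' @return Error in [0, 1].
#' @export
pair_error <- function(a, b) {
  l <- check_same_residues(a, b)
  if (length(l$a) < 2) stop("need at least 2 residues")
  sa <- outer(l$a, l$a, "==")
  sb <- outer(l$b, l$b, "==")
  ut <- upper.tri(sa)
  mean(sa[ut] != sb[ut])
}

#' Inconsistency error of a clustering against reference labels
#'
#' Size-weighted within-cluster label-mismatch rate:
#' \code{2 * sum_k (|C_k|/N) * (# discordant pairs in C_k) /
#' (|C_k| (|C_k|-1))}. Zero iff every cluster is label-pure; singleton
#' clusters contribute zero. Used to judge how well graph construction and
#' coarse-graining respect the true domain structure.
#'
#' @param partition List of vertex-index sets (the clustering).
#' @param truth Vector of reference labels indexed by vertex.
#' @return Inconsistency error (non-negative).
#' @export
inconsistency_error <- function(partition, truth) {
  N <- sum(lengths(partition))
  total <- 0
  for (ck in partition) {
    nk <- length(ck)
    if (nk < 2) next
    lab <- truth[ck]
    mism <- sum(outer(lab, lab, "!=")[upper.tri(diag(nk))])
    total <- total + (nk / N) * mism / (nk * (nk - 1))
  }
  2 * total
}
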