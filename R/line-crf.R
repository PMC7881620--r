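#' Modified line-graph transformation of a coarse-grained graph
#'
#' The edges of the coarse-grained graph become the vertices of the line
#' graph. Two line vertices are linked iff their coarse edges share exactly
#' one community AND the two non-shared end communities are not themselves
#' adjacent in the coarse graph -- the modification avoids duplicating
#' information already carried by a vertex. Each line vertex inherits the
#' mean variance xi of its community pair; each line edge carries the xi of
#' its two end communities.
#'
#' @param coarse A \code{coarse_graph}.
#' @return An object of class \code{line_graph}: list with \code{vertices}
#'   (data frame \code{c1}, \code{c2}, \code{xi}), \code{edges} (data frame
#'   \code{v1}, \code{v2}, \code{xi}), and \code{gamma_vertex} /
#'   \code{gamma_edge} slots (NULL until \code{\link{compute_gamma}}).
#' @export
line_graph <- function(coarse) {
  ce <- coarse$edges
  K <- length(coarse$communities)
  if (nrow(ce) == 0) {
    warning("coarse graph has no edges (single-community case); ",
            "line graph is empty")
    return(structure(list(
      vertices = data.frame(c1 = integer(0), c2 = integer(0), xi = numeric(0)),
      edges = data.frame(v1 = integer(0), v2 = integer(0), xi = numeric(0)),
      gamma_vertex = NULL, gamma_edge = NULL), class = "line_graph"))
  }
  adj <- matrix(FALSE, K, K)
  adj[cbind(ce$c1, ce$c2)] <- TRUE
  adj[cbind(ce$c2, ce$c1)] <- TRUE

  verts <- data.frame(c1 = ce$c1, c2 = ce$c2,
                      xi = coarse$xi[cbind(ce$c1, ce$c2)])
  # incidence lists: which line vertices touch community c
  inc <- vector("list", K)
  for (v in seq_len(nrow(verts))) {
    inc[[verts$c1[v]]] <- c(inc[[verts$c1[v]]], v)
    inc[[verts$c2[v]]] <- c(inc[[verts$c2[v]]], v)
  }
  e1 <- integer(0); e2 <- integer(0); exi <- numeric(0)
  for (c0 in seq_len(K)) {
    vs <- inc[[c0]]
    if (length(vs) < 2) next
    for (a in seq_len(length(vs) - 1)) {
      for (b in (a + 1):length(vs)) {
        va <- vs[a]; vb <- vs[b]
        enda <- if (verts$c1[va] == c0) verts$c2[va] else verts$c1[va]
        endb <- if (verts$c1[vb] == c0) verts$c2[vb] else verts$c1[vb]
        if (!adj[enda, endb]) {
          stopifnot(enda != endb)
          e1 <- c(e1, va); e2 <- c(e2, vb)
          exi <- c(exi, coarse$xi[enda, endb])
        }
      }
    }
  }
  structure(list(vertices = verts,
                 edges = data.frame(v1 = e1, v2 = e2, xi = exi),
                 gamma_vertex = NULL, gamma_edge = NULL),
            class = "line_graph")
}

#' @export
print.line_graph <- function(x, ...) {
  cat("Line graph: ", nrow(x$vertices), " vertices, ", nrow(x$edges),
      " edges", if (!is.null(x$gamma_vertex)) " (gamma computed)", "\n",
      sep = "")
  invisible(x)
}

#' One-sided MAD outlier indicators for an ascending array
#'
#' Marks entry i as an outlier (-1) iff it exceeds the median and its
#' distance from the median, normalised by 1.4826 times the median absolute
#' deviation, exceeds \code{threshold}. One-sided because only unusually
#' LARGE mean variances signal inter-domain relations. If the MAD is zero
#' the mean absolute deviation is used instead; if that is zero too, there
#' are no outliers.
#'
#' @param values Numeric vector sorted in ascending order.
#' @param threshold Positive cut on the normalised deviation (default 3).
#' @return Integer vector of +1 (regular) / -1 (outlier).
#' @export
mad_outliers <- function(values, threshold = 3) {
  if (length(values) == 0) return(integer(0))
  if (is.unsorted(values)) stop("values must be sorted in ascending order")
  if (threshold <= 0) stop("threshold must be positive")
  med <- stats::median(values)
  s <- stats::median(abs(values - med))
  if (s == 0) s <- mean(abs(values - med))
  if (s == 0) return(rep(1L, length(values)))
  score <- (values - med) / (1.4826 * s)
  ifelse(values > med & score > threshold, -1L, 1L)
}

#' Enlarge an outlier set by the largest non-outliers
#'
#' Additionally flags the \code{floor(fraction * length)} largest entries
#' not already marked, preserving the property that outlier indices form a
#' suffix of the ascending array.
#'
#' @param gamma Indicator vector (+1/-1) consistent with ascending order.
#' @param values The ascending values (same length).
#' @param fraction Non-negative expansion fraction (default 0).
#' @return The expanded indicator vector.
#' @export
expand_outliers <- function(gamma, values, fraction = 0) {
  if (fraction < 0) stop("fraction must be >= 0")
  n <- length(gamma)
  if (n == 0 || fraction == 0) return(gamma)
  out <- which(gamma == -1L)
  if (length(out) && !identical(out, seq.int(n - length(out) + 1L, n)))
    stop("gamma is inconsistent with ascending order (outliers must be a suffix)")
  k <- floor(fraction * n)
  unflagged <- which(gamma == 1L)
  if (k > 0 && length(unflagged)) {
    extra <- utils::tail(unflagged, k)
    gamma[extra] <- -1L
  }
  gamma
}

#' Compute outlier indicators for a line graph
#'
#' Sorts the vertex and edge mean-variance arrays in ascending order,
#' applies the one-sided MAD rule (optionally expanded), and stores the
#' resulting +1/-1 indicators on the line graph.
#'
#' @param lg A \code{line_graph}.
#' @param mad_threshold MAD cut (default 3).
#' @param expansion Expansion fraction passed to \code{\link{expand_outliers}}.
#' @return The \code{line_graph} with \code{gamma_vertex} and
#'   \code{gamma_edge} filled in.
#' @export
compute_gamma <- function(lg, mad_threshold = 3, expansion = 0) {
  flag <- function(xi) {
    if (length(xi) == 0) return(integer(0))
    ord <- order(xi)
    g_sorted <- mad_outliers(xi[ord], mad_threshold)
    g_sorted <- expand_outliers(g_sorted, xi[ord], expansion)
    g <- integer(length(xi))
    g[ord] <- g_sorted
    g
  }
  lg$gamma_vertex <- flag(lg$vertices$xi)
  lg$gamma_edge <- flag(lg$edges$xi)
  lg
}

# pairwise feature on one line edge; tolerance for the xi-equality sub-case
XI_EQ_TOL <- 1e-9

psi2 <- function(ge, gv1, gv2, y1, y2, xi1, xi2) {
  if (gv1 == 1L && gv2 == 1L) {
    # hinge case: both vertices regular; an outlier edge suggests the shared
    # community sits in a hinge and must side with the lower-variance vertex
    eq <- abs(xi1 - xi2) <= XI_EQ_TOL
    if (y1 * y2 == -1 && ge == -1L && eq) return(0)
    if (y1 == -1 && y2 == 1 && ge == -1L && !eq && xi1 > xi2) return(1)
    if (y1 == 1 && y2 == -1 && ge == -1L && !eq && xi1 < xi2) return(1)
    if (y1 == 1 && y2 == 1 && ge == 1L) return(1)
    return(-1)
  }
  if ((ge == -1L) + (gv1 == -1L) + (gv2 == -1L) >= 2) {
    # at least two indicators vote "inter-domain": reward full agreement of
    # the labels with the vertex indicators
    if (y1 * gv1 + y2 * gv2 == 2) return(1) else return(-1)
  }
  0
}

check_gamma <- function(lg) {
  if (is.null(lg$gamma_vertex) || is.null(lg$gamma_edge))
    stop("outlier indicators missing; call compute_gamma() first")
}

#' Log-score of a binary labeling under the line-graph CRF
#'
#' Unnormalised log-probability: the sum over vertices of
#' \code{gamma_v * y_v} plus the sum over edges of the pairwise feature,
#' which rewards labelings consistent with the outlier indicators and
#' resolves hinge communities toward the lower-variance side.
#'
#' @param lg A \code{line_graph} with gamma computed.
#' @param y Integer vector of +1/-1 labels, one per line vertex.
#' @return The scalar log-score.
#' @export
score_labeling <- function(lg, y) {
  check_gamma(lg)
  P <- nrow(lg$vertices)
  if (length(y) != P || !all(y %in% c(-1, 1)))
    stop("y must assign +1/-1 to every line vertex")
  s <- sum(lg$gamma_vertex * y)
  E <- lg$edges
  if (nrow(E)) {
    for (e in seq_len(nrow(E))) {
      v1 <- E$v1[e]; v2 <- E$v2[e]
      s <- s + psi2(lg$gamma_edge[e], lg$gamma_vertex[v1], lg$gamma_vertex[v2],
                    y[v1], y[v2], lg$vertices$xi[v1], lg$vertices$xi[v2])
    }
  }
  s
}

# ---- exact MAP inference ---------------------------------------------------
# Variables take values 1 (+1) and 2 (-1). A factor is a list(vars, tab)
# where vars is a sorted integer vector and tab a numeric vector of length
# 2^|vars| indexed with var order = stride order (first var fastest).

crf_factors <- function(lg) {
  P <- nrow(lg$vertices)
  fs <- lapply(seq_len(P), function(v)
    list(vars = v, tab = c(lg$gamma_vertex[v], -lg$gamma_vertex[v])))
  E <- lg$edges
  lab <- c(1, -1)
  for (e in seq_len(nrow(E))) {
    v1 <- E$v1[e]; v2 <- E$v2[e]
    xi1 <- lg$vertices$xi[v1]; xi2 <- lg$vertices$xi[v2]
    ge <- lg$gamma_edge[e]; g1 <- lg$gamma_vertex[v1]; g2 <- lg$gamma_vertex[v2]
    tab <- numeric(4)
    for (a in 1:2) for (b in 1:2) {
      val <- psi2(ge, g1, g2, lab[a], lab[b], xi1, xi2)
      if (v1 < v2) tab[(b - 1) * 2 + a] <- val else tab[(a - 1) * 2 + b] <- val
    }
    fs[[length(fs) + 1]] <- list(vars = sort(c(v1, v2)), tab = tab)
  }
  fs
}

capacity_error <- function(width) {
  stop(structure(class = c("rigidom_capacity_error", "error", "condition"),
                 list(message = paste0(
                   "inference boundary set too large (width ", width,
                   " > 25); use coarser communities (lower target_communities)"),
                   call = sys.call(-1))))
}

reduce_factor <- function(f, clamped) {
  hit <- f$vars %in% names2int(clamped)
  if (!any(hit)) return(f)
  keep <- f$vars[!hit]
  idx_all <- expand_assign(length(f$vars))
  fixed <- match(f$vars, names2int(clamped))
  sel <- rep(TRUE, nrow(idx_all))
  for (p in which(hit)) {
    sel <- sel & idx_all[, p] == clamped[[match(f$vars[p], names2int(clamped))]]
  }
  tab <- f$tab[sel]
  list(vars = keep, tab = tab)
}

names2int <- function(clamped) as.integer(names(clamped))

# assignment matrix for k binary vars, first column fastest (stride order)
expand_assign <- function(k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(expand.grid(rep(list(1:2), k)))
}

tab_index <- function(A, vars, scope) {
  # linear index into a factor over `vars` given assignment matrix A over `scope`
  pos <- match(vars, scope)
  idx <- rep(1L, nrow(A))
  stride <- 1L
  for (p in pos) {
    idx <- idx + (A[, p] - 1L) * stride
    stride <- stride * 2L
  }
  idx
}

# maximum total score over all completions, given clamped assignments
max_score_eliminate <- function(factors, clamped = integer(0)) {
  if (length(clamped)) {
    clamped <- stats::setNames(as.list(clamped), names(clamped))
    factors <- lapply(factors, reduce_factor, clamped = clamped)
  }
  const <- 0
  live <- list()
  for (f in factors) {
    if (length(f$vars) == 0) const <- const + f$tab[1] else live[[length(live) + 1]] <- f
  }
  vars_left <- sort(unique(unlist(lapply(live, `[[`, "vars"))))
  while (length(vars_left)) {
    # min-fill choice on the current interaction graph
    nb <- lapply(vars_left, function(x) {
      setdiff(sort(unique(unlist(lapply(live, function(f)
        if (x %in% f$vars) f$vars else NULL)))), x)
    })
    fill <- vapply(nb, function(s) {
      if (length(s) < 2) return(0L)
      cnt <- 0L
      for (a in seq_len(length(s) - 1)) for (b in (a + 1):length(s)) {
        linked <- any(vapply(live, function(f)
          s[a] %in% f$vars && s[b] %in% f$vars, logical(1)))
        if (!linked) cnt <- cnt + 1L
      }
      cnt
    }, integer(1))
    x <- vars_left[order(fill, lengths(nb), vars_left)][1]

    touch <- vapply(live, function(f) x %in% f$vars, logical(1))
    bucket <- live[touch]
    live <- live[!touch]
    scope <- sort(unique(unlist(lapply(bucket, `[[`, "vars"))))
    if (length(scope) > 25) capacity_error(length(scope))
    A <- expand_assign(length(scope))
    tot <- numeric(nrow(A))
    for (f in bucket) tot <- tot + f$tab[tab_index(A, f$vars, scope)]
    px <- match(x, scope)
    keep <- A[, px] == 1L
    newtab <- pmax(tot[keep], tot[!keep])
    newvars <- scope[-px]
    if (length(newvars) == 0) const <- const + newtab[1]
    else live[[length(live) + 1]] <- list(vars = newvars, tab = newtab)
    vars_left <- setdiff(vars_left, x)
  }
  for (f in live) const <- const + max(f$tab)   # disconnected leftovers
  const
}

#' MAP labeling of the line-graph CRF
#'
#' Computes the +1/-1 labeling of the line vertices that maximises
#' \code{\link{score_labeling}}. The \code{"exact"} backend runs
#' max-sum bucket elimination over a min-fill ordering (a boundary-set
#' generalisation of the Viterbi algorithm), exact whenever the induced
#' width stays within 25; beyond that a capacity error advises coarser
#' communities. The \code{"brute-force"} backend enumerates all labelings
#' (permitted up to 22 vertices). Ties are broken toward the
#' lexicographically smallest labeling under vertex order with +1 before
#' -1, for determinism.
#'
#' @param lg A \code{line_graph} with gamma computed.
#' @param backend \code{"exact"} (default) or \code{"brute-force"}.
#' @return Integer vector of +1/-1 labels (empty for an empty line graph).
#' @export
map_labeling <- function(lg, backend = c("exact", "brute-force")) {
  backend <- match.arg(backend)
  check_gamma(lg)
  P <- nrow(lg$vertices)
  if (P == 0) return(integer(0))
  if (backend == "brute-force") {
    if (P > 22) stop("brute-force backend limited to 22 vertices")
    return(brute_force_map(lg))
  }
  factors <- crf_factors(lg)
  opt <- max_score_eliminate(factors)
  clamped <- integer(0)
  y <- integer(P)
  for (v in seq_len(P)) {
    trial <- c(clamped, stats::setNames(1L, v))
    if (max_score_eliminate(factors, trial) >= opt - 1e-9) {
      clamped <- trial; y[v] <- 1L
    } else {
      clamped <- c(clamped, stats::setNames(2L, v)); y[v] <- -1L
    }
  }
  y
}

# exhaustive enumeration in lexicographic order (vertex 1 most significant,
# +1 before -1) so the first argmax is the tie-rule winner
brute_force_map <- function(lg) {
  P <- nrow(lg$vertices)
  n_lab <- 2^P
  idx <- 0:(n_lab - 1)
  L <- matrix(1L, n_lab, P)
  for (v in seq_len(P)) {
    bit <- bitwAnd(idx %/% (2^(P - v)), 1L)
    L[, v] <- ifelse(bit == 1L, -1L, 1L)
  }
  sc <- as.numeric(L %*% lg$gamma_vertex)
  E <- lg$edges
  if (nrow(E)) {
    lab <- c(1, -1)
    for (e in seq_len(nrow(E))) {
      v1 <- E$v1[e]; v2 <- E$v2[e]
      tabm <- matrix(0, 2, 2)
      for (a in 1:2) for (b in 1:2)
        tabm[a, b] <- psi2(lg$gamma_edge[e], lg$gamma_vertex[v1],
                           lg$gamma_vertex[v2], lab[a], lab[b],
                           lg$vertices$xi[v1], lg$vertices$xi[v2])
      i1 <- ifelse(L[, v1] == 1L, 1L, 2L)
      i2 <- ifelse(L[, v2] == 1L, 1L, 2L)
      sc <- sc + tabm[cbind(i1, i2)]
    }
  }
  L[which.max(sc), ]
}

#' Dump a line graph as TSV (debugging aid)
#'
#' Writes two blocks: vertices (community pair, xi, gamma) and edges
#' (vertex pair, xi, gamma).
#'
#' @param lg A \code{line_graph}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_line_graph_tsv <- function(lg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- cbind(lg$vertices,
             gamma = if (is.null(lg$gamma_vertex)) NA else lg$gamma_vertex)
  writeLines("# vertices", con)
  utils::write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("# edges", con)
  e <- cbind(lg$edges,
             gamma = if (is.null(lg$gamma_edge)) NA else lg$gamma_edge)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
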