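# -- tiny in-code fixtures and independent oracles ---------------------------

# build a conformation_ensemble from a list of N x 3 coordinate matrices
toy_ensemble <- function(conf_list, resno = NULL) {
  M <- length(conf_list)
  N <- nrow(conf_list[[1]])
  if (is.null(resno)) resno <- seq_len(N)
  coords <- array(NA_real_, dim = c(M, N, 3))
  for (m in seq_len(M)) coords[m, , ] <- conf_list[[m]]
  structure(list(coords = coords,
                 residue_ids = data.frame(chain = "A", resno = resno,
                                          insert = "", stringsAsFactors = FALSE),
                 source_labels = paste0("toy", seq_len(M))),
            class = "conformation_ensemble")
}

# random non-degenerate 3-D point cloud
rand_coords <- function(n, scale = 5) matrix(stats::rnorm(3 * n, sd = scale), n, 3)

# minimal hand-rolled PDB ATOM line (columns per the PDB v3 fixed format)
pdb_atom_line <- function(serial, name, alt, resid, chain, resno, icode,
                          x, y, z, occ) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, nm, alt, resid, chain, resno, icode, x, y, z, occ, 0)
}

write_test_pdb <- function(path, lines) writeLines(c(lines, "END"), path)

# three CA residues on a line, spacing 3.8 A
three_res_pdb <- function(path = tempfile(fileext = ".pdb")) {
  write_test_pdb(path, c(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 1, " ", 0.0, 0, 0, 1),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 2, " ", 3.8, 0, 0, 1),
    pdb_atom_line(3, "CA", " ", "ALA", "A", 3, " ", 7.6, 0, 0, 1)))
  path
}

# random labeled line graph with MAD-consistent indicators
rand_line_graph <- function(n, p = 0.3, mad_threshold = 3) {
  v <- data.frame(c1 = seq_len(n), c2 = seq_len(n) + n,
                  xi = round(stats::rgamma(n, 2, 1), 3))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- pr[stats::runif(nrow(pr)) < p, , drop = FALSE]
  e <- data.frame(v1 = pick[, 1], v2 = pick[, 2],
                  xi = round(stats::rgamma(nrow(pick), 2, 1), 3))
  lg <- structure(list(vertices = v, edges = e,
                       gamma_vertex = NULL, gamma_edge = NULL),
                  class = "line_graph")
  compute_gamma(lg, mad_threshold = mad_threshold)
}

# independently transcribed CRF scorer: explicit truth-table style, written
# separately from the production scorer on purpose
oracle_score <- function(lg, y) {
  total <- 0
  for (v in seq_len(nrow(lg$vertices))) {
    total <- total + lg$gamma_vertex[v] * y[v]
  }
  if (nrow(lg$edges) == 0) return(total)
  for (e in seq_len(nrow(lg$edges))) {
    a <- lg$edges$v1[e]; b <- lg$edges$v2[e]
    ga <- lg$gamma_vertex[a]; gb <- lg$gamma_vertex[b]; ge <- lg$gamma_edge[e]
    ya <- y[a]; yb <- y[b]
    xa <- lg$vertices$xi[a]; xb <- lg$vertices$xi[b]
    if (ga == 1 && gb == 1) {
      # hinge-resolution table
      term <- -1
      if (ya == 1 && yb == 1 && ge == 1) term <- 1
      if (ge == -1) {
        if (abs(xa - xb) <= 1e-9) {
          if (ya != yb) term <- 0
        } else if (xa > xb) {
          if (ya == -1 && yb == 1) term <- 1
        } else {
          if (ya == 1 && yb == -1) term <- 1
        }
      }
    } else {
      n_neg <- sum(c(ga, gb, ge) == -1)
      if (n_neg >= 2) {
        term <- if (ya == ga && yb == gb) 1 else -1
      } else {
        term <- 0
      }
    }
    total <- total + term
  }
  total
}

# all 2^n labelings, rows in lexicographic order (+1 before -1, vertex 1
# most significant)
all_labelings <- function(n) {
  idx <- 0:(2^n - 1)
  L <- matrix(1L, 2^n, n)
  for (v in seq_len(n)) {
    L[, v] <- ifelse(bitwAnd(idx %/% (2^(n - v)), 1L) == 1L, -1L, 1L)
  }
  L
}

# reference one-sided MAD outlier flags (independent of the production code)
ref_mad_flags <- function(values, threshold = 3) {
  med <- stats::median(values)
  m <- stats::median(abs(values - med))
  if (m == 0) m <- mean(abs(values - med))
  if (m == 0) return(rep(1L, length(values)))
  ifelse(values > med & (values - med) / (1.4826 * m) > threshold, -1L, 1L)
}

# all permutations of a small vector (recursive)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# brute-force overlap: best injective assignment between label sets
brute_overlap <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  if (length(ua) > length(ub)) return(brute_overlap(b, a))
  best <- 0
  for (p in perms(ub)) {
    assign_to <- p[seq_along(ua)]
    matched <- sum(vapply(seq_along(ua), function(k)
      sum(a == ua[k] & b == assign_to[k]), numeric(1)))
    best <- max(best, matched)
  }
  best / length(a)
}

# brute-force pairwise disagreement
brute_pair_error <- function(a, b) {
  n <- length(a)
  bad <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if ((a[i] == a[j]) != (b[i] == b[j])) bad <- bad + 1
  }
  bad / tot
}

# independent inconsistency error (double loop)
brute_inconsistency <- function(partition, truth) {
  N <- sum(lengths(partition))
  tot <- 0
  for (ck in partition) {
    nk <- length(ck)
    if (nk < 2) next
    mism <- 0
    for (i in 1:(nk - 1)) for (j in (i + 1):nk) {
      if (truth[ck[i]] != truth[ck[j]]) mism <- mism + 1
    }
    tot <- tot + (nk / N) * mism / (nk * (nk - 1))
  }
  2 * tot
}

# random segmentation labels
rand_labels <- function(n, k) sample.int(k, n, replace = TRUE)

# standard two-domain test fixture
two_domain_fixture <- function(seed = 3) {
  make_ensemble(fixture_spec(c(60, 60), 60, noise_sd = 0.3,
                             n_conformations = 2, seed = seed))
}
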