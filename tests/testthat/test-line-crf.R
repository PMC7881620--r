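coarse_stub <- function(K, edges, xi_fill = 1) {
  xi <- matrix(xi_fill, K, K); diag(xi) <- NA
  structure(list(communities = as.list(seq_len(K)), edges = edges, xi = xi),
            class = "coarse_graph")
}

test_that("line-graph construction follows the modified incidence rule", {
  # triangle: every incident pair has adjacent end nodes -> no line edges
  tri <- coarse_stub(3, data.frame(c1 = c(1, 1, 2), c2 = c(2, 3, 3)))
  lg <- line_graph(tri)
  expect_equal(nrow(lg$vertices), 3)
  expect_equal(nrow(lg$edges), 0)

  # path a-b-c: ends not adjacent -> one line edge with xi of the ends
  xi <- matrix(NA, 3, 3)
  xi[1, 2] <- xi[2, 1] <- 1; xi[2, 3] <- xi[3, 2] <- 2; xi[1, 3] <- xi[3, 1] <- 7
  pa <- structure(list(communities = as.list(1:3),
                       edges = data.frame(c1 = c(1, 2), c2 = c(2, 3)), xi = xi),
                  class = "coarse_graph")
  lgp <- line_graph(pa)
  expect_equal(nrow(lgp$vertices), 2)
  expect_equal(nrow(lgp$edges), 1)
  expect_equal(lgp$edges$xi, 7)
  expect_equal(lgp$vertices$xi, c(1, 2))

  # star with 4 leaves: line graph is the complete K4
  st <- coarse_stub(5, data.frame(c1 = 1, c2 = 2:5))
  expect_equal(nrow(line_graph(st)$edges), choose(4, 2))

  # no coarse edges: empty line graph with a warning
  expect_warning(lg0 <- line_graph(coarse_stub(2, data.frame(c1 = integer(0),
                                                             c2 = integer(0)))),
                 "empty")
  expect_equal(nrow(lg0$vertices), 0)
})

test_that("every line edge joins coarse edges with non-adjacent ends", {
  set.seed(91)
  for (rep in 1:25) {
    K <- sample(4:9, 1)
    pr <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
    pick <- pr[stats::runif(nrow(pr)) < 0.45, , drop = FALSE]
    if (nrow(pick) == 0) next
    cg <- coarse_stub(K, data.frame(c1 = pick[, 1], c2 = pick[, 2]))
    adj <- matrix(FALSE, K, K)
    adj[pick] <- TRUE; adj[pick[, 2:1, drop = FALSE]] <- TRUE
    lg <- line_graph(cg)
    if (nrow(lg$edges) == 0) next
    for (e in seq_len(nrow(lg$edges))) {
      v1 <- lg$edges$v1[e]; v2 <- lg$edges$v2[e]
      p1 <- unlist(lg$vertices[v1, c("c1", "c2")])
      p2 <- unlist(lg$vertices[v2, c("c1", "c2")])
      shared <- intersect(p1, p2)
      expect_length(shared, 1)
      ends <- c(setdiff(p1, shared), setdiff(p2, shared))
      expect_false(adj[ends[1], ends[2]])
    }
  }
})

test_that("MAD outlier flags follow the one-sided rule", {
  expect_equal(mad_outliers(c(2, 2, 2, 2)), rep(1L, 4))
  expect_equal(mad_outliers(c(1, 1, 1, 1, 1, 1, 1, 100)),
               c(rep(1L, 7), -1L))
  expect_error(mad_outliers(c(3, 1, 2)), "ascending")
  expect_error(mad_outliers(1:3, threshold = 0), "positive")

  # planted outliers in gamma noise match an independent reference
  set.seed(101)
  vals <- sort(c(rgamma(50, 2, 2), 40, 55, 70))
  got <- mad_outliers(vals, 3)
  expect_equal(got, ref_mad_flags(vals, 3))   # false positives match reference
  expect_true(all(51:53 %in% which(got == -1L)))  # planted values flagged
})

test_that("outlier expansion adds the largest non-outliers", {
  g <- c(rep(1L, 9), -1L)
  expect_equal(expand_outliers(g, 1:10, 0), g)
  expect_equal(expand_outliers(g, 1:10, 0.2), c(rep(1L, 7), -1L, -1L, -1L))
  expect_error(expand_outliers(g, 1:10, -0.1), "fraction")
  expect_error(expand_outliers(c(-1L, rep(1L, 9)), 1:10, 0.1), "suffix")
  # superset property on random inputs
  set.seed(111)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    vals <- sort(rgamma(n, 2, 1))
    g0 <- mad_outliers(vals, runif(1, 1, 4))
    g1 <- expand_outliers(g0, vals, runif(1, 0, 0.5))
    expect_true(all(which(g0 == -1L) %in% which(g1 == -1L)))
  }
})

test_that("scorer reproduces the spec'd spot values", {
  # isolated vertex: score is +/- gamma
  lone <- structure(list(vertices = data.frame(c1 = 1, c2 = 2, xi = 1),
                         edges = data.frame(v1 = integer(0), v2 = integer(0),
                                            xi = numeric(0)),
                         gamma_vertex = 1L, gamma_edge = integer(0)),
                    class = "line_graph")
  expect_equal(score_labeling(lone, 1), 1)
  expect_equal(score_labeling(lone, -1), -1)

  # 2-vertex path, all indicators +1, y = (+1,+1): 1 + 1 + (edge +1) = 3
  path2 <- structure(list(vertices = data.frame(c1 = c(1, 2), c2 = c(2, 3),
                                                xi = c(1, 2)),
                          edges = data.frame(v1 = 1, v2 = 2, xi = 7),
                          gamma_vertex = c(1L, 1L), gamma_edge = 1L),
                     class = "line_graph")
  expect_equal(score_labeling(path2, c(1, 1)), 3)
  expect_error(score_labeling(path2, c(1, 0)), "\\+1/-1")
  path2$gamma_vertex <- NULL
  expect_error(score_labeling(path2, c(1, 1)), "compute_gamma")
})

test_that("scorer agrees with an independent transcription over all labelings", {
  set.seed(121)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    lg <- rand_line_graph(n, p = 0.5, mad_threshold = runif(1, 0.5, 3))
    L <- all_labelings(n)
    for (r in seq_len(nrow(L))) {
      expect_equal(score_labeling(lg, L[r, ]), oracle_score(lg, L[r, ]))
    }
  }
})

test_that("MAP labeling maximises the score and is tie-deterministic", {
  # all-regular indicators, no edges: everything +1
  iso <- structure(list(vertices = data.frame(c1 = 1:3, c2 = 4:6, xi = c(1, 2, 3)),
                        edges = data.frame(v1 = integer(0), v2 = integer(0),
                                           xi = numeric(0)),
                        gamma_vertex = rep(1L, 3), gamma_edge = integer(0)),
                   class = "line_graph")
  expect_equal(map_labeling(iso), rep(1L, 3))

  # exact equals brute force on random instances
  set.seed(131)
  for (rep in 1:40) {
    lg <- rand_line_graph(sample(2:10, 1), p = 0.4,
                          mad_threshold = runif(1, 0.5, 3))
    ye <- map_labeling(lg, "exact")
    yb <- map_labeling(lg, "brute-force")
    expect_identical(ye, yb)
  }
})

test_that("MAP decomposes over disconnected components", {
  set.seed(141)
  lg1 <- rand_line_graph(4, p = 0.6)
  lg2 <- rand_line_graph(3, p = 0.6)
  n1 <- nrow(lg1$vertices)
  joint <- structure(list(
    vertices = rbind(lg1$vertices, lg2$vertices),
    edges = rbind(lg1$edges,
                  data.frame(v1 = lg2$edges$v1 + n1, v2 = lg2$edges$v2 + n1,
                             xi = lg2$edges$xi)),
    gamma_vertex = c(lg1$gamma_vertex, lg2$gamma_vertex),
    gamma_edge = c(lg1$gamma_edge, lg2$gamma_edge)), class = "line_graph")
  yj <- map_labeling(joint, "brute-force")
  s_joint <- score_labeling(joint, yj)
  s_parts <- score_labeling(lg1, map_labeling(lg1, "brute-force")) +
    score_labeling(lg2, map_labeling(lg2, "brute-force"))
  expect_equal(s_joint, s_parts)
})

test_that("flipping an isolated vertex changes the score by 2*gamma*y", {
  set.seed(151)
  for (rep in 1:10) {
    lg <- rand_line_graph(5, p = 0)       # no edges: all vertices isolated
    y <- sample(c(-1L, 1L), 5, replace = TRUE)
    for (v in 1:5) {
      y2 <- y; y2[v] <- -y2[v]
      expect_equal(score_labeling(lg, y) - score_labeling(lg, y2),
                   2 * lg$gamma_vertex[v] * y[v])
    }
  }
})

test_that("empty line graphs and oversized brute force are handled", {
  empty <- structure(list(vertices = data.frame(c1 = integer(0), c2 = integer(0),
                                                xi = numeric(0)),
                          edges = data.frame(v1 = integer(0), v2 = integer(0),
                                             xi = numeric(0)),
                          gamma_vertex = integer(0), gamma_edge = integer(0)),
                     class = "line_graph")
  expect_equal(map_labeling(empty), integer(0))
  big <- rand_line_graph(23, p = 0.1)
  expect_error(map_labeling(big, "brute-force"), "22")
})
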