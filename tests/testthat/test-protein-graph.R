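test_that("distance tensor matches hand values and a brute-force loop", {
  e <- toy_ensemble(list(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 1)),
                         rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 1))))
  d <- distance_tensor(e)$d
  expect_equal(d[1, 1, 2], 5)              # 3-4-5 triangle
  expect_equal(diag(d[1, , ]), rep(0, 3))
  expect_equal(d[1, , ], t(d[1, , ]))

  set.seed(11)
  e2 <- toy_ensemble(lapply(1:3, function(i) rand_coords(4)))
  d2 <- distance_tensor(e2)$d
  for (m in 1:3) for (k in 1:4) for (l in 1:4) {
    expect_equal(d2[m, k, l],
                 sqrt(sum((e2$coords[m, k, ] - e2$coords[m, l, ])^2)))
  }
})

test_that("contact-graph rules follow the max/min cutoff definitions", {
  # identical conformations, pair 1-2 at distance 5, cutoff 7.5: weight 1
  far <- c(100, 0, 0)                       # third residue outside any cutoff
  e <- toy_ensemble(list(rbind(c(0, 0, 0), c(5, 0, 0), far),
                         rbind(c(0, 0, 0), c(5, 0, 0), far)))
  g <- build_protein_graph(distance_tensor(e), delta = 7.5)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges[1, c("i", "j")], data.frame(i = 1L, j = 2L))
  expect_equal(g$edges$variance, 0)
  expect_equal(g$edges$weight, 1)

  # distances 7 and 8 across the cutoff 7.5: present only under "any"
  e2 <- toy_ensemble(list(rbind(c(0, 0, 0), c(7, 0, 0), far),
                          rbind(c(0, 0, 0), c(8, 0, 0), far)))
  t2 <- distance_tensor(e2)
  expect_equal(nrow(build_protein_graph(t2, 7.5, "all")$edges), 0)
  gany <- build_protein_graph(t2, 7.5, "any")
  expect_equal(nrow(gany$edges), 1)
  expect_equal(gany$edges$weight, 0.5)

  expect_error(build_protein_graph(t2, -1), "positive")
})

test_that("contact graph equals a brute-force implementation on random input", {
  set.seed(21)
  e <- toy_ensemble(lapply(1:3, function(i) rand_coords(6, 4)))
  tn <- distance_tensor(e)
  g <- build_protein_graph(tn, delta = 7.5)
  M <- 3
  for (k in 1:5) for (l in (k + 1):6) {
    ds <- vapply(1:M, function(m) tn$d[m, k, l], numeric(1))
    present <- max(ds) <= 7.5
    row <- g$edges[g$edges$i == k & g$edges$j == l, ]
    expect_equal(nrow(row), as.integer(present))
    if (present) {
      expect_equal(row$variance, stats::var(ds))
      expect_equal(row$weight, exp(-stats::var(ds)))
    }
  }
})

test_that("edge sets are monotone in delta and nested across rules", {
  set.seed(31)
  e <- toy_ensemble(lapply(1:3, function(i) rand_coords(15, 6)))
  tn <- distance_tensor(e)
  key <- function(g) paste(g$edges$i, g$edges$j)
  expect_true(all(key(build_protein_graph(tn, 6)) %in%
                  key(build_protein_graph(tn, 9))))
  expect_true(all(key(build_protein_graph(tn, 7.5, "all")) %in%
                  key(build_protein_graph(tn, 7.5, "any"))))
})

test_that("ensemble RMSD is zero under pure rigid motion and matches bio3d", {
  set.seed(41)
  A <- rand_coords(10)
  e_id <- toy_ensemble(list(A, A))
  expect_equal(ensemble_rmsd(e_id), 0, tolerance = 1e-10)

  R <- rigidom:::rotation_matrix(c(1, 2, -1), 1.1)
  B <- A %*% t(R) + matrix(rep(c(4, -2, 9), each = 10), 10, 3)
  expect_lt(ensemble_rmsd(toy_ensemble(list(A, B))), 1e-8)

  # independent Kabsch oracle on a deformed 4-point, 3-conformation toy
  confs <- list(rand_coords(4), rand_coords(4), rand_coords(4))
  e3 <- toy_ensemble(confs)
  ref <- 0
  for (m in 1:2) for (mp in (m + 1):3) {
    ref <- ref + bio3d::rmsd(as.vector(t(confs[[m]])),
                             as.vector(t(confs[[mp]])), fit = TRUE)
  }
  ref <- 2 * ref / (3 * 2)
  expect_equal(ensemble_rmsd(e3), ref, tolerance = 1e-3)  # bio3d rounds to 3 dp

  expect_error(ensemble_rmsd(e3, 1:2), "at least 3")
})

test_that("rigidity is a strict theta comparison on the hinge fixture", {
  fx <- two_domain_fixture()
  expect_false(is_rigid(fx$ensemble, 1:120, theta = 3.5))
  expect_true(is_rigid(fx$ensemble, 1:60, theta = 3.5))
  expect_true(is_rigid(fx$ensemble, 61:120, theta = 3.5))
  A <- rand_coords(5)
  expect_true(is_rigid(toy_ensemble(list(A, A)), 1:5, 1e-6))
})

test_that("prior reweighting scales exactly the cross-boundary edges", {
  set.seed(51)
  e <- toy_ensemble(lapply(1:2, function(i) rand_coords(12, 4)))
  g <- build_protein_graph(distance_tensor(e), 10)
  expect_gt(nrow(g$edges), 4)
  # single-domain prior: untouched
  expect_equal(apply_prior(g, rep(1, 12), 0.75)$edges$weight, g$edges$weight)
  # two-domain prior: cross edges scaled by exactly alpha
  prior <- rep(c(1, 2), each = 6)
  g2 <- apply_prior(g, prior, 0.75)
  cross <- prior[g$edges$i] != prior[g$edges$j]
  expect_equal(g2$edges$weight[cross], g$edges$weight[cross] * 0.75)
  expect_equal(g2$edges$weight[!cross], g$edges$weight[!cross])
  # multiplicativity
  g4 <- apply_prior(apply_prior(g, prior, 0.5), prior, 0.5)
  expect_equal(g4$edges$weight[cross], g$edges$weight[cross] * 0.25)
  expect_error(apply_prior(g, prior, 1.5), "alpha")
  expect_error(apply_prior(g, rep(1, 5), 0.5), "every vertex")
})

test_that("variance-weighted 'all' rule coarse-grains more consistently than the 'any' rule", {
  err <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    fx <- make_ensemble(fixture_spec(c(60, 60), 60, 0.3, 2, seed = 200 + s))
    tn <- distance_tensor(fx$ensemble)
    for (r in 1:2) {
      g <- build_protein_graph(tn, 7.5, c("all", "any")[r])
      part <- louvain_partition(g, resolution = 2, seed = s)
      err[s, r] <- inconsistency_error(part, fx$truth)
    }
  }
  expect_lte(mean(err[, 1]), mean(err[, 2]))
})
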