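prof <- function(id, labs) profile_from_labels(id, labs, REF)

test_that("distance matrices count differing compared sites", {
  d0 <- distance_matrix(list(prof("a", "100"), prof("b", "100")))
  expect_true(all(d0 == 0))

  d1 <- distance_matrix(list(prof("a", "73"), prof("b", "263")))
  expect_equal(d1["a", "b"], 2)
  expect_equal(diag(d1), c(a = 0, b = 0))

  set.seed(17)
  sites <- as.character(sample(500:600, 10))
  sets <- lapply(1:12, function(i) sample(sites, sample(0:5, 1)))
  ps <- Map(function(i, s) prof(paste0("s", i), s), 1:12, sets)
  d <- distance_matrix(ps)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(unname(d[i, j]),
                 length(union(sets[[i]], sets[[j]])) -
                   length(intersect(sets[[i]], sets[[j]])))
  }
  expect_true(isSymmetric(d))
})

test_that("two-level AMOVA reproduces the hand-solved 2x2 instance", {
  # difference counts: within A = 2, within B = 4, all between = 10.
  # By hand (counts as squared distances): SSD_T = (2+4+4*10)/4 = 11.5,
  # SSD_W = 2/2 + 4/2 = 3, SSD_A = 8.5; df = (1, 2); MS_W = 1.5 = sig_c;
  # n_c = 2 -> sig_a = (8.5 - 1.5)/2 = 3.5; PhiST = 3.5/5 = 0.7.
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 2
  d[3, 4] <- d[4, 3] <- 4
  d[1, 3] <- d[3, 1] <- d[1, 4] <- d[4, 1] <- 10
  d[2, 3] <- d[3, 2] <- d[2, 4] <- d[4, 2] <- 10
  am <- amova(d, c("A", "A", "B", "B"), n_perm = 0)
  expect_equal(unname(am$ssd), c(8.5, 3))
  expect_equal(unname(am$variance_components), c(3.5, 1.5))
  expect_equal(unname(am$phi_statistics["phi_st"]), 0.7)
  expect_equal(unname(am$percent_variation), c(70, 30))
  expect_equal(sum(am$percent_variation), 100, tolerance = 1e-9)
})

test_that("AMOVA limit cases: fixed differences and panmixia", {
  # identical within, different between -> PhiST = 1, within % = 0; with
  # groups this large the chance a permutation re-creates the pure split
  # is ~2/C(16,8), so the p-value sits at its floor 1/(m+1)
  ps <- c(lapply(1:8, function(i) prof(paste0("a", i), "100")),
          lapply(1:8, function(i) prof(paste0("b", i), c("200", "300"))))
  d <- distance_matrix(ps)
  am <- amova(d, rep(c("A", "B"), each = 8), n_perm = 199, seed = 3)
  expect_equal(unname(am$phi_statistics["phi_st"]), 1)
  expect_equal(unname(am$percent_variation["within_populations"]), 0)
  expect_equal(unname(am$p_values["phi_st"]), 1 / 200)

  # arbitrary splits of one panmictic pool: PhiST near 0 on average and
  # the permutation p roughly uniform (checked through its mean)
  set.seed(8)
  phis <- ps_null <- numeric(10)
  for (r in 1:10) {
    pool <- lapply(1:20, function(i)
      prof(paste0("s", i), as.character(sample(500:520, 3))))
    amp <- amova(distance_matrix(pool), rep(c("X", "Y"), 10),
                 n_perm = 99, seed = r)
    phis[r] <- amp$phi_statistics["phi_st"]
    ps_null[r] <- amp$p_values["phi_st"]
  }
  expect_lt(abs(mean(phis)), 0.1)
  expect_gt(mean(ps_null), 0.25)
  expect_lt(mean(ps_null), 0.75)
})

test_that("three-level AMOVA partitions variance among groups", {
  set.seed(21)
  g1 <- as.character(100:109); g2 <- as.character(200:209)
  mk <- function(pop, base_sites) lapply(1:4, function(i)
    prof(paste0(pop, i), c(base_sites, sample(900:999, 1))))
  ps <- c(mk("a", c(g1, "301")), mk("b", c(g1, "302")),
          mk("c", c(g2, "303")), mk("d", c(g2, "304")))
  d <- distance_matrix(ps)
  pops <- rep(c("A", "B", "C", "D"), each = 4)
  grps <- rep(c("G1", "G2"), each = 8)
  am <- amova(d, pops, groups = grps, n_perm = 99, seed = 2)
  expect_equal(am$levels, c("among_groups", "among_populations",
                            "within_populations"))
  expect_equal(sum(am$percent_variation), 100, tolerance = 1e-9)
  expect_true(all(c("phi_ct", "phi_sc", "phi_st") %in%
                  names(am$phi_statistics)))
  # groups explain the most variance here
  expect_gt(am$phi_statistics["phi_ct"], am$phi_statistics["phi_sc"])
})

test_that("pairwise PhiST equals two-population AMOVA and flags extremes", {
  set.seed(4)
  ps <- c(lapply(1:5, function(i) prof(paste0("a", i),
                                       as.character(sample(500:505, 2)))),
          lapply(1:5, function(i) prof(paste0("b", i),
                                       as.character(sample(600:605, 2)))),
          lapply(1:5, function(i) prof(paste0("c", i),
                                       as.character(sample(600:608, 2)))))
  pops <- rep(c("A", "B", "C"), each = 5)
  d <- distance_matrix(ps)
  pp <- pairwise_phist(d, pops, n_perm = 99, seed = 9)
  idx <- which(pops %in% c("A", "B"))
  am <- amova(d[idx, idx], pops[idx], n_perm = 0)
  expect_equal(pp$phi_st["A", "B"],
               unname(am$phi_statistics["phi_st"]))
  expect_true(isSymmetric(pp$phi_st))

  # identical populations give PhiST about 0
  ps2 <- c(lapply(1:4, function(i) prof(paste0("x", i), "100")),
           lapply(1:4, function(i) prof(paste0("y", i), "100")))
  pp2 <- pairwise_phist(distance_matrix(ps2), rep(c("X", "Y"), each = 4),
                        n_perm = 99, seed = 1)
  expect_true(is.nan(pp2$phi_st["X", "Y"]) ||
              abs(pp2$phi_st["X", "Y"]) < 1e-9)
})

test_that("permutation p-values are invariant to input row order", {
  set.seed(12)
  ps <- lapply(1:12, function(i)
    prof(paste0("s", i), as.character(sample(700:720, 2))))
  pops <- rep(c("A", "B"), 6)
  d <- distance_matrix(ps)
  am1 <- amova(d, pops, n_perm = 299, seed = 31)
  o <- sample(12)
  am2 <- amova(d[o, o], pops[o], n_perm = 299, seed = 31)
  expect_equal(am1$p_values, am2$p_values)
  expect_equal(am1$phi_statistics, am2$phi_statistics)
})

test_that("PhiST ignores variants shared by every sample", {
  set.seed(44)
  sets <- lapply(1:10, function(i) as.character(sample(500:520, 2)))
  ps <- Map(function(i, s) prof(paste0("s", i), s), 1:10, sets)
  pops <- rep(c("A", "B"), each = 5)
  base <- amova(distance_matrix(ps), pops, n_perm = 0)
  shared <- Map(function(i, s) prof(paste0("s", i), c(s, "9000", "9001")),
                1:10, sets)
  with_shared <- amova(distance_matrix(shared), pops, n_perm = 0)
  expect_equal(base$phi_statistics, with_shared$phi_statistics)
})

test_that("AMOVA rejects degenerate designs", {
  d <- matrix(0, 3, 3)
  expect_error(amova(d, c("A", "A", "B")), ">= 2 samples")
  expect_error(amova(d, c("A", "A", "A")), ">= 2 populations")
  expect_error(amova(matrix(0, 4, 4), rep(c("A", "B"), 2), n_perm = -1),
               "negative")
})

test_that("MDS embeds exactly embeddable configurations at zero stress", {
  x <- c(0, 1, 3, 6, 10)
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- paste0("p", 1:5)
  emb <- mds(D, dim = 2, seed = 1, restarts = 5)
  expect_lt(emb$stress, 1e-6)
  # collinear up to rotation/reflection: second principal axis ~ 0
  sv <- svd(scale(emb$coords, scale = FALSE))$d
  expect_lt(sv[2] / sv[1], 1e-3)
  expect_equal(colMeans(emb$coords), c(dim1 = 0, dim2 = 0),
               tolerance = 1e-8)

  emb2 <- mds(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                     dimnames = list(c("a", "b"), c("a", "b"))),
              dim = 2, seed = 1)
  expect_equal(emb2$stress, 0)

  expect_error(mds(matrix(c(0, 1, 2, 0), 2, 2)), "non-symmetric")
  expect_warning(mds(matrix(c(0, -0.01, 0, -0.01, 0, 0.5, 0, 0.5, 0), 3, 3),
                     seed = 1, restarts = 2),
                 "clamped")
})

test_that("MDS stress agrees with an independent nonmetric implementation", {
  skip_if_not_installed("vegan")
  set.seed(66)
  for (rep in 1:3) {
    n <- 6
    p <- matrix(runif(n * 4), n)
    D <- as.matrix(dist(p)) + matrix(runif(n * n, 0, 0.15), n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    rownames(D) <- colnames(D) <- paste0("q", 1:n)
    ours <- mds(D, dim = 2, seed = rep, restarts = 10)
    ref_stress <- min(vapply(1:10, function(s) {
      set.seed(s)
      fit <- vegan::monoMDS(as.dist(D), k = 2, model = "global")
      fit$stress
    }, numeric(1)))
    expect_equal(ours$stress, ref_stress, tolerance = 1e-3,
                 info = paste("rep", rep))
  }
})
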