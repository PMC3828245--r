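test_that("pairwise coalescence times match the analytic expectations", {
  # E[T_MRCA] for n = 2 is N generations (haploid size N)
  N <- 200
  t2 <- vapply(1:2000, function(r)
    simulate_genealogy(demographic_model("constant", N = N), 2,
                       seed = r)$tmrca_gen, numeric(1))
  se <- N / sqrt(2000)  # T2 ~ Exp(1/N), sd = N
  expect_lt(abs(mean(t2) - N), 3 * se)

  # E[T_MRCA] for n = 20 is 2N(1 - 1/n)
  t20 <- vapply(1:600, function(r)
    simulate_genealogy(demographic_model("constant", N = N), 20,
                       seed = 10000 + r)$tmrca_gen, numeric(1))
  expected <- 2 * N * (1 - 1 / 20)
  expect_lt(abs(mean(t20) - expected), 3 * sd(t20) / sqrt(600))

  # strong growth compresses the genealogy
  tg <- vapply(1:300, function(r)
    simulate_genealogy(demographic_model("exponential_growth", N = N,
                                         growth_rate = 0.05), 20,
                       seed = 20000 + r)$tmrca_gen, numeric(1))
  expect_lt(mean(tg), expected)

  expect_error(simulate_genealogy(demographic_model("constant", N = 100), 1),
               "n must be")
  expect_error(demographic_model("constant", N = -5), "sizes must be > 0")
})

test_that("two-epoch demography concentrates coalescence at the bottleneck", {
  # large recent size, tiny ancestral size: TMRCA just beyond the boundary
  mod <- demographic_model("two_epoch", N = 1e7, N_ancient = 20,
                           epoch_gen = 100)
  tm <- vapply(1:200, function(r)
    simulate_genealogy(mod, 10, seed = r)$tmrca_gen, numeric(1))
  expect_true(all(tm > 100))
  expect_lt(mean(tm - 100), 100)  # ancestral phase is fast (N_anc = 20)
})

test_that("mutation counts are Poisson with the configured mean", {
  sim <- simulate_genealogy(demographic_model("constant", N = 300), 10,
                            seed = 3)
  rate <- 1.665e-8; gt <- 25
  # uniform rates: expected total = rate * L * total branch years
  total_years <- sum(sim$phylo$edge.length) * gt
  mu <- rate * 16569 * total_years
  tot <- vapply(1:400, function(r)
    nrow(drop_mutations(sim, rate = rate, generation_time = gt, ref = REF,
                        hotspots = NULL, seed = r)$truth$events),
    numeric(1))
  expect_lt(abs(mean(tot) - mu), 3 * sqrt(mu / 400))

  # rate -> 0 limit: everything identical to the root
  out0 <- drop_mutations(sim, rate = 1e-15, ref = REF, seed = 5)
  expect_true(all(vapply(out0$sequences, function(s)
    identical(s$bases, REF$bases), logical(1))))
})

test_that("hotspot weighting concentrates mutations at hot positions", {
  sim <- simulate_genealogy(demographic_model("constant", N = 2000), 20,
                            seed = 9)
  hs <- default_hotspots()
  out <- drop_mutations(sim, ref = REF, hotspots = hs, seed = 21,
                        rate = 5e-8)
  ev <- out$truth$events
  hot_sub <- mean(ev$position[ev$type == "sub"] %in%
                  hs$position[hs$type == "sub"])
  # 3 sites at weight 30 vs 16566 at weight 1: expect far more than 3/16569
  expect_gt(hot_sub, 10 * 3 / 16569)
  expect_true(all(ev$type %in% c("sub", "ins")))
  if (any(ev$type == "ins"))
    expect_true(all(ev$position[ev$type == "ins"] %in% c(309L, 16189L)))
})

test_that("emitted sequences round-trip through variant calling", {
  found <- FALSE
  for (seed in 1:12) {
    sim <- simulate_genealogy(demographic_model("constant", N = 250),
                              n = 10, seed = seed)
    out <- drop_mutations(sim, ref = REF, hotspots = NULL,
                          seed = 500 + seed)
    if (length(out$truth$recurrent_sites) || nrow(out$truth$events) < 2)
      next
    found <- TRUE
    profs <- profiles_for(out$sequences, REF, no_mask())
    # per sample: called variants = substitutions accumulated on its path
    # (event node ids refer to the simulated tree itself)
    phy <- sim$phylo
    for (i in seq_along(profs)) {
      tip <- match(out$sequences[[i]]$sample_id, phy$tip.label)
      path_nodes <- tip
      cur <- tip
      repeat {
        e <- which(phy$edge[, 2] == cur)
        if (!length(e)) break
        cur <- phy$edge[e, 1]
        path_nodes <- c(path_nodes, cur)
      }
      onpath <- out$truth$events$node %in% path_nodes
      truth_pos <- sort(out$truth$events$position[onpath])
      expect_equal(sort(profs[[i]]$variants$position), truth_pos)
    }
    break
  }
  expect_true(found)
})

test_that("emitted files are deterministic under the seed", {
  sim <- simulate_genealogy(demographic_model("constant", N = 100), 3,
                            seed = 7)
  out <- drop_mutations(sim, ref = REF, hotspots = NULL, seed = 8)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  sim_emit(out$sequences, out$truth, d1)
  out_again <- drop_mutations(sim, ref = REF, hotspots = NULL, seed = 8)
  sim_emit(out_again$sequences, out_again$truth, d2)
  for (f in c("sequences.fasta", "metadata.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  fa <- Biostrings::readDNAStringSet(file.path(d1, "sequences.fasta"))
  expect_length(fa, 3)
  expect_true(all(Biostrings::width(fa) == 16569))

  # different seeds place mutations differently (deep tree so that both
  # realisations carry a non-trivial number of events)
  simd <- simulate_genealogy(demographic_model("constant", N = 2000), 5,
                             seed = 7)
  oa <- drop_mutations(simd, ref = REF, hotspots = NULL, seed = 8)
  ob <- drop_mutations(simd, ref = REF, hotspots = NULL, seed = 9)
  expect_false(identical(
    vapply(oa$sequences, `[[`, character(1), "bases"),
    vapply(ob$sequences, `[[`, character(1), "bases")))
})

test_that("island simulations carry their equilibrium FST truth", {
  cfg <- sim_config(n_per_population = 4, n_populations = 2, Nm = 0.5,
                    seed = 13)
  out <- simulate_island(cfg, REF)
  expect_equal(out$truth$expected_fst, 0.5)
  expect_equal(nrow(out$metadata), 8)
  expect_setequal(unique(out$metadata$population), c("pop1", "pop2"))

  # near-panmixia: huge Nm drives PhiST toward 0
  phis <- vapply(1:6, function(r) {
    cfgp <- sim_config(n_per_population = 6, n_populations = 2, Nm = 200,
                       seed = 40 + r)
    o <- simulate_island(cfgp, REF)
    p <- profiles_for(o$sequences, REF, no_mask())
    am <- amova(distance_matrix(p), o$metadata$population, n_perm = 0)
    unname(am$phi_statistics["phi_st"])
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.15)

  expect_error(sim_config(n_populations = 1), "n_populations")
  expect_error(sim_config(Nm = 0), "Nm")
})
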