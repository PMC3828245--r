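star_genealogy <- function(m = c(1, 2, 3, 2)) {
  clade_genealogy(parents = rep("r", length(m)),
                  children = paste0("L", seq_along(m)), m = m,
                  multiplicity = stats::setNames(rep(1L, length(m)),
                                                 paste0("L", seq_along(m))),
                  root = "r")
}

test_that("rho and sigma reproduce the hand-enumerated fixtures", {
  g <- star_genealogy()
  expect_equal(compute_rho(g), 2.0)
  expect_equal(compute_sigma(g), sqrt(8 / 16))

  # root with a direct leaf and a 2-mutation edge to a two-leaf cherry
  g2 <- clade_genealogy(parents = c("r", "r", "i", "i"),
                        children = c("L1", "i", "L2", "L3"),
                        m = c(0, 2, 1, 1),
                        multiplicity = c(L1 = 1L, L2 = 1L, L3 = 1L),
                        root = "r")
  expect_equal(compute_rho(g2), 2.0)
  expect_equal(compute_sigma(g2), sqrt(10 / 9))

  # degenerate cases
  g0 <- clade_genealogy(parents = "r", children = "L1", m = 0,
                        multiplicity = c(L1 = 3L), root = "r")
  expect_equal(compute_rho(g0), 0)
  expect_equal(compute_sigma(g0), 0)
})

test_that("rho/sigma equal brute-force enumeration on random genealogies", {
  set.seed(101)
  for (rep in 1:200) {
    g <- random_genealogy(n_nodes = sample(3:40, 1))
    expect_equal(compute_rho(g), brute_rho(g), info = paste("rho rep", rep))
    expect_equal(compute_sigma(g), brute_sigma(g),
                 info = paste("sigma rep", rep))
  }
})

test_that("star genealogies satisfy sigma = sqrt(rho)/sqrt(n)", {
  set.seed(55)
  for (rep in 1:20) {
    m <- sample(0:6, sample(2:30, 1), replace = TRUE)
    g <- star_genealogy(m)
    expect_equal(compute_sigma(g), sqrt(compute_rho(g)) / sqrt(length(m)))
  }
})

test_that("adding a mutation to any edge never decreases rho", {
  set.seed(13)
  for (rep in 1:10) {
    g <- random_genealogy(n_nodes = 12)
    r0 <- compute_rho(g)
    for (e in seq_len(nrow(g$edges))) {
      g2 <- g
      g2$edges$m[e] <- g2$edges$m[e] + 1
      expect_gte(compute_rho(g2), r0)
    }
  }
})

test_that("the linear clock converts rho to years with a floored interval", {
  est <- rho_to_time(2.0, sqrt(0.5), clock_model("complete_genome"))
  expect_equal(est$tmrca_years, 2 / (16569 * 1.665e-8), tolerance = 1e-12)
  expect_equal(est$tmrca_years, 7250, tolerance = 1e-3)

  expect_equal(rho_to_time(0, 0, clock_model())$tmrca_years, 0)

  est2 <- rho_to_time(1.0, 1.0, clock_model())
  expect_equal(est2$ci_years[1], 0)
  expect_equal(est2$ci_years[2], 2 / (16569 * 1.665e-8), tolerance = 1e-12)

  expect_error(rho_to_time(NaN, 1, clock_model()), "non-finite")

  # correction hook applies before conversion
  halved <- clock_model("complete_genome", correction = function(r) r / 2)
  expect_equal(rho_to_time(2, 0, halved)$tmrca_years,
               1 / (16569 * 1.665e-8))
})

test_that("clade_ages filters mutation labels per clock", {
  # edge labels: one control-region and one coding substitution
  g <- clade_genealogy(parents = c("r", "r"), children = c("L1", "L2"),
                       m = c(1, 1),
                       multiplicity = c(L1 = 1L, L2 = 1L), root = "r",
                       edge_labels = list("16311", "3By"))
  # build a genuinely synonymous label for edge 2 by searching codon space
  genes <- ANN[ANN$type == "coding" & ANN$strand == "+", ]
  syn_lab <- NULL
  for (pos in seq(genes$start[1] + 2, genes$start[1] + 400, by = 3)) {
    for (to in setdiff(c("A", "C", "G", "T"), ref_base(REF, pos))) {
      v <- data.frame(position = pos, insert_index = 0L, kind = "transversion",
                      derived = to, label = paste0(pos, to))
      v$kind <- ifelse(transition_partner(ref_base(REF, pos)) == to,
                       "transition", "transversion")
      v$label <- variant_label(pos, 0L, v$kind, to)
      if (annotate_variants(v, ANN, REF) == "synonymous") {
        syn_lab <- v$label; break
      }
    }
    if (!is.null(syn_lab)) break
  }
  expect_false(is.null(syn_lab))
  g$edge_labels[[2]] <- syn_lab
  ages <- clade_ages(g, clocks = list(clock_model("complete_genome"),
                                      clock_model("synonymous")),
                     annotation = ANN, ref = REF)
  expect_equal(nrow(ages), 2)
  expect_equal(ages$rho[ages$clock == "complete_genome"], 1.0)
  # only the synonymous label counts under the synonymous clock
  expect_equal(ages$rho[ages$clock == "synonymous"], 0.5)

  # no synonymous mutations -> synonymous rho of 0
  g0 <- clade_genealogy(parents = "r", children = "L1", m = 1,
                        multiplicity = c(L1 = 1L), root = "r",
                        edge_labels = list("16311"))
  a0 <- clade_ages(g0, clocks = list(clock_model("synonymous")),
                   annotation = ANN, ref = REF)
  expect_equal(a0$rho, 0)
  expect_equal(a0$tmrca_years, 0)

  expect_error(clade_ages(g0, clocks = list(clock_model("synonymous"))),
               "annotation")

  # composition: the star fixture dated equals rho_to_time of its rho
  gs <- star_genealogy()
  gs$edge_labels <- list("101", c("102", "103"), c("104", "105", "106"),
                         c("107", "108"))
  as <- clade_ages(gs, clocks = list(clock_model("complete_genome")))
  expect_equal(as$tmrca_years, rho_to_time(2, 0, clock_model())$tmrca_years)
})

test_that("hot-spot labels are excluded by the complete-genome clock", {
  g <- clade_genealogy(parents = c("r", "r"), children = c("L1", "L2"),
                       m = c(2, 1),
                       multiplicity = c(L1 = 1L, L2 = 1L), root = "r",
                       edge_labels = list(c("100", "16519"), "200"))
  a <- clade_ages(g, clocks = list(clock_model("complete_genome")))
  expect_equal(a$rho, 1.0)  # 16519 dropped: (1 + 1) / 2
})

test_that("empty genealogies are rejected", {
  g <- star_genealogy()
  g$nodes$multiplicity[] <- 0L
  g$n <- 0L
  expect_error(compute_rho(g), "empty")
  expect_error(compute_sigma(g), "empty")
})
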