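#' Diversity statistics for sets of variant profiles
#'
#' Segregating sites, haplotype diversity, nucleotide diversity, mean
#' pairwise differences and Tajima's D, computed from variant profiles
#' under an explicit site-deletion policy. Substitutions only by default
#' (indels excluded, configurable); by default no hot-spot masking is
#' applied here -- the hot-spot exclusions are scoped to dating and tree
#' building, not to diversity statistics.
#'
#' @name diversity
NULL

# Site-by-sample derived-state matrix for substitution sites.
# States: "" = reference; otherwise the derived base. Positions missing in
# a profile (ambiguity codes) are NA. Under complete deletion, positions
# with any NA are removed for the whole set.
state_matrix <- function(profiles, include_indels = FALSE,
                         deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  keep_kind <- if (include_indels)
    c("transition", "transversion", "insertion", "deletion")
  else c("transition", "transversion")
  pos_all <- sort(unique(unlist(lapply(profiles, function(p) {
    v <- p$variants
    v$position[v$kind %in% keep_kind & v$insert_index == 0L]
  }))))
  n <- length(profiles)
  m <- matrix("", length(pos_all), n,
              dimnames = list(pos_all, vapply(profiles, `[[`, character(1),
                                              "sample_id")))
  for (j in seq_len(n)) {
    p <- profiles[[j]]
    v <- p$variants
    v <- v[v$kind %in% keep_kind & v$insert_index == 0L, , drop = FALSE]
    i <- match(v$position, pos_all)
    m[i, j] <- ifelse(v$kind == "deletion", "-", v$derived)
    if (length(p$missing_positions)) {
      mi <- match(intersect(p$missing_positions, pos_all), pos_all)
      m[mi, j] <- NA_character_
    }
  }
  total_missing <- sort(unique(unlist(lapply(profiles,
                                             `[[`, "missing_positions"))))
  if (deletion == "complete" && length(total_missing)) {
    m <- m[!(as.integer(rownames(m)) %in% total_missing), , drop = FALSE]
    compared <- 16569L - length(total_missing)
  } else {
    compared <- 16569L
  }
  attr(m, "compared_sites") <- compared
  m
}

#' Number of segregating (variable) sites
#'
#' @param profiles list of `variant_profile` under a common mask.
#' @param include_indels count indel positions as sites?
#' @param deletion site-deletion policy.
#' @return integer count of positions with >= 2 observed states.
#' @export
segregating_sites <- function(profiles, include_indels = FALSE,
                              deletion = "complete") {
  if (!length(profiles)) stop_input("no profiles")
  m <- state_matrix(profiles, include_indels, deletion)
  if (!nrow(m)) return(0L)
  sum(apply(m, 1L, function(r) length(unique(r[!is.na(r)])) >= 2L))
}

#' Haplotype (gene) diversity with its sampling standard deviation
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype class frequencies, with
#' the standard sampling-variance formula for heterozygosity (Nei 1987).
#'
#' @param classes list of `haplotype_class` (or profiles, collapsed first).
#' @return list with `Hd` and `SD`.
#' @export
haplotype_diversity <- function(classes) {
  if (length(classes) && inherits(classes[[1]], "variant_profile"))
    classes <- collapse_haplotypes(classes)
  counts <- vapply(classes, `[[`, numeric(1), "multiplicity")
  n <- sum(counts)
  if (n < 2) stop_input("haplotype diversity needs n >= 2")
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, SD = sqrt(max(0, v)))
}

#' Mean pairwise differences, nucleotide diversity and its SD
#'
#' `k` is the mean over all unordered sample pairs of the per-pair count of
#' differing states at mutually compared sites; `Pi = k / L` with `L` the
#' number of compared sites; the SD is the standard total-variance
#' estimator for nucleotide diversity (Nei 1987 eq. 10.7).
#'
#' @inheritParams segregating_sites
#' @return list with `k`, `Pi`, `Pi_SD`, `compared_sites`.
#' @export
pairwise_stats <- function(profiles, include_indels = FALSE,
                           deletion = "complete") {
  n <- length(profiles)
  if (n < 2) stop_input("pairwise statistics need n >= 2")
  m <- state_matrix(profiles, include_indels, deletion)
  L <- attr(m, "compared_sites")
  if (L <= 0) stop_input("zero compared sites")
  npairs <- n * (n - 1) / 2
  if (!nrow(m)) {
    k <- 0
  } else {
    diffs <- apply(m, 1L, function(r) {
      ok <- !is.na(r)
      nn <- sum(ok)
      cnt <- table(r[ok])
      same <- sum(cnt * (cnt - 1) / 2)
      pairs_here <- nn * (nn - 1) / 2
      # pairwise deletion: scale each site to the full pair count
      (pairs_here - same) * (npairs / max(1, pairs_here))
    })
    k <- sum(diffs) / npairs
  }
  pi <- k / L
  v <- (n + 1) / (3 * (n - 1)) * pi / L +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  list(k = k, Pi = pi, Pi_SD = sqrt(max(0, v)), compared_sites = L)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the full constant
#' cascade from the sample size. Undefined (an explicit error, not NaN)
#' when `S = 0` or `n < 4`. Significance, when requested, is classified by
#' neutral coalescent simulation conditioned on `S` (mutations placed on
#' simulated genealogies proportionally to branch length) rather than the
#' beta approximation.
#'
#' @param S number of segregating sites.
#' @param k mean pairwise differences.
#' @param n sample size.
#' @param n_reps simulation replicates for the significance class
#'   (0 = no classification).
#' @param seed RNG seed for the simulation.
#' @return list with `D` and `significance` (one of `"ns"`, `"P<0.05"`,
#'   `"P<0.01"`, `"P<0.001"`, or `NA` when not classified).
#' @export
tajimas_d <- function(S, k, n, n_reps = 0L, seed = 1L) {
  if (n < 4) stop_input("Tajima's D requires n >= 4")
  if (S < 1) stop_input("Tajima's D is undefined at S = 0")
  cons <- tajima_constants(n)
  D <- (k - S / cons$a1) / sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
  sig <- NA_character_
  if (n_reps > 0) {
    sims <- simulate_neutral_d(n, S, n_reps, seed)
    p <- if (D < 0) mean(sims <= D) else mean(sims >= D)
    sig <- if (p < 0.001) "P<0.001" else if (p < 0.01) "P<0.01" else
      if (p < 0.05) "P<0.05" else "ns"
  }
  list(D = D, significance = sig)
}

# Neutral coalescent null distribution of D conditioned on S: simulate a
# constant-size genealogy, throw S mutations on branches proportionally to
# length, compute k from derived-allele counts.
simulate_neutral_d <- function(n, S, n_reps, seed) {
  local_rng(seed)
  cons <- tajima_constants(n)
  npairs <- n * (n - 1) / 2
  vapply(seq_len(n_reps), function(r) {
    sizes <- branch_subtree_sizes(n)
    counts <- sizes$size[sample.int(length(sizes$size), S, replace = TRUE,
                                    prob = sizes$len)]
    k <- sum(counts * (n - counts)) / npairs
    (k - S / cons$a1) / sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
  }, numeric(1))
}

# Simulate a standard constant-size coalescent topology and return, per
# branch, its length (in coalescent units) and the number of tips below it.
branch_subtree_sizes <- function(n) {
  size <- rep(1L, n)
  active <- seq_len(n)
  nsize <- integer(2 * n - 2); nlen <- numeric(2 * n - 2)
  born <- numeric(2 * n - 1)  # time each lineage (re)starts
  t <- 0; nxt <- n + 1L; ei <- 0L
  sizes <- c(size, integer(n - 1L))
  repeat {
    kk <- length(active)
    if (kk == 1L) break
    t <- t + stats::rexp(1, kk * (kk - 1) / 2)
    pair <- sample(active, 2L)
    for (ch in pair) {
      ei <- ei + 1L
      nsize[ei] <- sizes[ch]
      nlen[ei] <- t - born[ch]
    }
    sizes[nxt] <- sizes[pair[1]] + sizes[pair[2]]
    born[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  list(size = nsize[seq_len(ei)], len = nlen[seq_len(ei)])
}

#' Per-population diversity summary
#'
#' One row per population plus `"Total"`: sample size, haplotype count,
#' segregating sites, haplotype diversity (SD), nucleotide diversity (SD),
#' mean pairwise differences, Tajima's D and its significance class.
#' Populations with fewer than 2 samples are skipped with a warning.
#'
#' @param profiles list of `variant_profile`.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param include_indels,deletion see [pairwise_stats()].
#' @param d_reps,seed Tajima's D significance simulation settings.
#' @return data.frame shaped like a classical diversity table.
#' @export
diversity_summary <- function(profiles, metadata, include_indels = FALSE,
                              deletion = "complete", d_reps = 1000L,
                              seed = 1L) {
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  i <- match(ids, metadata$sample_id)
  if (anyNA(i))
    stop_input("samples missing from metadata: ",
               paste(ids[is.na(i)], collapse = ", "))
  pop <- as.character(metadata$population[i])
  groups <- c(split(seq_along(profiles), pop),
              list(Total = seq_along(profiles)))
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    if (length(idx) < 2) {
      warning("population ", gname, " has n < 2; skipped")
      return(NULL)
    }
    pr <- profiles[idx]
    cls <- collapse_haplotypes(pr)
    S <- segregating_sites(pr, include_indels, deletion)
    hd <- haplotype_diversity(cls)
    pw <- pairwise_stats(pr, include_indels, deletion)
    n <- length(idx)
    if (n >= 4 && S >= 1) {
      td <- tajimas_d(S, pw$k, n, n_reps = d_reps, seed = seed)
    } else {
      td <- list(D = NA_real_, significance = NA_character_)
    }
    data.frame(population = gname, n = n, h = length(cls), S = S,
               Hd = hd$Hd, Hd_SD = hd$SD, Pi = pw$Pi, Pi_SD = pw$Pi_SD,
               k = pw$k, D = td$D, D_sig = td$significance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
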