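#' Population structure: distances, AMOVA, PhiST, MDS
#'
#' Distances are raw pairwise difference counts (no substitution-model
#' correction), the common default for intra-species mtDNA work. AMOVA is
#' the distance-based hierarchical variance decomposition with
#' method-of-moments variance components and Phi statistics; p-values come
#' from permutation with the `(b+1)/(m+1)` estimator.
#'
#' @name structure
NULL

#' Pairwise difference-count distance matrix
#'
#' @param profiles list of `variant_profile` under a common mask.
#' @param include_indels,deletion see [pairwise_stats()].
#' @return symmetric nonnegative matrix with sample ids as dimnames and a
#'   zero diagonal.
#' @export
distance_matrix <- function(profiles, include_indels = FALSE,
                            deletion = "complete") {
  if (!length(profiles)) stop_input("no profiles")
  m <- state_matrix(profiles, include_indels, deletion)
  n <- ncol(m)
  ids <- colnames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(m)) {
    # one-hot encode site states; mismatches = sites - matches
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- m[, i]; b <- m[, j]
        ok <- !is.na(a) & !is.na(b)
        d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
      }
    }
  }
  d
}

amova_ssd <- function(d2, idx_groups) {
  # sum of squared deviations from squared distances for one grouping level
  vapply(idx_groups, function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, numeric(1))
}

amova_components <- function(d2, pop, grp = NULL) {
  N <- length(pop)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  ssd_t <- sum(d2) / (2 * N)
  ssd_wp <- sum(amova_ssd(d2, pops))
  n_p <- lengths(pops)
  if (is.null(grp)) {
    df_ap <- P - 1; df_wp <- N - P
    ms_ap <- (ssd_t - ssd_wp) / df_ap
    ms_wp <- ssd_wp / df_wp
    nc <- (N - sum(n_p^2) / N) / (P - 1)
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / nc
    comps <- c(among_populations = sig_b, within_populations = sig_c)
    total <- sig_b + sig_c
    phi <- c(phi_st = sig_b / total)
    list(components = comps, phi = phi, total = total,
         df = c(among_populations = df_ap, within_populations = df_wp),
         ssd = c(among_populations = ssd_t - ssd_wp,
                 within_populations = ssd_wp))
  } else {
    groups <- split(seq_len(N), grp)
    G <- length(groups)
    ssd_wg <- sum(amova_ssd(d2, groups))
    ssd_ag <- ssd_t - ssd_wg
    ssd_apwg <- ssd_wg - ssd_wp
    df_ag <- G - 1; df_apwg <- P - G; df_wp <- N - P
    ms_ag <- ssd_ag / df_ag
    ms_apwg <- ssd_apwg / df_apwg
    ms_wp <- ssd_wp / df_wp
    pop_by_grp <- split(pop, grp)
    n_pg2 <- vapply(names(groups), function(g) {
      tab <- table(pop_by_grp[[g]])
      sum(tab^2) / sum(tab)
    }, numeric(1))
    n1 <- (N - sum(n_pg2)) / (P - G)
    n2 <- (sum(n_pg2) - sum(n_p^2) / N) / (G - 1)
    n_g <- lengths(groups)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sig_c <- ms_wp
    sig_b <- (ms_apwg - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    comps <- c(among_groups = sig_a, among_populations = sig_b,
               within_populations = sig_c)
    total <- sum(comps)
    phi <- c(phi_ct = sig_a / total,
             phi_sc = sig_b / (sig_b + sig_c),
             phi_st = (sig_a + sig_b) / total)
    list(components = comps, phi = phi, total = total,
         df = c(among_groups = df_ag, among_populations = df_apwg,
                within_populations = df_wp),
         ssd = c(among_groups = ssd_ag, among_populations = ssd_apwg,
                 within_populations = ssd_wp))
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Two-level (populations within total) or three-level (populations within
#' groups within total) distance-based AMOVA. Following the molecular
#' convention, the entries of `d` (pairwise difference counts) are taken
#' as the squared Euclidean distances of the decomposition -- each
#' differing site contributes one squared unit. Variance components are
#' reported as computed (negative components are not clamped); the
#' percentage column is renormalised for display. Permutation p-values
#' permute samples among populations (and, for Phi_CT, whole populations
#' among groups), with a fixed seed: permutations act on matrix indices, so
#' results are invariant to input row order.
#'
#' @param d distance matrix from [distance_matrix()].
#' @param populations character vector of population labels, aligned with
#'   the rows of `d`.
#' @param groups optional higher-level group labels per sample.
#' @param n_perm number of permutations (0 = no p-values).
#' @param seed permutation RNG seed.
#' @return object of class `amova_result`.
#' @export
amova <- function(d, populations, groups = NULL, n_perm = 10000L,
                  seed = 1L) {
  d <- as.matrix(d)
  N <- nrow(d)
  stopifnot(length(populations) == N)
  if (n_perm < 0) stop_input("negative n_perm")
  if (any(table(populations) < 2))
    stop_input("every population needs >= 2 samples")
  if (length(unique(populations)) < 2)
    stop_input("need >= 2 populations")
  # canonical ordering (population, then sample id when available) makes
  # the fixed-seed permutation protocol invariant to input row order
  ord <- if (!is.null(rownames(d))) order(populations, rownames(d))
         else order(populations)
  d <- d[ord, ord]; populations <- populations[ord]
  if (!is.null(groups)) groups <- groups[ord]
  # molecular convention: pairwise difference counts ARE the squared
  # Euclidean distances of the decomposition (one unit per differing site)
  d2 <- d
  obs <- amova_components(d2, populations, groups)
  pvals <- rep(NA_real_, length(obs$phi))
  names(pvals) <- names(obs$phi)
  if (n_perm > 0) {
    local_rng(seed)
    hits <- stats::setNames(numeric(length(obs$phi)), names(obs$phi))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(N)
      ph <- amova_components(d2[perm, perm], populations, groups)$phi
      if (!is.na(obs$phi["phi_st"]) && !is.na(ph["phi_st"]) &&
          ph["phi_st"] >= obs$phi["phi_st"] - 1e-12)
        hits["phi_st"] <- hits["phi_st"] + 1
      if (!is.null(groups)) {
        # Phi_SC: permute samples among populations within their group
        perm_wg <- seq_len(N)
        for (idx in split(seq_len(N), groups))
          perm_wg[idx] <- idx[sample.int(length(idx))]
        ph_sc <- amova_components(d2[perm_wg, perm_wg], populations,
                                  groups)$phi["phi_sc"]
        if (!is.na(obs$phi["phi_sc"]) && !is.na(ph_sc) &&
            ph_sc >= obs$phi["phi_sc"] - 1e-12)
          hits["phi_sc"] <- hits["phi_sc"] + 1
      }
      if (!is.null(groups)) {
        # Phi_CT: permute whole populations among groups
        pops <- unique(populations)
        gl <- vapply(pops, function(p)
          groups[match(p, populations)], character(1))
        gl_perm <- sample(gl)
        grp_perm <- gl_perm[match(populations, pops)]
        ph_ct <- amova_components(d2, populations, grp_perm)$phi["phi_ct"]
        if (!is.na(obs$phi["phi_ct"]) && !is.na(ph_ct) &&
            ph_ct >= obs$phi["phi_ct"] - 1e-12)
          hits["phi_ct"] <- hits["phi_ct"] + 1
      }
    }
    pvals <- (hits + 1) / (n_perm + 1)
    pvals[is.na(obs$phi)] <- NA_real_
    if (is.null(groups)) pvals <- pvals["phi_st"]
  }
  pct <- 100 * obs$components / sum(obs$components)
  structure(list(levels = names(obs$components),
                 ssd = obs$ssd, df = obs$df,
                 variance_components = obs$components,
                 percent_variation = pct,
                 phi_statistics = obs$phi,
                 p_values = pvals,
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  df <- data.frame(source = x$levels, df = as.integer(x$df),
                   SSD = round(x$ssd, 3),
                   variance = round(x$variance_components, 4),
                   percent = round(x$percent_variation, 2))
  print(df, row.names = FALSE)
  cat("Phi:", paste(sprintf("%s=%.4f", names(x$phi_statistics),
                            x$phi_statistics), collapse = "  "), "\n")
  if (!all(is.na(x$p_values)))
    cat("p:", paste(sprintf("%s=%.4g", names(x$p_values), x$p_values),
                    collapse = "  "),
        sprintf(" (%d permutations)\n", x$n_permutations))
  invisible(x)
}

#' Write an AMOVA table as TSV
#' @param x an `amova_result`.
#' @param path output path.
#' @export
write_amova_tsv <- function(x, path) {
  df <- data.frame(source = x$levels, df = as.integer(x$df), ssd = x$ssd,
                   variance_component = x$variance_components,
                   percent = x$percent_variation)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise PhiST matrix with permutation p-values
#'
#' Every population pair is analysed as a two-population AMOVA;
#' `p = (b+1)/(m+1)` with `b` the number of permuted PhiST values at least
#' as large as the observed one.
#'
#' @inheritParams amova
#' @return list with matrices `phi_st` and `p`.
#' @export
pairwise_phist <- function(d, populations, n_perm = 10000L, seed = 1L) {
  d <- as.matrix(d)
  pops <- sort(unique(populations))
  np <- length(pops)
  phi <- p <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  diag(phi) <- 0
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      idx <- which(populations %in% c(pops[i], pops[j]))
      res <- amova(d[idx, idx], populations[idx], n_perm = n_perm,
                   seed = seed)
      phi[i, j] <- phi[j, i] <- unname(res$phi_statistics["phi_st"])
      p[i, j] <- p[j, i] <- unname(res$p_values["phi_st"])
    }
  }
  list(phi_st = phi, p = p, n_permutations = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Nonmetric multidimensional scaling of a PhiST matrix
#'
#' Kruskal stress-1 minimisation (via [MASS::isoMDS]) from a
#' classical-scaling start plus random restarts; the best configuration is
#' returned, centred at the origin. Slightly negative PhiST entries are
#' clamped to zero with a warning. Deterministic under a fixed seed.
#'
#' @param fst square symmetric dissimilarity matrix (e.g. pairwise PhiST).
#' @param dim embedding dimension (2 matches the conventional plot).
#' @param seed RNG seed for the restarts.
#' @param restarts number of random restarts on top of the classical start.
#' @param metric use metric (classical) scaling only, skipping the
#'   nonmetric stress minimisation.
#' @return object of class `mds_embedding`: `labels`, `coords`, `stress`
#'   (Kruskal stress-1, on the 0..1 scale), `seed`, `restarts`.
#' @export
mds <- function(fst, dim = 2L, seed = 1L, restarts = 10L, metric = FALSE) {
  fst <- as.matrix(fst)
  if (!isTRUE(all.equal(fst, t(fst), tolerance = 1e-8)))
    stop_input("non-symmetric input matrix")
  labels <- rownames(fst) %||% paste0("pop", seq_len(nrow(fst)))
  if (any(fst < 0)) {
    warning("negative dissimilarities clamped to 0")
    fst[fst < 0] <- 0
  }
  diag(fst) <- 0
  n <- nrow(fst)
  if (n <= dim) {
    # small configurations embed exactly; classical scaling suffices
    cmd <- stats::cmdscale(fst, k = min(dim, max(1, n - 1)))
    coords <- cbind(cmd, matrix(0, n, dim - ncol(cmd)))
    coords <- scale(coords, scale = FALSE)
    return(structure(list(labels = labels, coords = coords, stress = 0,
                          seed = as.integer(seed),
                          restarts = 0L, metric = metric),
                     class = "mds_embedding"))
  }
  # isoMDS requires positive off-diagonal dissimilarities
  dd <- fst
  off <- dd[upper.tri(dd)]
  eps <- if (any(off > 0)) min(off[off > 0]) * 1e-6 else 1e-9
  dd[dd <= 0] <- eps
  diag(dd) <- 0
  dis <- stats::as.dist(dd)
  # small configurations can have fewer positive eigenvalues than dim;
  # missing start columns are zero-filled below
  start <- suppressWarnings(stats::cmdscale(dd, k = dim))
  if (ncol(start) < dim)
    start <- cbind(start, matrix(0, n, dim - ncol(start)))
  if (metric) {
    coords <- scale(start, scale = FALSE)
    return(structure(list(labels = labels, coords = coords,
                          stress = kruskal_stress(dis, coords),
                          seed = as.integer(seed), restarts = 0L,
                          metric = TRUE),
                     class = "mds_embedding"))
  }
  local_rng(seed)
  fits <- vector("list", restarts + 1L)
  fits[[1]] <- suppressWarnings(MASS::isoMDS(dis, y = start, k = dim,
                                             trace = FALSE))
  for (r in seq_len(restarts)) {
    y0 <- matrix(stats::rnorm(n * dim), n, dim)
    fits[[r + 1L]] <- suppressWarnings(MASS::isoMDS(dis, y = y0, k = dim,
                                                    trace = FALSE))
  }
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- fits[[which.min(stresses)]]
  coords <- scale(best$points, scale = FALSE)
  dimnames(coords) <- list(labels, paste0("dim", seq_len(dim)))
  structure(list(labels = labels, coords = coords,
                 stress = best$stress / 100,  # isoMDS reports percent
                 seed = as.integer(seed), restarts = as.integer(restarts),
                 metric = FALSE),
            class = "mds_embedding")
}

kruskal_stress <- function(dis, coords) {
  dhat <- stats::dist(coords)
  d0 <- as.numeric(dis); d1 <- as.numeric(dhat)
  # stress-1 against a monotone regression of configuration distances
  iso <- stats::isoreg(d0, d1)
  fitted <- iso$yf[order(order(d0))]
  sqrt(sum((d1 - fitted)^2) / sum(d1^2))
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d points, stress-1 = %.4g (seed %d, %d restarts)\n",
              length(x$labels), x$stress, x$seed, x$restarts))
  invisible(x)
}
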