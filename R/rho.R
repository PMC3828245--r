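#' Rho-statistic molecular dating
#'
#' The rho statistic is the multiplicity-weighted mean number of mutational
#' steps from every sampled haplotype in a clade to the clade's root
#' haplotype. Its heuristic standard error is computed from the estimated
#' genealogy as a branch-weighted sum: with `n_e` the weighted number of
#' sampled lineages below edge `e` and `m_e` the mutations on that edge,
#' `sigma^2 = sum_e (n_e / n)^2 * m_e`. Under a linear clock,
#' `TMRCA = rho / (rate * effective_sites)` years.
#'
#' @name rho_clock
NULL

# Internal: root-to-node mutation distances and per-edge subtree weights.
genealogy_walk <- function(g) {
  children <- split(seq_len(nrow(g$edges)), g$edges$parent)
  depth <- stats::setNames(numeric(nrow(g$nodes)), g$nodes$id)
  below <- numeric(nrow(g$edges))
  mult <- stats::setNames(g$nodes$multiplicity, g$nodes$id)
  rec <- function(id, d) {
    depth[id] <<- d
    w <- mult[id]
    for (e in children[[id]] %||% integer(0)) {
      wc <- rec(g$edges$child[e], d + g$edges$m[e])
      below[e] <<- wc
      w <- w + wc
    }
    w
  }
  total <- rec(g$root, 0)
  list(depth = depth, below = below, total = total)
}

#' Compute the rho statistic of a rooted clade genealogy
#'
#' `rho = sum_i multiplicity_i * d(root, i) / sum_i multiplicity_i`, the
#' sum running over observed haplotypes and `d` counting mutations along
#' the genealogy path.
#' @param g a `clade_genealogy`.
#' @return nonnegative number.
#' @export
compute_rho <- function(g) {
  if (!nrow(g$nodes) || g$n == 0L) stop_input("empty genealogy")
  w <- genealogy_walk(g)
  mult <- g$nodes$multiplicity
  sum(mult * w$depth[g$nodes$id]) / sum(mult)
}

#' Heuristic standard error of rho
#'
#' @param g a `clade_genealogy`.
#' @return `sqrt( sum_e (n_e/n)^2 m_e )`.
#' @export
compute_sigma <- function(g) {
  if (!nrow(g$nodes) || g$n == 0L) stop_input("empty genealogy")
  if (!nrow(g$edges)) return(0)
  w <- genealogy_walk(g)
  sqrt(sum((w$below / w$total)^2 * g$edges$m))
}

#' Mutation clock models
#'
#' The complete-genome clock defaults to 1.665e-8 substitutions per site
#' per year over 16,569 sites. The synonymous clock counts only synonymous
#' substitutions; its rate and site count are configuration parameters. A
#' `correction` hook (identity by default) allows a rho -> rho' adjustment
#' (e.g. a purifying-selection correction) before conversion to years.
#'
#' @param name `"complete_genome"` or `"synonymous"`.
#' @param rate substitutions per site per year.
#' @param effective_sites sites counted by this clock.
#' @param correction function rho -> adjusted rho.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name = c("complete_genome", "synonymous"),
                        rate = NULL, effective_sites = NULL,
                        correction = identity) {
  name <- match.arg(name)
  # synonymous default: one synonymous substitution per 7884 years over
  # ~4212 synonymous sites, the conventional companion calibration to the
  # 1.665e-8 complete-genome clock
  if (is.null(rate))
    rate <- if (name == "complete_genome") 1.665e-8 else 3.011e-8
  if (is.null(effective_sites))
    effective_sites <- if (name == "complete_genome") 16569L else 4212L
  stopifnot(rate > 0, effective_sites >= 1)
  structure(list(name = name, rate = rate,
                 effective_sites = as.integer(effective_sites),
                 correction = correction),
            class = "clock_model")
}

#' Convert rho and sigma into a TMRCA estimate
#'
#' `t = correction(rho) / (rate * effective_sites)` years; the reported
#' interval converts `rho +/- k * sigma` through the same clock and is
#' floored at zero.
#'
#' @param rho,sigma rho statistic and its heuristic standard error.
#' @param clock a `clock_model`.
#' @param n weighted sample size (carried through for reporting).
#' @param k_sigma half-width of the interval in sigma units (1 by default,
#'   2 available by flag).
#' @return object of class `rho_estimate` with fields `rho`, `sigma`, `n`,
#'   `tmrca_years`, `ci_years`.
#' @export
rho_to_time <- function(rho, sigma = 0, clock = clock_model(), n = NA_real_,
                        k_sigma = 1) {
  if (!is.finite(rho) || !is.finite(sigma))
    stop_input("non-finite rho or sigma")
  conv <- function(r) clock$correction(r) / (clock$rate * clock$effective_sites)
  t <- max(0, conv(rho))
  lo <- max(0, conv(max(0, rho - k_sigma * sigma)))
  hi <- max(0, conv(rho + k_sigma * sigma))
  structure(list(rho = rho, sigma = sigma, n = n, clock = clock$name,
                 tmrca_years = t, ci_years = c(lo, hi),
                 k_sigma = k_sigma),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf(
    "<rho_estimate> %s: rho = %.3f (sigma %.3f), TMRCA = %.0f y [%.0f, %.0f]\n",
    x$clock, x$rho, x$sigma, x$tmrca_years, x$ci_years[1], x$ci_years[2]))
  invisible(x)
}

# Restrict a genealogy's edge mutation counts to the labels satisfying
# `keep_label`; edges keep their topology, only m_e changes.
filter_genealogy_mutations <- function(g, keep_label) {
  if (!nrow(g$edges)) return(g)
  g$edge_labels <- lapply(g$edge_labels, function(l) l[keep_label(l)])
  g$edges$m <- vapply(g$edge_labels, length, numeric(1))
  g
}

#' Date a clade under one or more clocks
#'
#' The complete-genome clock excludes masked hot-spot positions from the
#' edge mutation counts (they are normally masked upstream already); the
#' synonymous clock counts only synonymous substitutions, which requires
#' the genealogy's edge mutation labels plus the gene annotation.
#'
#' @param g a `clade_genealogy` whose edges carry mutation labels.
#' @param clocks list of `clock_model`.
#' @param annotation gene table from [mt_annotation()] (required when a
#'   synonymous clock is requested).
#' @param ref `reference_genome` (required with `annotation`).
#' @param policy mask applied to edge labels for the complete-genome clock.
#' @param k_sigma interval half-width in sigma units.
#' @return data.frame with one row per clock: `clock`, `rho`, `sigma`, `n`,
#'   `tmrca_years`, `ci_low`, `ci_high`.
#' @export
clade_ages <- function(g, clocks = list(clock_model("complete_genome")),
                       annotation = NULL, ref = NULL,
                       policy = mask_policy(), k_sigma = 1) {
  rows <- lapply(clocks, function(clock) {
    gg <- if (clock$name == "synonymous") {
      if (is.null(annotation) || is.null(ref))
        stop_input("synonymous clock requires annotation and ref")
      filter_genealogy_mutations(g, function(l) {
        if (!length(l)) return(logical(0))
        v <- parse_variant_labels(l, ref)
        sub <- v$kind %in% c("transition", "transversion")
        cls <- rep("", length(l))
        cls[sub] <- annotate_variants(v[sub, , drop = FALSE], annotation, ref)
        cls == "synonymous"
      })
    } else {
      filter_genealogy_mutations(g, function(l)
        l %in% mask_labels(l, policy))
    }
    est <- rho_to_time(compute_rho(gg), compute_sigma(gg), clock,
                       n = g$n, k_sigma = k_sigma)
    data.frame(clock = clock$name, rho = est$rho, sigma = est$sigma,
               n = g$n, tmrca_years = est$tmrca_years,
               ci_low = est$ci_years[1], ci_high = est$ci_years[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
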