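#' Coalescent simulation of complete mitogenomes
#'
#' Generates datasets with the statistical structure the analysis assumes:
#' Kingman-coalescent genealogies under constant-size, exponential-growth
#' or two-epoch demography (all sizes in haploid units, matching mtDNA
#' inheritance), mutations dropped as a Poisson process with per-site
#' hotspot multipliers, and a finite island model with a known equilibrium
#' FST. Every simulation emits a truth table (genealogy, realised TMRCA,
#' per-branch mutation events, recurrent-site flags) for recovery tests.
#'
#' @name synthetic_data
NULL

#' Demographic model for the coalescent simulator
#'
#' @param kind `"constant"`, `"exponential_growth"` or `"two_epoch"`.
#' @param N present-day effective size (haploid lineages).
#' @param growth_rate per-generation exponential growth rate (forwards in
#'   time), used by `"exponential_growth"`.
#' @param N_ancient ancestral size for `"two_epoch"`.
#' @param epoch_gen generations before present at which the two-epoch
#'   size switches from `N` to `N_ancient`.
#' @export
demographic_model <- function(kind = c("constant", "exponential_growth",
                                       "two_epoch"),
                              N = 1000, growth_rate = 0.01,
                              N_ancient = N / 10, epoch_gen = 0) {
  kind <- match.arg(kind)
  if (N <= 0 || N_ancient <= 0) stop_input("effective sizes must be > 0")
  if (epoch_gen < 0) stop_input("epoch boundary must be >= 0")
  if (kind == "exponential_growth" && growth_rate <= 0)
    stop_input("growth_rate must be > 0 for exponential growth")
  structure(list(kind = kind, N = N, growth_rate = growth_rate,
                 N_ancient = N_ancient, epoch_gen = epoch_gen),
            class = "demographic_model")
}

# Waiting time to the next coalescence for k lineages starting at backward
# time t, by inversion of the cumulative hazard of the inhomogeneous
# coalescent rate choose(k,2) / N(t).
coal_wait <- function(model, k, t) {
  rate0 <- k * (k - 1) / 2
  u <- stats::rexp(1)
  switch(model$kind,
    constant = u * model$N / rate0,
    exponential_growth = {
      g <- model$growth_rate
      # backwards size N(t) = N * exp(-g t)
      log(exp(g * t) + u * model$N * g / rate0) / g - t
    },
    two_epoch = {
      if (t >= model$epoch_gen) {
        u * model$N_ancient / rate0
      } else {
        w1 <- u * model$N / rate0
        if (t + w1 <= model$epoch_gen) w1 else {
          used <- (model$epoch_gen - t) * rate0 / model$N
          (model$epoch_gen - t) + (u - used) * model$N_ancient / rate0
        }
      }
    })
}

#' Simulate a coalescent genealogy
#'
#' Pairwise coalescence at rate `k(k-1)/2 / N(t)`; time-varying sizes are
#' handled by cumulative-hazard inversion. Times are in generations.
#'
#' @param model a [demographic_model()].
#' @param n number of sampled lineages (>= 2).
#' @param seed RNG seed.
#' @return object of class `sim_genealogy`: an `ape::phylo` tree (`phylo`),
#'   `tmrca_gen`, tip labels `s1..sn`.
#' @export
simulate_genealogy <- function(model, n, seed = 1L) {
  if (n < 2) stop_input("n must be >= 2")
  local_rng(seed)
  merges <- sim_merge_events(model, n)
  build_sim_genealogy(merges, n, populations = rep("pop1", n))
}

sim_merge_events <- function(model, n, t0 = 0) {
  active <- seq_len(n)
  t <- t0; nxt <- n + 1L
  merges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    k <- length(active)
    t <- t + coal_wait(model, k, t)
    pair <- sort(sample(active, 2L))
    merges[[i]] <- list(children = pair, id = nxt, time = t)
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  merges
}

# Convert merge events into an ape phylo (root = n+1) with edge lengths in
# generations.
build_sim_genealogy <- function(merges, n, populations) {
  nm <- length(merges)
  times <- c(rep(0, n), vapply(merges, `[[`, numeric(1), "time"))
  # internal node 'id' i (n+i) gets ape number 2n - i (root n+1 last merge)
  ape_id <- c(seq_len(n), 2L * n - seq_len(nm) + 0L)
  ape_id[(n + 1L):(n + nm)] <- 2L * n - seq_len(nm)
  edge <- matrix(0L, 2L * nm, 2L)
  elen <- numeric(2L * nm)
  r <- 0L
  for (i in seq_len(nm)) {
    m <- merges[[i]]
    for (ch in m$children) {
      r <- r + 1L
      edge[r, ] <- c(ape_id[m$id], ape_id[ch])
      elen[r] <- m$time - times[ch]
    }
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = paste0("s", seq_len(n)),
                        Nnode = nm),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  structure(list(phylo = phy, tmrca_gen = max(times),
                 populations = stats::setNames(populations,
                                               paste0("s", seq_len(n))),
                 n = n),
            class = "sim_genealogy")
}

#' Default mutational hotspot table
#'
#' Multiplicative rate factors at the classic hot spots (16182, 16183,
#' 16519) plus poly-C length-variation hotspots modelled as C-insertion
#' processes anchored at nps 309 and 16189. Factors are in units of the
#' genome-wide per-site rate.
#' @export
default_hotspots <- function() {
  data.frame(position = c(16182L, 16183L, 16519L, 309L, 16189L),
             factor = c(30, 30, 30, 10, 10),
             type = c("sub", "sub", "sub", "ins", "ins"),
             stringsAsFactors = FALSE)
}

#' Drop mutations onto a simulated genealogy
#'
#' Per-branch mutation counts are Poisson with mean
#' `rate * effective_site_weight * branch_years`; sites are chosen
#' proportionally to their weights (1 for ordinary sites, the hotspot
#' factor otherwise). Substitutions are transition-biased; insertion
#' hotspots add a C to their poly-C tract. Mutations are applied to the
#' reference-derived root sequence down the tree, so the sampled sequences
#' are full mitogenomes.
#'
#' @param sim a `sim_genealogy`.
#' @param rate substitutions per site per year.
#' @param generation_time years per generation.
#' @param ref a `reference_genome` used as the root sequence.
#' @param hotspots hotspot table as in [default_hotspots()] (`NULL` for a
#'   uniform rate).
#' @param ts_fraction fraction of substitutions that are transitions.
#' @param seed RNG seed.
#' @return list with `sequences` (list of `mt_sequence`) and `truth`
#'   (class `sim_truth`).
#' @export
drop_mutations <- function(sim, rate = 1.665e-8, generation_time = 25,
                           ref = mt_reference(), hotspots = default_hotspots(),
                           ts_fraction = 0.94, seed = 1L) {
  if (rate <= 0) stop_input("rate must be > 0")
  local_rng(seed)
  L <- nchar(ref$bases)
  w <- rep(1, L)
  ins_pos <- integer(0); ins_w <- numeric(0)
  if (!is.null(hotspots) && nrow(hotspots)) {
    subs <- hotspots[hotspots$type == "sub", , drop = FALSE]
    w[subs$position] <- subs$factor
    insr <- hotspots[hotspots$type == "ins", , drop = FALSE]
    ins_pos <- insr$position; ins_w <- insr$factor
  }
  site_pool <- c(seq_len(L), ins_pos)
  type_pool <- c(rep("sub", L), rep("ins", length(ins_pos)))
  weight_pool <- c(w, ins_w)
  total_w <- sum(weight_pool)
  phy <- sim$phylo
  n <- sim$n
  nnode <- n + phy$Nnode
  root <- n + 1L
  base0 <- strsplit(ref$bases, "")[[1]]
  seqs <- vector("list", nnode)
  inserts <- vector("list", nnode)
  seqs[[root]] <- base0
  inserts[[root]] <- integer(0)
  events <- list()
  branch_counts <- numeric(nrow(phy$edge))
  # preorder traversal (cladewise edge order guarantees parent before child)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    s <- seqs[[par]]; insv <- inserts[[par]]
    years <- phy$edge.length[e] * generation_time
    nmut <- stats::rpois(1, rate * total_w * years)
    branch_counts[e] <- nmut
    if (nmut > 0) {
      picks <- sample.int(length(site_pool), nmut, replace = TRUE,
                          prob = weight_pool)
      for (p in picks) {
        if (type_pool[p] == "sub") {
          pos <- site_pool[p]
          from <- s[pos]
          to <- if (stats::runif(1) < ts_fraction) transition_partner(from)
                else sample(setdiff(c("A", "C", "G", "T"),
                                    c(from, transition_partner(from))), 1L)
          s[pos] <- to
          events[[length(events) + 1L]] <-
            data.frame(edge = e, node = ch, position = pos, type = "sub",
                       from = from, to = to, stringsAsFactors = FALSE)
        } else {
          pos <- site_pool[p]
          nm <- as.character(pos)
          insv[nm] <- (if (nm %in% names(insv)) insv[nm] else 0L) + 1L
          events[[length(events) + 1L]] <-
            data.frame(edge = e, node = ch, position = pos, type = "ins",
                       from = "", to = "C", stringsAsFactors = FALSE)
        }
      }
    }
    seqs[[ch]] <- s; inserts[[ch]] <- insv
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(edge = integer(0), node = integer(0), position = integer(0),
               type = character(0), from = character(0), to = character(0))
  sub_events <- events[events$type == "sub", , drop = FALSE]
  recurrent <- sort(unique(sub_events$position[
    duplicated(sub_events$position)]))
  sequences <- lapply(seq_len(n), function(tip) {
    s <- seqs[[tip]]
    insv <- inserts[[tip]]
    if (length(insv)) {
      segs <- character(0); last <- 0L
      for (nm in as.character(sort(as.integer(names(insv))))) {
        pos <- as.integer(nm)
        segs <- c(segs, paste(s[(last + 1L):pos], collapse = ""),
                  strrep("C", insv[nm]))
        last <- pos
      }
      segs <- c(segs, paste(s[(last + 1L):L], collapse = ""))
      bases <- paste(segs, collapse = "")
    } else {
      bases <- paste(s, collapse = "")
    }
    structure(list(sample_id = phy$tip.label[tip], bases = bases,
                   population = unname(sim$populations[phy$tip.label[tip]]),
                   ethnic_group = NA_character_, province = NA_character_),
              class = "mt_sequence")
  })
  truth <- structure(list(
    newick = ape::write.tree(phy),
    tmrca_gen = sim$tmrca_gen,
    tmrca_years = sim$tmrca_gen * generation_time,
    generation_time = generation_time,
    rate = rate,
    events = events,
    branch_counts = branch_counts,
    recurrent_sites = recurrent,
    populations = sim$populations,
    expected_fst = sim$expected_fst %||% NA_real_,
    seed = as.integer(seed)),
    class = "sim_truth")
  list(sequences = sequences, truth = truth)
}

#' Simulation configuration for the island model
#'
#' @param n_per_population samples per sampled deme (recycled to
#'   `n_populations`).
#' @param n_populations number of sampled demes.
#' @param n_demes total demes in the island model. The truth value
#'   `expected_fst = 1/(1 + 2*Nm)` is the many-deme equilibrium for haploid
#'   demes; the default of 16 demes keeps the finite-island correction
#'   small.
#' @param Nm migration parameter (migrants per deme per generation).
#' @param deme_size haploid effective size per deme.
#' @param mutation_rate per site per year.
#' @param generation_time years per generation.
#' @param hotspots hotspot table (see [default_hotspots()]).
#' @param seed RNG seed, recorded in every output.
#' @export
sim_config <- function(n_per_population = 10L, n_populations = 4L,
                       n_demes = 16L, Nm = 1, deme_size = 500,
                       mutation_rate = 1.665e-8, generation_time = 25,
                       hotspots = default_hotspots(), seed = 1L) {
  if (n_populations < 2) stop_input("n_populations must be >= 2")
  if (Nm <= 0) stop_input("Nm must be > 0")
  if (mutation_rate <= 0) stop_input("mutation rate must be > 0")
  n_per <- rep_len(as.integer(n_per_population), n_populations)
  if (any(n_per < 1)) stop_input("all sample counts must be >= 1")
  list(n_per_population = n_per, n_populations = as.integer(n_populations),
       n_demes = max(as.integer(n_demes), as.integer(n_populations)),
       Nm = Nm, deme_size = deme_size, mutation_rate = mutation_rate,
       generation_time = generation_time, hotspots = hotspots,
       seed = as.integer(seed))
}

#' Simulate an island-model structured sample of mitogenomes
#'
#' Structured coalescent over `n_demes` demes of haploid size `deme_size`
#' under the textbook migrant-pool convention: forwards in time a fraction
#' `m = Nm / deme_size` of each deme is replaced from a pool drawn from all
#' demes (own deme included), so backwards each lineage moves to a
#' uniformly chosen *other* deme at rate `m (d-1)/d`. Under this convention
#' the equilibrium pairwise FST is exactly `1/(1 + 2Nm)` for any deme
#' count. Samples are taken from the first `n_populations` demes;
#' mutations are then dropped with [drop_mutations()].
#'
#' @param config from [sim_config()].
#' @param ref reference genome.
#' @return list with `sequences`, `truth` (carrying
#'   `expected_fst = 1/(1+2Nm)`) and `metadata` (sample_id, population).
#' @export
simulate_island <- function(config, ref = mt_reference()) {
  local_rng(config$seed)
  n_per <- config$n_per_population
  n <- sum(n_per)
  demes <- rep(seq_len(config$n_populations), n_per)
  N <- config$deme_size
  d <- config$n_demes
  # backward per-lineage rate of moving to a different deme (migrant-pool
  # convention: a migrant's source deme can be its own, so only (d-1)/d of
  # replacements move a lineage)
  m <- config$Nm / N * (d - 1) / d
  lineage_deme <- demes
  active <- seq_len(n)
  t <- 0; nxt <- n + 1L
  merges <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    repeat {
      k <- length(active)
      tab <- tabulate(lineage_deme[active], nbins = d)
      coal_rates <- tab * (tab - 1) / 2 / N
      tot_coal <- sum(coal_rates)
      tot_mig <- k * m
      t <- t + stats::rexp(1, tot_coal + tot_mig)
      if (stats::runif(1) < tot_coal / (tot_coal + tot_mig)) {
        deme <- sample.int(d, 1L, prob = coal_rates)
        here <- active[lineage_deme[active] == deme]
        pair <- sort(sample(here, 2L))
        merges[[i]] <- list(children = pair, id = nxt, time = t)
        lineage_deme[nxt] <- deme
        active <- c(setdiff(active, pair), nxt)
        nxt <- nxt + 1L
        break
      } else {
        lin <- active[sample.int(k, 1L)]
        lineage_deme[lin] <- sample(setdiff(seq_len(d),
                                            lineage_deme[lin]), 1L)
      }
    }
  }
  sim <- build_sim_genealogy(merges, n,
                             populations = paste0("pop", demes))
  sim$expected_fst <- 1 / (1 + 2 * config$Nm)
  out <- drop_mutations(sim, rate = config$mutation_rate,
                        generation_time = config$generation_time,
                        ref = ref, hotspots = config$hotspots,
                        seed = config$seed + 1L)
  out$metadata <- data.frame(
    sample_id = vapply(out$sequences, `[[`, character(1), "sample_id"),
    population = vapply(out$sequences, `[[`, character(1), "population"),
    stringsAsFactors = FALSE)
  out
}

#' Write a simulated dataset to disk
#'
#' FASTA, metadata TSV and truth JSON; byte-identical re-runs under the
#' same seed.
#'
#' @param sequences list of `mt_sequence`.
#' @param truth a `sim_truth`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
sim_emit <- function(sequences, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "sequences.fasta")
  ss <- Biostrings::DNAStringSet(vapply(sequences, `[[`, character(1),
                                        "bases"))
  names(ss) <- vapply(sequences, `[[`, character(1), "sample_id")
  Biostrings::writeXStringSet(ss, fa)
  md <- file.path(out_dir, "metadata.tsv")
  utils::write.table(
    data.frame(sample_id = names(ss),
               population = vapply(sequences, `[[`, character(1),
                                   "population")),
    md, sep = "\t", quote = FALSE, row.names = FALSE)
  tj <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(newick = truth$newick, tmrca_gen = truth$tmrca_gen,
         tmrca_years = truth$tmrca_years, rate = truth$rate,
         generation_time = truth$generation_time,
         expected_fst = truth$expected_fst,
         recurrent_sites = truth$recurrent_sites,
         n_events = nrow(truth$events), seed = truth$seed,
         events = truth$events),
    tj, auto_unbox = TRUE, digits = NA)
  invisible(c(fa, md, tj))
}

#' Variant profiles for simulated (or other) sequences
#'
#' Convenience composition: align each sequence to the reference, call
#' variants and apply a mask.
#' @param sequences list of `mt_sequence`.
#' @param ref reference genome.
#' @param policy mask policy (default the standard hot-spot mask).
#' @param params alignment parameters.
#' @export
profiles_for <- function(sequences, ref = mt_reference(),
                         policy = mask_policy(), params = align_params()) {
  lapply(sequences, function(s) {
    p <- call_variants(align_to_reference(s, ref, params), ref)
    apply_mask(p, policy)
  })
}
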