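#' Pipeline configuration and orchestration
#'
#' A single config drives the full analysis: variant profiling,
#' classification, diversity, dating and structure, with fixed seeds and a
#' structured run log. Every output file carries the config fingerprint in
#' a header comment, so a bundle is traceable to the exact settings that
#' produced it.
#'
#' @name pipeline_cli
NULL

#' Build a pipeline configuration
#'
#' @param sequences path to the input FASTA/GenBank file.
#' @param metadata path to the population metadata TSV
#'   (`sample_id`, `population`, ...).
#' @param haplotree optional path to a haplogroup tree file.
#' @param format sequence file format.
#' @param out_dir output directory.
#' @param mask list(excluded_positions, excluded_regions,
#'   drop_length_variants_in_regions) overriding [mask_policy()] defaults.
#' @param mask_diversity apply the hot-spot mask to diversity statistics
#'   too? (Off by default: the exclusions are scoped to dating/trees.)
#' @param include_indels count indels in diversity/distance statistics?
#' @param deletion site-deletion policy, `"complete"` or `"pairwise"`.
#' @param clocks character vector of clock names to date clades with.
#' @param epsilon median-joining relaxation parameter.
#' @param min_clade_size smallest clade dated.
#' @param n_perm AMOVA/PhiST permutations.
#' @param d_reps Tajima's D significance replicates.
#' @param seed master seed, recorded in all outputs.
#' @param stages character vector of stages to run (subset of
#'   `c("profile", "classify", "diversity", "date", "structure")`).
#' @export
pipeline_config <- function(sequences, metadata, haplotree = NULL,
                            format = "fasta", out_dir = "mtlineage_out",
                            mask = NULL, mask_diversity = FALSE,
                            include_indels = FALSE, deletion = "complete",
                            clocks = "complete_genome", epsilon = 0,
                            min_clade_size = 3L, n_perm = 10000L,
                            d_reps = 1000L, seed = 1L,
                            stages = c("profile", "classify", "diversity",
                                       "date", "structure")) {
  cfg <- list(sequences = sequences, metadata = metadata,
              haplotree = haplotree, format = format, out_dir = out_dir,
              mask = mask, mask_diversity = isTRUE(mask_diversity),
              include_indels = isTRUE(include_indels), deletion = deletion,
              clocks = clocks, epsilon = epsilon,
              min_clade_size = as.integer(min_clade_size),
              n_perm = as.integer(n_perm), d_reps = as.integer(d_reps),
              seed = as.integer(seed), stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

config_mask <- function(config) {
  if (is.null(config$mask)) return(mask_policy())
  m <- config$mask
  mask_policy(
    excluded_positions = m$excluded_positions %||% c(16182L, 16183L, 16519L),
    excluded_regions = m$excluded_regions %||%
      list(c(303L, 315L), c(16184L, 16194L)),
    drop_length_variants_in_regions =
      m$drop_length_variants_in_regions %||% TRUE)
}

#' Validate a pipeline configuration
#'
#' Reports problems without throwing: missing input files, samples absent
#' from the metadata, singleton populations, unset seeds.
#'
#' @param config a `pipeline_config`.
#' @return character vector of findings (empty when the config is clean).
#' @export
validate_pipeline <- function(config) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, paste0(...))
  for (f in c("sequences", "metadata")) {
    p <- config[[f]]
    if (is.null(p)) note("missing input: no ", f, " path configured")
    else if (!file.exists(p)) note("missing input: ", f, " file not found: ", p)
  }
  if (!is.null(config$haplotree) && !file.exists(config$haplotree))
    note("missing input: haplotree file not found: ", config$haplotree)
  if (is.null(config$seed)) note("unset seed")
  if (!is.null(config$sequences) && file.exists(config$sequences) &&
      !is.null(config$metadata) && file.exists(config$metadata)) {
    md <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    seqs <- tryCatch(read_sequences(config$sequences, config$format),
                     error = function(e) NULL)
    if (is.null(seqs)) {
      note("unreadable sequence file: ", config$sequences)
    } else {
      ids <- vapply(seqs, `[[`, character(1), "sample_id")
      unmapped <- setdiff(ids, md$sample_id)
      for (u in unmapped) note("unmapped sample: ", u)
      tab <- table(md$population[md$sample_id %in% ids])
      for (p in names(tab)[tab < 2]) note("singleton population: ", p)
    }
  }
  findings
}

out_file <- function(config, name, hash) {
  path <- file.path(config$out_dir, name)
  writeLines(paste0("# config_hash: ", hash), path)
  path
}

append_table <- function(df, path) {
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

#' Run the pipeline
#'
#' Produces, in order: variant profiles TSV; haplogroup assignment TSV and
#' frequency/component tables (when a haplotree is configured); a
#' diversity table; per-clade genealogies with a rho/sigma/TMRCA table; a
#' PhiST matrix, AMOVA table and MDS coordinates; and a run log with
#' seeds, record counts and the masking provenance. Determinism: identical
#' config and seed give byte-identical statistical outputs.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # fingerprint of the statistical settings (output location excluded)
  hash <- string_hash(unclass(config)[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logcon <- file(log_path, "w")
  on.exit(close(logcon), add = TRUE)
  logline <- function(stage, ...) {
    writeLines(paste0("[", stage, "] ", paste0(...)), logcon)
  }
  logline("init", "mtlineage ",
          as.character(utils::packageVersion("mtlineage")),
          " seed=", config$seed, " config_hash=", hash)
  policy <- config_mask(config)
  logline("init", "mask: positions {",
          paste(policy$excluded_positions, collapse = ","),
          "} regions {",
          paste(vapply(policy$excluded_regions, paste, character(1),
                       collapse = "-"), collapse = ","),
          "} drop_length_variants=",
          policy$drop_length_variants_in_regions)
  results <- list(config_hash = hash)
  stage_fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  ref <- mt_reference()
  seqs <- tryCatch({
    s <- read_sequences(config$sequences, config$format)
    md <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    attach_metadata(s, md)
  }, error = function(e) stage_fail("input", e))
  md <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  logline("input", "records_in=", length(seqs))

  profiles_raw <- profiles_masked <- NULL
  if ("profile" %in% config$stages) {
    tryCatch({
      profiles_raw <- profiles_for(seqs, ref, no_mask())
      profiles_masked <- lapply(profiles_raw, apply_mask, policy = policy)
      p_path <- out_file(config, "profiles.tsv", hash)
      lines <- vapply(profiles_masked, function(p) {
        labs <- collapse_deletion_labels(profile_labels(p))
        paste0(p$sample_id, "\t",
               if (length(labs)) paste(labs, collapse = " ") else "-")
      }, character(1))
      cat(lines, file = p_path, sep = "\n", append = TRUE)
      results$profiles <- profiles_masked
      logline("profile", "records_in=", length(seqs),
              " records_out=", length(profiles_masked))
    }, error = function(e) stage_fail("profile", e))
  }

  assignments <- NULL
  if ("classify" %in% config$stages && !is.null(config$haplotree)) {
    tryCatch({
      tree <- load_haplotree(config$haplotree)
      assignments <- classify_all(profiles_masked, tree, policy)
      a_path <- out_file(config, "assignments.tsv", hash)
      tmp <- tempfile(); write_assignments_tsv(assignments, tmp)
      file.append(a_path, tmp); unlink(tmp)
      freq <- frequency_table(assignments, md,
                              truncate = truncate_haplogroup)
      append_table(freq, out_file(config, "haplogroup_frequencies.tsv", hash))
      comp <- component_frequencies(assignments, md)
      append_table(comp, out_file(config, "component_frequencies.tsv", hash))
      results$assignments <- assignments
      results$frequencies <- freq
      logline("classify", "records_in=", length(profiles_masked),
              " records_out=", length(assignments))
    }, error = function(e) stage_fail("classify", e))
  }

  if ("diversity" %in% config$stages) {
    tryCatch({
      prof_div <- if (config$mask_diversity) profiles_masked else profiles_raw
      div <- diversity_summary(prof_div, md,
                               include_indels = config$include_indels,
                               deletion = config$deletion,
                               d_reps = config$d_reps, seed = config$seed)
      append_table(div, out_file(config, "diversity.tsv", hash))
      results$diversity <- div
      logline("diversity", "records_in=", length(prof_div),
              " rows_out=", nrow(div))
    }, error = function(e) stage_fail("diversity", e))
  }

  if ("date" %in% config$stages && !is.null(assignments)) {
    tryCatch({
      tree <- load_haplotree(config$haplotree)
      hg <- vapply(assignments, `[[`, character(1), "haplogroup")
      top <- vapply(hg, truncate_haplogroup, character(1))
      clocks <- lapply(config$clocks, clock_model)
      ann <- mt_annotation()
      ages <- list()
      for (cl in unique(top)) {
        idx <- which(top == cl)
        if (length(idx) < config$min_clade_size) next
        prof <- profiles_masked[idx]
        nodes_in_tree <- cl %in% tree$name
        root_labels <- if (nodes_in_tree)
          cumulative_motif(tree, cl, policy) else character(0)
        net <- build_network(collapse_haplotypes(prof),
                             epsilon = config$epsilon)
        g <- extract_genealogy(net, profile_from_labels("root", root_labels,
                                                        ref))
        export_genealogy(g, file.path(config$out_dir,
                                      paste0("genealogy_", cl)))
        a <- clade_ages(g, clocks, annotation = ann, ref = ref,
                        policy = policy)
        a$clade <- cl
        ages[[cl]] <- a
      }
      if (length(ages)) {
        ages <- do.call(rbind, ages)
        append_table(ages, out_file(config, "clade_ages.tsv", hash))
        results$clade_ages <- ages
      }
      logline("date", "clades_out=", length(unique(ages$clade %||%
                                                     character(0))))
    }, error = function(e) stage_fail("date", e))
  }

  if ("structure" %in% config$stages) {
    tryCatch({
      prof <- profiles_raw
      ids <- vapply(prof, `[[`, character(1), "sample_id")
      pops <- md$population[match(ids, md$sample_id)]
      d <- distance_matrix(prof, include_indels = config$include_indels,
                           deletion = config$deletion)
      am <- amova(d, pops, n_perm = config$n_perm, seed = config$seed)
      tmp <- tempfile()
      write_amova_tsv(am, tmp)
      file.append(out_file(config, "amova.tsv", hash), tmp); unlink(tmp)
      pp <- pairwise_phist(d, pops, n_perm = config$n_perm,
                           seed = config$seed)
      phi_df <- data.frame(population = rownames(pp$phi_st),
                           round(pp$phi_st, 6), check.names = FALSE)
      append_table(phi_df, out_file(config, "phist.tsv", hash))
      results$amova <- am
      results$phist <- pp
      if (nrow(pp$phi_st) >= 2) {
        emb <- mds(pp$phi_st, dim = 2, seed = config$seed)
        mds_df <- data.frame(population = emb$labels,
                             dim1 = emb$coords[, 1], dim2 = emb$coords[, 2],
                             stress = emb$stress)
        append_table(mds_df, out_file(config, "mds.tsv", hash))
        results$mds <- emb
      }
      logline("structure", "populations=", length(unique(pops)),
              " n_perm=", config$n_perm)
    }, error = function(e) stage_fail("structure", e))
  }
  logline("done", "outputs in ", config$out_dir)
  invisible(results)
}
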