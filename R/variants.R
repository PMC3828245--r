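#' Variants and variant profiles in standard mtDNA nomenclature
#'
#' A variant is a scored difference from the reference at a 1-based rCRS
#' coordinate. Canonical text labels follow the conventions used throughout
#' the mtDNA literature:
#' \itemize{
#'   \item transitions by bare position, e.g. `"73"`;
#'   \item transversions by position plus derived base, e.g. `"16318T"`;
#'   \item deletions per reference position, e.g. `"249del"` (multi-base
#'     runs may additionally be reported collapsed, e.g. `"8281-8289del"`);
#'   \item insertions as `"315.1C"` (position, dot, insert index, base).
#' }
#' A trailing `"!"` (back mutation) is only meaningful inside haplogroup
#' motifs and is handled by the haplotree module.
#'
#' @name variants
NULL

#' Build a variant table from canonical labels
#'
#' @param labels character vector of canonical variant labels.
#' @param ref a `reference_genome`; required to resolve the derived state of
#'   bare-position (transition) labels and to distinguish transitions from
#'   transversions when a base is given.
#' @return data.frame with columns `position`, `insert_index`, `kind`,
#'   `derived`, `label`.
#' @export
parse_variant_labels <- function(labels, ref = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  out <- data.frame(position = integer(n), insert_index = integer(n),
                    kind = character(n), derived = character(n),
                    label = labels, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (grepl("^\\d+\\.\\d+[ACGT]$", lab)) {
      pos <- as.integer(sub("^(\\d+)\\..*$", "\\1", lab))
      idx <- as.integer(sub("^\\d+\\.(\\d+).*$", "\\1", lab))
      base <- sub("^.*(\\w)$", "\\1", lab)
      out[i, c("position", "insert_index")] <- c(pos, idx)
      out$kind[i] <- "insertion"; out$derived[i] <- base
    } else if (grepl("^\\d+del$", lab)) {
      out$position[i] <- as.integer(sub("del$", "", lab))
      out$kind[i] <- "deletion"; out$derived[i] <- ""
    } else if (grepl("^\\d+-\\d+del$", lab)) {
      stop_input("collapsed deletion label '", lab,
                 "': expand with expand_deletion_label() first")
    } else if (grepl("^\\d+[ACGT]$", lab)) {
      pos <- as.integer(sub("[ACGT]$", "", lab))
      base <- sub("^\\d+", "", lab)
      out$position[i] <- pos; out$derived[i] <- base
      if (!is.null(ref) && is_transition(ref_base(ref, pos), base)) {
        out$kind[i] <- "transition"
        out$label[i] <- as.character(pos)
      } else {
        out$kind[i] <- "transversion"
      }
    } else if (grepl("^\\d+$", lab)) {
      pos <- as.integer(lab)
      out$position[i] <- pos
      out$kind[i] <- "transition"
      out$derived[i] <- if (is.null(ref)) NA_character_ else
        transition_partner(ref_base(ref, pos))
    } else {
      stop_input("unparseable variant label: '", lab, "'")
    }
  }
  out
}

#' Canonical label for a variant
#' @param position,insert_index,kind,derived variant fields (vectorised).
#' @export
variant_label <- function(position, insert_index, kind, derived) {
  ifelse(kind == "transition", as.character(position),
  ifelse(kind == "transversion", paste0(position, derived),
  ifelse(kind == "deletion", paste0(position, "del"),
         paste0(position, ".", insert_index, derived))))
}

#' Expand a collapsed deletion label into per-position labels
#' @param label e.g. `"8281-8289del"`.
#' @export
expand_deletion_label <- function(label) {
  if (!grepl("^\\d+-\\d+del$", label)) return(label)
  a <- as.integer(sub("^(\\d+)-.*$", "\\1", label))
  b <- as.integer(sub("^\\d+-(\\d+)del$", "\\1", label))
  paste0(seq(a, b), "del")
}

#' Collapse runs of adjacent per-position deletions
#' @param labels character vector of canonical labels.
#' @return labels with contiguous deletion runs of length > 1 replaced by
#'   `"start-enddel"`.
#' @export
collapse_deletion_labels <- function(labels) {
  del <- grepl("^\\d+del$", labels)
  if (!any(del)) return(labels)
  pos <- sort(as.integer(sub("del$", "", labels[del])))
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  collapsed <- vapply(runs, function(r) {
    if (length(r) == 1L) paste0(r, "del") else paste0(r[1], "-", r[length(r)], "del")
  }, character(1))
  c(labels[!del], unname(collapsed))
}

#' Construct a variant profile
#'
#' The atom of every downstream computation: a sample's ordered set of
#' scored differences from the reference, together with the number of
#' unambiguously compared reference positions.
#'
#' @param sample_id sample identifier.
#' @param variants data.frame as returned by [parse_variant_labels()].
#' @param compared_length number of unambiguously compared reference
#'   positions (at most 16569).
#' @param missing_positions integer vector of reference positions that were
#'   not compared (IUPAC ambiguity codes, treated as missing data).
#' @return object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, variants,
                            compared_length = 16569L,
                            missing_positions = integer()) {
  stopifnot(is.data.frame(variants))
  o <- order(variants$position, variants$insert_index)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  key <- paste(variants$position, variants$insert_index)
  if (anyDuplicated(key))
    stop_input("duplicate (position, insert_index) in profile for ", sample_id)
  if (compared_length > 16569L)
    stop_input("compared_length exceeds reference length")
  structure(list(sample_id = sample_id, variants = variants,
                 compared_length = as.integer(compared_length),
                 missing_positions = sort(unique(as.integer(missing_positions)))),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("<variant_profile>", x$sample_id, "-", nrow(x$variants), "variants,",
      x$compared_length, "compared positions\n")
  if (nrow(x$variants)) cat(" ", paste(x$variants$label, collapse = " "), "\n")
  invisible(x)
}

#' Shorthand: profile from labels
#' @inheritParams parse_variant_labels
#' @inheritParams variant_profile
#' @export
profile_from_labels <- function(sample_id, labels, ref = NULL,
                                compared_length = 16569L) {
  variant_profile(sample_id, parse_variant_labels(labels, ref),
                  compared_length = compared_length)
}

#' Canonical labels of a profile's variants
#' @param profile a `variant_profile`.
#' @export
profile_labels <- function(profile) profile$variants$label

#' Masking policy for hypermutable positions
#'
#' The default policy removes the classic hot spots at nps 16182, 16183 and
#' 16519 and drops length variation (insertions/deletions) inside the
#' control-region poly-C tracts at nps 303--315 and 16184--16194. Point
#' substitutions inside those tracts are retained.
#'
#' @param excluded_positions integer positions removed outright.
#' @param excluded_regions list of `c(start, end)` intervals.
#' @param drop_length_variants_in_regions drop insertions/deletions falling
#'   inside `excluded_regions`?
#' @return object of class `mask_policy`.
#' @export
mask_policy <- function(excluded_positions = c(16182L, 16183L, 16519L),
                        excluded_regions = list(c(303L, 315L),
                                                c(16184L, 16194L)),
                        drop_length_variants_in_regions = TRUE) {
  structure(list(excluded_positions = as.integer(excluded_positions),
                 excluded_regions = lapply(excluded_regions, as.integer),
                 drop_length_variants_in_regions =
                   isTRUE(drop_length_variants_in_regions)),
            class = "mask_policy")
}

#' An empty (no-op) masking policy
#' @export
no_mask <- function() {
  mask_policy(integer(), list(), FALSE)
}

in_regions <- function(positions, regions) {
  if (!length(regions)) return(rep(FALSE, length(positions)))
  Reduce(`|`, lapply(regions, function(r)
    positions >= r[1] & positions <= r[2]))
}

masked_out <- function(position, kind, policy) {
  drop <- position %in% policy$excluded_positions
  if (policy$drop_length_variants_in_regions) {
    len <- kind %in% c("insertion", "deletion")
    drop <- drop | (len & in_regions(position, policy$excluded_regions))
  }
  drop
}

#' Apply a masking policy to a variant profile
#'
#' Masking is idempotent and leaves the input unmodified.
#'
#' @param profile a `variant_profile`.
#' @param policy a `mask_policy`.
#' @return a new, masked `variant_profile` (possibly empty).
#' @export
apply_mask <- function(profile, policy = mask_policy()) {
  stopifnot(inherits(profile, "variant_profile"),
            inherits(policy, "mask_policy"))
  v <- profile$variants
  if (nrow(v) && (any(v$position < 1L) || any(v$position > 16569L)))
    stop_input("profile positions outside 1..16569")
  keep <- !masked_out(v$position, v$kind, policy)
  variant_profile(profile$sample_id, v[keep, , drop = FALSE],
                  compared_length = profile$compared_length,
                  missing_positions = profile$missing_positions)
}

#' Apply a masking policy to bare variant labels (e.g. haplogroup motifs)
#'
#' Back-mutation markers (`"!"`) are preserved on surviving labels.
#' @param labels canonical labels, optionally suffixed with `"!"`.
#' @param policy a `mask_policy`.
#' @export
mask_labels <- function(labels, policy = mask_policy()) {
  if (!length(labels)) return(labels)
  bare <- sub("!+$", "", labels)
  pos <- as.integer(sub("^(\\d+).*$", "\\1", bare))
  kind <- ifelse(grepl("\\.", bare), "insertion",
          ifelse(grepl("del$", bare), "deletion", "substitution"))
  labels[!masked_out(pos, kind, policy)]
}

#' Write variant profiles as TSV
#'
#' Two-column format: sample id, tab, space-separated variant labels
#' (`"-"` when the profile is empty).
#' @param profiles list of `variant_profile`.
#' @param path output path.
#' @param collapse_deletions report contiguous deletion runs collapsed?
#' @export
write_profiles_tsv <- function(profiles, path, collapse_deletions = FALSE) {
  lines <- vapply(profiles, function(p) {
    labs <- profile_labels(p)
    if (collapse_deletions) labs <- collapse_deletion_labels(labs)
    paste0(p$sample_id, "\t",
           if (length(labs)) paste(labs, collapse = " ") else "-")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read variant profiles from the TSV written by [write_profiles_tsv()]
#' @param path input path.
#' @param ref optional `reference_genome` for label resolution.
#' @export
read_profiles_tsv <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    labs <- if (length(parts) < 2L || parts[2] == "-") character() else
      strsplit(parts[2], " +")[[1]]
    labs <- unlist(lapply(labs, expand_deletion_label))
    profile_from_labels(parts[1], labs, ref)
  })
}

#' Write one profile as a JSON document
#' @param profile a `variant_profile`.
#' @param path output path.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(sample_id = profile$sample_id,
         variants = profile$variants,
         compared_length = profile$compared_length,
         missing_positions = profile$missing_positions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
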