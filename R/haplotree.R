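#' Haplogroup trees and classification
#'
#' A haplogroup tree is a rooted hierarchy of named clades, each edge
#' carrying the clade's defining mutations as canonical variant labels; a
#' trailing `"!"` marks a back mutation (the derived state reverts to the
#' ancestral one). Classification scores a masked variant profile against
#' the cumulative expected motif of every node.
#'
#' @name haplotree
NULL

#' Load a haplogroup tree
#'
#' File format: TSV with three columns `name`, `parent`, `motif`
#' (space-separated variant labels, `"-"` for none; parent `"-"` for the
#' root), or a JSON array of objects with the same fields.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @return object of class `haplo_tree`.
#' @export
load_haplotree <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df$motif <- vapply(df$motif, function(m)
      paste(unlist(m), collapse = " "), character(1))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            col.names = c("name", "parent", "motif"),
                            header = FALSE, comment.char = "#")
    if (identical(tolower(df$name[1]), "name")) df <- df[-1, , drop = FALSE]
  }
  haplo_tree(df$name, df$parent, df$motif)
}

#' Construct a haplogroup tree from vectors
#' @param name,parent,motif equal-length vectors; `parent` and `motif` use
#'   `"-"` (or `NA`/empty) for none.
#' @export
haplo_tree <- function(name, parent, motif) {
  name <- as.character(name); parent <- as.character(parent)
  motif <- as.character(motif)
  parent[parent %in% c("-", "")] <- NA_character_
  motif[is.na(motif)] <- ""
  motif[motif == "-"] <- ""
  if (anyDuplicated(name))
    stop_input("duplicate haplogroup names: ",
               paste(unique(name[duplicated(name)]), collapse = ", "))
  roots <- which(is.na(parent))
  if (length(roots) != 1L)
    stop_input("tree must have exactly one root, found ", length(roots))
  known <- parent[!is.na(parent)] %in% name
  if (!all(known))
    stop_input("orphan parents: ",
               paste(unique(parent[!is.na(parent)][!known]), collapse = ", "))
  motifs <- lapply(strsplit(motif, "\\s+"), function(x) x[nzchar(x)])
  for (toks in motifs)
    for (tok in toks)
      if (!grepl("^\\d+(del|[ACGT]|\\.\\d+[ACGT])?!?$", tok))
        stop_input("unparseable motif token: '", tok, "'")
  tree <- structure(list(name = name, parent = parent, motifs = motifs,
                         root = name[roots]),
                    class = "haplo_tree")
  # cycle / reachability check
  depth <- tree_depths(tree)
  if (any(is.na(depth)))
    stop_input("nodes unreachable from root (cycle?): ",
               paste(name[is.na(depth)], collapse = ", "))
  tree
}

tree_depths <- function(tree) {
  depth <- rep(NA_real_, length(tree$name))
  names(depth) <- tree$name
  depth[tree$root] <- 0
  repeat {
    todo <- is.na(depth) & tree$parent %in% names(depth)[!is.na(depth)]
    if (!any(todo)) break
    depth[tree$name[todo]] <- depth[tree$parent[todo]] + 1
  }
  depth
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("<haplo_tree>", length(x$name), "haplogroups, root:", x$root, "\n")
  invisible(x)
}

# Cumulative expected variant set along the root path of `node`.
# Back mutations ("label!") remove the matching expected variant.
cumulative_motif <- function(tree, node, policy = NULL) {
  path <- character(0)
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$parent[match(cur, tree$name)]
  }
  expected <- character(0)
  for (nd in path) {
    toks <- tree$motifs[[match(nd, tree$name)]]
    if (!is.null(policy)) toks <- mask_labels(toks, policy)
    for (tok in toks) {
      if (grepl("!$", tok)) {
        bare <- sub("!+$", "", tok)
        pos <- sub("^(\\d+).*$", "\\1", bare)
        hit <- sub("^(\\d+).*$", "\\1", expected) == pos
        expected <- expected[!hit]
      } else {
        expected <- union(expected, tok)
      }
    }
  }
  expected
}

#' Classify a variant profile into a haplogroup
#'
#' For every node the cumulative expected variant set along its root path is
#' computed (back mutations restore the ancestral state), and the node is
#' scored as `matched - missing` against the masked profile. The
#' maximal-score node wins; ties are broken by larger matched count, then
#' greater depth, then lexicographic name. All maximal-score nodes are
#' reported in `ties`.
#'
#' @param profile a `variant_profile` (will be masked with `policy`).
#' @param tree a `haplo_tree` (motifs are masked with the same policy).
#' @param policy classification mask, default [mask_policy()].
#' @return object of class `hg_assignment` with fields `sample_id`,
#'   `haplogroup`, `score`, `matched`, `missing`, `private`, `ties`.
#' @export
classify <- function(profile, tree, policy = mask_policy()) {
  if (!length(tree$name)) stop_input("empty haplogroup tree")
  prof <- apply_mask(profile, policy)
  labs <- profile_labels(prof)
  depth <- tree_depths(tree)
  stats <- lapply(tree$name, function(nd) {
    exp <- cumulative_motif(tree, nd, policy)
    matched <- intersect(labs, exp)
    missing <- setdiff(exp, labs)
    list(node = nd, matched = matched, missing = missing,
         score = length(matched) - length(missing))
  })
  scores <- vapply(stats, `[[`, numeric(1), "score")
  top <- which(scores == max(scores))
  ties <- tree$name[top]
  nmatched <- vapply(stats[top], function(s) length(s$matched), numeric(1))
  top <- top[nmatched == max(nmatched)]
  d <- depth[tree$name[top]]
  top <- top[d == max(d)]
  best <- stats[[top[order(tree$name[top])][1]]]
  structure(list(sample_id = prof$sample_id, haplogroup = best$node,
                 score = best$score, matched = best$matched,
                 missing = best$missing,
                 private = setdiff(labs, best$matched),
                 ties = sort(ties)),
            class = "hg_assignment")
}

#' @export
print.hg_assignment <- function(x, ...) {
  cat("<hg_assignment>", x$sample_id, "->", x$haplogroup,
      sprintf("(score %d, matched %d, missing %d)\n",
              x$score, length(x$matched), length(x$missing)))
  invisible(x)
}

#' Classify many profiles
#' @inheritParams classify
#' @param profiles list of `variant_profile`.
#' @return list of `hg_assignment`.
#' @export
classify_all <- function(profiles, tree, policy = mask_policy()) {
  lapply(profiles, classify, tree = tree, policy = policy)
}

#' Write assignments as TSV
#' @param assignments list of `hg_assignment`.
#' @param path output path.
#' @export
write_assignments_tsv <- function(assignments, path) {
  df <- data.frame(
    sample_id = vapply(assignments, `[[`, character(1), "sample_id"),
    haplogroup = vapply(assignments, `[[`, character(1), "haplogroup"),
    score = vapply(assignments, `[[`, numeric(1), "score"),
    matched = vapply(assignments, function(a) length(a$matched), numeric(1)),
    missing = vapply(assignments, function(a) length(a$missing), numeric(1)),
    private = vapply(assignments, function(a)
      paste(a$private, collapse = " "), character(1)),
    ties = vapply(assignments, function(a)
      paste(a$ties, collapse = " "), character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Haplogroup frequency table per population
#'
#' @param assignments list of `hg_assignment`.
#' @param metadata data.frame with `sample_id`, `population`.
#' @param truncate optional function mapping a fine haplogroup label to its
#'   reporting row (e.g. `"H13a2a1"` to `"H13"`); identity by default.
#' @return data.frame of percentages, haplogroups in rows, one column per
#'   population plus `"Total"`; each column sums to 100 within rounding.
#' @export
frequency_table <- function(assignments, metadata, truncate = NULL) {
  ids <- vapply(assignments, `[[`, character(1), "sample_id")
  hgs <- vapply(assignments, `[[`, character(1), "haplogroup")
  i <- match(ids, metadata$sample_id)
  if (anyNA(i))
    stop_input("samples missing from metadata: ",
               paste(ids[is.na(i)], collapse = ", "))
  pop <- as.character(metadata$population[i])
  if (!is.null(truncate)) hgs <- vapply(hgs, truncate, character(1))
  tab <- table(haplogroup = hgs, population = pop)
  pct <- prop.table(tab, margin = 2) * 100
  out <- as.data.frame.matrix(pct)
  out$Total <- as.numeric(prop.table(table(factor(hgs,
    levels = rownames(tab)))) * 100)
  cbind(haplogroup = rownames(out), out, row.names = NULL)
}

#' Truncate haplogroup labels to letter + leading digits
#'
#' `"H13a2a1"` becomes `"H13"`, `"U5a1g"` becomes `"U5"`, `"HV12"` stays
#' `"HV12"` (leading letters are kept in full).
#' @param label haplogroup label.
#' @export
truncate_haplogroup <- function(label) {
  sub("^([A-Za-z]+[0-9]*).*$", "\\1", label)
}

#' Default geographic component map
#'
#' Encodes the conventional continental components of the west-Eurasian
#' mtDNA literature: western Eurasian (N1, N2/W, N3, X, I, R0/HV/H/V,
#' R2'JT, U/K), eastern Eurasian (A, B, C, D, F, G), South Asian (Indian M
#' clades, R5/R8/R30, U2c/U2d) and African (L). Keys are matched to
#' assigned haplogroup labels by longest prefix.
#' @export
component_map <- function() {
  c(N1 = "western", I = "western", N2 = "western", W = "western",
    N3 = "western", X = "western", R0 = "western", H = "western",
    HV = "western", V = "western", R2 = "western", J = "western",
    T = "western", U = "western", K = "western",
    A = "eastern", B = "eastern", C = "eastern", D = "eastern",
    F = "eastern", G = "eastern", Z = "eastern",
    M = "south_asian", R5 = "south_asian", R8 = "south_asian",
    R30 = "south_asian", U2c = "south_asian", U2d = "south_asian",
    L = "african")
}

#' Component frequencies per population
#'
#' @inheritParams frequency_table
#' @param map named character vector mapping haplogroup prefixes to
#'   component names; longest matching prefix wins. Unmapped haplogroups are
#'   reported with a warning and binned as `"other"`.
#' @return data.frame of component percentages per population plus Total.
#' @export
component_frequencies <- function(assignments, metadata,
                                  map = component_map()) {
  ids <- vapply(assignments, `[[`, character(1), "sample_id")
  hgs <- vapply(assignments, `[[`, character(1), "haplogroup")
  i <- match(ids, metadata$sample_id)
  if (anyNA(i))
    stop_input("samples missing from metadata: ",
               paste(ids[is.na(i)], collapse = ", "))
  pop <- as.character(metadata$population[i])
  keys <- names(map)[order(nchar(names(map)), decreasing = TRUE)]
  comp <- vapply(hgs, function(h) {
    hit <- keys[startsWith(h, keys)]
    if (length(hit)) unname(map[hit[1]]) else NA_character_
  }, character(1))
  if (anyNA(comp)) {
    warning("unmapped haplogroups binned as 'other': ",
            paste(unique(hgs[is.na(comp)]), collapse = ", "))
    comp[is.na(comp)] <- "other"
  }
  tab <- table(component = comp, population = pop)
  pct <- prop.table(tab, margin = 2) * 100
  out <- as.data.frame.matrix(pct)
  out$Total <- as.numeric(prop.table(table(factor(comp,
    levels = rownames(tab)))) * 100)
  cbind(component = rownames(out), out, row.names = NULL)
}
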