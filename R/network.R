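#' Haplotype classes and median-joining networks
#'
#' Samples with identical masked variant profiles collapse into haplotype
#' classes; classes are then connected into a mutation-weighted network of
#' the median-joining family, from which a rooted, mutation-weighted clade
#' genealogy is extracted for rho/sigma dating.
#'
#' @name network
NULL

#' Collapse variant profiles into haplotype classes
#'
#' Equality is identity of the variant label sets; all profiles must have
#' been masked under the same policy beforehand.
#'
#' @param profiles list of `variant_profile`.
#' @return list of `haplotype_class` objects (`class_id`, `labels`,
#'   `multiplicity`, `members`, `profile`).
#' @export
collapse_haplotypes <- function(profiles) {
  keys <- vapply(profiles, function(p)
    paste(sort(profile_labels(p)), collapse = "|"), character(1))
  groups <- split(seq_along(profiles), keys)
  groups <- groups[order(names(groups))]
  out <- Map(function(idx, k, i) {
    structure(list(class_id = paste0("HC", i),
                   labels = sort(profile_labels(profiles[[idx[1]]])),
                   multiplicity = length(idx),
                   members = vapply(profiles[idx], `[[`, character(1),
                                    "sample_id"),
                   profile = profiles[[idx[1]]]),
              class = "haplotype_class")
  }, groups, names(groups), seq_along(groups))
  unname(out)
}

hamming_matrix <- function(mat) {
  m <- matrix(as.numeric(mat), nrow = nrow(mat))
  s <- tcrossprod(m)
  r <- rowSums(m)
  round(outer(r, r, "+") - 2 * s)
}

# Minimum spanning tree (Prim) over a distance matrix; returns edge matrix.
prim_mst <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(matrix(integer(0), ncol = 2))
  intree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1, ]; bestfrom <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(best[cand])]
    edges[k, ] <- c(bestfrom[v], v)
    intree[v] <- TRUE
    upd <- !intree & D[v, ] < best
    best[upd] <- D[v, upd]; bestfrom[upd] <- v
  }
  edges
}

# Minimax (bottleneck) distance between all pairs: max edge weight on the
# MST path. Used for the epsilon-relaxed minimum spanning network.
minimax_distance <- function(D) {
  n <- nrow(D)
  mst <- prim_mst(D)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mst))) {
    a <- mst[i, 1]; b <- mst[i, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, D[a, b]))
    adj[[b]] <- rbind(adj[[b]], c(a, D[a, b]))
  }
  mm <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        v <- nb[j, 1]
        if (is.na(dist[v])) {
          dist[v] <- max(dist[u], nb[j, 2])
          queue <- c(queue, v)
        }
      }
    }
    mm[s, ] <- dist
  }
  mm
}

# Feasible links of the epsilon-relaxed minimum spanning network:
# edge (u,v) is kept iff d(u,v) <= minimax(u,v) + epsilon. At epsilon = 0
# this is the union of all minimum spanning trees.
msn_edges <- function(D, epsilon = 0) {
  mm <- minimax_distance(D)
  keep <- which(upper.tri(D) & D <= mm + epsilon + 1e-9, arr.ind = TRUE)
  keep
}

#' Build a median-joining haplotype network
#'
#' At `epsilon = 0`: the minimum spanning network (union of all minimum
#' spanning trees) over the observed classes, augmented with
#' majority-consensus median vectors of mutually linked triplets, iterated
#' to a fixed point; obsolete medians (unobserved nodes of link degree
#' <= 2) are then removed. Larger `epsilon` relaxes the link-feasibility
#' criterion as in the median-joining method family. Characters are
#' presence/absence of each variant label and are unweighted (a per-site
#' weight hook is accepted but currently uniform).
#'
#' Nodes are content-addressed (id = the sorted variant labels joined by
#' `"|"`, the empty haplotype being `"@root"`), which makes the network
#' invariant to input order.
#'
#' @param classes list of `haplotype_class` (or `variant_profile`s, which
#'   are collapsed first).
#' @param epsilon nonnegative integer relaxation parameter.
#' @param site_weights optional named numeric vector of per-site weights
#'   (reserved; must currently be uniform).
#' @param max_nodes safety cap on network size.
#' @return object of class `haplo_network`.
#' @export
build_network <- function(classes, epsilon = 0, site_weights = NULL,
                          max_nodes = 2000L) {
  if (length(classes) && inherits(classes[[1]], "variant_profile"))
    classes <- collapse_haplotypes(classes)
  if (!length(classes)) stop_input("no haplotype classes")
  if (!is.null(site_weights) && length(unique(site_weights)) > 1L)
    stop_input("non-uniform site weights are not supported yet")
  sites <- sort(unique(unlist(lapply(classes, `[[`, "labels"))))
  vec_of <- function(labels) stats::setNames(sites %in% labels, sites)
  obs <- matrix(FALSE, length(classes), length(sites),
                dimnames = list(NULL, sites))
  for (i in seq_along(classes)) obs[i, ] <- vec_of(classes[[i]]$labels)
  keys <- row_keys(obs)
  if (anyDuplicated(keys)) stop_input("duplicate haplotype classes")
  mat <- obs[order(keys), , drop = FALSE]
  keys <- sort(keys)
  observed <- rep(TRUE, nrow(mat))
  aug <- augment_medians(mat, observed, epsilon, max_nodes)
  mat <- aug$mat; observed <- aug$observed
  # obsolete-median cleanup
  repeat {
    D <- hamming_matrix(mat)
    links <- msn_edges(D, epsilon)
    deg <- tabulate(c(links[, 1], links[, 2]), nbins = nrow(mat))
    obsolete <- !observed & deg <= 2L
    if (!any(obsolete) || nrow(mat) <= 1L) break
    mat <- mat[!obsolete, , drop = FALSE]
    observed <- observed[!obsolete]
  }
  keys <- row_keys(mat)
  o <- order(keys)
  mat <- mat[o, , drop = FALSE]; observed <- observed[o]; keys <- keys[o]
  rownames(mat) <- keys
  D <- hamming_matrix(mat)
  links <- msn_edges(D, epsilon)
  class_keys <- vapply(classes, function(cl)
    vec_key(vec_of(cl$labels)), character(1))
  multiplicity <- integer(nrow(mat))
  members <- rep(list(character(0)), nrow(mat))
  for (i in seq_along(classes)) {
    j <- match(class_keys[i], keys)
    multiplicity[j] <- classes[[i]]$multiplicity
    members[[j]] <- classes[[i]]$members
  }
  edge_labels <- lapply(seq_len(nrow(links)), function(e)
    sites[xor(mat[links[e, 1], ], mat[links[e, 2], ])])
  edges <- data.frame(from = keys[links[, 1]], to = keys[links[, 2]],
                      weight = D[links], stringsAsFactors = FALSE)
  structure(list(sites = sites, vectors = mat, observed = observed,
                 multiplicity = multiplicity, members = members,
                 edges = edges, edge_labels = edge_labels,
                 epsilon = epsilon),
            class = "haplo_network")
}

# Median augmentation to a fixed point. Candidate triples: a feasible link
# (u,v) of the current epsilon-relaxed MSN plus any third node, the
# generative rule of the median-joining method family.
augment_medians <- function(mat, observed, epsilon, max_nodes = 2000L) {
  keys <- row_keys(mat)
  repeat {
    D <- hamming_matrix(mat)
    links <- msn_edges(D, epsilon)
    new <- NULL
    if (nrow(mat) >= 3L && ncol(mat) > 0L) {
      for (e in seq_len(nrow(links))) {
        u <- links[e, 1]; v <- links[e, 2]
        for (w in seq_len(nrow(mat))) {
          if (w == u || w == v) next
          med <- (mat[u, ] + mat[v, ] + mat[w, ]) >= 2
          k <- vec_key(med)
          if (!(k %in% keys) && !(k %in% vapply(new, vec_key, character(1))))
            new <- c(new, list(med))
        }
      }
    }
    if (!length(new)) break
    mat <- rbind(mat, do.call(rbind, new))
    observed <- c(observed, rep(FALSE, length(new)))
    keys <- row_keys(mat)
    if (nrow(mat) > max_nodes)
      stop_input("network exceeded max_nodes = ", max_nodes)
  }
  list(mat = mat, observed = observed)
}

vec_key <- function(v) {
  s <- which(v)
  if (!length(s)) return("@root")
  nm <- names(v)
  if (is.null(nm)) paste(s, collapse = "|") else paste(nm[s], collapse = "|")
}

row_keys <- function(mat) {
  if (!nrow(mat)) return(character(0))
  if (!ncol(mat)) return(rep("@root", nrow(mat)))
  vapply(seq_len(nrow(mat)), function(i) vec_key(mat[i, ]), character(1))
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network>", nrow(x$vectors), "nodes (",
      sum(x$observed), "observed ),", nrow(x$edges), "links,",
      length(x$sites), "sites\n")
  invisible(x)
}

#' Write a network as an edge-list TSV
#' @param network a `haplo_network`.
#' @param path output path.
#' @export
write_network_tsv <- function(network, path) {
  df <- network$edges
  df$labels <- vapply(network$edge_labels, paste, character(1),
                      collapse = " ")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genealogy extraction -------------------------------------------------

#' Extract a rooted mutation-weighted genealogy from a network
#'
#' Edges are oriented away from the supplied root haplotype. Reticulations
#' are resolved by preferring the alternative that minimises total
#' mutations, then the one whose intermediate node has higher observed
#' multiplicity, then deterministic label order: with at most 9 terminal
#' haplotypes the minimum-mutation tree within the network is found exactly
#' (dynamic programming over terminal subsets); larger problems use a
#' deterministic shortest-path tree from the root with the same tie-breaks.
#'
#' @param network a `haplo_network`.
#' @param root_profile `variant_profile` of the ancestral (clade-root)
#'   haplotype, masked like the input profiles.
#' @param exact_limit terminal count up to which the exact search is used.
#' @return object of class `clade_genealogy`.
#' @export
extract_genealogy <- function(network, root_profile, exact_limit = 9L) {
  labs <- sort(profile_labels(root_profile))
  extra <- setdiff(labs, network$sites)
  sites <- c(network$sites, extra)
  mat <- cbind(network$vectors,
               matrix(FALSE, nrow(network$vectors), length(extra),
                      dimnames = list(NULL, extra)))
  colnames(mat) <- sites
  rootvec <- stats::setNames(sites %in% labs, sites)
  keys <- row_keys(mat)
  rk <- vec_key(rootvec)
  observed <- network$observed
  multiplicity <- network$multiplicity
  members <- network$members
  if (!(rk %in% keys)) {
    mat <- rbind(mat, rootvec)
    observed <- c(observed, FALSE)
    multiplicity <- c(multiplicity, 0L)
    members <- c(members, list(character(0)))
    keys <- c(keys, rk)
  }
  # re-augment with the root present so root-anchored medians (candidate
  # branching points of the rooted tree) are available to the search
  root_flag <- keys == rk
  aug <- augment_medians(mat, observed | root_flag, network$epsilon)
  if (nrow(aug$mat) > nrow(mat)) {
    extra_n <- nrow(aug$mat) - nrow(mat)
    mat <- aug$mat
    observed <- c(observed, rep(FALSE, extra_n))
    multiplicity <- c(multiplicity, rep(0L, extra_n))
    members <- c(members, rep(list(character(0)), extra_n))
    keys <- row_keys(mat)
  }
  # deterministic preference order: observed first, then multiplicity,
  # then key; the root pinned first so ties resolve toward it
  ord <- order(keys != rk, !observed, -multiplicity, keys)
  mat <- mat[ord, , drop = FALSE]
  observed <- observed[ord]; multiplicity <- multiplicity[ord]
  members <- members[ord]; keys <- keys[ord]
  D <- hamming_matrix(mat)
  terminals <- unique(c(1L, which(observed)))
  tree_edges <- if (length(terminals) <= exact_limit) {
    # exact search runs on the complete Hamming graph over the node set:
    # in Hamming space a tree path contracts to one edge of equal weight,
    # so only branching points need to exist as nodes
    steiner_tree_edges(D, terminals)
  } else {
    links <- msn_edges(D, network$epsilon)
    n_nodes <- nrow(mat)
    W <- matrix(Inf, n_nodes, n_nodes)
    W[links] <- D[links]; W <- pmin(W, t(W))
    diag(W) <- 0
    spt_edges(W, 1L, terminals)
  }
  build_genealogy(mat, observed, multiplicity, members, keys, sites,
                  tree_edges, root = 1L, terminals = terminals)
}

# Exact minimum Steiner tree within a weighted graph (Dreyfus-Wagner on the
# metric closure, paths re-expanded through the graph). Returns an edge
# matrix (graph vertex indices).
steiner_tree_edges <- function(W, terminals) {
  n <- nrow(W)
  # all-pairs shortest paths (Floyd-Warshall) with path reconstruction
  D <- W; via <- matrix(0L, n, n)
  for (k in seq_len(n)) {
    upd <- outer(D[, k], D[k, ], "+")
    better <- upd < D - 1e-9
    if (any(better)) { via[better] <- k; D[better] <- upd[better] }
  }
  expand_path <- function(i, j) {
    k <- via[i, j]
    if (k == 0L) {
      if (i == j) return(NULL)
      return(matrix(c(i, j), 1L))
    }
    rbind(expand_path(i, k), expand_path(k, j))
  }
  t1 <- terminals[1]; rest <- terminals[-1]
  k <- length(rest)
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  nmask <- bitwShiftL(1L, k) - 1L
  f <- matrix(Inf, nmask, n)       # f[X, v]
  choice <- vector("list", nmask)  # backtrack info per subset
  for (i in seq_len(k)) f[bitwShiftL(1L, i - 1L), ] <- D[rest[i], ]
  masks <- seq_len(nmask)
  masks <- masks[order(vapply(masks, bitcount, integer(1)))]
  for (X in masks) {
    if (bitcount(X) < 2L) { choice[[X]] <- list(kind = "leaf"); next }
    tX <- rep(Inf, n); bestY <- rep(0L, n)
    Y <- bitwAnd(X - 1L, X)
    while (Y > 0L) {
      comp <- bitwAnd(X, bitwNot(Y))
      if (Y < comp) {
        cand <- f[Y, ] + f[comp, ]
        upd <- cand < tX - 1e-12
        tX[upd] <- cand[upd]; bestY[upd] <- Y
      }
      Y <- bitwAnd(Y - 1L, X)
    }
    M <- D + tX            # M[u, v] = t[X, u] + D[u, v]
    f[X, ] <- apply(M, 2, min)
    mergeu <- apply(M, 2, which.min)
    choice[[X]] <- list(kind = "merge", tX = tX, bestY = bestY,
                        mergeu = mergeu)
  }
  edges <- NULL
  recurse <- function(X, v) {
    if (bitcount(X) == 1L) {
      ti <- rest[which(bitwAnd(X, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)]
      edges <<- rbind(edges, expand_path(v, ti))
      return(invisible(NULL))
    }
    ch <- choice[[X]]
    u <- ch$mergeu[v]
    edges <<- rbind(edges, expand_path(v, u))
    Y <- ch$bestY[u]
    recurse(Y, u)
    recurse(bitwAnd(X, bitwNot(Y)), u)
  }
  recurse(nmask, t1)
  if (is.null(edges)) return(matrix(integer(0), ncol = 2))
  # dedupe, then minimal spanning structure over the chosen subgraph
  e <- unique(t(apply(edges, 1L, sort)))
  prune_to_tree(e, W, terminals, n)
}

bitcount <- function(x) {
  c <- 0L
  while (x > 0L) { c <- c + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  c
}

# Spanning tree of the subgraph (Kruskal over its edges), terminals kept,
# non-terminal leaves pruned.
prune_to_tree <- function(e, W, terminals, n) {
  if (!nrow(e)) return(matrix(integer(0), ncol = 2))
  w <- W[e]
  o <- order(w, e[, 1], e[, 2])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(e))
  for (i in o) {
    a <- find(e[i, 1]); b <- find(e[i, 2])
    if (a != b) { parent[a] <- b; keep[i] <- TRUE }
  }
  e <- e[keep, , drop = FALSE]
  repeat {
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
    drop <- which(deg == 1L & !(seq_len(n) %in% terminals))
    if (!length(drop)) break
    rm_e <- e[, 1] %in% drop | e[, 2] %in% drop
    if (!any(rm_e)) break
    e <- e[!rm_e, , drop = FALSE]
  }
  e
}

# Deterministic Dijkstra shortest-path tree from `root`; nodes are assumed
# pre-sorted in preference order (observed, multiplicity, label), so the
# first minimal predecessor realises the documented tie-break.
spt_edges <- function(W, root, terminals) {
  n <- nrow(W)
  dist <- rep(Inf, n); dist[root] <- 0
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- which(is.finite(W[u, ]) & W[u, ] > 0)
    for (v in nb) {
      nd <- dist[u] + W[u, v]
      if (nd < dist[v] - 1e-9) { dist[v] <- nd; pred[v] <- u }
    }
  }
  e <- cbind(pred, seq_len(n))
  e <- e[!is.na(pred) & is.finite(dist), , drop = FALSE]
  prune_to_tree(e, W, terminals, n)
}

build_genealogy <- function(mat, observed, multiplicity, members, keys,
                            sites, tree_edges, root, terminals) {
  n_nodes <- nrow(mat)
  adj <- vector("list", n_nodes)
  if (nrow(tree_edges)) {
    for (i in seq_len(nrow(tree_edges))) {
      a <- tree_edges[i, 1]; b <- tree_edges[i, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  # orient away from root (BFS)
  parent <- rep(NA_integer_, n_nodes)
  seen <- rep(FALSE, n_nodes); seen[root] <- TRUE
  queue <- root; order_seen <- root
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!seen[v]) {
      seen[v] <- TRUE; parent[v] <- u
      queue <- c(queue, v); order_seen <- c(order_seen, v)
    }
  }
  if (!all(seen[terminals]))
    stop_input("root profile not connectable to all observed haplotypes")
  keep <- which(seen)
  ids <- paste0("n", seq_along(keep))
  names(ids) <- keep
  edges <- data.frame(parent = character(0), child = character(0),
                      m = numeric(0), stringsAsFactors = FALSE)
  edge_labels <- list()
  for (v in keep) {
    p <- parent[v]
    if (is.na(p)) next
    dlab <- sites[xor(mat[p, ], mat[v, ])]
    edges <- rbind(edges, data.frame(parent = ids[as.character(p)],
                                     child = ids[as.character(v)],
                                     m = length(dlab),
                                     stringsAsFactors = FALSE))
    edge_labels <- c(edge_labels, list(dlab))
  }
  nodes <- data.frame(id = ids,
                      key = keys[keep],
                      observed = observed[keep],
                      multiplicity = multiplicity[keep],
                      stringsAsFactors = FALSE)
  nodes$members <- I(members[keep])
  structure(list(nodes = nodes, edges = edges, edge_labels = edge_labels,
                 root = ids[as.character(root)],
                 n = sum(multiplicity[keep])),
            class = "clade_genealogy")
}

#' Construct a clade genealogy directly from parent/child tables
#'
#' Convenience constructor for fixtures and simulations.
#' @param parents,children character vectors of node ids per edge.
#' @param m numeric mutation count per edge.
#' @param multiplicity named integer vector: observed multiplicity per node
#'   id (absent ids count 0, i.e. inferred nodes).
#' @param root root node id.
#' @param edge_labels optional list of mutation-label vectors per edge.
#' @export
clade_genealogy <- function(parents, children, m, multiplicity, root,
                            edge_labels = NULL) {
  ids <- unique(c(root, parents, children))
  mult <- integer(length(ids)); names(mult) <- ids
  mult[names(multiplicity)] <- as.integer(multiplicity)
  nodes <- data.frame(id = ids, key = ids, observed = mult > 0L,
                      multiplicity = unname(mult), stringsAsFactors = FALSE)
  nodes$members <- I(rep(list(character(0)), length(ids)))
  edges <- data.frame(parent = parents, child = children, m = m,
                      stringsAsFactors = FALSE)
  if (is.null(edge_labels)) edge_labels <- rep(list(character(0)), nrow(edges))
  g <- structure(list(nodes = nodes, edges = edges,
                      edge_labels = edge_labels, root = root,
                      n = sum(mult)),
                 class = "clade_genealogy")
  validate_genealogy(g)
  g
}

validate_genealogy <- function(g) {
  if (any(g$edges$m < 0)) stop_input("negative edge mutation count")
  kids <- g$edges$child
  if (anyDuplicated(kids)) stop_input("node with two parents")
  if (g$root %in% kids) stop_input("root has a parent")
  invisible(g)
}

#' @export
print.clade_genealogy <- function(x, ...) {
  cat("<clade_genealogy>", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, n =", x$n, ", total mutations =", sum(x$edges$m), "\n")
  invisible(x)
}

#' Total mutation weight (parsimony length) of a genealogy
#' @param g a `clade_genealogy`.
#' @export
genealogy_length <- function(g) sum(g$edges$m)

#' Export a genealogy as newick plus an edge-label sidecar TSV
#' @param g a `clade_genealogy`.
#' @param prefix output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>_edges.tsv` (edge lengths are mutation counts).
#' @export
export_genealogy <- function(g, prefix) {
  children <- split(seq_len(nrow(g$edges)), g$edges$parent)
  rec <- function(id) {
    ch <- children[[id]]
    if (is.null(ch)) return(id)
    sub <- vapply(ch, function(e)
      paste0(rec(g$edges$child[e]), ":", g$edges$m[e]), character(1))
    paste0("(", paste(sub, collapse = ","), ")", id)
  }
  writeLines(paste0(rec(g$root), ";"), paste0(prefix, ".nwk"))
  df <- g$edges
  df$labels <- vapply(g$edge_labels, paste, character(1), collapse = " ")
  utils::write.table(df, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
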