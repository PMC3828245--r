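# Independent oracles and fixture builders used across the suite.

REF <- mt_reference()
ANN <- mt_annotation()

# internal helpers exercised directly by tests
transition_partner <- mtlineage:::transition_partner
.align_banded <- mtlineage:::.align_banded
cumulative_motif <- mtlineage:::cumulative_motif

tiny_reference <- function(bases, id = "window") {
  structure(list(id = id, bases = toupper(bases)),
            class = "reference_genome")
}

# ---- rho / sigma: brute-force path and edge enumeration -------------------

# Mean root distance by climbing parent pointers per observed node.
brute_rho <- function(g) {
  up <- stats::setNames(g$edges$parent, g$edges$child)
  m_up <- stats::setNames(g$edges$m, g$edges$child)
  tot <- 0; W <- 0
  for (i in seq_len(nrow(g$nodes))) {
    mult <- g$nodes$multiplicity[i]
    if (mult == 0) next
    id <- g$nodes$id[i]; d <- 0
    while (id != g$root) { d <- d + m_up[[id]]; id <- up[[id]] }
    tot <- tot + mult * d; W <- W + mult
  }
  tot / W
}

# sigma^2 by explicit subtree-weight computation per edge.
brute_sigma <- function(g) {
  up <- stats::setNames(g$edges$parent, g$edges$child)
  mult <- stats::setNames(g$nodes$multiplicity, g$nodes$id)
  n <- sum(mult)
  s2 <- 0
  for (e in seq_len(nrow(g$edges))) {
    below <- 0
    for (id in g$nodes$id) {
      cur <- id
      repeat {
        if (cur == g$edges$child[e]) { below <- below + mult[[id]]; break }
        if (cur == g$root) break
        cur <- up[[cur]]
      }
    }
    s2 <- s2 + (below / n)^2 * g$edges$m[e]
  }
  sqrt(s2)
}

# Random genealogy: random attachment topology, random edge mutation
# counts and observed multiplicities.
random_genealogy <- function(n_nodes = 12, max_m = 5) {
  ids <- paste0("g", seq_len(n_nodes))
  parents <- character(0); children <- character(0); m <- numeric(0)
  for (i in 2:n_nodes) {
    parents <- c(parents, ids[sample.int(i - 1L, 1L)])
    children <- c(children, ids[i])
    m <- c(m, sample(0:max_m, 1L))
  }
  mult <- sample(0:3, n_nodes, replace = TRUE)
  if (sum(mult) == 0) mult[n_nodes] <- 1L
  names(mult) <- ids
  clade_genealogy(parents, children, m, mult[mult > 0], root = ids[1])
}

# ---- Tajima's D: independent constant cascade -----------------------------

tajima_oracle <- function(S, k, n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# ---- diversity: O(n^2) brute force on label sets --------------------------

brute_pairwise_k <- function(label_sets) {
  n <- length(label_sets)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + length(union(label_sets[[i]], label_sets[[j]])) -
      length(intersect(label_sets[[i]], label_sets[[j]]))
  }
  tot / (n * (n - 1) / 2)
}

brute_hd <- function(label_sets) {
  keys <- vapply(label_sets, function(l) paste(sort(l), collapse = "|"),
                 character(1))
  n <- length(keys)
  p <- as.numeric(table(keys)) / n
  n / (n - 1) * (1 - sum(p^2))
}

# ---- Steiner-minimal parsimony length on the binary hypercube -------------

# Dreyfus-Wagner over the full s-dimensional hypercube with Hamming
# distances (exact; terminals <= ~8, sites <= 8).
steiner_min_length <- function(tmat) {
  tmat <- unique(tmat)
  t_n <- nrow(tmat); s <- ncol(tmat)
  if (t_n <= 1L) return(0L)
  if (s == 0L) return(0L)
  verts <- 0:(2^s - 1)
  popcnt <- vapply(verts, function(v) sum(bitwAnd(v, 2^(0:(s - 1))) > 0),
                   numeric(1))
  D <- outer(verts, verts, function(a, b)
    popcnt[bitwXor(a, b) + 1L])
  tv <- apply(tmat, 1L, function(r) sum(2^(which(r) - 1L))) + 1L  # 1-based
  q <- tv[1]; rest <- tv[-1]
  k <- length(rest)
  nmask <- 2^k - 1
  f <- matrix(Inf, nmask, length(verts))
  for (i in seq_len(k)) f[2^(i - 1), ] <- D[rest[i], ]
  masks <- seq_len(nmask)
  masks <- masks[order(popcnt_int(masks))]
  for (X in masks) {
    if (popcnt_int(X) < 2) next
    tX <- rep(Inf, length(verts))
    Y <- bitwAnd(X - 1L, X)
    while (Y > 0L) {
      comp <- bitwAnd(X, bitwNot(Y))
      if (Y < comp) tX <- pmin(tX, f[Y, ] + f[comp, ])
      Y <- bitwAnd(Y - 1L, X)
    }
    f[X, ] <- apply(D + tX, 2, min)
  }
  f[nmask, q]
}

popcnt_int <- function(x) {
  vapply(x, function(v) {
    c <- 0L
    while (v > 0L) { c <- c + bitwAnd(v, 1L); v <- bitwShiftR(v, 1L) }
    c
  }, integer(1))
}

# ---- exhaustive haplogroup-classification scorer --------------------------

oracle_classify <- function(labels, tree, policy = mask_policy()) {
  labels <- mask_labels(labels, policy)
  best <- NULL
  depths <- integer(length(tree$name)); names(depths) <- tree$name
  for (i in seq_along(tree$name)) {
    nd <- tree$name[i]
    chain <- nd
    while (!is.na(tree$parent[match(chain[1], tree$name)]))
      chain <- c(tree$parent[match(chain[1], tree$name)], chain)
    depths[nd] <- length(chain) - 1L
    expected <- character(0)
    for (anc in chain) {
      for (tok in mask_labels(tree$motifs[[match(anc, tree$name)]], policy)) {
        if (endsWith(tok, "!")) {
          p <- sub("^(\\d+).*", "\\1", sub("!$", "", tok))
          expected <- expected[sub("^(\\d+).*", "\\1", expected) != p]
        } else expected <- union(expected, tok)
      }
    }
    sc <- length(intersect(labels, expected)) -
      length(setdiff(expected, labels))
    cand <- list(node = nd, score = sc,
                 matched = length(intersect(labels, expected)),
                 depth = depths[nd])
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$matched > best$matched) ||
        (cand$score == best$score && cand$matched == best$matched &&
         cand$depth > best$depth) ||
        (cand$score == best$score && cand$matched == best$matched &&
         cand$depth == best$depth && cand$node < best$node))
      best <- cand
  }
  best$node
}

random_haplotree <- function(n_nodes = 20, positions = 100:400) {
  nms <- c("root", paste0("N", seq_len(n_nodes - 1L)))
  parent <- c(NA, nms[vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1))])
  motif <- vapply(seq_len(n_nodes), function(i) {
    if (i == 1) return("-")
    paste(sample(positions, sample(1:3, 1)), collapse = " ")
  }, character(1))
  haplo_tree(nms, ifelse(is.na(parent), "-", parent), motif)
}

# ---- misc -----------------------------------------------------------------

seq_with_variants <- function(ref, subs = NULL, ins = NULL, del = NULL) {
  ch <- strsplit(ref$bases, "")[[1]]
  if (!is.null(subs)) ch[subs$position] <- subs$base
  if (!is.null(del)) ch[del] <- NA
  out <- ch
  if (!is.null(ins)) {
    # ins: data.frame(position, base); applied after substitutions
    out <- character(0); last <- 0L
    for (i in seq_len(nrow(ins))) {
      out <- c(out, ch[(last + 1L):ins$position[i]], ins$base[i])
      last <- ins$position[i]
    }
    out <- c(out, ch[(last + 1L):length(ch)])
  }
  paste(out[!is.na(out)], collapse = "")
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(Map(function(id, s) c(paste0(">", id), s), ids, seqs))
  writeLines(lines, path)
  path
}
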