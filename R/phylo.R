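# Tree inference: Poisson-corrected distances, neighbor joining with
# bootstrap support, minimum-ancestor-deviation rooting, and a delegation
# hook for external maximum-likelihood builders.

# alignment rows as a named character vector (species -> aligned string)
alignment_rows <- function(msa) {
  if (inherits(msa, "supermatrix")) return(msa$rows)
  if (inherits(msa, "msta")) return(setNames(msa$aligned, msa$species_id))
  if (is.character(msa) && !is.null(names(msa))) return(msa)
  stop("cannot interpret alignment input", call. = FALSE)
}

#' Poisson-corrected pairwise distances from an alignment
#'
#' For each species pair, the mismatch fraction `p` over columns where both
#' rows are gap-free gives `d = -ln(1 - p)`; `p >= 0.95` is clamped to
#' `d = 3` with a warning. Errors if any pair has no overlapping columns.
#'
#' @param msa a `projected_msa`, `supermatrix`, or named character vector of
#'   equal-length aligned strings
#' @param d_max clamp value for saturated pairs (default 3)
#' @return symmetric species x species distance matrix
#' @export
pairwise_distance <- function(msa, d_max = 3.0) {
  rows <- alignment_rows(msa)
  n <- length(rows)
  if (n < 3L) stop("need at least 3 species", call. = FALSE)
  m <- do.call(rbind, lapply(rows, chars))
  rownames(m) <- names(rows)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  clamped <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("no overlapping columns for pair ", names(rows)[i], " / ",
             names(rows)[j], call. = FALSE)
      }
      p <- mean(m[i, ok] != m[j, ok])
      d <- if (p >= 0.95) {
        clamped <- c(clamped, paste0(names(rows)[i], "/", names(rows)[j]))
        d_max
      } else {
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (length(clamped) > 0) {
    warning("saturated distances clamped to ", d_max, " for: ",
            paste(clamped, collapse = ", "), call. = FALSE)
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei neighbor joining (via ape) on a symmetric distance
#' matrix; taxa are sorted by id first so the result is input-order
#' invariant, and negative branch lengths are clamped to zero.
#'
#' @param D symmetric distance matrix with taxon dimnames
#' @return unrooted `phylo`
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  ord <- order(rownames(D))
  tr <- ape::nj(D[ord, ord])
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Classical Felsenstein bootstrap: alignment columns are resampled with
#' replacement, a NJ tree is built per replicate, and each internal split's
#' support is the percentage of replicate trees containing it (stored in
#' `node.label`). Deterministic under `seed`.
#'
#' @inheritParams pairwise_distance
#' @param n_reps bootstrap replicates (default 100; 0 skips support)
#' @param seed RNG seed
#' @return unrooted `phylo`, with `node.label` support in 0..100 when
#'   `n_reps > 0`
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 42L) {
  rows <- alignment_rows(msa)
  tree <- nj_tree(pairwise_distance(msa))
  if (n_reps <= 0L) return(tree)
  m <- do.call(rbind, lapply(rows, chars))
  rownames(m) <- names(rows)
  nc <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      idx <- sample.int(nc, nc, replace = TRUE)
      rs <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
      tryCatch(nj_tree(pairwise_distance(rs)), error = function(e) NULL)
    })
  })
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / length(reps), 1)
  tree
}

# --- minimum ancestor deviation rooting -------------------------------------

# deviation terms for one candidate root edge of an unrooted tree:
# crossing pairs depend linearly on the root position x (distance from the
# edge's child end); same-side pairs contribute fixed terms through their
# ancestor node on the path.
mad_edge_stats <- function(tree, D, tips_below, edge_idx) {
  edge <- tree$edge
  v <- edge[edge_idx, 2L]; u <- edge[edge_idx, 1L]
  L <- tree$edge.length[edge_idx]
  n <- length(tree$tip.label)
  below <- tips_below[[v]]
  above <- setdiff(seq_len(n), below)
  alpha <- c(); beta <- c()
  fixed <- 0; n_fixed <- 0L
  for (b in below) {
    for (cc in above) {
      dbc <- D[b, cc]
      if (dbc <= 0) { n_fixed <- n_fixed + 1L; next } # deviation defined 0
      alpha <- c(alpha, 2 / dbc)
      beta <- c(beta, 2 * D[v, b] / dbc - 1)
    }
  }
  same_side_dev <- function(tipset, anchor) {
    # ancestor of a same-side pair = node on its path closest to the root
    # side; its deviation is |d(a,b) - d(a,c)| / d(b,c), independent of x
    dev <- c()
    ts <- tipset
    if (length(ts) < 2L) return(dev)
    for (ii in seq_len(length(ts) - 1L)) {
      for (jj in seq.int(ii + 1L, length(ts))) {
        b <- ts[ii]; cc <- ts[jj]
        dbc <- D[b, cc]
        if (dbc <= 0) { dev <- c(dev, 0); next }
        # node on path(b,c) minimizing distance to the anchor endpoint
        da <- (D[anchor, b] + D[anchor, cc] - dbc) / 2 # anchor to path
        dab <- D[anchor, b] - da                        # ancestor to b
        dev <- c(dev, abs(2 * dab / dbc - 1))
      }
    }
    dev
  }
  dev_below <- same_side_dev(below, u)
  dev_above <- same_side_dev(above, v)
  list(alpha = alpha, beta = beta, L = L,
       fixed_sq = sum(dev_below^2) + sum(dev_above^2),
       n_pairs = choose(n, 2))
}

#' Root a tree by minimum ancestor deviation
#'
#' Evaluates every branch and the optimal root position on it. For a
#' candidate root, each leaf pair (b, c) contributes the relative deviation
#' `|2 d(a,b) / d(b,c) - 1|` of its inferred ancestor `a` (the node on the
#' b-c path nearest the root) from the clocklike midpoint; the root
#' minimizing the root-mean-square deviation over all pairs wins. Pairs at
#' zero path length contribute deviation 0. The unrooted topology and total
#' branch length are preserved.
#'
#' @param tree unrooted `phylo` with branch lengths (>= 3 leaves); a 2-leaf
#'   tree is rooted at its midpoint
#' @return rooted `phylo` with attribute `mad_score` (the minimum RMS
#'   deviation)
#' @export
mad_root <- function(tree) {
  n <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("branch lengths required")
  if (n == 2L) {
    tot <- sum(tree$edge.length)
    out <- two_tip_tree(tree$tip.label)
    out$edge.length <- c(tot / 2, tot / 2)
    attr(out, "mad_score") <- 0
    return(out)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  D <- ape::dist.nodes(tree)
  tips_below <- tips_below_nodes(tree)
  best <- NULL
  for (e in seq_len(nrow(tree$edge))) {
    st <- mad_edge_stats(tree, D, tips_below, e)
    # minimize sum (alpha x + beta)^2 + fixed over x in [0, L]
    sa2 <- sum(st$alpha^2); sab <- sum(st$alpha * st$beta)
    x_star <- if (sa2 > 0) min(max(-sab / sa2, 0), st$L) else 0
    f <- sum((st$alpha * x_star + st$beta)^2) + st$fixed_sq
    score <- sqrt(f / st$n_pairs)
    if (is.null(best) || score < best$score - 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         tree$edge[e, 2L] < best$child)) {
      best <- list(edge = e, x = x_star, score = score,
                   child = tree$edge[e, 2L])
    }
  }
  rooted <- root_on_edge(tree, best$edge, best$x)
  attr(rooted, "mad_score") <- best$score
  rooted
}

#' RMS ancestor deviation of a candidate root position
#'
#' Exposes the objective [mad_root()] minimizes, for one root position given
#' as an edge index and a distance from that edge's child end.
#' @param tree unrooted `phylo`
#' @param edge_idx row of `tree$edge`
#' @param x distance from the child end, in `[0, edge length]`
#' @return RMS relative ancestor deviation over all leaf pairs
#' @export
mad_score_at <- function(tree, edge_idx, x) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  D <- ape::dist.nodes(tree)
  st <- mad_edge_stats(tree, D, tips_below_nodes(tree), edge_idx)
  x <- min(max(x, 0), st$L)
  sqrt((sum((st$alpha * x + st$beta)^2) + st$fixed_sq) / st$n_pairs)
}

# tip indices in the subtree below each node (keyed by node number)
tips_below_nodes <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(n)) out[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Root an unrooted tree on edge `edge_idx` at distance x from the child end:
# a new degree-2 root node splits the edge into parts x (child side) and
# L - x (parent side). Built by DFS into newick and re-read, so the result
# is in canonical ape form.
root_on_edge <- function(tree, edge_idx, x) {
  u <- tree$edge[edge_idx, 1L]; v <- tree$edge[edge_idx, 2L]
  L <- tree$edge.length[edge_idx]
  x <- min(max(x, 0), L)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  w <- nn + 1L
  from <- c(tree$edge[-edge_idx, 1L], w, w)
  to <- c(tree$edge[-edge_idx, 2L], v, u)
  len <- c(tree$edge.length[-edge_idx], x, L - x)
  adj <- vector("list", nn + 1L)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- rbind(adj[[from[k]]], c(to[k], len[k]))
    adj[[to[k]]] <- rbind(adj[[to[k]]], c(from[k], len[k]))
  }
  nwk <- function(node, parent) {
    if (node <= n) return(tree$tip.label[node])
    nbrs <- adj[[node]]
    parts <- character(0)
    for (k in seq_len(nrow(nbrs))) {
      if (nbrs[k, 1L] == parent) next
      parts <- c(parts, paste0(nwk(nbrs[k, 1L], node),
                               sprintf(":%.12g", nbrs[k, 2L])))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk(w, 0L), ";"))
}

#' Delegate tree inference to an external builder
#'
#' Shells out to an external maximum-likelihood tree program (e.g. IQ-TREE,
#' FastTree, RAxML-NG) with a verbatim options string and parses the newick
#' result. This is an interface hook: the built-in [nj_tree()] /
#' [bootstrap_support()] pipeline does not depend on it.
#'
#' @param msa_path alignment FASTA path
#' @param out_tree path the builder writes its newick tree to
#' @param binary program name on PATH
#' @param options_string forwarded verbatim (e.g. "-m JTT+F+I+G -B 1000")
#' @param partition_path optional partition file forwarded to the builder
#' @return `phylo`
#' @export
run_external_tree <- function(msa_path, out_tree, binary,
                              options_string = "", partition_path = NULL) {
  if (Sys.which(binary) == "") {
    stop("external tree builder '", binary, "' not found on PATH; ",
         "use the built-in nj_tree()/bootstrap_support() instead",
         call. = FALSE)
  }
  args <- c(options_string,
            if (!is.null(partition_path)) c("-p", partition_path),
            msa_path)
  status <- system2(binary, args, stdout = out_tree, stderr = FALSE)
  if (status != 0 || !file.exists(out_tree)) {
    stop("external tree builder failed (exit ", status, ")", call. = FALSE)
  }
  tr <- tryCatch(suppressWarnings(ape::read.tree(out_tree)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("could not parse newick output in ", out_tree,
                        call. = FALSE)
  tr
}

#' Write a tree as newick
#'
#' Support values are stored as internal-node labels; branch lengths use 6
#' significant digits.
#' @param tree a `phylo`
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path, digits = 6)
  invisible(path)
}
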