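# Tree comparison and characterization: brute-force quartet similarity,
# ultrametricity (dispersion of root-to-leaf depths), mean branch length,
# and congruence with a (possibly multifurcating) reference tree.

# Induced quartet topologies from topological (unit branch length) path
# distances, via the four-point condition. Returns a code per quartet:
# 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved.
quartet_codes <- function(tree, taxa, quartets) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  D <- ape::cophenetic.phylo(tr)[taxa, taxa]
  a <- quartets[1L, ]; b <- quartets[2L, ]
  cc <- quartets[3L, ]; d <- quartets[4L, ]
  s1 <- D[cbind(a, b)] + D[cbind(cc, d)]
  s2 <- D[cbind(a, cc)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, cc)]
  s <- cbind(s1, s2, s3)
  mins <- pmin(s1, s2, s3)
  n_min <- (s1 == mins) + (s2 == mins) + (s3 == mins)
  code <- max.col(-s, ties.method = "first")
  code[n_min > 1L] <- 0L
  code
}

#' Quartet similarity between two trees
#'
#' For every 4-leaf subset, the induced (unrooted) quartet topologies of the
#' two trees are compared; the similarity is the agreeing fraction.
#' Brute-force O(n^4) enumeration, intended for modest leaf counts.
#'
#' @param t1,t2 `phylo` objects on the same leaf set, fully resolved
#' @return list (n_quartets, n_agree, similarity)
#' @export
quartet_similarity <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("leaf sets differ: ", paste(diff, collapse = ", "), call. = FALSE)
  }
  for (t in list(t1, t2)) {
    if (!ape::is.binary(ape::unroot(t))) {
      stop("trees must be fully resolved", call. = FALSE)
    }
  }
  taxa <- l1
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 leaves", call. = FALSE)
  q <- combn(taxa, 4L)
  c1 <- quartet_codes(t1, taxa, q)
  c2 <- quartet_codes(t2, taxa, q)
  n_agree <- sum(c1 == c2)
  list(n_quartets = ncol(q), n_agree = n_agree,
       similarity = n_agree / ncol(q))
}

#' Ultrametricity of a rooted tree
#'
#' Coefficient of variation (sd/mean) of root-to-leaf path lengths: 0 for a
#' perfectly clocklike tree, invariant under uniform branch scaling.
#'
#' @param tree rooted `phylo` with branch lengths
#' @return nonnegative real
#' @export
ultrametricity <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  m <- mean(depths)
  if (m == 0) return(0)
  stats::sd(depths) / m
}

#' Mean branch length
#'
#' Arithmetic mean over all branches, internal and terminal.
#' @param tree `phylo` with branch lengths
#' @return real
#' @export
mean_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) stop("branch lengths required")
  mean(tree$edge.length)
}

#' Congruence with a reference tree
#'
#' Fraction of reference-resolved quartets whose topology the tree
#' reproduces. The reference may be multifurcating; quartets it leaves
#' unresolved are excluded from the denominator. The tree's leaves must be a
#' subset of the reference's (the reference is pruned to the shared set).
#'
#' @param tree fully resolved `phylo`
#' @param reference `phylo`, possibly multifurcating
#' @return numeric fraction between 0 and 1
#' @export
reference_congruence <- function(tree, reference) {
  if (!all(tree$tip.label %in% reference$tip.label)) {
    stop("tree leaves missing from reference: ",
         paste(setdiff(tree$tip.label, reference$tip.label),
               collapse = ", "), call. = FALSE)
  }
  ref <- ape::keep.tip(reference, tree$tip.label)
  taxa <- sort(tree$tip.label)
  q <- combn(taxa, 4L)
  ct <- quartet_codes(tree, taxa, q)
  cr <- quartet_codes(ref, taxa, q)
  resolved <- cr != 0L
  if (!any(resolved)) {
    stop("reference resolves no quartets", call. = FALSE)
  }
  sum(ct[resolved] == cr[resolved]) / sum(resolved)
}
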