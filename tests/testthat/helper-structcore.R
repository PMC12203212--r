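# Shared fixtures and independent oracles. All fixtures are built in code.

LETTERS20 <- structcore:::RESIDUE_LETTERS

# the default model is calibrated once and cached in the package session
test_model <- function() subst_model()

rnd_seq <- function(n) paste(sample(LETTERS20, n, replace = TRUE),
                             collapse = "")

# mutate k random positions to a different letter
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  for (i in sample(nchar(s), min(k, nchar(s)))) {
    v[i] <- sample(setdiff(LETTERS20, v[i]), 1)
  }
  paste(v, collapse = "")
}

rec <- function(species, protein, aa, tdi = aa) {
  tibble::tibble(species_id = species, protein_id = protein,
                 aa = aa, tdi = tdi)
}

make_db <- function(records, max_len = 4000L) {
  build_database(split(records, records$species_id), max_len = max_len)
}

# a small paired db with two planted families plus noise singletons
toy_family_db <- function(n_species = 4, fam_sizes = c(2, 2), len = 150,
                          n_noise = 2, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (f in seq_along(fam_sizes)) {
      root_aa <- rnd_seq(len); root_tdi <- rnd_seq(len)
      for (s in seq_len(fam_sizes[f])) {
        rows[[length(rows) + 1]] <- rec(
          sprintf("sp%d", s), sprintf("f%d", f),
          mutate_seq(root_aa, round(0.1 * len)),
          mutate_seq(root_tdi, round(0.05 * len)))
      }
    }
    for (k in seq_len(n_noise)) {
      rows[[length(rows) + 1]] <- rec(
        sprintf("sp%d", k), sprintf("noise%d", k),
        rnd_seq(len), rnd_seq(len))
    }
    make_db(dplyr::bind_rows(rows))
  })
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), path, width = 80L)
  path
}

# --- independent quartet oracle --------------------------------------------
# Induced quartet via subtree extraction: the cherry pair of the pruned
# 4-leaf unrooted tree (from its bipartitions), not via path distances.
oracle_quartet_code <- function(tree, four) {
  t4 <- ape::unroot(ape::keep.tip(tree, four))
  if (t4$Nnode < 2L) return(0L) # star: unresolved
  parts <- ape::prop.part(t4)
  labs <- attr(parts, "labels")
  pair <- NULL
  for (p in parts) {
    if (length(p) == 2L) pair <- sort(labs[p])
    if (length(p) == 3L) pair <- sort(setdiff(labs, labs[p]))
    if (!is.null(pair)) break
  }
  if (is.null(pair)) return(0L)
  four <- sort(four)
  combos <- list(four[c(1, 2)], four[c(1, 3)], four[c(1, 4)])
  other <- function(p) sort(setdiff(four, p))
  for (k in 1:3) {
    if (identical(pair, combos[[k]]) || identical(pair, other(combos[[k]]))) {
      return(k)
    }
  }
  0L
}

oracle_quartet_similarity <- function(t1, t2) {
  taxa <- sort(t1$tip.label)
  q <- combn(taxa, 4)
  c1 <- apply(q, 2, oracle_quartet_code, tree = t1)
  c2 <- apply(q, 2, oracle_quartet_code, tree = t2)
  mean(c1 == c2)
}

# --- independent MAD oracle -------------------------------------------------
# Brute force over root positions: for a rooted candidate, ancestors are
# actual MRCAs and deviations are computed from node distances, with no code
# shared with mad_root()'s per-edge quadratic form.
oracle_mad_eval <- function(rooted) {
  n <- length(rooted$tip.label)
  D <- ape::dist.nodes(rooted)
  M <- ape::mrca(rooted)
  dev2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      a <- M[i, j]
      dbc <- D[i, j]
      if (dbc > 0) dev2 <- dev2 + (2 * D[a, i] / dbc - 1)^2
    }
  }
  sqrt(dev2 / choose(n, 2))
}

oracle_mad_min <- function(tree, grid = 100) {
  tree <- ape::unroot(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    L <- tree$edge.length[e]
    f <- function(x) oracle_mad_eval(structcore:::root_on_edge(tree, e, x))
    xs <- seq(0, L, length.out = grid)
    vals <- vapply(xs, f, 1.0)
    k <- which.min(vals)
    best <- min(best, vals[k])
    lo <- xs[max(1, k - 1)]; hi <- xs[min(grid, k + 1)]
    if (hi > lo) {
      best <- min(best, optimize(f, c(lo, hi), tol = 1e-10)$objective)
    }
  }
  best
}

# run the core pipeline (no bootstrap, no per-gene trees) on a simulation
run_pipeline_tree <- function(cfg) {
  sim <- simulate_proteomes(cfg)
  db <- make_db(sim$records)
  cl <- cascade_cluster(db, seed = cfg$seed)
  pr <- stage_profile(db, cl, 0.8)
  aln <- stage_align(db, cl, pr$core_set)
  tree <- nj_tree(pairwise_distance(aln$supermatrix$rows))
  list(sim = sim, db = db, clusters = cl, profile = pr, aln = aln,
       tree = tree)
}
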