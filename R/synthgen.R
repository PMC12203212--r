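# Synthetic multi-species proteomes: a known species tree, planted gene
# families (core and accessory), per-species loss and duplication, and
# independently tunable AA and 3Di divergence so the twilight-zone regime
# (AA identity below 30%, 3Di conserved) can be emulated.

#' Synthetic proteome configuration
#'
#' Substitution is Jukes-Cantor-like in both alphabets: events arrive at
#' `rate * branch length` per site and replace the letter with a uniform
#' random other letter, so expected identity between two sequences at path
#' distance t is `1/20 + 19/20 * exp(-20/19 * rate * t)`. There is no indel
#' process. Core families are guaranteed (by redrawing loss/duplication
#' events) to stay single-copy in at least `core_min_coverage` of species;
#' accessory families are present in a random subset of species
#' (`accessory_presence` each) and kept below that coverage.
#'
#' @param n_species number of species (default 20)
#' @param n_core_families,n_accessory_families planted family counts
#'   (defaults 50/50)
#' @param seq_len_range family root sequence length range (default 120-400)
#' @param species_tree_height mean root-to-tip path length (default 1)
#' @param rate_aa,rate_3di substitutions per site per unit height (defaults
#'   0.5 and 0.1; must satisfy rate_aa >= rate_3di >= 0)
#' @param loss_prob,dup_prob per-species per-family event probabilities
#'   (defaults 0.1 and 0.05)
#' @param accessory_presence per-species presence probability of an
#'   accessory family (default 0.4)
#' @param core_min_coverage guaranteed single-copy coverage of core families
#'   (default 0.8)
#' @param seed RNG seed (default 42)
#' @return object of class `synth_config`
#' @export
synth_config <- function(n_species = 20L, n_core_families = 50L,
                         n_accessory_families = 50L,
                         seq_len_range = c(120L, 400L),
                         species_tree_height = 1,
                         rate_aa = 0.5, rate_3di = 0.1,
                         loss_prob = 0.1, dup_prob = 0.05,
                         accessory_presence = 0.4,
                         core_min_coverage = 0.8,
                         seed = 42L) {
  stopifnot(n_species >= 3, n_core_families >= 1, n_accessory_families >= 0,
            length(seq_len_range) == 2, seq_len_range[1] >= 10,
            seq_len_range[2] >= seq_len_range[1],
            species_tree_height > 0,
            rate_aa >= rate_3di, rate_3di >= 0,
            loss_prob >= 0, loss_prob <= 1,
            dup_prob >= 0, dup_prob <= 1,
            accessory_presence >= 0, accessory_presence <= 1,
            core_min_coverage > 0, core_min_coverage <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Twilight-zone preset
#'
#' Rates chosen from the Jukes-Cantor closed form so that mean within-family
#' AA identity falls below 30% while 3Di identity stays above 80%: amino
#' acids beyond the twilight zone, structure conserved.
#' @param n_species,n_families,seed see [synth_config()]
#' @export
synth_config_twilight <- function(n_species = 10L, n_families = 10L,
                                  seed = 42L) {
  synth_config(n_species = n_species, n_core_families = n_families,
               n_accessory_families = 0L, seq_len_range = c(120L, 250L),
               rate_aa = 1.2, rate_3di = 0.05,
               loss_prob = 0, dup_prob = 0, seed = seed)
}

random_seq <- function(len) {
  paste(sample(RESIDUE_LETTERS, len, replace = TRUE), collapse = "")
}

# Jukes-Cantor-like evolution: Poisson(rate * t * L) events, each replacing
# a uniform site with a uniform other letter
evolve_seq <- function(s, rate, t) {
  L <- nchar(s)
  k <- rpois(1L, rate * t * L)
  if (k == 0L) return(s)
  v <- chars(s)
  sites <- sample.int(L, k, replace = TRUE)
  for (site in sites) {
    v[site] <- sample(setdiff(RESIDUE_LETTERS, v[site]), 1L)
  }
  paste(v, collapse = "")
}

# random species tree: random topology, uniform branch lengths rescaled so
# the mean root-to-tip depth equals `height` (non-clocklike but with every
# edge long enough to carry signal)
random_species_tree <- function(n_species, height) {
  tr <- ape::rtree(n_species, rooted = TRUE, br = NULL)
  tr$tip.label <- sprintf("S%02d", seq_len(n_species))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_species)]
  tr$edge.length <- tr$edge.length * (height / mean(depths))
  tr
}

# evolve one family's root pair down the tree; returns tibble
# (species_id, aa, tdi)
evolve_family <- function(tree, root_aa, root_tdi, rate_aa, rate_3di) {
  n <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  nn <- n + tr$Nnode
  aa <- character(nn); tdi <- character(nn)
  root <- n + 1L
  aa[root] <- root_aa; tdi[root] <- root_tdi
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]; t <- tr$edge.length[e]
    aa[ch] <- evolve_seq(aa[p], rate_aa, t)
    tdi[ch] <- evolve_seq(tdi[p], rate_3di, t)
  }
  tibble::tibble(species_id = tr$tip.label,
                 aa = aa[seq_len(n)], tdi = tdi[seq_len(n)])
}

# per-species single-copy indicator implied by presence/dup vectors
single_copy_frac <- function(present, dup) mean(present & !dup)

#' Simulate paired proteomes with planted gene families
#'
#' Draws a species tree, evolves each family's independent random root AA
#' and 3Di sequences down it at their respective rates, applies per-species
#' loss and duplication (duplicates diverge for an extra 10% of tree
#' height), and returns both the per-species records and the ground truth.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synth_config()]
#' @return list with `records` (tibble: species_id, protein_id, aa, tdi) and
#'   `truth` (list: species_tree, assignments tibble with db-namespaced ids,
#'   families tibble with planted status and realized coverage, config)
#' @export
simulate_proteomes <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    tree <- random_species_tree(cfg$n_species, cfg$species_tree_height)
    n_fam <- cfg$n_core_families + cfg$n_accessory_families
    fam_ids <- sprintf("F%03d", seq_len(n_fam))
    status <- rep(c("core", "accessory"),
                  c(cfg$n_core_families, cfg$n_accessory_families))
    recs <- list()
    fam_rows <- list()
    assign_rows <- list()
    for (f in seq_len(n_fam)) {
      len <- sample(seq.int(cfg$seq_len_range[1], cfg$seq_len_range[2]), 1L)
      fam <- evolve_family(tree, random_seq(len), random_seq(len),
                           cfg$rate_aa, cfg$rate_3di)
      n_sp <- cfg$n_species
      repeat {
        if (status[f] == "core") {
          present <- runif(n_sp) >= cfg$loss_prob
        } else {
          present <- runif(n_sp) < cfg$accessory_presence
        }
        dup <- present & (runif(n_sp) < cfg$dup_prob)
        sc <- single_copy_frac(present, dup)
        if (status[f] == "core" && sc >= cfg$core_min_coverage) break
        if (status[f] == "accessory" && sc < cfg$core_min_coverage) break
      }
      gene <- paste0("g", sub("^F", "", fam_ids[f]))
      for (s in which(present)) {
        sp <- fam$species_id[s]
        recs[[length(recs) + 1L]] <- tibble::tibble(
          species_id = sp, protein_id = gene,
          aa = fam$aa[s], tdi = fam$tdi[s])
        assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
          species_id = sp, protein_id = gene, family_id = fam_ids[f],
          copy = 1L)
        if (dup[s]) {
          extra <- 0.1 * cfg$species_tree_height
          recs[[length(recs) + 1L]] <- tibble::tibble(
            species_id = sp, protein_id = paste0(gene, ".d1"),
            aa = evolve_seq(fam$aa[s], cfg$rate_aa, extra),
            tdi = evolve_seq(fam$tdi[s], cfg$rate_3di, extra))
          assign_rows[[length(assign_rows) + 1L]] <- tibble::tibble(
            species_id = sp, protein_id = paste0(gene, ".d1"),
            family_id = fam_ids[f], copy = 2L)
        }
      }
      fam_rows[[f]] <- tibble::tibble(
        family_id = fam_ids[f], status = status[f], length = len,
        single_copy_coverage = sc,
        any_copy_coverage = mean(present))
    }
    records <- dplyr::bind_rows(recs)
    assignments <- dplyr::bind_rows(assign_rows)
    assignments$db_id <- paste(assignments$species_id,
                               assignments$protein_id, sep = "|")
    list(records = records,
         truth = list(species_tree = tree,
                      assignments = assignments,
                      families = dplyr::bind_rows(fam_rows),
                      config = cfg))
  })
}

#' Write simulated proteomes as FASTA pairs plus ground truth
#'
#' One `<species>.fasta` + `<species>.3di.fasta` pair per species under
#' `dir`, and a `truth/` subdirectory with the newick species tree and TSV
#' family assignments.
#'
#' @param sim result of [simulate_proteomes()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_proteomes <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in unique(sim$records$species_id)) {
    sub <- sim$records[sim$records$species_id == sp, ]
    aa <- Biostrings::AAStringSet(setNames(sub$aa, sub$protein_id))
    tdi <- Biostrings::AAStringSet(setNames(sub$tdi, sub$protein_id))
    Biostrings::writeXStringSet(aa, file.path(dir, paste0(sp, ".fasta")),
                                width = 80L)
    Biostrings::writeXStringSet(tdi, file.path(dir,
                                               paste0(sp, ".3di.fasta")),
                                width = 80L)
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_newick(sim$truth$species_tree, file.path(tdir, "species_tree.nwk"))
  write.table(sim$truth$assignments, file.path(tdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$families, file.path(tdir, "families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score pipeline output against the planted ground truth
#'
#' Computes precision/recall/F1 of core-gene recovery (a planted core family
#' counts as recovered when some selected core cluster captures at least 80%
#' of its members, the same member-sharing rule as
#' [map_gene_to_cluster()]), the adjusted Rand index between a clustering
#' and the planted family assignment, and the quartet similarity between an
#' inferred species tree and the true one. Components are skipped (NA) when
#' the corresponding output is not supplied.
#'
#' @param truth `truth` element of [simulate_proteomes()]
#' @param clusters tibble (rep_id, member_id) over db-namespaced ids
#' @param core_ids character vector of selected core cluster ids
#' @param tree inferred species `phylo`
#' @return one-row tibble (precision, recall, f1, ari, quartet_similarity)
#' @export
truth_metrics <- function(truth, clusters = NULL, core_ids = NULL,
                          tree = NULL) {
  prec <- rec <- f1 <- ari <- qs <- NA_real_
  if (!is.null(clusters)) {
    asg <- truth$assignments
    common <- intersect(asg$db_id, clusters$member_id)
    lab_true <- asg$family_id[match(common, asg$db_id)]
    lab_clu <- clusters$rep_id[match(common, clusters$member_id)]
    ari <- mclust::adjustedRandIndex(lab_true, lab_clu)
    if (!is.null(core_ids)) {
      core_fams <- truth$families$family_id[truth$families$status == "core"]
      mapped <- vapply(core_fams, function(fid) {
        members <- asg$db_id[asg$family_id == fid]
        cl <- map_gene_to_cluster(members, clusters)
        !is.na(cl) && cl %in% core_ids
      }, TRUE)
      tp <- sum(mapped)
      # precision: selected core clusters that correspond to a planted core
      # family by the same 80% member-sharing rule
      cluster_fam <- vapply(core_ids, function(cid) {
        mem <- clusters$member_id[clusters$rep_id == cid]
        fams <- asg$family_id[match(mem, asg$db_id)]
        tab <- sort(table(fams), decreasing = TRUE)
        if (length(tab) == 0) return(NA_character_)
        fid <- names(tab)[1L]
        if (tab[1L] / length(mem) >= 0.8 && fid %in% core_fams) fid
        else NA_character_
      }, "")
      prec <- if (length(core_ids) > 0)
        sum(!is.na(cluster_fam)) / length(core_ids) else NA_real_
      rec <- tp / length(core_fams)
      f1 <- if (!is.na(prec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else 0
    }
  }
  if (!is.null(tree)) {
    qs <- quartet_similarity(tree, truth$species_tree)$similarity
  }
  tibble::tibble(precision = prec, recall = rec, f1 = f1, ari = ari,
                 quartet_similarity = qs)
}
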