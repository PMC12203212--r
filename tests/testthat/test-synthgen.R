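# Synthetic proteome generator: determinism, planted-family invariants,
# divergence calibration, and truth bookkeeping.

test_that("simulation is fully reproducible from the seed", {
  cfg <- synth_config(n_species = 5, n_core_families = 3,
                      n_accessory_families = 2, seed = 77)
  s1 <- simulate_proteomes(cfg)
  s2 <- simulate_proteomes(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(ape::write.tree(s1$truth$species_tree),
                   ape::write.tree(s2$truth$species_tree))
  # written FASTA pairs are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_proteomes(s1, d1); write_proteomes(s2, d2)
  f <- "S01.fasta"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("emitted records satisfy the paired-database invariants", {
  cfg <- synth_config(n_species = 6, n_core_families = 4,
                      n_accessory_families = 3, seed = 19)
  sim <- simulate_proteomes(cfg)
  expect_true(all(nchar(sim$records$aa) == nchar(sim$records$tdi)))
  expect_false(any(grepl("-", sim$records$aa, fixed = TRUE)))
  db <- make_db(sim$records) # must build cleanly
  expect_equal(nrow(db$records), nrow(sim$records))
})

test_that("event-free configurations are single-copy everywhere", {
  cfg <- synth_config(n_species = 5, n_core_families = 4,
                      n_accessory_families = 0, loss_prob = 0,
                      dup_prob = 0, seed = 23)
  sim <- simulate_proteomes(cfg)
  expect_true(all(sim$truth$families$single_copy_coverage == 1))
  # downstream bookkeeping: profiling the true family partition reproduces
  # the generator's recorded coverages
  db <- make_db(sim$records)
  asg <- sim$truth$assignments
  truth_clusters <- tibble::tibble(rep_id = asg$family_id,
                                   member_id = asg$db_id)
  profs <- profile_clusters(truth_clusters, db)
  expect_equal(
    profs$single_copy_coverage[match(sim$truth$families$family_id,
                                     profs$cluster_id)],
    sim$truth$families$single_copy_coverage)
})

test_that("planted status respects the configured coverage boundary", {
  cfg <- synth_config(n_species = 10, n_core_families = 8,
                      n_accessory_families = 8, seed = 29)
  sim <- simulate_proteomes(cfg)
  fams <- sim$truth$families
  expect_true(all(
    fams$single_copy_coverage[fams$status == "core"] >= 0.8))
  expect_true(all(
    fams$single_copy_coverage[fams$status == "accessory"] < 0.8))
})

test_that("pairwise identity tracks the substitution model expectation", {
  mean_identity <- function(height, rate, seed, what) {
    cfg <- synth_config(n_species = 6, n_core_families = 3,
                        n_accessory_families = 0, loss_prob = 0,
                        dup_prob = 0, species_tree_height = height,
                        rate_aa = rate, rate_3di = rate / 5, seed = seed)
    sim <- simulate_proteomes(cfg)
    tree <- sim$truth$species_tree
    paths <- ape::cophenetic.phylo(tree)
    ids <- c(); exp_ids <- c()
    for (fid in unique(sim$truth$assignments$family_id)) {
      asg <- sim$truth$assignments
      sub <- sim$records[paste(sim$records$species_id,
                               sim$records$protein_id, sep = "|") %in%
                           asg$db_id[asg$family_id == fid], ]
      r <- if (what == "aa") cfg$rate_aa else cfg$rate_3di
      s <- if (what == "aa") sub$aa else sub$tdi
      for (i in 1:(nrow(sub) - 1)) {
        for (j in (i + 1):nrow(sub)) {
          ids <- c(ids, mean(strsplit(s[i], "")[[1]] ==
                               strsplit(s[j], "")[[1]]))
          t <- paths[sub$species_id[i], sub$species_id[j]]
          exp_ids <- c(exp_ids, 1 / 20 + 19 / 20 * exp(-20 / 19 * r * t))
        }
      }
    }
    c(obs = mean(ids), expected = mean(exp_ids))
  }
  # observed identity matches the Jukes-Cantor-style closed form
  v <- mean_identity(1, 0.5, 37, "aa")
  expect_equal(v[["obs"]], v[["expected"]], tolerance = 0.05)
  # identity decreases monotonically with tree height
  obs <- vapply(c(0.5, 1, 2),
                function(h) mean_identity(h, 0.5, 41, "aa")[["obs"]], 1.0)
  expect_true(all(diff(obs) < 0))
})

test_that("the twilight preset decouples AA and 3Di divergence", {
  sim <- simulate_proteomes(synth_config_twilight(seed = 43))
  asg <- sim$truth$assignments
  idf <- function(x, y) mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  aa_ids <- c(); tdi_ids <- c()
  for (fid in unique(asg$family_id)) {
    sub <- sim$records[paste(sim$records$species_id,
                             sim$records$protein_id, sep = "|") %in%
                         asg$db_id[asg$family_id == fid], ]
    for (i in 1:(nrow(sub) - 1)) {
      for (j in (i + 1):nrow(sub)) {
        aa_ids <- c(aa_ids, idf(sub$aa[i], sub$aa[j]))
        tdi_ids <- c(tdi_ids, idf(sub$tdi[i], sub$tdi[j]))
      }
    }
  }
  expect_lt(mean(aa_ids), 0.30)
  expect_gt(mean(tdi_ids), 0.80)
})

test_that("truth metrics behave on perfect, split and shuffled clusterings", {
  cfg <- synth_config(n_species = 5, n_core_families = 4,
                      n_accessory_families = 2, loss_prob = 0,
                      dup_prob = 0, seed = 47)
  sim <- simulate_proteomes(cfg)
  asg <- sim$truth$assignments
  perfect <- tibble::tibble(rep_id = asg$family_id, member_id = asg$db_id)
  tm <- truth_metrics(sim$truth, clusters = perfect,
                      core_ids = unique(
                        asg$family_id[asg$family_id %in%
                          sim$truth$families$family_id[
                            sim$truth$families$status == "core"]]),
                      tree = sim$truth$species_tree)
  expect_equal(tm$f1, 1)
  expect_equal(tm$ari, 1)
  expect_equal(tm$quartet_similarity, 1)
  # splitting one family lowers ARI below 1
  split <- perfect
  idx <- which(split$rep_id == "F001")
  split$rep_id[idx[1:2]] <- "F001b"
  expect_lt(truth_metrics(sim$truth, clusters = split)$ari, 1)
  # label shuffling destroys agreement
  withr::with_seed(1, shuffled <- dplyr::mutate(
    perfect, rep_id = sample(rep_id)))
  expect_lt(abs(truth_metrics(sim$truth, clusters = shuffled)$ari), 0.2)
})
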