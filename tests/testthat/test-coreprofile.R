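# Single-copy coverage, core selection semantics, representation warnings,
# and external-gene diagnostics.

# a db of 10 species where family "g" is single-copy in 9 species and
# duplicated in the 10th, plus a lone protein in sp1
profile_fixture <- function() {
  withr::with_seed(2, {
    fam_aa <- rnd_seq(60); fam_tdi <- rnd_seq(60)
    rows <- dplyr::bind_rows(
      lapply(1:10, function(i) rec(sprintf("sp%02d", i), "g",
                                   fam_aa, fam_tdi)),
      rec("sp10", "g2", fam_aa, fam_tdi),
      rec("sp01", "lone", rnd_seq(60), rnd_seq(60)))
  })
  db <- make_db(rows)
  clusters <- tibble::tibble(
    rep_id = c(rep("sp01|g", 11), "sp01|lone"),
    member_id = c(paste0(sprintf("sp%02d", 1:10), "|g"), "sp10|g2",
                  "sp01|lone"))
  list(db = db, clusters = clusters)
}

test_that("coverage counts species with exactly one member", {
  fx <- profile_fixture()
  profs <- profile_clusters(fx$clusters, fx$db)
  fam <- profs[profs$cluster_id == "sp01|g", ]
  expect_equal(fam$single_copy_coverage, 0.9) # 9 single + 1 double
  expect_equal(fam$any_copy_coverage, 1.0)
  lone <- profs[profs$cluster_id == "sp01|lone", ]
  expect_equal(lone$single_copy_coverage, 0.1)
  # per-profile copy counts sum to cluster size, coverage always positive
  expect_equal(vapply(profs$copy_count, sum, 1), profs$n_members,
               ignore_attr = TRUE)
  expect_true(all(profs$single_copy_coverage > 0))
  expect_true(all(profs$any_copy_coverage >= profs$single_copy_coverage))
})

test_that("core selection is inclusive at the threshold and monotone", {
  fx <- profile_fixture()
  profs <- profile_clusters(fx$clusters, fx$db)
  expect_true("sp01|g" %in% select_core(profs, 0.9)$core_cluster_ids)
  expect_false("sp01|g" %in% select_core(profs, 0.91)$core_cluster_ids)
  expect_false("sp01|lone" %in% select_core(profs, 0.8)$core_cluster_ids)
  # threshold 1.0 keeps only clusters single-copy everywhere
  expect_equal(length(select_core(profs, 1.0)$core_cluster_ids), 0)
  expect_error(select_core(profs, 0), "threshold")
  expect_error(select_core(profs, 1.2), "threshold")
  # lowering the threshold never removes a cluster
  thresholds <- c(0.9, 0.5, 0.1)
  sets <- lapply(thresholds, function(t) select_core(profs, t)$core_cluster_ids)
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("under-represented proteomes are flagged by strict majority", {
  make_core <- function(n_core, present_count) {
    # species "weak" is single-copy in present_count of n_core genes
    profs <- tibble::tibble(
      cluster_id = sprintf("c%02d", seq_len(n_core)),
      n_members = 2L,
      single_copy_coverage = 1,
      any_copy_coverage = 1,
      copy_count = lapply(seq_len(n_core), function(i) {
        c(weak = if (i <= present_count) 1L else 0L, full = 1L)
      }))
    select_core(profs, 0.5)
  }
  w <- suppressWarnings(
    species_representation_warnings(make_core(13, 4), c("weak", "full")))
  expect_equal(w$species_id, "weak")
  expect_equal(w$n_core_present, 4L)
  # exactly half of an even count is not a strict majority
  w2 <- suppressWarnings(
    species_representation_warnings(make_core(12, 6), c("weak", "full")))
  expect_equal(w2$species_id, "weak")
  w3 <- suppressWarnings(
    species_representation_warnings(make_core(12, 7), c("weak", "full")))
  expect_equal(nrow(w3), 0)
  expect_warning(
    species_representation_warnings(
      structure(list(core = tibble::tibble()), class = "core_gene_set"),
      c("a")),
    "empty core")
})

test_that("gene-to-cluster mapping follows the 80% member-sharing rule", {
  clusters <- tibble::tibble(
    rep_id = c(rep("A", 8), rep("B", 7)),
    member_id = c(paste0("m", 1:8), paste0("m", 9:10), paste0("x", 1:5)))
  gene <- paste0("m", 1:10) # 8 members in A, 2 in B
  expect_equal(map_gene_to_cluster(gene, clusters), "A")
  split5 <- tibble::tibble(
    rep_id = c(rep("A", 5), rep("B", 5)),
    member_id = paste0("m", 1:10))
  expect_true(is.na(map_gene_to_cluster(gene, split5)))
  inside <- clusters[clusters$rep_id == "A", ]
  expect_equal(map_gene_to_cluster(paste0("m", 1:8), inside), "A")
  expect_error(map_gene_to_cluster(character(0), clusters), "empty")
})

test_that("fragmentation is called on close representatives with low coverage", {
  withr::with_seed(4, {
    whole_aa <- rnd_seq(300); whole_tdi <- rnd_seq(300)
  })
  # two halves overlapping by 140 residues: strong hit, partial coverage
  rows <- dplyr::bind_rows(
    rec("s1", "left", substr(whole_aa, 1, 220), substr(whole_tdi, 1, 220)),
    rec("s2", "right", substr(whole_aa, 81, 300),
        substr(whole_tdi, 81, 300)),
    rec("s1", "other", withr::with_seed(5, rnd_seq(200)),
        withr::with_seed(6, rnd_seq(200))))
  db <- make_db(rows)
  clusters <- tibble::tibble(rep_id = db$records$protein_id,
                             member_id = db$records$protein_id)
  gene <- c("s1|left", "s2|right")
  expect_true(detect_fragmentation(gene, clusters, db, test_model()))
  # unrelated representatives: hit fails the E-value cut, not fragmented
  expect_false(detect_fragmentation(c("s1|left", "s1|other"), clusters, db,
                                    test_model()))
  # gene overlapping a single cluster: precondition fallback
  expect_false(detect_fragmentation(c("s1|left"), clusters, db,
                                    test_model()))
})

test_that("tidiers expose the core set as tables", {
  fx <- profile_fixture()
  core <- select_core(profile_clusters(fx$clusters, fx$db), 0.8)
  td <- tidy(core)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$cluster_id, "sp01|g")
  gl <- glance(core)
  expect_equal(gl$n_core, 1L)
  expect_equal(gl$threshold, 0.8)
  expect_s3_class(autoplot(core), "ggplot")
})
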