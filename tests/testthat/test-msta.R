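# Progressive structural alignment, gappy-column filtering, amino-acid
# projection and supermatrix concatenation.

toy_msta <- function(rows, gene = "g") {
  structure(list(gene_id = gene,
                 species_id = paste0("s", seq_along(rows)),
                 protein_id = paste0("s", seq_along(rows), "|p"),
                 aligned = unname(rows), n_cols = nchar(rows[1])),
            class = "msta")
}

test_that("guide trees join close members first", {
  withr::with_seed(8, {
    a_aa <- rnd_seq(120); a_tdi <- rnd_seq(120)
    b_aa <- rnd_seq(120); b_tdi <- rnd_seq(120)
    members <- dplyr::bind_rows(
      rec("s1", "a1", a_aa, a_tdi),
      rec("s2", "a2", mutate_seq(a_aa, 12), mutate_seq(a_tdi, 6)),
      rec("s3", "b1", b_aa, b_tdi),
      rec("s4", "b2", mutate_seq(b_aa, 12), mutate_seq(b_tdi, 6)))
  })
  members$protein_id <- paste(members$species_id, members$protein_id,
                              sep = "|")
  gt <- guide_tree(members, test_model())
  expect_s3_class(gt, "phylo")
  # the two planted subfamilies come out as sister pairs
  expect_equal(oracle_quartet_code(gt, members$protein_id), 1L)
})

test_that("identical sequences align without gaps", {
  withr::with_seed(10, s <- rnd_seq(80))
  members <- dplyr::bind_rows(lapply(1:3, function(i)
    rec(paste0("s", i), "p", s, s)))
  members$protein_id <- paste(members$species_id, "p", sep = "|")
  ms <- progressive_align(members, test_model())
  expect_equal(ms$n_cols, 80)
  expect_false(any(grepl("-", ms$aligned, fixed = TRUE)))
})

test_that("length differences insert gaps and rows reproduce members", {
  members <- dplyr::bind_rows(
    rec("s1", "p", "MKVL", "DDVV"),
    rec("s2", "p", "MKV", "DDV"))
  members$protein_id <- paste(members$species_id, "p", sep = "|")
  ms <- progressive_align(members, test_model())
  expect_equal(ms$n_cols, 4)
  expect_equal(sum(strsplit(ms$aligned[2], "")[[1]] == "-"), 1)
  # gap-free rows reproduce the members exactly
  expect_equal(gsub("-", "", ms$aligned), members$tdi)
})

test_that("planted families realign gap-free at modest 3Di divergence", {
  # substitution-only evolution: the true alignment is positional, so a
  # correct MSA recovers every homologous column pair (full sum-of-pairs)
  cfg <- synth_config(n_species = 6, n_core_families = 2,
                      n_accessory_families = 0, loss_prob = 0,
                      dup_prob = 0, rate_3di = 0.05, rate_aa = 0.5,
                      seed = 33)
  sim <- simulate_proteomes(cfg)
  db <- make_db(sim$records)
  fam <- sim$truth$assignments
  ids <- fam$db_id[fam$family_id == "F001"]
  members <- db$records[match(ids, db$records$protein_id), ]
  ms <- progressive_align(members, test_model())
  expect_false(any(grepl("-", ms$aligned, fixed = TRUE)))
  expect_equal(gsub("-", "", ms$aligned), members$tdi)
})

test_that("gappy-column filtering implements the 50% rule exactly", {
  ms <- toy_msta(c("DDVVK", "DD-VK", "D--VK", "DDVV-"))
  # gap fractions by column: 0, .25, .5, 0, .25
  f <- filter_gappy_columns(ms, 0.5)
  expect_equal(f$kept, c(1L, 2L, 4L, 5L))
  expect_equal(f$msta$aligned[3], "D-VK")
  # idempotent, and counts are conserved
  f2 <- filter_gappy_columns(f$msta, 0.5)
  expect_equal(f2$msta$aligned, f$msta$aligned)
  expect_equal(length(f$kept) + 1L, ms$n_cols)
  # an all-gap column is always removed
  ms2 <- toy_msta(c("A-C", "A-C", "A-C", "A-C"))
  expect_equal(filter_gappy_columns(ms2)$kept, c(1L, 3L))
  # removing everything is an error naming the gene
  ms3 <- toy_msta(c("--", "AB", "--", "--"), gene = "badgene")
  expect_error(filter_gappy_columns(ms3), "badgene")
})

test_that("projection maps 3Di letters back to their residues", {
  db <- make_db(dplyr::bind_rows(
    rec("s1", "p", "MLKR", "DDVK"),
    rec("s2", "p", "MLK", "DDV")))
  ms <- structure(list(gene_id = "g", species_id = c("s1", "s2"),
                       protein_id = c("s1|p", "s2|p"),
                       aligned = c("DD-VK", "DD-V-"), n_cols = 5L),
                  class = "msta")
  proj <- project_to_aa(ms, db)
  expect_equal(proj$aligned, c("ML-KR", "ML-K-"))
  # gap-free row equals the record's aa
  ms2 <- structure(list(gene_id = "g", species_id = "s1",
                        protein_id = "s1|p", aligned = "DDVK",
                        n_cols = 4L), class = "msta")
  expect_equal(project_to_aa(ms2, db)$aligned, "MLKR")
  # gap masks of source and projection are identical
  expect_equal(gregexpr("-", proj$aligned[1])[[1]],
               gregexpr("-", ms$aligned[1])[[1]])
  # a row that does not reproduce the database record is a hard error
  bad <- ms
  bad$aligned <- c("DDKV-", "DD-V-")
  expect_error(project_to_aa(bad, db), "does not reproduce")
})

test_that("filtered projection keeps exactly the retained residues", {
  db <- make_db(dplyr::bind_rows(
    rec("s1", "p", "MLKRW", "DDVKC"),
    rec("s2", "p", "ML", "DD")))
  full <- structure(list(gene_id = "g", species_id = c("s1", "s2"),
                         protein_id = c("s1|p", "s2|p"),
                         aligned = c("DDVKC", "DD---"), n_cols = 5L),
                    class = "msta")
  f <- filter_gappy_columns(full, 0.5)
  expect_equal(f$kept, c(1L, 2L))
  proj <- project_to_aa(f$msta, db, full = full, kept = f$kept)
  expect_equal(proj$aligned, c("ML", "ML"))
})

test_that("concatenation records partitions and pads missing species", {
  p1 <- structure(list(gene_id = "g1", species_id = c("s1", "s2"),
                       protein_id = c("a", "b"),
                       aligned = c(strrep("M", 10), strrep("K", 10)),
                       n_cols = 10L), class = c("projected_msa", "msta"))
  p2 <- structure(list(gene_id = "g2", species_id = c("s1", "s3"),
                       protein_id = c("c", "d"),
                       aligned = c(strrep("A", 15), strrep("C", 15)),
                       n_cols = 15L), class = c("projected_msa", "msta"))
  sm <- concatenate(list(p1, p2), c("s1", "s2", "s3"))
  expect_equal(nchar(sm$rows[["s1"]]), 25)
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 25L))
  expect_equal(substr(sm$rows[["s2"]], 11, 25), strrep("-", 15))
  # a single gene concatenates to itself
  sm1 <- concatenate(list(p1), c("s1", "s2"))
  expect_equal(unname(sm1$rows), p1$aligned)
  # duplicate species in one gene is an error
  p_bad <- p1; p_bad$species_id <- c("s1", "s1")
  expect_error(concatenate(list(p_bad), c("s1", "s2")), "twice")
  # partition file format
  d <- withr::local_tempdir()
  write_partitions(sm, file.path(d, "parts.txt"))
  expect_equal(readLines(file.path(d, "parts.txt")),
               c("JTT+F+I+G, g1 = 1-10", "JTT+F+I+G, g2 = 11-25"))
})
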