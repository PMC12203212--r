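# Per-cluster single-copy coverage, core-gene selection, proteome
# representation warnings, and diagnostics mapping externally defined gene
# sets onto clusters.

#' Profile clusters: per-species copy counts and coverages
#'
#' `single_copy_coverage` is the fraction of all species in the database
#' (including species absent from the cluster) that have exactly one member
#' in the cluster; `any_copy_coverage` counts species with at least one.
#'
#' @param clusters tibble (rep_id, member_id) partitioning `db`
#' @param db a `paired_db`
#' @return tibble (cluster_id, n_members, single_copy_coverage,
#'   any_copy_coverage, copy_count) where `copy_count` is a list column of
#'   named per-species integer vectors over all species
#' @export
profile_clusters <- function(clusters, db) {
  all_species <- db$species_ids
  n_sp <- length(all_species)
  sp_of <- setNames(db$records$species_id, db$records$protein_id)
  tb <- clusters
  tb$species_id <- unname(sp_of[tb$member_id])
  if (anyNA(tb$species_id)) {
    stop("cluster member not present in database", call. = FALSE)
  }
  counts <- dplyr::count(tb, .data$rep_id, .data$species_id, name = "copies")
  profs <- counts |>
    dplyr::group_by(.data$rep_id) |>
    dplyr::summarise(
      n_members = sum(.data$copies),
      single_copy_coverage = sum(.data$copies == 1L) / n_sp,
      any_copy_coverage = dplyr::n() / n_sp,
      copy_count = list({
        cc <- setNames(rep(0L, n_sp), all_species)
        cc[.data$species_id] <- .data$copies
        cc
      }),
      .groups = "drop") |>
    dplyr::rename(cluster_id = "rep_id")
  profs[order(-profs$single_copy_coverage, profs$cluster_id), ]
}

#' Select structural core genes
#'
#' Clusters whose single-copy coverage is at least `threshold` (inclusive
#' comparison: a cluster single-copy in exactly 90% of species is selected
#' at `threshold = 0.9`). Ordered by descending coverage, then cluster id.
#'
#' @param profiles tibble from [profile_clusters()]
#' @param threshold coverage threshold in (0, 1]; default 0.8
#' @return object of class `core_gene_set`: list with `threshold`, `core`
#'   (the selected rows of `profiles`), and `core_cluster_ids`
#' @export
select_core <- function(profiles, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  core <- profiles[profiles$single_copy_coverage >= threshold, ]
  core <- core[order(-core$single_copy_coverage, core$cluster_id), ]
  structure(list(threshold = threshold, core = core,
                 core_cluster_ids = core$cluster_id),
            class = "core_gene_set")
}

#' @export
print.core_gene_set <- function(x, ...) {
  cat(sprintf("<core_gene_set> %d core genes at threshold %.2f\n",
              nrow(x$core), x$threshold))
  invisible(x)
}

#' Warn on proteomes under-representing the core genes
#'
#' A species is flagged when it is present as a single copy in fewer than a
#' strict majority of the core genes (reduced or unconventionally structured
#' proteomes distort the core set and downstream phylogeny).
#'
#' @param core_set a [select_core()] result
#' @param species_ids all species in the database; defaults to the species
#'   named in the profiles' copy counts
#' @return tibble (species_id, n_core_present, n_core_total), one row per
#'   flagged species; also emitted as warnings
#' @export
species_representation_warnings <- function(core_set, species_ids = NULL) {
  core <- core_set$core
  empty <- tibble::tibble(species_id = character(0),
                          n_core_present = integer(0),
                          n_core_total = integer(0))
  if (nrow(core) == 0) {
    warning("empty core gene set; no representation check possible",
            call. = FALSE)
    return(empty)
  }
  if (is.null(species_ids)) species_ids <- names(core$copy_count[[1]])
  n_core <- nrow(core)
  majority <- ceiling((n_core + 1) / 2) # strict majority
  present <- vapply(species_ids, function(sp) {
    sum(vapply(core$copy_count, function(cc) cc[[sp]] == 1L, TRUE))
  }, 1L)
  flag <- present < majority
  out <- tibble::tibble(species_id = species_ids[flag],
                        n_core_present = unname(present[flag]),
                        n_core_total = n_core)
  for (i in seq_len(nrow(out))) {
    warning(sprintf(
      "proteome '%s' is single-copy in only %d of %d core genes",
      out$species_id[i], out$n_core_present[i], n_core), call. = FALSE)
  }
  out
}

#' Map an external gene (member set) onto a cluster
#'
#' Returns the cluster holding at least 80% of the gene's members (the
#' cluster maximizing the shared fraction; ties by larger intersection, then
#' cluster id), or NA if no cluster reaches `min_share`.
#'
#' @param gene_members character vector of protein ids (nonempty)
#' @param clusters tibble (rep_id, member_id)
#' @param min_share minimum shared fraction (default 0.8)
#' @return cluster id (rep_id) or NA_character_
#' @export
map_gene_to_cluster <- function(gene_members, clusters, min_share = 0.8) {
  if (length(gene_members) == 0) {
    stop("empty gene member set", call. = FALSE)
  }
  hits <- clusters[clusters$member_id %in% gene_members, ]
  if (nrow(hits) == 0) return(NA_character_)
  ov <- dplyr::count(hits, .data$rep_id, name = "n_shared")
  ov$frac <- ov$n_shared / length(gene_members)
  ov <- ov[order(-ov$frac, -ov$n_shared, ov$rep_id), ]
  if (ov$frac[1L] >= min_share) ov$rep_id[1L] else NA_character_
}

#' Fragmentation diagnostic for an unmapped gene
#'
#' For a gene that no single cluster captures, takes the two clusters
#' sharing the most members with it and aligns their representatives: the
#' gene is called fragmented when the alignment has E-value below 1e-3 but
#' coverage below 0.8 on either side (homologs split across clusters by the
#' strict coverage threshold).
#'
#' @param gene_members character vector of protein ids
#' @param clusters tibble (rep_id, member_id)
#' @param db a `paired_db`
#' @param model a [subst_model()]
#' @return TRUE if fragmented
#' @export
detect_fragmentation <- function(gene_members, clusters, db, model) {
  hits <- clusters[clusters$member_id %in% gene_members, ]
  ov <- dplyr::count(hits, .data$rep_id, name = "n_shared")
  ov <- ov[order(-ov$n_shared, ov$rep_id), ]
  if (nrow(ov) < 2L) return(FALSE)
  a <- db_record(db, ov$rep_id[1L])
  b <- db_record(db, ov$rep_id[2L])
  hit <- pair_align(a, b, model, n_db = db_residues(db))
  hit$evalue < 1e-3 && min(hit$qcov, hit$tcov) < 0.8
}

#' Write cluster profiles as TSV (one column per species)
#' @param profiles tibble from [profile_clusters()]
#' @param path output TSV
#' @export
write_profiles <- function(profiles, path) {
  species <- names(profiles$copy_count[[1]])
  wide <- do.call(rbind, profiles$copy_count)
  out <- cbind(
    profiles[, c("cluster_id", "n_members", "single_copy_coverage",
                 "any_copy_coverage")],
    as.data.frame(wide))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
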