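# Stage entry points and the easy_core orchestrator. Each stage is a thin,
# file-producing wrapper over the module functions; easy_core chains them
# (createdb -> cluster -> profile -> align -> tree) and records a manifest
# sufficient to replay the run.

find_tdi_file <- function(aa_path, tdi_dir) {
  sp <- sub("\\.(fa|fasta|faa)(\\.gz)?$", "", basename(aa_path),
            ignore.case = TRUE)
  cands <- file.path(tdi_dir, paste0(sp, c(".3di.fasta", ".3di.fa",
                                           ".3di.fasta.gz")))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0) NULL else hit[1L]
}

#' Pipeline stages
#'
#' `stage_createdb()` reads per-species FASTA pairs (3Di files matched as
#' `<species>.3di.fasta` in `tdi_dir`), resolves missing 3Di strings through
#' the lookup table and/or converter, drops irrecoverable records with a
#' warning, and writes the paired database. The other stages consume and
#' produce the corresponding artifacts (cluster TSV, profiles and core-gene
#' tables, per-gene alignments plus supermatrix, newick trees).
#'
#' @param aa_fastas character vector of per-species amino-acid FASTA paths
#' @param tdi_dir directory holding matching 3Di FASTA files
#' @param lookup optional lookup table ([read_lookup_table()]) or its path
#' @param converter optional AA -> 3Di function (see [resolve_3di()])
#' @param max_len maximum sequence length retained (default 4000)
#' @param out database directory to write (NULL to skip writing)
#' @return `stage_createdb`: a `paired_db`
#' @export
stage_createdb <- function(aa_fastas, tdi_dir = NULL, lookup = NULL,
                           converter = NULL, max_len = 4000L, out = NULL) {
  if (is.character(lookup) && length(lookup) == 1L && file.exists(lookup)) {
    lookup <- read_lookup_table(lookup)
  }
  per_species <- lapply(aa_fastas, function(p) {
    tdi_path <- if (!is.null(tdi_dir)) find_tdi_file(p, tdi_dir) else NULL
    pr <- read_proteome(p, tdi_path)
    if (nrow(pr$unresolved) > 0) {
      res <- resolve_3di(pr$unresolved, lookup, converter)
      if (nrow(res$still_unresolved) > 0) {
        warning(nrow(res$still_unresolved), " protein(s) of '",
                pr$unresolved$species_id[1L],
                "' lack a 3Di source and were dropped", call. = FALSE)
      }
      pr$records <- dplyr::bind_rows(pr$records, res$resolved)
    }
    pr$records
  })
  db <- build_database(per_species, max_len = max_len)
  if (!is.null(out)) write_database(db, out)
  db
}

#' @param db a `paired_db`
#' @param params a [cluster_params()]
#' @param model a [subst_model()] (default model when NULL)
#' @param seed prefilter hash seed
#' @return `stage_cluster`: tibble (rep_id, member_id)
#' @rdname stage_createdb
#' @export
stage_cluster <- function(db, params = cluster_params(), model = NULL,
                          seed = 42L, out = NULL) {
  clusters <- cascade_cluster(db, params, model, seed = seed)
  if (!is.null(out)) write_clusters(clusters, out)
  clusters
}

#' @param clusters tibble (rep_id, member_id)
#' @param threshold single-copy coverage threshold (default 0.8)
#' @param outdir directory for profiles.tsv / core_genes.tsv / warnings.tsv
#' @return `stage_profile`: list(profiles, core_set, warnings)
#' @rdname stage_createdb
#' @export
stage_profile <- function(db, clusters, threshold = 0.8, outdir = NULL) {
  profiles <- profile_clusters(clusters, db)
  core_set <- select_core(profiles, threshold)
  warnings_tb <- withCallingHandlers(
    species_representation_warnings(core_set, db$species_ids),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_profiles(profiles, file.path(outdir, "profiles.tsv"))
    core_tb <- core_set$core[, c("cluster_id", "n_members",
                                 "single_copy_coverage",
                                 "any_copy_coverage")]
    core_tb$single_copy_coverage <-
      sprintf("%.6f", core_tb$single_copy_coverage)
    core_tb$any_copy_coverage <- sprintf("%.6f", core_tb$any_copy_coverage)
    write.table(core_tb, file.path(outdir, "core_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(warnings_tb, file.path(outdir, "warnings.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(profiles = profiles, core_set = core_set, warnings = warnings_tb)
}

#' @param core_set a [select_core()] result
#' @param gap_frac gappy-column removal threshold (default 0.5)
#' @return `stage_align`: list(mstas, projected, supermatrix)
#' @rdname stage_createdb
#' @export
stage_align <- function(db, clusters, core_set, model = NULL,
                        gap_frac = 0.5, outdir = NULL) {
  if (is.null(model)) model <- subst_model()
  sp_of <- setNames(db$records$species_id, db$records$protein_id)
  mstas <- list(); projected <- list()
  for (cid in core_set$core_cluster_ids) {
    members_all <- clusters$member_id[clusters$rep_id == cid]
    sp <- sp_of[members_all]
    single <- members_all[sp %in% names(which(table(sp) == 1L))]
    recs <- db$records[match(single, db$records$protein_id), ]
    msta <- progressive_align(recs, model, gene_id = cid)
    filt <- filter_gappy_columns(msta, gap_frac)
    proj <- project_to_aa(filt$msta, db, full = msta, kept = filt$kept)
    mstas[[cid]] <- msta
    projected[[cid]] <- proj
  }
  sm <- concatenate(projected, db$species_ids)
  if (!is.null(outdir)) {
    gdir <- file.path(outdir, "genes")
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (cid in names(mstas)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", cid)
      write_alignment(mstas[[cid]],
                      file.path(gdir, paste0(safe, ".3di.fasta")))
      write_alignment(projected[[cid]],
                      file.path(gdir, paste0(safe, ".aa.fasta")))
    }
    write_alignment(sm, file.path(outdir, "supermatrix.fasta"))
    write_partitions(sm, file.path(outdir, "partitions.txt"))
  }
  list(mstas = mstas, projected = projected, supermatrix = sm)
}

#' @param aln result of `stage_align()`
#' @param n_boot bootstrap replicates for the species tree (default 100)
#' @param tree_options verbatim options string for an external builder; NULL
#'   uses the built-in NJ + bootstrap
#' @param tree_binary external builder program name
#' @return `stage_tree`: list(species_tree, species_tree_rooted, gene_trees)
#' @rdname stage_createdb
#' @export
stage_tree <- function(aln, n_boot = 100L, seed = 42L, outdir = NULL,
                       tree_options = NULL, tree_binary = NULL) {
  sm <- aln$supermatrix
  # drop species with no data (all-gap rows would have no overlap)
  informative <- vapply(sm$rows, function(r) any(chars(r) != "-"), TRUE)
  rows <- sm$rows[informative]
  if (!is.null(tree_binary)) {
    tmp_msa <- tempfile(fileext = ".fasta")
    write_alignment(sm, tmp_msa)
    tree <- run_external_tree(tmp_msa, tempfile(fileext = ".nwk"),
                              tree_binary, tree_options %||% "")
  } else {
    tree <- bootstrap_support(rows, n_reps = n_boot, seed = seed)
  }
  rooted <- mad_root(tree)
  gene_trees <- list()
  for (cid in names(aln$projected)) {
    p <- aln$projected[[cid]]
    if (length(p$aligned) < 3L) next
    gt <- tryCatch(nj_tree(pairwise_distance(p)), error = function(e) NULL)
    if (!is.null(gt)) gene_trees[[cid]] <- gt
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(outdir, "species_tree.nwk"))
    write_newick(rooted, file.path(outdir, "species_tree.rooted.nwk"))
    gdir <- file.path(outdir, "gene_trees")
    dir.create(gdir, showWarnings = FALSE)
    for (cid in names(gene_trees)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", cid)
      write_newick(gene_trees[[cid]], file.path(gdir, paste0(safe, ".nwk")))
      write_newick(mad_root(gene_trees[[cid]]),
                   file.path(gdir, paste0(safe, ".rooted.nwk")))
    }
  }
  list(species_tree = tree, species_tree_rooted = rooted,
       gene_trees = gene_trees)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full core-gene pipeline
#'
#' Orchestrates createdb, cluster, profile, align and tree in order, writing
#' every stage artifact plus a `manifest.yaml` (parameters, seed, inputs,
#' artifact paths) under `out`. A stage failure stops the run with the stage
#' name; artifacts of completed stages are retained next to a
#' `FAILED.<stage>` marker file.
#'
#' @inheritParams stage_createdb
#' @param out output directory
#' @param threshold single-copy coverage threshold for core genes
#'   (default 0.8)
#' @param gap_frac gappy-column threshold (default 0.5)
#' @param params a [cluster_params()]
#' @param n_boot bootstrap replicates (default 100)
#' @param seed global seed threaded through every stochastic component
#' @param tree_options,tree_binary optional external-builder delegation (see
#'   [run_external_tree()])
#' @return list(db, clusters, profile, align, tree, out)
#' @export
easy_core <- function(aa_fastas, tdi_dir = NULL, out, lookup = NULL,
                      converter = NULL, threshold = 0.8, gap_frac = 0.5,
                      params = cluster_params(), max_len = 4000L,
                      n_boot = 100L, seed = 42L,
                      tree_options = NULL, tree_binary = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "createdb"
  res <- list(out = out)
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      file.create(file.path(out, paste0("FAILED.", name)))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res$db <- run_stage("createdb", stage_createdb(
    aa_fastas, tdi_dir, lookup, converter, max_len,
    out = file.path(out, "db")))
  res$clusters <- run_stage("cluster", stage_cluster(
    res$db, params, seed = seed, out = file.path(out, "clusters.tsv")))
  res$profile <- run_stage("profile", stage_profile(
    res$db, res$clusters, threshold, outdir = out))
  res$align <- run_stage("align", stage_align(
    res$db, res$clusters, res$profile$core_set, gap_frac = gap_frac,
    outdir = file.path(out, "aln")))
  res$tree <- run_stage("tree", stage_tree(
    res$align, n_boot = n_boot, seed = seed,
    outdir = file.path(out, "tree"),
    tree_options = tree_options, tree_binary = tree_binary))
  manifest <- list(
    tool = "structcore",
    version = as.character(utils::packageVersion("structcore")),
    seed = seed,
    parameters = list(
      threshold = threshold, gap_frac = gap_frac, max_len = max_len,
      n_boot = n_boot,
      cluster = params[c("min_cov", "max_evalue", "kmer_len",
                         "kmers_per_seq", "cascade_rounds", "reassign")],
      max_seqs = params$max_seqs %||% "AUTO",
      tree_options = tree_options %||% "built-in NJ"),
    inputs = list(aa_fastas = as.character(aa_fastas),
                  tdi_dir = tdi_dir %||% "", lookup = "none"),
    artifacts = list(db = "db", clusters = "clusters.tsv",
                     profiles = "profiles.tsv",
                     core_genes = "core_genes.tsv",
                     supermatrix = "aln/supermatrix.fasta",
                     partitions = "aln/partitions.txt",
                     species_tree = "tree/species_tree.nwk",
                     species_tree_rooted = "tree/species_tree.rooted.nwk"))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  res
}

#' Replay a pipeline run from its manifest
#'
#' Re-runs [easy_core()] with the parameters, inputs and seed recorded in a
#' `manifest.yaml`, writing to a new output directory.
#' @param manifest_path path to a manifest.yaml
#' @param out new output directory
#' @return see [easy_core()]
#' @export
replay_run <- function(manifest_path, out) {
  m <- yaml::read_yaml(manifest_path)
  p <- m$parameters
  cl <- p$cluster
  easy_core(m$inputs$aa_fastas,
            tdi_dir = if (nzchar(m$inputs$tdi_dir)) m$inputs$tdi_dir,
            out = out,
            threshold = p$threshold, gap_frac = p$gap_frac,
            params = cluster_params(
              min_cov = cl$min_cov, max_evalue = cl$max_evalue,
              kmer_len = cl$kmer_len, kmers_per_seq = cl$kmers_per_seq,
              cascade_rounds = cl$cascade_rounds, reassign = cl$reassign,
              max_seqs = if (!identical(p$max_seqs, "AUTO")) p$max_seqs),
            max_len = p$max_len, n_boot = p$n_boot, seed = m$seed)
}
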