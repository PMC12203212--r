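# Quasilinear structural clustering: minimizer k-mer prefilter over the 3Di
# strings, greedy longest-first centroid assignment on combined 3Di+AA local
# alignments, cascaded rounds over representatives, and member reassignment.
# A brute-force all-vs-all clusterer serves as the test oracle.

#' Clustering parameters
#'
#' @param min_cov minimum alignment coverage, applied to both query and
#'   target (default 0.8)
#' @param max_evalue maximum E-value for a member to join a cluster
#'   (default 1e-3)
#' @param kmer_len 3Di k-mer length for the prefilter (default 6)
#' @param kmers_per_seq minimizers selected per sequence (default 21)
#' @param cascade_rounds clustering rounds; rounds after the first cluster
#'   the previous round's representatives (default 2)
#' @param reassign re-attach every member to its best-scoring representative
#'   after cascading (default TRUE)
#' @param max_seqs cap on prefilter candidates per sequence; NULL resolves
#'   via [default_max_seqs()] at run time
#' @return object of class `cluster_params`
#' @export
cluster_params <- function(min_cov = 0.8, max_evalue = 1e-3,
                           kmer_len = 6L, kmers_per_seq = 21L,
                           cascade_rounds = 2L, reassign = TRUE,
                           max_seqs = NULL) {
  stopifnot(min_cov > 0, min_cov <= 1, max_evalue > 0,
            kmer_len >= 1, kmers_per_seq >= 1, cascade_rounds >= 1)
  structure(list(min_cov = min_cov, max_evalue = max_evalue,
                 kmer_len = as.integer(kmer_len),
                 kmers_per_seq = as.integer(kmers_per_seq),
                 cascade_rounds = as.integer(cascade_rounds),
                 reassign = isTRUE(reassign), max_seqs = max_seqs),
            class = "cluster_params")
}

#' Default candidate cap from the number of species
#'
#' The larger of 1,000 or 20 times the number of species.
#' @param n_species number of species (>= 1)
#' @return integer
#' @export
default_max_seqs <- function(n_species) {
  stopifnot(n_species >= 1)
  as.integer(max(1000L, 20L * as.integer(n_species)))
}

#' Select minimizer k-mers from a 3Di string
#'
#' Deterministic (seed-mixed hash) selection of the `kmers_per_seq` k-mers
#' with the smallest hash values; sequences shorter than `kmer_len` yield an
#' empty set. Ties break by position.
#'
#' @param tdi 3Di string
#' @param kmer_len k-mer length
#' @param kmers_per_seq number of k-mers to keep
#' @param seed integer mixed into the hash
#' @return tibble (kmer, pos)
#' @export
select_kmers <- function(tdi, kmer_len = 6L, kmers_per_seq = 21L, seed = 0L) {
  L <- nchar(tdi)
  if (L < kmer_len) {
    return(tibble::tibble(kmer = character(0), pos = integer(0)))
  }
  codes <- encode_residues(tdi)
  M <- 2147483647
  pows <- 31^(seq_len(kmer_len) - 1L)
  win <- embed(codes, kmer_len)[, kmer_len:1, drop = FALSE]
  poly <- as.vector(win %*% pows) %% M
  # seed-dependent mixing: the seed is expanded and drives both an xor and
  # the multiplier, so different seeds genuinely reorder the hash ranking
  # (an additive seed would only shift all hashes equally)
  smix <- (as.numeric(seed) * 7919 + 13) %% M
  mult <- 2971 + 2 * (as.numeric(seed) %% 997)
  h <- as.numeric(bitwXor(as.integer(poly), as.integer(smix)))
  h <- (h * mult + smix) %% M
  ord <- order(h, seq_along(h))
  keep <- sort(head(ord, kmers_per_seq))
  km <- substring(tdi, keep, keep + kmer_len - 1L)
  tibble::tibble(kmer = km, pos = keep)
}

# --- internal alignment plumbing on precomputed integer codes ---------------

encode_db_codes <- function(records) {
  list(tdi = lapply(records$tdi, encode_residues),
       aa = lapply(records$aa, encode_residues))
}

hit_fields <- function(res, qlen, tlen, model, n_db) {
  bits <- bits_from_raw(res$score, model)
  span_q <- if (res$qend >= res$qstart && res$qend > 0)
    res$qend - res$qstart + 1L else 0L
  span_t <- if (res$tend >= res$tstart && res$tend > 0)
    res$tend - res$tstart + 1L else 0L
  list(raw_score = res$score, bit_score = bits,
       evalue = evalue_from_bits(bits, qlen, n_db),
       qcov = span_q / qlen, tcov = span_t / tlen,
       seq_identity = if (res$ncols > 0) res$nident / res$ncols else 0,
       aln_cols = res$ncols)
}

align_codes <- function(codes, qi, ti, model, n_db, lens) {
  res <- .sw_align_cpp(codes$tdi[[qi]], codes$tdi[[ti]],
                       codes$aa[[qi]], codes$aa[[ti]],
                       model$wm3, model$wma,
                       model$gap_open, model$gap_extend)
  hit_fields(res, lens[qi], lens[ti], model, n_db)
}

hit_passes <- function(hit, params) {
  hit$evalue <= params$max_evalue &&
    hit$qcov >= params$min_cov && hit$tcov >= params$min_cov
}

#' Align two paired records with combined 3Di+AA scoring
#'
#' Gapped local (Smith-Waterman) alignment where each column scores
#' `w3di * S3di + waa * Saa`. The bit score is
#' `(lambda * raw - ln K) / ln 2` and the E-value `m * n_db * 2^-bits` with
#' `m` the query length and `n_db` the searched residue count.
#'
#' @param a,b records: lists or one-row tibbles with `aa`, `tdi` and
#'   optionally `protein_id`
#' @param model a [subst_model()]
#' @param n_db search-space size in residues (default: target length)
#' @return one-row tibble (query_id, target_id, raw_score, bit_score,
#'   evalue, qcov, tcov, seq_identity, aln_cols)
#' @export
pair_align <- function(a, b, model, n_db = NULL) {
  ga <- function(r, f, alt) if (!is.null(r[[f]]) && !is.na(r[[f]][1]))
    r[[f]][1] else alt
  aa_a <- toupper(ga(a, "aa", stop("record a lacks aa")))
  aa_b <- toupper(ga(b, "aa", stop("record b lacks aa")))
  tdi_a <- toupper(ga(a, "tdi", stop("record a lacks tdi")))
  tdi_b <- toupper(ga(b, "tdi", stop("record b lacks tdi")))
  if (is.null(n_db)) n_db <- nchar(aa_b)
  codes <- list(tdi = list(encode_residues(tdi_a), encode_residues(tdi_b)),
                aa = list(encode_residues(aa_a), encode_residues(aa_b)))
  hit <- align_codes(codes, 1L, 2L, model, n_db,
                     c(nchar(aa_a), nchar(aa_b)))
  tibble::tibble(query_id = ga(a, "protein_id", "query"),
                 target_id = ga(b, "protein_id", "target"),
                 raw_score = hit$raw_score, bit_score = hit$bit_score,
                 evalue = hit$evalue, qcov = hit$qcov, tcov = hit$tcov,
                 seq_identity = hit$seq_identity, aln_cols = hit$aln_cols)
}

# --- prefilter adjacency ----------------------------------------------------

# tibble (i, j, shared) of index pairs sharing >= 1 selected k-mer
kmer_pairs <- function(records, params, seed) {
  n <- nrow(records)
  km <- purrr::map(records$tdi, select_kmers,
                   kmer_len = params$kmer_len,
                   kmers_per_seq = params$kmers_per_seq, seed = seed)
  tab <- dplyr::bind_rows(
    purrr::imap(km, function(k, i) {
      if (nrow(k) == 0) return(NULL)
      tibble::tibble(idx = i, kmer = unique(k$kmer))
    }))
  if (nrow(tab) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          shared = integer(0)))
  }
  joined <- dplyr::inner_join(tab, tab, by = "kmer",
                              relationship = "many-to-many")
  prs <- joined[joined$idx.x < joined$idx.y, c("idx.x", "idx.y")]
  if (nrow(prs) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          shared = integer(0)))
  }
  dplyr::count(prs, .data$idx.x, .data$idx.y, name = "shared") |>
    dplyr::rename(i = "idx.x", j = "idx.y")
}

# neighbor index lists ordered by shared k-mer count (desc) then id (asc),
# capped at max_seqs
neighbor_lists <- function(pairs, records, max_seqs) {
  n <- nrow(records)
  ids <- records$protein_id
  both <- dplyr::bind_rows(
    tibble::tibble(a = pairs$i, b = pairs$j, shared = pairs$shared),
    tibble::tibble(a = pairs$j, b = pairs$i, shared = pairs$shared))
  nb <- vector("list", n)
  if (nrow(both) > 0) {
    both <- both[order(both$a, -both$shared, ids[both$b]), ]
    sp <- split(both$b, both$a)
    nb[as.integer(names(sp))] <- lapply(sp, head, max_seqs)
  }
  nb
}

# --- greedy round -----------------------------------------------------------

#' One greedy clustering round
#'
#' Candidate pairs share at least one selected k-mer. Sequences are visited
#' longest-first (ties by id); each unassigned sequence becomes a centroid
#' and absorbs its unassigned candidates whose alignment to it passes
#' `evalue <= max_evalue` and both coverages `>= min_cov`. Unassigned
#' sequences end as singletons; the result partitions the input.
#'
#' @param records tibble of records (protein_id, species_id, aa, tdi, length)
#' @param params a [cluster_params()]
#' @param model a [subst_model()]
#' @param seed prefilter hash seed
#' @param n_db E-value search space (default: total residues in `records`)
#' @return tibble (rep_id, member_id)
#' @export
greedy_cluster_round <- function(records, params, model, seed = 42L,
                                 n_db = NULL) {
  n <- nrow(records)
  ids <- records$protein_id
  lens <- nchar(records$aa)
  if (is.null(n_db)) n_db <- sum(lens)
  if (is.null(params$max_seqs)) {
    params$max_seqs <- default_max_seqs(length(unique(records$species_id)))
  }
  codes <- encode_db_codes(records)
  nb <- neighbor_lists(kmer_pairs(records, params, seed), records,
                       params$max_seqs)
  assigned <- integer(n) # 0 = unassigned, else rep index
  for (r in order(-lens, ids)) {
    if (assigned[r] != 0L) next
    assigned[r] <- r
    cand <- nb[[r]]
    cand <- cand[assigned[cand] == 0L]
    for (ci in cand) {
      hit <- align_codes(codes, ci, r, model, n_db, lens)
      if (hit_passes(hit, params)) assigned[ci] <- r
    }
  }
  tibble::tibble(rep_id = ids[assigned], member_id = ids)
}

#' Cascaded clustering with optional member reassignment
#'
#' Round 1 clusters all records; each later round clusters the previous
#' round's representatives with the same thresholds, merging member sets of
#' clusters whose representatives co-cluster. With `params$reassign`, every
#' non-representative member is then re-attached to the best-scoring passing
#' representative ([reassign_members()]). The result always partitions the
#' database.
#'
#' @param db a `paired_db`
#' @inheritParams greedy_cluster_round
#' @return tibble (rep_id, member_id)
#' @export
cascade_cluster <- function(db, params = cluster_params(), model = NULL,
                            seed = 42L) {
  if (is.null(model)) model <- subst_model()
  if (is.null(params$max_seqs)) {
    params$max_seqs <- default_max_seqs(length(db$species_ids))
  }
  clusters <- greedy_cluster_round(db$records, params, model, seed = seed)
  r <- 1L
  while (r < params$cascade_rounds) {
    r <- r + 1L
    reps <- unique(clusters$rep_id)
    sub <- db$records[match(reps, db$records$protein_id), ]
    rep_clusters <- greedy_cluster_round(sub, params, model,
                                         seed = seed + r - 1L)
    # merge: members of a rep follow the rep's new representative
    map <- setNames(rep_clusters$rep_id, rep_clusters$member_id)
    clusters$rep_id <- unname(map[clusters$rep_id])
  }
  if (params$reassign) {
    clusters <- reassign_members(clusters, db, params, model)
  }
  clusters[order(clusters$rep_id, clusters$member_id), ]
}

#' Re-attach members to their best representative
#'
#' Every non-representative member is re-aligned against all current
#' representatives and moves to the one with the best bit score among those
#' passing the E-value and coverage thresholds; if none pass it becomes a
#' singleton. Representatives stay put, so the output is still a partition.
#'
#' @param clusters tibble (rep_id, member_id) partitioning `db`
#' @param db a `paired_db`
#' @param params a [cluster_params()]
#' @param model a [subst_model()]
#' @return tibble (rep_id, member_id)
#' @export
reassign_members <- function(clusters, db, params, model) {
  records <- db$records
  ids <- records$protein_id
  lens <- records$length
  n_db <- sum(lens)
  codes <- encode_db_codes(records)
  reps <- sort(unique(clusters$rep_id))
  ri <- match(reps, ids)
  rep_t3 <- codes$tdi[ri]; rep_ta <- codes$aa[ri]
  new_rep <- setNames(clusters$rep_id, clusters$member_id)
  members <- clusters$member_id[!(clusters$member_id %in% reps)]
  for (mid in members) {
    mi <- match(mid, ids)
    raw <- .sw_score_batch_cpp(codes$tdi[[mi]], codes$aa[[mi]],
                               rep_t3, rep_ta, model$wm3, model$wma,
                               model$gap_open, model$gap_extend)
    bits <- bits_from_raw(raw, model)
    ev <- evalue_from_bits(bits, lens[mi], n_db)
    ord <- order(-bits, reps)
    chosen <- NA_character_
    for (k in ord) {
      if (ev[k] > params$max_evalue) break
      hit <- align_codes(codes, mi, ri[k], model, n_db, lens)
      if (hit_passes(hit, params)) { chosen <- reps[k]; break }
    }
    new_rep[[mid]] <- if (is.na(chosen)) mid else chosen
  }
  out <- tibble::tibble(rep_id = unname(new_rep[ids]), member_id = ids)
  out[order(out$rep_id, out$member_id), ]
}

#' Brute-force all-vs-all clustering (oracle)
#'
#' Aligns every pair, then greedily set-covers: repeatedly pick the
#' unclustered sequence with the most passing unclustered neighbors (ties by
#' id) as representative and absorb those neighbors. Intended as an
#' independent oracle for [cascade_cluster()] on small databases.
#'
#' @inheritParams cascade_cluster
#' @return tibble (rep_id, member_id)
#' @export
brute_force_cluster <- function(db, params = cluster_params(), model = NULL) {
  if (is.null(model)) model <- subst_model()
  records <- db$records
  n <- nrow(records)
  ids <- records$protein_id
  lens <- records$length
  n_db <- sum(lens)
  codes <- encode_db_codes(records)
  adj <- vector("list", n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        qi <- if (ids[i] <= ids[j]) i else j
        ti <- if (ids[i] <= ids[j]) j else i
        hit <- align_codes(codes, qi, ti, model, n_db, lens)
        if (hit_passes(hit, params)) {
          adj[[i]] <- c(adj[[i]], j)
          adj[[j]] <- c(adj[[j]], i)
        }
      }
    }
  }
  unclustered <- rep(TRUE, n)
  rep_of <- character(n)
  while (any(unclustered)) {
    cnt <- vapply(seq_len(n), function(i) {
      if (!unclustered[i]) return(-1L)
      length(adj[[i]][unclustered[adj[[i]]]])
    }, 1L)
    cand <- which(cnt == max(cnt))
    r <- cand[order(ids[cand])][1L]
    take <- c(r, adj[[r]][unclustered[adj[[r]]]])
    rep_of[take] <- ids[r]
    unclustered[take] <- FALSE
  }
  out <- tibble::tibble(rep_id = rep_of, member_id = ids)
  out[order(out$rep_id, out$member_id), ]
}

#' Write / read a cluster table (rep_id TAB member_id)
#' @param clusters tibble (rep_id, member_id)
#' @param path TSV path
#' @export
write_clusters <- function(clusters, path) {
  write.table(clusters[, c("rep_id", "member_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("rep_id", "member_id"),
                   colClasses = "character", quote = "")
  tibble::as_tibble(tb)
}
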