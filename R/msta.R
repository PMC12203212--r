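# Progressive multiple structural alignment in 3Di space, gappy-column
# filtering, back-projection to amino acids, and supermatrix concatenation.

new_msta <- function(gene_id, species_id, protein_id, aligned) {
  nc <- unique(nchar(aligned))
  stopifnot(length(nc) == 1L)
  structure(list(gene_id = gene_id, species_id = species_id,
                 protein_id = protein_id, aligned = aligned,
                 n_cols = nc),
            class = "msta")
}

#' @export
print.msta <- function(x, ...) {
  cat(sprintf("<msta> gene '%s': %d rows x %d columns\n",
              x$gene_id, length(x$aligned), x$n_cols))
  invisible(x)
}

#' Guide tree for progressive alignment
#'
#' Neighbor joining on pairwise distances `1 - bits(a,b) / min(bits(a,a),
#' bits(b,b))` from combined 3Di+AA local alignments, rooted deterministically
#' at the lexicographically first member. Returns a rooted binary `phylo`
#' whose topology fixes the profile merge order.
#'
#' @param members tibble of records (protein_id, aa, tdi)
#' @param model a [subst_model()]
#' @return rooted `phylo` with tip labels = protein ids
#' @export
guide_tree <- function(members, model) {
  n <- nrow(members)
  stopifnot(n >= 2L)
  ids <- members$protein_id
  if (n == 2L) return(two_tip_tree(sort(ids)))
  codes <- encode_db_codes(members)
  lens <- nchar(members$aa)
  self_bits <- vapply(seq_len(n), function(i) {
    hit <- align_codes(codes, i, i, model, 1, lens)
    hit$bit_score
  }, 1.0)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      hit <- align_codes(codes, i, j, model, 1, lens)
      d <- 1 - hit$bit_score / min(self_bits[i], self_bits[j])
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  ord <- order(ids)
  tr <- ape::nj(D[ord, ord])
  tr$edge.length <- pmax(tr$edge.length, 0)
  rooted <- ape::root(tr, outgroup = sort(ids)[1L], resolve.root = TRUE)
  ape::multi2di(rooted)
}

two_tip_tree <- function(ids) {
  structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 tip.label = ids, edge.length = c(0.5, 0.5), Nnode = 1L),
            class = "phylo")
}

# profile column counts (21 x n_cols); gaps contribute nothing
profile_counts <- function(rows_chars) {
  nc <- ncol(rows_chars)
  m <- matrix(0, 21L, nc)
  for (r in seq_len(nrow(rows_chars))) {
    v <- rows_chars[r, ]
    ok <- which(v != "-")
    if (length(ok) == 0L) next
    code <- .code_lut[utf8ToInt(paste(v[ok], collapse = "")) + 1L]
    code[is.na(code)] <- X_CODE
    for (z in seq_along(ok)) {
      m[code[z] + 1L, ok[z]] <- m[code[z] + 1L, ok[z]] + 1
    }
  }
  m
}

# merge two gapped blocks (lists of tdi/aa char matrices) by profile DP
merge_profiles <- function(A, B, model) {
  FA3 <- profile_counts(A$tdi); FB3 <- profile_counts(B$tdi)
  FAa <- profile_counts(A$aa); FBa <- profile_counts(B$aa)
  nA <- nrow(A$tdi); nB <- nrow(B$tdi)
  S <- (t(FA3) %*% model$wm3 %*% FB3 + t(FAa) %*% model$wma %*% FBa) /
    (nA * nB)
  path <- .nw_path_cpp(S, model$gap_open, model$gap_extend)
  la <- ncol(A$tdi); lb <- ncol(B$tdi)
  ai <- integer(length(path)); bi <- integer(length(path))
  ia <- 0L; ib <- 0L
  for (k in seq_along(path)) {
    if (path[k] != 3L) ia <- ia + 1L
    if (path[k] != 2L) ib <- ib + 1L
    ai[k] <- if (path[k] != 3L) ia else 0L
    bi[k] <- if (path[k] != 2L) ib else 0L
  }
  expand <- function(mat, idx) {
    out <- matrix("-", nrow(mat), length(idx))
    keep <- idx > 0L
    out[, keep] <- mat[, idx[keep], drop = FALSE]
    out
  }
  list(tdi = rbind(expand(A$tdi, ai), expand(B$tdi, bi)),
       aa = rbind(expand(A$aa, ai), expand(B$aa, bi)),
       ids = c(A$ids, B$ids))
}

#' Progressive multiple structural alignment of one gene cluster
#'
#' Profiles are merged along the guide tree; columns are scored by the mean
#' pairwise combined 3Di+AA score between the two profiles, with affine gaps
#' and high-road tie breaking. Removing gaps from any output row reproduces
#' that member's 3Di string exactly.
#'
#' @param members tibble of records (species_id, protein_id, aa, tdi)
#' @param model a [subst_model()]; default [subst_model()]
#' @param join_order optional rooted `phylo` from [guide_tree()]
#' @param gene_id label for the alignment (default: the representative /
#'   first member id)
#' @return an `msta`
#' @export
progressive_align <- function(members, model = NULL, join_order = NULL,
                              gene_id = NULL) {
  if (is.null(model)) model <- subst_model()
  if (is.null(gene_id)) gene_id <- members$protein_id[1L]
  if (any(nchar(members$aa) == 0L)) stop("empty member sequence")
  n <- nrow(members)
  block_of <- function(i) {
    list(tdi = matrix(chars(members$tdi[i]), 1L),
         aa = matrix(chars(members$aa[i]), 1L),
         ids = members$protein_id[i])
  }
  if (n == 1L) {
    merged <- block_of(1L)
  } else {
    if (is.null(join_order)) join_order <- guide_tree(members, model)
    tr <- ape::reorder.phylo(join_order, "postorder")
    blocks <- list()
    tip_block <- function(label) block_of(match(label, members$protein_id))
    get_block <- function(node) {
      if (node <= length(tr$tip.label)) tip_block(tr$tip.label[node])
      else blocks[[as.character(node)]]
    }
    # merge children at each internal node, bottom-up (postorder edge order
    # lists every child subtree before its parent)
    kids <- split(tr$edge[, 2L], tr$edge[, 1L])
    for (node in unique(tr$edge[, 1L])) {
      ch <- kids[[as.character(node)]]
      acc <- get_block(ch[1L])
      for (c2 in ch[-1L]) acc <- merge_profiles(acc, get_block(c2), model)
      blocks[[as.character(node)]] <- acc
    }
    merged <- blocks[[as.character(length(tr$tip.label) + 1L)]]
  }
  idx <- match(members$protein_id, merged$ids)
  aligned <- apply(merged$tdi, 1L, paste, collapse = "")[idx]
  new_msta(gene_id, members$species_id, members$protein_id, aligned)
}

# internal-node visit order (children before parents) for a postorder tree
reorder_postorder_nodes <- function(tr) {
  seq_len(nrow(tr$edge))
}

#' Remove gappy columns
#'
#' Drops every column whose gap fraction is `max_gap_frac` or higher
#' (default 0.5, i.e. a column with gaps in half the rows is removed).
#' Column order is preserved; the returned index map gives the original
#' position of each kept column.
#'
#' @param msta an `msta` (or `projected_msa`)
#' @param max_gap_frac removal threshold on the gap fraction (default 0.5)
#' @return list(msta, kept) where `kept` is an integer vector of original
#'   column positions
#' @export
filter_gappy_columns <- function(msta, max_gap_frac = 0.5) {
  m <- do.call(rbind, lapply(msta$aligned, chars))
  gap_frac <- colMeans(m == "-")
  kept <- which(gap_frac < max_gap_frac)
  if (length(kept) == 0L) {
    stop("all columns of gene '", msta$gene_id, "' are gappy", call. = FALSE)
  }
  out <- msta
  out$aligned <- apply(m[, kept, drop = FALSE], 1L, paste, collapse = "")
  out$n_cols <- length(kept)
  list(msta = out, kept = kept)
}

#' Project a 3Di alignment to amino acids
#'
#' The k-th 3Di letter of each aligned row maps to the k-th amino acid of
#' the same database record; gaps stay gaps. For filtered alignments pass
#' the `kept` column map so that positions index into the original
#' (unfiltered) alignment.
#'
#' @param msta the (filtered) `msta` to project
#' @param db a `paired_db` holding the member records
#' @param full the unfiltered `msta` the filter was applied to; required
#'   together with `kept` when `msta` has had columns removed
#' @param kept integer column map from [filter_gappy_columns()]
#' @return object of class `projected_msa` (rows = aligned AA strings)
#' @export
project_to_aa <- function(msta, db, full = NULL, kept = NULL) {
  if (is.null(full) != is.null(kept)) {
    stop("supply both 'full' and 'kept', or neither", call. = FALSE)
  }
  filtered <- !is.null(kept)
  aligned_aa <- character(length(msta$aligned))
  for (i in seq_along(msta$aligned)) {
    rec <- db_record(db, msta$protein_id[i])
    full_row <- chars(if (filtered) full$aligned[i] else msta$aligned[i])
    gapless <- paste(full_row[full_row != "-"], collapse = "")
    if (!identical(gapless, rec$tdi)) {
      stop("alignment row for '", msta$protein_id[i],
           "' does not reproduce the database 3Di string", call. = FALSE)
    }
    # rank of the residue sitting at each original alignment position
    k_at <- cumsum(full_row != "-")
    pos <- if (filtered) kept else seq_along(full_row)
    sub <- full_row[pos]
    if (filtered && !identical(paste(sub, collapse = ""), msta$aligned[i])) {
      stop("'kept' map does not reproduce the filtered row for '",
           msta$protein_id[i], "'", call. = FALSE)
    }
    aa_chars <- chars(rec$aa)
    out <- rep("-", length(pos))
    resid <- sub != "-"
    out[resid] <- aa_chars[k_at[pos][resid]]
    aligned_aa[i] <- paste(out, collapse = "")
  }
  structure(list(gene_id = msta$gene_id, species_id = msta$species_id,
                 protein_id = msta$protein_id, aligned = aligned_aa,
                 n_cols = nchar(aligned_aa[1])),
            class = c("projected_msa", "msta"))
}

#' Concatenate projected alignments into a supermatrix
#'
#' Species missing from a gene receive an all-gap block of that gene's
#' width. Partitions are recorded in input gene order with 1-based inclusive
#' coordinates.
#'
#' @param projected_msas list of `projected_msa` objects (single-copy rows:
#'   at most one row per species per gene)
#' @param all_species character vector of species ids for the row set
#' @return object of class `supermatrix`: list(rows = named character
#'   vector, partitions = tibble(gene_id, start, end))
#' @export
concatenate <- function(projected_msas, all_species) {
  rows <- setNames(rep("", length(all_species)), all_species)
  parts <- tibble::tibble(gene_id = character(0), start = integer(0),
                          end = integer(0))
  pos <- 0L
  for (p in projected_msas) {
    if (anyDuplicated(p$species_id)) {
      stop("species appears twice in gene '", p$gene_id, "'", call. = FALSE)
    }
    width <- p$n_cols
    block <- setNames(rep(strrep("-", width), length(all_species)),
                      all_species)
    present <- intersect(p$species_id, all_species)
    block[present] <- p$aligned[match(present, p$species_id)]
    rows[] <- paste0(rows, block[all_species])
    parts <- dplyr::bind_rows(parts, tibble::tibble(
      gene_id = p$gene_id, start = pos + 1L, end = pos + width))
    pos <- pos + width
  }
  structure(list(rows = rows, partitions = parts), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d species x %d columns, %d partitions\n",
              length(x$rows), nchar(x$rows[1]), nrow(x$partitions)))
  invisible(x)
}

#' Write an alignment or supermatrix to FASTA / a RAxML-style partition file
#'
#' @param x an `msta`, `projected_msa` or `supermatrix`
#' @param path output FASTA
#' @export
write_alignment <- function(x, path) {
  if (inherits(x, "supermatrix")) {
    seqs <- Biostrings::AAStringSet(x$rows)
  } else {
    seqs <- Biostrings::AAStringSet(setNames(x$aligned, x$protein_id))
  }
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @param sm a `supermatrix`
#' @param model_string per-gene model for the partition lines
#'   (default "JTT+F+I+G")
#' @rdname write_alignment
#' @export
write_partitions <- function(sm, path, model_string = "JTT+F+I+G") {
  lines <- sprintf("%s, %s = %d-%d", model_string, sm$partitions$gene_id,
                   sm$partitions$start, sm$partitions$end)
  writeLines(lines, path)
  invisible(path)
}
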