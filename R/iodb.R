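# Paired AA/3Di proteome database: reading FASTA pairs, resolving missing 3Di
# strings through an exact-sequence lookup or a pluggable converter, and the
# on-disk database directory format.

fasta_ids <- function(x) sub("\\s.*$", "", names(x))

read_fasta_seqs <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- fasta_ids(set)
  if (anyDuplicated(ids)) {
    stop("duplicate header '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  setNames(toupper(as.character(set)), ids)
}

#' Read one species proteome as paired AA/3Di records
#'
#' Records are paired by identical FASTA header id. Proteins present in the
#' AA file but lacking a 3Di source are returned separately as `unresolved`
#' (3Di set to NA) so they can be passed through [resolve_3di()].
#'
#' @param aa_fasta_path amino-acid FASTA (plain or gzip)
#' @param tdi_fasta_path optional matching 3Di FASTA; its headers must cover
#'   the AA headers they pair with
#' @param species_id species label; defaults to the AA file basename without
#'   extension
#' @return list with tibbles `records` (species_id, protein_id, aa, tdi) and
#'   `unresolved` (same columns, tdi = NA)
#' @export
read_proteome <- function(aa_fasta_path, tdi_fasta_path = NULL,
                          species_id = NULL) {
  if (is.null(species_id)) {
    species_id <- sub("\\.(fa|fasta|faa)(\\.gz)?$", "",
                      basename(aa_fasta_path), ignore.case = TRUE)
  }
  aa <- read_fasta_seqs(aa_fasta_path)
  tdi <- if (!is.null(tdi_fasta_path)) read_fasta_seqs(tdi_fasta_path)
         else character(0)
  ids <- names(aa)
  tdi_match <- tdi[match(ids, names(tdi))]
  has_tdi <- !is.na(tdi_match)
  bad <- has_tdi & nchar(tdi_match) != nchar(aa)
  if (any(bad)) {
    stop("length mismatch between AA and 3Di sequence for header '",
         ids[bad][1L], "'", call. = FALSE)
  }
  for (i in seq_along(ids)) check_seq(aa[[i]], "AA", ids[i])
  tb <- tibble::tibble(species_id = species_id, protein_id = ids,
                       aa = unname(aa), tdi = unname(tdi_match))
  list(records = tb[has_tdi, ], unresolved = tb[!has_tdi, ])
}

#' Read an exact-match AA-to-3Di lookup table
#'
#' Two-column TSV (aa_sequence, tdi_sequence); every 3Di string must have the
#' same length as its amino-acid key. Lookups are exact full-sequence matches
#' after uppercasing.
#'
#' @param path TSV path
#' @return named character vector (names = AA sequences)
#' @export
read_lookup_table <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("aa", "tdi"),
                   colClasses = "character", quote = "")
  aa <- toupper(tb$aa); tdi <- toupper(tb$tdi)
  if (any(nchar(aa) != nchar(tdi))) {
    stop("lookup entry with mismatched AA/3Di lengths in ", path,
         call. = FALSE)
  }
  setNames(tdi, aa)
}

#' Resolve missing 3Di strings via lookup, then converter
#'
#' Each unresolved record is resolved by exact amino-acid match in the lookup
#' table first; failing that, by the converter adapter (a function taking an
#' AA string and returning an equal-length 3Di string, e.g. a ProstT5
#' wrapper); otherwise it stays unresolved. Already-resolved records are
#' never modified.
#'
#' @param unresolved tibble as returned in `read_proteome()$unresolved`
#' @param lookup named character vector from [read_lookup_table()] (or NULL)
#' @param converter optional function(aa_string) -> 3Di string
#' @return list of tibbles `resolved` and `still_unresolved`
#' @export
resolve_3di <- function(unresolved, lookup = NULL, converter = NULL) {
  tb <- unresolved
  todo <- is.na(tb$tdi)
  if (!is.null(lookup) && any(todo)) {
    hit <- lookup[match(toupper(tb$aa[todo]), names(lookup))]
    tb$tdi[todo][!is.na(hit)] <- unname(hit[!is.na(hit)])
    todo <- is.na(tb$tdi)
  }
  if (!is.null(converter) && any(todo)) {
    for (i in which(todo)) {
      out <- converter(tb$aa[[i]])
      if (is.null(out) || length(out) != 1L || is.na(out)) next
      out <- toupper(out)
      if (nchar(out) != nchar(tb$aa[[i]])) {
        stop("converter returned a 3Di string of wrong length for '",
             tb$protein_id[[i]], "'", call. = FALSE)
      }
      tb$tdi[[i]] <- out
    }
  }
  ok <- !is.na(tb$tdi)
  list(resolved = tb[ok, ], still_unresolved = tb[!ok, ])
}

#' Assemble the paired AA+3Di database
#'
#' Combines per-species record tibbles, namespaces protein ids as
#' `species_id|protein_id`, and drops records longer than `max_len` residues
#' (logged with a message).
#'
#' @param record_list list of tibbles (species_id, protein_id, aa, tdi)
#' @param max_len maximum retained sequence length (default 4000)
#' @return object of class `paired_db`: list with `records` tibble
#'   (protein_id, species_id, aa, tdi, length) and `species_ids`
#' @export
build_database <- function(record_list, max_len = 4000L) {
  tb <- dplyr::bind_rows(record_list)
  species <- unique(tb$species_id)
  if (length(species) < 2L) {
    stop("a paired database needs at least 2 species", call. = FALSE)
  }
  if (any(is.na(tb$tdi))) {
    stop("unresolved records passed to build_database(); run resolve_3di()",
         call. = FALSE)
  }
  tb$aa <- toupper(tb$aa); tb$tdi <- toupper(tb$tdi)
  if (any(nchar(tb$aa) != nchar(tb$tdi))) {
    bad <- tb$protein_id[nchar(tb$aa) != nchar(tb$tdi)][1L]
    stop("length mismatch between AA and 3Di sequence for '", bad, "'",
         call. = FALSE)
  }
  tb$protein_id <- paste(tb$species_id, tb$protein_id, sep = "|")
  if (anyDuplicated(tb$protein_id)) {
    stop("duplicate protein id within one species: ",
         tb$protein_id[duplicated(tb$protein_id)][1L], call. = FALSE)
  }
  tb$length <- nchar(tb$aa)
  drop <- tb$length > max_len
  if (any(drop)) {
    message(sum(drop), " record(s) longer than max_len=", max_len,
            " excluded")
  }
  tb <- tb[!drop, c("protein_id", "species_id", "aa", "tdi", "length")]
  structure(list(records = tb, species_ids = species,
                 n_excluded = sum(drop)),
            class = "paired_db")
}

#' @export
print.paired_db <- function(x, ...) {
  cat(sprintf("<paired_db> %d proteins across %d species (%s residues)\n",
              nrow(x$records), length(x$species_ids),
              format(sum(x$records$length), big.mark = ",")))
  invisible(x)
}

# total residues in the database: the E-value search space
db_residues <- function(db) sum(db$records$length)

db_record <- function(db, id) {
  i <- match(id, db$records$protein_id)
  if (is.na(i)) stop("unknown protein id: ", id, call. = FALSE)
  db$records[i, ]
}

#' Write / load a paired database directory
#'
#' The on-disk format is a directory holding `db.aa.fasta`, `db.3di.fasta`
#' (ids = `species_id|protein_id`) and `db.meta.tsv` (protein_id, species_id,
#' length). `load_database(write_database(db, d))` reproduces `db`.
#'
#' @param db a `paired_db`
#' @param path directory (created if needed)
#' @return the path (write) or a `paired_db` (load)
#' @export
write_database <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  aa <- Biostrings::AAStringSet(setNames(db$records$aa, db$records$protein_id))
  tdi <- Biostrings::AAStringSet(setNames(db$records$tdi,
                                          db$records$protein_id))
  Biostrings::writeXStringSet(aa, file.path(path, "db.aa.fasta"), width = 80L)
  Biostrings::writeXStringSet(tdi, file.path(path, "db.3di.fasta"),
                              width = 80L)
  meta <- db$records[, c("protein_id", "species_id", "length")]
  write.table(meta, file.path(path, "db.meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
load_database <- function(path) {
  need <- file.path(path, c("db.aa.fasta", "db.3di.fasta", "db.meta.tsv"))
  if (!all(file.exists(need))) {
    stop("not a paired database directory (missing ",
         paste(basename(need[!file.exists(need)]), collapse = ", "),
         "): ", path, call. = FALSE)
  }
  aa <- read_fasta_seqs(need[1L])
  tdi <- read_fasta_seqs(need[2L])
  meta <- read.table(need[3L], sep = "\t", header = TRUE,
                     colClasses = c("character", "character", "integer"))
  if (!identical(sort(names(aa)), sort(meta$protein_id)) ||
      !identical(sort(names(tdi)), sort(meta$protein_id))) {
    stop("corrupted database: FASTA ids do not match db.meta.tsv",
         call. = FALSE)
  }
  tb <- tibble::tibble(
    protein_id = meta$protein_id,
    species_id = meta$species_id,
    aa = unname(aa[meta$protein_id]),
    tdi = unname(tdi[meta$protein_id]),
    length = meta$length)
  if (any(nchar(tb$aa) != tb$length) || any(nchar(tb$tdi) != tb$length)) {
    stop("corrupted database: sequence lengths disagree with db.meta.tsv",
         call. = FALSE)
  }
  structure(list(records = tb, species_ids = unique(tb$species_id),
                 n_excluded = 0L),
            class = "paired_db")
}
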