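#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, a header
#' row of letters, one labelled row per letter). Only the 20 standard residue
#' letters are retained; the matrix must be symmetric over them.
#'
#' @param path path to a matrix file
#' @return 20x20 integer matrix with residue-letter dimnames
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(labels, header)
  keep <- RESIDUE_LETTERS
  if (!all(keep %in% rownames(vals)) || !all(keep %in% colnames(vals))) {
    stop("matrix is missing residue letters: ", path)
  }
  m <- vals[keep, keep]
  if (!isSymmetric(unname(m))) stop("matrix is not symmetric: ", path)
  storage.mode(m) <- "integer"
  m
}

default_mat3di <- function() {
  read_score_matrix(system.file("extdata", "mat3di_synthetic.txt",
                                package = "structcore", mustWork = TRUE))
}

default_mataa <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62
  m <- b62[RESIDUE_LETTERS, RESIDUE_LETTERS]
  storage.mode(m) <- "integer"
  m
}

# Expand a weighted 20x20 matrix to the 21x21 integer matrix used by the C++
# kernels: row/column 21 is 'X' and scores 0 against everything.
weighted_matrix <- function(mat, weight) {
  wm <- matrix(0L, 21L, 21L)
  wm[1:20, 1:20] <- as.integer(round(weight * mat))
  wm
}

#' Combined 3Di+AA substitution model
#'
#' Bundles the two 20x20 score matrices, their weights, affine gap penalties,
#' and the Karlin-Altschul style parameters (lambda, K) used to convert raw
#' local-alignment scores into bit scores and E-values. Column scores are
#' `round(w3di * S3di) + round(waa * Saa)`; 'X' scores 0 against everything.
#'
#' Lambda and K are fitted once per matrix/weight/gap combination by a
#' method-of-moments Gumbel fit on local-alignment scores of shuffled random
#' sequence pairs (a fixed internal stream, independent of any analysis
#' seed), and cached for the session.
#'
#' @param mat3di 20x20 3Di score matrix (default: the synthetic match/mismatch
#'   matrix shipped with the package)
#' @param mataa 20x20 amino-acid score matrix (default BLOSUM62)
#' @param w3di,waa nonnegative weights for the two channels (defaults 2.1 and
#'   1.4, the convention used for combined 3Di+AA scoring)
#' @param gap_open,gap_extend positive affine gap penalties (defaults 10, 1)
#' @param calibrate fit lambda/K at construction (default TRUE); with FALSE a
#'   crude analytic ungapped lambda and K = 0.1 are used
#' @return object of class `subst_model`
#' @export
subst_model <- function(mat3di = NULL, mataa = NULL,
                        w3di = 2.1, waa = 1.4,
                        gap_open = 10L, gap_extend = 1L,
                        calibrate = TRUE) {
  if (is.null(mat3di)) mat3di <- default_mat3di()
  if (is.null(mataa)) mataa <- default_mataa()
  stopifnot(w3di >= 0, waa >= 0, w3di + waa > 0,
            gap_open > 0, gap_extend > 0)
  wm3 <- weighted_matrix(mat3di, w3di)
  wma <- weighted_matrix(mataa, waa)
  comb <- wm3[1:20, 1:20] + wma[1:20, 1:20]
  if (mean(comb) >= 0) {
    stop("expected combined score under uniform background must be negative")
  }
  model <- structure(
    list(mat3di = mat3di, mataa = mataa, w3di = w3di, waa = waa,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         wm3 = wm3, wma = wma),
    class = "subst_model")
  if (calibrate) {
    ev <- calibrate_evalue_params(model)
  } else {
    ev <- list(lambda = ungapped_lambda(comb), k_const = 0.1)
  }
  model$lambda <- ev$lambda
  model$k_const <- ev$k_const
  model
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf(
    "<subst_model> w3di=%.2f waa=%.2f gap=%d/%d lambda=%.4f K=%.3g\n",
    x$w3di, x$waa, x$gap_open, x$gap_extend, x$lambda, x$k_const))
  invisible(x)
}

# analytic ungapped lambda: solve mean(exp(lambda * S)) = 1 over uniform
# backgrounds (positive root)
ungapped_lambda <- function(comb) {
  f <- function(l) mean(exp(l * comb)) - 1
  uniroot(f, c(1e-4, 2), tol = 1e-9)$root
}

# Gumbel method-of-moments fit on shuffled-pair local alignment scores:
# lambda = pi / (sd * sqrt(6)); K from the fitted location parameter.
calibrate_evalue_params <- function(model, n_pairs = 80L, len = 200L) {
  key <- paste0("ev:", model$w3di, ":", model$waa, ":",
                model$gap_open, ":", model$gap_extend, ":",
                sum(model$wm3), ":", sum(model$wma))
  cached <- .structcore_cache[[key]]
  if (!is.null(cached)) return(cached)
  rng <- make_rng(760013L)
  scores <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    a3 <- rng$sample_codes(len); b3 <- rng$sample_codes(len)
    aa <- rng$sample_codes(len); ba <- rng$sample_codes(len)
    scores[i] <- .sw_score_cpp(a3, b3, aa, ba, model$wm3, model$wma,
                               model$gap_open, model$gap_extend)
  }
  lambda <- pi / (sd(scores) * sqrt(6))
  gamma_c <- 0.5772156649
  mu <- mean(scores) - gamma_c / lambda
  k_const <- exp(lambda * mu) / (as.numeric(len) * len)
  out <- list(lambda = lambda, k_const = max(k_const, 1e-12))
  .structcore_cache[[key]] <- out
  out
}

# small deterministic RNG helper isolated from the global .Random.seed
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- get0(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  env$with <- function(expr) {
    old <- get0(".Random.seed", globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  env$sample_codes <- function(n) {
    env$with(sample.int(20L, n, replace = TRUE) - 1L)
  }
  env
}

# run expr with a temporary global seed, restoring the previous RNG state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# bit score and E-value conversions (Karlin-Altschul form)
bits_from_raw <- function(raw, model) {
  (model$lambda * raw - log(model$k_const)) / log(2)
}

evalue_from_bits <- function(bits, m, n_db) {
  as.numeric(m) * as.numeric(n_db) * 2^(-bits)
}
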