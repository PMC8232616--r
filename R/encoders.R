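# Classical per-residue encodings: one-hot, physico-chemical factors,
# PSSM (+ sigmoid), and mean pooling to fixed-length per-protein vectors.

.sublocr_env <- new.env(parent = emptyenv())

new_encoding_matrix <- function(values, scheme) {
  structure(values, scheme = scheme, class = c("encoding_matrix", "matrix"))
}

#' @export
print.encoding_matrix <- function(x, ...) {
  cat(attr(x, "scheme"), "encoding:", nrow(x), "residues x",
      ncol(x), "features\n")
  invisible(x)
}

#' Load the packaged 20x10 physico-chemical factor table
#'
#' The ten orthogonal factors of Kidera and co-workers, obtained by
#' multivariate analysis of 188 residue-specific physical properties;
#' rows are the 20 standard residues in alphabetical order.
#'
#' @param path optional path to an alternative factor table (TSV with a
#'   `residue` column and ten numeric columns).
#' @return 20x10 numeric matrix with residue rownames.
#' @export
load_factor_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sublocr_env$factors)) return(.sublocr_env$factors)
    path <- system.file("extdata", "kidera_factors.tsv",
                        package = "sublocr", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!identical(dim(m), c(20L, 10L)) ||
      !setequal(rownames(m), AA_ALPHABET20) || !is.numeric(m))
    stop("malformed factor table: expected 20 residues x 10 factors")
  m <- m[AA_ALPHABET20, , drop = FALSE]
  if (cache) .sublocr_env$factors <- m
  m
}

#' One-hot encode a protein sequence
#'
#' Residue j maps to a 1x20 binary vector with a single 1 in position j;
#' columns are the 20 residues in alphabetical order (A first), so alanine
#' is 1 followed by nineteen 0s.  An `X` residue yields an all-zero row.
#'
#' @param record one row of a `protein_records` data frame (or any list
#'   with `id` and `sequence`).
#' @return `encoding_matrix`, L x 20.
#' @export
encode_onehot <- function(record) {
  aa <- strsplit(record$sequence, "")[[1]]
  m <- matrix(0, nrow = length(aa), ncol = 20,
              dimnames = list(NULL, AA_ALPHABET20))
  hit <- match(aa, AA_ALPHABET20)          # NA for X -> zero row
  keep <- !is.na(hit)
  m[cbind(which(keep), hit[keep])] <- 1
  new_encoding_matrix(m, "1HOT")
}

#' Physico-chemical factor encoding of a protein sequence
#'
#' Each residue maps to its ten-factor row of the packaged table; an `X`
#' residue maps to the column-wise mean of the 20 factor rows.
#'
#' @inheritParams encode_onehot
#' @param factors factor table as returned by [load_factor_table()].
#' @return `encoding_matrix`, L x 10.
#' @export
encode_prop <- function(record, factors = load_factor_table()) {
  aa <- strsplit(record$sequence, "")[[1]]
  hit <- match(aa, rownames(factors))
  m <- matrix(NA_real_, nrow = length(aa), ncol = ncol(factors),
              dimnames = list(NULL, colnames(factors)))
  keep <- !is.na(hit)
  m[keep, ] <- factors[hit[keep], , drop = FALSE]
  if (any(!keep)) m[!keep, ] <- rep(colMeans(factors), each = sum(!keep))
  new_encoding_matrix(m, "PROP")
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` dialect: a header line of amino-acid column
#' letters followed by one row per residue (`position residue score1 ...
#' score20 ...`).  Only the first 20 score columns (the log-odds block) are
#' used.  The file's residue column must match the record's sequence.
#'
#' @param path path to the ASCII PSSM file.
#' @inheritParams encode_onehot
#' @return `encoding_matrix` of raw integer scores, L x 20, columns ordered
#'   as in the file header.
#' @export
parse_pssm <- function(path, record) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_header <- vapply(toks, function(tk)
    length(tk) >= 20 && all(tk %in% AA_ALPHABET20), logical(1))
  hi <- which(is_header)
  if (!length(hi)) stop("truncated or malformed PSSM file: no header row")
  header <- toks[[hi[1]]][1:20]
  rows <- if (hi[1] < length(toks)) toks[(hi[1] + 1):length(toks)] else list()
  rows <- rows[vapply(rows, function(tk)
    length(tk) >= 2 && grepl("^[0-9]+$", tk[1]), logical(1))]
  if (!length(rows)) stop("truncated PSSM file: no residue rows")
  res <- vapply(rows, `[`, character(1), 2)
  scores <- lapply(rows, function(tk) {
    v <- suppressWarnings(as.numeric(tk[-(1:2)]))
    v <- v[!is.na(v)]
    if (length(v) < 20)
      stop("malformed PSSM row: expected at least 20 score columns, got ",
           length(v))
    v[1:20]
  })
  seqchr <- paste(res, collapse = "")
  if (!identical(seqchr, record$sequence))
    stop("PSSM/sequence mismatch for record ", record$id,
         ": file residues ", substr(seqchr, 1, 30),
         if (nchar(seqchr) > 30) "..." else "",
         " do not match the record sequence")
  m <- do.call(rbind, scores)
  colnames(m) <- header
  new_encoding_matrix(m, "PSSM")
}

#' Map raw PSSM scores into (0, 1) with the logistic sigmoid
#'
#' Elementwise \eqn{1 / (1 + e^{-x})}.
#'
#' @param m numeric matrix (typically raw PSSM scores).
#' @return matrix of the same shape with entries strictly in (0, 1).
#' @export
sigmoid_map <- function(m) {
  out <- 1 / (1 + exp(-m))
  attributes(out) <- attributes(m)
  out
}

#' Pool a per-residue encoding to one fixed-length vector
#'
#' Column-wise arithmetic mean over the L residue rows.  For the one-hot
#' encoding of an X-free sequence this is the amino-acid composition
#' frequency vector.
#'
#' @param m an `encoding_matrix` (or any numeric matrix with L >= 1 rows).
#' @return named numeric vector of length `ncol(m)` with attribute
#'   `scheme`.
#' @export
pool_encoding <- function(m) {
  if (nrow(m) < 1) stop("cannot pool an empty encoding matrix")
  structure(colMeans(m), scheme = attr(m, "scheme"))
}

#' Compute a pooled classical encoding block for a set of proteins
#'
#' Applies the requested encoder to every record and mean-pools each L x d
#' matrix to a 1 x d vector, yielding a per-protein feature block usable
#' alongside embedding blocks.
#'
#' @param records a `protein_records` data frame.
#' @param scheme one of `"1HOT"`, `"PROP"`, `"PSSM"`.
#' @param pssm_dir for `scheme = "PSSM"`, directory containing one
#'   `<id>.pssm` ASCII file per record; scores pass through
#'   [sigmoid_map()] before pooling.
#' @return an `embedding_block` (see [embedding_block()]) named after the
#'   scheme, width 20 (1HOT, PSSM) or 10 (PROP).
#' @export
encoding_block <- function(records, scheme = c("1HOT", "PROP", "PSSM"),
                           pssm_dir = NULL) {
  scheme <- match.arg(scheme)
  vecs <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    m <- switch(scheme,
      "1HOT" = encode_onehot(rec),
      "PROP" = encode_prop(rec),
      "PSSM" = {
        if (is.null(pssm_dir)) stop("PSSM encoding requires pssm_dir")
        f <- file.path(pssm_dir, paste0(rec$id, ".pssm"))
        sigmoid_map(parse_pssm(f, rec))
      })
    pool_encoding(m)
  })
  X <- do.call(rbind, vecs)
  rownames(X) <- records$id
  embedding_block(scheme, X, dim = ncol(X))
}
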