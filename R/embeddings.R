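# Per-protein embedding blocks: fixed-width vectors keyed by protein id,
# loaded from delimited tables produced by external embedders (or the
# synthetic generator), plus block concatenation and correlation screening.

#' Expected widths of the named embedding schemes
#' @export
EMBEDDING_DIMS <- c(UNIREP = 1900L, SEQVEC = 1024L)

#' Construct an embedding block
#'
#' @param name block name; `"UNIREP"` and `"SEQVEC"` carry fixed expected
#'   widths (1900 and 1024), any other name declares a custom block.
#' @param vectors numeric matrix, one row per protein, rownames = ids.
#' @param dim expected width; defaults to the named scheme's contract or,
#'   for custom blocks, to `ncol(vectors)`.
#' @return an `embedding_block`: list with `name`, `dim`, `vectors`.
#' @export
embedding_block <- function(name, vectors, dim = NULL) {
  name <- toupper(name)
  if (is.null(dim))
    dim <- if (name %in% names(EMBEDDING_DIMS)) EMBEDDING_DIMS[[name]]
           else ncol(vectors)
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != dim)
    stop("width mismatch for block ", name, ": expected ", dim,
         " columns, got ", ncol(vectors))
  if (is.null(rownames(vectors)) || any(!nzchar(rownames(vectors))))
    stop("embedding vectors must have protein-id rownames")
  if (anyDuplicated(rownames(vectors)))
    stop("duplicate ids in block ", name)
  if (!all(is.finite(vectors)))
    stop("non-finite values in block ", name)
  structure(list(name = name, dim = as.integer(dim), vectors = vectors),
            class = "embedding_block")
}

#' @export
print.embedding_block <- function(x, ...) {
  cat("embedding_block", x$name, ":", nrow(x$vectors), "proteins x",
      x$dim, "features\n")
  invisible(x)
}

#' Load a per-protein embedding table
#'
#' Dialect: tab-separated, no header, first column the protein id, the
#' remaining columns the numeric embedding (`id<TAB>v1<TAB>...<TAB>vD`).
#' The width is checked against the named scheme's contract (UNIREP 1900,
#' SEQVEC 1024); a missing protein is surfaced later, at assembly time,
#' as a per-protein error rather than being dropped.
#'
#' @param path path to the table.
#' @param name block name (see [embedding_block()]).
#' @param dim optional declared width for custom blocks.
#' @return an `embedding_block`.
#' @export
load_embedding_table <- function(path, name, dim = NULL) {
  if (!file.exists(path)) stop("embedding table not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = c("character", rep("numeric",
                      length(strsplit(readLines(path, n = 1),
                                      "\t")[[1]]) - 1L)))
  if (ncol(tab) < 2) stop("embedding table must have id + numeric columns")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in embedding table ", path)
  rownames(m) <- tab[[1]]
  colnames(m) <- NULL
  embedding_block(name, m, dim = dim)
}

#' Write an embedding block as a delimited table
#'
#' Values are printed with 17 significant digits so that a load/write/load
#' round trip is exact.
#'
#' @param block an `embedding_block`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(block, path) {
  stopifnot(inherits(block, "embedding_block"))
  lines <- vapply(seq_len(nrow(block$vectors)), function(i)
    paste(c(rownames(block$vectors)[i],
            sprintf("%.17g", block$vectors[i, ])), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Concatenate feature blocks into one assembly matrix
#'
#' Row-wise horizontal concatenation in the given block order; the result
#' width is the sum of member widths (UNIREP + SEQVEC gives 2924).
#'
#' @param blocks list of `embedding_block`s (embeddings or pooled
#'   encodings), optionally named.
#' @param ids ordered protein ids; every id must be present in every
#'   block.  Defaults to the ids of the first block.
#' @return a `feature_assembly`: list with `block_order`, `ids`, `X`
#'   (n x D matrix, rownames = ids).
#' @export
concat_blocks <- function(blocks, ids = NULL) {
  if (inherits(blocks, "embedding_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1)
  if (is.null(ids)) ids <- rownames(blocks[[1]]$vectors)
  parts <- lapply(blocks, function(b) {
    missing <- setdiff(ids, rownames(b$vectors))
    if (length(missing))
      stop("block ", b$name, " is missing embeddings for id(s): ",
           paste(missing, collapse = ", "))
    b$vectors[ids, , drop = FALSE]
  })
  X <- do.call(cbind, parts)
  rownames(X) <- ids
  colnames(X) <- NULL
  structure(list(block_order = vapply(blocks, `[[`, character(1), "name"),
                 ids = ids, X = X),
            class = "feature_assembly")
}

#' @export
print.feature_assembly <- function(x, ...) {
  cat("feature_assembly [", paste(x$block_order, collapse = " + "), "]:",
      nrow(x$X), "proteins x", ncol(x$X), "features\n")
  invisible(x)
}

#' Pairwise Pearson correlation between the features of two blocks
#'
#' Correlations are computed over the proteins shared by both blocks; a
#' zero-variance feature yields `NA` in its row/column and a warning.
#'
#' @param a,b `embedding_block`s.
#' @return `a$dim` x `b$dim` matrix of Pearson correlations.
#' @export
correlation_screen <- function(a, b) {
  shared <- intersect(rownames(a$vectors), rownames(b$vectors))
  if (length(shared) < 3)
    stop("correlation screen needs at least 3 shared proteins, got ",
         length(shared))
  A <- a$vectors[shared, , drop = FALSE]
  B <- b$vectors[shared, , drop = FALSE]
  zv <- c(apply(A, 2, var) == 0, apply(B, 2, var) == 0)
  if (any(zv))
    warning(sum(zv), " zero-variance feature(s): correlation undefined (NA)")
  suppressWarnings(cor(A, B))
}
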