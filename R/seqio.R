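#' @importFrom stats cor predict rnorm runif sd setNames var
#' @importFrom utils read.delim write.table
NULL

#' The canonical 20-letter amino-acid alphabet, alphabetical order
#'
#' Column order of the one-hot encoding: A first, as in the standard
#' alanine = 1 followed by nineteen 0s representation.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# nonstandard one-letter codes replaced by X on read
NONSTANDARD_AA <- c("B", "Z", "J", "U", "O")

new_protein_records <- function(id, sequence) {
  out <- data.frame(id = as.character(id),
                    sequence = as.character(sequence),
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Build a set of protein records from ids and sequences
#'
#' Validates and normalises sequences: uppercased, nonstandard residues
#' (B, Z, J, U, O, X) replaced by `X` with a warning, any other character
#' outside the 20-letter alphabet is an error naming the record.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @return A `protein_records` data frame with columns `id`, `sequence`,
#'   `length`.
#' @export
protein_records <- function(id, sequence) {
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  id <- as.character(id)
  if (any(!nzchar(id))) stop("empty protein id")
  if (anyDuplicated(id))
    stop("duplicate protein ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  has_nonstd <- grepl(paste0("[", paste(NONSTANDARD_AA, collapse = ""), "]"),
                      sequence)
  if (any(has_nonstd)) {
    warning("nonstandard residues (",
            paste(NONSTANDARD_AA, collapse = ", "),
            ") replaced by X in: ",
            paste(id[has_nonstd], collapse = ", "))
    sequence <- chartr(paste(NONSTANDARD_AA, collapse = ""),
                       strrep("X", length(NONSTANDARD_AA)), sequence)
  }
  ok <- paste0("^[", paste(AA_ALPHABET20, collapse = ""), "X]*$")
  bad <- !grepl(ok, sequence)
  if (any(bad))
    stop("sequence with characters outside the amino-acid alphabet ",
         "in record(s): ", paste(id[bad], collapse = ", "))
  new_protein_records(id, sequence)
}

#' Read protein sequences from a FASTA file
#'
#' Entries are returned in file order; sequences are uppercased and
#' validated against the 20-letter alphabet (nonstandard residues become
#' `X`, see [protein_records()]).  The id is the first whitespace-delimited
#' token of the header.
#'
#' @param path path to a FASTA file.
#' @return A `protein_records` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  protein_records(ids, as.character(set))
}

#' Write protein records to a FASTA file
#'
#' @param records a `protein_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(inherits(records, "protein_records"))
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach class labels to protein records
#'
#' @param records a `protein_records` data frame.
#' @param labels named character vector, names are record ids.
#' @param classes optional declared class-label set; defaults to the
#'   distinct labels observed.  Must have 2 or 4 members.
#' @return A `labeled_dataset`: list with `records`, `labels` (named,
#'   ordered as `records`), and `classes`.
#' @export
labeled_dataset <- function(records, labels, classes = NULL) {
  stopifnot(inherits(records, "protein_records"))
  if (is.null(names(labels))) stop("labels must be named by record id")
  extra <- setdiff(names(labels), records$id)
  if (length(extra))
    stop("label table ids absent from records: ",
         paste(extra, collapse = ", "))
  missing <- setdiff(records$id, names(labels))
  if (length(missing))
    stop("records lacking a label: ", paste(missing, collapse = ", "))
  labels <- labels[records$id]
  if (is.null(classes)) classes <- sort(unique(unname(labels)))
  outside <- setdiff(unique(labels), classes)
  if (length(outside))
    stop("label(s) outside the declared class set: ",
         paste(outside, collapse = ", "))
  if (!length(classes) %in% c(2L, 4L))
    stop("class-label set must have 2 or 4 members, got ", length(classes))
  structure(list(records = records, labels = labels,
                 classes = as.character(classes)),
            class = "labeled_dataset")
}

#' Read a two-column id/label table and join it to records
#'
#' The file is tab-separated, no header, UTF-8: `id<TAB>label`.
#'
#' @inheritParams labeled_dataset
#' @param path path to the label table.
#' @return A `labeled_dataset`.
#' @export
read_labels <- function(path, records, classes = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", quote = "",
                    fileEncoding = "UTF-8")
  if (ncol(tab) != 2) stop("label table must have exactly two columns")
  if (anyDuplicated(tab[[1]]))
    stop("duplicate ids in label table: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  labeled_dataset(records, setNames(tab[[2]], tab[[1]]), classes = classes)
}

#' Write a label table as `id<TAB>label`
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  write.table(data.frame(id = names(dataset$labels),
                         label = unname(dataset$labels)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records:", nrow(x), "sequences, lengths",
      min(x$length), "-", max(x$length), "\n")
  invisible(x)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", nrow(x$records), "proteins;",
      length(x$classes), "classes (",
      paste(sprintf("%s:%d", x$classes,
                    as.integer(table(factor(x$labels, x$classes)))),
            collapse = ", "), ")\n")
  invisible(x)
}
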