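# Shared fixtures built in code: tiny FASTA/label files and a compact
# class-structured dataset for selection tests.

write_tmp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

write_tmp_labels <- function(labels, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  path
}

# small SVM spec used where the search space itself is not under test
small_svm_spec <- function(mode = "binary",
                           weights = c("uniform", "balanced")) {
  classifier_spec("SVM",
                  grid = list(cost = c(0.01, 1, 100), kernel = "linear"),
                  class_weights = weights, mode = mode)
}

# two-block dataset emulating the curated binary study conditions at
# reduced width: informative block (3-sd class shift) + pure noise block
make_two_block_data <- function(n_per_class = c(membrane = 132, matrix = 28),
                                dims = c(INF = 50, NOISE = 30),
                                delta = 3, seed = 0) {
  sp <- synthetic_spec(n_per_class = n_per_class, dims = dims,
                       informative_blocks = names(dims)[1], delta = delta,
                       seed = seed, length_range = c(30, 60))
  ds <- gen_sequences(sp)
  blocks <- gen_embeddings(ds$records$id, ds$labels, sp)
  list(spec = sp, dataset = ds,
       mats = lapply(blocks, function(b) b$vectors),
       y = unname(ds$labels))
}
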