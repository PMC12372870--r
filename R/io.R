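#' Read and write pipeline TSV formats
#'
#' The abundance matrix is stored with the protein id in the first column
#' (`protein_id`) and one column per sample; empty cells are missing. The
#' design table has columns `sample_id`, `condition`, `treatment`,
#' `replicate_batch`. Writers prepend `#`-prefixed provenance comment
#' lines; readers skip them.
#'
#' @param mat Numeric matrix, proteins x samples.
#' @param path File path.
#' @param comments Character vector of provenance lines to prepend
#'   (written as `# <line>`).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name apms-io
NULL

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' @rdname apms-io
#' @export
write_abundance_tsv <- function(mat, path, comments = character()) {
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_commented(df, path, comments)
}

#' @rdname apms-io
#' @export
read_abundance_tsv <- function(path) {
  df <- read_tsv_commented(path)
  if (names(df)[1] != "protein_id") {
    stop("abundance TSV must have 'protein_id' as its first column",
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$protein_id
  mat
}

#' @rdname apms-io
#' @param design Sample design data.frame.
#' @export
write_design_tsv <- function(design, path, comments = character()) {
  write_tsv_commented(design, path, comments)
}

#' @rdname apms-io
#' @export
read_design_tsv <- function(path) {
  d <- read_tsv_commented(path)
  d$replicate_batch <- as.integer(d$replicate_batch)
  validate_design(d)
  d
}

#' Write the planted ground truth
#'
#' Two tables: the per-protein class/baseline assignment and the per-class
#' planted effect table.
#'
#' @param truth `truth` element of an [simulate_apms()] result.
#' @param dir Output directory.
#' @param comments Provenance comment lines.
#' @return Character vector of the written paths, invisibly.
#' @export
write_truth_tsv <- function(truth, dir, comments = character()) {
  p1 <- file.path(dir, "truth_proteins.tsv")
  p2 <- file.path(dir, "truth_effects.tsv")
  write_tsv_commented(truth$proteins, p1, comments)
  write_tsv_commented(truth$effects, p2, comments)
  invisible(c(p1, p2))
}

#' Build the gene-set collection for the planted module
#'
#' The planted module is one labeled set; to make "is the module the top
#' enriched term" a meaningful question, the collection also contains
#' seeded random decoy sets drawn uniformly from all prey ids (decoys carry
#' no planted signal and are named `decoy_01`, `decoy_02`, ...).
#'
#' @param truth `truth` element of an [simulate_apms()] result.
#' @param n_decoy Number of decoy sets.
#' @param set_size Size of each decoy set; defaults to the module size.
#' @param seed Seed for the decoy draw.
#' @return Named list of gene sets (class `gene_set_collection`).
#' @export
make_gene_sets <- function(truth, n_decoy = 19, set_size = NULL, seed = 1) {
  module <- truth$module_set
  if (length(module) == 0) {
    stop("the simulation has no planted module members", call. = FALSE)
  }
  if (is.null(set_size)) set_size <- length(module)
  prey_ids <- truth$proteins$protein_id[truth$proteins$class != "bait"]
  sets <- stats::setNames(list(module), truth$module_set_name)
  if (n_decoy > 0) {
    set.seed(seed)
    decoys <- lapply(seq_len(n_decoy), function(i) {
      sort(sample(prey_ids, min(set_size, length(prey_ids))))
    })
    names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoy))
    sets <- c(sets, decoys)
  }
  attr(sets, "descriptions") <- stats::setNames(
    c("planted co-regulated module",
      rep("random decoy set", n_decoy)), names(sets))
  class(sets) <- "gene_set_collection"
  sets
}
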