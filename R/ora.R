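#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then member ids. Duplicate members within a line are
#' stored once.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (class `gene_set_collection`)
#'   with attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed GMT line ", which(nf < 3)[1],
         ": expected >= 3 tab-separated fields", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicate set name(s) in GMT: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(sets) == 0)) {
    stop("empty gene set(s) in GMT", call. = FALSE)
  }
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2), names(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests whether a selected protein set overlaps each gene set more than
#' expected given a universe, with the hypergeometric upper tail
#' \eqn{P[X \ge k]} (overrepresentation). Sets with no members in the
#' universe are skipped; p-values are Benjamini-Hochberg adjusted across
#' the tested sets.
#'
#' @param selection Character vector of selected protein ids; must be a
#'   subset of `universe`.
#' @param universe Character vector defining the background (e.g. the
#'   correlated-binder subset).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param depletion If `TRUE`, test the lower tail \eqn{P[X \le k]}
#'   (underrepresentation) instead.
#' @return data.frame sorted by p-value: `set_name`, `universe_size` (N),
#'   `set_size` (K, within the universe), `selection_size` (n), `overlap`
#'   (k), `p_value`, `p_adj`, `enrichment_ratio` ((k/n)/(K/N)).
#' @examples
#' hypergeometric_ora(letters[1:5], letters[1:10],
#'                    list(S = letters[1:5])) # p = 1/252
#' @export
hypergeometric_ora <- function(selection, universe, collection,
                               depletion = FALSE) {
  selection <- unique(as.character(selection))
  universe <- unique(as.character(universe))
  if (!all(selection %in% universe)) {
    stop("selection must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(selection)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(selection, members))
    p <- if (depletion) {
      stats::phyper(k, K, N - K, n)
    } else {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(set_name = nm, universe_size = N, set_size = K,
               selection_size = n, overlap = k, p_value = p,
               enrichment_ratio = if (n == 0) NA_real_ else (k / n) / (K / N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no gene set has members in the universe", call. = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set_name), ,
             drop = FALSE]
  out <- out[, c("set_name", "universe_size", "set_size", "selection_size",
                 "overlap", "p_value", "p_adj", "enrichment_ratio")]
  row.names(out) <- NULL
  out
}

#' ORA of the top pi-ranked proteins
#'
#' Convenience wrapper: takes a ranked contrast table (see
#' [rank_binders()]), selects the `top_n` proteins at the head
#' (`direction = "top"`, enriched in condition A of the contrast) or tail
#' (`direction = "bottom"`, enriched in condition B) of the pi ranking, and
#' runs [hypergeometric_ora()] against the selected (correlated-binder)
#' universe.
#'
#' @param ranked Output of [rank_binders()].
#' @param collection Gene-set collection.
#' @param top_n Number of proteins to select; capped at the number of
#'   ranked proteins.
#' @param direction `"top"` or `"bottom"` of the pi ranking.
#' @param universe Defaults to all ranked (selected) proteins.
#' @return See [hypergeometric_ora()].
#' @export
ora_top_pi <- function(ranked, collection, top_n = 100,
                       direction = c("top", "bottom"), universe = NULL) {
  direction <- match.arg(direction)
  ranked <- ranked[!is.na(ranked$rank), , drop = FALSE]
  if (nrow(ranked) == 0) {
    stop("no ranked proteins to select from", call. = FALSE)
  }
  if (is.null(universe)) universe <- ranked$protein_id
  top_n <- min(top_n, nrow(ranked))
  picked <- if (direction == "top") {
    ranked$protein_id[ranked$rank <= top_n]
  } else {
    ranked$protein_id[ranked$rank > nrow(ranked) - top_n]
  }
  hypergeometric_ora(picked, universe, collection)
}
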