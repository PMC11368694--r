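#' Tracked hematopoietic lineages
#'
#' The barcode readout covers four lineages: B cells (`B`), erythroid cells
#' (`E`), monocytes (`M`) and neutrophils (`N`). This ordered set defines the
#' canonical lineage ordering used throughout the package.
#'
#' @return Character vector `c("B", "E", "M", "N")`.
#' @export
tracked_lineages <- function() c("B", "E", "M", "N")

#' Enumerate the non-empty lineage subsets
#'
#' Every clone that survives filtering has output in a non-empty subset of the
#' tracked lineages; over four lineages there are 15 such subsets. Subsets are
#' encoded as strings of lineage letters in canonical order (e.g. `"MN"` for
#' monocyte + neutrophil), ordered by subset size and then lexicographically.
#' This ordering is shared by fate summaries and the similarity matrix.
#'
#' @param lineages Ordered character vector of lineage labels.
#' @return Character vector of the `2^k - 1` subset codes.
#' @examples
#' lineage_subsets()
#' @export
lineage_subsets <- function(lineages = tracked_lineages()) {
  stopifnot(length(lineages) >= 1, !anyDuplicated(lineages))
  unlist(lapply(seq_along(lineages), function(k) {
    apply(combn(lineages, k), 2, paste, collapse = "")
  }), use.names = FALSE)
}

#' Encode a set of lineage labels as a canonical subset code
#'
#' @param x Character vector of lineage labels (one clone's detected set).
#' @param lineages Ordered lineage labels defining the canonical order.
#' @return A single subset code string.
#' @export
subset_code <- function(x, lineages = tracked_lineages()) {
  x <- unique(x)
  bad <- setdiff(x, lineages)
  if (length(bad) > 0) {
    stop("unknown lineage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(lineages[lineages %in% x], collapse = "")
}

#' Decode a subset code into its lineage labels
#'
#' @param code Character vector of subset codes.
#' @return A list of character vectors of lineage labels.
#' @export
subset_members <- function(code) {
  strsplit(as.character(code), "", fixed = TRUE)
}
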