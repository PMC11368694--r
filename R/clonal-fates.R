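#' The five clonal fate classes
#'
#' Ordered labels of the clonal-fate taxonomy over the B/E/M/N lineages:
#' complete multi-outcome (all four lineages), restricted multi-outcome
#' (B cells plus at least one erythro-myeloid lineage, but not all four),
#' erythro-myeloid restricted (two or more of E/M/N including E, no B),
#' myeloid restricted (exactly monocytes + neutrophils), and single-lineage
#' restricted.
#'
#' @return Character vector of the five class labels.
#' @export
fate_classes <- function() {
  c("complete_multi", "restricted_multi", "erythro_myeloid_restricted",
    "myeloid_restricted", "single_lineage")
}

#' Classify a clone's lineage output
#'
#' Maps every non-empty subset of \{B, E, M, N\} to exactly one of the five
#' fate classes (a total, mutually exclusive classification over the 15
#' subsets). Bi-lineage erythroid sets without B (\{E,M\}, \{E,N\}) fall under
#' erythro-myeloid restricted, the class being defined by erythro-myeloid
#' output in the absence of B cells.
#'
#' @param subset Character vector of subset codes (see [subset_code()]), e.g.
#'   `"BEMN"`, `"MN"`, `"E"`.
#' @return Factor with levels [fate_classes()], same length as `subset`.
#' @examples
#' classify_fate(c("BEMN", "MN", "E", "BM", "EM"))
#' @export
classify_fate <- function(subset) {
  members <- subset_members(subset)
  lin <- tracked_lineages()
  cls <- vapply(members, function(m) {
    if (length(m) == 0 || any(!m %in% lin) || anyDuplicated(m)) {
      stop("undetected clone: fate subset must be a non-empty subset of {",
           paste(lin, collapse = ","), "}", call. = FALSE)
    }
    n <- length(m)
    if (n == 4L) return("complete_multi")
    if (n == 1L) return("single_lineage")
    if ("B" %in% m) return("restricted_multi")
    if (setequal(m, c("M", "N"))) return("myeloid_restricted")
    "erythro_myeloid_restricted"
  }, character(1))
  factor(cls, levels = fate_classes())
}

#' Detect per-clone lineage output
#'
#' Builds one fate profile per clone from a filtered, replicate-collapsed
#' count table. A clone is a (recipient, barcode) pair — the same barcode
#' sequence in two recipients is two clones, since each recipient's graft
#' draws independently from the library. The lineage set is the set of
#' lineages with a surviving entry; CPM abundances are carried over when
#' present.
#'
#' @param table Filtered, replicate-collapsed count table (see
#'   [filter_barcodes()], [collapse_replicates()]); a `cpm` column is used if
#'   present.
#' @param lineages Ordered lineage labels.
#' @return Tibble with one row per clone: `clone_id`, `recipient`, `barcode`,
#'   `lineage_set` (subset code), `n_lineages`, one `cpm_<lineage>` column per
#'   lineage and `cpm_total`.
#' @export
detect_lineages <- function(table, lineages = tracked_lineages()) {
  if ("replicate" %in% names(table)) {
    stop("collapse replicates before detecting lineages ",
         "(see collapse_replicates())", call. = FALSE)
  }
  if (!"cpm" %in% names(table)) table$cpm <- NA_real_
  prof <- table |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::group_by(.data$recipient, .data$barcode) |>
    dplyr::summarise(
      lineage_set = subset_code(.data$lineage, lineages),
      n_lineages = dplyr::n_distinct(.data$lineage),
      .groups = "drop"
    )
  cpm_wide <- table |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::select("recipient", "barcode", "lineage", "cpm") |>
    tidyr::pivot_wider(names_from = "lineage", values_from = "cpm",
                       names_prefix = "cpm_", values_fill = 0)
  for (l in lineages) {
    nm <- paste0("cpm_", l)
    if (!nm %in% names(cpm_wide)) cpm_wide[[nm]] <- 0
  }
  prof <- dplyr::left_join(prof, cpm_wide, by = c("recipient", "barcode"))
  prof$cpm_total <- rowSums(prof[, paste0("cpm_", lineages)])
  prof |>
    dplyr::mutate(clone_id = paste0(.data$recipient, ":", .data$barcode)) |>
    dplyr::select("clone_id", "recipient", "barcode", "lineage_set",
                  "n_lineages", dplyr::all_of(paste0("cpm_", lineages)),
                  "cpm_total")
}

#' Summarize clonal fate frequencies for a population
#'
#' Clones are pooled across recipients within a population, matching how
#' published clone counts pool several recipients. Returns per-class and
#' per-subset (15-dimensional) counts and frequencies; each frequency vector
#' sums to 1.
#'
#' @param profiles Fate-profile tibble from [detect_lineages()].
#' @param population Population label attached to the summary.
#' @param lineages Ordered lineage labels.
#' @return A list of class `fate_summary` with elements `population`,
#'   `n_clones`, `class_table` (class, count, frequency) and `subset_table`
#'   (subset, count, frequency over all 15 subsets).
#' @export
fate_frequency_table <- function(profiles, population = "pooled",
                                 lineages = tracked_lineages()) {
  if (nrow(profiles) == 0) {
    stop("no clones to summarize for population '", population, "'",
         call. = FALSE)
  }
  subsets <- lineage_subsets(lineages)
  cls <- classify_fate(profiles$lineage_set)
  class_tab <- tibble::tibble(
    class = factor(fate_classes(), levels = fate_classes()),
    count = as.integer(table(cls)[fate_classes()])
  )
  class_tab$frequency <- class_tab$count / sum(class_tab$count)
  subset_tab <- tibble::tibble(
    subset = factor(subsets, levels = subsets),
    count = as.integer(table(factor(profiles$lineage_set,
                                    levels = subsets))[subsets])
  )
  subset_tab$frequency <- subset_tab$count / sum(subset_tab$count)
  structure(
    list(population = population, n_clones = nrow(profiles),
         class_table = class_tab, subset_table = subset_tab),
    class = "fate_summary"
  )
}

#' @export
print.fate_summary <- function(x, ...) {
  cat("Clonal fate summary:", x$population, "(", x$n_clones, "clones )\n")
  print(x$class_table)
  invisible(x)
}

#' Pearson similarity matrix of clonal outcomes between populations
#'
#' Correlates fate-frequency vectors between populations with the Pearson
#' coefficient. By default the 15-dimensional subset-frequency vectors are
#' used (the 5-class vectors are a linear collapse of them and are available
#' via `on = "class"`). The matrix is symmetric with unit diagonal; a
#' population with a zero-variance frequency vector yields undefined
#' correlations, reported as `NA` with a warning.
#'
#' @param summaries List of `fate_summary` objects (>= 2), all on the same
#'   subset ordering.
#' @param on `"subset"` (15-dim, default) or `"class"` (5-dim).
#' @return Square numeric matrix of Pearson r, dimnames = population labels.
#' @export
fate_similarity_matrix <- function(summaries, on = c("subset", "class")) {
  on <- match.arg(on)
  if (length(summaries) < 2) {
    stop("need at least two fate summaries", call. = FALSE)
  }
  vecs <- vapply(summaries, function(s) {
    stopifnot(inherits(s, "fate_summary"))
    if (on == "subset") s$subset_table$frequency else s$class_table$frequency
  }, numeric(if (on == "subset") 15 else 5))
  colnames(vecs) <- vapply(summaries, `[[`, "", "population")
  zero_var <- apply(vecs, 2, function(v) isTRUE(all.equal(var(v), 0)))
  if (any(zero_var)) {
    warning("zero-variance fate vector(s): ",
            paste(colnames(vecs)[zero_var], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(cor(vecs))
  diag(r) <- ifelse(zero_var, NA_real_, 1)
  r
}

#' Relative lineage biomass
#'
#' The share of a population's total barcode reads (CPM, post-filter)
#' attributable to each group: either each lineage outcome (`by = "lineage"`:
#' CPM summed per lineage divided by the population's total CPM) or each
#' clonal-outcome class (`by = "fate_class"`: CPM of all entries belonging to
#' clones of that class) or each of the 15 lineage subsets (`by = "subset"`).
#' Shares sum to 1 within the population.
#'
#' @param table Filtered, replicate-collapsed count table with a `cpm`
#'   column.
#' @param profiles Fate profiles from [detect_lineages()]; required for the
#'   `fate_class` and `subset` groupings.
#' @param by Grouping: `"lineage"`, `"fate_class"` or `"subset"`.
#' @return Tibble (group, cpm_sum, share).
#' @export
lineage_biomass <- function(table, profiles = NULL,
                            by = c("lineage", "fate_class", "subset")) {
  by <- match.arg(by)
  if (!"cpm" %in% names(table)) {
    stop("table has no `cpm` column; run normalize_cpm() first",
         call. = FALSE)
  }
  total <- sum(table$cpm)
  if (total <= 0) stop("zero total biomass", call. = FALSE)
  if (by == "lineage") {
    out <- table |>
      dplyr::group_by(group = .data$lineage) |>
      dplyr::summarise(cpm_sum = sum(.data$cpm), .groups = "drop")
  } else {
    if (is.null(profiles)) {
      stop("`profiles` required for by = \"", by, "\"", call. = FALSE)
    }
    profiles <- profiles |>
      dplyr::mutate(fate_class = as.character(classify_fate(.data$lineage_set)))
    key <- if (by == "fate_class") "fate_class" else "lineage_set"
    out <- table |>
      dplyr::left_join(profiles[, c("recipient", "barcode", key)],
                       by = c("recipient", "barcode")) |>
      dplyr::group_by(group = .data[[key]]) |>
      dplyr::summarise(cpm_sum = sum(.data$cpm), .groups = "drop")
  }
  out$share <- out$cpm_sum / total
  out
}
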