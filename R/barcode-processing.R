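#' Read a barcode count table
#'
#' Two dialects are supported: tidy TSV with columns
#' `barcode, recipient, lineage, replicate, reads`, and wide CSV with barcode
#' rows and one column per sample, sample names encoded
#' `recipient.lineage.replicate`. Counts must be non-negative integers and
#' lineage labels must belong to the declared ordered set.
#'
#' @param path File path.
#' @param dialect `"tidy"` (TSV) or `"wide"` (CSV).
#' @param lineages Declared ordered lineage set; unknown labels are rejected.
#' @return Tidy tibble (barcode, recipient, lineage, replicate, reads).
#' @export
read_counts <- function(path, dialect = c("tidy", "wide"),
                        lineages = tracked_lineages()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tidy") {
    tbl <- readr::read_tsv(path, col_types = readr::cols(
      barcode = readr::col_character(),
      recipient = readr::col_character(),
      lineage = readr::col_character(),
      replicate = readr::col_character(),
      reads = readr::col_double()
    ))
    probs <- readr::problems(tbl)
    if (nrow(probs) > 0) {
      stop("malformed row(s) at line(s): ",
           paste(unique(probs$row), collapse = ", "), call. = FALSE)
    }
  } else {
    wide <- readr::read_csv(path, col_types = readr::cols(
      barcode = readr::col_character(), .default = readr::col_double()
    ))
    tbl <- tidyr::pivot_longer(wide, -"barcode", names_to = "sample",
                               values_to = "reads")
    parts <- strsplit(tbl$sample, ".", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      stop("wide sample columns must be named `recipient.lineage.replicate`",
           call. = FALSE)
    }
    tbl$recipient <- vapply(parts, `[`, "", 1)
    tbl$lineage <- vapply(parts, `[`, "", 2)
    tbl$replicate <- vapply(parts, `[`, "", 3)
    tbl <- tbl[, c("barcode", "recipient", "lineage", "replicate", "reads")]
    tbl <- dplyr::filter(tbl, .data$reads != 0)
  }
  validate_counts(tbl, lineages)
}

#' Write a barcode count table
#'
#' @param table Tidy count table.
#' @param path Output path.
#' @param dialect `"tidy"` (TSV) or `"wide"` (CSV, zero-filled).
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path, dialect = c("tidy", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "tidy") {
    readr::write_tsv(table, path)
  } else {
    wide <- table |>
      dplyr::mutate(sample = paste(.data$recipient, .data$lineage,
                                   .data$replicate, sep = ".")) |>
      dplyr::select("barcode", "sample", "reads") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "reads",
                         values_fill = 0)
    readr::write_csv(wide, path)
  }
  invisible(path)
}

validate_counts <- function(table, lineages = tracked_lineages()) {
  # the replicate dimension is optional: collapsed tables lack it
  needed <- c("barcode", "recipient", "lineage", "reads")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(table$reads)) || any(table$reads < 0) ||
      any(table$reads != round(table$reads))) {
    stop("read counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(unique(table$lineage), lineages)
  if (length(bad) > 0) {
    stop("unknown lineage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  table$reads <- as.integer(round(table$reads))
  tibble::as_tibble(table)
}

#' Per-sample read totals
#'
#' Library-size totals per (recipient, lineage, replicate) sample.
#'
#' @param table Tidy count table.
#' @return Tibble (recipient, lineage, replicate, total).
#' @export
sample_totals <- function(table) {
  table |>
    dplyr::group_by(.data$recipient, .data$lineage, .data$replicate) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop")
}

#' Filter barcodes by read threshold and PCR-replicate concordance
#'
#' A barcode is retained in a (recipient, lineage) sample iff its reads summed
#' across PCR replicates reach `min_reads` (default 100; "below" the threshold
#' means strictly less, so a sum of exactly 100 is kept) and it is detected
#' (non-zero reads) in at least `min_replicates` replicates (default 2).
#' Entries failing either rule are removed from that sample; a barcode absent
#' from every sample afterwards disappears from the table. This is the only
#' detection rule applied before fate classification — strict filtering is
#' what guarantees the retained barcodes are legitimately clonal.
#'
#' @param table Tidy count table.
#' @param min_reads Minimum replicate-summed reads per sample (>= 0).
#' @param min_replicates Minimum replicates with non-zero reads (>= 1).
#' @return Filtered tidy count table, with a `filter_stats` attribute giving
#'   the number of (barcode, sample) pairs removed by each rule.
#' @export
filter_barcodes <- function(table, min_reads = 100, min_replicates = 2) {
  stopifnot(min_reads >= 0, min_replicates >= 1)
  table <- validate_counts(table)
  if (nrow(table) == 0) {
    return(structure(table, filter_stats = c(below_reads = 0L,
                                             below_replicates = 0L)))
  }
  flagged <- table |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::group_by(.data$barcode, .data$recipient, .data$lineage) |>
    dplyr::mutate(.sum = sum(.data$reads),
                  .nrep = sum(.data$reads > 0)) |>
    dplyr::ungroup()
  stats <- flagged |>
    dplyr::distinct(.data$barcode, .data$recipient, .data$lineage,
                    .data$.sum, .data$.nrep)
  kept <- flagged |>
    dplyr::filter(.data$.sum >= min_reads, .data$.nrep >= min_replicates) |>
    dplyr::select(-".sum", -".nrep")
  structure(
    kept,
    filter_stats = c(
      below_reads = sum(stats$.sum < min_reads),
      below_replicates = sum(stats$.sum >= min_reads &
                               stats$.nrep < min_replicates)
    )
  )
}

#' Normalize barcode reads to counts per million (CPM)
#'
#' CPM is computed per (recipient, lineage) sample with PCR replicates pooled:
#' `cpm = reads * 1e6 / sample_total`. Each non-empty sample's CPM values sum
#' to one million. Normalization is usually applied after filtering, on the
#' retained counts.
#'
#' @param table Tidy count table (filtered or not).
#' @return The table with a `cpm` column added.
#' @export
normalize_cpm <- function(table) {
  table <- validate_counts(table)
  if (nrow(table) == 0) {
    table$cpm <- numeric(0)
    return(table)
  }
  out <- table |>
    dplyr::group_by(.data$recipient, .data$lineage) |>
    dplyr::mutate(cpm = .data$reads * 1e6 / sum(.data$reads)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$cpm))) {
    warning("all-zero sample(s): CPM undefined, set to 0", call. = FALSE)
    out$cpm[!is.finite(out$cpm)] <- 0
  }
  out
}

#' Collapse PCR replicates
#'
#' Sums the replicate dimension out of a (typically filtered) count table.
#' CPM values, if present, are summed too — they were computed on the pooled
#' sample total, so the collapsed CPM is the barcode's sample CPM. The
#' operation is idempotent: a table without a replicate column is returned
#' unchanged.
#'
#' @param table Tidy count table.
#' @return Tibble (barcode, recipient, lineage, reads\[, cpm\]).
#' @export
collapse_replicates <- function(table) {
  if (!"replicate" %in% names(table)) return(tibble::as_tibble(table))
  has_cpm <- "cpm" %in% names(table)
  out <- table |>
    dplyr::group_by(.data$barcode, .data$recipient, .data$lineage) |>
    dplyr::summarise(
      reads = sum(.data$reads),
      dplyr::across(dplyr::any_of("cpm"), sum),
      .groups = "drop"
    )
  out
}
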