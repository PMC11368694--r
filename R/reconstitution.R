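#' Donor-derived reconstitution percentage
#'
#' Reconstitution % is the share of lineage-gated events carrying the donor
#' marker: `100 * donor_events / total_events`.
#'
#' @param donor_events Donor-marker-positive event counts.
#' @param total_events Lineage-gated event counts (> 0).
#' @return Percentages in \[0, 100\], vectorized.
#' @export
reconstitution_percent <- function(donor_events, total_events) {
  if (any(total_events <= 0)) {
    stop("total_events must be positive", call. = FALSE)
  }
  if (any(donor_events < 0) || any(donor_events > total_events)) {
    stop("need 0 <= donor_events <= total_events", call. = FALSE)
  }
  100 * donor_events / total_events
}

#' Call engraftment at a reconstitution threshold
#'
#' A recipient-lineage record is called engrafted when its donor
#' reconstitution percentage reaches the threshold (default 1%, the
#' conventional chimerism cut-off; the boundary counts as engrafted).
#'
#' @param records Data frame with columns `recipient`, `lineage`,
#'   `donor_events`, `total_events` (a `timepoint` column, if present, is
#'   carried through).
#' @param threshold_percent Engraftment threshold in percent (default 1).
#' @return The records with `percent` and `engrafted` columns added.
#' @export
call_engraftment <- function(records, threshold_percent = 1) {
  needed <- c("recipient", "lineage", "donor_events", "total_events")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  records$percent <- reconstitution_percent(records$donor_events,
                                            records$total_events)
  records$engrafted <- records$percent >= threshold_percent
  records
}

#' Fisher's exact test on engraftment outcomes of two groups
#'
#' Two-sided exact test on the 2x2 table of engrafted / not engrafted
#' recipients, as used for contingency analysis of reconstitution outcomes:
#' the p-value sums the hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one, and the odds
#' ratio is the conditional maximum-likelihood estimate.
#'
#' @param engrafted_a,total_a Engrafted and total recipients in group A.
#' @param engrafted_b,total_b Engrafted and total recipients in group B.
#' @return List with `p_value`, `odds_ratio` and the 2x2 `table`.
#' @examples
#' fisher_contingency(4, 4, 0, 6)
#' @export
fisher_contingency <- function(engrafted_a, total_a, engrafted_b, total_b) {
  for (v in list(c(engrafted_a, total_a), c(engrafted_b, total_b))) {
    if (v[2] < 1 || v[1] < 0 || v[1] > v[2]) {
      stop("need totals >= engrafted >= 0 and totals >= 1", call. = FALSE)
    }
  }
  tab <- matrix(c(engrafted_a, total_a - engrafted_a,
                  engrafted_b, total_b - engrafted_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("a", "b"),
                                outcome = c("engrafted", "not_engrafted")))
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Build a limiting-dilution table from engraftment calls
#'
#' Aggregates per-recipient engraftment calls into the (dose, tested,
#' responding) rows consumed by [estimate_frequency()]. A recipient responds
#' if it is engrafted in at least one of the designated readout lineages.
#'
#' @param calls Output of [call_engraftment()].
#' @param recipient_doses Data frame (recipient, dose) giving each
#'   recipient's transplanted cell dose.
#' @param lineages Readout lineage labels defining "responding"; `NULL`
#'   (default) uses every lineage present.
#' @return Tibble (dose, tested, responding), one row per dose.
#' @export
ld_table_from_calls <- function(calls, recipient_doses, lineages = NULL) {
  if (!all(c("recipient", "dose") %in% names(recipient_doses))) {
    stop("`recipient_doses` needs columns recipient and dose", call. = FALSE)
  }
  if (!is.null(lineages)) {
    calls <- dplyr::filter(calls, .data$lineage %in% lineages)
  }
  per_recipient <- calls |>
    dplyr::group_by(.data$recipient) |>
    dplyr::summarise(responding = any(.data$engrafted), .groups = "drop")
  recipient_doses |>
    dplyr::left_join(per_recipient, by = "recipient") |>
    dplyr::mutate(responding = !is.na(.data$responding) & .data$responding) |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(tested = dplyr::n(),
                     responding = sum(.data$responding), .groups = "drop") |>
    dplyr::arrange(.data$dose)
}
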