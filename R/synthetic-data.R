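#' Configuration for a simulated lentiviral barcoding experiment
#'
#' Defaults reproduce the design of the clonal-tracking experiments this
#' package analyses: a library of ~70,000 unique barcodes, at most 30,000
#' cells exposed at 1--2% transduction (so that barcode diversity exceeds the
#' expected clone count by >100-fold), clone expansion into the four tracked
#' lineages with subtype-specific fate probabilities, two PCR replicates per
#' lineage sample, and overdispersed (gamma-Poisson) sequencing counts.
#'
#' @param library_size Number of unique barcodes in the lentiviral library.
#' @param n_cells Number of cells exposed to the library.
#' @param transduction_rate Fraction of exposed cells transduced, in \[0, 1\].
#' @param n_recipients Number of transplant recipients the transduced cells
#'   are split across.
#' @param lineages Ordered lineage labels (default B, E, M, N).
#' @param fate_probabilities Named list mapping each cell-subtype label to a
#'   probability vector over the 15 non-empty lineage subsets (names must be
#'   `lineage_subsets(lineages)`); see [default_fate_probabilities()].
#' @param clone_output_mean Mean of the per-clone per-lineage output-cell
#'   distribution (arbitrary cell-equivalent units; only relative output
#'   within a sample matters for read allocation).
#' @param clone_output_dispersion Squared coefficient of variation of the
#'   gamma-distributed clone output; the marginal read counts are then
#'   negative binomial with this dispersion. Must be > 0.
#' @param depth_per_sample Expected sequencing reads per (recipient, lineage)
#'   sample, pooled over PCR replicates.
#' @param n_pcr_replicates Number of PCR replicates per sample (default 2).
#' @param replicate_dropout_rate Probability that a low-abundance barcode
#'   (below `dropout_read_ceiling` reads in a replicate) is missed in that
#'   replicate, mimicking stochastic PCR dropout.
#' @param dropout_read_ceiling Read count below which a replicate entry is
#'   eligible for stochastic dropout.
#' @param seed Single integer seed; all randomness flows from it.
#' @return A list of class `barcoding_sim_config`.
#' @export
barcoding_sim_config <- function(library_size = 70000,
                                 n_cells = 30000,
                                 transduction_rate = 0.02,
                                 n_recipients = 3,
                                 lineages = tracked_lineages(),
                                 fate_probabilities = default_fate_probabilities(),
                                 clone_output_mean = 1000,
                                 clone_output_dispersion = 0.5,
                                 depth_per_sample = 5e5,
                                 n_pcr_replicates = 2,
                                 replicate_dropout_rate = 0.05,
                                 dropout_read_ceiling = 100,
                                 seed = 1L) {
  check_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
      stop("invalid `", name, "`: must be a single integer >= ", min,
           call. = FALSE)
    }
  }
  check_prob <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
      stop("invalid `", name, "`: must be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  check_count(library_size, "library_size")
  check_count(n_cells, "n_cells", min = 0)
  check_prob(transduction_rate, "transduction_rate")
  check_count(n_recipients, "n_recipients")
  check_count(n_pcr_replicates, "n_pcr_replicates")
  check_prob(replicate_dropout_rate, "replicate_dropout_rate")
  for (nm in c("clone_output_mean", "depth_per_sample")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("invalid `", nm, "`: must be a single positive number",
           call. = FALSE)
    }
  }
  if (length(clone_output_dispersion) != 1 ||
      !is.finite(clone_output_dispersion) || clone_output_dispersion <= 0) {
    stop("invalid `clone_output_dispersion`: must be a single positive number",
         call. = FALSE)
  }
  if (n_cells * transduction_rate > library_size) {
    stop("invalid `transduction_rate`: expected transduced cells ",
         "(n_cells * transduction_rate) exceeds `library_size`",
         call. = FALSE)
  }
  subsets <- lineage_subsets(lineages)
  if (!is.list(fate_probabilities) || is.null(names(fate_probabilities))) {
    stop("invalid `fate_probabilities`: must be a named list of subset ",
         "probability vectors", call. = FALSE)
  }
  for (pop in names(fate_probabilities)) {
    p <- fate_probabilities[[pop]]
    if (!setequal(names(p), subsets)) {
      stop("invalid `fate_probabilities`: vector for '", pop,
           "' must be named by the ", length(subsets), " lineage subsets",
           call. = FALSE)
    }
    p <- p[subsets]
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("invalid `fate_probabilities`: vector for '", pop,
           "' must be non-negative and sum to 1 (+/- 1e-9)", call. = FALSE)
    }
    fate_probabilities[[pop]] <- p
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(library_size = as.integer(library_size),
         n_cells = as.integer(n_cells),
         transduction_rate = transduction_rate,
         n_recipients = as.integer(n_recipients),
         lineages = lineages,
         fate_probabilities = fate_probabilities,
         clone_output_mean = clone_output_mean,
         clone_output_dispersion = clone_output_dispersion,
         depth_per_sample = depth_per_sample,
         n_pcr_replicates = as.integer(n_pcr_replicates),
         replicate_dropout_rate = replicate_dropout_rate,
         dropout_read_ceiling = dropout_read_ceiling,
         seed = as.integer(seed)),
    class = "barcoding_sim_config"
  )
}

#' Default subtype fate-probability vectors
#'
#' Stylized fate-subset distributions for the five transplanted HSC/MPP
#' populations, shaped on the published clonal-fate histograms: the two HSC
#' subsets produce ~30% complete multi-outcome clones with the remainder
#' spread over restricted multi-outcome, erythro-myeloid and single-lineage
#' fates; iMPP2 places 86% of mass on single-lineage erythroid/myeloid fates;
#' iMPP3 is 68% single-lineage with ~30% restricted multi-outcome; iMPP4 is
#' B-cell biased. These are simulation defaults, not measured values.
#'
#' @param lineages Ordered lineage labels; only the default B/E/M/N set has
#'   built-in vectors.
#' @return Named list of probability vectors over [lineage_subsets()].
#' @export
default_fate_probabilities <- function(lineages = tracked_lineages()) {
  stopifnot(identical(lineages, c("B", "E", "M", "N")))
  mk <- function(...) {
    w <- c(...)
    p <- setNames(numeric(15), lineage_subsets(lineages))
    p[names(w)] <- w
    p / sum(p)
  }
  list(
    `iLT-HSC` = mk(BEMN = 0.30, BE = 0.08, BM = 0.08, BN = 0.06,
                   BEM = 0.06, BEN = 0.04, BMN = 0.05,
                   EM = 0.05, EMN = 0.05, MN = 0.06,
                   B = 0.07, E = 0.05, M = 0.03, N = 0.02),
    `iST-HSC` = mk(BEMN = 0.28, BE = 0.07, BM = 0.09, BN = 0.06,
                   BEM = 0.05, BEN = 0.04, BMN = 0.06,
                   EM = 0.05, EMN = 0.05, MN = 0.07,
                   B = 0.08, E = 0.05, M = 0.03, N = 0.02),
    iMPP2 = mk(E = 0.36, M = 0.30, N = 0.20, EM = 0.08, MN = 0.04,
               BM = 0.02),
    iMPP3 = mk(B = 0.25, M = 0.23, E = 0.20, BM = 0.14, BN = 0.08,
               BEM = 0.05, BE = 0.03, BEMN = 0.02),
    iMPP4 = mk(B = 0.45, M = 0.10, E = 0.05, N = 0.04, BE = 0.12,
               BM = 0.10, BN = 0.06, EM = 0.03, MN = 0.03, BEMN = 0.02)
  )
}

#' Simulate a lentiviral barcoding experiment
#'
#' Draws transduced cells binomially, assigns each a barcode uniformly with
#' replacement from the library (collisions possible, as in the real design
#' where a >100-fold diversity excess makes them rare), a recipient, and a
#' latent fate subset from the subtype's probability vector. Each clone's
#' per-lineage output is gamma-distributed; sequencing reads per (recipient,
#' lineage) sample are Poisson around depth-proportional expectations (so
#' marginally negative binomial), split multinomially across PCR replicates,
#' with stochastic dropout of low-count replicate entries. Lineage dropout
#' arises naturally when a clone's reads in a lineage fall to zero.
#'
#' @param config A [barcoding_sim_config()].
#' @param subtype Cell-subtype label; must name an entry of
#'   `config$fate_probabilities`.
#' @return A list with elements:
#'   \describe{
#'     \item{counts}{tidy tibble (barcode, recipient, lineage, replicate,
#'       reads) with only positive read counts;}
#'     \item{truth}{per-clone ground truth (clone_id, barcode, recipient,
#'       fate_subset, and `output_<lineage>` columns).}
#'   }
#' @export
simulate_barcoding_experiment <- function(config, subtype) {
  stopifnot(inherits(config, "barcoding_sim_config"))
  if (!subtype %in% names(config$fate_probabilities)) {
    stop("subtype '", subtype, "' has no entry in `fate_probabilities`",
         call. = FALSE)
  }
  set.seed(config$seed)
  lineages <- config$lineages
  subsets <- lineage_subsets(lineages)
  n_trans <- rbinom(1, config$n_cells, config$transduction_rate)

  empty_counts <- tibble::tibble(barcode = character(), recipient = character(),
                                 lineage = character(), replicate = character(),
                                 reads = integer())
  out_cols <- setNames(rep(list(numeric()), length(lineages)),
                       paste0("output_", lineages))
  empty_truth <- tibble::tibble(clone_id = character(), barcode = character(),
                                recipient = character(),
                                fate_subset = character(), !!!out_cols)
  if (n_trans == 0) {
    return(list(counts = empty_counts, truth = empty_truth))
  }

  width <- max(5, nchar(as.character(config$library_size)))
  barcode <- sprintf(paste0("bc%0", width, "d"),
                     sample.int(config$library_size, n_trans, replace = TRUE))
  recipient <- paste0("r", sample.int(config$n_recipients, n_trans,
                                      replace = TRUE))
  fate <- sample(subsets, n_trans, replace = TRUE,
                 prob = config$fate_probabilities[[subtype]])

  # gamma clone output per lineage in the fate subset (0 elsewhere)
  shape <- 1 / config$clone_output_dispersion
  output <- matrix(0, nrow = n_trans, ncol = length(lineages),
                   dimnames = list(NULL, lineages))
  in_set <- vapply(lineages, function(l) grepl(l, fate, fixed = TRUE),
                   logical(n_trans))
  in_set <- matrix(in_set, nrow = n_trans)
  n_active <- sum(in_set)
  output[in_set] <- rgamma(n_active, shape = shape,
                           scale = config$clone_output_mean / shape)

  truth <- tibble::tibble(
    clone_id = paste0(recipient, ":", barcode),
    barcode = barcode, recipient = recipient, fate_subset = fate
  )
  for (j in seq_along(lineages)) {
    truth[[paste0("output_", lineages[j])]] <- output[, j]
  }

  # reads per (recipient, lineage) sample: Poisson around depth-proportional
  # expectations, then multinomial split across replicates + dropout
  R <- config$n_pcr_replicates
  rows <- vector("list", config$n_recipients * length(lineages))
  k <- 0
  for (r in paste0("r", seq_len(config$n_recipients))) {
    idx <- which(recipient == r)
    if (length(idx) == 0) next
    for (j in seq_along(lineages)) {
      out_j <- output[idx, j]
      tot <- sum(out_j)
      if (tot <= 0) next
      lambda <- config$depth_per_sample * out_j / tot
      sample_reads <- rpois(length(idx), lambda)
      pos <- which(sample_reads > 0)
      if (length(pos) == 0) next
      rep_reads <- vapply(sample_reads[pos], function(n) {
        as.integer(rmultinom(1, n, rep(1 / R, R)))
      }, integer(R))
      rep_reads <- matrix(rep_reads, nrow = R)
      # stochastic dropout of low-count replicate entries
      low <- rep_reads > 0 & rep_reads < config$dropout_read_ceiling
      if (any(low) && config$replicate_dropout_rate > 0) {
        drop <- low & matrix(runif(length(rep_reads)) <
                               config$replicate_dropout_rate,
                             nrow = R)
        rep_reads[drop] <- 0L
      }
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        barcode = rep(barcode[idx][pos], each = R),
        recipient = r,
        lineage = lineages[j],
        replicate = rep(paste0("rep", seq_len(R)), times = length(pos)),
        reads = as.integer(rep_reads)
      )
    }
  }
  counts <- if (k == 0) empty_counts else dplyr::bind_rows(rows[seq_len(k)])
  counts <- dplyr::filter(counts, .data$reads > 0)
  # collapse barcode collisions within a (recipient, sample): indistinguishable
  counts <- counts |>
    dplyr::group_by(.data$barcode, .data$recipient, .data$lineage,
                    .data$replicate) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop")
  list(counts = counts, truth = truth)
}

#' Barcode-level ground-truth fate subsets
#'
#' Barcodes are drawn with replacement, so two transduced cells in the same
#' recipient can (rarely) share a barcode; any observer then sees one clone
#' whose lineage output is the union of both cells' fates. This helper
#' collapses the per-cell ground-truth table to that observable level: one
#' row per (recipient, barcode) with the union fate subset.
#'
#' @param truth Ground-truth table from [simulate_barcoding_experiment()].
#' @param lineages Ordered lineage labels.
#' @return Tibble (recipient, barcode, fate_subset).
#' @export
truth_fate_subsets <- function(truth, lineages = tracked_lineages()) {
  truth |>
    dplyr::group_by(.data$recipient, .data$barcode) |>
    dplyr::summarise(
      fate_subset = subset_code(unlist(subset_members(.data$fate_subset)),
                                lineages),
      .groups = "drop"
    )
}

#' Expected fold-excess of barcode diversity over clone numbers
#'
#' The library-design safety margin: unique barcodes divided by the expected
#' number of transduced cells. A large fold-excess (>100 in the design this
#' package emulates) makes repeat barcode use and hence clone mislabelling
#' unlikely.
#'
#' @param library_size Unique barcodes in the library.
#' @param n_cells Cells exposed to the library.
#' @param transduction_rate Transduction fraction.
#' @return Fold excess (dimensionless).
#' @examples
#' barcode_fold_excess(70000, 30000, 0.02) # 116.7
#' @export
barcode_fold_excess <- function(library_size, n_cells, transduction_rate) {
  expected_clones <- n_cells * transduction_rate
  if (expected_clones <= 0) stop("expected clone count must be positive")
  library_size / expected_clones
}

#' Expected number of barcode collisions (birthday problem)
#'
#' When `n_clones` cells each draw a barcode uniformly with replacement from
#' a library of `library_size`, the expected number of colliding pairs is
#' `choose(n_clones, 2) / library_size`.
#'
#' @param n_clones Number of transduced cells.
#' @param library_size Unique barcodes in the library.
#' @return Expected collision-pair count.
#' @examples
#' expected_barcode_collisions(600, 70000) # ~2.57
#' @export
expected_barcode_collisions <- function(n_clones, library_size) {
  choose(n_clones, 2) / library_size
}

#' Configuration for a simulated limiting-dilution experiment
#'
#' @param true_frequency Active (repopulating) cells per transplanted cell,
#'   in \[0, 1\]. Zero is allowed to model an inert population.
#' @param doses Vector of cell doses (positive integers).
#' @param recipients_per_dose Recipients tested at each dose (same length as
#'   `doses`, or length 1 and recycled).
#' @param detection_failure_rate Probability an engrafting unit is missed by
#'   the readout.
#' @param seed Integer seed.
#' @return A list of class `ld_sim_config`.
#' @export
ld_sim_config <- function(true_frequency,
                          doses = c(10, 50, 100, 1000),
                          recipients_per_dose = 5,
                          detection_failure_rate = 0,
                          seed = 1L) {
  if (length(true_frequency) != 1 || !is.finite(true_frequency) ||
      true_frequency < 0 || true_frequency > 1) {
    stop("invalid `true_frequency`: must be a single value in [0, 1]",
         call. = FALSE)
  }
  if (length(doses) < 1 || any(!is.finite(doses)) || any(doses < 1) ||
      any(doses != round(doses))) {
    stop("invalid `doses`: must be strictly positive integers", call. = FALSE)
  }
  if (length(recipients_per_dose) == 1) {
    recipients_per_dose <- rep(recipients_per_dose, length(doses))
  }
  if (length(recipients_per_dose) != length(doses) ||
      any(!is.finite(recipients_per_dose)) || any(recipients_per_dose < 1) ||
      any(recipients_per_dose != round(recipients_per_dose))) {
    stop("invalid `recipients_per_dose`: must be positive integers matching ",
         "`doses` in length", call. = FALSE)
  }
  if (length(detection_failure_rate) != 1 ||
      !is.finite(detection_failure_rate) || detection_failure_rate < 0 ||
      detection_failure_rate > 1) {
    stop("invalid `detection_failure_rate`: must be a single value in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(true_frequency = true_frequency,
         doses = as.integer(doses),
         recipients_per_dose = as.integer(recipients_per_dose),
         detection_failure_rate = detection_failure_rate,
         seed = as.integer(seed)),
    class = "ld_sim_config"
  )
}

#' Simulate a single-hit limiting-dilution experiment
#'
#' Per recipient at dose d, engrafting units are Poisson(true_frequency * d),
#' thinned binomially by the detection failure rate; the recipient responds
#' iff at least one unit survives. Returns the aggregated dose-response table
#' used by [estimate_frequency()].
#'
#' @param config An [ld_sim_config()].
#' @return Tibble with columns dose, tested, responding.
#' @export
simulate_limiting_dilution <- function(config) {
  stopifnot(inherits(config, "ld_sim_config"))
  set.seed(config$seed)
  f_eff <- config$true_frequency * (1 - config$detection_failure_rate)
  responding <- integer(length(config$doses))
  for (i in seq_along(config$doses)) {
    n <- config$recipients_per_dose[i]
    units <- rpois(n, config$true_frequency * config$doses[i])
    if (config$detection_failure_rate > 0) {
      units <- rbinom(n, units, 1 - config$detection_failure_rate)
    }
    responding[i] <- sum(units >= 1)
  }
  tibble::tibble(dose = config$doses,
                 tested = config$recipients_per_dose,
                 responding = responding)
}
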