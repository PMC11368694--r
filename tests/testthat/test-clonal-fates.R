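# Hand-enumerated expected classification of the 15 non-empty subsets,
# written out independently of the implementation's rule order.
expected_fate_map <- c(
  B = "single_lineage", E = "single_lineage", M = "single_lineage",
  N = "single_lineage",
  BE = "restricted_multi", BM = "restricted_multi", BN = "restricted_multi",
  EM = "erythro_myeloid_restricted", EN = "erythro_myeloid_restricted",
  MN = "myeloid_restricted",
  BEM = "restricted_multi", BEN = "restricted_multi", BMN = "restricted_multi",
  EMN = "erythro_myeloid_restricted",
  BEMN = "complete_multi"
)

test_that("fate classification is total and matches the taxonomy", {
  subsets <- lineage_subsets()
  got <- classify_fate(subsets)
  expect_false(anyNA(got))
  expect_identical(as.character(got), unname(expected_fate_map[subsets]))
  # partition sizes over the 15 subsets: 1 + 7 + 3 + 1 + 3... sanity via table
  expect_identical(as.integer(table(got)[fate_classes()]),
                   c(1L, 6L, 3L, 1L, 4L))
  expect_error(classify_fate(""), "undetected clone")
  expect_error(classify_fate("BX"), "undetected clone")
})

test_that("detected lineage sets mirror the surviving entries", {
  tbl <- tibble::tibble(
    barcode = c("a", "b", "b", "b", "b"), recipient = "r1",
    lineage = c("B", "B", "E", "M", "N"), reads = 500L
  )
  prof <- detect_lineages(normalize_cpm(tbl))
  expect_identical(prof$lineage_set[prof$barcode == "a"], "B")
  expect_identical(prof$lineage_set[prof$barcode == "b"], "BEMN")
  # same barcode in another recipient is another clone
  tbl2 <- dplyr::bind_rows(tbl, dplyr::mutate(tbl[1, ], recipient = "r2"))
  expect_identical(nrow(detect_lineages(normalize_cpm(tbl2))), 3L)
  expect_error(detect_lineages(make_tidy_counts()), "collapse replicates")
})

test_that("fate frequencies are exact fractions that sum to one", {
  prof <- tibble::tibble(
    clone_id = paste0("r1:bc", 1:10), recipient = "r1",
    barcode = paste0("bc", 1:10),
    lineage_set = c(rep("BEMN", 3), rep("MN", 7)), n_lineages = 2
  )
  s <- fate_frequency_table(prof, "toy")
  cls <- s$class_table
  expect_equal(cls$frequency[cls$class == "complete_multi"], 0.3)
  expect_equal(cls$frequency[cls$class == "myeloid_restricted"], 0.7)
  expect_equal(sum(cls$frequency), 1)
  expect_equal(sum(s$subset_table$frequency), 1)
  expect_identical(sum(cls$count), s$n_clones)
  expect_error(fate_frequency_table(prof[0, ]), "no clones")
})

test_that("similarity matrix is symmetric with unit diagonal", {
  one_hot <- function(pop, subset) {
    prof <- tibble::tibble(clone_id = paste0("r1:", 1:5), recipient = "r1",
                           barcode = paste0("bc", 1:5), lineage_set = subset,
                           n_lineages = nchar(subset))
    fate_frequency_table(prof, pop)
  }
  a <- one_hot("A", "B"); b <- one_hot("B2", "E"); c <- one_hot("C", "B")
  r <- fate_similarity_matrix(list(a, b, c))
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  # two one-hot 15-vectors on different subsets: Pearson r = -1/14
  expect_equal(r["A", "B2"], -1 / 14)
  expect_equal(r["A", "C"], 1)
  # permuting the populations permutes rows/columns consistently
  r2 <- fate_similarity_matrix(list(c, a, b))
  expect_equal(r2[c("A", "B2", "C"), c("A", "B2", "C")], r)
  # 5-class collapse is available
  r5 <- fate_similarity_matrix(list(a, b, c), on = "class")
  expect_identical(dim(r5), c(3L, 3L))
  expect_error(fate_similarity_matrix(list(a)), "at least two")
})

test_that("biomass shares sum to one and respect the class partition", {
  tbl <- tibble::tibble(
    barcode = c("a", "a", "b", "c"), recipient = "r1",
    lineage = c("B", "E", "M", "M"), reads = c(100L, 150L, 600L, 150L),
    cpm = c(250000, 375000, 1e6, 250000)
  )
  prof <- detect_lineages(tbl)
  by_lineage <- lineage_biomass(tbl, by = "lineage")
  expect_equal(sum(by_lineage$share), 1)
  by_class <- lineage_biomass(tbl, prof, by = "fate_class")
  by_subset <- lineage_biomass(tbl, prof, by = "subset")
  expect_equal(sum(by_class$share), 1)
  # merging subsets into their classes reproduces the per-class shares
  merged <- by_subset |>
    dplyr::mutate(class = as.character(classify_fate(group))) |>
    dplyr::group_by(class) |>
    dplyr::summarise(share = sum(share))
  expect_equal(
    dplyr::arrange(merged, class)$share,
    dplyr::arrange(by_class, group)$share
  )
  # one clone only -> share 1
  solo <- tbl[3, ]
  expect_equal(lineage_biomass(solo, by = "lineage")$share, 1)
  # 250k vs 750k split across two clones in different subsets -> 0.25 / 0.75
  duo <- tibble::tibble(barcode = c("x", "y"), recipient = "r1",
                        lineage = c("B", "E"), reads = c(1L, 3L),
                        cpm = c(250000, 750000))
  expect_equal(sort(lineage_biomass(duo, detect_lineages(duo),
                                    by = "subset")$share), c(0.25, 0.75))
  expect_error(lineage_biomass(dplyr::mutate(tbl, cpm = 0)), "zero total")
})

test_that("pipeline recovers a known single-lineage-heavy fate profile", {
  # fate vector massing 0.86 on singleton E/M/N subsets (the iMPP2 default)
  p <- default_fate_probabilities()$iMPP2
  single_mass <- sum(p[c("E", "M", "N")])
  expect_equal(single_mass, 0.86)
  cfg <- recovery_config(seed = 31, n_cells = 10000)
  sim <- simulate_barcoding_experiment(cfg, "iMPP2")
  prof <- run_clonal_pipeline(sim)
  s <- fate_frequency_table(prof, "iMPP2")
  got <- sum(s$class_table$frequency[s$class_table$class == "single_lineage"])
  n <- s$n_clones
  expect_gt(n, 150)
  expect_lt(abs(got - single_mass),
            3 * sqrt(single_mass * (1 - single_mass) / n))
})
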