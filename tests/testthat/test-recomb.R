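fixture_variants <- function() {
  fx <- wolbachia_complexes()
  cc <- find_clonal_complexes(build_slv_graph(fx$sts),
                              founder_hint = fx$founder_sts)
  extract_variants(cc, fx$sts, annotations = fx$annotations)
}

test_that("the published clonal-complex fixture yields 17 variant alleles", {
  v <- fixture_variants()
  expect_equal(nrow(v), 17)
  counts <- dplyr::count(v, classification, .drop = FALSE)
  expect_equal(counts$n[counts$classification == "unique_single"], 1L)
  expect_equal(counts$n[counts$classification == "nonunique_single"], 3L)
  expect_equal(counts$n[counts$classification == "double"], 2L)
  expect_equal(counts$n[counts$classification == "import"], 11L)
})

test_that("a variant allele is counted once per complex but across complexes", {
  fx <- wolbachia_complexes()
  cc <- find_clonal_complexes(build_slv_graph(fx$sts),
                              founder_hint = fx$founder_sts)
  v <- extract_variants(cc, fx$sts, annotations = fx$annotations)
  trmd6 <- v[v$locus == "trmD" & v$variant_allele == 6, ]
  # trmD allele 6 deviates in two complexes; within the first it is carried
  # by two member STs yet appears once
  expect_equal(nrow(trmd6), 2)
  expect_equal(sort(lengths(strsplit(trmd6$st_ids, ","))), c(1, 2))
})

test_that("complex members identical to the founder produce no variants", {
  loci <- c("A", "B")
  df <- tibble::tibble(st_id = 1:2, A = c(1L, 1L), B = c(1L, 2L),
                       frequency = c(3L, 1L))
  sts <- st_table_from_profiles(df, loci)
  cc <- find_clonal_complexes(build_slv_graph(sts))
  ann <- tibble::tibble(locus = "B", founder_allele = 1L,
                        variant_allele = 2L, n_diffs = 5L,
                        single_seen_elsewhere = NA,
                        allele_seen_elsewhere = NA)
  v <- extract_variants(cc, sts, annotations = ann)
  expect_equal(nrow(v), 1)
  expect_equal(as.character(v$classification), "import")
})

test_that("classification follows the diff-count and sharing rules", {
  base <- tibble::tibble(
    complex_id = "I", locus = "L", founder_allele = 1L,
    variant_allele = 2:6, st_ids = "1",
    n_diffs = c(1L, 1L, 2L, 3L, 9L),
    single_seen_elsewhere = c(FALSE, TRUE, NA, NA, NA),
    allele_seen_elsewhere = c(NA, NA, TRUE, NA, NA)
  )
  cls <- classify_variants(base)
  expect_equal(
    as.character(cls$classification),
    c("unique_single", "nonunique_single", "double", "import", "import")
  )
  # configurable import threshold
  cls5 <- classify_variants(base, import_threshold = 5)
  expect_equal(as.character(cls5$classification)[4], "double")
  # n_diffs = 0 violates the variant contract
  bad <- base; bad$n_diffs[1] <- 0L
  expect_error(classify_variants(bad), "n_diffs = 0")
})

test_that("strict and inclusive r:m ratios reproduce the fixture values", {
  est <- estimate_rm(fixture_variants())
  expect_equal(est$strict_num, 11L)
  expect_equal(est$strict_den, 1L)
  expect_equal(est$strict_ratio, 11)
  expect_equal(est$inclusive_num, 15L)
  expect_equal(est$inclusive_den, 2L)
  expect_equal(est$inclusive_ratio, 7.5)
  expect_equal(est$ratio_range, c(7.5, 11))
  g <- glance(est)
  expect_equal(g$ratio_low, 7.5)
  expect_equal(g$ratio_high, 11)
  expect_equal(sum(tidy(est)$n), est$n_variants)
})

test_that("ratio edge cases are reported, not crashed", {
  only_mut <- classify_variants(tibble::tibble(
    complex_id = "I", locus = "L", founder_allele = 1L,
    variant_allele = 2:4, st_ids = "1", n_diffs = 1L,
    single_seen_elsewhere = FALSE, allele_seen_elsewhere = NA
  ))
  est <- estimate_rm(only_mut)
  expect_equal(est$strict_ratio, 0)
  expect_equal(est$inclusive_ratio, 0)

  only_imp <- classify_variants(tibble::tibble(
    complex_id = "I", locus = "L", founder_allele = 1L,
    variant_allele = 2L, st_ids = "1", n_diffs = 6L,
    single_seen_elsewhere = NA, allele_seen_elsewhere = NA
  ))
  est2 <- estimate_rm(only_imp)
  expect_true(is.infinite(est2$strict_ratio))
  expect_false(est2$strict_defined)
})

test_that("adding imports/unique singles moves the ratios monotonically", {
  v <- fixture_variants()
  add_row <- function(v, n_diffs, seen = NA) {
    classify_variants(dplyr::bind_rows(
      tibble::as_tibble(v)[, setdiff(names(v), "classification")],
      tibble::tibble(complex_id = "Z", locus = "L", founder_allele = 1L,
                     variant_allele = 999L, st_ids = "999",
                     n_diffs = as.integer(n_diffs),
                     single_seen_elsewhere = seen,
                     allele_seen_elsewhere = NA)
    ))
  }
  base <- estimate_rm(v)
  plus_imp <- estimate_rm(add_row(v, 8))
  expect_gte(plus_imp$strict_ratio, base$strict_ratio)
  expect_gte(plus_imp$inclusive_ratio, base$inclusive_ratio)
  plus_mut <- estimate_rm(add_row(v, 1, seen = FALSE))
  expect_lte(plus_mut$strict_ratio, base$strict_ratio)
  expect_lte(plus_mut$inclusive_ratio, base$inclusive_ratio)
  # on the fixture composition the inclusive ratio sits below the strict
  expect_lte(base$inclusive_ratio, base$strict_ratio)
})

test_that("locus bias chi-square matches the closed form", {
  v <- fixture_variants()
  lb <- locus_bias_test(v, c("wsp", "ftsZ", "groEL", "trmD"))
  counts <- lb$counts[[1]]
  expect_equal(counts$n[counts$locus == "trmD"], 10L)
  expect_equal(counts$n[counts$locus == "wsp"], 3L)
  expect_equal(counts$n[counts$locus == "groEL"], 3L)
  expect_equal(counts$n[counts$locus == "ftsZ"], 1L)
  expect_equal(lb$statistic, 11, tolerance = 1e-12)
  expect_equal(lb$df, 3)
  expect_equal(lb$p_value, stats::pchisq(11, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  even <- tibble::tibble(locus = rep(c("A", "B"), each = 3))
  lb2 <- locus_bias_test(even, c("A", "B"))
  expect_equal(lb2$statistic, 0)
  expect_equal(lb2$p_value, 1)

  skew <- tibble::tibble(locus = rep("A", 5))
  lb3 <- locus_bias_test(skew, c("A", "B"))
  expect_equal(lb3$statistic, 5)
  expect_equal(lb3$df, 1)

  expect_error(locus_bias_test(tibble::tibble(locus = character()),
                               c("A", "B")), "no variant")
  expect_error(locus_bias_test(skew, "A"), ">= 2 loci")
})
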