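test_that("polymorphic matrix extracts variable columns and dot-masks", {
  aln <- make_aln(c("AAAA", "AATA", "AACA"), ids = c("r", "s", "t"))
  pm <- polymorphic_matrix(aln, reference = "r")
  expect_equal(pm$positions, 3)
  expect_equal(pm$rows$bases, c("A", "T", "C"))

  same <- make_aln(c("ACGT", "ACGT"), ids = c("a", "b"))
  pm2 <- polymorphic_matrix(same, reference = "a")
  expect_equal(length(pm2$positions), 0)

  expect_error(polymorphic_matrix(aln, reference = "nope"), "reference")
})

test_that("mosaic export and printing round-trip the site table", {
  aln <- make_aln(c("AAAAGG", "AATAGG", "AACACG"), ids = c("r", "s", "t"))
  pm <- polymorphic_matrix(aln, reference = "s")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_mosaic(pm, tmp)
  back <- readr::read_tsv(tmp, col_types = "cc")
  expect_equal(back$bases[1], paste(pm$positions, collapse = ","))
  expect_output(print(pm), "Polymorphic sites")
})

# deterministic triplet builders ---------------------------------------------

make_parents <- function(n_sites, len, seed) {
  set.seed(seed)
  a <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  b <- a
  pos <- sort(sample(len, n_sites))
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
  list(a = a, b = b, pos = pos)
}

test_that("a half-and-half mosaic is called at the splice point", {
  pp <- make_parents(24, 300, seed = 1)
  child <- pp$a
  splice_after <- pp$pos[12]
  child[(splice_after + 1):300] <- pp$b[(splice_after + 1):300]
  scan <- maxchi_breakpoints(
    paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
    paste(child, collapse = ""),
    n_permutations = 500, seed = 7
  )
  expect_false(scan$call$no_call)
  expect_lte(abs(scan$call$cut_index - 12), 2)
  expect_lte(scan$call$p_value, 0.01)
  # the reported column lies between the flanking informative sites
  expect_gte(scan$call$position, pp$pos[scan$call$cut_index])
  expect_lte(scan$call$position, pp$pos[scan$call$cut_index + 1])
})

test_that("a child identical to one parent gives no significant call", {
  pp <- make_parents(20, 250, seed = 2)
  scan <- maxchi_breakpoints(
    paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
    paste(pp$a, collapse = ""),
    n_permutations = 300, seed = 3
  )
  # no informative sites at all: child matches A everywhere
  expect_true(scan$call$no_call || scan$call$p_value > 0.05)
})

test_that("alternating parent matches give a near-zero statistic everywhere", {
  pp <- make_parents(20, 250, seed = 4)
  child <- pp$a
  child[pp$pos[seq(2, 20, 2)]] <- pp$b[pp$pos[seq(2, 20, 2)]]
  scan <- maxchi_breakpoints(
    paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
    paste(child, collapse = ""),
    n_permutations = 300, seed = 5
  )
  expect_false(scan$call$no_call)
  # perfectly interleaved: every 2x2 table is near-independent
  expect_lt(max(scan$profile$statistic), 5)
  expect_gt(scan$call$p_value, 0.05)
})

test_that("reversing the alignment mirrors the breakpoint", {
  pp <- make_parents(22, 280, seed = 6)
  child <- pp$a
  splice_after <- pp$pos[10]
  child[(splice_after + 1):280] <- pp$b[(splice_after + 1):280]
  fwd <- maxchi_breakpoints(
    paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
    paste(child, collapse = ""), n_permutations = 200, seed = 8
  )
  rev_str <- function(ch) paste(rev(ch), collapse = "")
  bwd <- maxchi_breakpoints(
    rev_str(pp$a), rev_str(pp$b), rev_str(child),
    n_permutations = 200, seed = 8
  )
  m <- fwd$call$n_informative
  expect_equal(bwd$call$n_informative, m)
  expect_lte(abs((m - bwd$call$cut_index) - fwd$call$cut_index), 1)
})

test_that("scans are reproducible under a fixed seed and flag thin data", {
  pp <- make_parents(20, 250, seed = 9)
  child <- pp$a
  child[pp$pos[11:20]] <- pp$b[pp$pos[11:20]]
  args <- list(paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
               paste(child, collapse = ""))
  s1 <- do.call(maxchi_breakpoints, c(args, n_permutations = 100, seed = 42))
  s2 <- do.call(maxchi_breakpoints, c(args, n_permutations = 100, seed = 42))
  expect_identical(s1$call, s2$call)

  thin <- maxchi_breakpoints("AAAA", "TTTT", "AATT",
                             min_sites_per_side = 3, n_permutations = 50)
  expect_true(thin$call$no_call)
  expect_equal(thin$call$n_informative, 4)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(12)
  pvals <- replicate(100, {
    pp <- make_parents(40, 300, seed = sample.int(1e6, 1))
    child <- pp$a
    swap <- pp$pos[stats::runif(40) < 0.5]
    child[swap] <- pp$b[swap]
    maxchi_breakpoints(
      paste(pp$a, collapse = ""), paste(pp$b, collapse = ""),
      paste(child, collapse = ""),
      n_permutations = 200, seed = sample.int(1e6, 1)
    )$call$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
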