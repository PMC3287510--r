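test_that("variable-site counting follows the >=2 distinct bases rule", {
  expect_equal(
    count_variable_sites(make_aln(c("ACGT", "ACGA")))$n_variable, 1)
  expect_equal(
    count_variable_sites(make_aln(c("ACGT", "ACGA")))$pct_variable, 25)
  expect_equal(
    count_variable_sites(make_aln(rep("ACGTACGT", 4)))$n_variable, 0)
  # gaps and N do not create variability
  expect_equal(
    count_variable_sites(make_aln(c("AC-T", "ACNT", "ACGT")))$n_variable, 0)
})

test_that("pi and max p-distance match hand-computable cases", {
  pair <- make_aln(c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(nucleotide_diversity(pair)$pi, 0.1)
  expect_equal(max_p_distance(pair)$max_p_pct, 10)
  same <- make_aln(rep("ACGTACGTAC", 5))
  expect_equal(nucleotide_diversity(same)$pi, 0)
  expect_equal(max_p_distance(same)$max_p_pct, 0)
  expect_error(nucleotide_diversity(make_aln("ACGT")), ">= 2")
})

test_that("pi equals the brute-force mean of all pairwise p-distances", {
  # four 12-bp sequences; oracle = direct average over the 6 pairs
  seqs <- c("ACGTACGTACGT", "ACGTACGTACGA", "ACGAACGTACGT", "TCGTACGTACGT")
  aln <- make_aln(seqs)
  mats <- strsplit(seqs, "")
  ps <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    ps <- c(ps, mean(mats[[i]] != mats[[j]]))
  }
  expect_equal(nucleotide_diversity(aln)$pi, mean(ps), tolerance = 1e-12)
  expect_equal(max_p_distance(aln)$max_p_pct, 100 * max(ps),
               tolerance = 1e-12)
})

test_that("pi and max p-distance agree with ape's pairwise-deletion raw distance", {
  set.seed(11)
  for (rep in 1:15) {
    aln <- random_aln(sample(3:10, 1), sample(10:50, 1),
                      p_gap = 0.05, p_n = 0.05)
    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(aln$seq), "")))
    d <- ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE)
    expect_equal(nucleotide_diversity(aln)$pi, mean(d), tolerance = 1e-12)
    expect_equal(max_p_distance(aln)$max_p_pct, 100 * max(d),
                 tolerance = 1e-12)
  }
})

test_that("pi is permutation-invariant and bounded by max p-distance", {
  set.seed(3)
  for (rep in 1:10) {
    aln <- random_aln(6, 30, p_gap = 0.02)
    pi1 <- nucleotide_diversity(aln)$pi
    pi2 <- nucleotide_diversity(aln[sample(6), ])$pi
    expect_equal(pi1, pi2, tolerance = 1e-12)
    expect_lte(pi1, max_p_distance(aln)$max_p_pct / 100 + 1e-12)
  }
})

test_that("potential synonymous sites match exhaustive single-base enumeration", {
  # independent oracle: enumerate the 9 single-base mutants directly
  oracle <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    chars <- strsplit(codon, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
        mut <- chars; mut[pos] <- b
        if (Biostrings::GENETIC_CODE[[paste(mut, collapse = "")]] == aa) {
          syn <- syn + 1
        }
      }
    }
    syn / 3
  }
  expect_equal(codon_syn_sites("TTT"), 1 / 3)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cd in sense) {
    expect_equal(codon_syn_sites(cd), oracle(cd), tolerance = 1e-12)
  }
  expect_error(codon_syn_sites("TAA"), "sense")
})

test_that("dN/dS behaves on degenerate and synonymous-only inputs", {
  # Phe -> Phe third-position change: purely synonymous, ratio 0
  aln <- make_aln(c("TTTAAAGGG", "TTCAAAGGG"))
  res <- nei_gojobori_dnds(aln)
  expect_equal(res$pn, 0)
  expect_gt(res$ps, 0)
  expect_equal(res$dnds, 0)

  ident <- make_aln(c("TTTAAAGGG", "TTTAAAGGG"))
  res2 <- nei_gojobori_dnds(ident)
  expect_equal(res2$ds, 0)
  expect_equal(res2$dn, 0)
  expect_true(is.na(res2$dnds))

  # internal stop codons are skipped with a warning
  expect_warning(nei_gojobori_dnds(make_aln(c("TTTTAAGGG", "TTCTAAGGG"))),
                 "stop")
})

test_that("potential site totals satisfy S + N = 3 x codons", {
  set.seed(5)
  for (rep in 1:8) {
    n_codons <- sample(3:10, 1)
    aln <- make_aln(vapply(1:4, function(i) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), n_codons * 3,
                          replace = TRUE), collapse = "")
        codons <- substring(s, seq(1, n_codons * 3, 3),
                            seq(3, n_codons * 3, 3))
        if (all(Biostrings::GENETIC_CODE[codons] != "*")) return(s)
      }
    }, character(1)))
    res <- nei_gojobori_dnds(aln)
    expect_equal(res$S + res$N, 3 * n_codons, tolerance = 1e-9)
  }
})

test_that("pathway counting is consistent for multi-position codon differences", {
  # sd + nd always equals the number of differing codon positions
  set.seed(31)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:40) {
    cds <- sample(sense, 2)
    d <- clonalrm:::codon_diff_counts(cds[1], cds[2])
    h <- sum(strsplit(cds[1], "")[[1]] != strsplit(cds[2], "")[[1]])
    expect_equal(unname(d["sd"] + d["nd"]), h, tolerance = 1e-12)
    # symmetric in the codon order
    d2 <- clonalrm:::codon_diff_counts(cds[2], cds[1])
    expect_equal(unname(d["sd"]), unname(d2["sd"]), tolerance = 1e-12)
  }
  # single synonymous difference
  d3 <- clonalrm:::codon_diff_counts("TTT", "TTC")
  expect_equal(unname(d3["sd"]), 1)
  expect_equal(unname(d3["nd"]), 0)
})

test_that("diversity summary assembles the per-locus panel", {
  aln <- dplyr::bind_rows(
    make_aln(c("TTTAAAGGGCCCATT", "TTCAAAGGGCCCATT", "TTTAAAGGGCCCATC"),
             locus = "genA"),
    make_aln(c("ACGTAC", "ACGTAC", "ATGTAC"), locus = "rrn")
  )
  tab <- diversity_summary(aln, coding = c(genA = TRUE, rrn = FALSE))
  expect_equal(tab$locus, c("genA", "rrn"))
  expect_equal(tab$size_bp, c(15L, 6L))
  expect_equal(tab$n_alleles, c(3L, 2L))
  expect_true(is.na(tab$dnds[2]))
  expect_false(is.na(tab$dnds[1]))
  expect_true(all(tab$pi >= 0 & tab$pi <= 1))
  expect_true(all(tab$variable_n <= tab$size_bp))
})
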