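#' Extract within-complex variant alleles
#'
#' For each ST within a clonal complex, each locus where the ST's allele
#' differs from the founding genotype's allele contributes a variant
#' allele.  A variant allele shared by several member STs of one complex is
#' counted once per complex; the same allele recurring in another complex
#' is counted again there.
#'
#' Nucleotide differences (`n_diffs`) between the variant and founder
#' alleles are computed column-wise, excluding columns where either allele
#' carries a gap, `N` or ambiguity code.  Two sharing flags are computed
#' against the full dataset:
#' \describe{
#'   \item{`single_seen_elsewhere`}{for 1-diff variants: the identical
#'     polymorphism (same column, same derived base) occurs in at least one
#'     other allele at this locus.}
#'   \item{`allele_seen_elsewhere`}{for 2-diff variants: the identical
#'     allele is carried by at least one ST outside this complex.}
#' }
#'
#' Alternatively, for fixture data without sequences, `annotations` may
#' supply `n_diffs` and the flags directly, keyed by
#' (`locus`, `founder_allele`, `variant_allele`).
#'
#' @param cc A `clonal_complexes` object.
#' @param sts The `st_tbl` the complexes were built from.
#' @param calls Allele calls with sequences ([call_alleles()] output), or
#'   `NULL` when `annotations` is given.
#' @param annotations Optional tibble with columns `locus`,
#'   `founder_allele`, `variant_allele`, `n_diffs`,
#'   `single_seen_elsewhere`, `allele_seen_elsewhere`.
#' @param import_threshold Passed to [classify_variants()].
#' @return A tibble of class `variant_tbl`: one row per
#'   (complex, locus, variant allele) with columns `complex_id`, `locus`,
#'   `founder_allele`, `variant_allele`, `st_ids` (comma-joined carrying
#'   STs), `n_diffs`, both flags, and `classification` (see
#'   [classify_variants()]).
#' @export
extract_variants <- function(cc, sts, calls = NULL, annotations = NULL,
                             import_threshold = 3) {
  locus_order <- cc$graph$locus_order
  prof <- as_tibble(sts)[, c("st_id", locus_order)]
  if (nrow(cc$complexes) == 0) {
    return(new_variant_tbl(empty_variants()))
  }
  rows <- purrr::list_rbind(purrr::pmap(
    cc$complexes[, c("complex_id", "founder_st_id", "members")],
    function(complex_id, founder_st_id, members) {
      founder <- prof[prof$st_id == founder_st_id, locus_order]
      if (anyNA(founder) || nrow(founder) == 0) {
        stop("founder ST ", founder_st_id, " lacks an allele at >=1 locus",
             call. = FALSE)
      }
      purrr::list_rbind(purrr::map(setdiff(members, founder_st_id),
        function(st) {
          p <- prof[prof$st_id == st, locus_order]
          dev <- locus_order[unlist(p) != unlist(founder)]
          purrr::list_rbind(purrr::map(dev, function(loc) {
            tibble(
              complex_id = complex_id, st_id = st, locus = loc,
              founder_allele = founder[[loc]], variant_allele = p[[loc]]
            )
          }))
        }))
    }
  ))
  if (nrow(rows) == 0) {
    return(new_variant_tbl(empty_variants()))
  }
  # de-duplicate per complex, keep the carrying STs
  variants <- rows |>
    dplyr::group_by(.data$complex_id, .data$locus,
                    .data$founder_allele, .data$variant_allele) |>
    dplyr::summarise(st_ids = paste(sort(.data$st_id), collapse = ","),
                     .groups = "drop")

  if (!is.null(calls)) {
    variants <- annotate_variants_from_sequences(variants, cc, sts, calls)
  } else if (!is.null(annotations)) {
    ann <- as_tibble(annotations) |>
      dplyr::distinct(.data$locus, .data$founder_allele,
                      .data$variant_allele, .keep_all = TRUE) |>
      dplyr::select("locus", "founder_allele", "variant_allele", "n_diffs",
                    "single_seen_elsewhere", "allele_seen_elsewhere")
    variants <- variants |>
      dplyr::left_join(ann, by = c("locus", "founder_allele",
                                   "variant_allele"))
    if (anyNA(variants$n_diffs)) {
      stop("annotations missing for some (locus, founder, variant) triples",
           call. = FALSE)
    }
  } else {
    stop("supply either 'calls' (sequences) or 'annotations'", call. = FALSE)
  }
  classify_variants(new_variant_tbl(variants), import_threshold)
}

empty_variants <- function() {
  tibble(
    complex_id = character(), locus = character(),
    founder_allele = integer(), variant_allele = integer(),
    st_ids = character(), n_diffs = integer(),
    single_seen_elsewhere = logical(), allele_seen_elsewhere = logical()
  )
}

new_variant_tbl <- function(x) {
  structure(x, class = c("variant_tbl", class(tibble())))
}

annotate_variants_from_sequences <- function(variants, cc, sts, calls) {
  alleles <- allele_sequences(calls)
  seq_of <- function(loc, id) {
    s <- alleles$seq[alleles$locus == loc & alleles$allele_id == id]
    if (length(s) != 1) {
      stop("allele ", id, " at locus '", loc, "' not found in calls",
           call. = FALSE)
    }
    s
  }
  assign_st <- st_assignments(sts)
  members_of <- stats::setNames(cc$complexes$members, cc$complexes$complex_id)
  locus_order <- cc$graph$locus_order
  prof <- as_tibble(sts)[, c("st_id", locus_order)]

  ann <- purrr::pmap(variants, function(complex_id, locus, founder_allele,
                                        variant_allele, st_ids) {
    f <- strsplit(seq_of(locus, founder_allele), "")[[1]]
    v <- strsplit(seq_of(locus, variant_allele), "")[[1]]
    ok <- f %in% .DNA_BASES & v %in% .DNA_BASES
    diff_cols <- which(ok & f != v)
    n_diffs <- length(diff_cols)
    single_seen <- NA
    allele_seen <- NA
    if (n_diffs == 1) {
      col <- diff_cols[1]
      derived <- v[col]
      others <- alleles[alleles$locus == locus &
                          alleles$allele_id != variant_allele, ]
      single_seen <- any(substring(others$seq, col, col) == derived)
    }
    if (n_diffs == 2) {
      outside_sts <- setdiff(prof$st_id, members_of[[complex_id]])
      carriers <- prof$st_id[prof[[locus]] == variant_allele]
      allele_seen <- length(intersect(carriers, outside_sts)) > 0
    }
    tibble(n_diffs = n_diffs,
           single_seen_elsewhere = single_seen,
           allele_seen_elsewhere = allele_seen)
  })
  dplyr::bind_cols(variants, purrr::list_rbind(ann))
}

#' Classify variant alleles as mutation- or recombination-derived
#'
#' Classification rules, applied to each within-complex variant allele:
#' \itemize{
#'   \item 1 nucleotide difference, polymorphism not seen elsewhere:
#'     `unique_single` (de novo point mutation);
#'   \item 1 difference, same polymorphism in another allele:
#'     `nonunique_single` (recombination under the inclusive rule);
#'   \item 2 differences: `double` (ambiguous; assigned by whether the
#'     allele recurs outside the complex, inclusive rule only);
#'   \item `import_threshold` or more differences: `import`
#'     (putative recombinational allele import).
#' }
#'
#' @param variants A `variant_tbl` (or tibble with `n_diffs` and the two
#'   sharing flags).
#' @param import_threshold Minimum diff count for `import` (default 3).
#' @return The input with a `classification` factor column.
#' @export
classify_variants <- function(variants, import_threshold = 3) {
  stopifnot(import_threshold >= 3)
  if (any(variants$n_diffs < 1)) {
    stop("variant with n_diffs = 0: not a variant allele", call. = FALSE)
  }
  cls <- dplyr::case_when(
    variants$n_diffs == 1 & !variants$single_seen_elsewhere ~ "unique_single",
    variants$n_diffs == 1 & variants$single_seen_elsewhere ~ "nonunique_single",
    variants$n_diffs >= import_threshold ~ "import",
    TRUE ~ "double"
  )
  variants$classification <- factor(
    cls, levels = c("unique_single", "nonunique_single", "double", "import")
  )
  new_variant_tbl(variants)
}

#' Estimate the recombination:mutation ratio from classified variants
#'
#' Two estimates of how many times more often new alleles arise by
#' recombination than point mutation during clonal diversification:
#' \describe{
#'   \item{strict}{imports : unique single changes, ignoring non-unique
#'     singles and 2-diff variants entirely.}
#'   \item{inclusive}{(imports + non-unique singles + 2-diff variants seen
#'     elsewhere) : (unique singles + 2-diff variants not seen elsewhere).}
#' }
#'
#' @param variants A classified `variant_tbl`.
#' @return Object of class `rm_estimate`: list with `counts` (tibble per
#'   classification), `n_variants`, `strict_ratio`, `inclusive_ratio`,
#'   `ratio_range` (sorted low/high), and the numerator/denominator pairs.
#'   A zero mutation denominator yields `Inf` with `defined = FALSE` for
#'   that rule; zero imports over a positive denominator yield 0.
#' @export
estimate_rm <- function(variants) {
  if (nrow(variants) == 0) stop("no variant alleles", call. = FALSE)
  counts <- variants |>
    dplyr::count(.data$classification, .drop = FALSE, name = "n")
  n_of <- function(cl) counts$n[counts$classification == cl]
  n_imp <- n_of("import")
  n_uni <- n_of("unique_single")
  n_non <- n_of("nonunique_single")
  doubles <- variants[variants$classification == "double", ]
  n_dbl_seen <- sum(doubles$allele_seen_elsewhere, na.rm = TRUE)
  n_dbl_unseen <- nrow(doubles) - n_dbl_seen

  ratio <- function(num, den) {
    if (den == 0) {
      if (num == 0) NA_real_ else Inf
    } else {
      num / den
    }
  }
  strict <- ratio(n_imp, n_uni)
  inclusive <- ratio(n_imp + n_non + n_dbl_seen, n_uni + n_dbl_unseen)
  rng <- sort(c(strict, inclusive), na.last = TRUE)
  structure(
    list(
      counts = counts,
      n_variants = nrow(variants),
      strict_num = n_imp, strict_den = n_uni,
      inclusive_num = n_imp + n_non + n_dbl_seen,
      inclusive_den = n_uni + n_dbl_unseen,
      strict_ratio = strict,
      inclusive_ratio = inclusive,
      ratio_range = rng,
      strict_defined = is.finite(strict) || n_imp == 0,
      inclusive_defined = is.finite(inclusive)
    ),
    class = "rm_estimate"
  )
}

#' @export
print.rm_estimate <- function(x, ...) {
  cat("Recombination:mutation ratio estimate\n")
  cat(sprintf("  %d variant alleles: %s\n", x$n_variants,
              paste(sprintf("%s=%d", x$counts$classification, x$counts$n),
                    collapse = ", ")))
  fmt <- function(r, num, den) {
    if (is.na(r)) "undefined (no events)" else if (is.infinite(r))
      sprintf("%d:0 (undefined, no mutational events)", num) else
      sprintf("%d:%d = %.3g", num, den, r)
  }
  cat("  strict    (imports : unique singles)            ",
      fmt(x$strict_ratio, x$strict_num, x$strict_den), "\n")
  cat("  inclusive (+ non-unique singles, shared doubles)",
      fmt(x$inclusive_ratio, x$inclusive_num, x$inclusive_den), "\n")
  invisible(x)
}

#' Chi-square test for uneven distribution of variant alleles across loci
#'
#' Goodness-of-fit of the observed per-locus variant-allele counts against
#' a uniform expectation over the loci (no continuity correction;
#' df = L - 1).
#'
#' @param variants A `variant_tbl`.
#' @param loci Character vector of all loci (including any with zero
#'   variants); default: the loci present in `variants`.
#' @return Tibble `statistic`, `df`, `p_value`, plus the per-locus counts
#'   as a list column `counts`.
#' @export
locus_bias_test <- function(variants, loci = NULL) {
  loci <- loci %||% unique(variants$locus)
  if (length(loci) < 2) stop("need >= 2 loci", call. = FALSE)
  obs <- vapply(loci, function(l) sum(variants$locus == l), numeric(1))
  if (sum(obs) == 0) stop("no variant alleles at any locus", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    counts = list(tibble(locus = loci, n = as.integer(obs)))
  )
}

#' Write the classified variants table as TSV
#'
#' @param variants A `variant_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(as_tibble(variants), path)
  invisible(path)
}
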