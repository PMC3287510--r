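#' Count variable sites per locus
#'
#' A site is variable when at least two distinct unambiguous bases
#' (`A`/`C`/`G`/`T`) occur among the sequences at that alignment column;
#' gaps, `N` and ambiguity codes do not create variability.
#'
#' @param aln Long alignment tibble (`locus`, `isolate`, `seq`).
#' @return Tibble `locus`, `n_variable`, `pct_variable`
#'   (`100 * n_variable / length`).
#' @export
count_variable_sites <- function(aln) {
  aln <- as_locus_alignment(aln)
  purrr::list_rbind(purrr::map(unique(aln$locus), function(loc) {
    m <- aln_matrix(aln[aln$locus == loc, ])
    var <- apply(m, 2, function(col) {
      length(unique(col[col %in% .DNA_BASES])) >= 2
    })
    tibble(
      locus = loc,
      n_variable = sum(var),
      pct_variable = 100 * sum(var) / ncol(m)
    )
  }))
}

# Pairwise p-distances with pairwise deletion: columns where either member
# of the pair has a gap, N or ambiguity code are dropped for that pair only.
# Returns a tibble of all unordered pairs with p (proportion) and the number
# of compared sites.
pairwise_p_distances <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need >= 2 sequences for pairwise distances", call. = FALSE)
  valid <- matrix(m %in% .DNA_BASES, nrow = n)
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ok <- valid[i, ] & valid[j, ]
    n_sites <- sum(ok)
    p <- if (n_sites == 0) NA_real_ else sum(m[i, ok] != m[j, ok]) / n_sites
    c(p = p, n_sites = n_sites)
  })
  tibble(
    seq_a = rownames(m)[pairs[1, ]],
    seq_b = rownames(m)[pairs[2, ]],
    p = res["p", ],
    n_sites = as.integer(res["n_sites", ])
  )
}

#' Nucleotide diversity (pi) per locus
#'
#' Mean over all unordered sequence pairs of the pairwise p-distance
#' (differences over compared sites, pairwise deletion of columns with a
#' gap, `N` or ambiguity code in either member).  Computed over all isolate
#' sequences, not one per allele.
#'
#' @param aln Long alignment tibble; each locus needs at least 2 sequences.
#' @return Tibble `locus`, `pi`, `n_seq`.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_locus_alignment(aln)
  purrr::list_rbind(purrr::map(unique(aln$locus), function(loc) {
    m <- aln_matrix(aln[aln$locus == loc, ])
    pd <- pairwise_p_distances(m)
    tibble(locus = loc, pi = mean(pd$p, na.rm = TRUE), n_seq = nrow(m))
  }))
}

#' Maximum pairwise p-distance per locus, in percent
#'
#' @inheritParams nucleotide_diversity
#' @return Tibble `locus`, `max_p_pct`.
#' @export
max_p_distance <- function(aln) {
  aln <- as_locus_alignment(aln)
  purrr::list_rbind(purrr::map(unique(aln$locus), function(loc) {
    m <- aln_matrix(aln[aln$locus == loc, ])
    pd <- pairwise_p_distances(m)
    tibble(locus = loc, max_p_pct = 100 * max(pd$p, na.rm = TRUE))
  }))
}

# ---- Nei-Gojobori (1986) dN/dS ---------------------------------------------

.codon_cache <- new.env(parent = emptyenv())

genetic_code_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Potential synonymous sites of a codon (Nei-Gojobori)
#'
#' For each codon position, the fraction of the three possible single-base
#' changes that preserve the encoded amino acid; summed over the three
#' positions.  Changes to stop codons count as nonsynonymous.  `TTT` gives
#' 1/3 (only the third-position change to `TTC` is synonymous).
#'
#' @param codon Three-letter codon string over `A`,`C`,`G`,`T`.
#' @return Number of potential synonymous sites (0..3); the nonsynonymous
#'   complement is `3 - s`.
#' @export
codon_syn_sites <- function(codon) {
  key <- paste0("s_", codon)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  aa <- genetic_code_aa(codon)
  if (is.na(aa) || aa == "*") {
    stop("codon_syn_sites: '", codon, "' is not a sense codon", call. = FALSE)
  }
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(.DNA_BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      mut_aa <- genetic_code_aa(paste(mut, collapse = ""))
      if (!is.na(mut_aa) && mut_aa == aa) s <- s + 1 / 3
    }
  }
  .codon_cache[[key]] <- s
  s
}

# Synonymous / nonsynonymous differences between two codons, averaging over
# all orderings of the differing positions (equal pathway weighting).
# Pathways passing through a stop codon are excluded; if every pathway is
# blocked, all are used.
codon_diff_counts <- function(c1, c2) {
  key <- paste0("d_", c1, "_", c2)
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  if (length(diff_pos) == 0) {
    out <- c(sd = 0, nd = 0)
    .codon_cache[[key]] <- out
    return(out)
  }
  perms <- if (length(diff_pos) == 1) list(diff_pos) else {
    idx <- seq_along(diff_pos)
    ords <- if (length(idx) == 2) list(c(1, 2), c(2, 1)) else {
      # all 6 orderings of 3 positions
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    }
    lapply(ords, function(o) diff_pos[o])
  }
  paths <- lapply(perms, function(order) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- genetic_code_aa(paste(cur, collapse = ""))
      aa2 <- genetic_code_aa(paste(nxt, collapse = ""))
      if (aa2 == "*" || aa1 == "*") blocked <- TRUE
      if (identical(aa1, aa2)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open) > 0) open else paths
  out <- c(
    sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd"))
  )
  .codon_cache[[key]] <- out
  out
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori dN/dS per locus
#'
#' Pairwise synonymous/nonsynonymous proportions by the Nei-Gojobori (1986)
#' counting method with equal pathway weighting for codons differing at more
#' than one position, averaged over all sequence pairs, Jukes-Cantor
#' corrected before taking the ratio.  Codons containing a gap, `N`,
#' ambiguity code, or a stop in either member of a pair are skipped for that
#' pair (internal stop codons raise a warning).
#'
#' @param aln Long alignment tibble of coding sequences.
#' @param frame_offset 0-based reading-frame offset (single value or named
#'   by locus); `(length - frame_offset)` must be at least 3.
#' @return Tibble with one row per locus: `locus`, `n_codons`, `S`, `N`
#'   (mean potential sites per pair), `ps`, `pn` (mean proportions), `ds`,
#'   `dn` (Jukes-Cantor corrected), `dnds` (`NA` when `ds` is 0 or
#'   undefined).
#' @export
nei_gojobori_dnds <- function(aln, frame_offset = 0) {
  aln <- as_locus_alignment(aln)
  loci <- unique(aln$locus)
  offsets <- if (length(frame_offset) == 1 && is.null(names(frame_offset))) {
    stats::setNames(rep(frame_offset, length(loci)), loci)
  } else {
    stats::setNames(frame_offset[loci], loci)
  }
  purrr::list_rbind(purrr::map(loci, function(loc) {
    sub <- aln[aln$locus == loc, ]
    off <- offsets[[loc]]
    len <- nchar(sub$seq[1])
    if (len - off < 3) {
      stop("locus '", loc, "': fewer than one codon after frame offset",
           call. = FALSE)
    }
    n_codons <- (len - off) %/% 3
    starts <- off + 1 + 3 * (0:(n_codons - 1))
    codons <- lapply(sub$seq, function(s) {
      substring(s, starts, starts + 2)
    })
    n <- length(codons)
    if (n < 2) stop("locus '", loc, "': need >= 2 sequences", call. = FALSE)
    sense <- function(cd) {
      grepl("^[ACGT]{3}$", cd) & genetic_code_aa(ifelse(
        grepl("^[ACGT]{3}$", cd), cd, "AAA")) != "*"
    }
    has_stop <- any(vapply(codons, function(cs) {
      any(grepl("^[ACGT]{3}$", cs) & genetic_code_aa(
        ifelse(grepl("^[ACGT]{3}$", cs), cs, "AAA")) == "*")
    }, logical(1)))
    if (has_stop) {
      warning("locus '", loc, "': internal stop codon(s) skipped",
              call. = FALSE)
    }
    pairs <- utils::combn(n, 2)
    acc <- apply(pairs, 2, function(ij) {
      c1 <- codons[[ij[1]]]
      c2 <- codons[[ij[2]]]
      use <- sense(c1) & sense(c2)
      if (!any(use)) return(c(S = NA, N = NA, ps = NA, pn = NA))
      S <- 0; N <- 0; Sd <- 0; Nd <- 0
      for (k in which(use)) {
        s_k <- (codon_syn_sites(c1[k]) + codon_syn_sites(c2[k])) / 2
        S <- S + s_k
        N <- N + (3 - s_k)
        d <- codon_diff_counts(c1[k], c2[k])
        Sd <- Sd + unname(d[["sd"]])
        Nd <- Nd + unname(d[["nd"]])
      }
      c(S = S, N = N, ps = Sd / S, pn = Nd / N)
    })
    ps <- mean(acc["ps", ], na.rm = TRUE)
    pn <- mean(acc["pn", ], na.rm = TRUE)
    ds <- jukes_cantor(ps)
    dn <- jukes_cantor(pn)
    dnds <- if (is.na(ds) || is.na(dn) || ds == 0) NA_real_ else dn / ds
    tibble(
      locus = loc, n_codons = n_codons,
      S = mean(acc["S", ], na.rm = TRUE),
      N = mean(acc["N", ], na.rm = TRUE),
      ps = ps, pn = pn, ds = ds, dn = dn, dnds = dnds
    )
  }))
}

#' Per-locus diversity summary table
#'
#' One row per locus with the classical MLST diversity panel: alignment
#' length, allele count, variable sites (count and percent), nucleotide
#' diversity, maximum p-distance (percent), and Nei-Gojobori dN/dS for
#' coding loci.
#'
#' @param aln Long alignment tibble.
#' @param coding Logical, single value or named by locus: compute dN/dS for
#'   this locus?  Non-coding loci (e.g. 16S rDNA) get `NA`.
#' @param frame_offset Passed to [nei_gojobori_dnds()].
#' @return Tibble `locus`, `size_bp`, `n_alleles`, `variable_n`,
#'   `variable_pct`, `pi`, `max_p_pct`, `dnds`.
#' @export
diversity_summary <- function(aln, coding = TRUE, frame_offset = 0) {
  aln <- as_locus_alignment(aln)
  loci <- unique(aln$locus)
  coding_by <- if (length(coding) == 1 && is.null(names(coding))) {
    stats::setNames(rep(coding, length(loci)), loci)
  } else {
    stats::setNames(as.logical(coding[loci]), loci)
  }
  calls <- call_alleles(aln)
  lens <- alignment_lengths(aln)
  n_all <- allele_sequences(calls) |>
    dplyr::count(.data$locus, name = "n_alleles")
  vs <- count_variable_sites(aln)
  pi_tbl <- nucleotide_diversity(aln)
  mp <- max_p_distance(aln)
  coding_loci <- loci[coding_by[loci]]
  dnds_tbl <- if (length(coding_loci) > 0) {
    nei_gojobori_dnds(aln[aln$locus %in% coding_loci, ], frame_offset) |>
      dplyr::select("locus", "dnds")
  } else {
    tibble(locus = character(), dnds = numeric())
  }
  lens |>
    dplyr::left_join(n_all, by = "locus") |>
    dplyr::left_join(vs, by = "locus") |>
    dplyr::left_join(pi_tbl |> dplyr::select("locus", "pi"), by = "locus") |>
    dplyr::left_join(mp, by = "locus") |>
    dplyr::left_join(dnds_tbl, by = "locus") |>
    dplyr::transmute(
      locus = .data$locus,
      size_bp = .data$length_bp,
      n_alleles = .data$n_alleles,
      variable_n = .data$n_variable,
      variable_pct = .data$pct_variable,
      pi = .data$pi,
      max_p_pct = .data$max_p_pct,
      dnds = .data$dnds
    ) |>
    dplyr::slice(match(loci, .data$locus))
}
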