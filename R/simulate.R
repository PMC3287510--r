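#' Configuration for the clonal-diversification simulator
#'
#' @param n_loci Number of loci (default 4, as in a typical endosymbiont
#'   MLST panel).
#' @param locus_length_bp Alignment length per locus; single value or
#'   vector of length `n_loci` (default 500).
#' @param n_founders Number of founding genotypes (default 2).
#' @param n_isolates Number of sampled isolates (default 60).
#' @param mutation_events_mean Expected de novo point mutations per isolate
#'   lineage (Poisson; default 0.05).
#' @param import_events_mean Expected recombinational allele imports per
#'   isolate lineage (Poisson; default 0.5).
#' @param import_divergence_nt Nucleotide differences between an imported
#'   donor allele and the founder allele it replaces (default 6; must be
#'   >= 3 so imports are recognizable, and < the locus length).
#' @param donor_pool_size Distinct donor alleles per (founder, locus)
#'   available for import (default 8).
#' @param founder_divergence_nt Differences between successive founder
#'   alleles at each locus (default 25), keeping founders well separated.
#' @param seed Integer random seed (required for reproducibility).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 4, locus_length_bp = 500, n_founders = 2,
                       n_isolates = 60, mutation_events_mean = 0.05,
                       import_events_mean = 0.5, import_divergence_nt = 6,
                       donor_pool_size = 8, founder_divergence_nt = 25,
                       seed = 1) {
  cfg <- list(
    n_loci = as.integer(n_loci),
    locus_length_bp = rep_len(as.integer(locus_length_bp), n_loci),
    n_founders = as.integer(n_founders),
    n_isolates = as.integer(n_isolates),
    mutation_events_mean = mutation_events_mean,
    import_events_mean = import_events_mean,
    import_divergence_nt = as.integer(import_divergence_nt),
    donor_pool_size = as.integer(donor_pool_size),
    founder_divergence_nt = as.integer(founder_divergence_nt),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_loci < 1 || n_founders < 1 || n_isolates < 1 ||
        donor_pool_size < 1) {
      stop("all counts must be positive", call. = FALSE)
    }
    if (mutation_events_mean < 0 || import_events_mean < 0) {
      stop("event means must be non-negative", call. = FALSE)
    }
    if (import_divergence_nt < 3) {
      stop("import_divergence_nt must be >= 3 (imports must be ",
           "distinguishable from point mutations)", call. = FALSE)
    }
    if (any(import_divergence_nt >= locus_length_bp) ||
        any(founder_divergence_nt >= locus_length_bp)) {
      stop("divergence must be smaller than the locus length", call. = FALSE)
    }
  })
  structure(cfg, class = "sim_config")
}

random_seq <- function(len) {
  sample(.DNA_BASES, len, replace = TRUE)
}

mutate_sites <- function(seq_chars, sites) {
  for (s in sites) {
    seq_chars[s] <- sample(setdiff(.DNA_BASES, seq_chars[s]), 1)
  }
  seq_chars
}

#' Simulate clonal diversification with mutation and allele import
#'
#' Forward simulator emulating short-term clonal diversification of a
#' maternally inherited endosymbiont: each isolate descends from a
#' uniformly chosen founding genotype; point mutations change one
#' previously unedited site at a uniformly chosen locus; imports replace
#' one locus's allele with a donor-pool allele at fixed divergence from the
#' founder allele.  Imports are applied first (at most one per locus per
#' isolate, loci drawn without replacement); mutation sites colliding with
#' an already edited site are resampled, so the number of sequence
#' differences between an isolate and its founder equals the sum of its
#' logged event edits exactly.
#'
#' @param config A [sim_config()].
#' @return List with elements `sequences` (long alignment tibble `locus`,
#'   `isolate`, `seq`), `metadata` (tibble `isolate`, `founder`), `truth`
#'   (tibble `isolate`, `event` in mutation/import, `locus`, `detail`),
#'   `true_rm_ratio` (imports : mutations over the dataset; `Inf` when no
#'   mutations, `NA` when neither), and the `config`.  Byte-identical for
#'   identical configs.
#' @export
simulate_clonal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  loci <- sprintf("locus%02d", seq_len(config$n_loci))
  # founder alleles: founder 1 random; founder f = founder 1 with a fresh
  # block of founder_divergence_nt sites changed (blocks disjoint across
  # founders, so founder STs are mutually distinct at every locus)
  founder_alleles <- list()
  for (li in seq_along(loci)) {
    len <- config$locus_length_bp[li]
    base <- random_seq(len)
    per_founder <- list(base)
    if (config$n_founders > 1) {
      avail <- seq_len(len)
      for (f in 2:config$n_founders) {
        sites <- sample(avail, config$founder_divergence_nt)
        avail <- setdiff(avail, sites)
        per_founder[[f]] <- mutate_sites(base, sites)
      }
    }
    founder_alleles[[loci[li]]] <- per_founder
  }
  # donor pools: per (locus, founder), donor_pool_size alleles at
  # import_divergence_nt differences from that founder's allele
  donors <- list()
  for (li in seq_along(loci)) {
    len <- config$locus_length_bp[li]
    donors[[loci[li]]] <- lapply(seq_len(config$n_founders), function(f) {
      lapply(seq_len(config$donor_pool_size), function(d) {
        sites <- sample(len, config$import_divergence_nt)
        list(seq = mutate_sites(founder_alleles[[loci[li]]][[f]], sites),
             sites = sort(sites))
      })
    })
  }

  iso_ids <- sprintf("iso%03d", seq_len(config$n_isolates))
  founder_of <- sample(config$n_founders, config$n_isolates, replace = TRUE)
  seq_rows <- list()
  truth_rows <- list()
  for (i in seq_len(config$n_isolates)) {
    f <- founder_of[i]
    genome <- lapply(loci, function(l) founder_alleles[[l]][[f]])
    names(genome) <- loci
    edited <- stats::setNames(vector("list", length(loci)), loci)

    n_imp <- min(stats::rpois(1, config$import_events_mean), config$n_loci)
    if (n_imp > 0) {
      imp_loci <- sample(loci, n_imp)
      for (l in imp_loci) {
        li <- match(l, loci)
        d <- sample(config$donor_pool_size, 1)
        donor <- donors[[l]][[f]][[d]]
        genome[[l]] <- donor$seq
        edited[[l]] <- donor$sites
        truth_rows[[length(truth_rows) + 1]] <- tibble(
          isolate = iso_ids[i], event = "import", locus = l,
          detail = sprintf("donor=%d", d)
        )
      }
    }
    n_mut <- stats::rpois(1, config$mutation_events_mean)
    for (k in seq_len(n_mut)) {
      l <- sample(loci, 1)
      li <- match(l, loci)
      free <- setdiff(seq_len(config$locus_length_bp[li]), edited[[l]])
      site <- if (length(free) == 1) free else sample(free, 1)
      genome[[l]] <- mutate_sites(genome[[l]], site)
      edited[[l]] <- c(edited[[l]], site)
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        isolate = iso_ids[i], event = "mutation", locus = l,
        detail = sprintf("site=%d,base=%s", site, genome[[l]][site])
      )
    }
    for (l in loci) {
      seq_rows[[length(seq_rows) + 1]] <- tibble(
        locus = l, isolate = iso_ids[i],
        seq = paste(genome[[l]], collapse = "")
      )
    }
  }
  truth <- if (length(truth_rows)) purrr::list_rbind(truth_rows) else
    tibble(isolate = character(), event = character(),
           locus = character(), detail = character())
  n_imp_tot <- sum(truth$event == "import")
  n_mut_tot <- sum(truth$event == "mutation")
  true_rm <- if (n_mut_tot == 0) {
    if (n_imp_tot == 0) NA_real_ else Inf
  } else {
    n_imp_tot / n_mut_tot
  }
  sequences <- purrr::list_rbind(seq_rows) |>
    dplyr::arrange(.data$locus, match(.data$isolate, iso_ids))
  list(
    sequences = sequences,
    metadata = tibble(isolate = iso_ids,
                      founder = sprintf("founder%d", founder_of)),
    truth = truth,
    true_rm_ratio = true_rm,
    config = config
  )
}

#' Write simulator output to disk
#'
#' Per-locus FASTA files, metadata TSV, truth-log TSV and the configuration
#' as a plain key=value file.
#'
#' @param sim Output of [simulate_clonal()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_locus_fasta(sim$sequences, dir)
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  writeLines(
    vapply(names(cfg), function(k) {
      sprintf("%s=%s", k, paste(cfg[[k]], collapse = ","))
    }, character(1)),
    file.path(dir, "config.txt")
  )
  invisible(dir)
}
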