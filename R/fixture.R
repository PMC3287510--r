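#' The published Wolbachia clonal-complex fixture
#'
#' The in-package acceptance dataset: the 22 sequence types grouped into
#' five clonal complexes in the source study's clonal-complex table, with
#' founder profiles, isolate frequencies, and per-variant annotations
#' (nucleotide differences from the founder allele and sharing flags).
#' The full-profile column of each complex is treated as the founding
#' genotype; `founder_sts` carries those STs as a hint for
#' [find_clonal_complexes()] (needed because one complex is a fully
#' connected SLV clique of equal-frequency STs, where degree and frequency
#' cannot break the founder tie).
#'
#' @return List with `sts` (an `st_tbl` of the 22 STs; locus order wsp,
#'   ftsZ, groEL, trmD), `profiles` (the raw tibble incl. host taxon and
#'   published complex labels), `annotations` (variant annotation tibble
#'   for [extract_variants()]), `founder_sts`, and `locus_order`.
#' @examples
#' fx <- wolbachia_complexes()
#' cc <- find_clonal_complexes(build_slv_graph(fx$sts),
#'                             founder_hint = fx$founder_sts)
#' cc$complexes
#' @export
wolbachia_complexes <- function() {
  locus_order <- c("wsp", "ftsZ", "groEL", "trmD")
  profiles <- readr::read_tsv(
    system.file("extdata", "wolbachia_cc_profiles.tsv",
                package = "clonalrm", mustWork = TRUE),
    col_types = readr::cols(
      st_id = "i", wsp = "i", ftsZ = "i", groEL = "i", trmD = "i",
      frequency = "i", complex = "c", is_founder = "l", host = "c"
    )
  )
  annotations <- readr::read_tsv(
    system.file("extdata", "wolbachia_cc_variants.tsv",
                package = "clonalrm", mustWork = TRUE),
    col_types = readr::cols(
      locus = "c", founder_allele = "i", variant_allele = "i",
      n_diffs = "i", single_seen_elsewhere = "l", allele_seen_elsewhere = "l"
    )
  )
  sts <- st_table_from_profiles(
    profiles[, c("st_id", locus_order, "frequency")],
    locus_order
  )
  list(
    sts = sts,
    profiles = profiles,
    annotations = annotations,
    founder_sts = profiles$st_id[profiles$is_founder],
    locus_order = locus_order
  )
}

# ---- fabricated sequence realization ---------------------------------------
#
# A deterministic sequence-level realization of the fixture: per locus,
# every allele is the locus background plus a set of single-base changes
# drawn from disjoint column blocks, so that each founder-variant diff
# count equals the fixture annotation exactly, the three non-unique single
# changes recur in another allele, the unique single does not, and the
# "seen elsewhere" 2-diff allele (groEL 11) recurs in one extra synthetic
# singleton ST outside the complexes.

fixture_allele_changes <- function() {
  # per locus: background allele id, and per allele a vector of columns
  # changed relative to background; columns are allocated sequentially so
  # blocks never collide.  Shared columns implement the sharing flags.
  alloc_env <- new.env()
  alloc <- function(locus, n) {
    cur <- alloc_env[[locus]] %||% 0L
    cols <- cur + seq_len(n)
    alloc_env[[locus]] <- cur + n
    cols
  }
  changes <- list()
  add <- function(locus, allele, cols) {
    changes[[locus]][[as.character(allele)]] <<- sort(unique(cols))
  }
  # wsp (background = allele 1)
  add("wsp", 1, integer())
  s5 <- alloc("wsp", 18); add("wsp", 5, s5)
  add("wsp", 3, c(s5, alloc("wsp", 8)))          # d(5,3) = 8
  s12 <- alloc("wsp", 12); add("wsp", 12, s12)
  add("wsp", 4, c(s12, alloc("wsp", 16)))        # d(12,4) = 16
  add("wsp", 6, alloc("wsp", 15))
  add("wsp", 20, alloc("wsp", 10))               # synthetic singleton ST
  # ftsZ (background = allele 2)
  add("ftsZ", 2, integer())
  add("ftsZ", 1, alloc("ftsZ", 1))               # unique single change
  add("ftsZ", 10, alloc("ftsZ", 10))
  add("ftsZ", 3, alloc("ftsZ", 8))
  add("ftsZ", 14, alloc("ftsZ", 12))
  add("ftsZ", 20, alloc("ftsZ", 9))
  # groEL (background = allele 8)
  add("groEL", 8, integer())
  add("groEL", 4, alloc("groEL", 4))             # d(8,4) = 4
  s12g <- alloc("groEL", 12); add("groEL", 12, s12g)
  add("groEL", 11, c(s12g, alloc("groEL", 2)))   # d(12,11) = 2
  add("groEL", 3, alloc("groEL", 10))
  # trmD (background = allele 1)
  add("trmD", 1, integer())
  c3 <- alloc("trmD", 1); add("trmD", 3, c3)     # single, shared with 10
  add("trmD", 10, c(c3, alloc("trmD", 14)))      # d(1,10) = 15
  c2 <- alloc("trmD", 1); add("trmD", 2, c2)     # single, shared with 14
  add("trmD", 14, c(c2, alloc("trmD", 8)))       # d(1,14) = 9
  c11 <- alloc("trmD", 1)
  add("trmD", 6, c(c11, alloc("trmD", 6)))       # d(1,6) = 7; carries c11
  add("trmD", 5, alloc("trmD", 2))               # ambiguous double
  s8 <- alloc("trmD", 12); add("trmD", 8, s8)
  add("trmD", 17, c(s8, alloc("trmD", 9)))       # d(8,17) = 9
  add("trmD", 15, c(s8, alloc("trmD", 8)))       # d(8,15) = 8
  s9 <- alloc("trmD", 12); add("trmD", 9, s9)
  add("trmD", 11, c(s9, c11))                    # d(9,11) = 1, shared via 6
  add("trmD", 20, alloc("trmD", 10))
  changes
}

.FIXTURE_LOCUS_LEN <- c(wsp = 525L, ftsZ = 507L, groEL = 491L, trmD = 453L)

fixture_background <- function(locus) {
  # deterministic background: cycle phase differs per locus
  len <- .FIXTURE_LOCUS_LEN[[locus]]
  phase <- match(locus, names(.FIXTURE_LOCUS_LEN))
  .DNA_BASES[((seq_len(len) * 7 + phase * 3) %% 4) + 1]
}

rotate_base <- function(b) {
  .DNA_BASES[(match(b, .DNA_BASES) %% 4) + 1]
}

fixture_allele_seq <- function(locus, cols) {
  bg <- fixture_background(locus)
  bg[cols] <- vapply(bg[cols], rotate_base, character(1))
  paste(bg, collapse = "")
}

#' Fabricated sequence realization of the clonal-complex fixture
#'
#' Builds aligned per-locus sequences realizing the fixture exactly: the 22
#' complexed STs at their published isolate frequencies, plus one extra
#' synthetic singleton ST (labelled `synthX1`) carrying groEL allele 11 so
#' that the "allele found elsewhere" flag of that 2-diff variant is
#' realized at sequence level.  Typing these sequences with
#' [call_alleles()] + [assign_sts()] reproduces the fixture's ST partition,
#' and [extract_variants()] on them reproduces every fixture diff count and
#' sharing flag.
#'
#' @return List with `sequences` (long alignment tibble), `metadata`
#'   (tibble `isolate`, `st_label`, `host`), and `locus_order`.
#' @export
fixture_sequences <- function() {
  fx <- wolbachia_complexes()
  changes <- fixture_allele_changes()
  profiles <- fx$profiles
  # one extra singleton ST outside the complexes (synthetic; carries
  # groEL 11 plus novel alleles elsewhere so it stays unlinked)
  extra <- tibble(
    st_id = 99L, wsp = 20L, ftsZ = 20L, groEL = 11L, trmD = 20L,
    frequency = 1L, complex = NA_character_, is_founder = FALSE,
    host = "synthetic"
  )
  profiles <- dplyr::bind_rows(profiles, extra)
  rows <- list()
  meta <- list()
  iso_n <- 0L
  for (r in seq_len(nrow(profiles))) {
    for (k in seq_len(profiles$frequency[r])) {
      iso_n <- iso_n + 1L
      iso <- if (profiles$st_id[r] == 99L) {
        "synthX1"
      } else {
        sprintf("iso%02d_ST%d", iso_n, profiles$st_id[r])
      }
      meta[[iso_n]] <- tibble(
        isolate = iso,
        st_label = profiles$st_id[r],
        host = profiles$host[r]
      )
      for (loc in fx$locus_order) {
        allele <- profiles[[loc]][r]
        rows[[length(rows) + 1]] <- tibble(
          locus = loc, isolate = iso,
          seq = fixture_allele_seq(loc, changes[[loc]][[as.character(allele)]])
        )
      }
    }
  }
  list(
    sequences = purrr::list_rbind(rows) |>
      dplyr::arrange(match(.data$locus, fx$locus_order)),
    metadata = purrr::list_rbind(meta),
    locus_order = fx$locus_order
  )
}

#' Write the fixture dataset to disk
#'
#' Emits the fixture in the pipeline's native formats: the profile and
#' variant-annotation TSVs, per-locus FASTA of the fabricated sequence
#' realization, and the isolate metadata TSV.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
emit_fixture_dataset <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- wolbachia_complexes()
  seqs <- fixture_sequences()
  write_locus_fasta(seqs$sequences, dir)
  readr::write_tsv(seqs$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(fx$profiles, file.path(dir, "complex_profiles.tsv"))
  readr::write_tsv(fx$annotations, file.path(dir, "variant_annotations.tsv"))
  invisible(dir)
}
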