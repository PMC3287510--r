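#' Assign allele identifiers to unique sequences at each locus
#'
#' Standard MLST allele calling: within each locus, identical aligned
#' sequences (exact string match after `U`→`T` normalization and case
#' folding; gaps count as characters, ambiguity codes match only on exact
#' equality) share an allele identifier.  Identifiers are consecutive
#' positive integers in order of first appearance in the input.
#'
#' @param aln Long alignment tibble (`locus`, `isolate`, `seq`) covering one
#'   or more loci.
#' @return A tibble with columns `locus`, `isolate`, `allele_id`, `seq` (the
#'   allele's aligned sequence).
#' @examples
#' aln <- tibble::tibble(
#'   locus = "x", isolate = c("a", "b", "c"),
#'   seq = c("ACGT", "ACGT", "ACGA")
#' )
#' call_alleles(aln)
#' @export
call_alleles <- function(aln) {
  aln <- as_locus_alignment(aln)
  aln |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(allele_id = match(.data$seq, unique(.data$seq))) |>
    dplyr::ungroup() |>
    dplyr::select("locus", "isolate", "allele_id", "seq")
}

#' Distinct allele sequences per locus
#'
#' @param calls Output of [call_alleles()].
#' @return Tibble `locus`, `allele_id`, `seq`, one row per allele.
#' @export
allele_sequences <- function(calls) {
  calls |>
    dplyr::distinct(.data$locus, .data$allele_id, .data$seq) |>
    dplyr::arrange(.data$locus, .data$allele_id)
}

#' Assign sequence types (STs) from per-locus allele calls
#'
#' Each unique allelic profile (tuple of allele ids across the loci in
#' `locus_order`) is one sequence type.  ST ids are consecutive from 1 in
#' order of first appearance.  Isolates not typed at every locus are
#' excluded from ST assignment and reported (they remain usable for
#' per-locus diversity).
#'
#' @param calls Tibble from [call_alleles()] (columns `locus`, `isolate`,
#'   `allele_id`).
#' @param locus_order Character vector fixing the locus order of the
#'   profile.  Default: order of first appearance in `calls`.
#' @return A sequence-type table of class `st_tbl`: one row per ST with
#'   columns `st_id`, one allele column per locus, `frequency` (number of
#'   isolates) and `isolates` (list column).  Attributes: `locus_order` and
#'   `excluded` (tibble of isolates missing one or more loci).
#' @export
assign_sts <- function(calls, locus_order = NULL) {
  locus_order <- locus_order %||% unique(calls$locus)
  missing_loci <- setdiff(locus_order, unique(calls$locus))
  if (length(missing_loci) > 0) {
    stop("locus_order names loci absent from the calls: ",
         paste(missing_loci, collapse = ", "), call. = FALSE)
  }
  wide <- calls |>
    dplyr::filter(.data$locus %in% locus_order) |>
    dplyr::select("locus", "isolate", "allele_id") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "allele_id")
  # preserve first-appearance order of isolates as in the input
  wide <- wide[order(match(wide$isolate, unique(calls$isolate))), ]

  complete <- stats::complete.cases(wide[, locus_order, drop = FALSE])
  excluded <- tibble(
    isolate = wide$isolate[!complete],
    missing_loci = vapply(which(!complete), function(i) {
      paste(locus_order[is.na(unlist(wide[i, locus_order]))], collapse = ",")
    }, character(1))
  )
  if (nrow(excluded) > 0) {
    message(nrow(excluded), " isolate(s) excluded from ST assignment ",
            "(missing >=1 locus): ", paste(excluded$isolate, collapse = ", "))
  }
  typed <- wide[complete, , drop = FALSE]
  if (nrow(typed) == 0) {
    stop("no isolate is typed at every locus; cannot assign STs",
         call. = FALSE)
  }
  key <- do.call(paste, c(typed[, locus_order, drop = FALSE], sep = "|"))
  typed$st_id <- match(key, unique(key))
  profiles <- typed |>
    dplyr::group_by(.data$st_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(locus_order), ~ .x[1]),
      frequency = dplyr::n(),
      isolates = list(.data$isolate),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$st_id)
  new_st_tbl(profiles, locus_order, excluded)
}

new_st_tbl <- function(profiles, locus_order, excluded = NULL) {
  structure(
    profiles,
    locus_order = locus_order,
    excluded = excluded %||% tibble(isolate = character(),
                                    missing_loci = character()),
    class = c("st_tbl", class(tibble()))
  )
}

#' Build a sequence-type table directly from an allelic-profile table
#'
#' For published MLST data where allele ids (not sequences) are available,
#' e.g. a clonal-complex table from a paper.  ST ids are taken from the
#' input.
#'
#' @param profiles Data frame with columns `st_id`, one integer allele
#'   column per locus, and optionally `frequency` (default 1) and
#'   `isolates` (list column; default synthetic ids).
#' @param locus_order Character vector naming the allele columns in order.
#' @return An `st_tbl` as from [assign_sts()].
#' @export
st_table_from_profiles <- function(profiles, locus_order) {
  profiles <- as_tibble(profiles)
  if (!all(c("st_id", locus_order) %in% names(profiles))) {
    stop("profiles must contain 'st_id' and all locus columns", call. = FALSE)
  }
  if (anyDuplicated(profiles$st_id)) {
    stop("duplicated st_id in profiles", call. = FALSE)
  }
  key <- do.call(paste, c(profiles[, locus_order, drop = FALSE], sep = "|"))
  if (anyDuplicated(key)) {
    stop("two STs share one allelic profile", call. = FALSE)
  }
  if (!"frequency" %in% names(profiles)) profiles$frequency <- 1L
  if (!"isolates" %in% names(profiles)) {
    profiles$isolates <- purrr::map2(
      profiles$st_id, profiles$frequency,
      function(st, f) sprintf("ST%s_iso%d", st, seq_len(f))
    )
  }
  new_st_tbl(
    profiles[, c("st_id", locus_order, "frequency", "isolates")],
    locus_order
  )
}

#' Per-isolate ST assignments
#'
#' @param sts An `st_tbl`.
#' @return Tibble `isolate`, `st_id`.
#' @export
st_assignments <- function(sts) {
  tibble(st_id = sts$st_id, isolate = sts$isolates) |>
    tidyr::unnest("isolate") |>
    dplyr::select("isolate", "st_id")
}

#' Write / read the allele table as TSV
#'
#' The TSV has columns `locus`, `allele_id`, `sequence` plus the per-isolate
#' map in a second file-independent form; [read_allele_table()] restores a
#' tibble equivalent to [call_alleles()] output.
#'
#' @param calls Output of [call_alleles()].
#' @param path Output TSV path.
#' @return `write_allele_table()`: `path`, invisibly.
#' @export
write_allele_table <- function(calls, path) {
  readr::write_tsv(
    calls |> dplyr::select("locus", "isolate", "allele_id", "seq"),
    path
  )
  invisible(path)
}

#' @rdname write_allele_table
#' @export
read_allele_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    locus = "c", isolate = "c", allele_id = "i", seq = "c"
  ))
}

#' Write / read the ST table as TSV
#'
#' One row per ST: `st_id`, allele id per locus, `frequency`, and the
#' comma-separated isolate list.
#'
#' @param sts An `st_tbl`.
#' @param path Output TSV path.
#' @return `write_st_table()`: `path`, invisibly; `read_st_table()`: an
#'   `st_tbl`.
#' @export
write_st_table <- function(sts, path) {
  locus_order <- attr(sts, "locus_order")
  flat <- as_tibble(sts) |>
    dplyr::mutate(isolates = vapply(.data$isolates, paste,
                                    character(1), collapse = ","))
  header <- paste0("# locus_order=", paste(locus_order, collapse = ","))
  writeLines(header, path)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_st_table
#' @export
read_st_table <- function(path) {
  header <- readLines(path, n = 1)
  locus_order <- strsplit(sub("^# locus_order=", "", header), ",")[[1]]
  flat <- readr::read_tsv(path, skip = 1, col_types = readr::cols())
  flat$isolates <- strsplit(flat$isolates, ",", fixed = TRUE)
  new_st_tbl(as_tibble(flat), locus_order)
}
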