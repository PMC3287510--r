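#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Bases treated as observed states in distance/diversity calculations.
.DNA_BASES <- c("A", "C", "G", "T")
# IUPAC ambiguity codes are retained verbatim but treated as missing data
# (like N) in all pairwise comparisons.
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.ALLOWED_CHARS <- c(.DNA_BASES, "N", "-", .IUPAC_AMBIG)

#' Read one per-locus multiple sequence alignment from FASTA
#'
#' Reads a pre-aligned FASTA file into the long tidy form used throughout the
#' package: one row per (locus, isolate), with the aligned sequence as an
#' uppercase string.  The record identifier (up to the first whitespace) is
#' taken as the isolate id.  `U` is normalized to `T`; IUPAC ambiguity codes
#' are retained but flagged with a message; any other character is an error.
#'
#' @param path Path to a FASTA file with at least one record.  All records
#'   must have identical aligned length.
#' @param locus Short locus label (e.g. `"wsp"`).  Defaults to the file name
#'   without extension.
#' @return A tibble with columns `locus`, `isolate`, `seq`, validated as a
#'   locus alignment.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGTACGTAA", ">b", "ACGTACGTAT"), fa)
#' read_locus_alignment(fa, locus = "demo")
#' @export
read_locus_alignment <- function(path, locus = NULL) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  locus <- locus %||% sub("\\.[^.]*$", "", basename(path))
  ids <- sub("\\s.*$", "", names(set))
  tbl <- tibble(
    locus = locus,
    isolate = ids,
    seq = unname(toupper(as.character(set)))
  )
  as_locus_alignment(tbl)
}

#' Read several per-locus alignments at once
#'
#' @param paths Character vector of FASTA paths, named by locus label
#'   (unnamed entries fall back to the file name).
#' @return A long tibble with columns `locus`, `isolate`, `seq` covering all
#'   loci, each locus validated independently.
#' @export
read_locus_alignments <- function(paths) {
  loci <- names(paths) %||% rep("", length(paths))
  if (is.null(names(paths))) names(paths) <- rep("", length(paths))
  purrr::list_rbind(purrr::imap(
    as.list(paths),
    function(p, nm) read_locus_alignment(p, locus = if (nzchar(nm)) nm else NULL)
  ))
}

#' Validate a long alignment tibble
#'
#' Checks the locus-alignment contract: columns `locus`, `isolate`, `seq`;
#' within each locus all sequences have the same length, isolate ids are
#' unique, and sequences contain only `A`, `C`, `G`, `T`, `N`, `-` or IUPAC
#' ambiguity codes (after `U` to `T` normalization and case folding).
#'
#' @param x A data frame with columns `locus`, `isolate`, `seq` (one or more
#'   loci).
#' @return The validated tibble (uppercased, `U` normalized), invisibly
#'   classed for internal reuse.
#' @export
as_locus_alignment <- function(x) {
  x <- as_tibble(x)
  need <- c("locus", "isolate", "seq")
  if (!all(need %in% names(x))) {
    stop("alignment table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) == 0) stop("alignment has no sequences", call. = FALSE)
  x$seq <- toupper(x$seq)
  x$seq <- gsub("U", "T", x$seq, fixed = TRUE)

  for (loc in unique(x$locus)) {
    sub <- x[x$locus == loc, ]
    w <- nchar(sub$seq)
    if (length(unique(w)) > 1) {
      bad <- sub$isolate[which(w != w[1])[1]]
      stop("ragged alignment at locus '", loc, "': record '", bad,
           "' has length ", nchar(sub$seq[sub$isolate == bad][1]),
           ", expected ", w[1], call. = FALSE)
    }
    if (w[1] == 0) stop("zero-length alignment at locus '", loc, "'",
                        call. = FALSE)
    if (anyDuplicated(sub$isolate)) {
      stop("duplicated isolate id(s) at locus '", loc, "': ",
           paste(unique(sub$isolate[duplicated(sub$isolate)]), collapse = ", "),
           call. = FALSE)
    }
    chars <- unique(strsplit(paste(sub$seq, collapse = ""), "")[[1]])
    bad <- setdiff(chars, .ALLOWED_CHARS)
    if (length(bad) > 0) {
      stop("invalid character(s) at locus '", loc, "': ",
           paste(bad, collapse = " "), call. = FALSE)
    }
    if (any(chars %in% .IUPAC_AMBIG)) {
      message("locus '", loc, "': IUPAC ambiguity codes present; ",
              "retained verbatim, treated as missing in comparisons")
    }
  }
  x
}

#' Alignment length per locus
#'
#' @param aln A long alignment tibble (`locus`, `isolate`, `seq`).
#' @return Tibble with columns `locus`, `n_seq`, `length_bp`.
#' @export
alignment_lengths <- function(aln) {
  aln <- as_locus_alignment(aln)
  aln |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(
      n_seq = dplyr::n(),
      length_bp = nchar(.data$seq[1]),
      .groups = "drop"
    )
}

# Character matrix (isolates x columns) for a single-locus alignment subset.
aln_matrix <- function(aln) {
  stopifnot(length(unique(aln$locus)) == 1)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$isolate
  m
}

#' Write a long alignment tibble to per-locus FASTA files
#'
#' @param aln Long alignment tibble.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written file paths (one per locus).
#' @export
write_locus_fasta <- function(aln, dir) {
  aln <- as_locus_alignment(aln)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- vapply(unique(aln$locus), function(loc) {
    sub <- aln[aln$locus == loc, ]
    set <- Biostrings::BStringSet(sub$seq)
    names(set) <- sub$isolate
    path <- file.path(dir, paste0(loc, ".fasta"))
    Biostrings::writeXStringSet(set, path)
    path
  }, character(1))
  invisible(out)
}
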