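#' Polymorphic-site matrix for visual mosaic inspection
#'
#' Extracts the variable columns of a (subset of a) locus alignment and
#' renders every non-reference row with a dot where it equals the reference
#' sequence, the classical layout for spotting intragenic mosaic structure
#' by eye.
#'
#' @param aln Long alignment tibble restricted to one locus (2+ sequences).
#' @param reference Isolate id of the reference row (differences are shown
#'   relative to it).
#' @return Object of class `polymorphic_matrix`: list with `locus`,
#'   `positions` (1-based variable columns), `reference`, and `rows`, a
#'   tibble (`isolate`, `bases` = dot-masked string).
#' @export
polymorphic_matrix <- function(aln, reference) {
  aln <- as_locus_alignment(aln)
  if (length(unique(aln$locus)) != 1) {
    stop("polymorphic_matrix expects a single locus", call. = FALSE)
  }
  if (!reference %in% aln$isolate) {
    stop("reference isolate '", reference, "' not in alignment",
         call. = FALSE)
  }
  m <- aln_matrix(aln)
  var <- apply(m, 2, function(col) {
    length(unique(col[col %in% .DNA_BASES])) >= 2
  })
  positions <- which(var)
  sub <- m[, positions, drop = FALSE]
  ref_row <- sub[reference, , drop = TRUE]
  rows <- purrr::map_chr(rownames(sub), function(id) {
    r <- sub[id, ]
    if (id != reference) r[r == ref_row] <- "."
    paste(r, collapse = "")
  })
  structure(
    list(
      locus = aln$locus[1],
      positions = positions,
      reference = reference,
      rows = tibble(isolate = rownames(sub), bases = rows)
    ),
    class = "polymorphic_matrix"
  )
}

#' @export
print.polymorphic_matrix <- function(x, ...) {
  cat(sprintf("Polymorphic sites, locus '%s' (%d variable columns), ref = %s\n",
              x$locus, length(x$positions), x$reference))
  if (length(x$positions) == 0) return(invisible(x))
  width <- max(nchar(x$rows$isolate)) + 2
  pos <- x$positions
  digits <- max(nchar(pos))
  for (d in seq_len(digits)) {
    line <- vapply(pos, function(p) {
      s <- formatC(p, width = digits)
      substring(s, d, d)
    }, character(1))
    cat(strrep(" ", width), paste(line, collapse = ""), "\n", sep = "")
  }
  for (i in seq_len(nrow(x$rows))) {
    cat(formatC(x$rows$isolate[i], width = -width), x$rows$bases[i], "\n",
        sep = "")
  }
  invisible(x)
}

#' Write a polymorphic-site matrix as TSV
#'
#' @param pm A `polymorphic_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(pm, path) {
  tbl <- dplyr::bind_rows(
    tibble(isolate = "position",
           bases = paste(pm$positions, collapse = ",")),
    pm$rows
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

# 2x2 chi-square (no continuity correction) for every cut of the
# informative-site match vector x (1 = child matches parent A).
maxchi_profile <- function(x, min_sites_per_side) {
  m <- length(x)
  ks <- seq.int(min_sites_per_side, m - min_sites_per_side)
  tot <- sum(x)
  cs <- cumsum(x)
  a <- cs[ks]                  # left, matches A
  b <- ks - a                  # left, matches B
  c_ <- tot - a                # right, matches A
  d <- (m - ks) - c_           # right, matches B
  den <- as.numeric(tot) * (m - tot) * ks * (m - ks)
  stat <- ifelse(den == 0, 0, m * (a * d - b * c_)^2 / den)
  list(ks = ks, stat = stat)
}

#' MaxChi-style breakpoint scan on a parent/parent/child triplet
#'
#' Over the informative sites (columns where the putative recombinant child
#' matches exactly one of the two parents, the parents differ, and all
#' three bases are unambiguous), every cut point splits the sites into a
#' left and right block; the 2x2 chi-square of (matches parent A vs parent
#' B) x (left vs right) is computed at each cut, and the maximizing cut
#' (leftmost on ties) is the candidate breakpoint.  Significance comes from
#' permuting the site labels.
#'
#' @param parent_a,parent_b,child Aligned sequences of equal length
#'   (character strings).
#' @param min_sites_per_side Minimum informative sites on each side of a
#'   cut (>= 2; default 3).
#' @param n_permutations Number of site-label permutations for the null
#'   (default 1000).
#' @param seed Optional integer seed making the permutation p-value
#'   reproducible.
#' @return Object of class `maxchi_scan`: list with `call` (one-row tibble:
#'   `n_informative`, `cut_index`, `position` = alignment column midway
#'   between the flanking informative sites, `statistic`, `p_value`,
#'   `no_call`) and `profile` (tibble `cut_index`, `position`,
#'   `statistic`).  With fewer than `2 * min_sites_per_side` informative
#'   sites a flagged no-call result is returned.
#' @export
maxchi_breakpoints <- function(parent_a, parent_b, child,
                               min_sites_per_side = 3,
                               n_permutations = 1000, seed = NULL) {
  stopifnot(min_sites_per_side >= 2)
  seqs <- toupper(c(a = parent_a, b = parent_b, child = child))
  if (length(unique(nchar(seqs))) != 1) {
    stop("parent_a, parent_b and child must have equal aligned length",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(chars, 2, function(col) all(col %in% .DNA_BASES))
  informative <- ok & chars["a", ] != chars["b", ] &
    (chars["child", ] == chars["a", ] | chars["child", ] == chars["b", ])
  pos <- which(informative)
  m <- length(pos)
  if (m < 2 * min_sites_per_side) {
    call <- tibble(
      n_informative = m, cut_index = NA_integer_, position = NA_integer_,
      statistic = NA_real_, p_value = NA_real_, no_call = TRUE
    )
    return(structure(list(call = call,
                          profile = tibble(cut_index = integer(),
                                           position = integer(),
                                           statistic = numeric())),
                     class = "maxchi_scan"))
  }
  x <- as.integer(chars["child", pos] == chars["a", pos])
  prof <- maxchi_profile(x, min_sites_per_side)
  best <- which.max(prof$stat)          # leftmost maximizing cut
  obs <- prof$stat[best]
  cut <- prof$ks[best]
  position <- (pos[cut] + pos[cut + 1]) %/% 2

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  perm_max <- vapply(seq_len(n_permutations), function(i) {
    max(maxchi_profile(sample(x), min_sites_per_side)$stat)
  }, numeric(1))
  p <- (1 + sum(perm_max >= obs)) / (1 + n_permutations)

  structure(
    list(
      call = tibble(
        n_informative = m, cut_index = cut, position = position,
        statistic = obs, p_value = p, no_call = FALSE
      ),
      profile = tibble(
        cut_index = prof$ks,
        position = (pos[prof$ks] + pos[prof$ks + 1]) %/% 2,
        statistic = prof$stat
      )
    ),
    class = "maxchi_scan"
  )
}

#' @export
print.maxchi_scan <- function(x, ...) {
  cat("MaxChi breakpoint scan\n")
  if (x$call$no_call) {
    cat(sprintf("  no call: only %d informative site(s)\n",
                x$call$n_informative))
  } else {
    cat(sprintf(
      "  %d informative sites; breakpoint after informative site %d (column ~%d)\n",
      x$call$n_informative, x$call$cut_index, x$call$position))
    cat(sprintf("  chi-square = %.3f, permutation p = %.4g\n",
                x$call$statistic, x$call$p_value))
  }
  invisible(x)
}
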