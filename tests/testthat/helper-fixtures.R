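# Shared builders for small in-memory alignments.

make_aln <- function(seqs, locus = "locusA", ids = NULL) {
  ids <- ids %||% sprintf("iso%02d", seq_along(seqs))
  tibble::tibble(locus = locus, isolate = ids, seq = seqs)
}

# Random alignment with optional gaps/Ns, fixed RNG state assumed by caller.
random_aln <- function(n_seq, len, locus = "locusA", p_gap = 0, p_n = 0) {
  chars <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_seq), function(i) {
    s <- sample(chars, len, replace = TRUE)
    if (p_gap > 0) s[stats::runif(len) < p_gap] <- "-"
    if (p_n > 0) s[stats::runif(len) < p_n] <- "N"
    paste(s, collapse = "")
  }, character(1))
  make_aln(seqs, locus = locus)
}

write_temp_fasta <- function(seqs, ids = NULL) {
  ids <- ids %||% sprintf("rec%d", seq_along(seqs))
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Random ST profile table for property tests.
random_st_tbl <- function(n_sts, n_loci, max_allele) {
  repeat {
    prof <- matrix(sample(max_allele, n_sts * n_loci, replace = TRUE),
                   nrow = n_sts)
    if (!anyDuplicated(apply(prof, 1, paste, collapse = "|"))) break
  }
  loci <- sprintf("L%d", seq_len(n_loci))
  df <- tibble::as_tibble(as.data.frame(prof))
  names(df) <- loci
  df$st_id <- seq_len(n_sts)
  df$frequency <- sample(5, n_sts, replace = TRUE)
  st_table_from_profiles(df, loci)
}

# Independent connected-components oracle: exhaustive pairwise SLV check +
# breadth-first closure, no igraph.
brute_force_components <- function(sts) {
  locus_order <- attr(sts, "locus_order")
  prof <- as.matrix(tibble::as_tibble(sts)[, locus_order])
  n <- nrow(prof)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sum(prof[i, ] != prof[j, ]) == 1) adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(sts$st_id, comp)
}
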