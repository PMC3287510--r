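#' Build the single-locus-variant (SLV) graph over sequence types
#'
#' Nodes are STs; an undirected edge links two STs whose allelic profiles
#' differ at exactly one locus (Hamming distance 1 over the allele tuple).
#'
#' @param sts An `st_tbl` from [assign_sts()] or [st_table_from_profiles()].
#' @return An object of class `slv_graph`: list with `nodes` (tibble
#'   `st_id`, `frequency`), `edges` (tibble `from`, `to`, `diff_locus`), and
#'   the `locus_order`.
#' @export
build_slv_graph <- function(sts) {
  locus_order <- attr(sts, "locus_order")
  if (is.null(locus_order)) {
    stop("sts must be an st_tbl with a locus_order attribute", call. = FALSE)
  }
  prof <- as.matrix(as_tibble(sts)[, locus_order, drop = FALSE])
  if (anyNA(prof)) stop("ST profiles contain missing alleles", call. = FALSE)
  n <- nrow(prof)
  edges <- list()
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      d <- prof[i, ] != prof[j, ]
      if (sum(d) == 1) {
        edges[[length(edges) + 1]] <- tibble(
          from = sts$st_id[i], to = sts$st_id[j],
          diff_locus = locus_order[which(d)]
        )
      }
    }
  }
  structure(
    list(
      nodes = tibble(st_id = sts$st_id, frequency = sts$frequency),
      edges = if (length(edges)) purrr::list_rbind(edges) else
        tibble(from = integer(), to = integer(), diff_locus = character()),
      locus_order = locus_order
    ),
    class = "slv_graph"
  )
}

#' Predict the founding genotype of a clonal complex
#'
#' eBURST-style founder prediction: the member with the greatest number of
#' SLV links within the complex; ties broken by higher isolate frequency,
#' then by lowest ST id.  If `founder_hint` contains a member, that ST is
#' taken as the founder (for published complexes whose founding genotype is
#' given).
#'
#' @param member_ids ST ids of the complex members.
#' @param graph An `slv_graph`.
#' @param founder_hint Optional ST ids of known/assumed founders.
#' @return List with `founder_st_id` and a `trace` tibble (st_id, slv_degree,
#'   frequency) recording the decision.
#' @export
predict_founder <- function(member_ids, graph, founder_hint = NULL) {
  edges <- graph$edges
  within <- edges[edges$from %in% member_ids & edges$to %in% member_ids, ]
  deg <- vapply(member_ids, function(st) {
    sum(within$from == st) + sum(within$to == st)
  }, numeric(1))
  freq <- graph$nodes$frequency[match(member_ids, graph$nodes$st_id)]
  trace <- tibble(st_id = member_ids, slv_degree = as.integer(deg),
                  frequency = freq) |>
    dplyr::arrange(dplyr::desc(.data$slv_degree),
                   dplyr::desc(.data$frequency), .data$st_id)
  hinted <- intersect(founder_hint %||% integer(), member_ids)
  founder <- if (length(hinted) > 0) hinted[1] else trace$st_id[1]
  list(founder_st_id = founder, trace = trace)
}

#' Infer clonal complexes from the SLV graph
#'
#' A clonal complex is a connected component of the SLV graph with at least
#' two STs; every member therefore shares identical alleles at all but one
#' locus (L-1 of L) with at least one other member.  Complexes are labelled
#' with Roman numerals in decreasing order of isolate total (ties: more STs,
#' then lowest member ST id).  Unlinked STs are reported as singletons.
#'
#' @param graph An `slv_graph` from [build_slv_graph()].
#' @param founder_hint Optional ST ids of known founders, passed to
#'   [predict_founder()].
#' @return Object of class `clonal_complexes`: list with
#'   `complexes` (tibble `complex_id`, `founder_st_id`, `n_sts`,
#'   `isolate_total`, `members` list column), `membership` (tibble `st_id`,
#'   `complex_id`, `is_founder`, `slv_degree`, `frequency`), `singletons`
#'   (tibble `st_id`, `frequency`), and the input `graph`.
#' @export
find_clonal_complexes <- function(graph, founder_hint = NULL) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes$st_id))
  )
  comp <- igraph::components(g)
  member_of <- split(
    as.integer(names(comp$membership)),
    comp$membership
  )
  sizes <- vapply(member_of, length, integer(1))
  cc_members <- unname(member_of[sizes >= 2])
  singleton_ids <- unlist(member_of[sizes < 2], use.names = FALSE)

  freq_of <- function(ids) {
    sum(graph$nodes$frequency[match(ids, graph$nodes$st_id)])
  }
  if (length(cc_members) > 0) {
    iso_tot <- vapply(cc_members, freq_of, numeric(1))
    n_sts <- vapply(cc_members, length, integer(1))
    min_id <- vapply(cc_members, min, integer(1))
    ord <- order(-iso_tot, -n_sts, min_id)
    cc_members <- cc_members[ord]
    labels <- as.character(utils::as.roman(seq_along(cc_members)))
    founders <- lapply(cc_members, predict_founder, graph = graph,
                       founder_hint = founder_hint)
    complexes <- tibble(
      complex_id = labels,
      founder_st_id = vapply(founders, `[[`, numeric(1), "founder_st_id"),
      n_sts = n_sts[ord],
      isolate_total = iso_tot[ord],
      members = lapply(cc_members, sort)
    )
    membership <- purrr::list_rbind(purrr::map2(
      labels, founders,
      function(lab, f) dplyr::mutate(f$trace, complex_id = lab)
    )) |>
      dplyr::mutate(is_founder = .data$st_id %in% complexes$founder_st_id) |>
      dplyr::select("st_id", "complex_id", "is_founder",
                    "slv_degree", "frequency")
  } else {
    complexes <- tibble(
      complex_id = character(), founder_st_id = numeric(),
      n_sts = integer(), isolate_total = numeric(), members = list()
    )
    membership <- tibble(
      st_id = integer(), complex_id = character(), is_founder = logical(),
      slv_degree = integer(), frequency = numeric()
    )
  }
  singletons <- tibble(
    st_id = sort(singleton_ids %||% integer()),
    frequency = graph$nodes$frequency[
      match(sort(singleton_ids %||% integer()), graph$nodes$st_id)]
  )
  structure(
    list(complexes = complexes, membership = membership,
         singletons = singletons, graph = graph),
    class = "clonal_complexes"
  )
}

#' @export
print.clonal_complexes <- function(x, ...) {
  cat("Clonal complexes (SLV-connected ST groups)\n")
  cat(sprintf("  %d complex(es), %d ST(s) grouped, %g isolates grouped, %d singleton ST(s)\n",
              nrow(x$complexes), sum(x$complexes$n_sts),
              sum(x$complexes$isolate_total), nrow(x$singletons)))
  if (nrow(x$complexes) > 0) {
    print(dplyr::select(x$complexes, -"members"))
  }
  invisible(x)
}

#' Write the complexes table and SLV edge list as TSV
#'
#' @param cc A `clonal_complexes` object.
#' @param complexes_path,edges_path Output TSV paths (either may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
write_complexes <- function(cc, complexes_path = NULL, edges_path = NULL) {
  out <- character()
  if (!is.null(complexes_path)) {
    flat <- cc$complexes |>
      dplyr::mutate(members = vapply(.data$members, paste,
                                     character(1), collapse = ","))
    readr::write_tsv(flat, complexes_path)
    out <- c(out, complexes_path)
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(cc$graph$edges, edges_path)
    out <- c(out, edges_path)
  }
  invisible(out)
}
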