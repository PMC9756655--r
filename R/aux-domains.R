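#' Venn partition of auxiliary domains across enzyme groups
#'
#' Assigns every observed auxiliary domain to exactly one of the 15
#' non-empty subsets of {GGDEF, EAL, GGDEF_EAL, HD_GYP} according to which
#' groups it occurs in. The primary count is of distinct domains per
#' region; a sequence-weighted count (total sequences carrying the
#' region's domains, summed per group) is emitted alongside.
#'
#' @param group_domains Named list of four character vectors: auxiliary
#'   domain names observed in each enzyme group (duplicates allowed; they
#'   are collapsed).
#' @return `data.frame` with one row per region: `region` (group names
#'   joined by `&`), `n_domains`, `domains` (comma-joined), `n_sequences`
#'   (weighted count; `NA` when `group_domains` carries no duplicates to
#'   weight by -- pass the full per-sequence multiset to weight).
#' @export
venn_partition <- function(group_domains) {
  stopifnot(all(CDG_CLASSES %in% names(group_domains)))
  group_domains <- group_domains[CDG_CLASSES]
  uniq <- lapply(group_domains, unique)
  all_domains <- sort(unique(unlist(uniq)))
  membership <- vapply(all_domains, function(d)
    vapply(uniq, function(s) d %in% s, logical(1)), logical(length(CDG_CLASSES)))
  # all 15 non-empty subsets, in size order then lexicographic
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(CDG_CLASSES, k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(ss) {
    pat <- CDG_CLASSES %in% ss
    in_region <- if (length(all_domains))
      apply(membership == pat, 2L, all) else logical(0)
    doms <- all_domains[in_region]
    nseq <- sum(vapply(ss, function(g)
      sum(group_domains[[g]] %in% doms), numeric(1)))
    data.frame(region = paste(ss, collapse = "&"),
               n_domains = length(doms),
               domains = paste(doms, collapse = ","),
               n_sequences = nseq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of sequences with none, one, or more than one auxiliary domain
#'
#' Auxiliary domains are deduplicated per sequence before counting, so a
#' repeated occurrence of the same domain counts as one.
#'
#' @param aux_sets List of character vectors: each sequence's auxiliary
#'   domain names (possibly with repeats).
#' @return List with `n_sequences` and `percentages` (named: `none`, `one`,
#'   `more_than_one`; sums to 100).
#' @export
aux_count_categories <- function(aux_sets) {
  if (!length(aux_sets))
    stop("empty group: auxiliary-domain categories undefined")
  k <- vapply(aux_sets, function(s) length(unique(s)), integer(1))
  n <- length(k)
  pct <- 100 * c(none = sum(k == 0), one = sum(k == 1),
                 more_than_one = sum(k > 1)) / n
  list(n_sequences = n, percentages = pct)
}

#' Auxiliary-domain co-occurrence network
#'
#' Nodes are auxiliary domains with occurrence counts (number of sequences
#' carrying the domain); an edge's weight is the number of sequences in
#' which the unordered pair co-occurs. Sequences with fewer than two
#' distinct auxiliary domains contribute node counts only. Networks are
#' intended per (order, enzyme group).
#'
#' @param aux_sets List of character vectors (one per sequence).
#' @return List (`cooccurrence_network`) with `nodes` (`domain`, `count`)
#'   and `edges` (`domain_a`, `domain_b`, `weight`; `domain_a <
#'   domain_b`).
#' @export
build_cooccurrence_network <- function(aux_sets) {
  sets <- lapply(aux_sets, function(s) sort(unique(s)))
  node_tab <- table(unlist(sets))
  nodes <- data.frame(domain = names(node_tab),
                      count = as.integer(node_tab), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$domain), , drop = FALSE]
  pair_rows <- lapply(sets, function(s) {
    if (length(s) < 2L) return(NULL)
    p <- utils::combn(s, 2L)
    data.frame(domain_a = p[1, ], domain_b = p[2, ], stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs) || !nrow(pairs)) {
    edges <- data.frame(domain_a = character(), domain_b = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  } else {
    key <- paste(pairs$domain_a, pairs$domain_b, sep = "\r")
    wt <- table(key)
    sp <- strsplit(names(wt), "\r", fixed = TRUE)
    edges <- data.frame(domain_a = vapply(sp, `[`, "", 1L),
                        domain_b = vapply(sp, `[`, "", 2L),
                        weight = as.integer(wt), stringsAsFactors = FALSE)
    edges <- edges[order(edges$domain_a, edges$domain_b), , drop = FALSE]
  }
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "cooccurrence_network")
}

#' Convert a co-occurrence network to igraph / export GraphML
#'
#' @param network A `cooccurrence_network`.
#' @return An `igraph` graph with `count` vertex and `weight` edge
#'   attributes.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes$domain,
                          count = network$nodes$count))
  g
}

#' @rdname as_igraph
#' @param path Output GraphML path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Protein-length threshold for carrying annotated auxiliary domains
#'
#' Within one enzyme group, finds the minimum length among sequences with
#' identified auxiliary domains and the percentage of auxiliary-domain-free
#' sequences shorter than that minimum (candidates for unannotated
#' domains).
#'
#' @param lengths_with_aux Lengths (aa) of sequences carrying >= 1
#'   identified auxiliary domain.
#' @param lengths_without_aux Lengths (aa) of sequences with none.
#' @return List with `min_len_with_aux`, `pct_noaux_below`,
#'   `pct_noaux_at_or_above` (the two percentages sum to 100).
#' @export
length_threshold <- function(lengths_with_aux, lengths_without_aux) {
  if (!length(lengths_with_aux) || !length(lengths_without_aux))
    stop("length threshold undefined: need sequences on both sides")
  m <- min(lengths_with_aux)
  below <- 100 * mean(lengths_without_aux < m)
  list(min_len_with_aux = m, pct_noaux_below = below,
       pct_noaux_at_or_above = 100 - below)
}

#' Per-group auxiliary-domain analytics from a classification table
#'
#' Convenience wrapper: splits a [classify_genomes()] table by enzyme group
#' (optionally within one order) and returns the aux sets used by
#' [venn_partition()], [aux_count_categories()],
#' [build_cooccurrence_network()] and [length_threshold()].
#'
#' @param classified Classification table.
#' @param taxonomy Optional taxonomy table to restrict by `order`.
#' @param order Optional order name.
#' @return Named list (one element per enzyme group) of lists of per-sequence
#'   auxiliary-domain character vectors, with protein lengths attached as
#'   attribute `lengths`.
#' @export
aux_sets_by_group <- function(classified, taxonomy = NULL, order = NULL) {
  tab <- classified[classified$class %in% CDG_CLASSES, , drop = FALSE]
  if (!is.null(order)) {
    stopifnot(!is.null(taxonomy))
    keep <- taxonomy$genome_id[taxonomy$order == order]
    tab <- tab[tab$genome_id %in% keep, , drop = FALSE]
  }
  out <- lapply(CDG_CLASSES, function(k) {
    d <- tab[tab$class == k, , drop = FALSE]
    sets <- lapply(strsplit(d$aux_domains, ","), function(s) s[nzchar(s)])
    attr(sets, "lengths") <- d$length
    sets
  })
  names(out) <- CDG_CLASSES
  out
}
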