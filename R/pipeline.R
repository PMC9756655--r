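#' Load a dataset directory into genome records
#'
#' Reads the file layout the generator emits (and that mirrors a curated
#' download): `domain_hits.tsv`, `taxonomy.tsv`, optional `ori.tsv`,
#' `proteins.faa`, and per-genome `annotations/<genome_id>.gff3` (+
#' `.fasta`).
#'
#' @param dir Dataset directory.
#' @return List with `genomes`, `taxonomy`, `ori_table` (or `NULL`),
#'   `hits`.
#' @export
load_dataset <- function(dir) {
  hits <- read_domain_table(file.path(dir, "domain_hits.tsv"))
  taxonomy <- read_taxonomy_table(file.path(dir, "taxonomy.tsv"))
  ori_path <- file.path(dir, "ori.tsv")
  ori_table <- if (file.exists(ori_path)) read_ori_table(ori_path) else NULL
  aa_path <- file.path(dir, "proteins.faa")
  aa <- if (file.exists(aa_path)) read_protein_fasta(aa_path) else character()
  genomes <- list()
  for (gid in taxonomy$genome_id) {
    gff <- file.path(dir, "annotations", paste0(gid, ".gff3"))
    if (!file.exists(gff)) stop("missing annotation for genome ", gid)
    fasta <- file.path(dir, "annotations", paste0(gid, ".fasta"))
    rec <- read_genome_annotation(gff, if (file.exists(fasta)) fasta,
                                  genome_id = gid)
    trow <- taxonomy[taxonomy$genome_id == gid, ]
    rec$order <- trow$order; rec$genus <- trow$genus
    rec$species <- trow$species_or_strain
    rec$hits <- hits[hits$protein_id %in% rec$proteins$protein_id, ,
                     drop = FALSE]
    if (length(aa)) {
      rec$proteins$length <- ifelse(
        rec$proteins$protein_id %in% names(aa),
        nchar(aa[rec$proteins$protein_id]), rec$proteins$length)
      rec$proteins$sequence <- unname(aa[rec$proteins$protein_id])
    }
    if (!is.null(ori_table)) {
      m <- match(rec$replicons$replicon_id, ori_table$replicon_id)
      ok <- !is.na(m) & !ori_table$ambiguous[m]
      rec$replicons$ori[ok] <- ori_table$ori[m[ok]]
    }
    genomes[[gid]] <- rec
  }
  list(genomes = genomes, taxonomy = taxonomy, ori_table = ori_table,
       hits = hits)
}

#' Run the full analysis pipeline
#'
#' Orchestrates classification, ori placement, normalized positions, kernel
#' density estimates and pairwise KS comparisons per enzyme group, count
#' summaries (genus means, class ratios, per-class medians), the size-count
#' Spearman correlation, auxiliary-domain analytics (Venn partition,
#' count categories, co-occurrence networks, length thresholds) and
#' replicon accounting. Genomes whose replicons lack an unambiguous ori are
#' excluded from positional statistics and counted in the result.
#'
#' @param genomes List of [genome_record()]s.
#' @param taxonomy Taxonomy table.
#' @param ori_table Optional ori table; when `NULL`, oris are taken from
#'   the records or estimated by GC skew where sequences are available.
#' @param out_dir Optional directory: result tables + manifest are written
#'   there via [write_results()].
#' @param kde_bandwidth Optional KDE bandwidth override.
#' @param ks_method `"asymptotic"` or `"exact_permutation"`.
#' @param secondary_cutoff_bp Secondary-chromosome size cutoff.
#' @param gc_skew_window GC-skew estimator window (bp).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of result objects; see the individual stage functions.
#' @export
run_pipeline <- function(genomes, taxonomy, ori_table = NULL, out_dir = NULL,
                         kde_bandwidth = NULL,
                         ks_method = c("asymptotic", "exact_permutation"),
                         secondary_cutoff_bp = 800000,
                         gc_skew_window = 1000L, seed = NULL) {
  ks_method <- match.arg(ks_method)
  cg <- classify_genomes(genomes)
  if (is.null(ori_table))
    ori_table <- ori_calls_for_genomes(genomes, window = gc_skew_window)
  pos <- normalized_positions_table(cg$classified, genomes, ori_table)

  kdes <- list(); ks_rows <- list()
  by_class <- split(pos$positions$position, pos$positions$class)
  for (k in names(by_class))
    if (length(by_class[[k]]) >= 2)
      kdes[[k]] <- kde_circular(by_class[[k]], bandwidth = kde_bandwidth)
  cls_pairs <- if (length(by_class) >= 2)
    utils::combn(names(by_class), 2, simplify = FALSE) else list()
  for (pr in cls_pairs) {
    x <- by_class[[pr[1]]]; y <- by_class[[pr[2]]]
    if (!length(x) || !length(y)) next
    if (ks_method == "exact_permutation" && length(x) + length(y) > 16) next
    ks <- ks_two_sample(x, y, method = ks_method)
    ks_rows[[paste(pr, collapse = "_vs_")]] <- data.frame(
      class_x = pr[1], class_y = pr[2], d_statistic = ks$d_statistic,
      p_value = ks$p_value, n_x = ks$n_x, n_y = ks$n_y,
      method = ks$method, stringsAsFactors = FALSE)
  }
  ks_table <- if (length(ks_rows)) do.call(rbind, ks_rows) else NULL
  if (!is.null(ks_table)) rownames(ks_table) <- NULL

  genus <- per_genus_mean_counts(cg$counts, taxonomy)
  ratios <- class_ratios(cg$counts, taxonomy)
  medians <- data.frame(
    class = CDG_CLASSES,
    median_count = vapply(CDG_CLASSES, function(k)
      median_counts(cg$counts, k), numeric(1)), stringsAsFactors = FALSE)

  chrom_len <- vapply(genomes, function(g) max(g$replicons$length_bp),
                      numeric(1))
  totals <- rowSums(cg$counts[, CDG_CLASSES])
  corr <- if (length(genomes) >= 3)
    size_count_correlation(chrom_len, totals) else NULL

  aux_sets <- aux_sets_by_group(cg$classified)
  venn <- venn_partition(lapply(aux_sets, function(s) unlist(s) %||%
                                  character()))
  aux_cat <- lapply(Filter(length, aux_sets), aux_count_categories)
  networks <- lapply(Filter(length, aux_sets), build_cooccurrence_network)
  thresholds <- list()
  for (k in CDG_CLASSES) {
    lens <- attr(aux_sets[[k]], "lengths")
    has <- vapply(aux_sets[[k]], function(s) length(s) > 0, logical(1))
    if (any(has) && any(!has))
      thresholds[[k]] <- length_threshold(lens[has], lens[!has])
  }

  locs <- gene_location_proportions(cg$classified, genomes, taxonomy,
                                    secondary_cutoff_bp)
  replicon_classes <- do.call(rbind, lapply(genomes, function(g)
    cbind(genome_id = g$genome_id,
          classify_replicons(g, secondary_cutoff_bp))))
  rownames(replicon_classes) <- NULL

  res <- list(classified = cg$classified, counts = cg$counts,
              ori_table = ori_table, positions = pos$positions,
              excluded_replicons = pos$excluded_replicons, kdes = kdes,
              ks_table = ks_table, genus_means = genus$genus_means,
              order_summary = genus$order_summary, ratios = ratios,
              medians = medians, correlation = corr, venn = venn,
              aux_categories = aux_cat, networks = networks,
              length_thresholds = thresholds,
              location = locs, replicon_classes = replicon_classes)
  if (!is.null(out_dir)) {
    tables <- list(classified_proteins = res$classified,
                   class_counts = res$counts,
                   ori_calls = res$ori_table,
                   positions = res$positions,
                   genus_means = res$genus_means,
                   ratios = res$ratios$genus_means,
                   medians = res$medians,
                   venn = res$venn,
                   replicon_classes = res$replicon_classes,
                   location_per_order = res$location$per_order)
    if (!is.null(res$ks_table)) tables$ks_tests <- res$ks_table
    for (k in names(res$kdes))
      tables[[paste0("kde_", k)]] <- data.frame(
        grid = res$kdes[[k]]$grid, density = res$kdes[[k]]$density)
    for (k in names(res$networks))
      tables[[paste0("network_", k)]] <- res$networks[[k]]$edges
    write_results(tables, out_dir,
                  parameters = list(ks_method = ks_method,
                                    kde_bandwidth = kde_bandwidth,
                                    secondary_cutoff_bp = secondary_cutoff_bp,
                                    gc_skew_window = gc_skew_window,
                                    n_excluded_replicons =
                                      length(res$excluded_replicons)),
                  seed = seed)
  }
  res
}
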