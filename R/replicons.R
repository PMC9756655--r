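#' Classify replicons as primary/secondary chromosome or extrachromosomal
#'
#' The largest replicon of a genome is the primary chromosome; any other
#' replicon larger than the secondary-chromosome cutoff (default 800 kb) is
#' a secondary chromosome; the remainder are extrachromosomal. Ties for
#' largest are broken by lexicographic `replicon_id` and flagged.
#'
#' @param genome A [genome_record()].
#' @param secondary_cutoff_bp Size cutoff in bp (default 800,000).
#' @return `data.frame`: `replicon_id`, `length_bp`, `class`, `tie_flagged`.
#' @export
classify_replicons <- function(genome, secondary_cutoff_bp = 800000) {
  reps <- genome$replicons
  stopifnot(nrow(reps) >= 1)
  ord <- order(-reps$length_bp, reps$replicon_id)
  reps <- reps[ord, , drop = FALSE]
  cls <- ifelse(reps$length_bp > secondary_cutoff_bp, "secondary_chromosome",
                "extrachromosomal")
  cls[1] <- "primary_chromosome"
  tie <- nrow(reps) > 1 && reps$length_bp[2] == reps$length_bp[1]
  out <- data.frame(replicon_id = reps$replicon_id,
                    length_bp = reps$length_bp, class = cls,
                    tie_flagged = tie, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Where c-di-GMP genes live: primary vs non-primary replicons
#'
#' Per genome, the fraction of c-di-GMP-metabolizing genes on the primary
#' chromosome versus elsewhere; per order, the share of genomes with at
#' least one gene off the primary chromosome, the share of all c-di-GMP
#' genes located on secondary chromosomes, and the distribution of genomes
#' having 1, 2, or more than 2 replicons above the secondary-chromosome
#' cutoff.
#'
#' @param classified Classification table from [classify_genomes()].
#' @param genomes List of [genome_record()]s.
#' @param taxonomy Taxonomy table.
#' @param secondary_cutoff_bp Size cutoff in bp (default 800,000).
#' @return List with `per_genome` (`genome_id`, `n_genes`, `frac_primary`,
#'   `frac_nonprimary`) and `per_order` (`order`, `n_genomes`,
#'   `pct_genomes_with_nonprimary_gene`, `pct_genes_on_secondary`,
#'   `pct_0_replicons`, `pct_1_replicon`, `pct_2_replicons`,
#'   `pct_gt2_replicons`; the four shares sum to 100).
#' @export
gene_location_proportions <- function(classified, genomes, taxonomy,
                                      secondary_cutoff_bp = 800000) {
  rep_cls <- do.call(rbind, lapply(genomes, function(g)
    cbind(genome_id = g$genome_id,
          classify_replicons(g, secondary_cutoff_bp))))
  tab <- classified[classified$class %in% CDG_CLASSES &
                      !is.na(classified$replicon_id), , drop = FALSE]
  tab <- merge(tab, rep_cls[, c("genome_id", "replicon_id", "class")],
               by = c("genome_id", "replicon_id"),
               suffixes = c("", "_replicon"))
  per_genome <- do.call(rbind, lapply(split(tab, tab$genome_id), function(d) {
    n <- nrow(d)
    fp <- mean(d$class_replicon == "primary_chromosome")
    data.frame(genome_id = d$genome_id[1], n_genes = n, frac_primary = fp,
               frac_nonprimary = 1 - fp, stringsAsFactors = FALSE)
  }))
  rownames(per_genome) <- NULL
  # per-order shares over *all* genomes of the order (incl. gene-free ones)
  tax <- taxonomy
  big_counts <- vapply(genomes, function(g)
    sum(g$replicons$length_bp > secondary_cutoff_bp), integer(1))
  names(big_counts) <- vapply(genomes, `[[`, "", "genome_id")
  tax$n_big <- big_counts[tax$genome_id]
  per_order <- do.call(rbind, lapply(split(tax, tax$order), function(d) {
    ids <- d$genome_id
    gsub <- per_genome[per_genome$genome_id %in% ids, , drop = FALSE]
    has_np <- sum(gsub$frac_nonprimary > 0)
    tsub <- tab[tab$genome_id %in% ids, , drop = FALSE]
    on_sec <- if (nrow(tsub))
      100 * mean(tsub$class_replicon == "secondary_chromosome") else NA_real_
    data.frame(order = d$order[1], n_genomes = length(ids),
               pct_genomes_with_nonprimary_gene = 100 * has_np / length(ids),
               pct_genes_on_secondary = on_sec,
               pct_0_replicons = 100 * mean(d$n_big == 0),
               pct_1_replicon = 100 * mean(d$n_big == 1),
               pct_2_replicons = 100 * mean(d$n_big == 2),
               pct_gt2_replicons = 100 * mean(d$n_big > 2),
               stringsAsFactors = FALSE)
  }))
  rownames(per_order) <- NULL
  list(per_genome = per_genome, per_order = per_order)
}
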