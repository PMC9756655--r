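#' Configuration for the synthetic-genome generator
#'
#' Describes the study conditions a synthetic dataset plants: taxonomy
#' breadth, replicon sizes, per-class gene-count means (Poisson), per-class
#' positional models (mixtures of wrapped normals on the ori-anchored
#' 0-100% scale), auxiliary-domain models, the HHExxxxxGYP motif rate among
#' HD-superfamily proteins, and secondary-replicon settings. All
#' randomness flows from `seed`.
#'
#' @param n_orders,n_genera_per_order,n_genomes_per_genus Taxonomy shape.
#' @param replicon_length_bp Primary-chromosome length (default 4 Mb).
#' @param class_count_means Named numeric: Poisson mean gene count per
#'   genome for each enzyme group.
#' @param position_model Named list per class, each `list(mean, sd,
#'   weight)` parallel numeric vectors defining a wrapped-normal mixture on
#'   `[0, 100)` (weights sum to 1).
#' @param aux_model List with `alphabet` (named list per class: candidate
#'   auxiliary domain names), `count_probs` (named list per class:
#'   probabilities of 0, 1, 2, 3 auxiliary domains per sequence) and
#'   `pair_boost` (probability that a second domain is drawn as the
#'   alphabet neighbour of the first, planting co-occurrence structure).
#' @param aux_len_threshold Named integer per class: minimum length (aa)
#'   planted for auxiliary-domain-bearing sequences.
#' @param short_noaux_frac Fraction of auxiliary-free sequences drawn below
#'   the class threshold.
#' @param motif_rate Fraction of HD-domain proteins carrying the motif
#'   (the rest are emitted as unclassifiable HD decoys).
#' @param secondary_chromosome_prob Probability a genome carries a
#'   secondary chromosome.
#' @param secondary_length_bp,secondary_gene_fraction Secondary-chromosome
#'   length and the fraction of the genome's c-di-GMP genes placed on it
#'   when present.
#' @param emit_sequences Generate replicon nucleotide sequences with a GC
#'   skew switch at the planted ori (needed for GC-skew ori recovery;
#'   expensive for many multi-Mb genomes).
#' @param gc_skew_strength Excess probability of G over C on the leading
#'   strand (default 0.1).
#' @param seed Integer seed.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_orders = 1L, n_genera_per_order = 5L, n_genomes_per_genus = 4L,
    replicon_length_bp = 4e6,
    class_count_means = c(GGDEF = 4, EAL = 2, GGDEF_EAL = 2, HD_GYP = 1),
    position_model = list(
      GGDEF = list(mean = c(25, 50, 75), sd = c(5, 5, 5),
                   weight = c(1, 1, 1) / 3),
      EAL = list(mean = 5, sd = 6, weight = 1),
      GGDEF_EAL = list(mean = 8, sd = 8, weight = 1),
      HD_GYP = list(mean = 50, sd = 15, weight = 1)),
    aux_model = list(
      alphabet = list(
        GGDEF = c("PAS", "PAS_3", "PAS_4", "REC", "GAF", "HAMP", "dCache_1",
                  "CHASE3", "PHY", "HisKA"),
        EAL = c("REC", "CSS-motif", "GAF_2", "HisKA", "Hpt", "HAMP"),
        GGDEF_EAL = c("PAS", "PAS_3", "PAS_4", "PAS_7", "PAS_9", "MHYT",
                      "REC", "GAF"),
        HD_GYP = c("HD_5", "DUF3369", "DUF3391", "REC")),
      count_probs = list(
        GGDEF = c(0.35, 0.35, 0.20, 0.10),
        EAL = c(0.50, 0.30, 0.15, 0.05),
        GGDEF_EAL = c(0.25, 0.35, 0.25, 0.15),
        HD_GYP = c(0.20, 0.45, 0.25, 0.10)),
      pair_boost = 0.5),
    aux_len_threshold = c(GGDEF = 275, EAL = 375, GGDEF_EAL = 450,
                          HD_GYP = 300),
    short_noaux_frac = 0.49,
    motif_rate = 0.5,
    secondary_chromosome_prob = 0.2,
    secondary_length_bp = 1.2e6,
    secondary_gene_fraction = 0.3,
    emit_sequences = FALSE,
    gc_skew_strength = 0.1,
    seed = 1L) {
  cfg <- as.list(environment())
  for (k in CDG_CLASSES) {
    pm <- cfg$position_model[[k]]
    stopifnot(abs(sum(pm$weight) - 1) < 1e-9,
              length(pm$mean) == length(pm$sd),
              length(pm$mean) == length(pm$weight))
  }
  stopifnot(cfg$motif_rate > 0, cfg$motif_rate <= 1,
            cfg$short_noaux_frac >= 0, cfg$short_noaux_frac <= 1,
            cfg$secondary_chromosome_prob >= 0,
            cfg$secondary_chromosome_prob <= 1)
  structure(cfg, class = "synthetic_config")
}

#' Study-condition profile mirroring the headline positional pattern
#'
#' A ready-made configuration encoding the qualitative Rhodobacterales-like
#' pattern: EAL-encoding genes concentrated near ori (single wrapped-normal
#' mode at 5%), GGDEF genes tri-modal with peaks mid-replichore and at ter
#' (25/50/75%), and a GGDEF:EAL mean-count ratio of 2 (Poisson means 4 and
#' 2).
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
default_paper_profile <- function(seed = 1L, ...) {
  args <- list(n_orders = 1L, n_genera_per_order = 10L,
               n_genomes_per_genus = 4L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

#' Draw normalized positions from a planted class model
#'
#' Samples from the wrapped-normal mixture a configuration plants for one
#' enzyme group; useful for direct power/size experiments on the
#' distributional statistics.
#'
#' @param cfg A `synthetic_config`.
#' @param class Enzyme group name.
#' @param n Sample size.
#' @return Numeric vector in `[0, 100)`.
#' @export
sample_positions <- function(cfg, class, n) {
  pm <- cfg$position_model[[class]]
  stopifnot(!is.null(pm))
  comp <- sample.int(length(pm$weight), n, replace = TRUE, prob = pm$weight)
  stats::rnorm(n, pm$mean[comp], pm$sd[comp]) %% 100
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# aa sequence of given length, with/without the HD-GYP motif planted at
# `motif_at` (1-based); sequences required motif-free are re-drawn if the
# motif arises by chance (probability ~ 20^-6 per site).
make_protein_sequence <- function(length, with_motif = FALSE, motif_at = NULL) {
  repeat {
    s <- random_aa(length)
    if (!with_motif) {
      if (!grepl("HHE.{5}GYP", s)) return(s)
    } else {
      core <- paste0("HHE", random_aa(5), "GYP")
      at <- if (is.null(motif_at)) sample.int(length - 10L, 1L) else motif_at
      substr(s, at, at + 10L) <- core
      return(s)
    }
  }
}

# nucleotide sequence with a GC-skew switch at `ori`: the half circle
# downstream of ori is G-rich, the other half C-rich; G/C totals balance so
# the cumulative skew is rotation-clean.
make_skewed_sequence <- function(length_bp, ori, strength = 0.1) {
  base <- c("A", "C", "G", "T")
  p_lead <- c(0.25, 0.25 - strength / 2, 0.25 + strength / 2, 0.25)
  p_lag <- c(0.25, 0.25 + strength / 2, 0.25 - strength / 2, 0.25)
  half <- length_bp %/% 2
  lead <- sample(base, half, replace = TRUE, prob = p_lead)
  lag <- sample(base, length_bp - half, replace = TRUE, prob = p_lag)
  # sequence positions ori..ori+half-1 are leading (G-rich)
  s <- character(length_bp)
  idx_lead <- ((ori - 1 + seq_len(half) - 1) %% length_bp) + 1
  s[idx_lead] <- lead
  s[-idx_lead] <- lag
  paste(s, collapse = "")
}

sample_aux_set <- function(class, aux_model) {
  probs <- aux_model$count_probs[[class]]
  k <- sample.int(length(probs), 1L, prob = probs) - 1L
  if (k == 0L) return(character())
  alpha <- aux_model$alphabet[[class]]
  first <- sample(alpha, 1L)
  out <- first
  while (length(out) < k) {
    if (stats::runif(1) < aux_model$pair_boost) {
      # co-occurrence boost: prefer the alphabet neighbour of the first pick
      nb <- alpha[(match(first, alpha) %% length(alpha)) + 1L]
      out <- union(out, nb)
    } else {
      out <- union(out, sample(alpha, 1L))
    }
  }
  out
}

sample_protein_length <- function(class, has_aux, thr, short_frac) {
  # minimum room for the catalytic domain architecture
  base_len <- switch(class, GGDEF = 180L, EAL = 250L, GGDEF_EAL = 430L,
                     HD_GYP = 200L, NONE = 200L)
  if (has_aux) {
    thr[class] + 5L + stats::rgeom(1L, 1 / 150) %% 400L
  } else if (stats::runif(1) < short_frac) {
    sample(seq(base_len + 5L, thr[class] - 1L), 1L)
  } else {
    sample(seq(thr[class], thr[class] + 400L), 1L)
  }
}

# total span of the catalytic hits (incl. inter-hit gaps) per class
catalytic_span <- function(class) {
  switch(class, GGDEF = 166L, EAL = 236L, GGDEF_EAL = 402L,
         HD_GYP = 176L, NONE = 176L)
}

# domain hit layout on one protein: catalytic domains first, auxiliaries
# after, non-overlapping, all within [1, len]
layout_hits <- function(protein_id, class, aux, len) {
  doms <- switch(class,
                 GGDEF = list(c("PF00990", "GGDEF", 160L)),
                 EAL = list(c("PF00563", "EAL", 230L)),
                 GGDEF_EAL = list(c("PF00990", "GGDEF", 160L),
                                  c("PF00563", "EAL", 230L)),
                 HD_GYP = list(c("PF01966", "HD", 170L)),
                 NONE = list(c("PF01966", "HD", 170L)))
  for (a in aux) doms <- c(doms, list(c("", a, 70L)))
  pos <- 1L
  rows <- list()
  for (d in doms) {
    w <- as.integer(d[3])
    end <- min(pos + w - 1L, len)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = protein_id, domain_acc = d[1], domain_name = d[2],
      start = pos, end = end, evalue = NA_real_, stringsAsFactors = FALSE)
    pos <- end + 6L
    if (pos >= len) break
  }
  do.call(rbind, rows)
}

#' Generate a synthetic dataset with a truth record
#'
#' Builds genomes whose statistical structure matches the configuration:
#' per-genome enzyme-class counts are Poisson draws, gene positions come
#' from the planted wrapped-normal mixtures (rotated by each replicon's
#' planted ori and converted to nucleotide coordinates), HD-GYP proteins
#' carry the HHExxxxxGYP motif embedded in otherwise random sequence,
#' auxiliary-domain sets and protein lengths follow the planted models,
#' and (optionally) replicon FASTA sequences carry a GC-skew switch at the
#' planted ori so the skew estimator can recover it. Genes are placed
#' non-overlapping with >= 50 bp spacing; an infeasible configuration
#' (more gene length than replicon) is an error. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes the domain table,
#'   per-genome GFF3 (+ FASTA when sequences are generated), protein FASTA,
#'   taxonomy TSV, ori TSV and the truth record as JSON.
#' @return List with `genomes` (list of [genome_record()]s), `taxonomy`,
#'   `ori_table` (planted oris, unambiguous), `hits` (full domain table)
#'   and `truth` (planted per-genome class counts, per-gene classes,
#'   sampled positions and aux sets, planted model parameters).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  genomes <- list()
  tax_rows <- list()
  ori_rows <- list()
  truth_genes <- list()
  truth_counts <- list()
  g_idx <- 0L
  for (o in seq_len(cfg$n_orders)) {
    order_name <- sprintf("Order%02d", o)
    for (ge in seq_len(cfg$n_genera_per_order)) {
      genus_name <- sprintf("%s_Genus%02d", order_name, ge)
      for (gm in seq_len(cfg$n_genomes_per_genus)) {
        g_idx <- g_idx + 1L
        gid <- sprintf("G%04d", g_idx)
        species <- sprintf("%s sp. strain %02d", genus_name, gm)
        gen <- generate_one_genome(cfg, gid, order_name, genus_name, species)
        genomes[[gid]] <- gen$genome
        tax_rows[[gid]] <- data.frame(genome_id = gid, order = order_name,
                                      genus = genus_name,
                                      species_or_strain = species,
                                      stringsAsFactors = FALSE)
        ori_rows[[gid]] <- gen$ori_table
        truth_genes[[gid]] <- gen$gene_truth
        truth_counts[[gid]] <- data.frame(genome_id = gid,
                                          as.list(gen$planted_counts),
                                          stringsAsFactors = FALSE)
      }
    }
  }
  taxonomy <- do.call(rbind, tax_rows)
  ori_table <- do.call(rbind, ori_rows)
  hits <- do.call(rbind, lapply(genomes, `[[`, "hits"))
  gene_truth <- do.call(rbind, truth_genes)
  planted_counts <- do.call(rbind, truth_counts)
  rownames(taxonomy) <- rownames(ori_table) <- rownames(hits) <-
    rownames(gene_truth) <- rownames(planted_counts) <- NULL
  truth <- list(planted_counts = planted_counts, genes = gene_truth,
                position_model = cfg$position_model,
                aux_len_threshold = as.list(cfg$aux_len_threshold),
                short_noaux_frac = cfg$short_noaux_frac,
                seed = cfg$seed)
  out <- list(genomes = genomes, taxonomy = taxonomy, ori_table = ori_table,
              hits = hits, truth = truth)
  if (!is.null(out_dir)) write_dataset_files(out, cfg, out_dir)
  out
}

generate_one_genome <- function(cfg, gid, order_name, genus_name, species) {
  L1 <- cfg$replicon_length_bp
  reps <- data.frame(replicon_id = paste0(gid, "_chr1"), length_bp = L1,
                     stringsAsFactors = FALSE)
  if (stats::runif(1) < cfg$secondary_chromosome_prob)
    reps <- rbind(reps, data.frame(replicon_id = paste0(gid, "_chr2"),
                                   length_bp = cfg$secondary_length_bp,
                                   stringsAsFactors = FALSE))
  reps$ori_true <- vapply(reps$length_bp, function(L)
    sample.int(L, 1L), integer(1))

  counts <- vapply(CDG_CLASSES, function(k)
    stats::rpois(1L, cfg$class_count_means[[k]]), integer(1))
  n_hd_decoy <- if (cfg$motif_rate < 1)
    stats::rbinom(1L, counts[["HD_GYP"]] + 2L, 1 - cfg$motif_rate) else 0L

  classes <- c(rep(names(counts), counts), rep("NONE", n_hd_decoy))
  n_genes <- length(classes)
  prot_rows <- list(); hit_rows <- list(); truth_rows <- list()
  for (i in seq_len(n_genes)) {
    cl <- classes[i]
    pid <- sprintf("%s_p%03d", gid, i)
    if (cl == "NONE") {
      aux <- character()
      plen <- 250L
      pos <- stats::runif(1, 0, 100)
      seq_aa <- make_protein_sequence(plen, with_motif = FALSE)
    } else {
      aux <- sample_aux_set(cl, cfg$aux_model)
      plen <- sample_protein_length(cl, length(aux) > 0,
                                    cfg$aux_len_threshold,
                                    cfg$short_noaux_frac)
      if (length(aux))  # room for every planted hit in the layout
        plen <- max(plen, catalytic_span(cl) + 76L * length(aux) + 10L)
      pos <- sample_positions(cfg, cl, 1L)
      if (cl == "HD_GYP") {
        hd_start <- 1L  # HD hit laid out first; plant motif inside it
        seq_aa <- make_protein_sequence(plen, with_motif = TRUE,
                                        motif_at = hd_start + 20L)
      } else {
        seq_aa <- make_protein_sequence(plen, with_motif = FALSE)
      }
    }
    # replicon assignment: secondary gets its planted share of genes
    rid <- reps$replicon_id[1]
    if (nrow(reps) > 1 && stats::runif(1) < cfg$secondary_gene_fraction)
      rid <- reps$replicon_id[2]
    L <- reps$length_bp[reps$replicon_id == rid]
    ori <- reps$ori_true[reps$replicon_id == rid]
    glen <- 3L * plen + 3L
    mid <- ((pos / 100 * L + ori - 1) %% L) + 1
    start <- round(mid - glen / 2)  # may fall outside [1, L]; normalized below
    end <- start + glen - 1L
    prot_rows[[i]] <- data.frame(
      protein_id = pid, length = plen, sequence = seq_aa, replicon_id = rid,
      start = start, end = end,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    hit_rows[[i]] <- layout_hits(pid, cl, aux, plen)
    truth_rows[[i]] <- data.frame(
      genome_id = gid, protein_id = pid, true_class = cl,
      true_position = if (cl == "NONE") NA_real_ else pos,
      replicon_id = rid, aux_domains = paste(sort(aux), collapse = ","),
      length = plen, stringsAsFactors = FALSE)
  }

  proteins <- if (n_genes) do.call(rbind, prot_rows) else
    data.frame(protein_id = character(), length = integer(),
               sequence = character(), replicon_id = character(),
               start = numeric(), end = numeric(), strand = character(),
               stringsAsFactors = FALSE)
  # resolve overlaps per replicon on the circle: shift later genes right
  # (>= 50 bp gaps); genes pushed past the linear end wrap into the gap
  # before the first gene so circular positions stay near the sampled ones
  for (rid in reps$replicon_id) {
    L <- reps$length_bp[reps$replicon_id == rid]
    idx <- which(proteins$replicon_id == rid)
    if (!length(idx)) next
    gl <- proteins$end[idx] - proteins$start[idx] + 1
    if (sum(gl + 51) > L)
      stop("infeasible configuration: total gene length exceeds replicon ",
           rid)
    st <- ((proteins$start[idx] - 1) %% L) + 1
    done <- FALSE
    for (iter in 1:10) {
      ord <- order(st)
      st_o <- st[ord]; gl_o <- gl[ord]
      en_o <- st_o + gl_o - 1
      for (j in seq_along(ord)[-1]) {
        min_start <- en_o[j - 1] + 51
        if (st_o[j] < min_start) {
          st_o[j] <- min_start
          en_o[j] <- min_start + gl_o[j] - 1
        }
      }
      st[ord] <- st_o
      over <- which(en_o > L)
      if (!length(over)) { done <- TRUE; break }
      cursor <- 1  # overflowers wrap into the front, then re-relax
      for (j in over) {
        st[ord[j]] <- cursor
        cursor <- cursor + gl_o[j] + 50
      }
    }
    if (!done)
      stop("infeasible configuration: genes exceed replicon ", rid,
           " after spacing")
    proteins$start[idx] <- st
    proteins$end[idx] <- st + gl - 1
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    empty_domain_table()

  seqs <- NULL
  replicons <- data.frame(replicon_id = reps$replicon_id,
                          length_bp = reps$length_bp, ori = NA_real_,
                          stringsAsFactors = FALSE)
  if (cfg$emit_sequences) {
    replicons$sequence <- vapply(seq_len(nrow(reps)), function(k)
      make_skewed_sequence(reps$length_bp[k], reps$ori_true[k],
                           cfg$gc_skew_strength), character(1))
  }
  genome <- genome_record(gid, order = order_name, genus = genus_name,
                          species = species, replicons = replicons,
                          proteins = proteins, hits = hits)
  ori_table <- data.frame(replicon_id = reps$replicon_id,
                          ori = reps$ori_true, method = "user_supplied",
                          ambiguous = FALSE, stringsAsFactors = FALSE)
  list(genome = genome, ori_table = ori_table,
       planted_counts = counts,
       gene_truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
         NULL)
}

write_dataset_files <- function(dataset, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$hits, file.path(out_dir, "domain_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_ori_table(dataset$ori_table, file.path(out_dir, "ori.tsv"))
  ann_dir <- file.path(out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  aa <- character(); aa_names <- character()
  for (g in dataset$genomes) {
    write_gff3_genome(g, file.path(ann_dir, paste0(g$genome_id, ".gff3")))
    if (!is.null(g$replicons$sequence)) {
      dna <- Biostrings::DNAStringSet(g$replicons$sequence)
      names(dna) <- g$replicons$replicon_id
      Biostrings::writeXStringSet(dna, file.path(
        ann_dir, paste0(g$genome_id, ".fasta")))
    }
    aa <- c(aa, g$proteins$sequence)
    aa_names <- c(aa_names, g$proteins$protein_id)
  }
  aaset <- Biostrings::AAStringSet(aa)
  names(aaset) <- aa_names
  Biostrings::writeXStringSet(aaset, file.path(out_dir, "proteins.faa"))
  jsonlite::write_json(dataset$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# plain GFF3 writer: region feature per replicon + one CDS per protein
write_gff3_genome <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (k in seq_len(nrow(genome$replicons))) {
    r <- genome$replicons[k, ]
    writeLines(sprintf("##sequence-region %s 1 %d", r$replicon_id,
                       as.integer(r$length_bp)), con)
  }
  for (k in seq_len(nrow(genome$replicons))) {
    r <- genome$replicons[k, ]
    writeLines(sprintf("%s\tcdgmap\tregion\t1\t%d\t.\t+\t.\tID=%s",
                       r$replicon_id, as.integer(r$length_bp),
                       r$replicon_id), con)
  }
  p <- genome$proteins
  for (k in seq_len(nrow(p))) {
    writeLines(sprintf(
      "%s\tcdgmap\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;protein_id=%s",
      p$replicon_id[k], as.integer(p$start[k]), as.integer(p$end[k]),
      p$strand[k], p$protein_id[k], p$protein_id[k]), con)
  }
  invisible(path)
}

#' Fixture group with an exact planted length threshold
#'
#' Constructs, deterministically, one enzyme group's protein lengths so the
#' minimum auxiliary-bearing length and the share of short auxiliary-free
#' sequences are planted exactly: the aux-bearing side contains one protein
#' exactly at `threshold`, and `round(pct_short/100 * n_without)` of the
#' aux-free side lie below it.
#'
#' @param threshold Planted minimum length (aa) for aux-bearing proteins.
#' @param pct_short Planted percentage of aux-free proteins below it.
#' @param n_with,n_without Group sizes.
#' @return List with `lengths_with_aux`, `lengths_without_aux`.
#' @export
plant_length_threshold_group <- function(threshold = 375, pct_short = 49,
                                         n_with = 50, n_without = 100) {
  stopifnot(n_with >= 1, n_without >= 1)
  with_aux <- c(threshold, threshold + seq_len(n_with - 1) * 7)
  n_short <- round(pct_short / 100 * n_without)
  without <- c(threshold - 1 - (seq_len(n_short) - 1) %% (threshold - 60),
               threshold + (seq_len(n_without - n_short) - 1) * 5)
  list(lengths_with_aux = with_aux, lengths_without_aux = without)
}
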