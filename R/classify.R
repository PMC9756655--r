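#' Detect the HD-GYP catalytic motif
#'
#' HD-superfamily domains are only counted as c-di-GMP phosphodiesterases
#' when the sequence carries the HHExxxxxGYP signature: H, H, E, five
#' arbitrary residues, then G, Y, P. The scan is case-insensitive and, by
#' default, runs over the whole sequence; `within` restricts it to given
#' amino-acid intervals (e.g. HD hit bounds padded by 10 aa).
#'
#' @param sequence Amino-acid string (20 standard residues plus X/B/Z/U and
#'   `*`/`-`).
#' @param within Optional two-column matrix or data.frame of 1-based
#'   inclusive aa intervals to restrict the scan to.
#' @return `TRUE` if the motif occurs (in any requested window).
#' @export
scan_hdgyp_motif <- function(sequence, within = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  seq <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZU*-]", seq))
    stop("sequence contains characters outside the amino-acid alphabet")
  pattern <- "HHE.{5}GYP"
  if (is.null(within)) return(grepl(pattern, seq))
  within <- as.matrix(within)
  for (k in seq_len(nrow(within))) {
    lo <- max(1L, as.integer(within[k, 1]))
    hi <- min(nchar(seq), as.integer(within[k, 2]))
    if (hi >= lo && grepl(pattern, substr(seq, lo, hi))) return(TRUE)
  }
  FALSE
}

#' Classify one protein into an enzyme group
#'
#' Assigns exactly one of `GGDEF`, `EAL`, `GGDEF_EAL`, `HD_GYP` or `NONE`
#' from the protein's domain architecture:
#' * GGDEF and EAL both present -> `GGDEF_EAL` (hybrid);
#' * GGDEF only -> `GGDEF`; EAL only -> `EAL`;
#' * an HD hit with no GGDEF/EAL and the HHExxxxxGYP motif -> `HD_GYP`;
#' * otherwise `NONE`.
#'
#' Auxiliary domains are all distinct domain names on the protein minus
#' GGDEF and EAL, and minus HD only when the protein is classed `HD_GYP`;
#' an HD domain without the motif on a GGDEF/EAL protein therefore counts
#' as auxiliary. Repeated occurrences of a domain are counted once.
#'
#' @param hits `data.frame` of this protein's domain hits (`domain_acc`,
#'   `domain_name`, `start`, `end`).
#' @param sequence Amino-acid sequence; required only when an HD hit must be
#'   motif-checked to decide the class (HD present, no GGDEF/EAL).
#' @param motif_scope `"whole_sequence"` (default) scans the entire
#'   sequence; `"hd_hits"` restricts the scan to HD hit intervals +/- 10 aa.
#' @return List with `class`, `cdg_domains` (character), `aux_domains`
#'   (character, deduplicated, sorted).
#' @export
classify_protein <- function(hits, sequence = NULL,
                             motif_scope = c("whole_sequence", "hd_hits")) {
  motif_scope <- match.arg(motif_scope)
  ident <- domain_identity(hits)
  is_ggdef <- ident == CDG_ACCESSIONS[["GGDEF"]] | hits$domain_name == "GGDEF"
  is_eal <- ident == CDG_ACCESSIONS[["EAL"]] | hits$domain_name == "EAL"
  is_hd <- ident == CDG_ACCESSIONS[["HD"]] | hits$domain_name == "HD"
  has_ggdef <- any(is_ggdef)
  has_eal <- any(is_eal)
  has_hd <- any(is_hd)

  cls <- "NONE"
  motif <- FALSE
  if (has_ggdef && has_eal) cls <- "GGDEF_EAL"
  else if (has_ggdef) cls <- "GGDEF"
  else if (has_eal) cls <- "EAL"
  else if (has_hd) {
    if (is.null(sequence) || is.na(sequence))
      stop("motif check impossible: HD hit present but no sequence available")
    within <- if (motif_scope == "hd_hits")
      cbind(hits$start[is_hd] - 10L, hits$end[is_hd] + 10L) else NULL
    motif <- scan_hdgyp_motif(sequence, within = within)
    if (motif) cls <- "HD_GYP"
  }

  names_all <- unique(hits$domain_name)
  cdg <- character()
  if (has_ggdef) cdg <- c(cdg, "GGDEF")
  if (has_eal) cdg <- c(cdg, "EAL")
  aux <- setdiff(names_all, c("GGDEF", "EAL"))
  if (cls == "HD_GYP") {
    cdg <- "HD"
    aux <- setdiff(aux, "HD")
  }
  list(class = cls, cdg_domains = sort(cdg), aux_domains = sort(aux))
}

# Domain identity is the Pfam accession when present, else the name; keeps
# PAS subfamilies (PAS_3, PAS_4, ...) distinct.
domain_identity <- function(hits) {
  acc <- hits$domain_acc
  ifelse(is.na(acc) | acc == "", hits$domain_name, acc)
}

#' Classify every protein of a genome
#'
#' Runs [classify_protein()] over all proteins and tallies per-class counts.
#' A protein contributes at most once per class no matter how many copies of
#' a catalytic domain it carries. Proteins without any hit are classed
#' `NONE`.
#'
#' @param genome A [genome_record()].
#' @inheritParams classify_protein
#' @return List with `classified` (a `data.frame`: `genome_id`, `protein_id`,
#'   `class`, `cdg_domains`, `aux_domains`, `n_aux`, `length`, `replicon_id`,
#'   `start`, `end`) and `counts` (named integer vector over the four enzyme
#'   groups, `NONE` excluded).
#' @export
classify_genome <- function(genome, motif_scope = c("whole_sequence", "hd_hits")) {
  motif_scope <- match.arg(motif_scope)
  prot <- genome$proteins
  hits <- genome$hits
  n <- nrow(prot)
  cls <- character(n); cdg <- character(n); aux <- character(n)
  n_aux <- integer(n)
  hit_idx <- split(seq_len(nrow(hits)), hits$protein_id)
  seqs <- if (!is.null(prot$sequence)) prot$sequence else rep(NA_character_, n)
  for (i in seq_len(n)) {
    h <- hits[hit_idx[[prot$protein_id[i]]] %||% integer(), , drop = FALSE]
    res <- classify_protein(h, sequence = seqs[i], motif_scope = motif_scope)
    cls[i] <- res$class
    cdg[i] <- paste(res$cdg_domains, collapse = ",")
    aux[i] <- paste(res$aux_domains, collapse = ",")
    n_aux[i] <- length(res$aux_domains)
  }
  classified <- data.frame(
    genome_id = rep(genome$genome_id, n), protein_id = prot$protein_id,
    class = cls,
    cdg_domains = cdg, aux_domains = aux, n_aux = n_aux,
    length = prot$length,
    replicon_id = prot$replicon_id %||% rep(NA_character_, n),
    start = prot$start %||% rep(NA_real_, n),
    end = prot$end %||% rep(NA_real_, n),
    stringsAsFactors = FALSE)
  counts <- vapply(CDG_CLASSES, function(k) sum(cls == k), integer(1))
  list(classified = classified, counts = counts)
}

#' Classify a list of genomes
#'
#' @param genomes List of [genome_record()]s.
#' @inheritParams classify_protein
#' @return List with `classified` (row-bound table over all genomes) and
#'   `counts` (`data.frame`: `genome_id`, one column per enzyme group).
#' @export
classify_genomes <- function(genomes, motif_scope = c("whole_sequence", "hd_hits")) {
  motif_scope <- match.arg(motif_scope)
  res <- lapply(genomes, classify_genome, motif_scope = motif_scope)
  classified <- do.call(rbind, lapply(res, `[[`, "classified"))
  counts <- do.call(rbind, lapply(res, function(r)
    as.data.frame(as.list(r$counts))))
  counts <- cbind(genome_id = vapply(genomes, `[[`, "", "genome_id"), counts,
                  stringsAsFactors = FALSE)
  rownames(classified) <- rownames(counts) <- NULL
  list(classified = classified, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
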