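#' cdgmap: comparative genomics of c-di-GMP signaling genes
#'
#' Tools for surveying genes that encode c-di-GMP-metabolizing enzymes
#' (diguanylate cyclases with GGDEF domains, phosphodiesterases with EAL or
#' HD-GYP domains, and GGDEF_EAL hybrids) across bacterial genomes: domain
#' architecture classification, ori/ter-anchored chromosomal positioning,
#' distributional statistics, auxiliary-domain analytics, replicon accounting,
#' and a synthetic-genome generator for end-to-end validation.
#'
#' @name cdgmap-package
#' @keywords internal
"_PACKAGE"

#' Enzyme group labels
#'
#' The five mutually exclusive enzyme groups a protein can be assigned to.
#' `NONE` marks proteins that carry no c-di-GMP-metabolizing domain (including
#' HD-superfamily proteins lacking the HHExxxxxGYP motif).
#'
#' @export
CDG_CLASSES <- c("GGDEF", "EAL", "GGDEF_EAL", "HD_GYP")

# Pfam accessions of the catalytic domains the survey keys on.
CDG_ACCESSIONS <- c(GGDEF = "PF00990", EAL = "PF00563", HD = "PF01966")

#' Construct a genome record
#'
#' A `genome_record` bundles one genome's replicons, proteins and taxonomy into
#' the container the downstream stages consume. Replicons are circular;
#' coordinates are 1-based inclusive nucleotide (gene loci) or amino-acid
#' (domain hits) intervals, matching GenBank/GFF3 conventions.
#'
#' @param genome_id Genome identifier (string).
#' @param order,genus,species Taxonomy labels.
#' @param replicons `data.frame` with columns `replicon_id`, `length_bp`, and
#'   optionally `ori` (nt, `NA` if unknown) and `sequence` (nt string).
#' @param proteins `data.frame` with columns `protein_id`, `length` (aa) and
#'   optionally `sequence` (aa string), `replicon_id`, `start`, `end`,
#'   `strand` for proteins whose gene locus is known.
#' @param hits `data.frame` of domain hits as returned by
#'   [read_domain_table()], restricted to this genome's proteins.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, order = NA_character_, genus = NA_character_,
                          species = NA_character_, replicons, proteins,
                          hits = empty_domain_table()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  replicons <- as.data.frame(replicons)
  proteins <- as.data.frame(proteins)
  if (!all(c("replicon_id", "length_bp") %in% names(replicons)))
    stop("replicons must have columns replicon_id and length_bp")
  if (is.null(replicons$ori)) replicons$ori <- NA_real_
  if (anyDuplicated(replicons$replicon_id))
    stop("duplicated replicon_id within genome ", genome_id)
  bad_ori <- !is.na(replicons$ori) &
    (replicons$ori < 1 | replicons$ori > replicons$length_bp)
  if (any(bad_ori))
    stop("ori outside [1, length_bp] for replicon ",
         replicons$replicon_id[bad_ori][1])
  if (!all(c("protein_id", "length") %in% names(proteins)))
    stop("proteins must have columns protein_id and length")
  if (!is.null(proteins$replicon_id)) {
    known <- !is.na(proteins$replicon_id)
    orphan <- setdiff(proteins$replicon_id[known], replicons$replicon_id)
    if (length(orphan))
      stop("gene locus references unknown replicon: ", orphan[1])
  }
  if (!is.null(proteins$sequence)) {
    has_seq <- !is.na(proteins$sequence)
    if (any(has_seq & nchar(proteins$sequence) != proteins$length))
      stop("protein sequence length disagrees with declared length")
  }
  structure(list(genome_id = genome_id, order = order, genus = genus,
                 species = species, replicons = replicons,
                 proteins = proteins, hits = hits),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s / %s / %s)\n", x$genome_id,
              x$order, x$genus, x$species))
  cat(sprintf("  %d replicon(s), total %.2f Mb; %d protein(s), %d domain hit(s)\n",
              nrow(x$replicons), sum(x$replicons$length_bp) / 1e6,
              nrow(x$proteins), nrow(x$hits)))
  invisible(x)
}

empty_domain_table <- function() {
  data.frame(protein_id = character(), domain_acc = character(),
             domain_name = character(), start = integer(), end = integer(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# Normalize a wrap-around CDS (end < start on a circular replicon) to
# start..(end + length): keeps start <= end while preserving the circular
# midpoint.
normalize_locus <- function(start, end, length_bp) {
  wrap <- end < start
  end[wrap] <- end[wrap] + length_bp[wrap]
  list(start = start, end = end)
}
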