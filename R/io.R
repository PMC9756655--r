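#' Read a per-protein domain-hit table
#'
#' Reads a TSV emulating Pfam per-protein annotations: one row per domain hit
#' with 1-based inclusive amino-acid coordinates. Malformed coordinate rows
#' are rejected with the offending line number.
#'
#' @param path Path to a TSV with header columns `protein_id`, `domain_acc`,
#'   `domain_name`, `start`, `end` and optionally `evalue`.
#' @param evalue_max Optional e-value ceiling; hits above it are dropped.
#'   Default `NULL` accepts all rows (Pfam-style tables are typically already
#'   thresholded by the curated gathering cutoffs).
#' @return A `data.frame` with one row per retained hit.
#' @export
read_domain_table <- function(path, evalue_max = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("protein_id", "domain_acc", "domain_name", "start", "end")
  missing_col <- setdiff(required, names(tab))
  if (length(missing_col))
    stop("domain table ", path, " is missing required column(s): ",
         paste(missing_col, collapse = ", "))
  if (nrow(tab) == 0L) return(empty_domain_table())
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  bad <- is.na(start) | is.na(end) | start < 1L | start > end
  if (any(bad))
    stop("malformed domain coordinates at data line ", which(bad)[1],
         " of ", path, " (need 1 <= start <= end)")
  evalue <- if (is.null(tab$evalue)) rep(NA_real_, nrow(tab)) else
    suppressWarnings(as.numeric(tab$evalue))
  out <- data.frame(protein_id = tab$protein_id, domain_acc = tab$domain_acc,
                    domain_name = tab$domain_name, start = start, end = end,
                    evalue = evalue, stringsAsFactors = FALSE)
  if (!is.null(evalue_max))
    out <- out[is.na(out$evalue) | out$evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read taxonomy labels
#'
#' @param path TSV with columns `genome_id`, `order`, `genus`,
#'   `species_or_strain`.
#' @return `data.frame` of taxonomy labels.
#' @export
read_taxonomy_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("genome_id", "order", "genus", "species_or_strain")
  missing_col <- setdiff(required, names(tab))
  if (length(missing_col))
    stop("taxonomy table is missing column(s): ",
         paste(missing_col, collapse = ", "))
  tab
}

#' Read or write a replication-origin table
#'
#' The ori table carries curated or estimated replication origins per
#' replicon; supplying one replaces the built-in GC-skew estimator. Ambiguous
#' calls are retained in the table but excluded from positional analysis.
#'
#' @param path TSV path with columns `replicon_id`, `ori` and optionally
#'   `method`, `ambiguous`.
#' @return `data.frame` with columns `replicon_id`, `ori`, `method`,
#'   `ambiguous`.
#' @export
read_ori_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("replicon_id", "ori") %in% names(tab)))
    stop("ori table needs columns replicon_id and ori")
  if (is.null(tab$method)) tab$method <- "user_supplied"
  if (is.null(tab$ambiguous)) tab$ambiguous <- FALSE
  tab$ambiguous <- as.logical(tab$ambiguous)
  tab[c("replicon_id", "ori", "method", "ambiguous")]
}

#' @rdname read_ori_table
#' @param ori_table `data.frame` of ori calls.
#' @export
write_ori_table <- function(ori_table, path) {
  utils::write.table(ori_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genome annotation (GFF3 + FASTA, or GenBank flat file)
#'
#' Builds a [genome_record()] from standard annotation formats. GFF3 is read
#' through `rtracklayer`; replicon lengths come from `region` features or,
#' failing that, from the FASTA. CDS features must carry a `protein_id` (or
#' `ID`) attribute; CDS lacking one are skipped with a warning. GenBank flat
#' files are parsed for LOCUS length and CDS `/protein_id` qualifiers;
#' `join()` spans wrapping the origin are normalized to `start..end+length`.
#'
#' @param annotation_path Path to a `.gff`/`.gff3` or GenBank (`.gb`,
#'   `.gbk`, `.gbff`) file.
#' @param fasta_path Optional nucleotide FASTA supplying replicon sequences
#'   (and lengths when the annotation lacks them).
#' @param genome_id Identifier for the resulting record; defaults to the
#'   annotation file stem.
#' @return A `genome_record` (taxonomy fields left `NA`; attach them from a
#'   taxonomy table).
#' @export
read_genome_annotation <- function(annotation_path, fasta_path = NULL,
                                   genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]+$", "", basename(annotation_path))
  ext <- tolower(sub(".*\\.", "", annotation_path))
  seqs <- NULL
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*", "", names(seqs))
  }
  if (ext %in% c("gff", "gff3")) {
    rec <- parse_gff3_annotation(annotation_path, seqs, genome_id)
  } else if (ext %in% c("gb", "gbk", "gbff", "genbank")) {
    rec <- parse_genbank_annotation(annotation_path, genome_id)
  } else {
    stop("unrecognized annotation format: ", annotation_path)
  }
  rec
}

parse_gff3_annotation <- function(path, seqs, genome_id) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  regions <- gr[type == "region"]
  if (length(regions)) {
    replicons <- data.frame(replicon_id = as.character(GenomeInfoDb::seqnames(regions)),
                            length_bp = BiocGenerics::end(regions),
                            stringsAsFactors = FALSE)
  } else if (!is.null(seqs)) {
    replicons <- data.frame(replicon_id = names(seqs),
                            length_bp = Biostrings::width(seqs),
                            stringsAsFactors = FALSE)
  } else {
    stop("replicon lengths unavailable: annotation has no region features ",
         "and no FASTA was given")
  }
  replicons$ori <- NA_real_
  if (!is.null(seqs)) {
    replicons$sequence <- as.character(seqs[replicons$replicon_id])
  }
  cds <- gr[type == "CDS"]
  pid <- if (!is.null(cds$protein_id)) as.character(cds$protein_id)
         else as.character(cds$ID)
  skipped <- sum(is.na(pid))
  if (skipped)
    warning(skipped, " CDS feature(s) without protein_id skipped")
  keep <- !is.na(pid)
  cds <- cds[keep]; pid <- pid[keep]
  rid <- as.character(GenomeInfoDb::seqnames(cds))
  orphan <- setdiff(rid, replicons$replicon_id)
  if (length(orphan))
    stop("CDS references unknown replicon: ", orphan[1])
  proteins <- data.frame(
    protein_id = pid,
    length = as.integer(floor((BiocGenerics::width(cds) - 3) / 3)),
    replicon_id = rid,
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds),
    strand = as.character(BiocGenerics::strand(cds)),
    stringsAsFactors = FALSE)
  genome_record(genome_id, replicons = replicons, proteins = proteins)
}

# Minimal GenBank flat-file reader: LOCUS lines give replicon ids and
# lengths; CDS features give coordinates and /protein_id qualifiers.
# Handles complement() and simple join() locations; a join whose end lies
# before its start on a circular record is normalized across the origin.
parse_genbank_annotation <- function(path, genome_id) {
  lines <- readLines(path)
  locus_idx <- grep("^LOCUS", lines)
  if (!length(locus_idx))
    stop("GenBank file ", path, " has no LOCUS line (replicon length absent)")
  locus_idx <- c(locus_idx, length(lines) + 1L)
  replicons <- data.frame(replicon_id = character(), length_bp = numeric(),
                          stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = character(), length = integer(),
                         replicon_id = character(), start = numeric(),
                         end = numeric(), strand = character(),
                         stringsAsFactors = FALSE)
  skipped <- 0L
  for (k in seq_len(length(locus_idx) - 1L)) {
    block <- lines[locus_idx[k]:(locus_idx[k + 1L] - 1L)]
    toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
    rid <- toks[2]
    len <- suppressWarnings(as.numeric(toks[3]))
    if (is.na(len))
      stop("LOCUS line for ", rid, " lacks a parseable length")
    replicons <- rbind(replicons, data.frame(replicon_id = rid, length_bp = len,
                                             stringsAsFactors = FALSE))
    feat <- grep("^     CDS ", block)
    for (f in feat) {
      loc <- trimws(sub("^     CDS\\s+", "", block[f]))
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2) next
      start <- min(nums[1], utils::tail(nums, 1))
      end <- max(nums[1], utils::tail(nums, 1))
      if (grepl("join", loc) && nums[1] > utils::tail(nums, 1)) {
        norm <- normalize_locus(nums[1], utils::tail(nums, 1), len)
        start <- norm$start; end <- norm$end
      }
      # scan forward for the protein_id qualifier of this feature
      j <- f + 1L
      pid <- NA_character_
      while (j <= length(block) && !grepl("^     \\S", block[j])) {
        m <- regmatches(block[j], regexec("/protein_id=\"([^\"]+)\"", block[j]))[[1]]
        if (length(m) == 2) { pid <- m[2]; break }
        j <- j + 1L
      }
      if (is.na(pid)) { skipped <- skipped + 1L; next }
      proteins <- rbind(proteins, data.frame(
        protein_id = pid, length = as.integer(floor((end - start + 1 - 3) / 3)),
        replicon_id = rid, start = start, end = end, strand = strand,
        stringsAsFactors = FALSE))
    }
  }
  if (skipped)
    warning(skipped, " CDS feature(s) without protein_id skipped")
  replicons$ori <- NA_real_
  genome_record(genome_id, replicons = replicons, proteins = proteins)
}

#' Read protein sequences from an amino-acid FASTA
#'
#' Sequences are required for the HHExxxxxGYP motif check on HD-superfamily
#' proteins; headers are truncated at the first whitespace.
#'
#' @param path Amino-acid FASTA.
#' @return Named character vector of sequences keyed by protein id.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*", "", names(aa))
  out
}

#' Write result tables and a run manifest
#'
#' Emits each named table as a deterministic TSV (rows sorted over all
#' columns, fixed column order) plus a JSON manifest recording the table
#' files, parameters and seed, so that identical inputs produce
#' byte-identical outputs.
#'
#' @param tables Named list of `data.frame`s. May be empty.
#' @param out_dir Output directory, created if needed.
#' @param parameters Named list recorded verbatim in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, parameters = list(), seed = NULL) {
  if (length(tables) && (is.null(names(tables)) || any(names(tables) == "")))
    stop("every result table must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (is.null(names(tab)) || any(is.na(names(tab))) || any(names(tab) == ""))
      stop("table '", nm, "' has an unnamed column")
    if (nrow(tab) > 1L) {
      ord <- do.call(order, unname(lapply(tab, function(col)
        if (is.list(col)) vapply(col, paste, "", collapse = ",") else col)))
      tab <- tab[ord, , drop = FALSE]
    }
    for (cn in names(tab))
      if (is.list(tab[[cn]]))
        tab[[cn]] <- vapply(tab[[cn]], paste, "", collapse = ",")
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[nm] <- basename(path)
  }
  manifest <- list(tables = as.list(files), parameters = parameters,
                   seed = seed,
                   versions = list(cdgmap = as.character(utils::packageVersion("cdgmap")),
                                   R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
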