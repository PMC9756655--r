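# Shared fixtures built in code.

hit_row <- function(protein_id, name, acc = "", start = 1L, end = start + 69L) {
  data.frame(protein_id = protein_id, domain_acc = acc, domain_name = name,
             start = as.integer(start), end = as.integer(end),
             evalue = NA_real_, stringsAsFactors = FALSE)
}

hits_for <- function(names, protein_id = "p1") {
  starts <- cumsum(c(1L, rep(80L, length(names) - 1L)))
  do.call(rbind, Map(function(nm, st) hit_row(protein_id, nm, start = st),
                     names, starts))
}

# random aa sequence; motif-free unless asked
rand_seq <- function(n, with_motif = FALSE) {
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                    replace = TRUE), collapse = "")
  if (with_motif) {
    at <- sample.int(n - 11L, 1L)
    substr(s, at, at + 10L) <- paste0("HHE", substr(rand_seq(5), 1, 5), "GYP")
  } else {
    while (grepl("HHE.{5}GYP", s)) s <- rand_seq(n)
  }
  s
}

tiny_genome <- function(genome_id = "G1", classes = c("GGDEF", "EAL"),
                        L = 1e4) {
  n <- length(classes)
  prot <- data.frame(protein_id = paste0(genome_id, "_p", seq_len(n)),
                     length = 300L,
                     sequence = vapply(classes, function(cl)
                       rand_seq(300, with_motif = cl == "HD_GYP"),
                       character(1)),
                     replicon_id = paste0(genome_id, "_chr"),
                     start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 899,
                     strand = "+", stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(seq_len(n), function(i) {
    nm <- switch(classes[i], GGDEF = "GGDEF", EAL = "EAL",
                 GGDEF_EAL = c("GGDEF", "EAL"), HD_GYP = "HD", NONE = "PAS")
    hits_for(nm, prot$protein_id[i])
  }))
  genome_record(genome_id, order = "OrderA", genus = "GenusA",
                species = "sp. 1",
                replicons = data.frame(replicon_id = paste0(genome_id, "_chr"),
                                       length_bp = L, ori = 1,
                                       stringsAsFactors = FALSE),
                proteins = prot, hits = hits)
}
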