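#' Estimate the replication origin from cumulative GC skew
#'
#' On most bacterial chromosomes the leading strand is G-rich, so the
#' cumulative GC skew S(i) (G as +1, C as -1, A/T as 0, summed per window)
#' attains its minimum at the replication origin and its maximum at the
#' terminus. A coarse window-level scan locates the global minimum of S;
#' the estimate is then refined to the base-level cumulative-skew argmin
#' within two windows of it. The call is flagged ambiguous when the skew
#' curve is flat or when a competing local minimum elsewhere on the
#' chromosome (beyond five windows from the global one) comes within 5% of
#' the skew range, mirroring the requirement of one unambiguously
#' identified ori per chromosome.
#'
#' @param sequence Circular nucleotide sequence (string), length >= 10
#'   windows.
#' @param window Window size in bp (default 1000).
#' @param replicon_id Optional id stored in the result.
#' @param ambiguity_frac Two local minima closer than this fraction of the
#'   skew range make the call ambiguous (default 0.05).
#' @return List (`ori_call`) with `replicon_id`, `ori` (nt), `method =
#'   "gc_skew"`, `ambiguous`.
#' @export
estimate_ori_gcskew <- function(sequence, window = 1000L,
                                replicon_id = NA_character_,
                                ambiguity_frac = 0.05) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 10L * window)
    stop("sequence length ", L, " is shorter than 10 windows of ", window, " bp")
  base <- strsplit(toupper(sequence), "")[[1]]
  val <- (base == "G") - (base == "C")
  nwin <- L %/% window
  used <- nwin * window
  wsum <- rowsum(val[seq_len(used)], rep(seq_len(nwin), each = window))[, 1]
  S <- cumsum(wsum)
  rng <- diff(range(S))
  midpoints <- (seq_len(nwin) - 1L) * window + (window + 1) / 2
  i_min <- which.min(S)
  # base-level refinement: argmin of the cumulative skew within +/- 2
  # windows of the coarse minimum (local cumsum; the constant offset does
  # not move the argmin)
  center <- round(midpoints[i_min])
  region <- ((center - 2L * window):(center + 2L * window) - 1L) %% L + 1L
  ori <- region[which.min(cumsum(val[region]))]
  ambiguous <- FALSE
  if (rng == 0) {
    ambiguous <- TRUE
  } else {
    # a competing minimum elsewhere on the chromosome makes the call
    # ambiguous; jitter minima adjacent to the global one (within 5
    # windows) are the same candidate, not a second ori
    left <- S[c(nwin, seq_len(nwin - 1L))]
    right <- S[c(seq_len(nwin)[-1L], 1L)]
    is_min <- S <= left & S <= right & (S < left | S < right)
    dist_w <- abs(seq_len(nwin) - i_min)
    far <- pmin(dist_w, nwin - dist_w) > 5L
    competing <- S[is_min & far]
    if (length(competing) &&
        (min(competing) - S[i_min]) < ambiguity_frac * rng)
      ambiguous <- TRUE
  }
  structure(list(replicon_id = replicon_id, ori = ori, method = "gc_skew",
                 ambiguous = ambiguous), class = "ori_call")
}

#' Terminus position opposite the origin
#'
#' The replication terminus is assumed diametrically opposite ori on the
#' circular chromosome: `ter = ((ori - 1 + floor(L/2)) mod L) + 1`.
#'
#' @param ori Origin position (nt, 1-based).
#' @param length_bp Replicon length L.
#' @return Terminus position (nt, 1-based).
#' @export
ter_from_ori <- function(ori, length_bp) {
  stopifnot(all(ori >= 1), all(ori <= length_bp))
  ((ori - 1 + length_bp %/% 2) %% length_bp) + 1
}

#' Ori-anchored normalized gene position
#'
#' Maps a gene to the 0-100% scale on which ori sits at 0 and ter at 50.
#' The representative point is the CDS midpoint `m = start + (end-start)/2`
#' on the unwrapped circle (wrap-around genes must already be normalized to
#' `end >= start`); the value is `100 * (((m - ori) mod L) / L)`.
#'
#' @param start,end Gene coordinates (nt, 1-based inclusive; `end` may
#'   exceed `length_bp` for origin-spanning genes).
#' @param ori Origin position (nt).
#' @param length_bp Replicon length L.
#' @return Numeric vector in `[0, 100)`.
#' @export
normalized_position <- function(start, end, ori, length_bp) {
  stopifnot(all(end >= start))
  m <- start + (end - start) / 2
  100 * (((m - ori) %% length_bp) / length_bp)
}

#' Normalized positions for all classified c-di-GMP genes
#'
#' Applies [normalized_position()] to every classified protein with a known
#' locus on a replicon with an unambiguous ori. Replicons with an ambiguous
#' or missing ori are excluded and reported.
#'
#' @param classified Classification table from [classify_genomes()].
#' @param genomes The list of [genome_record()]s the table came from.
#' @param ori_table `data.frame` (`replicon_id`, `ori`, `ambiguous`) as from
#'   [read_ori_table()] or [ori_calls_for_genomes()].
#' @return List with `positions` (`data.frame`: `genome_id`, `protein_id`,
#'   `class`, `replicon_id`, `position`) and `excluded_replicons`
#'   (character).
#' @export
normalized_positions_table <- function(classified, genomes, ori_table) {
  reps <- do.call(rbind, lapply(genomes, function(g)
    cbind(genome_id = g$genome_id,
          g$replicons[, c("replicon_id", "length_bp"), drop = FALSE])))
  ok_ori <- ori_table[!ori_table$ambiguous & !is.na(ori_table$ori), , drop = FALSE]
  excluded <- setdiff(reps$replicon_id, ok_ori$replicon_id)
  tab <- classified[classified$class %in% CDG_CLASSES &
                      !is.na(classified$replicon_id), , drop = FALSE]
  tab <- merge(tab, ok_ori[, c("replicon_id", "ori")], by = "replicon_id")
  tab <- merge(tab, reps[, c("replicon_id", "length_bp")], by = "replicon_id")
  pos <- normalized_position(tab$start, tab$end, tab$ori, tab$length_bp)
  out <- data.frame(genome_id = tab$genome_id, protein_id = tab$protein_id,
                    class = tab$class, replicon_id = tab$replicon_id,
                    position = pos, stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  list(positions = out, excluded_replicons = sort(unique(excluded)))
}

#' Origin calls for a list of genomes
#'
#' Uses the ori recorded on each replicon when present (method
#' `user_supplied`), otherwise falls back to the GC-skew estimator when the
#' replicon sequence is available; replicons with neither are returned with
#' `ori = NA` and `ambiguous = TRUE`.
#'
#' @param genomes List of [genome_record()]s.
#' @param window GC-skew window (bp).
#' @return `data.frame`: `replicon_id`, `ori`, `method`, `ambiguous`.
#' @export
ori_calls_for_genomes <- function(genomes, window = 1000L) {
  rows <- list()
  for (g in genomes) {
    for (k in seq_len(nrow(g$replicons))) {
      r <- g$replicons[k, ]
      if (!is.na(r$ori)) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = r$replicon_id, ori = r$ori, method = "user_supplied",
          ambiguous = FALSE, stringsAsFactors = FALSE)
      } else if (!is.null(r$sequence) && !is.na(r$sequence)) {
        oc <- estimate_ori_gcskew(r$sequence, window = window,
                                  replicon_id = r$replicon_id)
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = oc$replicon_id, ori = oc$ori, method = oc$method,
          ambiguous = oc$ambiguous, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = r$replicon_id, ori = NA_real_, method = "none",
          ambiguous = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
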