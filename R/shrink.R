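## Two-pass shrink: pass 1 decides which taxonomic nodes pass the rank and
## read-count filters; pass 2 rewrites the LCA and alignment files keeping
## only reads assigned to kept nodes and alignments above the similarity
## threshold.

#' Shrink configuration
#'
#' @param rank_threshold keep only nodes at or below this rank (default
#'   `"family"`).
#' @param min_reads minimum aggregated read count for a node to be kept
#'   (default 5). Aggregated: a genus inherits support from its species.
#' @param min_similarity minimum alignment similarity, inclusive (default
#'   0.9); similarity is matched columns / full read length.
#' @param exclude_taxids taxids to exclude; a read is dropped if ANY node of
#'   its path is excluded (so excluding a genus removes its species' reads),
#'   and remaining reads are re-aggregated afterwards.
#' @param max_dust optional DUST-score ceiling; reads scoring above it are
#'   dropped in pass 2 (pass-1 counts are pre-DUST).
#' @param annotate_pmd add a `pd:f` PMD-score tag to every retained
#'   alignment (default FALSE).
#' @param pmd_stranded chemistry for PMD annotation (default "ds").
#' @param seed RNG seed (PMD tie-breaking and any sampling; default 4711).
#' @return list of class `shrink_config`.
#' @export
shrink_config <- function(rank_threshold = "family", min_reads = 5L,
                          min_similarity = 0.9, exclude_taxids = character(0),
                          max_dust = NULL, annotate_pmd = FALSE,
                          pmd_stranded = "ds", seed = 4711L) {
  stopifnot(min_similarity >= 0, min_similarity <= 1, min_reads >= 1)
  structure(list(rank_threshold = rank_threshold,
                 min_reads = as.integer(min_reads),
                 min_similarity = min_similarity,
                 exclude_taxids = as.character(exclude_taxids),
                 max_dust = max_dust, annotate_pmd = isTRUE(annotate_pmd),
                 pmd_stranded = pmd_stranded, seed = as.integer(seed)),
            class = "shrink_config")
}

#' Pass 1: select taxonomic nodes that survive filtering
#'
#' Reads whose path intersects `exclude_taxids` are dropped first; remaining
#' reads are aggregated up the taxonomy. A node is kept iff it is at or
#' below the rank threshold (the threshold rank occurs at its position or
#' above in some read's path) and its aggregated count reaches `min_reads`.
#'
#' @param lca_path LCA file path.
#' @param cfg a [shrink_config()].
#' @return character vector of kept taxids.
#' @export
select_kept_nodes <- function(lca_path, cfg = shrink_config()) {
  counts <- new.env(parent = emptyenv())
  below <- new.env(parent = emptyenv())
  rd <- lca_reader(lca_path)
  on.exit(rd$close())
  excl <- cfg$exclude_taxids
  while (!is.null(a <- rd$next_assignment())) {
    tids <- a$path$taxid
    if (length(excl) && any(tids %in% excl)) next
    ranks <- a$path$rank
    ok <- rev(cumsum(rev(ranks == cfg$rank_threshold)) > 0)  # node i at/below?
    for (i in seq_along(tids)) {
      tid <- tids[i]
      counts[[tid]] <- (if (is.null(counts[[tid]])) 0 else counts[[tid]]) + 1
      if (ok[i]) below[[tid]] <- TRUE
    }
  }
  ids <- ls(counts)
  keep <- vapply(ids, function(i) counts[[i]] >= cfg$min_reads &&
                   isTRUE(below[[i]]), logical(1L))
  sort(ids[keep])
}

#' Pass 2: write the shrunken LCA and alignment files
#'
#' Keeps exactly the reads whose assigned (first) node is in `kept`, in the
#' original order, and for those reads only the alignments with similarity
#' >= `min_similarity`. Reads failing the optional DUST ceiling, and kept
#' reads whose alignments all fail similarity, are dropped from both
#' outputs. The SAM header is carried through with a `@PG taphos-shrink`
#' line appended.
#'
#' @param aln_path input BAM/SAM (read-name grouped).
#' @param lca_path input LCA file (same order).
#' @param kept character vector of kept taxids from [select_kept_nodes()].
#' @param cfg a [shrink_config()].
#' @param out_aln,out_lca output paths (`.bam` or `.sam`; text LCA).
#' @return report list: reads/alignments in and out, and drop tallies.
#' @export
write_shrunken_outputs <- function(aln_path, lca_path, kept, cfg,
                                   out_aln, out_lca) {
  set.seed(cfg$seed)
  br <- bundle_reader(aln_path, lca_path)
  on.exit(br$close())
  lca_out <- list()
  sam_out <- list()
  rep_ <- list(reads_in = 0L, reads_out = 0L, alignments_in = 0L,
               alignments_out = 0L, reads_dropped_dust = 0L,
               reads_dropped_similarity = 0L, alignments_failed = 0L)
  while (!is.null(b <- br$next_bundle())) {
    rep_$reads_in <- rep_$reads_in + 1L
    rep_$alignments_in <- rep_$alignments_in + length(b$alignments)
    if (!(b$lca$path$taxid[1L] %in% kept)) next
    if (!is.null(cfg$max_dust)) {
      mol <- read_molecule(b)
      if (dust_score(mol) > cfg$max_dust) {
        rep_$reads_dropped_dust <- rep_$reads_dropped_dust + 1L
        next
      }
    }
    keep_lines <- character(0)
    for (al in b$alignments) {
      sim <- tryCatch(alignment_similarity(al, b$query_len),
                      taphos_md_error = function(e) {
                        rep_$alignments_failed <<- rep_$alignments_failed + 1L
                        NA_real_
                      })
      if (is.na(sim) || sim < cfg$min_similarity) next
      line <- al$line
      if (cfg$annotate_pmd) {
        sc <- tryCatch(
          pmd_score(oriented_substitutions(al), stranded = cfg$pmd_stranded),
          taphos_md_error = function(e) NA_real_)
        if (!is.na(sc)) line <- paste0(line, sprintf("\tpd:f:%.4f", sc))
      }
      keep_lines <- c(keep_lines, line)
    }
    if (length(keep_lines) == 0L) {
      rep_$reads_dropped_similarity <- rep_$reads_dropped_similarity + 1L
      next
    }
    rep_$reads_out <- rep_$reads_out + 1L
    rep_$alignments_out <- rep_$alignments_out + length(keep_lines)
    lca_out[[length(lca_out) + 1L]] <- b$lca_line
    sam_out[[length(sam_out) + 1L]] <- keep_lines
  }
  header <- c(br$header, "@PG\tID:taphos-shrink\tPN:taphos")
  write_alignment_file(header, unlist(sam_out), out_aln)
  writeLines(unlist(lca_out), out_lca)
  rep_
}

# The read as sequenced: stored SEQ, complement-flipped back for
# reverse-strand alignments.
read_molecule <- function(bundle) {
  al <- bundle$alignments[[1L]]
  if (is_reverse(al)) revcomp(al$seq) else al$seq
}

#' Shrink an alignment/LCA pair
#'
#' The two-pass filter: [select_kept_nodes()] then
#' [write_shrunken_outputs()]. Idempotent: shrinking a shrunken output with
#' the same configuration is a fixed point.
#'
#' @inheritParams write_shrunken_outputs
#' @param cfg a [shrink_config()].
#' @return the pass-2 report, with `kept_nodes` attached.
#' @export
shrink <- function(aln_path, lca_path, out_aln, out_lca,
                   cfg = shrink_config()) {
  kept <- select_kept_nodes(lca_path, cfg)
  rep_ <- write_shrunken_outputs(aln_path, lca_path, kept, cfg,
                                 out_aln, out_lca)
  rep_$kept_nodes <- kept
  rep_
}
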