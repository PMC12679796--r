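## Single pass over a shrunken alignment/LCA pair, accumulating per-node
## authentication statistics and finalizing the per-node tsv plus the
## substitution-frequency file.

BASES <- c("A", "C", "G", "T")

#' Compute configuration
#'
#' @param mode alignment weighting: 1 = best alignment per read (AS tag,
#'   seeded random tie-break), 2 = weight 1/m over a read's m alignments,
#'   3 = weight 1 on every alignment. Default 1.
#' @param stranded library chemistry, `"ds"` (3' damage read as G-to-A) or
#'   `"ss"` (3' C-to-T). No default at the command line; the API defaults to
#'   `"ds"` for programmatic use.
#' @param k k-mer length for duplicity/unique-k-mer counting (default 29).
#' @param P terminal offsets tracked per read end (default 15).
#' @param precision HyperLogLog register exponent (default 14, ~0.8% RSE).
#' @param seed RNG seed for AS tie-breaking (default 4711).
#' @return list of class `compute_config`.
#' @export
compute_config <- function(mode = 1L, stranded = c("ds", "ss"), k = 29L,
                           P = 15L, precision = 14L, seed = 4711L) {
  stranded <- match.arg(stranded)
  mode <- as.integer(mode)
  stopifnot(mode %in% 1:3)
  structure(list(mode = mode, stranded = stranded, k = as.integer(k),
                 P = as.integer(P), precision = as.integer(precision),
                 seed = as.integer(seed)),
            class = "compute_config")
}

new_node_stats <- function(taxid, name, rank, path_str, cfg) {
  e <- new.env(parent = emptyenv())
  e$taxid <- taxid; e$name <- name; e$rank <- rank; e$path_str <- path_str
  e$total_reads <- 0L; e$unaggregated_reads <- 0L
  e$total_kmers <- 0L
  e$sketch <- kmer_sketch(cfg$precision, cfg$k)
  e$dust_sum <- 0; e$length_sum <- 0; e$read_gc_sum <- 0
  e$ani_wsum <- 0; e$ref_gc_wsum <- 0; e$weight_sum <- 0
  e$subs <- array(0, dim = c(2L, cfg$P, 4L, 4L),
                  dimnames = list(c("p5", "p3"), NULL, BASES, BASES))
  e
}

# Per-alignment features needed by the accumulator; NULL on MD/CIGAR failure.
alignment_features <- function(al, P) {
  tryCatch({
    prof <- oriented_substitutions(al, P)
    seg <- reconstruct_reference_segment(al)
    list(profile = prof, ref_gc = gc_fraction(seg),
         ani = if (prof$n_aligned > 0) prof$n_matched / prof$n_aligned else NA_real_)
  }, taphos_md_error = function(e) NULL)
}

#' Accumulate one read bundle into the per-node statistics
#'
#' Read-level quantities (read count, DUST, length, read GC, k-mers) are
#' alignment-independent and added once per read to the assigned node and
#' every ancestor on its path; alignment-level quantities (substitution
#' counts, ANI, reference GC) are added with the mode weights.
#' `unaggregated_reads` is incremented only at the assigned node.
#'
#' @param stats an environment mapping taxid to node accumulators (created
#'   on demand).
#' @param bundle a `read_bundle`.
#' @param cfg a [compute_config()].
#' @return number of alignment-feature failures (invisibly).
#' @export
accumulate_bundle <- function(stats, bundle, cfg) {
  path <- bundle$lca$path
  n <- nrow(path)
  path_strs <- vapply(seq_len(n), function(i)
    paste(path$taxid[i:n], path$name[i:n], path$rank[i:n],
          sep = ":", collapse = ";"), character(1L))
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    tid <- path$taxid[i]
    if (is.null(stats[[tid]]))
      stats[[tid]] <- new_node_stats(tid, path$name[i], path$rank[i],
                                     path_strs[i], cfg)
    nodes[[i]] <- stats[[tid]]
  }
  mol <- read_molecule(bundle)
  dust <- dust_score(mol)
  rgc <- gc_fraction(mol)
  len <- nchar(mol)
  feats <- lapply(bundle$alignments, alignment_features, P = cfg$P)
  failed <- sum(vapply(feats, is.null, logical(1L)))
  okidx <- which(!vapply(feats, is.null, logical(1L)))
  w <- numeric(length(bundle$alignments))
  if (length(okidx)) {
    if (cfg$mode == 1L) {
      bi <- best_alignment_index(bundle$alignments[okidx])
      w[okidx[bi]] <- 1
    } else if (cfg$mode == 2L) {
      w[okidx] <- 1 / length(okidx)
    } else {
      w[okidx] <- 1
    }
  }
  first <- TRUE
  for (e in nodes) {
    e$total_reads <- e$total_reads + 1L
    if (first) e$unaggregated_reads <- e$unaggregated_reads + 1L
    e$dust_sum <- e$dust_sum + dust
    e$length_sum <- e$length_sum + len
    e$read_gc_sum <- e$read_gc_sum + rgc
    e$total_kmers <- e$total_kmers + sketch_add_read(e$sketch, mol, cfg$k)
    for (j in okidx) {
      if (w[j] == 0) next
      ft <- feats[[j]]
      e$weight_sum <- e$weight_sum + w[j]
      if (!is.na(ft$ani)) e$ani_wsum <- e$ani_wsum + w[j] * ft$ani
      e$ref_gc_wsum <- e$ref_gc_wsum + w[j] * ft$ref_gc
      pr <- ft$profile$pairs
      p5 <- pr[pr$off5 <= cfg$P, , drop = FALSE]
      if (nrow(p5)) for (r in seq_len(nrow(p5)))
        e$subs["p5", p5$off5[r], p5$ref[r], p5$read[r]] <-
          e$subs["p5", p5$off5[r], p5$ref[r], p5$read[r]] + w[j]
      p3 <- pr[pr$off3 <= cfg$P, , drop = FALSE]
      if (nrow(p3)) for (r in seq_len(nrow(p3)))
        e$subs["p3", p3$off3[r], p3$ref[r], p3$read[r]] <-
          e$subs["p3", p3$off3[r], p3$ref[r], p3$read[r]] + w[j]
    }
    first <- FALSE
  }
  invisible(failed)
}

#' Run the compute stage over an alignment/LCA pair
#'
#' @param aln_path BAM/SAM path (read-name grouped; normally shrink output).
#' @param lca_path LCA path in the same read order.
#' @param cfg a [compute_config()].
#' @return an object of class `node_stats_set`: list with `stats` (env of
#'   per-node accumulators), `n_reads` (LCA lines processed), `n_failed`
#'   (alignments skipped for MD/CIGAR problems), `cfg`.
#' @export
compute_stats <- function(aln_path, lca_path, cfg = compute_config()) {
  set.seed(cfg$seed)
  br <- bundle_reader(aln_path, lca_path)
  on.exit(br$close())
  stats <- new.env(parent = emptyenv())
  n_reads <- 0L
  n_failed <- 0L
  while (!is.null(b <- br$next_bundle())) {
    n_reads <- n_reads + 1L
    n_failed <- n_failed + accumulate_bundle(stats, b, cfg)
  }
  structure(list(stats = stats, n_reads = n_reads, n_failed = n_failed,
                 cfg = cfg),
            class = "node_stats_set")
}

damage_freq <- function(subs, end, offset, ref, read) {
  den <- sum(subs[end, offset, ref, ])
  if (den <= 0) return(NA_real_)
  subs[end, offset, ref, read] / den
}

#' Finalize the per-node statistics table
#'
#' One row per taxonomic node: duplicity (total k-mers / HLL-unique k-mers),
#' mean DUST, terminal damage frequencies conditional on the reference base
#' (5' C-to-T; 3' G-to-A for ds or C-to-T for ss), mean read length, ANI,
#' mean read and reference GC, unique k-mers, unaggregated reads and the
#' full taxonomic path. Rows are ordered by total reads descending, ties by
#' taxid ascending. Zero denominators yield NA.
#'
#' @param res a `node_stats_set` from [compute_stats()].
#' @return data.frame of class `stats_table`.
#' @export
finalize_stats_table <- function(res) {
  stopifnot(inherits(res, "node_stats_set"))
  cfg <- res$cfg
  ids <- ls(res$stats)
  rows <- lapply(ids, function(tid) {
    e <- res$stats[[tid]]
    nr <- e$total_reads
    uniq <- sketch_estimate(e$sketch)
    dup <- if (uniq > 0) e$total_kmers / uniq else 0
    d5 <- damage_freq(e$subs, "p5", 1L, "C", "T")
    d3 <- if (cfg$stranded == "ds") damage_freq(e$subs, "p3", 1L, "G", "A")
          else damage_freq(e$subs, "p3", 1L, "C", "T")
    data.frame(
      name = e$name, taxid = e$taxid, total_reads = nr,
      duplicity = dup, mean_dust = e$dust_sum / nr,
      damage_5 = d5, damage_3 = d3,
      mean_length = e$length_sum / nr,
      ani = if (e$weight_sum > 0) e$ani_wsum / e$weight_sum else NA_real_,
      mean_read_gc = e$read_gc_sum / nr,
      mean_ref_gc = if (e$weight_sum > 0) e$ref_gc_wsum / e$weight_sum else NA_real_,
      unique_kmers = round(uniq),
      unaggregated_reads = e$unaggregated_reads,
      tax_path = e$path_str, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(name = character(0), taxid = character(0),
                      total_reads = integer(0), duplicity = numeric(0),
                      mean_dust = numeric(0), damage_5 = numeric(0),
                      damage_3 = numeric(0), mean_length = numeric(0),
                      ani = numeric(0), mean_read_gc = numeric(0),
                      mean_ref_gc = numeric(0), unique_kmers = numeric(0),
                      unaggregated_reads = integer(0), tax_path = character(0))
  } else {
    tab <- tab[order(-tab$total_reads, tab$taxid), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("stats_table", "data.frame")
  tab
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                format(round(x), scientific = FALSE, trim = TRUE),
                sprintf("%.6g", x)))
}

#' Write the statistics tsv
#'
#' Numeric columns are written with 6 significant digits; NA is the literal
#' string `NA`.
#'
#' @param tab a `stats_table`.
#' @param path output path.
#' @export
write_stats_tsv <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1L))
  for (j in which(num)) out[[j]] <- fmt_num(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a statistics tsv back
#'
#' @param path tsv path written by [write_stats_tsv()].
#' @return a `stats_table` data.frame.
#' @export
read_stats_tsv <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(taxid = "character"))
  class(tab) <- c("stats_table", "data.frame")
  tab
}

## Substitution file ------------------------------------------------------
## One record per node: taxid, name, then sparse "end:offset:REF>READ=count"
## tokens in deterministic order (zeros omitted). Counts carry 6 significant
## digits, so write -> read -> write is byte-identical.

#' Write the per-node substitution-count file
#'
#' @param res a `node_stats_set`.
#' @param path output path.
#' @export
write_subs_file <- function(res, path) {
  stopifnot(inherits(res, "node_stats_set"))
  ids <- sort(ls(res$stats))
  lines <- vapply(ids, function(tid) {
    e <- res$stats[[tid]]
    toks <- character(0)
    for (end in c("p5", "p3")) for (off in seq_len(dim(e$subs)[2L]))
      for (rb in BASES) for (qb in BASES) {
        v <- e$subs[end, off, rb, qb]
        if (v > 0)
          toks <- c(toks, sprintf("%s:%d:%s>%s=%s", end, off, rb, qb,
                                  sprintf("%.6g", v)))
      }
    paste(c(tid, e$name, toks), collapse = "\t")
  }, character(1L))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a substitution-count file
#'
#' @param path file written by [write_subs_file()].
#' @param P terminal offsets (defaults to the max offset present, min 15).
#' @return named list taxid -> list(name, subs array \[end, offset, ref,
#'   read\]).
#' @export
read_subs_file <- function(path, P = NULL) {
  lines <- readLines(path)
  out <- list()
  parsed <- lapply(lines, function(ln) strsplit(ln, "\t", fixed = TRUE)[[1L]])
  maxoff <- 15L
  for (f in parsed) {
    if (length(f) > 2L) {
      off <- as.integer(sub("^p[53]:([0-9]+):.*$", "\\1", f[-(1:2)]))
      maxoff <- max(maxoff, off)
    }
  }
  if (is.null(P)) P <- maxoff
  for (f in parsed) {
    subs <- array(0, dim = c(2L, P, 4L, 4L),
                  dimnames = list(c("p5", "p3"), NULL, BASES, BASES))
    if (length(f) > 2L) {
      for (tok in f[-(1:2)]) {
        m <- regmatches(tok,
          regexec("^(p[53]):([0-9]+):([ACGT])>([ACGT])=(.+)$", tok))[[1L]]
        if (length(m) != 6L) stop(sprintf("bad substitution token '%s'", tok))
        subs[m[2L], as.integer(m[3L]), m[4L], m[5L]] <- as.numeric(m[6L])
      }
    }
    out[[f[1L]]] <- list(name = f[2L], subs = subs)
  }
  out
}

#' Full compute stage with file outputs
#'
#' @inheritParams compute_stats
#' @param out_tsv,out_subs output paths.
#' @return the `stats_table`, invisibly.
#' @export
compute <- function(aln_path, lca_path, out_tsv, out_subs,
                    cfg = compute_config()) {
  res <- compute_stats(aln_path, lca_path, cfg)
  tab <- finalize_stats_table(res)
  write_stats_tsv(tab, out_tsv)
  write_subs_file(res, out_subs)
  invisible(tab)
}
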