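## Alignment-level machinery: SAM record parsing, MD/CIGAR reference
## reconstruction, similarity, and read-oriented terminal substitutions.
##
## All record logic operates on SAM text; BAM input is converted with
## Rsamtools (htslib) and then streamed line by line, so at most one read's
## alignments are ever held in memory.

FLAG_UNMAPPED <- 4L
FLAG_REVERSE <- 16L

#' Parse one SAM record line
#'
#' @param line a single SAM alignment line (tab-separated, >= 11 fields).
#' @return a list of class `sam_record` with the standard fields (`qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`, `qual`), a named `tags`
#'   character vector of raw tag strings, and the original `line`.
#' @export
parse_sam_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L) stop("malformed SAM record: fewer than 11 fields")
  tags <- character(0)
  if (length(f) > 11L) {
    tg <- f[-(1:11)]
    tags <- setNames(tg, substr(tg, 1L, 2L))
  }
  structure(
    list(qname = f[1L], flag = as.integer(f[2L]), rname = f[3L],
         pos = as.integer(f[4L]), mapq = as.integer(f[5L]), cigar = f[6L],
         seq = f[10L], qual = f[11L], tags = tags, line = line),
    class = "sam_record")
}

sam_tag <- function(rec, tag) {
  t <- rec$tags[tag]
  if (is.na(t)) return(NA_character_)
  unname(sub(sprintf("^%s:[AifZHB]:", tag), "", t))
}

sam_tag_int <- function(rec, tag) {
  v <- sam_tag(rec, tag)
  if (is.na(v)) NA_integer_ else as.integer(v)
}

is_reverse <- function(rec) bitwAnd(rec$flag, FLAG_REVERSE) != 0L
is_unmapped <- function(rec) bitwAnd(rec$flag, FLAG_UNMAPPED) != 0L

parse_cigar <- function(cigar) {
  if (cigar == "*") return(data.frame(op = character(0), len = integer(0)))
  m <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(m) || nchar(paste(m, collapse = "")) != nchar(cigar))
    stop(sprintf("malformed CIGAR '%s'", cigar))
  data.frame(op = substr(m, nchar(m), nchar(m)),
             len = as.integer(substr(m, 1L, nchar(m) - 1L)),
             stringsAsFactors = FALSE)
}

md_error <- function(msg, rec = NULL) {
  stop(structure(
    class = c("taphos_md_error", "error", "condition"),
    list(message = paste0("MD/CIGAR inconsistency: ", msg,
                          if (!is.null(rec)) sprintf(" (read %s)", rec$qname)),
         call = NULL)))
}

# Expand an MD string into per-reference-base events:
# type "m" (match), "x" (mismatch, ref base given), "d" (deleted ref base).
expand_md <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  if (nchar(paste(toks, collapse = "")) != nchar(md))
    md_error(sprintf("unparseable MD string '%s'", md))
  type <- character(0); base <- character(0)
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      n <- as.integer(tk)
      if (n > 0L) { type <- c(type, rep("m", n)); base <- c(base, rep(NA, n)) }
    } else if (startsWith(tk, "^")) {
      b <- strsplit(substr(tk, 2L, nchar(tk)), "")[[1L]]
      type <- c(type, rep("d", length(b))); base <- c(base, b)
    } else {
      type <- c(type, "x"); base <- c(base, tk)
    }
  }
  list(type = type, base = base)
}

# Core CIGAR+MD walk over one record. Returns the aligned columns (M/=/X) in
# query order with reconstructed reference bases, the full reference segment
# (including deleted bases, reference order), and match/aligned tallies.
align_columns <- function(rec) {
  cig <- parse_cigar(rec$cigar)
  md <- sam_tag(rec, "MD")
  if (is.na(md)) md_error("missing MD tag", rec)
  ev <- expand_md(toupper(md))
  qpos <- 1L
  ei <- 1L
  nev <- length(ev$type)
  qpos_out <- integer(0); ref_out <- character(0); read_out <- character(0)
  ref_seg <- character(0)
  sbases <- strsplit(rec$seq, "", fixed = TRUE)[[1L]]
  for (i in seq_len(nrow(cig))) {
    op <- cig$op[i]; len <- cig$len[i]
    if (op %in% c("M", "=", "X")) {
      idx <- ei:(ei + len - 1L)
      if (ei + len - 1L > nev) md_error("MD shorter than CIGAR match length", rec)
      t <- ev$type[idx]
      if (any(t == "d")) md_error("deletion event inside match run", rec)
      rb <- ifelse(t == "m", sbases[qpos:(qpos + len - 1L)], ev$base[idx])
      qpos_out <- c(qpos_out, qpos:(qpos + len - 1L))
      ref_out <- c(ref_out, rb)
      read_out <- c(read_out, sbases[qpos:(qpos + len - 1L)])
      ref_seg <- c(ref_seg, rb)
      qpos <- qpos + len
      ei <- ei + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op == "D") {
      idx <- ei:(ei + len - 1L)
      if (ei + len - 1L > nev) md_error("MD shorter than CIGAR deletion", rec)
      if (any(ev$type[idx] != "d")) md_error("CIGAR deletion without MD ^ bases", rec)
      ref_seg <- c(ref_seg, ev$base[idx])
      ei <- ei + len
    } else if (op %in% c("H", "P")) {
      # no query or reference bases stored
    } else {
      md_error(sprintf("unsupported CIGAR op '%s'", op), rec)
    }
  }
  if (qpos - 1L != length(sbases))
    md_error("CIGAR does not consume the stored query length", rec)
  if (ei - 1L != nev) md_error("MD longer than CIGAR", rec)
  matched <- sum(ref_out == read_out)
  list(qpos = qpos_out, ref = ref_out, read = read_out,
       ref_seg = paste(ref_seg, collapse = ""),
       n_aligned = length(ref_out), n_matched = matched)
}

#' Reconstruct the aligned reference segment of a record
#'
#' Rebuilds, from the stored query plus CIGAR and MD, the reference bases
#' spanned by the alignment (mismatch bases substituted, deleted bases
#' restored, insertions dropped). No reference FASTA is needed, which matters
#' because competitive-mapping databases are far too large to carry around.
#'
#' @param rec a `sam_record` (or a SAM line).
#' @return the reference sequence as a single string; its length equals the
#'   reference-consuming CIGAR length.
#' @export
reconstruct_reference_segment <- function(rec) {
  if (is.character(rec)) rec <- parse_sam_record(rec)
  align_columns(rec)$ref_seg
}

#' Alignment similarity
#'
#' Number of alignment columns where the read base equals the reference base,
#' divided by the full read length (soft-clipped bases count in the
#' denominator but can never be matches, so clipping is penalized).
#'
#' @param rec a `sam_record`.
#' @param query_len the full read length; defaults to the stored SEQ length.
#' @return numeric in \[0, 1\].
#' @export
alignment_similarity <- function(rec, query_len = nchar(rec$seq)) {
  if (is.character(rec)) rec <- parse_sam_record(rec)
  ac <- align_columns(rec)
  ac$n_matched / query_len
}

#' Read-oriented substitution profile of one alignment
#'
#' Reports, for every aligned column, the reference and read base together
#' with the column's 1-based offset from the sequenced molecule's 5' and 3'
#' ends. Reverse-strand alignments are complement-flipped first, so "5'"
#' always refers to the molecule as sequenced. Insertions (no reference
#' base), deletions (no read base) and columns involving non-ACGT characters
#' are excluded.
#'
#' @param rec a `sam_record`.
#' @param P number of terminal offsets of interest (metadata; all pairs are
#'   returned and carry both offsets, so callers filter as needed).
#' @return an object of class `oriented_mismatch_profile`: list with `pairs`
#'   (data.frame `off5`, `off3`, `ref`, `read`), `n_aligned`, `n_matched`,
#'   `query_len`, `P`.
#' @export
oriented_substitutions <- function(rec, P = 15L) {
  if (is.character(rec)) rec <- parse_sam_record(rec)
  ac <- align_columns(rec)
  L <- nchar(rec$seq)
  ref <- ac$ref; read <- ac$read; qpos <- ac$qpos
  if (is_reverse(rec)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- ifelse(ref %in% names(comp), comp[ref], "N")
    read <- ifelse(read %in% names(comp), comp[read], "N")
    off5 <- L - qpos + 1L
  } else {
    off5 <- qpos
  }
  off3 <- L - off5 + 1L
  keep <- ref %in% c("A", "C", "G", "T") & read %in% c("A", "C", "G", "T")
  structure(
    list(pairs = data.frame(off5 = off5[keep], off3 = off3[keep],
                            ref = unname(ref[keep]), read = unname(read[keep]),
                            stringsAsFactors = FALSE),
         n_aligned = ac$n_aligned, n_matched = ac$n_matched,
         query_len = L, P = as.integer(P)),
    class = "oriented_mismatch_profile")
}

## ---------------------------------------------------------------------------
## Streaming: SAM/BAM reader grouped by read name, synchronized with the LCA.

# Accepts a .sam path directly or converts .bam to a temporary SAM first.
open_alignment_stream <- function(path) {
  stopifnot(file.exists(path))
  sam_path <- path
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    Rsamtools::asSam(path, tools::file_path_sans_ext(tmp), overwrite = TRUE)
    sam_path <- tmp
  }
  con <- file(sam_path, open = "r")
  header <- character(0)
  pushed <- NULL
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) break
    if (startsWith(ln, "@")) header <- c(header, ln) else { pushed <- ln; break }
  }
  list(con = con, header = header, pushed = pushed)
}

# Iterator over qname groups of a read-name-grouped SAM stream.
sam_group_reader <- function(path) {
  st <- open_alignment_stream(path)
  con <- st$con
  pending <- st$pushed   # first record line beyond the header, if any
  finished <- is.null(pending)
  next_group <- function() {
    if (finished) return(NULL)
    recs <- list(parse_sam_record(pending))
    qname <- recs[[1L]]$qname
    repeat {
      ln <- readLines(con, n = 1L, warn = FALSE)
      if (length(ln) == 0L) { finished <<- TRUE; pending <<- NULL; break }
      r <- parse_sam_record(ln)
      if (r$qname == qname) {
        recs[[length(recs) + 1L]] <- r
      } else {
        pending <<- ln
        break
      }
    }
    list(qname = qname, records = recs)
  }
  list(header = st$header, next_group = next_group,
       close = function() close(con))
}

#' Synchronized BAM/LCA bundle reader
#'
#' Streams a read-name-grouped BAM (or SAM) alongside its ngsLCA-style
#' assignment file, yielding one `read_bundle` per LCA line. The LCA file is
#' the driver: alignment groups whose read does not appear in the LCA stream
#' are skipped silently (a pre-filtered LCA file is legitimate input), but an
#' LCA read that can no longer be met by forward scanning of the alignment
#' stream is a fatal desynchronization error.
#'
#' @param aln_path BAM or SAM file path, read-name grouped.
#' @param lca_path LCA file path, same read order.
#' @return a list with `next_bundle()` (returns a `read_bundle` or `NULL`),
#'   `header` (SAM header lines), and `close()`. A `read_bundle` holds
#'   `read_id`, `query_len`, `alignments` (mapped `sam_record`s), `lca` (the
#'   assignment) and `lca_line` (raw text). Unmapped records are dropped; an
#'   LCA read whose group has no mapped alignment is skipped.
#' @export
bundle_reader <- function(aln_path, lca_path) {
  gr <- sam_group_reader(aln_path)
  lr <- lca_reader(lca_path)
  pending_group <- NULL
  next_bundle <- function() {
    repeat {
      a <- lr$next_assignment()
      if (is.null(a)) return(NULL)
      repeat {
        g <- if (!is.null(pending_group)) {
          pg <- pending_group; pending_group <<- NULL; pg
        } else gr$next_group()
        if (is.null(g))
          stop(sprintf(
            "bam/lca desynchronization: LCA read '%s' not found by forward scan of the alignment stream",
            a$read_field))
        if (lca_id_matches(a$read_field, g$qname)) break
        # alignment group not in (pre-filtered) LCA stream: skip it
      }
      mapped <- Filter(Negate(is_unmapped), g$records)
      if (length(mapped) == 0L) next  # read present but nothing aligned
      qlen <- nchar(mapped[[1L]]$seq)
      return(structure(
        list(read_id = g$qname, query_len = qlen, alignments = mapped,
             lca = a, lca_line = lr$next_line()),
        class = "read_bundle"))
    }
  }
  list(next_bundle = next_bundle, header = gr$header,
       close = function() { gr$close(); lr$close() })
}

# Pick the best-AS alignment of a bundle; ties broken uniformly at random
# with the caller's RNG state (seed it for reproducibility).
best_alignment_index <- function(alignments) {
  as_vals <- vapply(alignments, function(r) {
    v <- sam_tag_int(r, "AS")
    if (is.na(v)) -Inf else as.numeric(v)
  }, numeric(1L))
  best <- which(as_vals == max(as_vals))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

## SAM writing -----------------------------------------------------------

# Write header + record lines as SAM; convert to BAM if path ends in .bam.
write_alignment_file <- function(header, lines, path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".sam")
    writeLines(c(header, lines), tmp)
    out <- Rsamtools::asBam(tmp, tools::file_path_sans_ext(path),
                            indexDestination = FALSE)
    unlink(tmp)
    invisible(out)
  } else {
    writeLines(c(header, lines), path)
    invisible(path)
  }
}
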