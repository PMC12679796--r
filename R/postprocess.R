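## Multi-sample combination, per-taxon read extraction, Krona XML emission,
## and plotting of deamination / read-length / mismatch series.

#' Combine per-sample statistics tables into a multi-sample matrix
#'
#' Rows are the union of taxa across samples. For each selected metric the
#' output carries one column per sample plus a read-weighted mean
#' `sum(reads_s * metric_s) / sum(reads_s)` over the samples where the
#' metric is non-NA. Read counts are 0 where a taxon is absent.
#'
#' @param tables named list of `stats_table` data.frames (or tsv paths);
#'   names are the sample ids.
#' @param metrics metric columns to carry (default damage_5, duplicity,
#'   mean_dust, mean_length).
#' @return data.frame: `taxid`, `name`, `tax_path`, `reads_<sample>` columns,
#'   `total_reads`, then per metric `<metric>_<sample>` and `<metric>_wmean`.
#' @export
combine_tables <- function(tables,
                           metrics = c("damage_5", "duplicity",
                                       "mean_dust", "mean_length")) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be a named list (sample ids)")
  if (anyDuplicated(names(tables))) stop("duplicate sample ids")
  tables <- lapply(tables, function(t)
    if (is.character(t)) read_stats_tsv(t) else t)
  samples <- names(tables)
  all_tax <- unique(unlist(lapply(tables, function(t) t$taxid)))
  meta <- do.call(rbind, lapply(tables, function(t)
    t[, c("taxid", "name", "tax_path")]))
  meta <- meta[!duplicated(meta$taxid), , drop = FALSE]
  out <- meta[match(all_tax, meta$taxid), , drop = FALSE]
  rownames(out) <- NULL
  reads <- sapply(tables, function(t)
    ifelse(is.na(match(all_tax, t$taxid)), 0,
           t$total_reads[match(all_tax, t$taxid)]))
  reads <- matrix(reads, nrow = length(all_tax),
                  dimnames = list(NULL, samples))
  for (s in samples) out[[paste0("reads_", s)]] <- reads[, s]
  out$total_reads <- rowSums(reads)
  for (m in metrics) {
    vals <- sapply(tables, function(t) {
      v <- t[[m]][match(all_tax, t$taxid)]
      as.numeric(v)
    })
    vals <- matrix(vals, nrow = length(all_tax),
                   dimnames = list(NULL, samples))
    for (s in samples) out[[paste0(m, "_", s)]] <- vals[, s]
    wm <- vapply(seq_along(all_tax), function(i) {
      ok <- !is.na(vals[i, ]) & reads[i, ] > 0
      if (!any(ok)) return(NA_real_)
      sum(reads[i, ok] * vals[i, ok]) / sum(reads[i, ok])
    }, numeric(1L))
    out[[paste0(m, "_wmean")]] <- wm
  }
  out <- out[order(-out$total_reads, out$taxid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract alignments of reads assigned to given taxa
#'
#' A read qualifies iff its taxonomic path intersects `taxids` (so passing a
#' genus extracts its species' reads too). Optionally keep only the AS-best
#' alignment per read (seeded tie-break) and/or only alignments to the "top"
#' reference - the reference hit by the most distinct qualifying reads (ties
#' broken towards the lexicographically smallest name). The output header
#' retains exactly the `@SQ` lines of references present in the output.
#'
#' @param aln_path,lca_path synchronized input pair.
#' @param taxids character vector of taxids.
#' @param out_aln output BAM/SAM path.
#' @param best_only keep one best alignment per read (default FALSE).
#' @param top_reference_only keep only the top reference (default FALSE).
#' @param seed RNG seed for tie-breaks.
#' @return report list (reads/alignments written, top reference if used).
#' @export
extract_taxa_bam <- function(aln_path, lca_path, taxids, out_aln,
                             best_only = FALSE, top_reference_only = FALSE,
                             seed = 4711L) {
  taxids <- as.character(taxids)
  top_ref <- NULL
  if (top_reference_only) {
    br <- bundle_reader(aln_path, lca_path)
    tally <- new.env(parent = emptyenv())
    while (!is.null(b <- br$next_bundle())) {
      if (!any(b$lca$path$taxid %in% taxids)) next
      for (rn in unique(vapply(b$alignments, `[[`, "", "rname")))
        tally[[rn]] <- (if (is.null(tally[[rn]])) 0L else tally[[rn]]) + 1L
    }
    br$close()
    refs <- ls(tally)
    if (length(refs)) {
      cnt <- vapply(refs, function(r) tally[[r]], integer(1L))
      top_ref <- sort(refs[cnt == max(cnt)])[1L]
    }
  }
  set.seed(seed)
  br <- bundle_reader(aln_path, lca_path)
  on.exit(br$close())
  out_lines <- list()
  reads_out <- 0L
  while (!is.null(b <- br$next_bundle())) {
    if (!any(b$lca$path$taxid %in% taxids)) next
    alns <- b$alignments
    if (!is.null(top_ref))
      alns <- Filter(function(a) a$rname == top_ref, alns)
    if (length(alns) == 0L) next
    if (best_only) alns <- alns[best_alignment_index(alns)]
    out_lines[[length(out_lines) + 1L]] <- vapply(alns, `[[`, "", "line")
    reads_out <- reads_out + 1L
  }
  out_lines <- unlist(out_lines)
  if (is.null(out_lines)) out_lines <- character(0)
  if (reads_out == 0L)
    warning("no reads assigned at or below the requested taxids; writing an empty file")
  used_refs <- unique(vapply(strsplit(out_lines, "\t"), `[[`, "", 3L))
  header <- br$header
  is_sq <- startsWith(header, "@SQ")
  sn <- sub("^.*\tSN:([^\t]+).*$", "\\1", header)
  header <- header[!is_sq | sn %in% used_refs]
  write_alignment_file(c(header, "@PG\tID:taphos-extract\tPN:taphos"),
                       out_lines, out_aln)
  list(reads_out = reads_out, alignments_out = length(out_lines),
       top_reference = top_ref)
}

## Krona XML --------------------------------------------------------------

#' Emit multi-sample Krona XML
#'
#' Builds the taxon tree from the `tax_path` column of one or more
#' statistics tables and writes XML for KronaTools' `ktImportXML`: node
#' magnitudes are aggregated read counts, and each node carries per-dataset
#' damage (5' C-to-T), duplicity, mean DUST and mean read length attributes,
#' with node colour bound to the damage attribute. NA damage is rendered as
#' 0 with `damage_defined` 0.
#'
#' @param tables named list of `stats_table`s (or tsv paths); names are the
#'   dataset (sample) ids.
#' @param path output XML path.
#' @return the path, invisibly.
#' @export
krona_xml <- function(tables, path) {
  tables <- lapply(tables, function(t)
    if (is.character(t)) read_stats_tsv(t) else t)
  if (is.null(names(tables))) stop("tables must be named by sample id")
  samples <- names(tables)
  # union tree keyed by taxid; parent = next entry of any path
  nodes <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (t in tables) for (p in t$tax_path) {
    entries <- strsplit(p, ";", fixed = TRUE)[[1L]]
    tid <- sub(":.*$", "", entries)
    nm <- vapply(strsplit(entries, ":", fixed = TRUE),
                 function(x) paste(x[-c(1L, length(x))], collapse = ":"),
                 character(1L))
    for (i in seq_along(tid)) {
      if (is.null(nodes[[tid[i]]])) {
        nodes[[tid[i]]] <- list(name = nm[i],
                                parent = if (i < length(tid)) tid[i + 1L] else NA)
        order_seen <- c(order_seen, tid[i])
      }
    }
  }
  get_metric <- function(t, tid, col) {
    i <- match(tid, t$taxid)
    if (is.na(i)) NA_real_ else as.numeric(t[[col]][i])
  }
  reads_of <- function(tid) vapply(tables, function(t) {
    v <- get_metric(t, tid, "total_reads"); if (is.na(v)) 0 else v
  }, numeric(1L))
  # children map + consistency check
  # "" is not a usable list name in R, so absent parents key on a sentinel
  kids <- split(order_seen,
                vapply(order_seen, function(id) {
                  p <- nodes[[id]]$parent
                  if (is.na(p)) ".root." else p
                }, character(1L)))
  for (id in order_seen) {
    ch <- kids[[id]]
    if (is.null(ch)) next
    pr <- reads_of(id)
    for (c_ in ch) if (any(reads_of(c_) > pr + 1e-9))
      stop(sprintf("inconsistent read counts: child taxid %s exceeds parent %s",
                   c_, id))
  }
  doc <- xml2::xml_new_root("krona")
  attrs <- xml2::xml_add_child(doc, "attributes", magnitude = "reads")
  for (a in list(c("reads", "Reads"), c("damage", "5' C-to-T frequency"),
                 c("damage_defined", "Damage defined"),
                 c("duplicity", "K-mer duplicity"),
                 c("dust", "Mean DUST score"),
                 c("length", "Mean read length"))) {
    at <- xml2::xml_add_child(attrs, "attribute", display = a[2L])
    xml2::xml_text(at) <- a[1L]
  }
  xml2::xml_add_child(doc, "color", attribute = "damage",
                      valueStart = "0", valueEnd = "0.3",
                      hueStart = "240", hueEnd = "0", default = "false")
  ds <- xml2::xml_add_child(doc, "datasets")
  for (s in samples) {
    d <- xml2::xml_add_child(ds, "dataset")
    xml2::xml_text(d) <- s
  }
  add_vals <- function(node_el, tag, vals) {
    el <- xml2::xml_add_child(node_el, tag)
    for (v in vals) {
      vv <- xml2::xml_add_child(el, "val")
      xml2::xml_text(vv) <- fmt_num(v)
    }
  }
  emit <- function(parent_el, tid) {
    info <- nodes[[tid]]
    el <- xml2::xml_add_child(parent_el, "node", name = info$name, taxid = tid)
    add_vals(el, "reads", reads_of(tid))
    dmg <- vapply(tables, get_metric, numeric(1L), tid = tid, col = "damage_5")
    add_vals(el, "damage", ifelse(is.na(dmg), 0, dmg))
    add_vals(el, "damage_defined", as.numeric(!is.na(dmg)))
    add_vals(el, "duplicity",
             vapply(tables, get_metric, numeric(1L), tid = tid, col = "duplicity"))
    add_vals(el, "dust",
             vapply(tables, get_metric, numeric(1L), tid = tid, col = "mean_dust"))
    add_vals(el, "length",
             vapply(tables, get_metric, numeric(1L), tid = tid, col = "mean_length"))
    for (c_ in kids[[tid]]) emit(el, c_)
    el
  }
  roots <- kids[[".root."]]
  if (length(roots) == 1L) {
    emit(doc, roots)
  } else {
    wrap <- xml2::xml_add_child(doc, "node", name = "root")
    add_vals(wrap, "reads",
             Reduce(`+`, lapply(roots, reads_of)))
    for (r in roots) emit(wrap, r)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## Plotting ---------------------------------------------------------------

subs_frequency_series <- function(subs, stranded, P) {
  off <- seq_len(P)
  f5 <- vapply(off, function(i) {
    den <- sum(subs["p5", i, "C", ])
    if (den > 0) subs["p5", i, "C", "T"] / den else 0
  }, numeric(1L))
  if (stranded == "ds") {
    f3 <- vapply(off, function(i) {
      den <- sum(subs["p3", i, "G", ])
      if (den > 0) subs["p3", i, "G", "A"] / den else 0
    }, numeric(1L))
  } else {
    f3 <- vapply(off, function(i) {
      den <- sum(subs["p3", i, "C", ])
      if (den > 0) subs["p3", i, "C", "T"] / den else 0
    }, numeric(1L))
  }
  list(offset = off, freq5 = f5, freq3 = f3)
}

#' Deamination plot for one taxonomic node
#'
#' Plots terminal substitution frequency against offset for the 5' C-to-T
#' series and the 3' series (G-to-A for ds, C-to-T for ss), one curve per
#' sample, from substitution files written by [write_subs_file()].
#'
#' @param subs_paths named character vector/list of substitution file paths
#'   (names are sample labels).
#' @param taxid node to plot.
#' @param out output image path (PDF, vector format).
#' @param stranded `"ds"` or `"ss"`.
#' @param P offsets to show (default 15).
#' @return invisibly, a named list of per-sample frequency series (these,
#'   not the rendering, are the tested contract).
#' @export
render_damage_plot <- function(subs_paths, taxid, out, stranded = c("ds", "ss"),
                               P = 15L) {
  stranded <- match.arg(stranded)
  if (is.null(names(subs_paths)))
    names(subs_paths) <- paste0("sample", seq_along(subs_paths))
  parsed <- lapply(subs_paths, read_subs_file)
  have <- vapply(parsed, function(p) !is.null(p[[taxid]]), logical(1L))
  if (!any(have)) {
    avail <- sort(unique(unlist(lapply(parsed, names))))
    stop(sprintf("taxid '%s' not present in any substitution file; available: %s",
                 taxid, paste(avail, collapse = ", ")))
  }
  series <- lapply(parsed[have], function(p)
    subs_frequency_series(p[[taxid]]$subs, stranded, P))
  grDevices::pdf(out, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  cols <- grDevices::hcl.colors(max(3L, length(series)), "Dark 3")
  ymax <- max(0.05, unlist(lapply(series, function(s) c(s$freq5, s$freq3))))
  graphics::plot(NA, xlim = c(1, P), ylim = c(0, ymax), xlab = "5' offset",
                 ylab = "C-to-T frequency", main = sprintf("taxid %s", taxid))
  for (i in seq_along(series))
    graphics::lines(series[[i]]$offset, series[[i]]$freq5, col = cols[i], lwd = 2)
  graphics::legend("topright", legend = names(series), lwd = 2,
                   col = cols[seq_along(series)], bty = "n", cex = 0.8)
  lab3 <- if (stranded == "ds") "G-to-A frequency" else "C-to-T frequency"
  graphics::plot(NA, xlim = c(P, 1), ylim = c(0, ymax), xlab = "3' offset",
                 ylab = lab3, main = sprintf("taxid %s", taxid))
  for (i in seq_along(series))
    graphics::lines(series[[i]]$offset, series[[i]]$freq3, col = cols[i], lwd = 2)
  invisible(series)
}

#' Read-length and mismatch histograms
#'
#' Streams one or more alignment files and plots, per sample, the read
#' length distribution and the per-read mismatch (NM of the AS-best
#' alignment) distribution. Histogram counts sum to the number of reads.
#'
#' @param aln_paths named vector/list of BAM/SAM paths.
#' @param out output PDF path.
#' @return invisibly, per-sample lists with `lengths` and `mismatches`
#'   integer vectors (one entry per read).
#' @export
render_baminfo_plot <- function(aln_paths, out) {
  if (is.null(names(aln_paths)))
    names(aln_paths) <- paste0("sample", seq_along(aln_paths))
  per_sample <- lapply(aln_paths, function(p) {
    gr <- sam_group_reader(p)
    on.exit(gr$close())
    lens <- integer(0); mms <- integer(0)
    while (!is.null(g <- gr$next_group())) {
      mapped <- Filter(Negate(is_unmapped), g$records)
      if (!length(mapped)) next
      lens <- c(lens, nchar(mapped[[1L]]$seq))
      bi <- best_alignment_index(mapped)
      nm <- sam_tag_int(mapped[[bi]], "NM")
      mms <- c(mms, if (is.na(nm)) 0L else nm)
    }
    list(lengths = lens, mismatches = mms)
  })
  grDevices::pdf(out, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  cols <- grDevices::hcl.colors(max(3L, length(per_sample)), "Dark 3")
  lens <- lapply(per_sample, `[[`, "lengths")
  brks <- seq(min(unlist(lens)) - 0.5, max(unlist(lens)) + 0.5)
  graphics::plot(NA, xlim = range(unlist(lens)),
                 ylim = c(0, max(vapply(lens, function(l) max(tabulate(l)), 1))),
                 xlab = "read length (bp)", ylab = "reads", main = "Read length")
  for (i in seq_along(lens)) {
    h <- graphics::hist(lens[[i]], breaks = brks, plot = FALSE)
    graphics::lines(h$mids, h$counts, col = cols[i], lwd = 2, type = "s")
  }
  graphics::legend("topright", legend = names(per_sample), lwd = 2,
                   col = cols[seq_along(per_sample)], bty = "n", cex = 0.8)
  mms <- lapply(per_sample, `[[`, "mismatches")
  graphics::plot(NA, xlim = c(0, max(unlist(mms)) + 1),
                 ylim = c(0, max(vapply(mms, length, 1L))),
                 xlab = "mismatches per read (NM)", ylab = "reads",
                 main = "Mismatches")
  for (i in seq_along(mms)) {
    tb <- table(factor(mms[[i]], levels = 0:max(unlist(mms))))
    graphics::lines(as.integer(names(tb)), as.integer(tb),
                    col = cols[i], lwd = 2, type = "s")
  }
  invisible(per_sample)
}
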