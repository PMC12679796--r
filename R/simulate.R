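## Deterministic synthetic-fixture generator: a toy taxonomy, homologous toy
## references, reads with injectable terminal deamination, multi-alignment
## reads, and a matched read-name-grouped SAM/BAM + LCA pair. Everything any
## pipeline stage needs can be generated from a seed, so no external data is
## ever required.

#' Default toy taxonomy
#'
#' A small rooted taxonomy: one order carrying two families (two and one
#' genera; five species in total) plus a second order with no family below
#' it, so that reads can be planted above the family rank threshold.
#'
#' @return data.frame with columns `taxid`, `name`, `rank`, `parent`.
#' @export
toy_taxonomy <- function() {
  data.frame(
    taxid  = c("1", "10", "11", "100", "200", "110", "120", "210",
               "111", "112", "121", "211", "212"),
    name   = c("root", "Ordoa", "Ordob", "Famalpha", "Fambeta",
               "Genea", "Geneb", "Genec",
               "Spec aa", "Spec ab", "Spec ba", "Spec ca", "Spec cb"),
    rank   = c("no rank", "order", "order", "family", "family",
               "genus", "genus", "genus",
               "species", "species", "species", "species", "species"),
    parent = c(NA, "1", "1", "10", "10", "100", "100", "200",
               "110", "110", "120", "210", "210"),
    stringsAsFactors = FALSE)
}

# Path (assigned node first, root last) for a taxid in a taxonomy table.
taxonomy_path <- function(tax, taxid) {
  rows <- list()
  cur <- taxid
  while (!is.na(cur)) {
    i <- match(cur, tax$taxid)
    if (is.na(i)) stop(sprintf("taxid '%s' not in taxonomy", cur))
    rows[[length(rows) + 1L]] <- tax[i, c("taxid", "name", "rank")]
    cur <- tax$parent[i]
  }
  do.call(rbind, rows)
}

format_path_entries <- function(path_df) {
  paste(path_df$taxid, path_df$name, path_df$rank, sep = ":")
}

#' Fixture specification
#'
#' The stated world the generator emulates: ancient-DNA-sized fragments
#' drawn from per-species references, with geometric terminal deamination
#' (`d0 * r^(offset-1)`), a flat sequencing-error rate, occasional secondary
#' alignments to a sibling species (which push the LCA up to the genus), and
#' a configurable fraction of reads assigned above the family rank.
#'
#' @param taxonomy taxonomy table as from [toy_taxonomy()].
#' @param reads_per_species reads simulated per species (default 50).
#' @param ref_len reference length per species, bp (default 800).
#' @param read_len_mean,read_len_sd,read_len_range read length distribution
#'   (normal, rounded, clamped); defaults 60 +- 10 in \[35, 90\] bp, typical
#'   of ancient environmental DNA.
#' @param d0 terminal deamination amplitude (default 0.3).
#' @param decay geometric decay per offset (default 0.5).
#' @param seq_error flat per-base sequencing error rate (default 0.002).
#' @param multi_align_prob probability a read also aligns to a sibling
#'   species (LCA then falls at the genus; default 0.3).
#' @param above_family_frac fraction of reads assigned to their order node,
#'   i.e. above the family threshold (default 0.15).
#' @param low_complexity_frac fraction of reads replaced by a poly-T
#'   homopolymer contaminant (default 0).
#' @param indel_prob,softclip_prob per-read probabilities of carrying a 1-2
#'   bp indel / a 1-5 bp terminal soft clip (defaults 0.05 each).
#' @param divergence substitution divergence between sibling species
#'   references (default 0.05).
#' @param stranded library chemistry, `"ds"` or `"ss"` (default `"ds"`).
#' @param lca_metadata append `:<length>:<sequence>` metadata to LCA read
#'   fields, as ngsLCA does (default TRUE).
#' @param k unused by the generator itself; recorded for convenience.
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(taxonomy = toy_taxonomy(), reads_per_species = 50L,
                         ref_len = 800L, read_len_mean = 60, read_len_sd = 10,
                         read_len_range = c(35L, 90L), d0 = 0.3, decay = 0.5,
                         seq_error = 0.002, multi_align_prob = 0.3,
                         above_family_frac = 0.15, low_complexity_frac = 0,
                         indel_prob = 0.05, softclip_prob = 0.05,
                         divergence = 0.05, stranded = c("ds", "ss"),
                         lca_metadata = TRUE, k = 29L, seed = 42L) {
  stranded <- match.arg(stranded)
  stopifnot(d0 >= 0, d0 <= 1, decay >= 0, decay <= 1,
            seq_error >= 0, seq_error < 1, reads_per_species >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(seq, rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    alt <- vapply(b[hit], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
                  character(1L))
    b[hit] <- alt
  }
  paste(b, collapse = "")
}

# Geometric terminal deamination on the molecule as sequenced.
apply_damage <- function(molecule, d0, r, stranded) {
  b <- strsplit(molecule, "", fixed = TRUE)[[1L]]
  L <- length(b)
  n5 <- 0L; n3 <- 0L
  p <- d0 * r^(seq_len(L) - 1)
  flip5 <- b == "C" & runif(L) < p
  b[flip5] <- "T"
  n5 <- sum(flip5)
  p3 <- rev(p)
  if (stranded == "ds") {
    flip3 <- b == "G" & runif(L) < p3
    b[flip3] <- "A"
  } else {
    flip3 <- b == "C" & runif(L) < p3
    b[flip3] <- "T"
  }
  n3 <- sum(flip3)
  list(seq = paste(b, collapse = ""), n5 = n5, n3 = n3)
}

#' Simulate damaged reads with truth labels
#'
#' Draws fragments from the per-species references, applies terminal
#' deamination (C-to-T from the 5' end; C-to-T or G-to-A from the 3' end per
#' chemistry) with probability `d0 * decay^(offset-1)`, then flat sequencing
#' errors. Truth (source taxon, strand, coordinates, injected damage counts,
#' assigned LCA node) is retained for oracle tests.
#'
#' @param spec a [fixture_spec()].
#' @return a list with `reads` (data.frame of truth labels and molecule
#'   sequences), `refs` (named character vector of species references), and
#'   `spec`.
#' @export
simulate_damaged_reads <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  tax <- spec$taxonomy
  species <- tax$taxid[tax$rank == "species"]
  # homologous references: one ancestral sequence per genus, species diverge
  refs <- character(0)
  for (g in tax$taxid[tax$rank == "genus"]) {
    anc <- random_seq(spec$ref_len)
    for (s in tax$taxid[tax$rank == "species" & tax$parent == g])
      refs[s] <- mutate_seq(anc, spec$divergence)
  }
  rows <- list()
  idx <- 0L
  for (s in species) {
    ref <- refs[[s]]
    genus <- tax$parent[match(s, tax$taxid)]
    siblings <- setdiff(tax$taxid[tax$rank == "species" & tax$parent == genus], s)
    family <- tax$parent[match(genus, tax$taxid)]
    order_id <- tax$parent[match(family, tax$taxid)]
    for (j in seq_len(spec$reads_per_species)) {
      idx <- idx + 1L
      L <- round(rnorm(1L, spec$read_len_mean, spec$read_len_sd))
      L <- max(spec$read_len_range[1L], min(spec$read_len_range[2L], L))
      pos <- sample.int(spec$ref_len - L + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      lowc <- runif(1L) < spec$low_complexity_frac
      frag <- substr(ref, pos, pos + L - 1L)
      molecule0 <- if (strand == "+") frag else revcomp(frag)
      if (lowc) {
        b <- rep("T", L)
        few <- sample.int(L, max(1L, round(L * 0.05)))
        b[few] <- sample(c("A", "C", "G"), length(few), replace = TRUE)
        molecule0 <- paste(b, collapse = "")
      }
      dm <- apply_damage(molecule0, spec$d0, spec$decay, spec$stranded)
      mol <- mutate_seq(dm$seq, spec$seq_error)
      multi <- !lowc && length(siblings) > 0L && runif(1L) < spec$multi_align_prob
      sib <- if (multi) sample(siblings, 1L) else NA_character_
      above <- runif(1L) < spec$above_family_frac
      assigned <- if (above) order_id else if (multi) genus else s
      rows[[idx]] <- data.frame(
        read_id = sprintf("read%05d", idx), taxid = s, assigned = assigned,
        pos = pos, len = L, strand = strand, molecule = mol,
        fragment = frag, sibling = sib, low_complexity = lowc,
        n_damage5 = dm$n5, n_damage3 = dm$n3, stringsAsFactors = FALSE)
    }
  }
  list(reads = do.call(rbind, rows), refs = refs, spec = spec)
}

# Build one SAM record from an op structure (forward-reference coordinates).
# ops: data.frame(op, q = query segment, r = reference segment)
build_sam_record <- function(qname, flag, rname, pos, ops) {
  seq <- paste(ops$q[ops$op %in% c("S", "M", "I")], collapse = "")
  cigar <- paste0(nchar(ifelse(ops$op == "D", ops$r, ops$q)), ops$op, collapse = "")
  md <- character(0)
  nm <- 0L
  run <- 0L
  matches <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    if (op == "M") {
      q <- strsplit(ops$q[i], "")[[1L]]
      r <- strsplit(ops$r[i], "")[[1L]]
      for (jj in seq_along(q)) {
        if (q[jj] == r[jj]) {
          run <- run + 1L; matches <- matches + 1L
        } else {
          md <- c(md, as.character(run), r[jj]); run <- 0L; nm <- nm + 1L
        }
      }
    } else if (op == "D") {
      md <- c(md, as.character(run), paste0("^", ops$r[i])); run <- 0L
      nm <- nm + nchar(ops$r[i])
    } else if (op == "I") {
      nm <- nm + nchar(ops$q[i])
    }
  }
  md <- paste(c(md, as.character(run)), collapse = "")
  as_score <- 2L * matches - 4L * nm
  list(line = paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq,
                    paste(rep("I", nchar(seq)), collapse = ""),
                    paste0("AS:i:", as_score), paste0("NM:i:", nm),
                    paste0("MD:Z:", md), sep = "\t"),
       as_score = as_score, seq = seq)
}

# Alignment ops of one read against a reference fragment, optionally adding
# an indel and soft clips (which lengthen/shorten the stored query).
make_ops <- function(stored_query, fragment, add_indel, add_clip) {
  ops <- data.frame(op = "M", q = stored_query, r = fragment,
                    stringsAsFactors = FALSE)
  L <- nchar(stored_query)
  if (add_indel && L > 20L) {
    at <- sample(8:(L - 8L), 1L)
    ilen <- sample(1:2, 1L)
    if (runif(1L) < 0.5) {  # insertion in the read
      ins <- random_seq(ilen)
      ops <- data.frame(
        op = c("M", "I", "M"),
        q = c(substr(stored_query, 1L, at), ins,
              substr(stored_query, at + 1L, L)),
        r = c(substr(fragment, 1L, at), "", substr(fragment, at + 1L, L)),
        stringsAsFactors = FALSE)
    } else {                # deletion from the read
      ops <- data.frame(
        op = c("M", "D", "M"),
        q = c(substr(stored_query, 1L, at), "",
              substr(stored_query, at + ilen + 1L, L)),
        r = c(substr(fragment, 1L, at), substr(fragment, at + 1L, at + ilen),
              substr(fragment, at + ilen + 1L, L)),
        stringsAsFactors = FALSE)
    }
  }
  if (add_clip) {
    clen <- sample(1:5, 1L)
    clip <- data.frame(op = "S", q = random_seq(clen), r = "",
                       stringsAsFactors = FALSE)
    if (runif(1L) < 0.5) ops <- rbind(clip, ops) else ops <- rbind(ops, clip)
  }
  ops
}

#' Emit a matched SAM/BAM + LCA fixture pair
#'
#' Writes a read-name-grouped alignment file and an LCA file in the same
#' read order. Every alignment's CIGAR, MD, NM and AS are computed against
#' the true toy references, so reference reconstruction can be checked
#' exactly against generator truth. Reads flagged as multi-alignment gain a
#' secondary alignment to the homologous position on a sibling species
#' reference.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param basename file stem (default "fixture").
#' @param bam write a BAM (TRUE) or keep SAM text (FALSE, default).
#' @param sim optional pre-computed result of [simulate_damaged_reads()].
#' @return list with `aln` (SAM/BAM path), `lca` (LCA path), `truth`
#'   (read-level truth data.frame, including each read's emitted alignment
#'   count and true reference substrings), `refs`, `spec`.
#' @export
emit_fixture_pair <- function(spec, dir = tempfile("fixture"),
                              basename = "fixture", bam = FALSE, sim = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(sim)) sim <- simulate_damaged_reads(spec)
  set.seed(spec$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tax <- spec$taxonomy
  refs <- sim$refs
  reads <- sim$reads
  sam_lines <- vector("list", nrow(reads))
  lca_lines <- character(nrow(reads))
  n_aln <- integer(nrow(reads))
  true_ref <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    stored <- if (rd$strand == "+") rd$molecule else revcomp(rd$molecule)
    flag0 <- if (rd$strand == "+") 0L else 16L
    ops <- make_ops(stored, rd$fragment,
                    add_indel = runif(1L) < spec$indel_prob,
                    add_clip = runif(1L) < spec$softclip_prob)
    rec <- build_sam_record(rd$read_id, flag0, rd$taxid, rd$pos, ops)
    lines_i <- rec$line
    true_ref[i] <- paste(ops$r, collapse = "")
    if (!is.na(rd$sibling)) {
      frag2 <- substr(refs[[rd$sibling]], rd$pos, rd$pos + rd$len - 1L)
      ops2 <- data.frame(op = "M", q = stored, r = frag2, stringsAsFactors = FALSE)
      rec2 <- build_sam_record(rd$read_id, flag0 + 256L, rd$sibling, rd$pos, ops2)
      lines_i <- c(lines_i, rec2$line)
    }
    n_aln[i] <- length(lines_i)
    sam_lines[[i]] <- lines_i
    path_df <- taxonomy_path(tax, rd$assigned)
    field <- rd$read_id
    if (isTRUE(spec$lca_metadata))
      field <- paste(field, nchar(rec$seq), rec$seq, sep = ":")
    lca_lines[i] <- paste(c(field, format_path_entries(path_df)), collapse = "\t")
  }
  sam_lines <- unlist(sam_lines)
  header <- c("@HD\tVN:1.6\tSO:unsorted\tGO:query",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)),
              "@PG\tID:taphos-simulate\tPN:taphos")
  aln_path <- file.path(dir, paste0(basename, if (bam) ".bam" else ".sam"))
  write_alignment_file(header, sam_lines, aln_path)
  lca_path <- file.path(dir, paste0(basename, ".lca"))
  writeLines(lca_lines, lca_path)
  truth <- reads
  truth$n_alignments <- n_aln
  truth$true_ref <- true_ref
  list(aln = aln_path, lca = lca_path, truth = truth, refs = refs, spec = spec)
}
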