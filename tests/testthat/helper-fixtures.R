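# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

make_sam_line <- function(qname, flag = 0L, rname = "ref1", pos = 1L,
                          cigar, seq, md, as = 0L, nm = 0L) {
  paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq,
        paste(rep("I", nchar(seq)), collapse = ""),
        paste0("AS:i:", as), paste0("NM:i:", nm), paste0("MD:Z:", md),
        sep = "\t")
}

write_test_sam <- function(lines, refs = c(ref1 = 1000L), path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unsorted\tGO:query",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refs), refs))
  writeLines(c(header, lines), path)
  path
}

write_test_lca <- function(lines, path = tempfile(fileext = ".lca")) {
  writeLines(lines, path)
  path
}

# LCA line for a read assigned to `taxid` in the default toy taxonomy.
toy_lca_line <- function(read_id, taxid, tax = toy_taxonomy()) {
  p <- taphos:::taxonomy_path(tax, taxid)
  paste(c(read_id, paste(p$taxid, p$name, p$rank, sep = ":")), collapse = "\t")
}

# Independent R oracle for canonical k-mers (no shared code with the C++).
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  wins <- substring(seq, 1:(n - k + 1), k:n)
  rc <- vapply(wins, function(w) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1]]), collapse = "")
  }, character(1))
  ok <- !grepl("[^ACGT]", wins)
  unname(ifelse(wins < rc, wins, rc)[ok])
}

# Independent similarity oracle straight off the SAM text: matched columns =
# M-columns from CIGAR minus mismatch letters in MD (outside ^-runs),
# divided by the stored read length.
oracle_similarity <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  cigar <- f[6]; seq <- f[10]
  md <- sub("^MD:Z:", "", grep("^MD:Z:", f, value = TRUE))
  ops <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  mcols <- sum(as.integer(sub("[A-Z=]", "", ops[grepl("[M=X]$", ops)])))
  md_clean <- gsub("\\^[A-Z]+", "", md)
  mism <- nchar(gsub("[0-9]", "", md_clean))
  (mcols - mism) / nchar(seq)
}

# Small cached end-to-end fixture shared across test files.
.fx_cache <- new.env(parent = emptyenv())
small_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    spec <- fixture_spec(reads_per_species = 25L, seed = 101L)
    .fx_cache$fx <- emit_fixture_pair(spec)
  }
  .fx_cache$fx
}

shrunk_fixture <- function() {
  if (is.null(.fx_cache$shrunk)) {
    fx <- small_fixture()
    d <- tempfile("shrunk")
    dir.create(d)
    out_aln <- file.path(d, "s.sam"); out_lca <- file.path(d, "s.lca")
    rep_ <- shrink(fx$aln, fx$lca, out_aln, out_lca)
    .fx_cache$shrunk <- list(aln = out_aln, lca = out_lca, report = rep_,
                             fx = fx)
  }
  .fx_cache$shrunk
}
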