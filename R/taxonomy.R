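## Parsing of ngsLCA-style assignment files and read-count aggregation up the
## taxonomy. Taxids are always compared as strings: custom databases may use
## non-numeric identifiers.

parse_error <- function(msg, line_number = NA_integer_) {
  stop(structure(
    class = c("taphos_parse_error", "error", "condition"),
    list(message = sprintf("LCA parse error at line %s: %s",
                           ifelse(is.na(line_number), "?", line_number), msg),
         call = NULL, line = line_number)))
}

# ngsLCA read-identifier fields may carry ":<length>:<sequence>"-style
# metadata after the true read name. The companion BAM is the real authority
# (see lca_id_matches()); this heuristic only trims unambiguous trailing
# all-digit / all-nucleotide segments for standalone LCA parsing.
strip_read_metadata <- function(field) {
  parts <- strsplit(field, ":", fixed = TRUE)[[1L]]
  while (length(parts) > 1L &&
         grepl("^([0-9]+|[ACGTNacgtn]+)$", parts[length(parts)])) {
    parts <- parts[-length(parts)]
  }
  paste(parts, collapse = ":")
}

# BAM-authoritative identifier match: the LCA field equals the BAM read name,
# or extends it with colon-separated metadata.
lca_id_matches <- function(lca_field, qname) {
  lca_field == qname | startsWith(lca_field, paste0(qname, ":"))
}

#' Parse one line of an ngsLCA-style assignment file
#'
#' A line is a read-identifier field followed by tab-separated path entries
#' `taxid:name:rank`, ordered from the assigned (lowest) node up to the root.
#' Taxon names may themselves contain colons, so the taxid is taken from the
#' left of the first colon and the rank from the right of the last colon,
#' with the remainder kept intact as the name.
#'
#' @param line a single text line.
#' @param line_number used in error messages.
#' @return an object of class `lca_assignment`: a list with `read_id` (the
#'   identifier with trailing numeric/sequence metadata stripped),
#'   `read_field` (the raw identifier field), and a `path` data.frame with
#'   columns `taxid`, `name`, `rank` (assigned node first).
#' @export
parse_lca_line <- function(line, line_number = NA_integer_) {
  if (length(line) != 1L || is.na(line) || !nzchar(trimws(line)))
    parse_error("empty line", line_number)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 2L)
    parse_error("no taxonomic path entries", line_number)
  entries <- fields[-1L]
  first <- regexpr(":", entries, fixed = TRUE)
  last <- vapply(gregexpr(":", entries, fixed = TRUE),
                 function(m) m[length(m)], integer(1L))
  bad <- first < 1L | first == last
  if (any(bad))
    parse_error(sprintf("path entry '%s' not splittable into taxid:name:rank",
                        entries[which(bad)[1L]]), line_number)
  taxid <- substr(entries, 1L, first - 1L)
  rank <- substr(entries, last + 1L, nchar(entries))
  name <- substr(entries, first + 1L, last - 1L)
  if (any(!nzchar(taxid)))
    parse_error("empty taxid in path entry", line_number)
  if (anyDuplicated(taxid))
    parse_error("duplicate taxid within one path", line_number)
  structure(
    list(read_id = strip_read_metadata(fields[1L]),
         read_field = fields[1L],
         path = data.frame(taxid = taxid, name = name, rank = rank,
                           stringsAsFactors = FALSE)),
    class = "lca_assignment")
}

#' Reserialize an assignment to its ngsLCA-style line
#'
#' @param x an `lca_assignment`.
#' @return a single text line; `parse_lca_line()` of it is a fixed point.
#' @export
format_lca_assignment <- function(x) {
  stopifnot(inherits(x, "lca_assignment"))
  paste(c(x$read_field,
          paste(x$path$taxid, x$path$name, x$path$rank, sep = ":")),
        collapse = "\t")
}

#' Streaming reader over an LCA file
#'
#' Returns a closure yielding one parsed `lca_assignment` per call, or `NULL`
#' at end of input. A leading comment/header line (starting with `#`, or
#' whose first path entry does not look like `taxid:name:rank`) is skipped.
#'
#' @param path LCA file path.
#' @return a list with `next_assignment()`, `next_line()` (the raw line of
#'   the last yielded assignment), and `close()`.
#' @export
lca_reader <- function(path) {
  con <- file(path, open = "r")
  lineno <- 0L
  raw_line <- NULL
  first <- TRUE
  read1 <- function() {
    repeat {
      ln <- readLines(con, n = 1L, warn = FALSE)
      lineno <<- lineno + 1L
      if (length(ln) == 0L) return(NULL)
      if (first) {
        first <<- FALSE
        if (startsWith(ln, "#") || (length(strsplit(ln, "\t")[[1L]]) < 2L)) next
      }
      if (!nzchar(trimws(ln))) next
      raw_line <<- ln
      return(parse_lca_line(ln, lineno))
    }
  }
  list(next_assignment = read1,
       next_line = function() raw_line,
       line_number = function() lineno,
       close = function() close(con))
}

#' Read a whole LCA file
#'
#' @param path LCA file path.
#' @return list of `lca_assignment` objects, in file order.
#' @export
read_lca <- function(path) {
  rd <- lca_reader(path)
  on.exit(rd$close())
  out <- list()
  i <- 0L
  while (!is.null(a <- rd$next_assignment())) {
    i <- i + 1L
    out[[i]] <- a
  }
  out
}

#' Is an assignment at or below a taxonomic rank?
#'
#' TRUE iff some node of the path (the assigned node or an ancestor) carries
#' exactly the threshold rank name. Rank-ladder ordering is deliberately not
#' hard-coded: what ngsLCA encodes is path membership, and rank ladders are
#' database-dependent.
#'
#' @param x an `lca_assignment`, or a character vector of ranks
#'   (assigned node first).
#' @param threshold_rank rank name, e.g. `"family"`.
#' @return logical scalar.
#' @export
is_at_or_below_rank <- function(x, threshold_rank) {
  ranks <- if (inherits(x, "lca_assignment")) x$path$rank else as.character(x)
  threshold_rank %in% ranks
}

#' Aggregate read counts up the taxonomy
#'
#' Each read increments the count of its assigned node and of every ancestor
#' on its path exactly once, so `count(node)` is the number of reads assigned
#' to that node or any of its descendants.
#'
#' @param assignments list of `lca_assignment` objects.
#' @return named numeric vector, taxid -> aggregated read count.
#' @export
aggregate_counts <- function(assignments) {
  env <- new.env(parent = emptyenv())
  for (a in assignments) {
    for (tid in a$path$taxid) {
      env[[tid]] <- (if (is.null(env[[tid]])) 0 else env[[tid]]) + 1
    }
  }
  ids <- ls(env)
  setNames(vapply(ids, function(i) env[[i]], numeric(1L)), ids)
}
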