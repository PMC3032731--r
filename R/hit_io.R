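#' Read a proteome FASTA into a length index
#'
#' Builds an index of protein identifiers and residue lengths from a protein
#' FASTA file. Only identifiers (the first whitespace-delimited token of each
#' header) and sequence lengths are retained; translation stop characters
#' (`*`) do not count towards the length.
#'
#' @param path Path to a protein FASTA file (UTF-8, Unix or Windows line
#'   endings).
#' @param organism_id Identifier recorded for the organism this proteome
#'   belongs to.
#' @return An object of class `proteome_index`: a list with elements
#'   `organism_id`, `protein_ids` (character, in file order) and `lengths`
#'   (named integer vector, residues per protein).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "MKV", ">p2", "MA"), fa)
#' idx <- read_fasta_index(fa)
#' idx$lengths
#' @export
read_fasta_index <- function(path, organism_id = "reference") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  # length excludes '*' stop characters
  nstop <- Biostrings::vcountPattern("*", seqs)
  lens <- Biostrings::width(seqs) - nstop
  if (any(lens < 1L)) {
    stop("zero-length sequence(s): ", paste(ids[lens < 1L], collapse = ", "))
  }
  lengths <- stats::setNames(as.integer(lens), ids)
  structure(list(organism_id = organism_id,
                 protein_ids = ids,
                 lengths = lengths),
            class = "proteome_index")
}

#' @export
print.proteome_index <- function(x, ...) {
  cat("<proteome_index> ", x$organism_id, ": ", length(x$protein_ids),
      " proteins, median length ",
      stats::median(x$lengths), "\n", sep = "")
  invisible(x)
}

# Column order of the tabular hit dialect
# (BLAST+ -outfmt "6 qseqid sseqid evalue pident ppos length
#                    qstart qend sstart send qlen slen")
.hit_cols12 <- c("qseqid", "sseqid", "evalue", "pident", "ppos", "length",
                 "qstart", "qend", "sstart", "send", "qlen", "slen")

# Canonical AlignmentHit column names used throughout the package
.hit_fields <- c("query_id", "target_id", "organism_id", "evalue",
                 "identity_pct", "similarity_pct", "aln_len",
                 "query_len", "target_len", "query_gaps", "target_gaps",
                 "q_start", "q_end", "t_start", "t_end")

#' Read an alignment hit table
#'
#' Parses a tab-separated alignment hit table (one row per HSP) in the
#' 12-column dialect `qseqid sseqid evalue pident ppos length qstart qend
#' sstart send qlen slen` (BLAST+ `-outfmt 6` with those columns), or the
#' reduced 10-column dialect without `qlen`/`slen`, in which case sequence
#' lengths are filled from the supplied proteome indexes.
#'
#' Per-row gap counts are derived from the alignment coordinates:
#' `query_gaps = length - (qend - qstart + 1)` and analogously for the
#' target. Coordinates are 1-based inclusive. An e-value printed as `0.0`
#' is accepted; it compares below every positive threshold.
#'
#' @param path Path to the tab-separated hit table (no header).
#' @param organism_id Identifier of the target organism the table belongs to.
#' @param lengths_q `proteome_index` of the query (reference) proteome.
#'   Every `qseqid` must be present in it.
#' @param lengths_t Optional `proteome_index` of the target proteome;
#'   required for the 10-column dialect.
#' @return A `data.frame` of alignment hits with columns `query_id`,
#'   `target_id`, `organism_id`, `evalue`, `identity_pct`, `similarity_pct`,
#'   `aln_len`, `query_len`, `target_len`, `query_gaps`, `target_gaps`,
#'   `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
read_hit_table <- function(path, organism_id, lengths_q, lengths_t = NULL) {
  stopifnot(inherits(lengths_q, "proteome_index"))
  if (!file.exists(path)) stop("hit table not found: ", path)
  if (file.size(path) == 0L) {
    # an organism with no collected hits is legitimate: explicit absence
    h <- .empty_hits()
    return(h)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  nc <- ncol(raw)
  if (!nc %in% c(10L, 12L)) {
    stop("hit table ", path, ": expected 10 or 12 tab-separated columns, got ",
         nc)
  }
  names(raw) <- .hit_cols12[seq_len(nc)]

  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x))
    if (length(bad) > 0L) {
      stop("hit table ", path, " line ", bad[1L], ": malformed ", what,
           " value '", raw[[col]][bad[1L]], "'")
    }
    x
  }
  evalue <- num("evalue", "evalue")
  pident <- num("pident", "pident")
  ppos   <- num("ppos", "ppos")
  alen   <- as.integer(num("length", "length"))
  qstart <- as.integer(num("qstart", "qstart"))
  qend   <- as.integer(num("qend", "qend"))
  sstart <- as.integer(num("sstart", "sstart"))
  send   <- as.integer(num("send", "send"))

  unknown <- setdiff(unique(raw$qseqid), names(lengths_q$lengths))
  if (length(unknown) > 0L) {
    stop("hit table ", path, ": query identifier(s) not in reference ",
         "proteome: ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  qlen <- if (nc == 12L) as.integer(num("qlen", "qlen")) else
    unname(lengths_q$lengths[raw$qseqid])
  if (nc == 12L) {
    slen <- as.integer(num("slen", "slen"))
  } else {
    if (is.null(lengths_t)) {
      stop("hit table ", path, ": 10-column dialect requires a target ",
           "proteome index (lengths_t)")
    }
    miss <- setdiff(unique(raw$sseqid), names(lengths_t$lengths))
    if (length(miss) > 0L) {
      stop("hit table ", path, ": target identifier(s) not in target ",
           "proteome index: ", paste(utils::head(miss, 5L), collapse = ", "))
    }
    slen <- unname(lengths_t$lengths[raw$sseqid])
  }

  hits <- data.frame(
    query_id       = raw$qseqid,
    target_id      = raw$sseqid,
    organism_id    = organism_id,
    evalue         = evalue,
    identity_pct   = pident,
    similarity_pct = ppos,
    aln_len        = alen,
    query_len      = qlen,
    target_len     = slen,
    query_gaps     = alen - (qend - qstart + 1L),
    target_gaps    = alen - (send - sstart + 1L),
    q_start        = qstart,
    q_end          = qend,
    t_start        = sstart,
    t_end          = send,
    stringsAsFactors = FALSE
  )
  bad <- .validate_hits(hits)
  if (!is.null(bad)) {
    stop("hit table ", path, " line ", bad$line, ": ", bad$msg)
  }
  hits
}

# Returns NULL when valid, else list(line, msg) for the first offending row.
.validate_hits <- function(h) {
  checks <- list(
    list(h$evalue < 0,                    "negative evalue"),
    list(h$identity_pct < 0 | h$identity_pct > 100, "pident out of [0,100]"),
    list(h$similarity_pct < h$identity_pct,
         "ppos (similarity) below pident (identity)"),
    list(h$similarity_pct > 100,          "ppos out of [0,100]"),
    list(h$q_start < 1 | h$q_start > h$q_end, "invalid query coordinates"),
    list(h$t_start < 1 | h$t_start > h$t_end, "invalid target coordinates"),
    list(h$q_end > h$query_len,           "qend exceeds query length"),
    list(h$t_end > h$target_len,          "send exceeds target length"),
    list(h$query_gaps < 0,  "alignment length below query span (negative query gaps)"),
    list(h$target_gaps < 0, "alignment length below target span (negative target gaps)"),
    list(h$aln_len > h$query_len + h$target_len,
         "alignment longer than both sequences combined")
  )
  for (ck in checks) {
    w <- which(ck[[1L]])
    if (length(w) > 0L) return(list(line = w[1L], msg = ck[[2L]]))
  }
  NULL
}

#' Write alignment hits in the 12-column tabular dialect
#'
#' Inverse of [read_hit_table()]: re-reading the written file yields
#' field-identical hits.
#'
#' @param hits Alignment hit `data.frame` (see [read_hit_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$target_id,
    evalue = format(hits$evalue, digits = 17, trim = TRUE, scientific = TRUE),
    pident = format(hits$identity_pct, digits = 15, trim = TRUE),
    ppos   = format(hits$similarity_pct, digits = 15, trim = TRUE),
    length = hits$aln_len,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$t_start, send = hits$t_end,
    qlen = hits$query_len, slen = hits$target_len
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse multiple HSPs per protein pair to the best one
#'
#' Keeps exactly one hit per (query, target) pair within each organism: the
#' HSP with the smallest e-value, ties broken by the largest alignment
#' length, then by the smallest target start coordinate.
#'
#' @param hits Alignment hit `data.frame`.
#' @return Subset of `hits` with unique (query_id, target_id, organism_id)
#'   keys.
#' @export
collapse_hsps <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, hits$target_id, hits$organism_id,
             hits$evalue, -hits$aln_len, hits$t_start)
  h <- hits[o, , drop = FALSE]
  key <- paste(h$query_id, h$target_id, h$organism_id, sep = "\r")
  h <- h[!duplicated(key), , drop = FALSE]
  rownames(h) <- NULL
  h
}
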