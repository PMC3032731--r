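# Test fixtures and independent oracles.
#
# make_hit() builds AlignmentHit rows directly from high-level statistics,
# independently of the package's simulator, so tests do not inherit its
# geometry conventions.

make_hit <- function(query_id = "p1", target_id = "x1",
                     organism_id = "orgA",
                     evalue = 1e-50, identity = 60, similarity = 80,
                     query_len = 100L, target_len = NULL,
                     span_q = 0.9, q_gaps = 0L, t_gaps = 0L,
                     q_start = 1L, t_start = 1L) {
  aq <- as.integer(round(span_q * query_len))
  aln <- aq + q_gaps
  at <- aln - t_gaps
  if (is.null(target_len)) target_len <- as.integer(at + 10L)
  data.frame(query_id = query_id, target_id = target_id,
             organism_id = organism_id, evalue = evalue,
             identity_pct = identity, similarity_pct = similarity,
             aln_len = aln, query_len = as.integer(query_len),
             target_len = as.integer(target_len),
             query_gaps = as.integer(q_gaps),
             target_gaps = as.integer(t_gaps),
             q_start = as.integer(q_start),
             q_end = as.integer(q_start + aq - 1L),
             t_start = as.integer(t_start),
             t_end = as.integer(t_start + at - 1L),
             stringsAsFactors = FALSE)
}

# Random valid AlignmentHits spanning the full parameter space
# (including e-values above the collection cutoff).
random_hits <- function(n, evalue_exp_range = c(-200, 0)) {
  L1 <- sample(50:2000, n, replace = TRUE)
  aq <- vapply(L1, function(l) sample.int(l, 1L), 1L)
  g1 <- sample(0:10, n, replace = TRUE)
  g2 <- pmin(sample(0:10, n, replace = TRUE), aq + g1 - 1L)
  at <- aq + g1 - g2
  L2 <- at + sample(0:500, n, replace = TRUE)
  identity <- runif(n, 0, 100)
  similarity <- identity + runif(n) * (100 - identity)
  qs <- vapply(L1 - aq + 1L, function(m) sample.int(m, 1L), 1L)
  ts <- vapply(L2 - at + 1L, function(m) sample.int(m, 1L), 1L)
  data.frame(query_id = sprintf("q%06d", seq_len(n)),
             target_id = sprintf("t%06d", seq_len(n)),
             organism_id = "orgR",
             evalue = 10^runif(n, evalue_exp_range[1L], evalue_exp_range[2L]),
             identity_pct = identity, similarity_pct = similarity,
             aln_len = aq + g1, query_len = L1, target_len = L2,
             query_gaps = g1, target_gaps = g2,
             q_start = qs, q_end = qs + aq - 1L,
             t_start = ts, t_end = ts + at - 1L,
             stringsAsFactors = FALSE)
}

# Independent restatement of the classification rules, scalar and literal:
# collect at e <= 1e-10; ortholog iff the alignment covers > 85% of either
# sequence and (e < 1e-36 or identity > 30); else homolog.
pair_class_oracle <- function(hit) {
  if (hit$evalue > 1e-10) return("NONE")
  cov_q <- (hit$q_end - hit$q_start + 1) / hit$query_len
  cov_t <- (hit$t_end - hit$t_start + 1) / hit$target_len
  if ((cov_q > 0.85 || cov_t > 0.85) &&
      (hit$evalue < 1e-36 || hit$identity_pct > 30)) {
    return("ORTHOLOG_CANDIDATE")
  }
  "HOMOLOG"
}

# Brute-force Hamming count, position by position.
hamming_oracle <- function(v, w) {
  stopifnot(length(v) == length(w))
  d <- 0L
  for (i in seq_along(v)) if (v[i] != w[i]) d <- d + 1L
  d
}

write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# A tiny deterministic proteome index without touching the filesystem
# reader: three organisms' worth of reference proteins.
tiny_reference <- function(n = 6L, len = 200L, organism_id = "reference") {
  ids <- sprintf("p%d", seq_len(n))
  path <- write_fasta(stats::setNames(
    as.list(vapply(seq_len(n), function(i)
      paste(rep("M", len), collapse = ""), "")), ids))
  read_fasta_index(path, organism_id = organism_id)
}

# Small simulated bundle shared by several test files (built once).
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_pathways = 4L, genes_per_pathway = 6L,
                        organisms = data.frame(
                          organism_id = c("orgHi", "orgMid", "orgLo"),
                          retention = c(0.9, 0.5, 0.2),
                          homolog_decay = 0.5,
                          domain = c("DomA", "DomA", "DomB"),
                          kingdom = c("KingA", "KingB", "KingC"),
                          phylum = c("Phy1", "Phy2", "Phy3"),
                          stringsAsFactors = FALSE),
                        seed = 7L)
      dir <- file.path(tempdir(), "orthorank-small-bundle")
      cache <<- simulate_bundle(cfg, dir)
    }
    cache
  }
})
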