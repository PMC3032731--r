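#' Default classification thresholds
#'
#' Thresholds separating orthologs from homologs, calibrated on pairwise
#' proteome comparisons: hits are collected at e-value <= 1e-10; a pair is
#' an ortholog candidate when the alignment spans more than 85% of either
#' sequence and either the e-value is below 1e-36 or the identity exceeds
#' 30%; every other collected pair is a homolog.
#'
#' @param collect_evalue Inclusive e-value cutoff for considering a hit at
#'   all (default `1e-10`).
#' @param ortholog_evalue Strict e-value cutoff in the ortholog rule
#'   (default `1e-36`).
#' @param ortholog_identity Strict identity cutoff (percent) in the ortholog
#'   rule (default `30`).
#' @param span_fraction Strict coverage cutoff: fraction of either sequence
#'   covered by ungapped aligned residues (default `0.85`).
#' @return A named list of the four thresholds.
#' @export
classification_thresholds <- function(collect_evalue = 1e-10,
                                      ortholog_evalue = 1e-36,
                                      ortholog_identity = 30,
                                      span_fraction = 0.85) {
  stopifnot(collect_evalue > 0, ortholog_evalue > 0,
            ortholog_evalue < collect_evalue,
            ortholog_identity >= 0, ortholog_identity <= 100,
            span_fraction > 0, span_fraction < 1)
  list(collect_evalue = collect_evalue,
       ortholog_evalue = ortholog_evalue,
       ortholog_identity = ortholog_identity,
       span_fraction = span_fraction)
}

# Ungapped aligned residues of the query / target rows.
.aligned_query  <- function(h) h$q_end - h$q_start + 1L
.aligned_target <- function(h) h$t_end - h$t_start + 1L

#' Classify protein pairs as ortholog candidates, homologs, or neither
#'
#' Applies the threshold rules to each hit. A hit above the collection
#' e-value cutoff is `NONE`. A hit is an `ORTHOLOG_CANDIDATE` when the
#' alignment spans more than `span_fraction` of either the query or the
#' target sequence (ungapped aligned residues over full length) AND either
#' its e-value is strictly below `ortholog_evalue` or its identity is
#' strictly above `ortholog_identity`. Every other collected hit is a
#' `HOMOLOG`. Boundary values (e-value exactly at the ortholog cutoff,
#' identity exactly at the identity cutoff, span exactly at the coverage
#' cutoff) fall on the non-ortholog side.
#'
#' @param hits Alignment hit `data.frame` (see [read_hit_table()]).
#' @param thresholds Output of [classification_thresholds()].
#' @return Character vector, one of `"ORTHOLOG_CANDIDATE"`, `"HOMOLOG"`,
#'   `"NONE"` per hit.
#' @export
pair_class <- function(hits, thresholds = classification_thresholds()) {
  span_q <- .aligned_query(hits) / hits$query_len
  span_t <- .aligned_target(hits) / hits$target_len
  is_orth <- (span_q > thresholds$span_fraction |
              span_t > thresholds$span_fraction) &
             (hits$evalue < thresholds$ortholog_evalue |
              hits$identity_pct > thresholds$ortholog_identity)
  ifelse(hits$evalue > thresholds$collect_evalue, "NONE",
         ifelse(is_orth, "ORTHOLOG_CANDIDATE", "HOMOLOG"))
}

#' Composite orthology score of an alignment
#'
#' Computes, per hit, the composite orthology score `F = F1 + F2 - F3`
#' used to pick the most likely ortholog among several candidates:
#'
#' * `F1 = (S/100 + I/100) / 2` — mean of similarity and identity
#'   fractions; in `[0, 1]`, 1 for a perfect match.
#' * `F2 = AL' / PL` — fraction of the query covered by the alignment,
#'   with `AL'` the ungapped aligned query residues
#'   (`q_end - q_start + 1`) and `PL` the query length; in `[0, 1]`.
#' * `F3 = G1/L1 + G2/L2` — gap load: gaps in the aligned query row over
#'   query length plus gaps in the aligned target row over target length;
#'   `>= 0`, 0 when gapless.
#'
#' `F` is bounded above by 2, attained only by a full-length gapless
#' alignment of identical sequences; it increases with identity/similarity
#' and coverage and decreases with gap load.
#'
#' @param hits Alignment hit `data.frame`.
#' @return A `data.frame` with columns `f1`, `f2`, `f3`, `f`, one row per
#'   hit.
#' @examples
#' h <- data.frame(query_id = "p", target_id = "t", organism_id = "o",
#'                 evalue = 1e-50, identity_pct = 60, similarity_pct = 80,
#'                 aln_len = 92, query_len = 100, target_len = 120,
#'                 query_gaps = 2, target_gaps = 3,
#'                 q_start = 1, q_end = 90, t_start = 1, t_end = 89)
#' fscore(h)  # f1 = 0.70, f2 = 0.90, f3 = 0.045, f = 1.555
#' @export
fscore <- function(hits) {
  if (any(hits$query_len <= 0L) || any(hits$target_len <= 0L)) {
    stop("fscore: zero-length sequence")
  }
  f1 <- (hits$similarity_pct / 100 + hits$identity_pct / 100) / 2
  f2 <- .aligned_query(hits) / hits$query_len
  f3 <- hits$query_gaps / hits$query_len + hits$target_gaps / hits$target_len
  data.frame(f1 = f1, f2 = f2, f3 = f3, f = f1 + f2 - f3)
}

#' Select the most likely ortholog among candidates
#'
#' Given all ortholog-candidate hits of one reference protein against one
#' organism, returns the candidate with the highest composite F score as
#' the ortholog; the remaining candidates are flagged as in-paralogs.
#' Ties are broken deterministically: smaller e-value, then larger
#' identity, then lexicographically smallest target identifier.
#'
#' @param candidates `data.frame` of ortholog-candidate hits for a single
#'   (query, organism), augmented with the columns of [fscore()] (`f1`,
#'   `f2`, `f3`, `f`). If the score columns are missing they are computed.
#' @return A list with elements `ortholog_id` (character scalar) and
#'   `inparalog_ids` (character vector, possibly empty, ordered by
#'   decreasing score).
#' @export
select_ortholog <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("select_ortholog: empty candidate list")
  }
  if (!"f" %in% names(candidates)) {
    candidates <- cbind(candidates, fscore(candidates))
  }
  o <- order(-candidates$f, candidates$evalue, -candidates$identity_pct,
             candidates$target_id)
  ids <- candidates$target_id[o]
  list(ortholog_id = ids[1L], inparalog_ids = ids[-1L])
}

#' Build ortholog/homolog/absent clusters for every reference protein
#'
#' Runs the full classification over HSP-collapsed hit tables: for every
#' reference protein and every organism the status is `ORTHOLOG_FOUND`
#' when at least one ortholog candidate exists (the best-scoring candidate
#' becomes the ortholog, the rest become in-paralogs; homolog-class hits
#' are recorded alongside), `HOMOLOG_ONLY` when only homolog-class hits
#' exist, and `ABSENT` otherwise. Absence is explicit: proteins with no
#' hits anywhere still receive a call per organism.
#'
#' @param hits_by_organism Either a named list of hit `data.frame`s (names
#'   are organism identifiers; overrides any `organism_id` column), or a
#'   single hit `data.frame` carrying its own `organism_id` column.
#' @param reference `proteome_index` of the reference proteome.
#' @param organisms Character vector of all target organism identifiers in
#'   the run (absence is recorded for organisms with no hit table rows).
#' @param thresholds Output of [classification_thresholds()].
#' @return An object of class `cluster_set`: list with `calls` (one row
#'   per protein x organism: `query_id`, `organism_id`, `status`,
#'   `ortholog_id`, `f1`..`f`, and list columns `inparalog_ids`,
#'   `homolog_ids`), `proteins`, `organisms`, `reference_id`, `thresholds`
#'   and a `terms` slot filled by [annotate_clusters()].
#' @export
build_clusters <- function(hits_by_organism, reference, organisms,
                           thresholds = classification_thresholds()) {
  stopifnot(inherits(reference, "proteome_index"))
  organisms <- as.character(organisms)
  if (anyDuplicated(organisms)) stop("duplicate organism identifiers")
  if (reference$organism_id %in% organisms) {
    stop("reference organism '", reference$organism_id,
         "' must not appear among target organisms")
  }

  if (is.data.frame(hits_by_organism)) {
    h <- hits_by_organism
  } else {
    stopifnot(is.list(hits_by_organism))
    if (length(hits_by_organism) > 0L && is.null(names(hits_by_organism))) {
      stop("hits_by_organism list must be named by organism")
    }
    h <- do.call(rbind, lapply(names(hits_by_organism), function(org) {
      x <- hits_by_organism[[org]]
      if (nrow(x) > 0L) x$organism_id <- org
      x
    }))
    if (is.null(h)) h <- .empty_hits()
  }

  extra <- setdiff(unique(h$organism_id), organisms)
  if (length(extra) > 0L) {
    stop("hit data contains organism(s) not in the organisms list: ",
         paste(extra, collapse = ", "))
  }
  unknown <- setdiff(unique(h$query_id), reference$protein_ids)
  if (length(unknown) > 0L) {
    stop("hit data contains query protein(s) not in the reference ",
         "proteome: ", paste(utils::head(unknown, 5L), collapse = ", "))
  }

  h <- collapse_hsps(h)
  if (nrow(h) > 0L) {
    h$.class <- pair_class(h, thresholds)
    h <- h[h$.class != "NONE", , drop = FALSE]
  }

  orth_best <- cbind(.empty_hits(),
                     data.frame(f1 = numeric(0), f2 = numeric(0),
                                f3 = numeric(0), f = numeric(0)))
  ip_by_key <- list(); hom_by_key <- list()
  if (nrow(h) > 0L) {
    h <- cbind(h, fscore(h))
    key <- paste(h$query_id, h$organism_id, sep = "\r")
    oc <- h[h$.class == "ORTHOLOG_CANDIDATE", , drop = FALSE]
    ockey <- key[h$.class == "ORTHOLOG_CANDIDATE"]
    if (nrow(oc) > 0L) {
      o <- order(ockey, -oc$f, oc$evalue, -oc$identity_pct, oc$target_id)
      oc <- oc[o, , drop = FALSE]; ockey <- ockey[o]
      first <- !duplicated(ockey)
      orth_best <- oc[first, , drop = FALSE]
      rownames(orth_best) <- ockey[first]
      ip_by_key <- split(oc$target_id[!first], ockey[!first])
    }
    hm <- h[h$.class == "HOMOLOG", , drop = FALSE]
    hmkey <- key[h$.class == "HOMOLOG"]
    if (nrow(hm) > 0L) {
      o <- order(hmkey, hm$evalue, hm$target_id)
      hom_by_key <- split(hm$target_id[o], hmkey[o])
    }
  }

  proteins <- reference$protein_ids
  grid <- expand.grid(query_id = proteins, organism_id = organisms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gkey <- paste(grid$query_id, grid$organism_id, sep = "\r")
  oidx <- match(gkey, rownames(orth_best))
  has_orth <- !is.na(oidx)
  has_hom <- gkey %in% names(hom_by_key)

  calls <- data.frame(
    query_id = grid$query_id,
    organism_id = grid$organism_id,
    status = ifelse(has_orth, "ORTHOLOG_FOUND",
                    ifelse(has_hom, "HOMOLOG_ONLY", "ABSENT")),
    ortholog_id = ifelse(has_orth, orth_best$target_id[oidx], NA_character_),
    f1 = orth_best$f1[oidx], f2 = orth_best$f2[oidx],
    f3 = orth_best$f3[oidx], f  = orth_best$f[oidx],
    stringsAsFactors = FALSE
  )
  empty <- rep(list(character(0)), nrow(grid))
  ip <- empty
  hit_ip <- match(gkey, names(ip_by_key))
  ip[!is.na(hit_ip)] <- ip_by_key[hit_ip[!is.na(hit_ip)]]
  hom <- empty
  hit_hm <- match(gkey, names(hom_by_key))
  hom[!is.na(hit_hm)] <- hom_by_key[hit_hm[!is.na(hit_hm)]]
  calls$inparalog_ids <- ip
  calls$homolog_ids <- hom

  structure(list(calls = calls,
                 proteins = proteins,
                 organisms = organisms,
                 reference_id = reference$organism_id,
                 thresholds = thresholds,
                 terms = NULL),
            class = "cluster_set")
}

.empty_hits <- function() {
  h <- data.frame(query_id = character(0), target_id = character(0),
                  organism_id = character(0), evalue = numeric(0),
                  identity_pct = numeric(0), similarity_pct = numeric(0),
                  aln_len = integer(0), query_len = integer(0),
                  target_len = integer(0), query_gaps = integer(0),
                  target_gaps = integer(0), q_start = integer(0),
                  q_end = integer(0), t_start = integer(0),
                  t_end = integer(0), stringsAsFactors = FALSE)
  h
}

#' @export
print.cluster_set <- function(x, ...) {
  tab <- table(factor(x$calls$status,
                      c("ORTHOLOG_FOUND", "HOMOLOG_ONLY", "ABSENT")))
  cat("<cluster_set> ", length(x$proteins), " reference proteins x ",
      length(x$organisms), " organisms\n", sep = "")
  cat("  ortholog: ", tab[[1L]], "  homolog-only: ", tab[[2L]],
      "  absent: ", tab[[3L]], "\n", sep = "")
  if (!is.null(x$terms)) {
    cat("  annotated with", length(unique(x$terms$term_id)), "terms in",
        length(unique(x$terms$namespace)), "namespace(s)\n")
  }
  invisible(x)
}

#' Status matrix of a cluster set
#'
#' @param clusters A `cluster_set` from [build_clusters()].
#' @return Character matrix (proteins x organisms) of status codes
#'   `"O"` (ortholog found), `"H"` (homolog only), `"A"` (absent).
#' @export
status_matrix <- function(clusters) {
  code <- c(ORTHOLOG_FOUND = "O", HOMOLOG_ONLY = "H", ABSENT = "A")
  m <- matrix(code[clusters$calls$status],
              nrow = length(clusters$proteins),
              ncol = length(clusters$organisms),
              dimnames = list(clusters$proteins, clusters$organisms))
  m
}

#' Write clusters as JSON lines
#'
#' One JSON record per reference protein with its per-organism status,
#' chosen ortholog, in-paralog and homolog identifiers and F-score
#' components, plus any attached functional terms.
#'
#' @param clusters A `cluster_set`.
#' @param path Output file path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_clusters_jsonl <- function(clusters, path) {
  calls <- clusters$calls
  idx <- split(seq_len(nrow(calls)), calls$query_id)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in clusters$proteins) {
    rows <- idx[[p]]
    per_org <- lapply(rows, function(i) {
      r <- list(status = calls$status[i])
      if (!is.na(calls$ortholog_id[i])) {
        r$ortholog <- calls$ortholog_id[i]
        r$f <- list(f1 = calls$f1[i], f2 = calls$f2[i],
                    f3 = calls$f3[i], f = calls$f[i])
      }
      if (length(calls$inparalog_ids[[i]]) > 0L)
        r$inparalogs <- calls$inparalog_ids[[i]]
      if (length(calls$homolog_ids[[i]]) > 0L)
        r$homologs <- calls$homolog_ids[[i]]
      r
    })
    names(per_org) <- calls$organism_id[rows]
    rec <- list(query_id = p, organisms = per_org)
    if (!is.null(clusters$terms)) {
      tt <- clusters$terms[clusters$terms$query_id == p, , drop = FALSE]
      if (nrow(tt) > 0L) {
        rec$terms <- lapply(split(tt$term_id, tt$namespace), as.list)
      }
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write the protein-by-organism status table
#'
#' @param clusters A `cluster_set`.
#' @param path Output TSV path; first column `protein`, one column per
#'   organism with codes O/H/A.
#' @return `path`, invisibly.
#' @export
write_status_tsv <- function(clusters, path) {
  m <- status_matrix(clusters)
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
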