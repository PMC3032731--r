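.namespaces <- c("GO_process", "GO_function", "GO_component", "KEGG_pathway")
.gaf_aspect <- c(GO_process = "P", GO_function = "F", GO_component = "C")

#' Load a protein-to-term annotation map
#'
#' Reads protein-to-term associations for one namespace from either a
#' two/three-column TSV (`protein_id`, `term_id`, optional `term_name`) or,
#' for GO namespaces, a GAF 2.x file (associations whose qualifier contains
#' `NOT` are dropped; the aspect column selects the namespace; other
#' evidence codes and qualifiers are kept as-is, matching the use of flat
#' curated GO-slim annotations).
#'
#' Associations to proteins not present in the reference proteome are
#' skipped with a warning. Reference proteins with no association in the
#' namespace are collected under the `UNANNOTATED` pseudo-term, so the
#' namespace always covers the proteome.
#'
#' @param path Path to the annotation file.
#' @param namespace One of `"GO_process"`, `"GO_function"`,
#'   `"GO_component"`, `"KEGG_pathway"`.
#' @param proteome `proteome_index` of the reference proteome.
#' @return An object of class `term_map_set`: list with `namespace`,
#'   `terms` (named list: term_id -> character vector of proteins),
#'   `term_names` (named character) and `proteome` (protein identifiers).
#' @export
load_term_map <- function(path, namespace, proteome) {
  namespace <- match.arg(namespace, .namespaces)
  stopifnot(inherits(proteome, "proteome_index"))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  body <- lines[!startsWith(lines, "!")]
  if (length(body) == 0L) stop("empty annotation file: ", path)

  nfield <- length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]])
  if (nfield >= 15L) {
    if (!namespace %in% names(.gaf_aspect)) {
      stop("GAF input is only valid for GO namespaces, not ", namespace)
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 15L)
    if (length(short) > 0L) {
      stop("annotation file ", path, ": malformed GAF row ", short[1L])
    }
    m <- do.call(rbind, lapply(fields, `[`, c(2L, 4L, 5L, 9L)))
    keep <- m[, 4L] == .gaf_aspect[[namespace]] & !grepl("NOT", m[, 2L])
    ann <- data.frame(protein_id = m[keep, 1L], term_id = m[keep, 3L],
                      term_name = NA_character_, stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 2L)
    if (length(short) > 0L) {
      stop("annotation file ", path, ": row ", short[1L],
           " has fewer than 2 tab-separated columns")
    }
    ann <- data.frame(
      protein_id = vapply(fields, `[`, "", 1L),
      term_id = vapply(fields, `[`, "", 2L),
      term_name = vapply(fields, function(x)
        if (length(x) >= 3L) x[3L] else NA_character_, ""),
      stringsAsFactors = FALSE)
  }

  known <- ann$protein_id %in% proteome$protein_ids
  if (any(!known)) {
    warning("annotation file ", path, ": skipped ", sum(!known),
            " association(s) to protein(s) absent from the reference ",
            "proteome (e.g. ",
            paste(utils::head(unique(ann$protein_id[!known]), 3L),
                  collapse = ", "), ")")
    ann <- ann[known, , drop = FALSE]
  }
  if (nrow(ann) == 0L) stop("annotation file ", path,
                            ": no usable associations")

  terms <- lapply(split(ann$protein_id, ann$term_id),
                  function(p) sort(unique(p)))
  nm <- ann$term_name[!is.na(ann$term_name)]
  names(nm) <- ann$term_id[!is.na(ann$term_name)]
  term_names <- nm[!duplicated(names(nm))]

  unannotated <- setdiff(proteome$protein_ids, unique(ann$protein_id))
  terms[["UNANNOTATED"]] <- sort(unannotated)
  structure(list(namespace = namespace, terms = terms,
                 term_names = term_names,
                 proteome = proteome$protein_ids),
            class = "term_map_set")
}

#' @export
print.term_map_set <- function(x, ...) {
  cat("<term_map_set> ", x$namespace, ": ",
      sum(names(x$terms) != "UNANNOTATED"), " terms over ",
      length(x$proteome), " proteins (",
      length(x$terms[["UNANNOTATED"]]), " unannotated)\n", sep = "")
  invisible(x)
}

#' Build the ordered protein superset of a term
#'
#' The comparison vector of a term is laid over the superset of proteins
#' that could participate in the process in any organism. The superset is
#' the sorted union of the reference members of the term and an optional
#' extension with members known from other organisms but absent from the
#' reference; the extension makes the comparison two-sided, so that a
#' target whose pathway members are a superset of the reference's is not
#' mistaken for identical.
#'
#' @param proteins Character vector: reference proteins annotated to the
#'   term.
#' @param extension Optional character vector of additional member
#'   identifiers.
#' @return Sorted character vector without duplicates (lexicographic, so
#'   the order is identical across runs and platforms).
#' @export
build_superset <- function(proteins, extension = character(0)) {
  sort(unique(c(as.character(proteins), as.character(extension))))
}

#' Ordered comparison-vector specifications for every retained term
#'
#' @param map_set A `term_map_set` from [load_term_map()].
#' @param min_genes Minimum number of reference members for a term to be
#'   retained (default 1; 5 reproduces a "more than 4 genes" filter).
#' @param extensions Named list (term_id -> character vector) of superset
#'   extensions, see [build_superset()].
#' @param include_unannotated Keep the `UNANNOTATED` pseudo-term as a
#'   column (default `FALSE`: it is excluded from distance matrices).
#' @return Named list: term_id -> ordered protein superset.
#' @export
make_vector_specs <- function(map_set, min_genes = 1L,
                              extensions = list(),
                              include_unannotated = FALSE) {
  stopifnot(inherits(map_set, "term_map_set"), min_genes >= 1L)
  ids <- names(map_set$terms)
  if (!include_unannotated) ids <- setdiff(ids, "UNANNOTATED")
  ids <- ids[lengths(map_set$terms[ids]) >= min_genes]
  specs <- lapply(ids, function(t)
    build_superset(map_set$terms[[t]],
                   if (t %in% names(extensions)) extensions[[t]]
                   else character(0)))
  names(specs) <- ids
  specs[order(names(specs))]
}

#' Attach functional terms to clusters
#'
#' Each cluster inherits every (namespace, term) of its reference protein,
#' including the `UNANNOTATED` pseudo-terms.
#'
#' @param clusters A `cluster_set` from [build_clusters()].
#' @param maps A `term_map_set` or a list of them (one per namespace).
#' @return The `cluster_set` with its `terms` slot filled: a `data.frame`
#'   with columns `query_id`, `namespace`, `term_id`.
#' @export
annotate_clusters <- function(clusters, maps) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (inherits(maps, "term_map_set")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    stopifnot(inherits(m, "term_map_set"))
    tid <- rep(names(m$terms), lengths(m$terms))
    data.frame(query_id = unlist(m$terms, use.names = FALSE),
               namespace = m$namespace, term_id = tid,
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, rows)
  terms <- terms[terms$query_id %in% clusters$proteins, , drop = FALSE]
  terms <- terms[order(terms$query_id, terms$namespace, terms$term_id), ]
  rownames(terms) <- NULL
  clusters$terms <- terms
  clusters
}
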