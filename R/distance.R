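#' Organism-by-cluster presence matrix
#'
#' Binary matrix with one row per organism (the reference first, all 1s by
#' definition) and one column per reference protein; an entry is 1 when
#' the organism contributes a sequence to that protein's cluster.
#'
#' @param clusters A `cluster_set` from [build_clusters()].
#' @param mode `"ortholog"` counts only `ORTHOLOG_FOUND` cells as present;
#'   `"homolog-or-ortholog"` also counts `HOMOLOG_ONLY`.
#' @return Integer 0/1 matrix, `(n_organisms + 1) x n_proteins`, with the
#'   reference organism as the first row.
#' @export
presence_matrix <- function(clusters,
                            mode = c("ortholog", "homolog-or-ortholog")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clusters, "cluster_set"))
  s <- status_matrix(clusters)  # proteins x organisms
  present <- if (mode == "ortholog") s == "O" else s != "A"
  m <- t(present) * 1L
  rbind(matrix(1L, 1L, ncol(m),
               dimnames = list(clusters$reference_id, colnames(m))),
        m)
}

#' Hamming distance between two presence vectors
#'
#' Number of positions at which the two equal-length binary vectors
#' disagree; symmetric, zero on identical vectors.
#'
#' @param v,w Equal-length vectors (0/1 or logical).
#' @return Non-negative integer count.
#' @export
hamming <- function(v, w) {
  if (length(v) != length(w)) {
    stop("hamming: vector lengths differ (", length(v), " vs ",
         length(w), ")")
  }
  sum(v != w)
}

#' Per-term Normalized Hamming Distance table
#'
#' For every retained term, lays the reference's annotated members and each
#' organism's presence bits over the term's ordered protein superset and
#' computes the Hamming distance to the reference vector. Distances are
#' normalized per term by the maximum distance observed across all
#' organisms (`NHD = HD / max HD`), so 0 means an identical protein set
#' and 1 the most different set seen for that term. Terms on which every
#' organism ties the reference are flagged degenerate and get NHD 0 rather
#' than being dropped, keeping matrices aligned across namespaces.
#'
#' Rows are ordered by growing overall NHD (mean across terms), the
#' reference first, ties by organism identifier.
#'
#' @param pm Presence matrix from [presence_matrix()] (reference row
#'   first).
#' @param map_set `term_map_set` of the namespace to tabulate.
#' @param min_genes,extensions Passed to [make_vector_specs()].
#' @param normalization `"per-term"` (each column scaled by its own
#'   maximum, the default) or `"global"` (one maximum for the whole
#'   table).
#' @return An object of class `distance_table`: list with `namespace`,
#'   `term_ids`, `organisms`, integer matrix `hd` and numeric matrix `nhd`
#'   (rows = reference + organisms, columns = terms), logical `degenerate`
#'   per term, `row_order` (row names sorted by growing overall NHD) and
#'   `reference_id`.
#' @export
nhd_table <- function(pm, map_set, min_genes = 1L, extensions = list(),
                      normalization = c("per-term", "global")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(map_set, "term_map_set"), is.matrix(pm))
  specs <- make_vector_specs(map_set, min_genes = min_genes,
                             extensions = extensions)
  if (length(specs) == 0L) stop("no terms retained at min_genes = ",
                                min_genes)
  reference_id <- rownames(pm)[1L]
  organisms <- rownames(pm)[-1L]

  hd <- matrix(0L, nrow = nrow(pm), ncol = length(specs),
               dimnames = list(rownames(pm), names(specs)))
  for (t in names(specs)) {
    sp <- specs[[t]]
    ref_bits <- as.integer(sp %in% map_set$terms[[t]])
    idx <- match(sp, colnames(pm))
    bits <- matrix(0L, nrow = length(organisms), ncol = length(sp))
    known <- !is.na(idx)
    if (any(known)) {
      bits[, known] <- pm[-1L, idx[known], drop = FALSE]
    }
    hd[-1L, t] <- as.integer(rowSums(bits !=
      matrix(ref_bits, nrow = length(organisms), ncol = length(sp),
             byrow = TRUE)))
  }

  if (normalization == "per-term") {
    denom <- apply(hd, 2L, max)
  } else {
    denom <- rep(max(hd), ncol(hd))
  }
  degenerate <- denom == 0L
  nhd <- sweep(hd, 2L, pmax(denom, 1L), "/")
  nhd[, degenerate] <- 0

  overall <- rowMeans(nhd)
  ord <- rownames(pm)[order(overall, rownames(pm))]
  ord <- c(reference_id, setdiff(ord, reference_id))

  structure(list(namespace = map_set$namespace,
                 term_ids = names(specs),
                 organisms = organisms,
                 hd = hd, nhd = nhd,
                 degenerate = stats::setNames(degenerate, names(specs)),
                 row_order = ord,
                 normalization = normalization,
                 reference_id = reference_id),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("<distance_table> ", x$namespace, ": ", length(x$organisms),
      " organisms x ", length(x$term_ids), " terms (",
      sum(x$degenerate), " degenerate)\n", sep = "")
  cat("  closest organisms:",
      paste(utils::head(setdiff(x$row_order, x$reference_id), 3L),
            collapse = ", "), "\n")
  invisible(x)
}

#' Mean NHD per organism ("overall NHD")
#'
#' @param dt A `distance_table`.
#' @return Named numeric vector, mean NHD across terms per organism
#'   (reference included, always 0), in `row_order`.
#' @export
overall_nhd <- function(dt) {
  stopifnot(inherits(dt, "distance_table"))
  rowMeans(dt$nhd)[dt$row_order]
}

#' Write a distance table as TSV plus JSON sidecar
#'
#' The TSV has term identifiers as header, organism identifiers as row
#' labels, rows in `row_order`; the sidecar records the row order,
#' degenerate term flags and normalization mode.
#'
#' @param dt A `distance_table`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param what `"nhd"` (default) or `"hd"`.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(dt, path, what = c("nhd", "hd")) {
  what <- match.arg(what)
  m <- dt[[what]][dt$row_order, , drop = FALSE]
  df <- data.frame(organism = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(namespace = dt$namespace, value = what,
         reference = dt$reference_id, row_order = dt$row_order,
         degenerate_terms = dt$term_ids[dt$degenerate],
         normalization = dt$normalization),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Heat map of a distance table
#'
#' Draws the per-term NHD matrix with rows in growing-overall-NHD order,
#' green for low distance through red for complete absence of the term's
#' protein set (NHD 1).
#'
#' @param dt A `distance_table`.
#' @param file Optional output image path (`.png` or `.svg`); when `NULL`
#'   the plot is drawn on the current device.
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_nhd_heatmap <- function(dt, file = NULL, ...) {
  stopifnot(inherits(dt, "distance_table"))
  m <- dt$nhd[dt$row_order, , drop = FALSE]
  pal <- grDevices::colorRampPalette(
    c("#1a9641", "#a6d96a", "#ffffbf", "#fdae61", "#d7191c"))(100)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    if (ext == "svg") grDevices::svg(file, width = 10, height = 7)
    else grDevices::png(file, width = 1400, height = 1000, res = 120)
    on.exit(grDevices::dev.off())
  }
  p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                          color = pal, breaks = seq(0, 1, length.out = 101),
                          main = paste0(dt$namespace,
                                        " NHD to ", dt$reference_id),
                          ...)
  invisible(p)
}

#' Per-clade conservation summary
#'
#' Rolls the per-organism calls up to clades (domain, kingdom or phylum):
#' for each clade it counts reference proteins with an ortholog in at
#' least one member, with an ortholog in every member, with at least a
#' homolog in every member while lacking an ortholog in some member, and
#' absent from every member.
#'
#' @param clusters A `cluster_set`.
#' @param organisms_meta `data.frame` with column `organism_id` plus one
#'   column per clade level; every organism of the run must be labeled at
#'   the requested level.
#' @param level Name of the clade column to roll up by (e.g. `"domain"`,
#'   `"kingdom"`, `"phylum"`).
#' @return `data.frame` with one row per clade: `clade`, `n_organisms`,
#'   counts `ortholog_in_any`, `ortholog_in_all`, `homolog_in_all`,
#'   `absent_in_all` and the corresponding fractions of the reference
#'   proteome (`frac_*`).
#' @export
clade_summary <- function(clusters, organisms_meta, level) {
  stopifnot(inherits(clusters, "cluster_set"),
            is.data.frame(organisms_meta),
            "organism_id" %in% names(organisms_meta),
            level %in% names(organisms_meta))
  lab <- organisms_meta[[level]][match(clusters$organisms,
                                       organisms_meta$organism_id)]
  bad <- clusters$organisms[is.na(lab) | !nzchar(as.character(lab))]
  if (length(bad) > 0L) {
    stop("organism(s) without a '", level, "' label: ",
         paste(bad, collapse = ", "))
  }
  s <- status_matrix(clusters)  # proteins x organisms
  n_prot <- nrow(s)
  res <- lapply(split(clusters$organisms, as.character(lab)), function(mem) {
    sm <- s[, mem, drop = FALSE]
    orth_any <- rowSums(sm == "O") > 0L
    orth_all <- rowSums(sm == "O") == length(mem)
    nonabs_all <- rowSums(sm != "A") == length(mem)
    abs_all <- rowSums(sm == "A") == length(mem)
    c(n_organisms = length(mem),
      ortholog_in_any = sum(orth_any),
      ortholog_in_all = sum(orth_all),
      homolog_in_all = sum(nonabs_all & !orth_all),
      absent_in_all = sum(abs_all))
  })
  out <- data.frame(clade = names(res),
                    do.call(rbind, res),
                    stringsAsFactors = FALSE)
  for (col in c("ortholog_in_any", "ortholog_in_all",
                "homolog_in_all", "absent_in_all")) {
    out[[paste0("frac_", col)]] <- out[[col]] / n_prot
  }
  rownames(out) <- NULL
  out
}
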