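#' Default alignment-statistic regimes for the simulator
#'
#' Parameter boxes from which simulated hit statistics are drawn, placed
#' strictly inside the classification regions so that no sampled hit lands
#' on a threshold boundary:
#'
#' * `ortholog`: e-value exponent in \[-180, -40\] (so e <= 1e-40, below
#'   the 1e-36 cutoff), identity in \[40, 70\] percent, query span in
#'   \[0.90, 0.99\], 0-3 gaps per row.
#' * `homolog`: e-value exponent in \[-30, -12\] (inside the collection
#'   window), identity in \[15, 25\] percent, spans of both sequences in
#'   \[0.40, 0.80\], 0-3 gaps per row.
#'
#' The ortholog box is internally split into a `primary` band (high
#' identity/coverage) and an `inparalog` band whose composite F score is
#' strictly lower than any primary draw, so the intended ortholog always
#' outranks its in-paralogs.
#'
#' @return Nested named list of ranges.
#' @export
default_regimes <- function() {
  list(
    ortholog = list(
      evalue_exp = c(-180, -40),
      identity = c(40, 70),
      similarity_gap = c(0, 10),   # similarity = identity + this
      span = c(0.90, 0.99),
      gaps = c(0L, 3L),
      primary = list(evalue_exp = c(-180, -120), identity = c(60, 70),
                     span = c(0.95, 0.99), gaps = c(0L, 1L)),
      inparalog = list(evalue_exp = c(-100, -40), identity = c(40, 50),
                       span = c(0.90, 0.93), gaps = c(2L, 3L))
    ),
    homolog = list(
      evalue_exp = c(-30, -12),
      identity = c(15, 25),
      similarity_gap = c(5, 15),
      span = c(0.40, 0.75),
      gaps = c(0L, 3L)
    )
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic fixture
#' generator. Defaults describe the standard study conditions used by the
#' package's own calibration experiments: 20 pathways of 25 genes each
#' (a 500-protein reference proteome) compared against 20 organisms laid
#' out on an ortholog-retention gradient of 0.9, 0.7, 0.5 and 0.3 (five
#' replicate organisms per level), each non-retained protein surviving as
#' a homolog with probability 0.5.
#'
#' @param n_pathways Number of pathways (default 20).
#' @param genes_per_pathway Genes per pathway (default 25).
#' @param organisms Optional `data.frame` with columns `organism_id`,
#'   `retention`, `homolog_decay`, `domain`, `kingdom`, `phylum`. When
#'   `NULL` the default retention-gradient panel is built.
#' @param retention_levels Retention gradient used for the default panel.
#' @param replicates Organisms per retention level in the default panel.
#' @param homolog_decay Probability that a non-retained protein is still
#'   detectable as a homolog (default 0.5).
#' @param kegg_unannotated_frac Fraction of reference proteins left
#'   without a KEGG pathway annotation, emulating proteomes where most
#'   proteins map to no curated pathway (default 0.1).
#' @param seed Integer seed; fully determines every simulator output.
#' @param regimes Statistic regimes, see [default_regimes()].
#' @param thresholds Classification thresholds the regimes must respect,
#'   see [classification_thresholds()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pathways = 20L, genes_per_pathway = 25L,
                       organisms = NULL,
                       retention_levels = c(0.9, 0.7, 0.5, 0.3),
                       replicates = 5L,
                       homolog_decay = 0.5,
                       kegg_unannotated_frac = 0.1,
                       seed = 1L,
                       regimes = default_regimes(),
                       thresholds = classification_thresholds()) {
  stopifnot(n_pathways >= 1L, genes_per_pathway >= 1L,
            homolog_decay >= 0, homolog_decay <= 1,
            kegg_unannotated_frac >= 0, kegg_unannotated_frac < 1)
  if (is.null(organisms)) {
    n_org <- length(retention_levels) * replicates
    organisms <- data.frame(
      organism_id = sprintf("org%02d", seq_len(n_org)),
      retention = rep(retention_levels, each = replicates),
      homolog_decay = homolog_decay,
      domain = rep(c("DomainA", "DomainB"), length.out = n_org),
      kingdom = rep(sprintf("Kingdom%d", seq_len(min(4L, n_org))),
                    length.out = n_org),
      phylum = sprintf("Phylum%02d", ((seq_len(n_org) - 1L) %/% 2L) + 1L),
      stringsAsFactors = FALSE)
  }
  need <- c("organism_id", "retention", "homolog_decay",
            "domain", "kingdom", "phylum")
  miss <- setdiff(need, names(organisms))
  if (length(miss) > 0L) stop("organisms table lacks column(s): ",
                              paste(miss, collapse = ", "))
  stopifnot(!anyDuplicated(organisms$organism_id),
            all(organisms$retention >= 0), all(organisms$retention <= 1),
            all(organisms$homolog_decay >= 0),
            all(organisms$homolog_decay <= 1))
  cfg <- structure(list(n_pathways = as.integer(n_pathways),
                        genes_per_pathway = as.integer(genes_per_pathway),
                        organisms = organisms,
                        kegg_unannotated_frac = kegg_unannotated_frac,
                        seed = as.integer(seed),
                        regimes = regimes,
                        thresholds = thresholds),
                   class = "sim_config")
  rc <- regime_check(cfg)
  if (!all(rc$uniform)) {
    stop("regime(s) not uniformly classified (overlap a threshold ",
         "boundary): ",
         paste(rc$regime[!rc$uniform], collapse = ", "))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_pathways, " pathways x ", x$genes_per_pathway,
      " genes = ", x$n_pathways * x$genes_per_pathway, " proteins; ",
      nrow(x$organisms), " organisms; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Build one syntactically valid hit from sampled statistics.
.hit_from_stats <- function(query_id, target_id, organism_id, evalue,
                            identity, similarity, span_q, g1, g2, L1,
                            span_t = NULL) {
  aq <- max(1L, as.integer(round(span_q * L1)))
  aq <- min(aq, L1)
  aln <- aq + g1
  at <- aln - g2
  if (at < 1L) { g2 <- aln - 1L; at <- 1L }
  if (is.null(span_t)) {
    L2 <- at + sample.int(max(1L, round(0.08 * at)), 1L)
  } else {
    L2 <- max(at, as.integer(ceiling(at / span_t)))
  }
  q_start <- sample.int(L1 - aq + 1L, 1L)
  t_start <- sample.int(L2 - at + 1L, 1L)
  data.frame(query_id = query_id, target_id = target_id,
             organism_id = organism_id, evalue = evalue,
             identity_pct = identity, similarity_pct = similarity,
             aln_len = aln, query_len = L1, target_len = L2,
             query_gaps = g1, target_gaps = g2,
             q_start = q_start, q_end = q_start + aq - 1L,
             t_start = t_start, t_end = t_start + at - 1L,
             stringsAsFactors = FALSE)
}

.runifr <- function(n, r) stats::runif(n, r[1L], r[2L])
.sampr <- function(r) if (r[1L] == r[2L]) r[1L] else
  sample(seq.int(r[1L], r[2L]), 1L)

#' Verify that the simulator regimes classify uniformly
#'
#' Evaluates [pair_class()] on every corner and the center of each
#' regime's parameter box (e-value exponent x identity x span, with
#' minimal and maximal gap counts) and reports whether all points land in
#' the intended class. A regime straddling a classification boundary is
#' flagged non-uniform.
#'
#' @param config A `sim_config` (or the arguments to build one; regimes
#'   and thresholds are taken from it).
#' @return `data.frame` with one row per regime: `regime`, `intended`,
#'   `n_points`, `uniform`, `observed` (comma-joined classes seen).
#' @export
regime_check <- function(config) {
  regimes <- config$regimes
  thresholds <- config$thresholds
  check_one <- function(box, intended, span_t_box = NULL) {
    grid <- expand.grid(e = box$evalue_exp, i = box$identity,
                        s = box$span, g = range(box$gaps),
                        KEEP.OUT.ATTRS = FALSE)
    grid <- rbind(grid, data.frame(e = mean(box$evalue_exp),
                                   i = mean(box$identity),
                                   s = mean(box$span),
                                   g = round(mean(range(box$gaps)))))
    sim_gap <- if (!is.null(box$similarity_gap)) box$similarity_gap else
      c(0, 10)
    cls <- vapply(seq_len(nrow(grid)), function(k) {
      h <- .hit_from_stats("q", "t", "o",
                           evalue = 10^grid$e[k],
                           identity = grid$i[k],
                           similarity = min(100, grid$i[k] + max(sim_gap)),
                           span_q = grid$s[k],
                           g1 = as.integer(grid$g[k]),
                           g2 = as.integer(grid$g[k]),
                           L1 = 400L,
                           span_t = if (is.null(span_t_box)) NULL else
                             mean(span_t_box))
      pair_class(h, thresholds)
    }, "")
    data.frame(regime = NA_character_, intended = intended,
               n_points = length(cls),
               uniform = all(cls == intended),
               observed = paste(sort(unique(cls)), collapse = ","),
               stringsAsFactors = FALSE)
  }
  rows <- list(
    ortholog = check_one(regimes$ortholog, "ORTHOLOG_CANDIDATE"),
    ortholog_primary = check_one(utils::modifyList(
      regimes$ortholog, regimes$ortholog$primary), "ORTHOLOG_CANDIDATE"),
    ortholog_inparalog = check_one(utils::modifyList(
      regimes$ortholog, regimes$ortholog$inparalog), "ORTHOLOG_CANDIDATE"),
    homolog = check_one(regimes$homolog, "HOMOLOG",
                        span_t_box = regimes$homolog$span)
  )
  out <- do.call(rbind, rows)
  out$regime <- names(rows)
  rownames(out) <- NULL
  out[, c("regime", "intended", "n_points", "uniform", "observed")]
}

#' Generate a complete synthetic fixture bundle
#'
#' Emits every input the pipeline consumes — reference proteome FASTA,
#' GO-slim and KEGG annotation TSVs, one alignment-hit table per organism,
#' organism metadata — together with the generating ground truth. For each
#' (reference protein, organism) the true status is drawn independently:
#' ortholog with the organism's retention probability, otherwise homolog
#' with probability `homolog_decay`, otherwise absent. Non-absent pairs
#' receive 1-3 HSP rows with statistics from the matching regime (extra
#' HSPs are strictly worse, exercising HSP collapsing), and ortholog pairs
#' additionally receive 0-2 in-paralog candidates whose composite F score
#' is strictly below the intended ortholog's. Identical seed and
#' configuration give byte-identical output files.
#'
#' Sequence content is random filler (uniform residues, lengths 100-1000):
#' classification consumes alignment statistics only, so no actual
#' alignment is performed.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named: `fasta`, `kegg`,
#'   `go_process`, `go_function`, `go_component`, `organisms`,
#'   `ground_truth`, `hits_dir`, and per-organism hit tables under
#'   `hits`), `truth` (`data.frame`: `query_id`, `organism_id`, `status`,
#'   `ortholog_id`), `pathway_truth` (`data.frame`: `organism_id`,
#'   `pathway`, `n_genes`, `retained_frac`) and `config`.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hits_dir <- file.path(dir, "hits")
  dir.create(hits_dir, showWarnings = FALSE)
  set.seed(config$seed)

  n_prot <- config$n_pathways * config$genes_per_pathway
  proteins <- sprintf("SC%04d", seq_len(n_prot))
  lengths <- sample(100:1000, n_prot, replace = TRUE)
  pathway <- rep(sprintf("path%03d", seq_len(config$n_pathways)),
                 each = config$genes_per_pathway)

  # reference proteome FASTA (random residue filler)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  fasta <- file.path(dir, "reference.fasta")
  con <- file(fasta, "wt")
  for (i in seq_len(n_prot)) {
    writeLines(c(paste0(">", proteins[i]),
                 paste(sample(aa, lengths[i], replace = TRUE),
                       collapse = "")), con)
  }
  close(con)

  # annotations: KEGG pathways (a fraction unannotated), GO-slim process
  # terms grouping pathways 4-by-4, and random function/component slices
  n_unann <- round(config$kegg_unannotated_frac * n_prot)
  unann <- if (n_unann > 0L) sort(sample(proteins, n_unann)) else character(0)
  kegg <- data.frame(protein = proteins, term = pathway,
                     stringsAsFactors = FALSE)
  kegg <- kegg[!kegg$protein %in% unann, ]
  go_proc <- data.frame(
    protein = proteins,
    term = sprintf("GO_P%02d", (match(pathway,
      sort(unique(pathway))) - 1L) %/% 4L + 1L),
    stringsAsFactors = FALSE)
  go_fun <- data.frame(
    protein = proteins,
    term = sprintf("GO_F%02d", sample.int(8L, n_prot, replace = TRUE)),
    stringsAsFactors = FALSE)
  go_comp <- data.frame(
    protein = proteins,
    term = sprintf("GO_C%02d", sample.int(6L, n_prot, replace = TRUE)),
    stringsAsFactors = FALSE)
  ann_paths <- c(kegg = file.path(dir, "kegg.tsv"),
                 go_process = file.path(dir, "go_process.tsv"),
                 go_function = file.path(dir, "go_function.tsv"),
                 go_component = file.path(dir, "go_component.tsv"))
  for (nm in names(ann_paths)) {
    tab <- switch(nm, kegg = kegg, go_process = go_proc,
                  go_function = go_fun, go_component = go_comp)
    utils::write.table(tab, ann_paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }

  meta_path <- file.path(dir, "organisms.tsv")
  utils::write.table(
    config$organisms[, c("organism_id", "domain", "kingdom", "phylum")],
    meta_path, sep = "\t", quote = FALSE, row.names = FALSE)

  reg <- config$regimes
  truth_list <- vector("list", nrow(config$organisms))
  hit_paths <- character(nrow(config$organisms))
  for (k in seq_len(nrow(config$organisms))) {
    org <- config$organisms$organism_id[k]
    r <- config$organisms$retention[k]
    decay <- config$organisms$homolog_decay[k]
    u1 <- stats::runif(n_prot); u2 <- stats::runif(n_prot)
    status <- ifelse(u1 < r, "ORTHOLOG_FOUND",
                     ifelse(u2 < decay, "HOMOLOG_ONLY", "ABSENT"))
    ortholog_id <- ifelse(status == "ORTHOLOG_FOUND",
                          paste0(org, "_", proteins, "_t1"), NA_character_)
    rows <- list()
    for (i in which(status != "ABSENT")) {
      p <- proteins[i]; L1 <- lengths[i]
      if (status[i] == "ORTHOLOG_FOUND") {
        pb <- reg$ortholog$primary
        sim_gap <- .runifr(1L, reg$ortholog$similarity_gap)
        idy <- .runifr(1L, pb$identity)
        prim_e <- .runifr(1L, pb$evalue_exp)
        prim <- .hit_from_stats(p, ortholog_id[i], org,
                                evalue = 10^prim_e,
                                identity = idy,
                                similarity = min(100, idy + sim_gap),
                                span_q = .runifr(1L, pb$span),
                                g1 = .sampr(pb$gaps), g2 = .sampr(pb$gaps),
                                L1 = L1)
        rows[[length(rows) + 1L]] <- prim
        # extra HSPs of the same pair: strictly worse e-value, shorter
        for (j in seq_len(sample.int(3L, 1L) - 1L)) {
          e2 <- min(prim_e + stats::runif(1L, 5, 20),
                    reg$ortholog$evalue_exp[2L])
          rows[[length(rows) + 1L]] <- .hit_from_stats(
            p, ortholog_id[i], org, evalue = 10^e2,
            identity = idy, similarity = min(100, idy + sim_gap),
            span_q = max(0.90, .runifr(1L, pb$span) - 0.04),
            g1 = .sampr(pb$gaps), g2 = .sampr(pb$gaps), L1 = L1)
        }
        # in-paralog candidates with strictly lower F
        ib <- reg$ortholog$inparalog
        for (j in seq_len(sample.int(3L, 1L) - 1L)) {
          idy2 <- .runifr(1L, ib$identity)
          rows[[length(rows) + 1L]] <- .hit_from_stats(
            p, paste0(org, "_", p, "_ip", j), org,
            evalue = 10^.runifr(1L, ib$evalue_exp),
            identity = idy2,
            similarity = min(100, idy2 + .runifr(1L,
              reg$ortholog$similarity_gap)),
            span_q = .runifr(1L, ib$span),
            g1 = .sampr(ib$gaps), g2 = .sampr(ib$gaps), L1 = L1)
        }
      } else {
        hb <- reg$homolog
        idy <- .runifr(1L, hb$identity)
        sim_gap <- .runifr(1L, hb$similarity_gap)
        he <- .runifr(1L, hb$evalue_exp)
        n_hsp <- sample.int(3L, 1L)
        for (j in seq_len(n_hsp)) {
          ej <- if (j == 1L) he else
            min(he + stats::runif(1L, 1, 5), hb$evalue_exp[2L])
          rows[[length(rows) + 1L]] <- .hit_from_stats(
            p, paste0(org, "_", p, "_h1"), org, evalue = 10^ej,
            identity = idy, similarity = min(100, idy + sim_gap),
            span_q = .runifr(1L, hb$span),
            g1 = .sampr(hb$gaps), g2 = .sampr(hb$gaps), L1 = L1,
            span_t = .runifr(1L, hb$span))
        }
      }
    }
    hits <- if (length(rows) > 0L) do.call(rbind, rows) else .empty_hits()
    hit_paths[k] <- file.path(hits_dir, paste0(org, ".tsv"))
    write_hit_table(hits, hit_paths[k])
    truth_list[[k]] <- data.frame(query_id = proteins, organism_id = org,
                                  status = status,
                                  ortholog_id = ortholog_id,
                                  pathway = pathway,
                                  stringsAsFactors = FALSE)
  }
  names(hit_paths) <- config$organisms$organism_id
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  agg <- stats::aggregate(status ~ organism_id + pathway, data = truth,
                          FUN = function(s)
                            mean(s == "ORTHOLOG_FOUND"))
  names(agg)[3L] <- "retained_frac"
  agg$n_genes <- config$genes_per_pathway
  pathway_truth <- agg[order(agg$organism_id, agg$pathway),
                       c("organism_id", "pathway", "n_genes",
                         "retained_frac")]
  rownames(pathway_truth) <- NULL

  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    paths = list(fasta = fasta, kegg = ann_paths[["kegg"]],
                 go_process = ann_paths[["go_process"]],
                 go_function = ann_paths[["go_function"]],
                 go_component = ann_paths[["go_component"]],
                 organisms = meta_path, ground_truth = truth_path,
                 hits_dir = hits_dir, hits = hit_paths),
    truth = truth, pathway_truth = pathway_truth, config = config))
}
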