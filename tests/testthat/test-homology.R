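test_that("threshold rules classify the documented regimes", {
  # strong alignment with high identity and coverage -> ortholog candidate
  expect_identical(
    pair_class(make_hit(evalue = 1e-40, identity = 35, span_q = 0.90)),
    "ORTHOLOG_CANDIDATE")
  # collected pair with low identity in the homolog e-value window
  expect_identical(
    pair_class(make_hit(evalue = 1e-20, identity = 25, span_q = 0.90)),
    "HOMOLOG")
  # above the collection cutoff: never considered
  expect_identical(pair_class(make_hit(evalue = 1e-5)), "NONE")
  # rule gap (identity high, span low on both sequences) resolves to homolog
  gap <- make_hit(evalue = 1e-20, identity = 45, span_q = 0.60,
                  query_len = 100L, target_len = 100L)
  expect_lt((gap$t_end - gap$t_start + 1) / gap$target_len, 0.85)
  expect_identical(pair_class(gap), "HOMOLOG")
})

test_that("boundary values fall on the non-ortholog side", {
  # e-value exactly 1e-36, identity exactly 30: neither strict condition met
  expect_identical(
    pair_class(make_hit(evalue = 1e-36, identity = 30, span_q = 0.95)),
    "HOMOLOG")
  # span exactly 0.85 on both sequences
  b <- make_hit(evalue = 1e-50, identity = 60, span_q = 0.85,
                query_len = 100L, target_len = 100L)
  expect_identical((b$q_end - b$q_start + 1) / b$query_len, 0.85)
  expect_identical(pair_class(b), "HOMOLOG")
  # collection cutoff itself is inclusive
  expect_identical(
    pair_class(make_hit(evalue = 1e-10, identity = 20, span_q = 0.5,
                        target_len = 300L)),
    "HOMOLOG")
  # target-side span alone qualifies
  t_span <- make_hit(evalue = 1e-50, identity = 60, span_q = 0.5,
                     query_len = 200L, target_len = 100L)
  expect_identical(pair_class(t_span), "ORTHOLOG_CANDIDATE")
})

test_that("pair_class agrees with the brute-force oracle on random hits", {
  set.seed(101)
  h <- random_hits(10000)
  got <- pair_class(h)
  want <- vapply(seq_len(nrow(h)), function(i)
    pair_class_oracle(h[i, ]), "")
  expect_identical(got, want)
})

test_that("fscore matches hand-evaluated components", {
  # S=80, I=60, aligned query 90 of 100, G1=2 (L1=100), G2=3 (L2=120)
  h <- make_hit(identity = 60, similarity = 80, query_len = 100L,
                span_q = 0.90, q_gaps = 2L, t_gaps = 3L, target_len = 120L)
  fs <- fscore(h)
  expect_equal(fs$f1, 0.70)
  expect_equal(fs$f2, 0.90)
  expect_equal(fs$f3, 0.045)
  expect_equal(fs$f, 1.555)
})

test_that("fscore attains its analytic extremes", {
  # perfect match: full-length gapless alignment of identical sequences
  perfect <- make_hit(identity = 100, similarity = 100, query_len = 150L,
                      span_q = 1, q_gaps = 0L, t_gaps = 0L,
                      target_len = 150L)
  expect_identical(fscore(perfect)$f, 2)
  # degenerate floor of the default forms
  floor_hit <- make_hit(identity = 0, similarity = 0, span_q = 1 / 300,
                        query_len = 300L, q_gaps = 0L, t_gaps = 0L)
  fs <- fscore(floor_hit)
  expect_equal(fs$f, fs$f2)  # only the residual coverage term remains
  expect_error(fscore(transform(perfect, query_len = 0L)), "zero-length")
})

test_that("fscore bounds and monotonicity hold over random sweeps", {
  set.seed(202)
  h <- random_hits(5000)
  fs <- fscore(h)
  expect_true(all(fs$f1 >= 0 & fs$f1 <= 1))
  expect_true(all(fs$f2 >= 0 & fs$f2 <= 1))
  expect_true(all(fs$f3 >= 0))
  expect_true(all(fs$f <= 2))
  # increasing identity never decreases f
  h2 <- h
  h2$identity_pct <- pmin(h$identity_pct + 10, h$similarity_pct)
  expect_true(all(fscore(h2)$f >= fs$f))
  # increasing query gaps (at fixed coordinates) never increases f
  h3 <- h
  h3$query_gaps <- h$query_gaps + 5L
  h3$aln_len <- h$aln_len + 5L
  expect_true(all(fscore(h3)$f <= fs$f))
})

test_that("select_ortholog picks the top F score with deterministic ties", {
  cands <- rbind(
    make_hit(target_id = "x1", identity = 90, similarity = 95,
             span_q = 0.95),
    make_hit(target_id = "x2", identity = 40, similarity = 60,
             span_q = 0.90))
  sel <- select_ortholog(cands)
  expect_identical(sel$ortholog_id, "x1")
  expect_identical(sel$inparalog_ids, "x2")

  single <- select_ortholog(make_hit(target_id = "only"))
  expect_identical(single$ortholog_id, "only")
  expect_length(single$inparalog_ids, 0L)

  # exact F tie: smaller e-value wins
  tie <- rbind(make_hit(target_id = "a", evalue = 1e-50),
               make_hit(target_id = "b", evalue = 1e-60))
  sel2 <- select_ortholog(tie)
  expect_identical(sel2$ortholog_id, "b")
  expect_error(select_ortholog(make_hit()[0, ]), "empty")
})

test_that("build_clusters assigns one explicit status per protein-organism", {
  ref <- tiny_reference(n = 3L)
  hits <- list(
    orgA = make_hit("p1", "a1", evalue = 1e-60, identity = 60,
                    span_q = 0.95),
    orgB = make_hit("p1", "b1", evalue = 1e-20, identity = 20,
                    span_q = 0.95, query_len = 200L),
    orgC = make_hit()[0, ])
  hits$orgA$query_len <- 200L
  cl <- build_clusters(hits, ref, c("orgA", "orgB", "orgC"))
  calls <- cl$calls
  st <- function(p, o)
    calls$status[calls$query_id == p & calls$organism_id == o]
  expect_identical(st("p1", "orgA"), "ORTHOLOG_FOUND")
  expect_identical(st("p1", "orgB"), "HOMOLOG_ONLY")
  expect_identical(st("p1", "orgC"), "ABSENT")
  # proteins with no hits anywhere are explicitly absent everywhere
  expect_true(all(calls$status[calls$query_id %in% c("p2", "p3")] ==
                  "ABSENT"))
  expect_identical(nrow(calls), 9L)
})

test_that("multiple candidates become one ortholog plus in-paralogs", {
  ref <- tiny_reference(n = 1L)
  hits <- rbind(
    make_hit("p1", "best", evalue = 1e-80, identity = 80, similarity = 90,
             span_q = 0.98, query_len = 200L),
    make_hit("p1", "ip1", evalue = 1e-50, identity = 50, similarity = 60,
             span_q = 0.90, query_len = 200L),
    make_hit("p1", "ip2", evalue = 1e-45, identity = 45, similarity = 55,
             span_q = 0.90, query_len = 200L),
    make_hit("p1", "hom", evalue = 1e-20, identity = 20, similarity = 30,
             span_q = 0.50, query_len = 200L, target_len = 500L))
  cl <- build_clusters(hits, ref, "orgA")
  call <- cl$calls[1L, ]
  expect_identical(call$status, "ORTHOLOG_FOUND")
  expect_identical(call$ortholog_id, "best")
  expect_setequal(call$inparalog_ids[[1L]], c("ip1", "ip2"))
  expect_identical(call$homolog_ids[[1L]], "hom")
  # the three id collections are pairwise disjoint
  expect_length(intersect(call$ortholog_id,
                          c(call$inparalog_ids[[1L]],
                            call$homolog_ids[[1L]])), 0L)
})

test_that("statuses partition the protein-organism grid", {
  b <- small_bundle()
  ref <- read_fasta_index(b$paths$fasta)
  hl <- lapply(names(b$paths$hits), function(o)
    collapse_hsps(read_hit_table(b$paths$hits[[o]], o, ref)))
  names(hl) <- names(b$paths$hits)
  cl <- build_clusters(hl, ref, names(hl))
  tab <- table(cl$calls$status)
  expect_identical(sum(tab), length(cl$proteins) * length(cl$organisms))
  expect_true(all(cl$calls$status %in%
                  c("ORTHOLOG_FOUND", "HOMOLOG_ONLY", "ABSENT")))
  # status implies the id fields
  orth <- cl$calls$status == "ORTHOLOG_FOUND"
  expect_true(all(!is.na(cl$calls$ortholog_id[orth])))
  expect_true(all(is.na(cl$calls$ortholog_id[!orth])))
  abs_rows <- cl$calls$status == "ABSENT"
  expect_true(all(lengths(cl$calls$inparalog_ids[abs_rows]) == 0L))
  expect_true(all(lengths(cl$calls$homolog_ids[abs_rows]) == 0L))
})

test_that("organisms outside the declared list are rejected", {
  ref <- tiny_reference(n = 1L)
  h <- make_hit("p1", organism_id = "mystery", query_len = 200L)
  expect_error(build_clusters(h, ref, c("orgA")), "mystery")
})
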