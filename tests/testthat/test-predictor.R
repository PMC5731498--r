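test_that("interface probability is the retrieved interface fraction", {
  kb <- kb_with_distances(c(0, 0, 0, 2), interface = c(TRUE, TRUE, TRUE, TRUE))
  # a 2-node toy graph whose center has aa 'A' (key "1")
  ann <- toy_annotations(rbind(c(0, 0, 0), c(4, 0, 0)), aa = c("A", "A"))
  g <- build_graph(ann)
  params <- kb_params(kb, n = 3)
  p <- suppressWarnings(predict_residue(g, 1, kb, params))
  expect_equal(p$prob, 1.0)
  expect_true(p$call)

  kb2 <- kb_with_distances(c(0, 0, 0, 0), interface = c(TRUE, TRUE, TRUE,
                                                        FALSE))
  p2 <- suppressWarnings(predict_residue(g, 1, kb2, kb_params(kb2, n = 1)))
  expect_equal(p2$prob, 0.75)
  expect_equal(p2$n_interface, 3L)
  expect_equal(p2$n_retrieved, 4L)
})

test_that("the decision threshold is strict", {
  kb <- kb_with_distances(c(0, 0), interface = c(TRUE, FALSE))
  ann <- toy_annotations(rbind(c(0, 0, 0), c(4, 0, 0)), aa = c("A", "A"))
  g <- build_graph(ann)
  p <- suppressWarnings(predict_residue(g, 1, kb, kb_params(kb, n = 2, threshold = 0.5)))
  expect_equal(p$prob, 0.5)
  expect_false(p$call)  # 0.5 > 0.5 is FALSE
  p2 <- suppressWarnings(predict_residue(g, 1, kb, kb_params(kb, n = 2, threshold = 0.5175)))
  expect_false(p2$call)
  kb3 <- kb_with_distances(c(0, 0, 0, 0, 0),
                           interface = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  p3 <- suppressWarnings(predict_residue(g, 1, kb3, kb_params(kb3, n = 5, threshold = 0.5175)))
  expect_equal(p3$prob, 0.6)
  expect_true(p3$call)
})

test_that("nothing retrievable yields an undefined, non-interface call", {
  kb <- kb_with_distances(c(0, 1), interface = c(TRUE, TRUE),
                          structure_id = c("q", "q"))
  ann <- toy_annotations(rbind(c(0, 0, 0), c(4, 0, 0)), aa = c("A", "A"),
                         structure_id = "q")
  g <- build_graph(ann)
  g$structure_id <- "q"
  p <- suppressWarnings(
    predict_residue(g, 1, kb, kb_params(kb), exclude_structure = "q")
  )
  expect_false(p$defined)
  expect_false(p$call)
  expect_true(is.na(p$prob))
})

test_that("incompatible parameter sets are refused", {
  kb <- kb_with_distances(c(0), interface = TRUE)  # header: c_4, l = 63
  bad <- ppi_params(neighborhood = "c", size = 4, config = feature_config(l = 1023))
  ann <- toy_annotations(rbind(c(0, 0, 0), c(4, 0, 0)))
  g <- build_graph(ann)
  expect_error(predict_residue(g, 1, kb, bad), "incompatible")
  bad2 <- ppi_params(neighborhood = "d", size = 4, config = feature_config(l = 63))
  expect_error(predict_residue(g, 1, kb, bad2), "incompatible")
})

corpus <- make_kb_corpus(n_complexes = 5, seed = 21, n_res = c(14, 14),
                         contact_window = 6:9, motif_span = 3:12)
kbc <- build_kb(lapply(corpus, `[[`, "structure"),
                config = feature_config(l = 255), neighborhood = "c", size = 4)

test_that("whole-structure prediction is deterministic and complete", {
  p1 <- predict_structure(corpus[[2]]$structure, kbc, exclude_self = FALSE)
  p2 <- predict_structure(corpus[[2]]$structure, kbc, exclude_self = FALSE)
  expect_equal(p1, p2)
  expect_equal(nrow(p1), 28)
  expect_true(all(p1$defined))
  expect_true(all(p1$n_interface + (p1$n_retrieved - p1$n_interface) ==
                    p1$n_retrieved))
})

test_that("self-exclusion restricts retrieval to other structures", {
  p <- predict_structure(corpus[[1]]$structure, kbc, exclude_self = TRUE)
  # the planted motif guarantees exact cross-structure matches; their
  # nearest distance must be 0 even though own records are disregarded
  expect_true(any(p$nearest_dist == 0))
  # re-run each query through the oracle with the exclusion applied
  expect_true(all(p$n_retrieved >= 1))
})

test_that("probabilities are invariant to duplicating the knowledge base", {
  kbdup <- kbc
  kbdup$records <- dplyr::bind_rows(
    kbc$records,
    dplyr::mutate(kbc$records, structure_id = paste0(structure_id, "_copy"))
  )
  p <- predict_structure(corpus[[3]]$structure, kbc, exclude_self = FALSE)
  pd <- predict_structure(corpus[[3]]$structure, kbdup, exclude_self = FALSE)
  expect_equal(pd$prob, p$prob)
})

test_that("raising the threshold never adds interface calls", {
  p <- predict_structure(corpus[[4]]$structure, kbc, exclude_self = TRUE)
  taus <- seq(0, 1, by = 0.1)
  calls <- vapply(taus, function(tau) {
    sum(!is.na(p$prob) & p$prob > tau)
  }, numeric(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("the published preset resolves to the comparison configuration", {
  pp <- ppi_params(preset = "published")
  expect_equal(pp$neighborhood, "c")
  expect_equal(pp$size, 12L)
  expect_equal(pp$n, 1L)
  expect_equal(pp$threshold, 0.5175)
  expect_equal(pp$config$l, 1023L)
  expect_equal(pp$config$fingerprint_features, "aa_type")
  expect_equal(pp$config$central_features, "aa_type")
})
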