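test_that("surface masks implement the benchmark rules", {
  r <- c(0, 0.04, 0.05, 0.3, NA)
  expect_equal(surface_mask(r, "ge_0.05"), c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(surface_mask(r, "gt_0"), c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(surface_mask(r, "none"), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(surface_mask(r, "custom", custom = function(x) x > 0.1),
               c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("confusion counts are exact and masked", {
  call <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  truth <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  cc <- confusion_counts(call, truth)
  expect_equal(as.integer(cc), c(2L, 1L, 1L, 1L))
  cc2 <- confusion_counts(call, truth, mask = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(cc2), 4L)
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)), "length mismatch")

  set.seed(3)
  for (rep in 1:5) {
    call <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    cc <- confusion_counts(call, truth)
    # independent recount
    expect_equal(cc[["tp"]], sum(mapply(function(a, b) a && b, call, truth)))
    expect_equal(cc[["tn"]], sum(mapply(function(a, b) !a && !b, call, truth)))
    expect_equal(sum(cc), 60L)
  }
})

test_that("MCC hits its landmark values and convention", {
  expect_equal(mcc(c(tp = 10, fn = 0, fp = 0, tn = 10)), 1.0)
  expect_equal(mcc(c(tp = 0, fn = 10, fp = 10, tn = 0)), -1.0)
  expect_equal(mcc(c(tp = 0, fn = 0, fp = 10, tn = 10)), 0)  # zero factor
  expect_equal(mcc(c(tp = 0, fn = 0, fp = 0, tn = 0)), 0)
  expect_equal(
    mcc(c(tp = 50, fn = 5, fp = 10, tn = 40)),
    (50 * 40 - 10 * 5) / sqrt((50 + 10) * (50 + 5) * (40 + 10) * (40 + 5))
  )
})

test_that("MCC symmetry properties hold", {
  set.seed(11)
  for (rep in 1:20) {
    c0 <- setNames(as.numeric(sample(0:30, 4, replace = TRUE)),
                   c("tp", "fn", "fp", "tn"))
    swapped <- c(tp = c0[["tn"]], fn = c0[["fp"]], fp = c0[["fn"]],
                 tn = c0[["tp"]])
    expect_equal(mcc(swapped), mcc(c0))
    complement <- c(tp = c0[["fn"]], fn = c0[["tp"]], fp = c0[["tn"]],
                    tn = c0[["fp"]])
    expect_equal(mcc(complement), -mcc(c0))
  }
})

test_that("secondary metrics match direct formula evaluation", {
  m <- ppi_metrics(c(tp = 10, fn = 0, fp = 0, tn = 10))
  expect_equal(unlist(m), c(mcc = 1, precision = 1, recall = 1,
                            accuracy = 1, f1 = 1))

  m0 <- ppi_metrics(c(tp = 0, fn = 5, fp = 0, tn = 10))
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_true("precision" %in% attr(m0, "undefined"))

  set.seed(7)
  for (rep in 1:50) {
    v <- sample(1:40, 4, replace = TRUE)
    counts <- c(tp = v[1], fn = v[2], fp = v[3], tn = v[4])
    m <- ppi_metrics(counts)
    expect_equal(m$precision, v[1] / (v[1] + v[3]))
    expect_equal(m$recall, v[1] / (v[1] + v[2]))
    expect_equal(m$accuracy, (v[1] + v[4]) / sum(v))
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    expect_equal(
      m$mcc,
      (v[1] * v[4] - v[3] * v[2]) /
        sqrt(prod(c(v[1] + v[3], v[1] + v[2], v[4] + v[3], v[4] + v[2])))
    )
  }
})

test_that("metrics are invariant to residue order and misalignment errors out", {
  pred <- tibble::tibble(
    structure_id = "s", res_id = paste0("A:", 1:10, ":"),
    rasa = runif(10, 0.1, 1), prob = runif(10),
    call = rep(c(TRUE, FALSE), 5)
  )
  truth <- tibble::tibble(
    structure_id = "s", res_id = pred$res_id,
    interface = rep(c(TRUE, FALSE), each = 5)
  )
  ev1 <- evaluate_predictions(pred, truth)
  ev2 <- evaluate_predictions(pred[sample(10), ], truth[sample(10), ])
  expect_equal(ev1$counts, ev2$counts)

  bad <- truth
  bad$res_id[1] <- "A:99:"
  expect_error(evaluate_predictions(pred, bad), "offenders")
})

test_that("threshold sweeps are monotone and consistent with fresh calls", {
  set.seed(15)
  n <- 40
  pred <- tibble::tibble(
    structure_id = "s", res_id = paste0("A:", 1:n, ":"),
    rasa = runif(n, 0.06, 1),
    prob = sample(seq(0, 1, 0.25), n, replace = TRUE),
    call = FALSE
  )
  truth <- tibble::tibble(structure_id = "s", res_id = pred$res_id,
                          interface = runif(n) < 0.3)
  sw <- sweep_thresholds(pred, truth, thresholds = seq(0, 1, 0.1),
                         surface_rule = "ge_0.05")
  expect_true(all(diff(sw$n_calls) <= 0))
  expect_equal(sw$n_calls[1], sum(pred$prob > 0))
  expect_equal(sw$n_calls[nrow(sw)], 0L)

  tau <- 0.5
  fresh <- dplyr::mutate(pred, call = !is.na(prob) & prob > tau)
  ev <- evaluate_predictions(fresh, truth, surface_rule = "ge_0.05")
  row <- sw[sw$threshold == tau, ]
  expect_equal(row$mcc, glance(ev)$mcc)
  expect_equal(row$tp, glance(ev)$tp)
})

test_that("tidy and glance expose counts and metrics", {
  pred <- tibble::tibble(
    structure_id = c("s1", "s1", "s2", "s2"),
    res_id = c("A:1:", "A:2:", "A:1:", "A:2:"),
    rasa = 1, prob = c(1, 0, 1, 0), call = c(TRUE, FALSE, TRUE, FALSE)
  )
  truth <- tibble::tibble(
    structure_id = pred$structure_id, res_id = pred$res_id,
    interface = c(TRUE, FALSE, FALSE, TRUE)
  )
  ev <- evaluate_predictions(pred, truth, per_protein = TRUE)
  td <- tidy(ev)
  expect_equal(td$count[td$quantity == "tp"], 1L)
  gl <- glance(ev)
  expect_equal(gl$n_evaluated, 4L)
  expect_equal(nrow(ev$per_protein), 2)
  expect_equal(ev$per_protein$mcc, c(1, -1))
})
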