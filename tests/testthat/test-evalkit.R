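# independent straightforward re-implementations used as oracles
oracle_regression <- function(p, y) {
  c(mae = sum(abs(p - y)) / length(y),
    mdae = stats::median(abs(p - y)),
    mape = sum(abs(p - y) / y) / length(y),
    mdape = stats::median(abs(p - y) / y),
    r2 = 1 - sum((p - y)^2) / sum((y - mean(y))^2))
}

oracle_weighted_prf <- function(truth, hat) {
  out <- c(precision = 0, recall = 0, f1 = 0)
  for (cl in unique(truth)) {
    tp <- sum(truth == cl & hat == cl)
    prec <- if (sum(hat == cl) > 0) tp / sum(hat == cl) else 0
    rec <- tp / sum(truth == cl)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    w <- sum(truth == cl) / length(truth)
    out <- out + w * c(prec, rec, f1)
  }
  out
}

pset <- function(p, y, ids = paste0("S", seq_along(y))) {
  data.frame(specimen_id = ids, camera_id = 0, frame_index = seq_along(y),
             fold = 1, pred_mass_mg = p, true_mass_mg = y,
             stringsAsFactors = FALSE)
}

cset <- function(truth, hat, ids = paste0("S", seq_along(truth))) {
  data.frame(specimen_id = ids, pred_label = hat, true_label = truth,
             stringsAsFactors = FALSE)
}

test_that("regression metrics match the worked example exactly", {
  m <- regression_metrics(pset(c(2, 4, 6), c(1, 4, 8)))
  expect_equal(unname(m$frame["mae"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(m$frame["mdae"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(m$frame["mape"]), 5 / 12, tolerance = 1e-9)
  expect_equal(unname(m$frame["mdape"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(m$frame["r2"]), 1 - 5 / (222 / 9), tolerance = 1e-9)
})

test_that("regression metrics handle perfect and mean predictors", {
  y <- c(0.5, 2, 9, 30)
  perfect <- regression_metrics(pset(y, y))$frame
  expect_equal(unname(perfect[c("mae", "mdae", "mape", "mdape")]),
               rep(0, 4))
  expect_equal(unname(perfect["r2"]), 1)
  const <- regression_metrics(pset(rep(mean(y), 4), y))$frame
  expect_equal(unname(const["r2"]), 0, tolerance = 1e-12)
  empty <- data.frame(specimen_id = character(0),
                      pred_mass_mg = numeric(0),
                      true_mass_mg = numeric(0))
  expect_error(regression_metrics(empty), "empty")
})

test_that("regression metrics agree with an independent oracle", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    y <- stats::rlnorm(n, 1, 1)
    p <- y * exp(stats::rnorm(n, 0, 0.4))
    m <- regression_metrics(pset(p, y))$frame
    o <- oracle_regression(p, y)
    expect_equal(unname(m[names(o)]), unname(o), tolerance = 1e-10)
  }
})

test_that("specimen-level metrics use per-specimen median predictions", {
  pr <- pset(c(1, 3, 10), c(2, 2, 10), ids = c("A", "A", "B"))
  m <- regression_metrics(pr)
  expect_equal(unname(m$specimen["n"]), 2)
  expect_equal(unname(m$specimen["mae"]), mean(c(0, 0)))
})

test_that("classification metrics match the hand-computed example", {
  m <- classification_metrics(cset(c("A", "A", "A", "B"),
                                   c("A", "A", "B", "B")))
  expect_equal(unname(m$weighted["precision"]), 0.875, tolerance = 1e-9)
  expect_equal(unname(m$weighted["recall"]), 0.75, tolerance = 1e-9)
  expect_equal(unname(m$weighted["f1"]), 0.7666667, tolerance = 1e-6)
})

test_that("all-correct predictions give unit metrics and 100*I confusion", {
  m <- classification_metrics(cset(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(m$weighted), c(1, 1, 1))
  expect_equal(unname(m$confusion_pct), 100 * diag(3))
})

test_that("confusion rows sum to 100 and weights follow support", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    classes <- LETTERS[1:sample(2:5, 1)]
    truth <- sample(classes, n, replace = TRUE)
    hat <- sample(classes, n, replace = TRUE)
    m <- classification_metrics(cset(truth, hat))
    expect_equal(unname(rowSums(m$confusion_pct)),
                 rep(100, nrow(m$confusion_pct)), tolerance = 1e-9)
    o <- oracle_weighted_prf(truth, hat)
    expect_equal(unname(m$weighted), unname(o), tolerance = 1e-10)
    f1s <- m$per_class$f1[m$per_class$support > 0]
    expect_gte(m$weighted["f1"], min(f1s) - 1e-12)
    expect_lte(m$weighted["f1"], max(f1s) + 1e-12)
  }
})

test_that("a never-predicted class gets precision 0, not an error", {
  m <- classification_metrics(cset(c("A", "B"), c("A", "A")))
  expect_equal(m$per_class$precision[m$per_class$class == "B"], 0)
})

test_that("grouping to a coarser rank collapses confusion correctly", {
  taxonomy <- data.frame(
    species = c("s1", "s2", "s3"), genus = c("g1", "g2", "g3"),
    family = c("f1", "f1", "f2"), order = c("O1", "O1", "O2"),
    stringsAsFactors = FALSE
  )
  truth <- c("s1", "s1", "s2", "s3")
  hat <- c("s2", "s1", "s1", "s3")   # s1/s2 confusion is within O1
  m_order <- group_confusion(cset(truth, hat), taxonomy, "order")
  expect_equal(unname(m_order$weighted["f1"]), 1)
  m_sp <- group_confusion(cset(truth, hat), taxonomy, "species")
  expect_equal(m_sp$weighted, classification_metrics(cset(truth, hat))$weighted)
  # hand-summed 2-order matrix
  expect_equal(unname(m_order$confusion_pct["O1", "O1"]), 100)
  expect_error(group_confusion(cset("sX", "s1"), taxonomy, "order"),
               "missing")
})

test_that("fold combining enforces exactly-once specimen coverage", {
  f1 <- pset(c(1, 2), c(1, 2), ids = c("A", "B"))
  f2 <- pset(3, 3, ids = "C")
  combined <- combine_folds(list(f1, f2), expected_specimens = c("A", "B", "C"))
  expect_equal(nrow(combined), 3)
  expect_error(combine_folds(list(f1, f1)), "more than one fold")
  expect_error(combine_folds(list(f1), expected_specimens = c("A", "B", "C")),
               "coverage")
  # combined metrics equal metrics of the concatenated rows
  m <- regression_metrics(combined)$frame
  o <- oracle_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(m[names(o)]), unname(o), tolerance = 1e-12)
})

test_that("metrics are invariant to row permutation", {
  set.seed(12)
  y <- stats::rlnorm(20); p <- y * exp(stats::rnorm(20, 0, 0.3))
  a <- regression_metrics(pset(p, y))$frame
  ix <- sample(20)
  b <- regression_metrics(pset(p[ix], y[ix]))$frame
  expect_equal(a, b, tolerance = 1e-12)
})
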