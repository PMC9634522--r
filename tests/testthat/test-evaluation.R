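rel_df <- function(...) {
  rows <- list(...)
  data.frame(doc_id = vapply(rows, `[[`, character(1), 1L),
             e1 = vapply(rows, `[[`, character(1), 2L),
             e2 = vapply(rows, `[[`, character(1), 3L),
             rtype = vapply(rows, `[[`, character(1), 4L))
}

test_that("perfect predictions score 100 everywhere", {
  gold <- rel_df(c("d1", "T1", "T2", "Lives_In"),
                 c("d1", "T3", "T4", "Exhibits"))
  rep <- score(gold, gold)
  expect_equal(rep$overall$precision, 100)
  expect_equal(rep$overall$recall, 100)
  expect_equal(rep$overall$f1, 100)
  expect_equal(rep$by_category$f1, c(100, 100))
})

test_that("matching is unordered in the entity pair and strict in category", {
  gold <- rel_df(c("d1", "T1", "T2", "Lives_In"))
  rep <- score(rel_df(c("d1", "T2", "T1", "Lives_In")), gold)
  expect_equal(rep$overall$tp, 1L)
  rep2 <- score(rel_df(c("d1", "T1", "T2", "Exhibits")), gold)
  expect_equal(rep2$overall$tp, 0L)
  expect_equal(rep2$overall$fp, 1L)
  expect_equal(rep2$overall$fn, 1L)
})

test_that("duplicate predictions collapse with a warning", {
  gold <- rel_df(c("d1", "T1", "T2", "Lives_In"))
  expect_warning(
    rep <- score(rel_df(c("d1", "T1", "T2", "Lives_In"),
                        c("d1", "T2", "T1", "Lives_In")), gold),
    "duplicate")
  expect_equal(rep$overall$tp, 1L)
  expect_equal(rep$overall$fp, 0L)
})

test_that("F1 is the harmonic mean of printed precision/recall pairs", {
  # published score-table rows; P and R are printed at two decimals, so the
  # recomputed harmonic mean can differ from the printed F1 in the last digit
  expect_equal(f1_score(69.50, 62.05), 65.56, tolerance = 0.011 / 65)
  expect_equal(f1_score(69.38, 56.64), 62.36, tolerance = 0.011 / 62)
  expect_equal(f1_score(69.75, 68.27), 69.00, tolerance = 0.011 / 69)
  expect_equal(f1_score(69.77, 77.92), 73.62, tolerance = 0.011 / 73)
  expect_equal(f1_score(70.18, 86.96), 77.67, tolerance = 0.011 / 77)
  expect_equal(round_half_up(f1_score(69.50, 62.05)), 65.56)
  expect_equal(f1_score(0, 0), 0)
})

test_that("micro counts equal a brute-force set-intersection oracle", {
  withr::with_seed(21, {
    for (rep in 1:15) {
      cats <- c("A", "B", "C")
      mk <- function(n) {
        data.frame(doc_id = sample(c("d1", "d2"), n, TRUE),
                   e1 = sample(sprintf("T%d", 1:4), n, TRUE),
                   e2 = sample(sprintf("T%d", 5:8), n, TRUE),
                   rtype = sample(cats, n, TRUE))
      }
      pred <- unique(mk(8)); gold <- unique(mk(8))
      rep_ <- suppressWarnings(score(pred, gold))
      key <- function(x) paste(x$doc_id, pmin(x$e1, x$e2), pmax(x$e1, x$e2),
                               x$rtype)
      tp <- length(intersect(key(pred), key(gold)))
      expect_equal(rep_$overall$tp, tp)
      expect_equal(rep_$overall$fp, length(unique(key(pred))) - tp)
      expect_equal(rep_$overall$fn, length(unique(key(gold))) - tp)
      # micro-averaging conservation over per-category rows
      expect_equal(sum(rep_$by_category$tp), rep_$overall$tp)
      expect_equal(sum(rep_$by_category$fp), rep_$overall$fp)
      expect_equal(sum(rep_$by_category$fn), rep_$overall$fn)
      # swapping predicted and gold swaps precision and recall
      swapped <- suppressWarnings(score(gold, pred))
      expect_equal(swapped$overall$precision, rep_$overall$recall)
      expect_equal(swapped$overall$recall, rep_$overall$precision)
    }
  })
})

test_that("intersentence gold counts against recall but not intrasentence recall", {
  gold <- rel_df(c("d1", "T1", "T2", "Lives_In"),
                 c("d1", "T3", "T4", "Lives_In"))
  gold$intra <- c(TRUE, FALSE)
  rep <- score(rel_df(c("d1", "T1", "T2", "Lives_In")), gold)
  expect_equal(rep$overall$recall, 50)
  expect_equal(rep$intra$recall, 100)
  expect_gt(rep$intra$f1, rep$overall$f1)
})

test_that("cluster pooling conserves counts and matches hand computation", {
  gold <- rel_df(c("d1", "T1", "T2", "A"), c("d1", "T3", "T4", "A"),
                 c("d1", "T5", "T6", "B"), c("d2", "T1", "T2", "C"))
  pred <- rel_df(c("d1", "T1", "T2", "A"),   # tp for A
                 c("d1", "T5", "T6", "C"),   # fp for C, fn for B
                 c("d2", "T1", "T2", "C"))   # tp for C
  rep <- score(pred, gold)

  one <- cluster_report(rep, c(A = "all", B = "all", C = "all"))
  expect_equal(one$tp, rep$overall$tp)
  expect_equal(one$f1, rep$overall$f1)

  two <- cluster_report(rep, c(A = "x", B = "y", C = "y"))
  expect_equal(sum(two$tp), rep$overall$tp)
  x <- two[two$cluster == "x", ]
  # cluster x = category A alone: tp 1, fp 0, fn 1 -> P 100, R 50, F1 66.67
  expect_equal(x$precision, 100)
  expect_equal(x$recall, 50)
  expect_equal(round_half_up(x$f1), 66.67)
  y <- two[two$cluster == "y", ]
  # cluster y pools B and C: tp 1, fp 1, fn 1 -> P 50, R 50, F1 50
  expect_equal(y$tp, 1L)
  expect_equal(y$fp, 1L)
  expect_equal(y$fn, 1L)
  expect_equal(y$f1, 50)

  expect_error(cluster_report(rep, c(A = "x", B = "y")), "C")
})

test_that("the shipped cluster mapping file loads and covers its categories", {
  path <- system.file("extdata", "seedev_clusters.yaml", package = "biorel")
  gold <- rel_df(c("d1", "T1", "T2", "Binds_To"),
                 c("d1", "T3", "T4", "Regulates_Process"))
  rep <- score(gold, gold)
  cl <- cluster_report(rep, path)
  expect_setequal(cl$cluster, c("interaction", "regulation"))
  expect_equal(cl$f1, c(100, 100))
})

test_that("gold relations inherit the intrasentence flag from parses", {
  cc <- cached_instances()
  gold <- gold_relations(cc$corpus$documents)
  expect_true(all(c("doc_id", "e1", "e2", "rtype", "intra") %in% names(gold)))
  expect_equal(sum(!gold$intra), cc$corpus$manifest$n_intersentence)
})

test_that("predictions_to_relations drops the nonrelation label", {
  cc <- cached_instances()
  inst <- cc$inst[1:4]
  labs <- c("Lives_In", "none", "Exhibits", "none")
  rel <- predictions_to_relations(inst, labs)
  expect_equal(nrow(rel), 2L)
  expect_equal(rel$rtype, c("Lives_In", "Exhibits"))
  expect_equal(rel$e1[1], inst[[1]]$e1_id)
})
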