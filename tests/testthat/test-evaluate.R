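test_that("the five metrics reproduce the worked confusion tables", {
  m <- metrics_from_counts(tp = 128, fn = 67, fp = 46, tn = 149)
  expect_equal(round(m$precision, 1), 73.6)
  expect_equal(round(m$recall, 1), 65.6)
  expect_equal(round(m$specificity, 1), 76.4)
  expect_equal(round(m$accuracy, 1), 71.0)
  expect_equal(round(m$f1, 1), 0.7)
  m2 <- metrics_from_counts(tp = 17, fn = 17, fp = 5, tn = 29)
  expect_equal(round(m2$precision, 1), 77.3)
  expect_equal(round(m2$recall, 1), 50.0)
  expect_equal(round(m2$specificity, 1), 85.3)
  expect_equal(round(m2$f1, 1), 0.6)
})

test_that("metric identities hold and undefined terms stay NA", {
  set.seed(42)
  for (i in 1:20) {
    cts <- as.list(sample(0:50, 4, replace = TRUE))
    names(cts) <- c("tp", "fn", "fp", "tn")
    m <- do.call(metrics_from_counts, cts)
    total <- cts$tp + cts$fn + cts$fp + cts$tn
    if (total > 0) {
      expect_equal(m$accuracy, 100 * (cts$tp + cts$tn) / total)
    }
    if (!is.na(m$precision)) {
      # precision plus the false-discovery rate among predicted positives is 1
      expect_equal(m$precision / 100 + cts$fp / (cts$tp + cts$fp), 1)
    }
    if (!is.na(m$f1)) {
      p <- m$precision / 100; r <- m$recall / 100
      expect_equal(m$f1, 2 * p * r / (p + r))
    }
  }
  expect_true(is.na(metrics_from_counts(0, 5, 0, 5)$precision))
  expect_true(is.na(metrics_from_counts(0, 0, 3, 7)$recall))
})

test_that("positive-set extraction takes the 300 nt upstream, strand-aware", {
  set.seed(9)
  s <- random_seq(6000)
  rec <- genome_record("g", s)
  regions <- data.frame(start = c(1001L, 3000L), end = c(1500L, 5000L),
                        strand = c("+", "-"))
  pos <- build_positive_set(rec, regions)
  expect_equal(nrow(pos), 2L)
  expect_equal(pos$sequence[1], substr(s, 701, 1000))
  expect_equal(pos$sequence[2], revcomp(substr(s, 5001, 5300)))
  # insufficient context is skipped with a warning
  expect_warning(
    short <- build_positive_set(rec, data.frame(start = 100L, end = 400L,
                                                strand = "+")),
    "skipped")
  expect_equal(nrow(short), 0L)
})

test_that("negative set keeps only divergent intergenic gaps of 200-300 nt", {
  set.seed(10)
  rec <- genome_record("g", random_seq(9000))
  cds <- data.frame(
    record_id = "g",
    start = c(500L, 1251L, 2500L, 3100L, 4000L, 4700L, 6000L, 6199L,
              7000L, 7302L),
    end   = c(1000L, 2000L, 3000L, 3900L, 4500L, 5600L, 6100L, 6800L,
              7100L, 7900L),
    strand = c("-", "+",   # gap 250: divergent, kept
               "+", "+",   # same orientation: dropped
               "-", "-",   # convergent-side pair: dropped
               "-", "+",   # gap 98: too short
               "-", "+"))  # gap 201: kept
  neg <- build_negative_set(rec, cds)
  expect_equal(neg$start, c(1001L, 7101L))
  expect_equal(neg$length, c(250L, 201L))
  expect_equal(neg$sequence[1], substr(rec$sequence, 1001, 1250))
})

test_that("balanced evaluation is reproducible and counts one TP per sequence", {
  set.seed(3)
  pos <- replicate(25, random_seq(120))
  neg <- replicate(15, random_seq(120))
  # deterministic toy predictor: fires iff the sequence contains "ACGTAC"
  toy <- function(s) if (grepl("ACGTAC", s)) data.frame(x = 1) else data.frame(x = numeric(0))
  r1 <- evaluate_balanced(pos, neg, toy, n_repeats = 5, seed = 7)
  r2 <- evaluate_balanced(pos, neg, toy, n_repeats = 5, seed = 7)
  expect_identical(r1$per_repeat, r2$per_repeat)
  # balanced subsampling: each repeat evaluates equal-size sets
  expect_true(all(r1$per_repeat$tp + r1$per_repeat$fn == 15))
  expect_true(all(r1$per_repeat$fp + r1$per_repeat$tn == 15))
  # a predictor that always predicts
  always <- function(s) data.frame(x = 1)
  ra <- evaluate_balanced(pos, neg, always, n_repeats = 2, seed = 1)
  expect_equal(ra$recall, 100)
  expect_equal(ra$specificity, 0)
  expect_error(evaluate_balanced(character(0), neg, toy), "non-empty")
  fails <- function(s) stop("boom")
  expect_error(evaluate_balanced(pos, neg, fails), "positive sequence 1")
})

test_that("synthetic benchmark metrics are a deterministic function of the seed", {
  run_once <- function() {
    set.seed(500)
    mk_pos <- function() {
      rut <- make_rut_window(2, 12)
      hp <- make_hairpin(6, 4)
      paste0(random_seq(100, 50), rut,
             paste(sample(c("A", "T"), 20, TRUE), collapse = ""), hp,
             random_seq(300 - 100 - 78 - 20 - nchar(hp), 50))
    }
    pos <- replicate(20, mk_pos())
    neg <- replicate(20, random_seq(300, 50))
    evaluate_balanced(pos, neg, make_scan_predictor(genome_gc = 50),
                      n_repeats = 2, seed = 11)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_equal(r1$recall, 100)   # strong planted signals are always recovered
})

test_that("coverage validation applies the expression gate and drop ratio", {
  pred <- data.frame(
    record_id = "g", strand = c("+", "+", "+", "+", "-"),
    rut_start = c(101L, 501L, 901L, 1301L, 1701L),
    rut_end = c(178L, 578L, 978L, 1378L, 1778L),
    score = 8)
  v <- rep(30, 2000)
  v[178 + 150] <- 10            # prediction 1: ratio 3.0 -> validated
  v[501] <- 9                   # prediction 2: below the >= 10 gate
  v[901] <- 12; v[978 + 150] <- 10    # prediction 3: ratio 1.2 -> not validated
  v[1378 + 150] <- 0            # prediction 4: zero downstream -> Inf, validated
  v[1701 - 150] <- 15           # prediction 5 (minus strand): 30/15 = 2
  out <- validate_with_coverage(pred, list(g = v))
  expect_equal(out$read_ratio[1], 3)
  expect_true(out$validated[1])
  expect_false(out$expressed[2])
  expect_false(out$validated[2])
  expect_equal(out$read_ratio[3], 1.2)
  expect_false(out$validated[3])
  expect_identical(out$read_ratio[4], Inf)
  expect_true(out$validated[4])
  expect_equal(out$read_ratio[5], 2)
  expect_true(out$validated[5])
  # percentage is over expressed predictions only: 3 of 4
  expect_equal(attr(out, "percent_validated"), 75)
  expect_error(validate_with_coverage(pred, list(other = v)), "no coverage")
  # downstream point beyond the record is excluded, not counted
  pred_edge <- data.frame(record_id = "g", strand = "+", rut_start = 1901L,
                          rut_end = 1978L, score = 8)
  expect_message(out_edge <- validate_with_coverage(pred_edge, list(g = v)),
                 "excluded")
  expect_true(out_edge$excluded[1])
})

test_that("overlap counting uses the 50-nt edge-gap rule", {
  a <- data.frame(record_id = "g", start = 101L, end = 150L)
  b1 <- data.frame(record_id = "g", start = 181L, end = 200L)  # gap 30
  b2 <- data.frame(record_id = "g", start = 251L, end = 300L)  # gap 100
  expect_equal(overlap_count(a, b1)$count, 1L)
  expect_equal(overlap_count(a, b2)$count, 0L)
  expect_equal(overlap_count(a, rbind(b1, b2))$percent, 50)
  # intersecting intervals have gap 0
  expect_equal(overlap_count(a, data.frame(record_id = "g", start = 120L,
                                           end = 220L))$count, 1L)
  set.seed(606)
  for (i in 1:10) {
    mk <- function(n) {
      st <- sample(1:5000, n)
      data.frame(record_id = sample(c("g1", "g2"), n, TRUE),
                 start = st, end = st + sample(20:80, n, TRUE))
    }
    a <- mk(15); b <- mk(25)
    expect_equal(overlap_count(a, b)$count, oracle_overlap_count(a, b))
  }
})
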